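# Directed information-flow metrics between population signals:
# z-scoring, zero-phase band-pass filtering, Hilbert instantaneous
# phase, dPLI / PLI, and the band sweep with one-sample tests against
# the no-lead value 0.5.

#' Z-score a population signal
#'
#' @param x Numeric vector (e.g. a PSTH) with nonzero variance.
#' @return Zero-mean, unit-SD numeric vector.
#' @export
zscore_signal <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant (zero-variance) signal")
  (x - mean(x)) / s
}

#' Zero-phase Butterworth band-pass filter
#'
#' A Butterworth filter of the given order applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion -- essential when
#' the filtered signals feed phase-lead metrics.
#'
#' @param x Numeric signal.
#' @param band Length-2 numeric `[f_lo, f_hi]` (Hz), inside
#'   `(0, fs/2)`.
#' @param fs Sampling rate (Hz), default 500 (2 ms bins).
#' @param order Filter order (default 4).
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_filter <- function(x, band, fs = 500, order = 4) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            band[2] < fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, as.numeric(x))
  if (any(!is.finite(y)))
    stop("band-pass filter unstable for band [", band[1], ", ", band[2],
         "] Hz at order ", order,
         "; widen the band or reduce the filter order")
  y
}

# analytic signal via the frequency-domain Hilbert transformer
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Builds the analytic signal (the discrete Hilbert transform supplies
#' the imaginary part) and extracts the quadrant-resolved instantaneous
#' phase and amplitude envelope. The first and last `edge_frac` of the
#' samples are flagged for exclusion from downstream averaging, since
#' the transform is unreliable near the edges.
#'
#' @param x Numeric signal (typically z-scored and band-passed).
#' @param fs Sampling rate (Hz).
#' @param edge_frac Fraction of samples flagged at each edge (default
#'   0.05).
#' @return An object of class `phase_series`: list with `phase`
#'   (radians, in (-pi, pi]), `amplitude`, `fs`, and `interior`
#'   (logical mask of non-edge samples).
#' @export
hilbert_phase <- function(x, fs = 500, edge_frac = 0.05) {
  z <- analytic_signal(x)
  n <- length(z)
  n_edge <- floor(edge_frac * n)
  interior <- rep(TRUE, n)
  if (n_edge > 0) {
    interior[seq_len(n_edge)] <- FALSE
    interior[seq(n - n_edge + 1L, n)] <- FALSE
  }
  structure(list(phase = Arg(z), amplitude = Mod(z), fs = fs,
                 interior = interior),
            class = "phase_series")
}

# wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

phase_diff <- function(phase_a, phase_b) {
  pa <- if (inherits(phase_a, "phase_series")) phase_a$phase else as.numeric(phase_a)
  pb <- if (inherits(phase_b, "phase_series")) phase_b$phase else as.numeric(phase_b)
  if (length(pa) != length(pb)) stop("phase series lengths differ")
  keep <- rep(TRUE, length(pa))
  if (inherits(phase_a, "phase_series")) keep <- keep & phase_a$interior
  if (inherits(phase_b, "phase_series")) keep <- keep & phase_b$interior
  wrap_phase(pa - pb)[keep]
}

#' Directed phase lag index
#'
#' `dPLI = mean_t H(dphi(t))` with `dphi = phase_a - phase_b` wrapped to
#' `(-pi, pi]` and the Heaviside convention `H(0) = 0.5`. A value above
#' 0.5 means signal `a` leads signal `b`; 0.5 means no consistent lead.
#' Edge-flagged samples of `phase_series` inputs are excluded.
#'
#' @param phase_a,phase_b `phase_series` objects (or plain phase
#'   vectors) of equal length. In the E/I experiments `a` is the
#'   interneuron population and `b` the Pyr population, so dPLI > 0.5
#'   indicates the interneurons lead.
#' @return A value in [0, 1].
#' @export
dpli <- function(phase_a, phase_b) {
  d <- phase_diff(phase_a, phase_b)
  n_pos <- sum(d > 0)
  n_zero <- sum(d == 0)
  (n_pos + 0.5 * n_zero) / length(d)
}

#' Phase lag index
#'
#' `PLI = |mean_t sign(dphi(t))|` with `sign(0) = 0`. Zero indicates no
#' consistent nonzero phase lag; one indicates perfect locking at a
#' constant nonzero lag. Satisfies `PLI = 2 * |0.5 - dPLI|` exactly
#' under the `H(0) = 0.5` / `sign(0) = 0` conventions.
#'
#' @inheritParams dpli
#' @return A value in [0, 1].
#' @export
pli <- function(phase_a, phase_b) {
  d <- phase_diff(phase_a, phase_b)
  abs(sum(d > 0) - sum(d < 0)) / length(d)
}

#' Contiguous frequency bands for the flow sweep
#'
#' @param lo,hi Sweep range (Hz), default 10-80.
#' @param step Band step (Hz), default 5.
#' @param width Band width (Hz); defaults to `step` (contiguous
#'   windows). `width = 10, step = 10` gives the coarser variant.
#' @return A list of length-2 numeric vectors.
#' @export
flow_bands <- function(lo = 10, hi = 80, step = 5, width = step) {
  starts <- seq(lo, hi - width, by = step)
  lapply(starts, function(s) c(s, s + width))
}

#' Per-band dPLI/PLI sweep over trials
#'
#' For each frequency band and each trial, both PSTHs are z-scored,
#' band-pass filtered (zero-phase Butterworth), Hilbert-transformed, and
#' the trial's dPLI and PLI are computed from the wrapped phase
#' difference (interneuron minus Pyr) with edge samples excluded. Per
#' band, a two-sided one-sample t test of the trial dPLI values against
#' 0.5 asks whether one population consistently leads.
#'
#' @param psth_a,psth_b Lists of per-trial `psth` objects (or numeric
#'   vectors), equal lengths; `a` is the leading-candidate (interneuron)
#'   signal, `b` the reference (Pyr) signal.
#' @param bands List of bands as from [flow_bands()].
#' @param fs Sampling rate (Hz); taken from the PSTH attributes when
#'   present.
#' @param order Band-pass filter order.
#' @return An object of class `flow_metrics`: list with `bands`,
#'   `dpli` and `pli` (trials x bands matrices), and `summary`
#'   (data.frame `band_lo`, `band_hi`, `mean_dpli`, `mean_pli`,
#'   `t_statistic`, `p_value`, `n_trials`).
#' @export
band_sweep <- function(psth_a, psth_b, bands = flow_bands(), fs = NULL,
                       order = 4) {
  if (!is.list(psth_a)) psth_a <- list(psth_a)
  if (!is.list(psth_b)) psth_b <- list(psth_b)
  stopifnot(length(psth_a) == length(psth_b))
  n_trials <- length(psth_a)
  if (is.null(fs)) {
    fs <- attr(psth_a[[1]], "fs")
    if (is.null(fs)) fs <- 500
  }
  nb <- length(bands)
  dpli_m <- matrix(NA_real_, n_trials, nb)
  pli_m <- matrix(NA_real_, n_trials, nb)
  for (tr in seq_len(n_trials)) {
    za <- zscore_signal(psth_a[[tr]])
    zb <- zscore_signal(psth_b[[tr]])
    for (bi in seq_len(nb)) {
      b <- bands[[bi]]
      ha <- hilbert_phase(bandpass_filter(za, b, fs, order), fs)
      hb <- hilbert_phase(bandpass_filter(zb, b, fs, order), fs)
      dpli_m[tr, bi] <- dpli(ha, hb)
      pli_m[tr, bi] <- pli(ha, hb)
    }
  }
  summ <- data.frame(
    band_lo = vapply(bands, `[`, 0, 1),
    band_hi = vapply(bands, `[`, 0, 2),
    mean_dpli = colMeans(dpli_m),
    mean_pli = colMeans(pli_m),
    t_statistic = NA_real_,
    p_value = NA_real_,
    n_trials = n_trials
  )
  if (n_trials >= 2) {
    for (bi in seq_len(nb)) {
      x <- dpli_m[, bi]
      if (stats::sd(x) > 0) {
        tt <- stats::t.test(x, mu = 0.5)
        summ$t_statistic[bi] <- unname(tt$statistic)
        summ$p_value[bi] <- tt$p.value
      }
    }
  }
  structure(list(bands = bands, dpli = dpli_m, pli = pli_m, summary = summ),
            class = "flow_metrics")
}

#' @export
print.flow_metrics <- function(x, ...) {
  cat("flow_metrics over", nrow(x$dpli), "trial(s),",
      length(x$bands), "band(s)\n")
  df <- x$summary
  df$sig <- ifelse(is.na(df$p_value), "",
                   ifelse(df$p_value < 0.01, "**",
                          ifelse(df$p_value < 0.05, "*",
                                 ifelse(df$p_value < 0.1, "-", ""))))
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}
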