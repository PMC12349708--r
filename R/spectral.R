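# PSTH construction, Gaussian smoothing, trial-averaged power spectra,
# cross-condition band normalization, and aperiodic/periodic spectral
# parameterization.

#' Peristimulus time histogram of one neuron class
#'
#' Counts class-member spikes in contiguous half-open bins
#' `[lo + b*w, lo + (b+1)*w)` over the analysis window. Raw counts are
#' used (not rates): the histogram is the population signal fed to the
#' spectral and phase analyses.
#'
#' @param rec A `spike_record`.
#' @param class Neuron class (`"Pyr"`, `"PV"`, `"SOM"`, `"VIP"`).
#' @param bin_width Bin width (ms), default 2.
#' @param window Length-2 analysis window (ms); must be an exact
#'   multiple of `bin_width` long. Defaults to `[500, duration]`.
#' @return An object of class `psth`: numeric vector of counts with
#'   attributes `bin_width`, `window`, `class` and `fs` (sampling rate
#'   of the binned signal, Hz).
#' @export
compute_psth <- function(rec, class, bin_width = 2, window = c(500, rec$duration)) {
  class <- match.arg(class, neuron_classes())
  stopifnot(window[1] >= 0, window[2] <= rec$duration, window[1] < window[2])
  len <- window[2] - window[1]
  n_bins <- len / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("bin_width must divide the window length exactly")
  n_bins <- as.integer(round(n_bins))
  code <- match(class, neuron_classes())
  tt <- rec$spikes$time[rec$class_of[rec$spikes$neuron_id] == code]
  tt <- tt[tt >= window[1] & tt < window[2]]
  counts <- tabulate(pmin(n_bins, floor((tt - window[1]) / bin_width) + 1L),
                     nbins = n_bins)
  structure(as.numeric(counts), bin_width = bin_width, window = window,
            class_label = class, fs = 1000 / bin_width, class = "psth")
}

new_psth_like <- function(x, template) {
  structure(as.numeric(x),
            bin_width = attr(template, "bin_width"),
            window = attr(template, "window"),
            class_label = attr(template, "class_label"),
            fs = attr(template, "fs"),
            class = "psth")
}

#' Gaussian smoothing of a PSTH
#'
#' Discrete convolution with a unit-sum Gaussian kernel of the given
#' variance (in ms^2), truncated at +/- 4 SD and renormalized; the
#' signal is zero-padded at the edges. Smoothing attenuates bin-scale
#' periodicity before the Fourier transform.
#'
#' @param p A `psth` (or plain numeric vector).
#' @param gaussian_var Kernel variance (ms^2), default 5.
#' @return Smoothed `psth` of the same length.
#' @export
smooth_psth <- function(p, gaussian_var = 5) {
  stopifnot(gaussian_var > 0)
  bw <- attr(p, "bin_width")
  if (is.null(bw)) bw <- 1
  sd_bins <- sqrt(gaussian_var) / bw
  half <- max(1L, ceiling(4 * sd_bins))
  kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
  kern <- kern / sum(kern)
  x <- as.numeric(p)
  n <- length(x)
  padded <- c(numeric(half), x, numeric(half))
  sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
  out <- as.numeric(sm[(half + 1):(half + n)])
  if (inherits(p, "psth")) new_psth_like(out, p) else out
}

#' One-sided power spectrum of PSTH signals
#'
#' Each trial's signal has its mean removed and is decomposed with the
#' FFT; power is the squared modulus of the (two-sided-normalized)
#' amplitude at each non-negative frequency. When several trials are
#' supplied, per-trial spectra are averaged arithmetically.
#'
#' @param p A `psth`/numeric vector, or a list of them (one per trial,
#'   equal lengths).
#' @return An object of class `power_spectrum`: list with `freq` (Hz),
#'   `power`, and `n_trials`.
#' @export
power_spectrum <- function(p) {
  trials <- if (is.list(p) && !inherits(p, "psth")) p else list(p)
  n <- length(as.numeric(trials[[1]]))
  fs <- attr(trials[[1]], "fs")
  if (is.null(fs)) fs <- 500
  stopifnot(all(vapply(trials, function(x) length(as.numeric(x)), 0L) == n))
  n_keep <- n %/% 2 + 1L
  acc <- numeric(n_keep)
  for (x in trials) {
    x <- as.numeric(x)
    x <- x - mean(x)
    sp <- Mod(stats::fft(x) / n)^2
    acc <- acc + sp[seq_len(n_keep)]
  }
  structure(list(freq = (seq_len(n_keep) - 1) * fs / n,
                 power = acc / length(trials),
                 n_trials = length(trials)),
            class = "power_spectrum")
}

#' Min-max normalization of spectra across conditions, per band
#'
#' For each frequency band, the power values of all conditions at all
#' in-band frequency bins are pooled and affinely mapped so the pooled
#' minimum is 0 and the pooled maximum is 1 (per-panel normalization,
#' matching how cross-condition band panels are displayed). A per-bin
#' mode (each frequency bin normalized over conditions separately) is
#' available.
#'
#' @param spectra Named list of `power_spectrum` objects on identical
#'   frequency grids (one per condition; at least two).
#' @param bands List of length-2 numeric vectors `[f_lo, f_hi]` (Hz).
#' @param per_bin Logical; use per-frequency-bin normalization instead
#'   of the per-panel pooled normalization.
#' @return A list, one element per band, each a list with `band`,
#'   `freq` and a matrix `normalized` (conditions x frequency bins) in
#'   [0, 1].
#' @export
normalize_across_conditions <- function(spectra, bands, per_bin = FALSE) {
  stopifnot(length(spectra) >= 2)
  f <- spectra[[1]]$freq
  for (s in spectra) stopifnot(isTRUE(all.equal(s$freq, f)))
  lapply(bands, function(b) {
    sel <- f >= b[1] & f <= b[2]
    m <- do.call(rbind, lapply(spectra, function(s) s$power[sel]))
    rownames(m) <- names(spectra)
    if (per_bin) {
      norm <- apply(m, 2, function(col) {
        rng <- range(col)
        if (diff(rng) == 0) rep(0.5, length(col)) else (col - rng[1]) / diff(rng)
      })
      if (is.null(dim(norm))) norm <- matrix(norm, nrow = nrow(m))
    } else {
      rng <- range(m)
      if (diff(rng) == 0) {
        warning("degenerate band ", b[1], "-", b[2],
                " Hz: all powers equal; returning 0.5")
        norm <- matrix(0.5, nrow(m), ncol(m))
      } else {
        norm <- (m - rng[1]) / diff(rng)
      }
    }
    dimnames(norm) <- list(names(spectra), NULL)
    list(band = b, freq = f[sel], normalized = norm)
  })
}

#' Fit the aperiodic component and oscillatory peaks of a spectrum
#'
#' A simplified spectral parameterization in the spirit of the
#' specparam/FOOOF approach: (1) robust log-log linear fit of the
#' aperiodic (1/f-like) background `log10 P = b - chi * log10 f`;
#' (2) up to `max_peaks` Gaussian peaks fitted iteratively to the
#' largest positive residual (in log10-power) and subtracted; (3) the
#' aperiodic component refitted on the peak-removed spectrum. The
#' robust fit is a two-pass ordinary least squares in which bins with
#' large positive residuals (oscillatory peaks) are down-weighted out
#' of the second pass.
#'
#' @param spec A `power_spectrum`.
#' @param max_peaks Maximum number of Gaussian peaks (default 3).
#' @param fit_range Frequency range to fit (Hz), default `c(3, 100)`.
#' @param min_height Minimum residual height (log10-power units) for a
#'   peak to be accepted, default 0.05.
#' @return An object of class `peak_set`: list with `peaks` (data.frame
#'   `center_freq`, `relative_strength`, `bandwidth`) sorted by center
#'   frequency, and `aperiodic` (named vector `offset`, `exponent`).
#' @export
fit_aperiodic_and_peaks <- function(spec, max_peaks = 3, fit_range = c(3, 100),
                                    min_height = 0.05) {
  sel <- spec$freq >= fit_range[1] & spec$freq <= fit_range[2] & spec$freq > 0
  f <- spec$freq[sel]
  p <- spec$power[sel]
  floor_p <- max(p) * 1e-12
  p <- pmax(p, floor_p)
  lf <- log10(f)
  lp <- log10(p)

  fit_aperiodic <- function(y) {
    fit1 <- stats::lm.fit(cbind(1, lf), y)
    r <- fit1$residuals
    # drop the peaky upper tail of residuals, keep the bulk
    keep <- r <= stats::quantile(r, 0.66)
    fit2 <- stats::lm.fit(cbind(1, lf[keep]), y[keep])
    fit2$coefficients
  }

  ap <- fit_aperiodic(lp)
  resid <- lp - (ap[1] + ap[2] * lf)
  gauss <- function(f0, h, w) h * exp(-(f - f0)^2 / (2 * w^2))
  peaks <- list()
  model_peaks <- numeric(length(f))
  for (k in seq_len(max_peaks)) {
    i0 <- which.max(resid)
    h0 <- resid[i0]
    if (!is.finite(h0) || h0 < min_height) break
    f0 <- f[i0]
    # crude width from half-height crossing
    above <- resid > h0 / 2
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    j <- which(run$values & starts <= i0 & ends >= i0)
    w0 <- max(1, (f[ends[j]] - f[starts[j]]) / 2.355)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ h * exp(-(f - f0)^2 / (2 * w^2)),
        data = list(r = resid, f = f),
        start = list(h = h0, f0 = f0, w = w0),
        lower = c(h = min_height / 2, f0 = max(min(f), f0 - 2 * w0), w = 0.5),
        upper = c(h = 2.5 * h0, f0 = min(max(f), f0 + 2 * w0), w = 15),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), error = function(e) NULL)
    if (is.null(fit)) {
      cf <- c(h = h0, f0 = f0, w = w0)
    } else {
      cf <- stats::coef(fit)
    }
    g <- gauss(cf[["f0"]], cf[["h"]], cf[["w"]])
    model_peaks <- model_peaks + g
    resid <- resid - g
    peaks[[k]] <- data.frame(center_freq = cf[["f0"]],
                             relative_strength = cf[["h"]],
                             bandwidth = 2.355 * cf[["w"]])
  }
  # refit aperiodic with peaks removed
  ap <- fit_aperiodic(lp - model_peaks)
  pk <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(center_freq = numeric(0), relative_strength = numeric(0),
               bandwidth = numeric(0))
  pk <- pk[order(pk$center_freq), , drop = FALSE]
  rownames(pk) <- NULL
  structure(list(peaks = pk,
                 aperiodic = c(offset = unname(ap[1]),
                               exponent = unname(-ap[2]))),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: aperiodic offset %.3f, exponent %.3f; %d peak(s)\n",
              x$aperiodic[["offset"]], x$aperiodic[["exponent"]],
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks, digits = 3)
  invisible(x)
}
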