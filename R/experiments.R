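# Experiment orchestration: the E/I-ratio grid (PV- and SOM-conversion
# series), deterministic seed derivation, per-condition simulation and
# analysis, and the flow-reversal report.

#' Derive a reproducible sub-seed
#'
#' Counter-based hash mixing a master seed with string/integer keys,
#' yielding a seed in [1, 2^31 - 2]. Adding trials or conditions never
#' changes the seeds of earlier ones.
#'
#' @param master Integer master seed.
#' @param ... Keys (character or integer) identifying the consumer,
#'   e.g. `derive_seed(1, "pv_conversion", 4.5, "trial", 7)`.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (key in list(...)) {
    bytes <- utf8ToInt(paste0(as.character(key), "|"))
    for (b in bytes) h <- (h * 69069 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

condition_label <- function(series, ratio) {
  sprintf("%s_%.1f", sub("_conversion", "", series), ratio)
}

#' Plan an E/I-ratio experiment grid
#'
#' @param series Character vector from `c("pv_conversion",
#'   "som_conversion")`: which interneuron subtype is traded against Pyr
#'   neurons.
#' @param ratios E/I ratios to simulate; the control ratio 3.5 is the
#'   normalization anchor and is added if missing.
#' @param config A [simulation_config()] (trial length, dt, number of
#'   trials, scale).
#' @param master_seed Master seed from which all condition and trial
#'   seeds are derived.
#' @param bands Frequency bands for the dPLI/PLI sweep, default
#'   [flow_bands()] (10-80 Hz in 5 Hz windows).
#' @param norm_bands Frequency band panels for cross-condition power
#'   normalization (Hz).
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(series = c("pv_conversion", "som_conversion"),
                            ratios = c(3.0, 3.5, 4.0, 4.5),
                            config = simulation_config(),
                            master_seed = 1L,
                            bands = flow_bands(),
                            norm_bands = list(c(10, 20), c(20, 35),
                                              c(35, 60), c(60, 100))) {
  series <- match.arg(series, several.ok = TRUE)
  if (!any(vapply(ratios, function(r) isTRUE(all.equal(r, 3.5)), TRUE)))
    ratios <- sort(c(ratios, 3.5))
  structure(list(series = series, ratios = sort(ratios), config = config,
                 master_seed = as.integer(master_seed), bands = bands,
                 norm_bands = norm_bands),
            class = "experiment_plan")
}

#' Simulate and analyze one E/I condition
#'
#' Builds the network for the condition's population sizes (at
#' `config$scale`), runs `config$n_trials` independent trials, and
#' returns per-trial class rates and per-trial PSTHs (2 ms bins over the
#' post-transient window) of the Pyr, PV and SOM populations.
#'
#' @param series `"pv_conversion"` or `"som_conversion"`.
#' @param ratio Target E/I ratio (3.5 denotes the control circuit).
#' @param config A [simulation_config()].
#' @param master_seed Master seed (condition and trial seeds are derived
#'   from it).
#' @param keep_spikes Keep the raw spike records (memory-heavy).
#' @return A list of class `condition_result` with `series`, `ratio`,
#'   `label`, `sizes` (scaled counts), `rates` (trials x classes),
#'   `psth` (list with per-trial `Pyr`, `PV`, `SOM` lists), `window`,
#'   `seeds`, and optionally `records`.
#' @export
simulate_condition <- function(series, ratio, config = simulation_config(),
                               master_seed = 1L, keep_spikes = FALSE) {
  series <- match.arg(series, c("pv_conversion", "som_conversion"))
  varied <- if (series == "pv_conversion") "PV" else "SOM"
  sizes_full <- condition_sizes(ratio, varied)
  sizes <- scale_sizes(sizes_full, config$scale)
  n_ff <- max(1L, as.integer(round(feedforward_input_spec()$n_fibers * config$scale)))
  label <- condition_label(series, ratio)

  net_seed <- derive_seed(master_seed, label, "network")
  net <- build_network(sizes, seed = net_seed, n_ff_fibers = n_ff)
  cnet <- compile_network(net, config$dt)

  window <- c(config$discard, config$duration)
  classes_tracked <- c("Pyr", "PV", "SOM")
  rates <- matrix(NA_real_, config$n_trials, 4,
                  dimnames = list(NULL, neuron_classes()))
  psth <- stats::setNames(
    lapply(classes_tracked, function(cl) vector("list", config$n_trials)),
    classes_tracked)
  records <- if (keep_spikes) vector("list", config$n_trials) else NULL
  seeds <- integer(config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    seeds[tr] <- derive_seed(master_seed, label, "trial", tr)
    rec <- integrate_trial(cnet, config, trial_seed = seeds[tr])
    rates[tr, ] <- compute_rates(rec, window)
    for (cl in classes_tracked)
      psth[[cl]][[tr]] <- compute_psth(rec, cl, bin_width = 2, window = window)
    if (keep_spikes) records[[tr]] <- rec
  }
  out <- list(series = series, ratio = ratio, label = label,
              sizes = sizes, sizes_full = sizes_full,
              rates = rates, psth = psth, window = window,
              config = config, net_seed = net_seed, seeds = seeds)
  if (keep_spikes) out$records <- records
  structure(out, class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat("condition", x$label, "-", nrow(x$rates), "trial(s), sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = " "), "\n")
  cat("mean rates (Hz):",
      paste(sprintf("%s=%.2f", colnames(x$rates), colMeans(x$rates)),
            collapse = " "), "\n")
  invisible(x)
}

# trial-averaged Pyr power spectrum of a condition (Gaussian-smoothed
# PSTHs, per-trial FFT, arithmetic mean across trials)
condition_spectrum <- function(cond, gaussian_var = 5) {
  power_spectrum(lapply(cond$psth$Pyr, smooth_psth, gaussian_var = gaussian_var))
}

#' Run the full experiment grid
#'
#' Simulates every (series, ratio) condition of the plan and assembles
#' the analysis bundle: per-condition mean class rates, trial-averaged
#' Pyr power spectra, cross-condition normalized band panels (per
#' series), aperiodic-removed peak sets, and dPLI/PLI flow metrics from
#' the PV and SOM populations to the Pyr population.
#'
#' @param plan An [experiment_plan()].
#' @param progress Print per-condition progress lines.
#' @return A list of class `result_bundle` with elements `conditions`
#'   (named list of per-condition results, each carrying `spectrum`,
#'   `peaks`, `flow` with `PV` and `SOM` entries), `normalized` (per
#'   series), `plan`, and `provenance`.
#' @export
run_experiment <- function(plan, progress = interactive()) {
  stopifnot(inherits(plan, "experiment_plan"))
  conditions <- list()
  for (series in plan$series) {
    for (ratio in plan$ratios) {
      label <- condition_label(series, ratio)
      if (!is.null(conditions[[label]])) next
      # the control circuit (nominal 3.5) is one and the same condition
      # for both series; simulate it once
      if (isTRUE(all.equal(ratio, 3.5)) &&
          any(grepl("_3\\.5$", names(conditions)))) next
      if (progress) message("simulating ", label, " ...")
      cond <- simulate_condition(series, ratio, plan$config, plan$master_seed)
      cond$spectrum <- condition_spectrum(cond)
      cond$peaks <- fit_aperiodic_and_peaks(cond$spectrum)
      cond$flow <- list(
        PV = band_sweep(cond$psth$PV, cond$psth$Pyr, plan$bands),
        SOM = band_sweep(cond$psth$SOM, cond$psth$Pyr, plan$bands)
      )
      cond$psth <- NULL  # PSTHs are large; analyses above retain what is needed
      conditions[[label]] <- cond
    }
  }
  # control (3.5) is shared: both series' normalization panels include it
  normalized <- list()
  for (series in plan$series) {
    labels <- vapply(plan$ratios, function(r) condition_label(series, r), "")
    labels[vapply(plan$ratios, function(r) isTRUE(all.equal(r, 3.5)), TRUE)] <-
      grep("_3\\.5$", names(conditions), value = TRUE)[1]
    spectra <- lapply(conditions[labels], `[[`, "spectrum")
    names(spectra) <- sprintf("%.1f", plan$ratios)
    normalized[[series]] <- if (length(spectra) >= 2) {
      normalize_across_conditions(spectra, plan$norm_bands)
    }  # cross-condition panels need at least two conditions
  }
  structure(list(
    conditions = conditions,
    normalized = normalized,
    plan = plan,
    provenance = list(master_seed = plan$master_seed,
                      scale = plan$config$scale,
                      n_trials = plan$config$n_trials,
                      duration = plan$config$duration,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "result_bundle")
}

#' Summarize the direction-of-flow reversal between the two series
#'
#' Reports, per frequency band, the mean dPLI from the PV population to
#' the Pyr population for every simulated ratio in each series, and
#' flags a reversal when, at the highest shared ratio, the PV-conversion
#' series shows PV leading (mean dPLI > 0.5) while the SOM-conversion
#' series shows Pyr leading (mean dPLI < 0.5).
#'
#' @param bundle A `result_bundle` from [run_experiment()].
#' @param at_ratio Ratio at which the two series are compared (default
#'   4.5).
#' @param band_range Bands (Hz) over which the comparison is averaged,
#'   default `c(20, 80)` (beta through high gamma).
#' @return A list of class `flow_reversal_report` with `table`
#'   (data.frame series x ratio x band mean dPLI), `comparison` and
#'   `reversal` (logical, NA when a series is missing).
#' @export
summarize_flow_reversal <- function(bundle, at_ratio = 4.5,
                                    band_range = c(20, 80)) {
  stopifnot(inherits(bundle, "result_bundle"))
  rows <- list()
  for (label in names(bundle$conditions)) {
    cond <- bundle$conditions[[label]]
    s <- cond$flow$PV$summary
    rows[[label]] <- data.frame(series = cond$series, ratio = cond$ratio,
                                band_lo = s$band_lo, band_hi = s$band_hi,
                                mean_dpli_pv = s$mean_dpli,
                                p_value = s$p_value)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  series_mean <- function(series) {
    sel <- tab$series == series &
      vapply(tab$ratio, function(r) isTRUE(all.equal(r, at_ratio)), TRUE) &
      tab$band_lo >= band_range[1] & tab$band_hi <= band_range[2]
    if (!any(sel)) return(NA_real_)
    mean(tab$mean_dpli_pv[sel])
  }
  pv_mean <- series_mean("pv_conversion")
  som_mean <- series_mean("som_conversion")
  reversal <- if (is.na(pv_mean) || is.na(som_mean)) NA else
    (pv_mean > 0.5 && som_mean < 0.5)
  structure(list(
    table = tab,
    comparison = data.frame(at_ratio = at_ratio,
                            band_lo = band_range[1], band_hi = band_range[2],
                            pv_series_mean_dpli = pv_mean,
                            som_series_mean_dpli = som_mean),
    reversal = reversal
  ), class = "flow_reversal_report")
}

#' @export
print.flow_reversal_report <- function(x, ...) {
  cat("Flow direction comparison (dPLI PV->Pyr):\n")
  print(x$comparison, digits = 3, row.names = FALSE)
  verdict <- if (is.na(x$reversal)) "incomplete (missing series)"
  else if (x$reversal) "REVERSAL: PV leads in the PV series, Pyr leads in the SOM series"
  else "no reversal"
  cat(verdict, "\n")
  invisible(x)
}

#' Write the bundle's tables to a directory
#'
#' Emits TSV tables (`rates.tsv`, `spectra.tsv`, `flow.tsv`) and a JSON
#' summary (`peaks.json`) with condition and seed provenance.
#'
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rates <- do.call(rbind, lapply(bundle$conditions, function(cond) {
    data.frame(condition = cond$label, trial = seq_len(nrow(cond$rates)),
               cond$rates, check.names = FALSE)
  }))
  utils::write.table(rates, file.path(dir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spectra <- do.call(rbind, lapply(bundle$conditions, function(cond) {
    data.frame(condition = cond$label, freq = cond$spectrum$freq,
               power = cond$spectrum$power)
  }))
  utils::write.table(spectra, file.path(dir, "spectra.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  flow <- do.call(rbind, lapply(bundle$conditions, function(cond) {
    do.call(rbind, lapply(names(cond$flow), function(pair) {
      s <- cond$flow[[pair]]$summary
      data.frame(condition = cond$label, pair = paste0(pair, "->Pyr"), s)
    }))
  }))
  utils::write.table(flow, file.path(dir, "flow.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  peaks <- lapply(bundle$conditions, function(cond) {
    list(condition = cond$label, aperiodic = as.list(cond$peaks$aperiodic),
         peaks = cond$peaks$peaks)
  })
  jsonlite::write_json(list(provenance = bundle$provenance,
                            peaks = unname(peaks)),
                       file.path(dir, "peaks.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
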