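test_that("PSTH bins spikes half-open and conserves counts", {
  rec <- make_record(integer(0), numeric(0))
  p0 <- compute_psth(rec, "Pyr")
  expect_length(p0, 1250)             # (3000 - 500) / 2
  expect_true(all(p0 == 0))
  # half-open binning: 501 and 501.9 in bin 1, 503 in bin 2
  rec3 <- make_record(c(1, 2, 3), c(501, 501.9, 503))
  p3 <- compute_psth(rec3, "Pyr")
  expect_equal(p3[1:3], c(2, 1, 0))
  # count conservation on random in-window spikes
  set.seed(81)
  tt <- runif(500, 500, 3000)
  recr <- make_record(sample(1:4, 500, TRUE), tt)
  pr <- compute_psth(recr, "Pyr")
  n_in <- sum(recr$class_of[recr$spikes$neuron_id] == 1)
  expect_equal(sum(pr), n_in)
  # class selection: PV spikes only counted for PV
  expect_equal(sum(compute_psth(recr, "PV")),
               sum(recr$class_of[recr$spikes$neuron_id] == 2))
  expect_error(compute_psth(rec3, "Pyr", bin_width = 3), "divide")
})

test_that("gaussian smoothing is unit-mass and variance-reducing", {
  z <- make_psth(numeric(400))
  expect_true(all(smooth_psth(z) == 0))
  imp <- make_psth(c(numeric(200), 1, numeric(199)))
  sm <- smooth_psth(imp)
  expect_equal(sum(sm), 1, tolerance = 1e-10)
  expect_equal(which.max(sm), 201)
  # white noise variance shrinks by the kernel sum-of-squares factor
  set.seed(82)
  x <- make_psth(rnorm(20000))
  smx <- smooth_psth(x)
  bw <- 2; sd_bins <- sqrt(5) / bw
  half <- ceiling(4 * sd_bins)
  k <- dnorm(seq(-half, half), sd = sd_bins); k <- k / sum(k)
  expect_equal(var(as.numeric(smx)) / var(as.numeric(x)), sum(k^2),
               tolerance = 0.05)
})

test_that("power spectrum locates pure tones exactly and respects Parseval", {
  n <- 1250; fs <- 500
  t <- (0:(n - 1)) / fs
  const <- make_psth(rep(3, n))
  spc <- power_spectrum(const)
  expect_true(all(spc$power[spc$freq > 0] < 1e-20))
  tone <- make_psth(sin(2 * pi * 40 * t))
  sp <- power_spectrum(tone)
  expect_equal(sp$freq[which.max(sp$power)], 40)
  two <- make_psth(sin(2 * pi * 16 * t) + 0.8 * sin(2 * pi * 40 * t))
  sp2 <- power_spectrum(two)
  near <- function(f0) which(abs(sp2$freq - f0) < 3)
  expect_equal(sp2$freq[near(16)[which.max(sp2$power[near(16)])]], 16)
  expect_equal(sp2$freq[near(40)[which.max(sp2$power[near(40)])]], 40)
  # Parseval: two-sided power sum equals signal variance (up to n/(n-1))
  set.seed(83)
  x <- make_psth(rnorm(n))
  spx <- power_spectrum(x)
  expect_equal(2 * sum(spx$power) - spx$power[1],
               mean((as.numeric(x) - mean(as.numeric(x)))^2),
               tolerance = 0.02)
  # trial averaging is the arithmetic mean of per-trial spectra
  y <- make_psth(rnorm(n))
  spm <- power_spectrum(list(x, y))
  expect_equal(spm$power, (power_spectrum(x)$power + power_spectrum(y)$power) / 2)
  expect_identical(spm$n_trials, 2L)
})

test_that("cross-condition normalization maps panel extremes to 0 and 1", {
  f <- seq(0, 100, by = 0.5)
  mk <- function(p) structure(list(freq = f, power = p, n_trials = 1),
                              class = "power_spectrum")
  a <- mk(rep(1, length(f))); b <- mk(rep(3, length(f)))
  out <- normalize_across_conditions(list(lo = a, hi = b),
                                     bands = list(c(10, 20)))
  expect_true(all(out[[1]]$normalized["lo", ] == 0))
  expect_true(all(out[[1]]$normalized["hi", ] == 1))
  # monotone conditions preserve order; range [0, 1] attained per panel
  set.seed(84)
  sp4 <- lapply(1:4, function(i) mk(10^runif(length(f), -2, 0)))
  names(sp4) <- paste0("c", 1:4)
  out4 <- normalize_across_conditions(sp4, bands = list(c(5, 30), c(30, 90)))
  for (panel in out4) {
    expect_true(all(panel$normalized >= 0 & panel$normalized <= 1))
    expect_equal(min(panel$normalized), 0)
    expect_equal(max(panel$normalized), 1)
  }
  # invariance to common positive rescaling
  sp4b <- lapply(sp4, function(s) mk(s$power * 37.5))
  out4b <- normalize_across_conditions(sp4b, bands = list(c(5, 30)))
  expect_equal(out4b[[1]]$normalized,
               normalize_across_conditions(sp4, bands = list(c(5, 30)))[[1]]$normalized)
  # degenerate panel warns and returns 0.5
  expect_warning(
    outd <- normalize_across_conditions(list(a = a, b = a),
                                        bands = list(c(10, 20))),
    "degenerate")
  expect_true(all(outd[[1]]$normalized == 0.5))
})

test_that("aperiodic fit recovers power-law exponents without spurious peaks", {
  sp <- make_spectrum(exponent = 2, offset = 1)
  ps <- fit_aperiodic_and_peaks(sp)
  expect_identical(nrow(ps$peaks), 0L)
  expect_lt(abs(ps$aperiodic[["exponent"]] - 2) / 2, 0.01)
  sp2 <- make_spectrum(exponent = 0.7, offset = -1)
  expect_lt(abs(fit_aperiodic_and_peaks(sp2)$aperiodic[["exponent"]] - 0.7) / 0.7,
            0.01)
})

test_that("injected spectral bumps are recovered in location and height", {
  sp <- make_spectrum(exponent = 1.5, offset = 0.5,
                      bumps = list(c(25, 0.6, 3)))
  ps <- fit_aperiodic_and_peaks(sp)
  expect_identical(nrow(ps$peaks), 1L)
  expect_lt(abs(ps$peaks$center_freq - 25), 2)
  expect_lt(abs(ps$peaks$relative_strength - 0.6) / 0.6, 0.15)
  sp3 <- make_spectrum(exponent = 2, offset = 1,
                       bumps = list(c(14, 0.5, 2.5), c(27, 0.45, 3),
                                    c(44, 0.4, 4)))
  ps3 <- fit_aperiodic_and_peaks(sp3)
  expect_identical(nrow(ps3$peaks), 3L)
  expect_equal(order(ps3$peaks$center_freq), 1:3)  # sorted by frequency
  expect_true(all(abs(ps3$peaks$center_freq - c(14, 27, 44)) < 2))
})

test_that("peak recovery holds over randomized synthetic spectra", {
  set.seed(85)
  n_cases <- 100
  hits <- 0; total <- 0
  for (i in seq_len(n_cases)) {
    k <- sample(1:3, 1)
    centers <- sort(sample(seq(12, 80, by = 2), k))
    while (k > 1 && min(diff(centers)) < 12) {
      centers <- sort(sample(seq(12, 80, by = 2), k))
    }
    bumps <- lapply(centers, function(cf) c(cf, runif(1, 0.3, 0.9),
                                            runif(1, 1.5, 4)))
    sp <- make_spectrum(exponent = runif(1, 0.5, 3),
                        offset = runif(1, -1, 1), bumps = bumps)
    ps <- fit_aperiodic_and_peaks(sp)
    total <- total + k
    for (cf in centers)
      if (nrow(ps$peaks) && min(abs(ps$peaks$center_freq - cf)) <= 3)
        hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})
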