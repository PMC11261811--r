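test_that("baseline flattening removes a linear ramp exactly", {
  sp <- synth_spectrum(tibble::tibble(center = numeric(), height = numeric(),
                                      width = numeric()),
                       baseline_slope = 0.004)
  out <- preprocess_spectrum(sp, window = 1)
  expect_lt(max(abs(out$absorbance)), 1e-6)
  expect_equal(out$wavenumber, sp$wavenumber)
})

test_that("window 1 smoothing is the identity and oversize windows error", {
  sp <- preset_spectrum("parallel")
  out <- preprocess_spectrum(sp, window = 1)
  flat <- preprocess_spectrum(sp, window = 1,
                              anchors = list(c(1550, 1560), c(1740, 1750)))
  expect_equal(nrow(out), nrow(sp))
  expect_error(preprocess_spectrum(sp, window = 10000), "window")
})

test_that("smoothing recovers a noisy peak height within 3%", {
  set.seed(21)
  sp <- synth_spectrum(tibble::tibble(center = 1628, height = 1, width = 8),
                       noise_sd = 0.01, seed = 22)
  out <- preprocess_spectrum(sp, window = 9)
  h <- max(out$absorbance[out$wavenumber > 1600 & out$wavenumber < 1660])
  expect_lt(abs(h - 1), 0.03)
})

test_that("Gaussian deconvolution recovers constructed peaks", {
  sp <- synth_spectrum(tibble::tibble(center = 1625, height = 1, width = 8))
  fit <- fit_amide_i(sp, init_centers = c(1628, 1665))
  main <- fit$peaks[which.max(fit$peaks$height), ]
  expect_lt(abs(main$center - 1625), 0.2)
  expect_lt(abs(main$height - 1), 0.02)

  two <- synth_spectrum(tibble::tibble(center = c(1625, 1692),
                                       height = c(1, 0.3), width = c(8, 6)))
  fit2 <- fit_amide_i(two, init_centers = c(1628, 1695))
  pk <- fit2$peaks[order(fit2$peaks$center), ]
  expect_lt(abs(pk$height[1] - 1), 0.02)
  expect_lt(abs(pk$height[2] - 0.3), 0.02 * 0.3 + 0.005)

  zero <- synth_spectrum(tibble::tibble(center = numeric(),
                                        height = numeric(), width = numeric()))
  fz <- fit_amide_i(zero)
  expect_true(all(fz$peaks$height == 0))
})

test_that("beta index is the constructed height ratio and classifies by 0.1", {
  mk_fit <- function(h_high, h_main = 1) {
    peaks <- tibble::tibble(center = c(1628, if (!is.na(h_high)) 1695),
                            height = c(h_main, if (!is.na(h_high)) h_high),
                            width = 8)
    structure(list(peaks = peaks, residual_norm = 0), class = "peak_fit")
  }
  r <- beta_index(mk_fit(0.05))
  expect_equal(r$beta_index, 0.05)
  expect_equal(r$call, "parallel")
  expect_equal(r$main_peak_freq, 1628)

  r0 <- beta_index(mk_fit(NA))
  expect_equal(r0$beta_index, 0)
  expect_equal(r0$call, "parallel")

  r3 <- beta_index(mk_fit(0.3))
  expect_equal(r3$beta_index, 0.3)
  expect_equal(r3$call, "antiparallel")

  # strict boundary: exactly 0.1 is antiparallel, just under is parallel
  expect_equal(beta_index(mk_fit(0.1))$call, "antiparallel")
  expect_equal(beta_index(mk_fit(0.1 - 1e-6))$call, "parallel")

  no_main <- structure(list(peaks = tibble::tibble(center = 1660, height = 1,
                                                   width = 8),
                            residual_norm = 0), class = "peak_fit")
  expect_error(beta_index(no_main), "no beta-sheet signature")
})

test_that("noiseless generator round trip recovers the index to 1e-6", {
  # anchors in signal-free regions so the flat baseline is preserved
  anchors <- list(c(1550, 1556), c(1744, 1750))
  for (ratio in c(0, 0.25)) {
    peaks <- tibble::tibble(center = c(1625, if (ratio > 0) 1695),
                            height = c(1, if (ratio > 0) ratio),
                            width = c(8, if (ratio > 0) 6))
    sp <- synth_spectrum(peaks)
    fit <- fit_amide_i(preprocess_spectrum(sp, window = 1, anchors = anchors),
                       init_centers = c(1625, 1695))
    expect_lt(abs(beta_index(fit)$beta_index - ratio), 1e-6)
  }
})

test_that("beta index is invariant under intensity scaling", {
  sp <- preset_spectrum("antiparallel")
  f1 <- fit_amide_i(preprocess_spectrum(sp, window = 1))
  sp2 <- sp
  sp2$absorbance <- sp2$absorbance * 37.5
  f2 <- fit_amide_i(preprocess_spectrum(sp2, window = 1))
  expect_equal(beta_index(f1)$beta_index, beta_index(f2)$beta_index,
               tolerance = 1e-6)
})

test_that("noisy presets classify correctly with main peak within 0.5/cm", {
  for (seed in 1:3) {
    par_sp <- preset_spectrum("parallel", noise_sd = 0.005, seed = seed)
    anti_sp <- preset_spectrum("antiparallel", noise_sd = 0.005, seed = seed + 10)
    rp <- beta_index(fit_amide_i(preprocess_spectrum(par_sp)))
    ra <- beta_index(fit_amide_i(preprocess_spectrum(anti_sp)))
    expect_equal(rp$call, "parallel")
    expect_equal(ra$call, "antiparallel")
    expect_lt(abs(ra$beta_index - 0.25), 0.02)
    expect_lt(abs(rp$main_peak_freq - 1628), 0.5)
    expect_lt(abs(ra$main_peak_freq - 1625), 0.5)
  }
})

test_that("one-tailed group comparison behaves like the t distribution", {
  # identical groups: t = 0, one-tailed p = 0.5
  a <- c(0.1, 0.2, 0.3)
  expect_equal(compare_groups(a, a, var_equal = TRUE)$p_value, 0.5)

  par_idx <- c(0, 0, 0.004, 0.072, 0)
  anti_idx <- c(0.3, 0.35, 0.4, 0.45, 0.5)
  res <- compare_groups(par_idx, anti_idx, "less", var_equal = TRUE)
  expect_lt(res$p_value, 0.001)
  # closed-form check of the pooled-variance t statistic
  n1 <- 5; n2 <- 5
  sp2 <- ((n1 - 1) * var(par_idx) + (n2 - 1) * var(anti_idx)) / (n1 + n2 - 2)
  t_manual <- (mean(par_idx) - mean(anti_idx)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, pt(t_manual, n1 + n2 - 2), tolerance = 1e-12)
  # reversing the alternative complements the p-value
  res_gt <- compare_groups(par_idx, anti_idx, "greater", var_equal = TRUE)
  expect_equal(res$p_value + res_gt$p_value, 1, tolerance = 1e-12)

  expect_error(compare_groups(0.1, c(0.2, 0.3)), "at least 2")
})

test_that("batch classification reads two-column CSV spectra", {
  dir <- withr::local_tempdir()
  for (m in c("parallel", "antiparallel")) {
    sp <- preset_spectrum(m, noise_sd = 0.003, seed = 31)
    utils::write.csv(as.data.frame(sp), file.path(dir, paste0(m, ".csv")),
                     row.names = FALSE)
  }
  res <- classify_spectra(dir)
  expect_equal(nrow(res), 2)
  expect_equal(res$call[res$label == "parallel"], "parallel")
  expect_equal(res$call[res$label == "antiparallel"], "antiparallel")
  expect_error(classify_spectra(withr::local_tempdir()), "no .csv")
})
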