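#' Synthetic amide-I spectrum
#'
#' Generates a spectrum on a 1 cm^-1 grid as a sum of Gaussian peaks plus
#' a linear baseline and seeded white noise; used to emulate amide-I
#' spectra with parallel (strong ~1628 cm^-1, no high-frequency peak) or
#' antiparallel (additional ~1692 cm^-1 peak) beta-sheet signatures.
#'
#' @param peaks Data frame or tibble with columns `center` (cm^-1, within
#'   1500-1800), `height`, `width` (Gaussian sd, cm^-1).
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline_slope Linear baseline slope (absorbance per cm^-1).
#' @param from,to Wavenumber range.
#' @param label Spectrum label.
#' @param seed Optional seed for the noise.
#' @return A `spectrum` tibble: wavenumber, absorbance; label attribute.
#' @export
synth_spectrum <- function(peaks, noise_sd = 0, baseline_slope = 0,
                           from = 1550, to = 1750, label = "synthetic",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(peaks) > 0 && any(peaks$center < 1500 | peaks$center > 1800)) {
    abort("peak centers must lie within 1500-1800 cm^-1")
  }
  wn <- seq(from, to, by = 1)
  ab <- rep(0, length(wn))
  for (i in seq_len(nrow(peaks))) {
    ab <- ab + peaks$height[i] *
      exp(-(wn - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  ab <- ab + baseline_slope * (wn - from)
  if (noise_sd > 0) ab <- ab + rnorm(length(wn), 0, noise_sd)
  out <- tibble(wavenumber = wn, absorbance = ab)
  attr(out, "label") <- label
  class(out) <- c("spectrum", class(out))
  out
}

#' Parallel / antiparallel amide-I presets
#'
#' `"parallel"`: main beta-sheet peak at 1628 cm^-1 with no high-frequency
#' component; `"antiparallel"`: main peak at 1625 cm^-1 plus a 1695 cm^-1
#' peak at ratio 0.25 (placed inside the 1693-1697 cm^-1 window the
#' beta-index intensity ratio reads); both include a small random-coil
#' band near 1665.
#'
#' @param motif `"parallel"` or `"antiparallel"`.
#' @inheritParams synth_spectrum
#' @return A `spectrum` tibble.
#' @export
preset_spectrum <- function(motif = c("parallel", "antiparallel"),
                            noise_sd = 0, baseline_slope = 0, seed = NULL) {
  motif <- match.arg(motif)
  peaks <- if (motif == "parallel") {
    tibble(center = c(1628, 1665), height = c(1, 0.15), width = c(8, 12))
  } else {
    tibble(center = c(1625, 1665, 1695), height = c(1, 0.15, 0.25),
           width = c(8, 12, 6))
  }
  synth_spectrum(peaks, noise_sd = noise_sd, baseline_slope = baseline_slope,
                 label = motif, seed = seed)
}

#' Preprocess a spectrum: baseline flattening and smoothing
#'
#' Subtracts a linear baseline fitted through two anchor windows (mean
#' wavenumber/absorbance in each), then applies Savitzky-Golay smoothing.
#' The wavenumber grid is unchanged.
#'
#' @param spec A spectrum tibble (wavenumber, absorbance).
#' @param window Smoothing window length in points (odd; 1 = no
#'   smoothing).
#' @param poly_order Polynomial order of the smoother.
#' @param anchors List of two numeric ranges (cm^-1) used as baseline
#'   anchor windows.
#' @return The preprocessed spectrum tibble.
#' @export
preprocess_spectrum <- function(spec, window = 9, poly_order = 3,
                                anchors = list(c(1590, 1605), c(1710, 1725))) {
  stopifnot(all(c("wavenumber", "absorbance") %in% names(spec)))
  if (window > nrow(spec)) abort("smoothing window larger than the spectrum")
  wn <- spec$wavenumber
  ab <- spec$absorbance
  pts <- lapply(anchors, function(rg) {
    sel <- wn >= rg[1] & wn <= rg[2]
    if (!any(sel)) {
      # fall back to the nearest edge point when the anchor window is
      # outside the recorded range
      sel <- which.min(pmin(abs(wn - rg[1]), abs(wn - rg[2])))
    }
    c(mean(wn[sel]), mean(ab[sel]))
  })
  slope <- (pts[[2]][2] - pts[[1]][2]) / (pts[[2]][1] - pts[[1]][1])
  base <- pts[[1]][2] + slope * (wn - pts[[1]][1])
  ab <- ab - base
  if (window > 1) {
    if (window %% 2 == 0) window <- window + 1
    ab <- signal::sgolayfilt(ab, p = min(poly_order, window - 1), n = window)
  }
  out <- spec
  out$absorbance <- ab
  out
}

#' Gaussian deconvolution of the amide-I band
#'
#' Least-squares fit of a sum of Gaussians to the 1600-1700 cm^-1 region
#' (Levenberg-Marquardt). Initial centers default to the canonical
#' amide-I components: main beta (1628), oligomer/alpha band (1650),
#' random coil (1665) and high-frequency beta (1695).
#'
#' @param spec Preprocessed spectrum covering 1600-1700 cm^-1.
#' @param init_centers Numeric vector of initial peak centers (cm^-1);
#'   its length sets the number of Gaussians.
#' @param window Fit window (cm^-1).
#' @return A `peak_fit` object: tibble of peaks (center, height, width)
#'   plus `residual_norm`.
#' @export
fit_amide_i <- function(spec, init_centers = c(1628, 1650, 1665, 1695),
                        window = c(1600, 1700)) {
  stopifnot(all(c("wavenumber", "absorbance") %in% names(spec)))
  sel <- spec$wavenumber >= window[1] & spec$wavenumber <= window[2]
  wn <- spec$wavenumber[sel]
  ab <- spec$absorbance[sel]
  if (length(wn) < 3 * length(init_centers)) {
    abort("spectrum does not cover the amide-I fit window densely enough")
  }
  n <- length(init_centers)
  if (max(abs(ab)) < 1e-12) {
    pk <- tibble(center = init_centers, height = rep(0, n),
                 width = rep(8, n))
    return(structure(list(peaks = pk, residual_norm = 0), class = "peak_fit"))
  }
  # parameters: per peak log-height offset handled by bounds via nlsLM
  start <- list(h = pmax(stats::approx(wn, ab, xout = init_centers,
                                       rule = 2)$y, 1e-3),
                c = init_centers,
                w = rep(8, n))
  model <- function(par, x) {
    y <- 0
    for (k in seq_len(n)) {
      y <- y + par$h[k] * exp(-(x - par$c[k])^2 / (2 * par$w[k]^2))
    }
    y
  }
  fn <- function(p) {
    par <- list(h = p[1:n], c = p[n + 1:n], w = p[2 * n + 1:n])
    model(par, wn) - ab
  }
  fit <- minpack.lm::nls.lm(
    par = unlist(start), fn = fn,
    lower = c(rep(0, n), init_centers - 12, rep(2, n)),
    upper = c(rep(Inf, n), init_centers + 12, rep(25, n)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5)) {
    abort(sprintf("amide-I fit did not converge (residual norm %.4g)",
                  sqrt(sum(fit$fvec^2))))
  }
  p <- fit$par
  pk <- tibble(center = p[n + 1:n], height = p[1:n], width = p[2 * n + 1:n]) |>
    arrange(.data$center)
  structure(list(peaks = pk, residual_norm = sqrt(sum(fit$fvec^2))),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("<peak_fit> residual norm", signif(x$residual_norm, 4), "\n")
  print(as.data.frame(x$peaks))
  invisible(x)
}

#' @export
tidy.peak_fit <- function(x, ...) x$peaks

#' Beta-sheet organizational index and parallel/antiparallel call
#'
#' The beta-index is the ratio of the fitted intensity (Gaussian height)
#' of the high-frequency peak between 1693 and 1697 cm^-1 to that of the
#' main beta-sheet peak between 1624 and 1632 cm^-1; if no peak falls in
#' the high-frequency window the index is 0. Indices below the threshold
#' (default 0.1) are called parallel; an index at or above it is called
#' antiparallel (the "under 0.1" rule read strictly).
#'
#' @param fit A `peak_fit`, or a spectrum tibble (which is then
#'   preprocessed with defaults and fitted).
#' @param threshold Classification threshold.
#' @param min_height Minimum height for a peak to count as present.
#' @return A one-row tibble: beta_index, main_peak_freq, call.
#' @export
beta_index <- function(fit, threshold = 0.1, min_height = 1e-3) {
  if (!inherits(fit, "peak_fit")) {
    fit <- fit_amide_i(preprocess_spectrum(fit))
  }
  pk <- fit$peaks
  main <- pk[pk$center >= 1624 & pk$center <= 1632 & pk$height > min_height, ]
  if (nrow(main) == 0) abort("no beta-sheet signature (no peak in 1624-1632 cm^-1)")
  main <- main[which.max(main$height), ]
  high <- pk[pk$center >= 1693 & pk$center <= 1697 & pk$height > min_height, ]
  idx <- if (nrow(high) == 0) 0 else max(high$height) / main$height
  tibble(
    beta_index = idx,
    main_peak_freq = main$center,
    call = if (idx < threshold) "parallel" else "antiparallel"
  )
}

#' One-tailed two-sample t-test between beta-index groups
#'
#' @param indices_a,indices_b Numeric vectors (n >= 2 each).
#' @param alternative Direction, as in [stats::t.test()] (`"less"` tests
#'   that group A has the smaller mean).
#' @param var_equal Use the equal-variance (Student) variant instead of
#'   Welch.
#' @return One-row tibble: estimate_a, estimate_b, statistic, p_value.
#' @export
compare_groups <- function(indices_a, indices_b,
                           alternative = c("less", "greater"),
                           var_equal = FALSE) {
  alternative <- match.arg(alternative)
  if (length(indices_a) < 2 || length(indices_b) < 2) {
    abort("each group needs at least 2 observations")
  }
  tt <- t.test(indices_a, indices_b, alternative = alternative,
               var.equal = var_equal)
  tibble(estimate_a = mean(indices_a), estimate_b = mean(indices_b),
         statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Batch beta-index classification of spectra files
#'
#' Reads two-column CSV spectra (wavenumber, absorbance) from a
#' directory, preprocesses, fits and classifies each.
#'
#' @param dir Directory of `.csv` spectra.
#' @param threshold Classification threshold.
#' @return Tibble: label, beta_index, main_peak_freq, call.
#' @export
classify_spectra <- function(dir, threshold = 0.1) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) abort(paste0("no .csv spectra in ", dir))
  purrr::map_dfr(files, function(f) {
    sp <- utils::read.csv(f)
    names(sp)[1:2] <- c("wavenumber", "absorbance")
    res <- beta_index(fit_amide_i(preprocess_spectrum(as_tibble(sp))),
                      threshold = threshold)
    mutate(res, label = sub("\\.csv$", "", basename(f)), .before = 1)
  })
}

#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$wavenumber, y = .data$absorbance)) +
    geom_line() +
    ggplot2::scale_x_reverse() +
    labs(x = expression(wavenumber ~ (cm^-1)), y = "absorbance") +
    theme_minimal()
}
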