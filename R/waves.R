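# Travelling-wave detection for annual defoliation series. The chain is
# log(x+1) -> three-point Hunn smoothing -> stationarization, after which
# cyclicity is read off a smoothed, zero-padded periodogram and inter-region
# delays off the lagged cross-correlation function.

#' Read an outbreak panel from CSV
#'
#' Long-format CSV with header `year,region,hectares`: annual area of forest
#' defoliated in each region (0 = no outbreak that year).
#'
#' @param path CSV path.
#' @return A validated tibble (`region`, `year`, `hectares`).
#' @export
read_outbreak_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("outbreak panel not found: ", path), class = "mothwaves_input_error")
  }
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_outbreak_panel(panel)
}

#' Validate an outbreak panel
#'
#' Checks non-negative values and that every region covers every year of the
#' panel's range with no interior gaps.
#'
#' @param panel Data frame with `region`, `year`, `hectares`.
#' @return The validated tibble, ordered by region then year.
#' @export
validate_outbreak_panel <- function(panel) {
  need <- c("region", "year", "hectares")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    abort("outbreak panel needs columns region, year, hectares",
          class = "mothwaves_input_error")
  }
  panel <- as_tibble(panel)[, need]
  if (any(panel$hectares < 0)) {
    abort("defoliated areas must be >= 0", class = "mothwaves_input_error")
  }
  yrs <- seq(min(panel$year), max(panel$year))
  by_region <- split(panel$year, panel$region)
  for (r in names(by_region)) {
    if (!setequal(by_region[[r]], yrs) || anyDuplicated(by_region[[r]])) {
      abort(paste0("region ", r, " does not cover every year ",
                   min(yrs), "-", max(yrs), " exactly once"),
            class = "mothwaves_input_error")
    }
  }
  dplyr::arrange(panel, .data$region, .data$year)
}

#' log(x + 1) transform
#'
#' Shifts by one hectare before taking logs so zero-defoliation years map to
#' exactly 0 rather than -Inf.
#'
#' @param x Non-negative numeric vector.
#' @return `log(x + 1)` elementwise.
#' @export
log_plus_one <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("log_plus_one needs non-negative input", class = "mothwaves_input_error")
  }
  log(x + 1)
}

#' Three-point Hunn smoothing filter
#'
#' Interior points are replaced by the weighted average
#' `0.24*x(i-1) + 0.52*x(i) + 0.24*x(i+1)`, which suppresses components above
#' 0.25 cycles/year; the two endpoints are copied unfiltered so the printed
#' interior formula is applied exactly.
#'
#' @param x Numeric vector, length >= 3.
#' @return Filtered vector of the same length.
#' @export
hunn_filter <- function(x) {
  n <- length(x)
  if (n < 3) {
    abort("the Hunn filter needs at least 3 points", class = "mothwaves_input_error")
  }
  out <- x
  i <- 2:(n - 1)
  out[i] <- 0.24 * x[i - 1] + 0.52 * x[i] + 0.24 * x[i + 1]
  out
}

#' Stationarize a series
#'
#' Removes a least-squares linear trend, then centers and scales to unit
#' variance, so mean and standard deviation no longer drift over time. A
#' (detrended-)constant series comes back as all zeros with attribute
#' `constant = TRUE`.
#'
#' @param x Numeric vector, length >= 4.
#' @param method `"detrend"` (linear detrend + standardize, default) or
#'   `"diff"` (first differences + standardize; one observation shorter).
#' @return Stationarized series (mean 0, sd 1 unless constant).
#' @export
stationarize <- function(x, method = c("detrend", "diff")) {
  method <- match.arg(method)
  if (length(x) < 4) {
    abort("stationarize needs at least 4 points", class = "mothwaves_input_error")
  }
  if (method == "diff") {
    r <- diff(x)
  } else {
    t <- seq_along(x)
    r <- residuals(lm(x ~ t))
  }
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12) {
    out <- rep(0, length(r))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- as.numeric((r - mean(r)) / s)
  attr(out, "constant") <- FALSE
  out
}

#' Smoothed periodogram and dominant outbreak period
#'
#' Periodogram of a (stationarized) series on a zero-padded frequency grid,
#' smoothed with a modified Daniell window of width 3 (weights 1/4, 1/2,
#' 1/4, renormalized at the grid edges). Spectral mass above
#' `cutoff` cycles/year — the band the Hunn filter is designed to remove —
#' and the zero frequency are excluded from the peak search; the dominant
#' cycle length is `period_L = 1/f_max` years.
#'
#' @param x Numeric series, length >= 8 (stationarized upstream).
#' @param pad_to Grid length after zero-padding (default 256, giving a
#'   frequency step of 1/256 cycles/year).
#' @param cutoff Peak search is restricted to `0 < f <= cutoff` (default
#'   0.25 cycles/year).
#' @param smooth Apply modified-Daniell smoothing of width 3 (default
#'   `TRUE`).
#' @return An object of class `spectral_result` with the frequency grid,
#'   density, `f_max`, `peak_value`, and `period_L`.
#' @export
spectral_density <- function(x, pad_to = 256, cutoff = 0.25, smooth = TRUE) {
  n <- length(x)
  if (n < 8) {
    abort("spectral density needs at least 8 points", class = "mothwaves_input_error")
  }
  if (sd(x) < 1e-12 || isTRUE(attr(x, "constant"))) {
    abort("spectrum undefined for a constant (or all-zero) series",
          class = "mothwaves_undefined_spectrum")
  }
  N <- max(pad_to, n)
  padded <- c(x - mean(x), rep(0, N - n))
  per <- Mod(fft(padded))^2 / n
  nf <- floor(N / 2)
  freq <- (1:nf) / N
  dens <- per[2:(nf + 1)]
  if (smooth) {
    sm <- dens
    if (nf >= 3) {
      i <- 2:(nf - 1)
      sm[i] <- 0.25 * dens[i - 1] + 0.5 * dens[i] + 0.25 * dens[i + 1]
      sm[1] <- (0.5 * dens[1] + 0.25 * dens[2]) / 0.75
      sm[nf] <- (0.25 * dens[nf - 1] + 0.5 * dens[nf]) / 0.75
    }
    dens <- sm
  }
  in_band <- freq <= cutoff
  if (!any(in_band)) {
    abort("no frequencies below the cutoff; increase pad_to",
          class = "mothwaves_input_error")
  }
  imax <- which(in_band)[which.max(dens[in_band])]
  structure(
    list(
      frequencies = freq, density = dens,
      f_max = freq[imax], peak_value = dens[imax],
      period_L = 1 / freq[imax],
      n = n, pad_to = N, cutoff = cutoff
    ),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> f_max = %.4g /year, period L = %.1f years (peak %.3g)\n",
              x$f_max, x$period_L, x$peak_value))
  invisible(x)
}

#' @export
tidy.spectral_result <- function(x, ...) {
  tibble(frequency = x$frequencies, density = x$density)
}

#' @export
glance.spectral_result <- function(x, ...) {
  tibble(f_max = x$f_max, peak_value = x$peak_value, period_L = x$period_L,
         n = x$n, pad_to = x$pad_to)
}

#' @export
autoplot.spectral_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$frequency <= object$cutoff, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$f_max, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "frequency (cycles/year)", y = "spectral density") +
    ggplot2::theme_minimal()
}

#' Lagged cross-correlation between two series
#'
#' For each lag `k` in `-max_lag..max_lag`, the Pearson correlation of
#' `x(t - k)` against `y(t)` over the overlapping window. Sign convention:
#' a best lag of `+d` means the wave in `y` arrives `d` years AFTER the wave
#' in `x` (`x` leads). Zero-variance overlaps yield `NA` at that lag.
#'
#' @param x,y Numeric series of equal length `n`.
#' @param max_lag Maximum lag magnitude, `max_lag <= n - 3`.
#' @param alpha Two-sided significance level for the t flag.
#' @return An object of class `crosscorr_result`: a tibble (`lag`, `value`,
#'   `t_value`, `n_overlap`, `significant`) with attributes `best_lag` and
#'   `best_value`.
#' @export
cross_correlation <- function(x, y, max_lag = 2, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n) {
    abort("series must have equal length", class = "mothwaves_input_error")
  }
  if (max_lag > n - 3 || max_lag < 0) {
    abort("max_lag must be between 0 and n - 3", class = "mothwaves_input_error")
  }
  lags <- (-max_lag):max_lag
  rows <- purrr::map(lags, function(k) {
    if (k >= 0) {
      xs <- x[seq_len(n - k)]
      ys <- y[seq_len(n - k) + k]
    } else {
      xs <- x[seq_len(n + k) - k]
      ys <- y[seq_len(n + k)]
    }
    no <- length(xs)
    r <- if (sd(xs) < 1e-12 || sd(ys) < 1e-12) NA_real_ else cor(xs, ys)
    sig <- if (is.na(r)) {
      tibble(t_value = NA_real_, significant = NA, critical = NA_real_)
    } else {
      ccf_significance(r, no, alpha)
    }
    tibble(lag = k, value = r, t_value = sig$t_value, n_overlap = no,
           significant = sig$significant)
  }) |> purrr::list_rbind()
  best <- best_lag_of(rows)
  structure(rows,
            class = c("crosscorr_result", class(rows)),
            best_lag = best$lag, best_value = best$value)
}

best_lag_of <- function(rows) {
  ok <- rows[!is.na(rows$value), ]
  if (nrow(ok) == 0) return(list(lag = NA_integer_, value = NA_real_))
  ok <- ok[order(-ok$value, abs(ok$lag), ok$lag), ]
  list(lag = ok$lag[1], value = ok$value[1])
}

#' Best lag of a cross-correlation result
#'
#' @param ccr A `crosscorr_result`.
#' @return Integer lag at which the cross-correlation attains its maximum
#'   (ties broken toward smaller magnitude, then negative first).
#' @export
best_lag <- function(ccr) {
  stopifnot(inherits(ccr, "crosscorr_result"))
  attr(ccr, "best_lag")
}

#' @export
tidy.crosscorr_result <- function(x, ...) {
  as_tibble(unclass(x)[c("lag", "value", "t_value", "n_overlap", "significant")])
}

#' @export
glance.crosscorr_result <- function(x, ...) {
  b <- attr(x, "best_lag")
  row <- as_tibble(x)[as_tibble(x)$lag == b, ]
  tibble(best_lag = b, best_value = attr(x, "best_value"),
         t_value = row$t_value[1], n_overlap = row$n_overlap[1],
         significant = row$significant[1])
}

#' @export
autoplot.crosscorr_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::labs(x = "lag (years)", y = "cross-correlation") +
    ggplot2::theme_minimal()
}

#' t-based significance of a cross-correlation value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, flagged significant when `|t|`
#' exceeds the two-sided critical value at level `alpha` with `n - 2`
#' degrees of freedom.
#'
#' @param value Correlation `r` with `|r| <= 1`.
#' @param n_overlap Number of overlapping observations, `>= 4`.
#' @param alpha Two-sided level (default 0.05).
#' @return One-row tibble (`t_value`, `significant`, `critical`); `|r| = 1`
#'   yields an infinite t flagged significant.
#' @export
ccf_significance <- function(value, n_overlap, alpha = 0.05) {
  if (n_overlap < 4) {
    abort("significance needs an overlap of at least 4", class = "mothwaves_input_error")
  }
  crit <- stats::qt(1 - alpha / 2, df = n_overlap - 2)
  if (abs(value) >= 1) {
    t <- sign(value) * Inf
    return(tibble(t_value = t, significant = TRUE, critical = crit))
  }
  t <- value * sqrt(n_overlap - 2) / sqrt(1 - value^2)
  tibble(t_value = t, significant = abs(t) > crit, critical = crit)
}

#' Preprocess a defoliation series for wave analysis
#'
#' The full chain `log_plus_one()` -> `hunn_filter()` -> `stationarize()`.
#'
#' @param x Non-negative series (hectares).
#' @param method Stationarization method, see [stationarize()].
#' @return Stationarized series.
#' @export
preprocess_series <- function(x, method = "detrend") {
  stationarize(hunn_filter(log_plus_one(x)), method)
}

#' Region-pair travelling-wave report for an outbreak panel
#'
#' Runs the full pipeline per region (preprocess, smoothed periodogram) and
#' per region pair (lagged cross-correlation with t flags), assembles the
#' conventional square presentation (values/t above the diagonal, lags
#' below), and — when a geographic ordering is declared — tests whether the
#' lags of the first region against the others increase strictly along that
#' axis (the travelling-wave signature).
#'
#' @param panel Outbreak panel tibble (`region`, `year`, `hectares`).
#' @param axis_order Optional character vector of region names in geographic
#'   order along the supposed wave axis.
#' @param max_lag Maximum lag for the cross-correlations (default 10 years,
#'   clipped to `n - 3`).
#' @param pad_to Periodogram grid length, see [spectral_density()].
#' @param alpha Significance level for the t flags.
#' @return An object of class `wave_report`: `spectra` (per-region f_max,
#'   peak, period), `pairs` (per ordered pair best lag, value, t), `matrix`
#'   (character, Table-style), `monotone` (axis test or `NULL`).
#' @export
wave_report <- function(panel, axis_order = NULL, max_lag = 10, pad_to = 256,
                        alpha = 0.05) {
  panel <- validate_outbreak_panel(panel)
  regions <- unique(panel$region)
  if (length(regions) < 2) {
    abort("wave report needs at least 2 regions", class = "mothwaves_input_error")
  }
  if (!is.null(axis_order)) {
    if (!setequal(axis_order, regions)) {
      abort("axis_order must be a permutation of the panel's regions",
            class = "mothwaves_input_error")
    }
    regions <- axis_order
  }
  series <- lapply(regions, function(r) panel$hectares[panel$region == r])
  names(series) <- regions
  n <- length(series[[1]])
  max_lag <- min(max_lag, n - 3)
  pre <- lapply(series, preprocess_series)
  spectra <- purrr::imap(pre, function(s, r) {
    sp <- tryCatch(spectral_density(s, pad_to), mothwaves_undefined_spectrum = function(e) NULL)
    if (is.null(sp)) {
      tibble(region = r, f_max = NA_real_, peak_value = NA_real_, period_L = NA_real_)
    } else {
      tibble(region = r, f_max = sp$f_max, peak_value = sp$peak_value,
             period_L = sp$period_L)
    }
  }) |> purrr::list_rbind()
  pairs <- purrr::list_rbind(purrr::map(seq_along(regions), function(i) {
    purrr::list_rbind(purrr::map(seq_len(i - 1L), function(j) {
      cc <- cross_correlation(pre[[j]], pre[[i]], max_lag, alpha)
      g <- glance(cc)
      tibble(region_x = regions[j], region_y = regions[i],
             best_lag = g$best_lag, value = g$best_value,
             t_value = g$t_value, n_overlap = g$n_overlap,
             significant = g$significant)
    }))
  }))
  p <- length(regions)
  m <- matrix("", p, p, dimnames = list(regions, regions))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$region_y[r], regions)
    j <- match(pairs$region_x[r], regions)
    star <- if (isTRUE(pairs$significant[r])) "*" else ""
    m[j, i] <- sprintf("%.2f/%.2f%s", pairs$value[r], pairs$t_value[r], star)
    m[i, j] <- sprintf("%d", pairs$best_lag[r])
  }
  monotone <- NULL
  if (!is.null(axis_order)) {
    lead <- regions[1]
    lags <- vapply(regions[-1], function(r) {
      row <- pairs[pairs$region_x == lead & pairs$region_y == r, ]
      as.numeric(row$best_lag[1])
    }, numeric(1))
    monotone <- list(axis = regions, lead = lead, lags = lags,
                     strictly_increasing = all(diff(lags) > 0))
  }
  structure(
    list(spectra = spectra, pairs = pairs, matrix = m, monotone = monotone,
         max_lag = max_lag, alpha = alpha),
    class = "wave_report"
  )
}

#' @export
print.wave_report <- function(x, ...) {
  cat("<wave_report> ", nrow(x$spectra), " regions, max lag ", x$max_lag, "\n", sep = "")
  print(x$spectra)
  cat("value/t above diagonal, lag below:\n")
  print(x$matrix, quote = FALSE)
  if (!is.null(x$monotone)) {
    cat("lags of", x$monotone$lead, "vs axis:",
        paste(x$monotone$lags, collapse = ", "),
        if (x$monotone$strictly_increasing) "(strictly increasing)\n" else "(not monotone)\n")
  }
  invisible(x)
}

#' @export
tidy.wave_report <- function(x, ...) x$pairs

#' @export
glance.wave_report <- function(x, ...) {
  tibble(
    n_regions = nrow(x$spectra),
    median_period = stats::median(x$spectra$period_L, na.rm = TRUE),
    n_significant = sum(x$pairs$significant, na.rm = TRUE),
    n_pairs = nrow(x$pairs),
    monotone_axis = if (is.null(x$monotone)) NA else x$monotone$strictly_increasing
  )
}

#' Plot an outbreak panel
#'
#' Faceted annual defoliation series, one panel per region.
#'
#' @param panel Outbreak panel tibble.
#' @return A ggplot object.
#' @export
plot_outbreak_panel <- function(panel) {
  panel <- validate_outbreak_panel(panel)
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$year, y = .data$hectares)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "defoliated area (ha)") +
    ggplot2::theme_minimal()
}
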