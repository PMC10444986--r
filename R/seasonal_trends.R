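#' Seasonal trend models of resources and visits
#'
#' Seasonal fluctuation is modelled per site with a generalized additive
#' model: a penalized thin-plate spline smooth of census day (days since the
#' site's first survey) spanning both study years.  Resource series (sugar
#' ug/m^2 or pollen uL/m^2 per plot and occasion) are positive continuous
#' data that include exact zeros, so the response is shifted by a small
#' offset (+0.0001) and fitted with a gamma error distribution and log
#' link.  Visit counts are overdispersed and fitted with a negative binomial
#' distribution (log link) whose theta is estimated during fitting.
#'
#' @param data A data frame of per-plot observations with a census-day
#'   column and the response column.
#' @param response_col,day_col Column names (defaults `"value"`,
#'   `"census_day"`).
#' @param offset Shift added to the resource response before the gamma fit
#'   (default 0.0001).
#' @param k Smooth basis dimension (default 10, i.e. reference df about 9).
#' @param method Smoothness-selection criterion passed to [mgcv::gam()].
#'   Gamma fits default to `"GCV.Cp"`; negative-binomial fits use `"REML"`,
#'   which theta estimation requires.
#' @param alpha Significance level used when reporting whether seasonality
#'   was detected (default 0.05).
#' @param response Label stored in the fit (e.g. `"sugar"`,
#'   `"visits_hoverfly"`).
#' @return An object of class `seasonal_trend_fit`: a list with the
#'   intercept estimate and SE, smooth effective df (`edf`), reference df,
#'   test statistic and p-value, percent deviance explained, `theta`
#'   (negative binomial only), and a `predictions` tibble (`census_day`,
#'   `prediction`) on a one-day grid.
#' @export
fit_resource_trend <- function(data, response_col = "value",
                               day_col = "census_day", offset = 1e-4,
                               k = 10, method = "GCV.Cp", alpha = 0.05,
                               response = "resource") {
  d <- check_trend_data(data, response_col, day_col)
  if (any(d$y < 0)) {
    stop_florivis("resource values must be >= 0", "florivis_validation_error")
  }
  d$y <- d$y + offset
  if (stats::var(d$y) == 0) {
    # a constant response carries no seasonal information; the gamma
    # likelihood is degenerate, so return the intercept-only limit directly
    return(constant_trend_fit(d, family = "gamma_log", response = response,
                              alpha = alpha))
  }
  fit <- mgcv::gam(y ~ s(day, k = k), data = d,
                   family = stats::Gamma(link = "log"), method = method)
  summarize_trend_fit(fit, d, family = "gamma_log", response = response,
                      alpha = alpha)
}

#' @rdname fit_resource_trend
#' @param count_col Column holding nonnegative integer visit counts.
#' @export
fit_visit_trend <- function(data, count_col = "count",
                            day_col = "census_day", k = 10,
                            method = "REML", alpha = 0.05,
                            response = "visits") {
  d <- check_trend_data(data, count_col, day_col)
  if (any(d$y < 0) || any(d$y != round(d$y))) {
    stop_florivis("visit counts must be nonnegative integers",
                  "florivis_validation_error")
  }
  if (all(d$y == 0)) {
    return(structure(list(fitted = FALSE, response = response,
                          family = "negbin_log", n = nrow(d),
                          reason = "all counts zero"),
                     class = "seasonal_trend_fit"))
  }
  fit <- try(mgcv::gam(y ~ s(day, k = k), data = d, family = mgcv::nb(),
                       method = method), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(fitted = FALSE, response = response,
                          family = "negbin_log", n = nrow(d),
                          reason = attr(fit, "condition")$message),
                     class = "seasonal_trend_fit"))
  }
  summarize_trend_fit(fit, d, family = "negbin_log", response = response,
                      alpha = alpha)
}

#' Local maxima of a fitted seasonal curve
#'
#' Interior strict local maxima of the prediction grid, used to locate
#' seasonal peaks (e.g. the late-spring/early-summer and autumn peaks of
#' floral resources).  Maxima below `min_height_frac` of the curve's range
#' above its minimum are discarded as noise.
#'
#' @param fit A `seasonal_trend_fit`.
#' @param min_height_frac Prominence threshold relative to the curve range
#'   (default 0.05).
#' @return Census days of the local maxima, in decreasing order of height.
#' @export
trend_peaks <- function(fit, min_height_frac = 0.05) {
  stopifnot(inherits(fit, "seasonal_trend_fit"))
  if (!isTRUE(fit$fitted)) return(numeric(0))
  p <- fit$predictions
  y <- p$prediction
  n <- length(y)
  if (n < 3) return(numeric(0))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1
  if (!length(i)) return(numeric(0))
  floor_y <- min(y) + min_height_frac * diff(range(y))
  i <- i[y[i] >= floor_y]
  i <- i[order(y[i], decreasing = TRUE)]
  p$census_day[i]
}

#' Fit seasonal trends for every site and response of a survey
#'
#' Convenience wrapper running [fit_resource_trend()] on the two resource
#' totals and [fit_visit_trend()] on the pooled and per-group visit counts,
#' separately per site.  Visit counts are summed over species within each
#' plot and occasion.
#'
#' @param availability A [plot_availability()] object.
#' @param visits Filtered visit records.
#' @param k,alpha See [fit_resource_trend()].
#' @return A list with `fits` (named list of `seasonal_trend_fit`),
#'   `summary` (tibble: site, response, family, edf, ref_df, statistic,
#'   p_value, deviance_explained, theta) and `predictions` (long tibble).
#' @export
fit_site_trends <- function(availability, visits, k = 10, alpha = 0.05) {
  tot <- availability$totals
  fits <- list()

  for (site in unique(tot$site)) {
    st <- tot[tot$site == site, , drop = FALSE]
    day0 <- min(st$date)
    for (res in RESOURCE_MEASURES) {
      col <- if (res == "sugar") "sugar_ug_m2" else "pollen_ul_m2"
      d <- tibble::tibble(value = st[[col]],
                          census_day = as.numeric(st$date - day0))
      fits[[paste(site, res, sep = ".")]] <-
        c_site(fit_resource_trend(d, k = k, alpha = alpha, response = res),
               site)
    }

    sv <- visits[visits$site == site, , drop = FALSE]
    plot_occ <- unique(st[c("site", "date", "plot_id")])
    for (vm in VISIT_MEASURES) {
      grp <- sub("^visits_", "", vm)
      sub <- if (grp == "all") sv else sv[sv$insect_group == grp, , drop = FALSE]
      agg <- dplyr::summarise(dplyr::group_by(sub, .data$date, .data$plot_id),
                              count = sum(.data$count), .groups = "drop")
      # plots observed with zero visits enter as zero counts
      d <- dplyr::left_join(plot_occ, agg, by = c("date", "plot_id"))
      d$count[is.na(d$count)] <- 0L
      d$census_day <- as.numeric(d$date - day0)
      fits[[paste(site, vm, sep = ".")]] <-
        c_site(fit_visit_trend(d, k = k, alpha = alpha, response = vm), site)
    }
  }

  summary <- dplyr::bind_rows(lapply(fits, tidy_trend_fit))
  preds <- dplyr::bind_rows(lapply(fits, function(f) {
    if (!isTRUE(f$fitted)) return(NULL)
    dplyr::mutate(f$predictions, site = f$site, response = f$response,
                  .before = 1)
  }))
  list(fits = fits, summary = summary, predictions = preds)
}

#' @export
print.seasonal_trend_fit <- function(x, ...) {
  cat(sprintf("<seasonal_trend_fit> %s (%s)\n", x$response, x$family))
  if (!isTRUE(x$fitted)) {
    cat(sprintf("  not fitted: %s\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf("  n = %d; intercept %.3f (SE %.3f)\n", x$n, x$intercept,
              x$intercept_se))
  cat(sprintf("  s(census day): edf %.3f, ref df %.3f, stat %.2f, p = %.4g\n",
              x$edf, x$ref_df, x$statistic, x$p_value))
  cat(sprintf("  deviance explained %.1f%%", x$deviance_explained))
  if (!is.null(x$theta)) cat(sprintf("; theta = %.3f", x$theta))
  cat("\n")
  invisible(x)
}

# ---- internals --------------------------------------------------------------

check_trend_data <- function(data, response_col, day_col) {
  data <- tibble::as_tibble(data)
  if (!all(c(response_col, day_col) %in% names(data))) {
    stop_florivis(sprintf("trend data must have columns '%s' and '%s'",
                          response_col, day_col),
                  "florivis_format_error")
  }
  d <- tibble::tibble(y = as.numeric(data[[response_col]]),
                      day = as.numeric(data[[day_col]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 20) {
    stop_florivis("need at least 20 observations to fit a seasonal trend",
                  "florivis_fitting_error")
  }
  if (length(unique(d$day)) < 3) {
    stop_florivis("need at least 3 distinct census days",
                  "florivis_fitting_error")
  }
  d
}

constant_trend_fit <- function(d, family, response, alpha) {
  grid <- seq(min(d$day), max(d$day), by = 1)
  structure(list(
    fitted = TRUE, response = response, family = family, n = nrow(d),
    intercept = log(mean(d$y)), intercept_se = 0,
    edf = 0, ref_df = 0, statistic = 0, p_value = 1,
    deviance_explained = 0, theta = NULL, alpha = alpha,
    significant = FALSE,
    predictions = tibble::tibble(census_day = grid,
                                 prediction = rep(mean(d$y), length(grid)))
  ), class = "seasonal_trend_fit")
}

summarize_trend_fit <- function(fit, d, family, response, alpha) {
  s <- mgcv::summary.gam(fit)
  grid <- tibble::tibble(day = seq(min(d$day), max(d$day), by = 1))
  pred <- as.numeric(mgcv::predict.gam(fit, newdata = grid,
                                       type = "response"))
  theta <- if (family == "negbin_log") fit$family$getTheta(TRUE) else NULL
  structure(list(
    fitted = TRUE,
    response = response,
    family = family,
    n = nrow(d),
    intercept = unname(s$p.coeff[1]),
    intercept_se = unname(s$se[1]),
    edf = unname(s$s.table[1, "edf"]),
    ref_df = unname(s$s.table[1, "Ref.df"]),
    statistic = unname(s$s.table[1, 3]),
    p_value = unname(s$s.table[1, "p-value"]),
    deviance_explained = 100 * s$dev.expl,
    theta = theta,
    alpha = alpha,
    significant = unname(s$s.table[1, "p-value"]) < alpha,
    predictions = tibble::tibble(census_day = grid$day, prediction = pred),
    gam = fit
  ), class = "seasonal_trend_fit")
}

tidy_trend_fit <- function(f) {
  tibble::tibble(
    site = f$site %||% NA_character_,
    response = f$response,
    family = f$family,
    fitted = isTRUE(f$fitted),
    edf = if (isTRUE(f$fitted)) f$edf else NA_real_,
    ref_df = if (isTRUE(f$fitted)) f$ref_df else NA_real_,
    statistic = if (isTRUE(f$fitted)) f$statistic else NA_real_,
    p_value = if (isTRUE(f$fitted)) f$p_value else NA_real_,
    deviance_explained = if (isTRUE(f$fitted)) f$deviance_explained else NA_real_,
    theta = if (isTRUE(f$fitted) && !is.null(f$theta)) f$theta else NA_real_
  )
}

c_site <- function(fit, site) {
  fit$site <- site
  fit
}
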