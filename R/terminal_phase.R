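#' Best-fit log-linear regression of the terminal phase
#'
#' Estimates the terminal elimination rate constant (lambda-z, equal to Ke
#' under one-compartment kinetics), the log-concentration intercept and the
#' half-life from a pooled profile, using a best-fit window search: every
#' window formed by the last `k` post-peak bins (`k = min_points` up to all
#' post-peak bins) is regressed on the log scale, and the window with the
#' highest adjusted R-squared among those with a negative slope is
#' returned. Ties in adjusted R-squared are broken toward the window with
#' more points, which stabilizes extrapolation.
#'
#' For extravascular profiles the peak bin itself is excluded from the
#' candidate windows because it is still contaminated by absorption.
#'
#' @param profile a `pooled_profile` from [pool_observations()], or a data
#'   frame/list with `tad` and `conc` columns.
#' @param min_points minimum number of bins in a regression window
#'   (default 3).
#' @param route `"bolus"`, `"infusion"` or `"extravascular"`; defaults to
#'   the profile's own route. Only extravascular profiles drop the peak
#'   bin.
#' @return an object of class `terminal_fit` with elements `lambda_z`,
#'   `beta0` (intercept of log concentration at TAD 0), `t_half`,
#'   `n_points`, `adj_r2`, `point_indices` (bin indices used) and
#'   `windows` (the diagnostics table of all candidate windows), or `NULL`
#'   when no candidate window has a negative slope ("terminal phase not
#'   estimable").
#' @examples
#' prof <- list(tad = c(4, 8, 12, 16, 20, 24),
#'              conc = 10 * exp(-0.1 * c(4, 8, 12, 16, 20, 24)))
#' fit_lambda_z(prof)
#' @export
fit_lambda_z <- function(profile, min_points = 3, route = NULL) {
  if (inherits(profile, "pooled_profile")) {
    if (is.null(route)) route <- profile$route
    tad <- profile$bins$tad
    conc <- profile$bins$conc
  } else {
    tad <- profile$tad
    conc <- profile$conc
  }
  if (is.null(route) || is.na(route)) route <- "bolus"
  keep <- is.finite(tad) & is.finite(conc) & conc > 0
  tad <- tad[keep]
  conc <- conc[keep]
  idx_all <- which(keep)
  n <- length(tad)
  if (n < min_points) return(NULL)

  peak <- which.max(conc)
  post <- if (identical(route, "extravascular")) {
    which(seq_len(n) > peak)
  } else {
    which(seq_len(n) >= peak)
  }
  if (length(post) < min_points) return(NULL)

  m <- length(post)
  rows <- lapply(seq(min_points, m), function(k) {
    w <- post[(m - k + 1L):m]
    fit <- stats::lm(log(conc[w]) ~ tad[w])
    slope <- unname(stats::coef(fit)[2L])
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    data.frame(k = k, slope = slope, beta0 = unname(stats::coef(fit)[1L]),
               adj_r2 = r2, first_bin = w[1L])
  })
  windows <- do.call(rbind, rows)
  ok <- which(is.finite(windows$slope) & windows$slope < 0)
  if (!length(ok)) return(NULL)

  best_r2 <- max(windows$adj_r2[ok])
  tied <- ok[windows$adj_r2[ok] >= best_r2 - 1e-9]
  best <- tied[which.max(windows$k[tied])]

  k <- windows$k[best]
  w <- post[(m - k + 1L):m]
  structure(list(
    lambda_z = -windows$slope[best],
    beta0 = windows$beta0[best],
    t_half = log(2) / -windows$slope[best],
    n_points = k,
    adj_r2 = windows$adj_r2[best],
    point_indices = idx_all[w],
    windows = windows
  ), class = "terminal_fit")
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf(
    "Terminal-phase fit: lambda_z = %.5g 1/h (t1/2 = %.4g h), %d points, adj R2 = %.5f\n",
    x$lambda_z, x$t_half, x$n_points, x$adj_r2))
  invisible(x)
}

#' Pooled half-life estimation
#'
#' The one-compartment methods need a pooled half-life. The best-fit
#' terminal regression is attempted on the first-dose pooled group
#' (first-dose data are uncontaminated by accumulation) and then on the
#' mixed group. When the best-fit search is infeasible -- sparse designs
#' may leave fewer post-peak bins than the minimum window -- the
#' half-life alone is recovered by a plain log-linear regression over all
#' pooled bins with a negative fitted slope (two bins suffice). That
#' simple estimate supports the single-point method, but does not
#' constitute a terminal best fit: NCA and the graphical methods, which
#' extrapolate from the fitted line, still require the strict fit and are
#' skipped without it.
#'
#' @param annotated a `pk_annotated` object.
#' @param n_bins number of pooling bins.
#' @param min_points minimum regression window size for the best fit.
#' @return a list with `fit` (`terminal_fit` or `NULL`), `profile` /
#'   `profile_group` (the data the usable estimate came from), `halflife`
#'   (list `t_half`, `lambda_z`, `source` in
#'   `{"best_fit", "simple", "none"}`) and `profiles` (all three pooled
#'   groups).
#' @export
pooled_halflife <- function(annotated, n_bins = 10, min_points = 3) {
  profs <- list(
    first_dose = pool_observations(annotated, "first_dose", n_bins),
    multi_dose = pool_observations(annotated, "multi_dose", n_bins),
    mixed      = pool_observations(annotated, "mixed", n_bins)
  )
  fit <- fit_lambda_z(profs$first_dose, min_points)
  used <- "first_dose"
  if (is.null(fit)) {
    fit <- fit_lambda_z(profs$mixed, min_points)
    used <- "mixed"
  }
  if (!is.null(fit)) {
    hl <- list(t_half = fit$t_half, lambda_z = fit$lambda_z,
               source = "best_fit")
  } else {
    used <- "mixed"
    hl <- halflife_simple(profs$mixed)
  }
  list(fit = fit, profile = profs[[used]], profile_group = used,
       halflife = hl, profiles = profs)
}

# plain log-linear regression over all pooled bins; a fallback half-life
# for sparse profiles where the best-fit window search is infeasible
halflife_simple <- function(profile) {
  none <- list(t_half = NA_real_, lambda_z = NA_real_, source = "none")
  bins <- profile$bins[profile$bins$conc > 0, , drop = FALSE]
  if (nrow(bins) < 2L) return(none)
  fit <- stats::lm(log(conc) ~ tad, data = bins)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) return(none)
  list(t_half = log(2) / -slope, lambda_z = -slope, source = "simple")
}
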