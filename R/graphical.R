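#' Graphical method for intravenous data
#'
#' On pooled first-dose data, the terminal regression line extrapolated to
#' time zero gives the initial concentration; its inverse (per unit dose)
#' is the extrapolated volume `V_extrap = 1 / Y_intercept`, and
#' `CL = lambda_z * V_extrap`.
#'
#' @param profile a dose-normalized `pooled_profile` (intravenous).
#' @param fit a `terminal_fit` for the profile.
#' @return a `pk_onecpt_estimate`, or `NULL` when no terminal fit is
#'   available.
#' @export
graphical_iv <- function(profile, fit) {
  if (is.null(fit)) return(NULL)
  v <- 1 / exp(fit$beta0)
  structure(list(
    method = "graphical", cl = fit$lambda_z * v, v = v, ka = NA_real_,
    source = list(cl = "lambda_z_times_v", v = "extrapolated_intercept",
                  ka = NA_character_),
    lambda_z = fit$lambda_z
  ), class = "pk_onecpt_estimate")
}

#' Method of residuals for extravascular data
#'
#' Strips the extrapolated terminal exponential from a pooled
#' extravascular profile: `C_residual(t) = C_extrap(t) - C(t)` with
#' `C_extrap(t) = exp(beta0 - lambda_z * t)`, over the bins strictly
#' before the peak bin. The regression of `ln(C_residual)` on time has
#' slope `-Ka`. The volume is approximated as `Dose / C_extrap(0)`
#' (exact in the limit `Ka >> Ke`), and `CL = lambda_z * V`.
#'
#' Residual points that are non-positive are dropped. When fewer than two
#' strictly-pre-peak residuals remain (sparse profiles), the residual
#' line's own intercept relation `ln(C_residual) = ln C0 - Ka t` is used
#' instead: the line is anchored at the extrapolated `ln C0` and its
#' slope fitted through the positive residuals at or before the peak, so
#' a single residual point still yields Ka.
#'
#' @param profile a dose-normalized `pooled_profile` (extravascular).
#' @param fit a `terminal_fit` for the profile.
#' @return a `pk_onecpt_estimate` including the `residual_points` used,
#'   or `NULL` when unavailable.
#' @export
residuals_ka <- function(profile, fit) {
  if (is.null(fit)) return(NULL)
  bins <- profile$bins[profile$bins$conc > 0, , drop = FALSE]
  if (nrow(bins) < 3L) return(NULL)
  peak <- which.max(bins$conc)
  pre <- which(seq_len(nrow(bins)) < peak)

  resid_at <- function(idx) {
    t <- bins$tad[idx]
    exp(fit$beta0 - fit$lambda_z * t) - bins$conc[idx]
  }
  t <- bins$tad[pre]
  resid <- resid_at(pre)
  ok <- resid > 0
  if (sum(ok) >= 2L) {
    rfit <- stats::lm(log(resid[ok]) ~ t[ok])
    ka <- -unname(stats::coef(rfit)[2L])
    t <- t[ok]; resid <- resid[ok]
  } else {
    # anchored fallback: least squares for Ka with intercept fixed at
    # beta0, over positive residuals at or before the peak bin
    upto <- which(seq_len(nrow(bins)) <= peak)
    t <- bins$tad[upto]
    resid <- resid_at(upto)
    ok <- resid > 0 & t > 0
    if (!sum(ok)) return(NULL)
    t <- t[ok]; resid <- resid[ok]
    ka <- sum(t * (fit$beta0 - log(resid))) / sum(t^2)
  }
  if (!is.finite(ka) || ka <= 0) return(NULL)

  v <- 1 / exp(fit$beta0)   # Dose/C_extrap(0) per unit dose
  structure(list(
    method = "graphical", cl = fit$lambda_z * v, v = v, ka = ka,
    source = list(cl = "lambda_z_times_v", v = "extrapolated_intercept",
                  ka = "method_of_residuals"),
    lambda_z = fit$lambda_z,
    residual_points = data.frame(t = t, c_residual = resid)
  ), class = "pk_onecpt_estimate")
}

#' Graphical one-compartment estimation
#'
#' Applies the graphical methods to pooled first-dose data: the
#' extrapolated-intercept volume for intravenous profiles, or the method
#' of residuals (Ka plus intercept volume) for extravascular profiles. The
#' terminal fit is re-derived on the first-dose group itself when the
#' supplied fit was obtained on a different group.
#'
#' On sparse first-dose profiles where the best-fit window search is
#' infeasible (fewer than three post-peak bins), the terminal line is
#' drawn through the available post-peak bins directly (two points
#' minimum), since the graphical constructions only need the line's slope
#' and intercept.
#'
#' @param annotated a `pk_annotated` object.
#' @param profiles list of pooled profiles (`first_dose` element used).
#' @param fit a `terminal_fit` fitted on the first-dose group (refitted
#'   here when `NULL`).
#' @return a `pk_onecpt_estimate`, or `NULL` when unavailable (e.g. no
#'   first-dose data).
#' @export
graphical_estimate <- function(annotated, profiles, fit = NULL) {
  prof <- profiles$first_dose
  if (!nrow(prof$bins)) return(NULL)
  if (is.null(fit)) fit <- fit_lambda_z(prof)
  if (is.null(fit)) fit <- terminal_line_minimal(prof)
  if (is.null(fit)) return(NULL)
  if (identical(prof$route, "extravascular")) {
    residuals_ka(prof, fit)
  } else {
    graphical_iv(prof, fit)
  }
}

# two-point terminal line for sparse first-dose profiles: post-peak bins
# (the peak itself is admitted for intravenous profiles but excluded for
# extravascular ones, where it is absorption-contaminated), negative slope
# required; returns a terminal_fit-shaped list or NULL
terminal_line_minimal <- function(profile) {
  bins <- profile$bins[profile$bins$conc > 0, , drop = FALSE]
  if (nrow(bins) < 2L) return(NULL)
  peak <- which.max(bins$conc)
  post <- if (identical(profile$route, "extravascular")) {
    which(seq_len(nrow(bins)) > peak)
  } else {
    which(seq_len(nrow(bins)) >= peak)
  }
  if (length(post) < 2L) return(NULL)
  fit <- stats::lm(log(conc) ~ tad, data = bins[post, , drop = FALSE])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) return(NULL)
  structure(list(lambda_z = -slope,
                 beta0 = unname(stats::coef(fit)[1L]),
                 t_half = log(2) / -slope,
                 n_points = length(post),
                 adj_r2 = NA_real_,
                 point_indices = post,
                 windows = NULL),
            class = "terminal_fit")
}
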