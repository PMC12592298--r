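#' Linear-up log-down trapezoidal AUC
#'
#' Integrates a concentration-time profile segment by segment: rising or
#' flat segments use the linear trapezoid `(Ci + Cj)/2 * dt`; strictly
#' falling segments with both endpoints positive use the log trapezoid
#' `(Ci - Cj)/ln(Ci/Cj) * dt` (exact on mono-exponential decay); a fall to
#' zero reverts to the linear rule.
#'
#' @param times strictly increasing sampling times.
#' @param concs non-negative concentrations.
#' @return the AUC over the observed range; `NA` with fewer than 2 points.
#' @examples
#' auc_linuplogdown(c(0, 1, 2), c(0, 10, 5))  # 5 + 5/log(2)
#' @export
auc_linuplogdown <- function(times, concs) {
  stopifnot(length(times) == length(concs))
  if (length(times) < 2L) return(NA_real_)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(concs < 0)) stop("negative concentrations")
  c1 <- concs[-length(concs)]
  c2 <- concs[-1L]
  dt <- diff(times)
  seg <- ifelse(c2 < c1 & c2 > 0,
                (c1 - c2) / log(c1 / c2) * dt,
                (c1 + c2) / 2 * dt)
  sum(seg)
}

# log-down interpolation/extrapolation of a falling profile at time t,
# given the last two (or terminal-fit) log-slope
logdown_value <- function(t_from, c_from, lambda_z, t) {
  c_from * exp(-lambda_z * (t - t_from))
}

#' Naive pooled non-compartmental analysis
#'
#' Computes clearance and the terminal-phase volume from a dose-normalized
#' pooled profile. For single-dose data `CL = 1 / AUC(0-Inf)` with
#' `AUC(0-Inf) = AUC(0-tlast) + Clast / lambda_z`; for multiple-dose data
#' `CL = 1 / AUC(0-tau)`, integrating the pooled TAD profile over one
#' dosing interval (log-down extension at `lambda_z` when the last bin
#' falls short of `tau`, log interpolation when it extends beyond). In both
#' cases `Vz = CL / lambda_z`. The dose is standardized to 1 by the
#' pooling step, so the AUC is per unit dose.
#'
#' The profile is anchored at TAD 0 before integration: a bolus profile
#' starts at the back-extrapolated terminal intercept, an infusion or
#' extravascular single-dose profile at zero, and a multiple-dose
#' extravascular profile at its own interval-end value (steady-state
#' continuity).
#'
#' @param profile a dose-normalized `pooled_profile`.
#' @param dosing `"single"` or `"multiple"`.
#' @param fit a `terminal_fit` for the same data.
#' @param tau dosing interval for multiple dosing (the most common
#'   interval in the dataset).
#' @return an object of class `pk_onecpt_estimate` with `cl`, `v` (= Vz),
#'   `auc` details and a `warnings` character vector (e.g. when more than
#'   half of `AUC(0-Inf)` is extrapolated); `NULL` when the AUC cannot be
#'   formed.
#' @export
nca_onecpt <- function(profile, dosing = c("single", "multiple"), fit,
                       tau = NA_real_) {
  dosing <- match.arg(dosing)
  if (is.null(fit)) return(NULL)
  bins <- profile$bins[profile$bins$conc > 0, , drop = FALSE]
  if (nrow(bins) < 2L) return(NULL)
  route <- profile$route
  times <- bins$tad
  concs <- bins$conc
  warnings <- character(0)

  lambda_z <- fit$lambda_z

  if (dosing == "multiple" && (!is.finite(tau) || tau <= 0)) return(NULL)

  # anchor the profile at TAD 0
  if (times[1L] > 0) {
    c0 <- if (identical(route, "bolus")) {
      exp(fit$beta0)
    } else if (dosing == "multiple") {
      # steady-state continuity: C(0) = C(tau)
      if (times[length(times)] >= tau) {
        i <- max(which(times <= tau))
        if (times[i] == tau) concs[i]
        else logdown_value(times[i], concs[i], lambda_z, tau)
      } else {
        logdown_value(times[length(times)], concs[length(concs)],
                      lambda_z, tau)
      }
    } else {
      0
    }
    times <- c(0, times)
    concs <- c(c0, concs)
  }

  if (dosing == "single") {
    auc_t <- auc_linuplogdown(times, concs)
    c_last <- concs[length(concs)]
    auc_extra <- c_last / lambda_z
    auc_inf <- auc_t + auc_extra
    extrap_frac <- auc_extra / auc_inf
    if (extrap_frac >= 0.5) {
      warnings <- c(warnings,
                    sprintf("%.0f%% of AUC(0-Inf) is extrapolated",
                            100 * extrap_frac))
    }
    auc <- auc_inf
    auc_detail <- list(auc_0_t = auc_t, auc_0_inf = auc_inf,
                       c_last = c_last, extrapolated_fraction = extrap_frac)
  } else {
    t_last <- times[length(times)]
    if (t_last < tau) {
      c_tau <- logdown_value(t_last, concs[length(concs)], lambda_z, tau)
      times <- c(times, tau)
      concs <- c(concs, c_tau)
    } else if (t_last > tau) {
      keep <- times <= tau
      if (max(times[keep]) < tau) {
        i <- max(which(keep))
        c_tau <- logdown_value(times[i], concs[i], lambda_z, tau)
        times <- c(times[keep], tau)
        concs <- c(concs[keep], c_tau)
      } else {
        times <- times[keep]
        concs <- concs[keep]
      }
    }
    auc <- auc_linuplogdown(times, concs)
    auc_detail <- list(auc_0_tau = auc, c_last = concs[length(concs)])
  }
  if (!is.finite(auc) || auc <= 0) return(NULL)

  cl <- 1 / auc          # dose standardized to 1
  vz <- cl / lambda_z
  structure(list(
    method = "nca", cl = cl, v = vz, ka = NA_real_,
    source = list(cl = paste0("auc_", dosing), v = "cl_over_lambda_z",
                  ka = NA_character_),
    auc = auc_detail, lambda_z = lambda_z, dosing = dosing,
    warnings = warnings
  ), class = "pk_onecpt_estimate")
}

#' Wagner-Nelson estimation of the absorption rate constant
#'
#' Mass-balance estimate of Ka from an extravascular pooled profile: the
#' fraction absorbed is `F(t) = (Ct + ke * AUC(0-t)) / (ke * AUC(0-Inf))`
#' with the cumulative AUC computed by the plain linear trapezoid, and Ka
#' is minus the slope of `ln(1 - F(t))` regressed on time over the
#' absorption-phase bins (`t <= Tmax`) with positive fraction remaining.
#'
#' @param profile a `pooled_profile` (extravascular).
#' @param ke elimination rate constant, 1/h.
#' @return list with `ka`, the number of points used (`n_used`), and the
#'   per-point table (`t`, `frac_remaining`); `NULL` when fewer than 2
#'   usable absorption-phase points exist.
#' @export
wagner_nelson_ka <- function(profile, ke) {
  stopifnot(is.finite(ke), ke > 0)
  bins <- profile$bins[profile$bins$conc > 0, , drop = FALSE]
  if (nrow(bins) < 3L) return(NULL)
  t <- bins$tad
  conc <- bins$conc

  # cumulative linear-trapezoid AUC from the first bin
  cum <- c(0, cumsum((conc[-1L] + conc[-length(conc)]) / 2 * diff(t)))
  auc_inf <- cum[length(cum)] + conc[length(conc)] / ke
  frac_abs <- (conc + ke * cum) / (ke * auc_inf)
  frac_rem <- 1 - frac_abs

  t_max <- t[which.max(conc)]
  use <- which(t <= t_max & frac_rem > 0)
  if (length(use) < 2L) return(NULL)
  fit <- stats::lm(log(frac_rem[use]) ~ t[use])
  ka <- -unname(stats::coef(fit)[2L])
  if (!is.finite(ka) || ka <= 0) return(NULL)
  list(ka = ka, n_used = length(use),
       points = data.frame(t = t[use], frac_remaining = frac_rem[use]))
}

#' Pooled NCA estimation of CL, Vz and Ka
#'
#' Orchestrates the naive pooled NCA method: multiple-dose analysis on the
#' multi-dose pooled group when multi-dose observations exist (with `tau`
#' the most common dosing interval), otherwise single-dose analysis on the
#' first-dose group; either falls back to the mixed group when its
#' preferred group is empty. For extravascular data Ka is estimated by the
#' Wagner-Nelson method on the same profile.
#'
#' @param annotated a `pk_annotated` object.
#' @param profiles list of the three pooled profiles (`first_dose`,
#'   `multi_dose`, `mixed`) as returned by [pooled_halflife()].
#' @param fit a `terminal_fit`.
#' @return a `pk_onecpt_estimate`, or `NULL` when the method is
#'   unavailable.
#' @export
nca_estimate <- function(annotated, profiles, fit) {
  if (is.null(fit)) return(NULL)
  obs <- annotated$observations
  multi <- any(obs$occasion == "multi_dose")
  if (multi) {
    prof <- profiles$multi_dose
    if (!nrow(prof$bins)) prof <- profiles$mixed
    tau <- modal_tau(annotated)
    res <- nca_onecpt(prof, "multiple", fit, tau)
  } else {
    prof <- profiles$first_dose
    if (!nrow(prof$bins)) prof <- profiles$mixed
    res <- nca_onecpt(prof, "single", fit)
  }
  if (is.null(res)) return(NULL)
  if (identical(prof$route, "extravascular")) {
    wn <- wagner_nelson_ka(prof, fit$lambda_z)
    if (!is.null(wn)) {
      res$ka <- wn$ka
      res$source$ka <- "wagner_nelson"
      res$wagner_nelson <- wn
    }
  }
  res
}

#' Most common dosing interval in a dataset
#'
#' @param annotated a `pk_annotated` object.
#' @return the modal inter-dose interval (h), or `NA` when no subject
#'   received more than one dose.
#' @export
modal_tau <- function(annotated) {
  taus <- annotated$doses$tau
  taus <- taus[is.finite(taus) & taus > 0]
  if (!length(taus)) return(NA_real_)
  tab <- sort(table(taus), decreasing = TRUE)
  as.numeric(names(tab)[1L])
}
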