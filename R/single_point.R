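#' Fraction eliminated after a multiple of the half-life
#'
#' Under linear elimination the fraction of drug eliminated after
#' `f_halflife` half-lives is `1 - exp(-ln(2) * f_halflife)`. At 20% of the
#' half-life this is about 13%, which motivates the eligibility window used
#' by the single-point volume calculations: a sample drawn within
#' 0.2 half-lives of the dose still approximates the time-zero
#' concentration.
#'
#' @param f_halflife elapsed time expressed in half-lives (>= 0).
#' @return fraction eliminated, in `[0, 1)`.
#' @examples
#' elimination_fraction(0.2)  # ~0.13
#' @export
elimination_fraction <- function(f_halflife) {
  if (any(f_halflife < 0)) stop("`f_halflife` must be non-negative")
  1 - exp(-log(2) * f_halflife)
}

#' Single-point volume of distribution from the first sample
#'
#' `Vd = Dose / C1`, using the first concentration observed after the
#' initial dose. Applicable to intravenous doses only, and only when the
#' sample was drawn within 20% of the half-life after dosing (so that `C1`
#' approximates the time-zero concentration).
#'
#' @param dose dose amount.
#' @param c1 first observed concentration (> 0).
#' @param t1_tad time after dose of that sample, h.
#' @param t_half elimination half-life, h (`NA` makes the point
#'   ineligible).
#' @param route `"bolus"`, `"infusion"` or `"extravascular"`.
#' @return the volume, or `NA` when the point is ineligible.
#' @export
sp_vd_first_point <- function(dose, c1, t1_tad, t_half, route) {
  if (!route %in% c("bolus", "infusion")) return(NA_real_)
  if (!is.finite(t_half) || t_half <= 0) return(NA_real_)
  if (!is.finite(c1) || c1 <= 0) return(NA_real_)
  if (t1_tad > 0.2 * t_half) return(NA_real_)
  dose / c1
}

#' Steady-state clearance from peak/trough concentrations
#'
#' `CL = Dose / (Css,avg * tau)` with `Css,avg = (Css,max + Css,min)/2`.
#' When only one extreme was observed, the other is reconstructed from the
#' elimination rate constant -- `Css,min = Css,max * exp(-ke * tau)` for a
#' bolus, or `exp(-ke * (tau - t_inf))` for an infusion -- and the average
#' is taken from the reconstructed pair. Single-extreme completion is only
#' applicable to intravenous dosing.
#'
#' @param window list/data frame with `c_ss_max` and/or `c_ss_min` (one may
#'   be `NA`), `tau`, `t_inf` and `route`.
#' @param dose dose amount administered each interval.
#' @param ke elimination rate constant 1/h (needed only for single-extreme
#'   completion).
#' @return clearance, or `NA` when ineligible.
#' @examples
#' sp_cl_steady_state(list(c_ss_max = 10, c_ss_min = 6, tau = 12,
#'                         t_inf = 0, route = "bolus"), dose = 100)
#' @export
sp_cl_steady_state <- function(window, dose, ke = NA_real_) {
  cmax <- window$c_ss_max %||% NA_real_
  cmin <- window$c_ss_min %||% NA_real_
  tau <- window$tau
  if (!is.finite(tau) || tau <= 0) return(NA_real_)
  route <- window$route
  if (is.na(cmax) || is.na(cmin)) {
    if (!route %in% c("bolus", "infusion")) return(NA_real_)
    if (!is.finite(ke) || ke <= 0) return(NA_real_)
    decay <- if (route == "infusion") {
      t_inf <- window$t_inf %||% 0
      exp(-ke * (tau - t_inf))
    } else {
      exp(-ke * tau)
    }
    if (is.na(cmin)) cmin <- cmax * decay
    else if (is.na(cmax)) cmax <- cmin / decay
  }
  if (!is.finite(cmax) || !is.finite(cmin) || cmax <= 0 || cmin <= 0) {
    return(NA_real_)
  }
  c_avg <- (cmax + cmin) / 2
  dose / (c_avg * tau)
}

#' Volume of distribution from clearance and half-life
#'
#' Extended-phase relation `Vd = CL * t_half / ln(2)`.
#'
#' @param cl clearance, L/h (> 0).
#' @param t_half half-life, h (> 0).
#' @return volume, L.
#' @export
sp_vd_from_halflife <- function(cl, t_half) {
  stopifnot(is.finite(cl), cl > 0, is.finite(t_half), t_half > 0)
  cl * t_half / log(2)
}

#' Steady-state accumulation ratio
#'
#' `Rac = 1 / (1 - exp(-ke * tau))`; the factor by which repeated dosing at
#' interval `tau` accumulates concentrations relative to a single dose.
#'
#' @param ke elimination rate constant, 1/h (> 0).
#' @param tau dosing interval, h (> 0).
#' @return accumulation ratio (>= 1).
#' @export
accumulation_ratio <- function(ke, tau) {
  stopifnot(ke > 0, tau > 0)
  1 / (1 - exp(-ke * tau))
}

#' Central volume from an observed Cmax
#'
#' `Vc = Dose / Cmax`, where the Cmax sample must fall within 20% of the
#' half-life after dosing. For multiple-dose (steady-state) data the
#' observed `Cmax,ss` is first converted back to a single-dose `Cmax` by
#' dividing by the accumulation ratio.
#'
#' @param dose dose amount.
#' @param c_max_obs observed maximum concentration (> 0).
#' @param occasion `"first_dose"` or `"multi_dose"`.
#' @param ke elimination rate constant (needed for the multi-dose
#'   correction).
#' @param tau dosing interval (multi-dose).
#' @param tad_at_cmax time after dose of the Cmax sample.
#' @param t_half half-life, h.
#' @return the central volume, or `NA` when ineligible.
#' @export
sp_vc_from_cmax <- function(dose, c_max_obs, occasion, ke = NA_real_,
                            tau = NA_real_, tad_at_cmax, t_half) {
  if (!is.finite(c_max_obs) || c_max_obs <= 0) return(NA_real_)
  if (!is.finite(t_half) || t_half <= 0) return(NA_real_)
  if (tad_at_cmax > 0.2 * t_half) return(NA_real_)
  if (identical(occasion, "multi_dose")) {
    if (!is.finite(ke) || !is.finite(tau) || ke <= 0 || tau <= 0) {
      return(NA_real_)
    }
    c_max_obs <- c_max_obs / accumulation_ratio(ke, tau)
  }
  dose / c_max_obs
}

#' Solve the one-compartment oral equation for Ka
#'
#' Finds the absorption rate constant for which the analytic
#' one-compartment first-order-absorption solution passes through an
#' observed absorption-phase concentration, by root-finding (Brent's
#' method, `uniroot`) over `ka` in `(ke * (1 + 1e-6), 1000]`. The lower
#' bracket guard keeps the search away from the `ka = ke` singularity of
#' the analytic solution. Bioavailability is fixed at 1.
#'
#' For single doses the equation is
#' `C(t) = D ka / (V (ka - ke)) (exp(-ke t) - exp(-ka t))`; at steady state
#' under interval `tau` each exponential is divided by
#' `1 - exp(-k tau)`.
#'
#' @param conc observed concentration (> 0).
#' @param t time after dose of the observation, h.
#' @param dose dose amount.
#' @param cl,vd clearance and volume from the preceding steps; `ke = cl/vd`.
#' @param tau dosing interval for steady-state dosing; `NA` for a single
#'   dose.
#' @param tol convergence tolerance on `ka`.
#' @return the root, or `NA` when no sign change exists in the bracket
#'   (the observation is then skipped).
#' @export
solve_ka_onecpt <- function(conc, t, dose, cl, vd, tau = NA_real_,
                            tol = 1e-8) {
  stopifnot(cl > 0, vd > 0, conc > 0, t > 0)
  ke <- cl / vd
  f <- function(ka) {
    if (is.finite(tau) && tau > 0) {
      dose * ka / (vd * (ka - ke)) *
        (exp(-ke * t) / (1 - exp(-ke * tau)) -
           exp(-ka * t) / (1 - exp(-ka * tau))) - conc
    } else {
      dose * ka / (vd * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)) - conc
    }
  }
  lo <- ke * (1 + 1e-6)
  hi <- 1000
  if (lo >= hi) return(NA_real_)
  flo <- f(lo)
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Trimmed geometric mean
#'
#' Summarizes per-individual parameter values robustly: with total trim
#' fraction `trim`, the `floor(n * trim / 2)` smallest and largest values
#' are dropped (2.5% per tail at the default 0.05) and the geometric mean
#' of the remainder is returned. Non-positive values are excluded with a
#' warning before trimming.
#'
#' @param values numeric vector.
#' @param trim total trim fraction (default 0.05).
#' @return the trimmed geometric mean, or `NA` for an empty input.
#' @export
trimmed_geomean <- function(values, trim = 0.05) {
  values <- values[is.finite(values)]
  if (any(values <= 0)) {
    warning("excluding ", sum(values <= 0), " non-positive value(s)")
    values <- values[values > 0]
  }
  n <- length(values)
  if (!n) return(NA_real_)
  k <- floor(n * trim / 2)
  if (k > 0) {
    values <- sort(values)[(k + 1):(n - k)]
  }
  exp(mean(log(values)))
}

#' Adaptive single-point estimation of CL, V and Ka
#'
#' Runs the two-phase adaptive single-point method on an annotated
#' dataset:
#'
#' * **Base phase** -- per subject, `Vd = Dose/C1` from the first sample
#'   after the initial dose (intravenous, within 0.2 half-lives), and
#'   `CL = Dose/(Css,avg * tau)` from peak/trough concentrations in the
#'   most recent steady-state interval (a single observed extreme is
#'   completed via the elimination rate constant for intravenous dosing).
#' * **Extended phase** -- missing CL or Vd is derived from the pooled
#'   half-life via `Vd = CL t_half / ln 2`; when both are missing, a
#'   Cmax-based central volume (accumulation-corrected for multiple
#'   dosing) substitutes for Vd. For extravascular data Ka is solved per
#'   absorption-phase observation from the analytic one-compartment
#'   equations; per-observation roots are combined into a per-individual
#'   geometric mean.
#'
#' Individual values are summarized across subjects by the 0.05-trimmed
#' geometric mean.
#'
#' @param annotated a `pk_annotated` object (steady-state flags ideally
#'   refreshed via [update_ss_flags()]).
#' @param t_half pooled elimination half-life, h (may be `NA`; several
#'   sub-methods then become ineligible).
#' @param peak_tad pooled-profile peak time; observations with
#'   `tad <= peak_tad` count as absorption phase for the Ka root-finding.
#' @return an object of class `pk_onecpt_estimate` with elements `method`
#'   (`"single_point"`), `cl`, `v`, `ka`, `vc` (each `NA` when
#'   unavailable), per-parameter `source` labels, `n_used` counts and a
#'   `per_individual` diagnostics table.
#' @export
single_point_estimate <- function(annotated, t_half, peak_tad = NA_real_) {
  obs <- annotated$observations
  ke <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else NA_real_

  per <- list()
  for (sid in unique(obs$id)) {
    o <- obs[obs$id == sid, , drop = FALSE]
    rec <- list(id = sid, vd = NA_real_, cl = NA_real_, vc = NA_real_,
                ka = NA_real_)

    # base phase: Vd from first sample after the initial dose; for an
    # infusion the clock starts at the end of the infusion (a sample drawn
    # mid-infusion does not approximate Dose/Vd)
    fd <- o[o$dose_number == 1L, , drop = FALSE]
    if (nrow(fd)) {
      if (identical(fd$route[1L], "infusion")) {
        fd <- fd[fd$tad >= fd$t_inf, , drop = FALSE]
      }
      if (nrow(fd)) {
        fd1 <- fd[which.min(fd$tad), ]
        tad_eff <- fd1$tad - if (fd1$route == "infusion") fd1$t_inf else 0
        rec$vd <- sp_vd_first_point(fd1$dose_amount, fd1$dv, tad_eff,
                                    t_half, fd1$route)
      }
    }

    # base phase: CL from the most recent steady-state interval. For
    # intravenous dosing with a known ke, every sample in the interval is
    # decay-corrected back to the interval peak (single-point completion,
    # averaged across the interval's samples); without ke, or for
    # extravascular dosing, the observed extremes stand in for the true
    # peak and trough (requires at least two samples when extravascular).
    ss <- o[o$at_steady_state & is.finite(o$tau) & o$tau > 0 &
              is.finite(o$dv) & o$dv > 0, , drop = FALSE]
    if (nrow(ss)) {
      last_int <- max(ss$dose_number)
      w <- ss[ss$dose_number == last_int, , drop = FALSE]
      tau <- w$tau[1L]
      iv <- w$route[1L] %in% c("bolus", "infusion")
      win <- NULL
      if (iv && is.finite(ke)) {
        t_inf <- w$t_inf[1L]
        wp <- w[w$tad >= t_inf, , drop = FALSE]
        if (nrow(wp)) {
          cmax_each <- wp$dv * exp(ke * (wp$tad - t_inf))
          win <- list(c_ss_max = exp(mean(log(cmax_each))),
                      c_ss_min = NA_real_, tau = tau, t_inf = t_inf,
                      route = w$route[1L])
        }
      } else if (nrow(w) >= 2L) {
        win <- list(c_ss_max = max(w$dv), c_ss_min = min(w$dv), tau = tau,
                    t_inf = w$t_inf[1L], route = w$route[1L])
      }
      if (!is.null(win)) {
        rec$cl <- sp_cl_steady_state(win, w$dose_amount[1L], ke)
      }
    }

    # extended phase: Cmax-based central volume
    if (is.finite(t_half)) {
      cand <- o[is.finite(o$dv) & o$dv > 0, , drop = FALSE]
      if (nrow(cand)) {
        imax <- which.max(cand$dv)
        cm <- cand[imax, ]
        rec$vc <- sp_vc_from_cmax(cm$dose_amount, cm$dv, cm$occasion, ke,
                                  cm$tau, cm$tad, t_half)
      }
    }
    per[[sid]] <- rec
  }
  per_df <- do.call(rbind, lapply(per, function(r)
    data.frame(id = r$id, vd = r$vd, cl = r$cl, vc = r$vc,
               stringsAsFactors = FALSE)))

  cl <- trimmed_geomean(per_df$cl)
  vd <- trimmed_geomean(per_df$vd)
  vc <- trimmed_geomean(per_df$vc)
  src <- list(cl = if (is.finite(cl)) "base" else NA_character_,
              v = if (is.finite(vd)) "base" else NA_character_)

  # extended phase completion of CL / Vd from the pooled half-life
  if (is.finite(cl) && !is.finite(vd) && is.finite(t_half)) {
    vd <- sp_vd_from_halflife(cl, t_half)
    src$v <- "extended_halflife"
  } else if (is.finite(vd) && !is.finite(cl) && is.finite(t_half)) {
    cl <- vd * log(2) / t_half
    src$cl <- "extended_halflife"
  } else if (!is.finite(cl) && !is.finite(vd) && is.finite(vc) &&
             is.finite(t_half)) {
    vd <- vc
    cl <- vd * log(2) / t_half
    src$v <- "extended_vc"
    src$cl <- "extended_halflife"
  }

  # extended phase: Ka for extravascular data
  ka <- NA_real_
  ka_per <- NULL
  extravasc <- any(obs$route == "extravascular")
  if (extravasc && is.finite(cl) && is.finite(vd) && is.finite(peak_tad)) {
    ka_vals <- vapply(unique(obs$id), function(sid) {
      o <- obs[obs$id == sid & obs$route == "extravascular" &
                 is.finite(obs$dv) & obs$dv > 0, , drop = FALSE]
      o <- o[o$tad <= peak_tad & o$tad > 0, , drop = FALSE]
      if (!nrow(o)) return(NA_real_)
      roots <- vapply(seq_len(nrow(o)), function(i) {
        tau_i <- if (identical(o$occasion[i], "multi_dose") &&
                     o$at_steady_state[i]) o$tau[i] else NA_real_
        solve_ka_onecpt(o$dv[i], o$tad[i], o$dose_amount[i], cl, vd, tau_i)
      }, numeric(1))
      roots <- roots[is.finite(roots) & roots > 0]
      if (!length(roots)) return(NA_real_)
      exp(mean(log(roots)))
    }, numeric(1))
    ka_per <- ka_vals
    ka <- suppressWarnings(trimmed_geomean(ka_vals))
  }

  structure(list(
    method = "single_point",
    cl = cl, v = vd, ka = ka, vc = vc,
    source = list(cl = src$cl, v = src$v,
                  ka = if (is.finite(ka)) "extended_ka" else NA_character_),
    n_used = list(cl = sum(is.finite(per_df$cl)),
                  v = sum(is.finite(per_df$vd)),
                  vc = sum(is.finite(per_df$vc)),
                  ka = if (is.null(ka_per)) 0L else sum(is.finite(ka_per))),
    per_individual = per_df
  ), class = "pk_onecpt_estimate")
}

#' @export
print.pk_onecpt_estimate <- function(x, ...) {
  fmt <- function(v) if (is.finite(v)) sprintf("%.4g", v) else "--"
  cat(sprintf("%s estimate: CL = %s L/h, V = %s L, Ka = %s 1/h",
              x$method, fmt(x$cl), fmt(x$v), fmt(x$ka %||% NA_real_)))
  if (!is.null(x$vc) && is.finite(x$vc)) cat(sprintf(", Vc = %s L", fmt(x$vc)))
  cat("\n")
  invisible(x)
}
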