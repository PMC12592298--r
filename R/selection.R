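#' Relative root mean squared error
#'
#' `rRMSE [%] = 100 * sqrt(mean(((p - o) / ((p + o)/2))^2))`: squared
#' differences scaled by the squared pointwise mean of prediction and
#' observation. The metric is symmetric in its arguments, invariant under
#' common positive scaling, and bounded by 200%.
#'
#' Pairs where `predicted + observed == 0` carry no information under this
#' scaling and are excluded; non-finite pairs are excluded too.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @param metric `"rrmse_pairwise"` (default, the pointwise-mean
#'   denominator above), `"rrmse_obsmean"` (denominator = mean of the
#'   observed values) or `"mape"` (mean absolute percentage error).
#' @return the score in percent, or `NA` when no usable pair remains.
#' @examples
#' rrmse(3, 1)   # 100
#' rrmse(0, 5)   # 200
#' @export
rrmse <- function(predicted, observed,
                  metric = c("rrmse_pairwise", "rrmse_obsmean", "mape")) {
  metric <- match.arg(metric)
  stopifnot(length(predicted) == length(observed))
  ok <- is.finite(predicted) & is.finite(observed)
  p <- predicted[ok]
  o <- observed[ok]
  if (metric == "rrmse_pairwise") {
    keep <- (p + o) != 0
    p <- p[keep]; o <- o[keep]
    if (!length(p)) return(NA_real_)
    100 * sqrt(mean(((p - o)^2) / (((p + o) / 2)^2)))
  } else if (metric == "rrmse_obsmean") {
    if (!length(o) || mean(o) == 0) return(NA_real_)
    100 * sqrt(mean((p - o)^2)) / mean(o)
  } else {
    keep <- o != 0
    p <- p[keep]; o <- o[keep]
    if (!length(p)) return(NA_real_)
    100 * mean(abs((p - o) / o))
  }
}

#' Select the recommended one-compartment parameter set
#'
#' Scores every complete candidate parameter set -- the per-method sets
#' from the adaptive single-point, pooled NCA and graphical methods, plus
#' all cross-method hybrids (the Cartesian product of the available
#' per-parameter values, any available volume being eligible as the
#' candidate V) -- by simulating each subject's actual dose and sampling
#' schedule under the linear one-compartment model and computing the
#' rRMSE against the individual-level observations. The candidate with
#' the lowest score wins; ties within 1e-9 are broken by method priority
#' NCA > single-point > graphical > hybrids.
#'
#' @param estimates named list of `pk_onecpt_estimate` objects (entries
#'   may be `NULL` for unavailable methods); expected names
#'   `single_point`, `nca`, `graphical`.
#' @param annotated a `pk_annotated` object (individual-level scoring
#'   data).
#' @param metric scoring metric, see [rrmse()].
#' @return an object of class `scored_candidate`: `params` (named list
#'   `cl`, `v`, `ka`), per-parameter `source`, `rrmse_pct`, `n_obs`, and
#'   the full `candidates` score table. Errors when no complete candidate
#'   exists.
#' @export
select_base_params <- function(estimates, annotated,
                               metric = "rrmse_pairwise") {
  obs <- annotated$observations
  needs_ka <- any(obs$route == "extravascular")
  avail <- Filter(Negate(is.null), estimates)
  if (!length(avail)) stop("no method produced estimates")

  complete <- function(e) {
    is.finite(e$cl) && e$cl > 0 && is.finite(e$v) && e$v > 0 &&
      (!needs_ka || (is.finite(e$ka) && e$ka > 0))
  }

  cands <- list()
  add <- function(cl, v, ka, src, label) {
    key <- paste(signif(cl, 12), signif(v, 12), signif(ka, 12))
    if (!is.null(cands[[key]])) return(invisible(NULL))
    cands[[key]] <<- list(cl = cl, v = v, ka = ka, source = src,
                          label = label)
    invisible(NULL)
  }

  # pure per-method sets first (priority order), then hybrids
  for (m in c("nca", "single_point", "graphical")) {
    e <- avail[[m]]
    if (!is.null(e) && complete(e)) {
      add(e$cl, e$v, if (needs_ka) e$ka else NA_real_,
          list(cl = m, v = m, ka = if (needs_ka) m else NA_character_), m)
    }
  }
  cl_pool <- list(); v_pool <- list(); ka_pool <- list()
  for (m in names(avail)) {
    e <- avail[[m]]
    if (is.finite(e$cl) && e$cl > 0) cl_pool[[m]] <- e$cl
    if (is.finite(e$v) && e$v > 0) v_pool[[paste0(m, ":v")]] <- e$v
    if (!is.null(e$vc) && is.finite(e$vc) && e$vc > 0) {
      v_pool[[paste0(m, ":vc")]] <- e$vc
    }
    if (needs_ka && is.finite(e$ka) && e$ka > 0) ka_pool[[m]] <- e$ka
  }
  if (length(cl_pool) && length(v_pool) && (!needs_ka || length(ka_pool))) {
    for (mc in names(cl_pool)) for (mv in names(v_pool)) {
      if (needs_ka) {
        for (mk in names(ka_pool)) {
          add(cl_pool[[mc]], v_pool[[mv]], ka_pool[[mk]],
              list(cl = mc, v = mv, ka = mk), "hybrid")
        }
      } else {
        add(cl_pool[[mc]], v_pool[[mv]], NA_real_,
            list(cl = mc, v = mv, ka = NA_character_), "hybrid")
      }
    }
  }
  if (!length(cands)) {
    stop("no complete candidate parameter set (CL, V",
         if (needs_ka) ", Ka" else "", ") from any method")
  }

  scores <- vapply(cands, function(cand) {
    pred <- tryCatch(
      predict_profiles(list(cl = cand$cl, v = cand$v, ka = cand$ka),
                       annotated),
      error = function(e) rep(NA_real_, nrow(obs)))
    rrmse(pred, obs$dv, metric)
  }, numeric(1))
  scores[!is.finite(scores)] <- Inf
  if (all(!is.finite(scores) | scores == Inf)) {
    stop("no candidate could be scored")
  }
  # lowest score wins; earlier (higher-priority) candidates win ties
  best <- which(scores <= min(scores) + 1e-9)[1L]
  cand <- cands[[best]]

  tab <- data.frame(
    label = vapply(cands, `[[`, "", "label"),
    cl = vapply(cands, `[[`, 0, "cl"),
    v = vapply(cands, `[[`, 0, "v"),
    ka = vapply(cands, function(x) x$ka %||% NA_real_, 0),
    rrmse_pct = unname(scores),
    row.names = NULL
  )
  structure(list(
    params = list(cl = cand$cl, v = cand$v, ka = cand$ka),
    source = cand$source,
    label = cand$label,
    rrmse_pct = unname(scores[best]),
    n_obs = sum(is.finite(obs$dv)),
    metric = metric,
    candidates = tab
  ), class = "scored_candidate")
}

#' @export
print.scored_candidate <- function(x, ...) {
  fmt <- function(v) if (is.finite(v)) sprintf("%.4g", v) else "--"
  cat(sprintf(
    "Selected parameter set (%s, rRMSE = %.3f%% over %d obs):\n",
    x$label, x$rrmse_pct, x$n_obs))
  cat(sprintf("  CL = %s [%s]  V = %s [%s]  Ka = %s [%s]\n",
              fmt(x$params$cl), x$source$cl,
              fmt(x$params$v), x$source$v,
              fmt(x$params$ka %||% NA_real_), x$source$ka %||% "--"))
  invisible(x)
}
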