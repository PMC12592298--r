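#' Michaelis-Menten sweep grid
#'
#' Builds the candidate grid for Vmax and Km. Km is scaled relative to the
#' maximum observed concentration, by default over the ratio ladder
#' 4:1, 2:1, 1:1, 1:2, 1:4, 1:10, 1:20 (endpoints 4:1 and 1:20, with a
#' log-spaced interior). For each Km, Vmax follows from the
#' Michaelis-Menten relation `CL = Vmax / (Km + C)` evaluated at working
#' concentrations of 0.05, 0.1, 0.25, 0.5 and 0.75 times Cmax, with CL
#' fixed at its Part-1 value: `Vmax = CL * (Km + C)`. The default grid has
#' 7 x 5 = 35 candidates.
#'
#' @param cl clearance from Part 1, L/h.
#' @param c_max maximum observed concentration.
#' @param km_ratios Km : Cmax ratios.
#' @param c_fractions working-concentration fractions of Cmax.
#' @return an object of class `sweep_grid` with `model = "mm"`, the
#'   `candidates` data frame (`vmax`, `km`, `km_ratio`, `c_fraction`) and
#'   the fixed inputs.
#' @export
build_mm_grid <- function(cl, c_max,
                          km_ratios = c(4, 2, 1, 1/2, 1/4, 1/10, 1/20),
                          c_fractions = c(0.05, 0.1, 0.25, 0.5, 0.75)) {
  stopifnot(cl > 0, c_max > 0)
  grid <- expand.grid(km_ratio = km_ratios, c_fraction = c_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  grid$km <- grid$km_ratio * c_max
  grid$vmax <- cl * (grid$km + grid$c_fraction * c_max)
  structure(list(model = "mm", fixed = list(cl = cl, c_max = c_max),
                 candidates = grid[, c("vmax", "km", "km_ratio",
                                       "c_fraction")]),
            class = "sweep_grid")
}

#' Multi-compartment sweep grid
#'
#' Builds the candidate grid for peripheral volumes and
#' inter-compartmental clearances. Each candidate central volume (the
#' Part-1 Vd and, when distinct, the extended-phase Vc) is combined with
#' peripheral volumes from Vc-to-Vp ratios 10:1, 5:1, 2:1, 1:1, 1:2, 1:5
#' and 1:10 (`vp = vc / ratio`) and Q values at 0.25-, 0.5-, 1- and 2-fold
#' of CL. Three-compartment grids repeat the same ratio and fold sets for
#' `vp2` and `q2`.
#'
#' @param cl clearance from Part 1.
#' @param v_candidates numeric vector of candidate central volumes
#'   (deduplicated).
#' @param n_compartments 2 or 3.
#' @param vp_ratios Vc:Vp ratio set.
#' @param q_folds Q-to-CL fold set.
#' @return a `sweep_grid` with `model = "2cpt"` or `"3cpt"` and a
#'   candidate data frame of size `|v| * 7 * 4` (times `7 * 4` again for
#'   three compartments).
#' @export
build_cpt_grid <- function(cl, v_candidates, n_compartments = 2,
                           vp_ratios = c(10, 5, 2, 1, 1/2, 1/5, 1/10),
                           q_folds = c(0.25, 0.5, 1, 2)) {
  stopifnot(cl > 0, n_compartments %in% c(2, 3))
  v_candidates <- unique(v_candidates[is.finite(v_candidates) &
                                        v_candidates > 0])
  stopifnot(length(v_candidates) >= 1)
  if (n_compartments == 2) {
    grid <- expand.grid(vc = v_candidates, vp_ratio = vp_ratios,
                        q_fold = q_folds, KEEP.OUT.ATTRS = FALSE)
  } else {
    grid <- expand.grid(vc = v_candidates, vp_ratio = vp_ratios,
                        q_fold = q_folds, vp2_ratio = vp_ratios,
                        q2_fold = q_folds, KEEP.OUT.ATTRS = FALSE)
  }
  grid$vp <- grid$vc / grid$vp_ratio
  grid$q <- cl * grid$q_fold
  if (n_compartments == 3) {
    grid$vp2 <- grid$vc / grid$vp2_ratio
    grid$q2 <- cl * grid$q2_fold
  }
  structure(list(model = paste0(n_compartments, "cpt"),
                 fixed = list(cl = cl),
                 candidates = grid),
            class = "sweep_grid")
}

#' Run a parameter sweep
#'
#' Simulates every candidate in the grid on each subject's actual dose
#' and sampling schedule with the ODE engine and scores it by rRMSE
#' against the individual-level observations. The lowest-scoring
#' candidate is returned; exact ties go to the smaller grid index, and a
#' candidate whose integration fails is marked with an infinite score
#' rather than aborting the sweep.
#'
#' @param grid a `sweep_grid` from [build_mm_grid()] or
#'   [build_cpt_grid()].
#' @param annotated a `pk_annotated` object.
#' @param fixed named list of non-test parameters held fixed across
#'   candidates: `v` (central volume, Michaelis-Menten sweeps) and `ka`
#'   (extravascular data).
#' @param metric scoring metric, see [rrmse()].
#' @return an object of class `sweep_result`: the winning `params`, its
#'   `rrmse_pct`, the winning row `index`, and the full `scores` table.
#' @export
run_sweep <- function(grid, annotated, fixed = list(),
                      metric = "rrmse_pairwise") {
  stopifnot(inherits(grid, "sweep_grid"))
  cand <- grid$candidates
  if (!nrow(cand)) stop("empty sweep grid")
  obs <- annotated$observations
  extravasc <- any(obs$route == "extravascular")
  if (extravasc && is.null(fixed$ka)) {
    stop("extravascular data require a fixed `ka` for sweeping")
  }

  if (grid$model == "mm") {
    spec <- pk_model_spec(1, "michaelis_menten")
    stopifnot(!is.null(fixed$v))
    mk <- function(row) list(vmax = row$vmax, km = row$km, vc = fixed$v,
                             ka = fixed$ka)
  } else if (grid$model == "2cpt") {
    spec <- pk_model_spec(2, "linear")
    mk <- function(row) list(cl = grid$fixed$cl, vc = row$vc, vp = row$vp,
                             q = row$q, ka = fixed$ka)
  } else {
    spec <- pk_model_spec(3, "linear")
    mk <- function(row) list(cl = grid$fixed$cl, vc = row$vc, vp = row$vp,
                             q = row$q, vp2 = row$vp2, q2 = row$q2,
                             ka = fixed$ka)
  }

  scores <- vapply(seq_len(nrow(cand)), function(i) {
    params <- mk(cand[i, , drop = FALSE])
    pred <- tryCatch(predict_profiles(params, annotated, spec),
                     error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    s <- rrmse(pred, obs$dv, metric)
    if (!is.finite(s)) Inf else s
  }, numeric(1))

  if (all(scores == Inf)) stop("all sweep candidates failed integration")
  best <- which.min(scores)
  out <- cand[best, , drop = FALSE]
  tab <- cand
  tab$rrmse_pct <- scores
  structure(list(
    model = grid$model,
    params = mk(out),
    winner = out,
    index = best,
    rrmse_pct = scores[best],
    scores = tab
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s): winner rRMSE = %.3f%%\n",
              x$model, x$rrmse_pct))
  print(x$winner, row.names = FALSE)
  invisible(x)
}
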