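#' Specify a simulated study design
#'
#' Describes one simulated concentration-time study: route, structural
#' model and true parameters, number of subjects, dosing regimen, sampling
#' template, inter-individual variability and residual error. The built-in
#' sampling templates emulate the usual simulated design families:
#'
#' * `rich` -- every subject sampled at 0.25, 0.5, 1, 2, 4, 6, 8, 12 and
#'   24 h after the (single, by default) dose;
#' * `semi_sparse` -- subjects split round-robin into three groups, each
#'   group contributing two samples within a single dosing interval after
#'   multiple doses, at post-dose pairs (2, 8), (4, 12) and (6, 24) h
#'   drawn from the set 2, 4, 6, 8, 12, 24 h;
#' * `sparse1` -- two (intravenous) or three (oral, adding 2 h) samples at
#'   20 and 24 h after the last of multiple doses;
#' * `sparse2` -- the same sampling times after a single dose;
#' * `custom` -- explicit `sample_times` after the last dose.
#'
#' Multiple-dose templates default to six doses at a 24 h interval so
#' that the final-interval samples are at steady state.
#'
#' @param route `"bolus"`, `"infusion"` or `"extravascular"`.
#' @param model a [pk_model_spec()]; defaults to a linear one-compartment
#'   model with the given route.
#' @param true_params named list of typical-value parameters (`cl`, `vc`,
#'   `ka`, `vmax`, `km`, `vp`, `q`, `vp2`, `q2` as required by the model).
#' @param n_subjects number of subjects (default 30).
#' @param dose_amount dose per administration (default 100).
#' @param tau dosing interval, h (default 24).
#' @param n_doses number of doses; defaults to 1 for `rich`/`sparse2` and
#'   6 for `semi_sparse`/`sparse1`.
#' @param t_inf infusion duration, h (infusion route; default 1).
#' @param sampling template name (above).
#' @param sample_times explicit post-(last-)dose times for
#'   `sampling = "custom"`.
#' @param iiv_omega2 named per-parameter log-scale variances (default 0.1
#'   on `cl` and `vc`, and `ka` when extravascular).
#' @param sigma_add,sigma_prop residual error components (defaults 0.02
#'   and 0.2, a combined error model).
#' @param seed integer seed fixing all randomness.
#' @return a list of class `pk_design`.
#' @export
pk_design <- function(route = c("bolus", "infusion", "extravascular"),
                      model = NULL,
                      true_params = list(cl = 4, vc = 70, ka = 1),
                      n_subjects = 30,
                      dose_amount = 100, tau = 24, n_doses = NULL,
                      t_inf = 1,
                      sampling = c("rich", "semi_sparse", "sparse1",
                                   "sparse2", "custom"),
                      sample_times = NULL,
                      iiv_omega2 = NULL,
                      sigma_add = 0.02, sigma_prop = 0.2,
                      seed = 1L) {
  route <- match.arg(route)
  sampling <- tryCatch(match.arg(sampling), error = function(e)
    stop("unknown sampling template; valid templates: rich, semi_sparse, ",
         "sparse1, sparse2, custom"))
  if (is.null(model)) model <- pk_model_spec(1, "linear", route)
  if (is.null(n_doses)) {
    n_doses <- if (sampling %in% c("semi_sparse", "sparse1")) 6L else 1L
  }
  if (sampling == "custom" && is.null(sample_times)) {
    stop("`sample_times` required for the custom template")
  }
  if (is.null(iiv_omega2)) {
    iiv_omega2 <- list(cl = 0.1, vc = 0.1)
    if (route == "extravascular") iiv_omega2$ka <- 0.1
  }
  structure(list(route = route, model = model, true_params = true_params,
                 n_subjects = n_subjects, dose_amount = dose_amount,
                 tau = tau, n_doses = as.integer(n_doses), t_inf = t_inf,
                 sampling = sampling, sample_times = sample_times,
                 iiv_omega2 = iiv_omega2, sigma_add = sigma_add,
                 sigma_prop = sigma_prop, seed = as.integer(seed)),
            class = "pk_design")
}

sampling_times_for <- function(design, subject_index) {
  last_dose_time <- (design$n_doses - 1L) * design$tau
  post <- switch(design$sampling,
    rich = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24),
    semi_sparse = {
      pairs <- list(c(2, 8), c(4, 12), c(6, 24))
      pairs[[((subject_index - 1L) %% 3L) + 1L]]
    },
    sparse1 = ,
    sparse2 = {
      if (design$route == "extravascular") c(2, 20, 24) else c(20, 24)
    },
    custom = design$sample_times
  )
  last_dose_time + post
}

#' Generate a synthetic PK dataset
#'
#' Draws per-subject parameters lognormally around the design's typical
#' values (`p_i = p * exp(eta)`, `eta ~ N(0, omega2)` per parameter),
#' simulates each subject's concentration-time course with the
#' closed-form engine (linear one-compartment) or the ODE engine
#' (anything else), applies combined residual error
#' `y = f * (1 + eps_prop) + eps_add` with negative results truncated at
#' zero, and emits the records in the NONMEM column convention
#' (`ID, TIME, AMT, RATE, EVID, CMT, DV`). Oral doses go into compartment
#' 1 with observations in compartment 2, so that depot dosing is
#' detectable from the dataset alone.
#'
#' With the seed fixed the output is reproducible; with all variability
#' set to zero every subject equals the deterministic simulation.
#'
#' @param design a [pk_design()].
#' @return a `data.frame` in NONMEM column convention, dose rows first per
#'   subject.
#' @examples
#' d <- pk_design("bolus", sampling = "rich", n_subjects = 3, seed = 7)
#' head(generate_pk_dataset(d))
#' @export
generate_pk_dataset <- function(design) {
  stopifnot(inherits(design, "pk_design"))
  set.seed(design$seed)
  tp <- design$true_params
  onecpt_linear <- design$model$n_compartments == 1 &&
    design$model$elimination == "linear"

  dose_times <- (seq_len(design$n_doses) - 1L) * design$tau
  rate <- if (design$route == "infusion") design$dose_amount / design$t_inf
          else 0
  dose_cmt <- if (design$route == "extravascular") 1L else 1L
  obs_cmt <- if (design$route == "extravascular") 2L else 1L

  rows <- list()
  for (i in seq_len(design$n_subjects)) {
    p_i <- tp
    for (nm in names(design$iiv_omega2)) {
      om2 <- design$iiv_omega2[[nm]]
      if (!is.null(p_i[[nm]]) && om2 > 0) {
        p_i[[nm]] <- p_i[[nm]] * exp(stats::rnorm(1, 0, sqrt(om2)))
      }
    }
    times <- sampling_times_for(design, i)
    de <- data.frame(time = dose_times, amount = design$dose_amount,
                     rate = rate, route = design$route)
    f <- if (onecpt_linear) {
      simulate_onecpt(list(cl = p_i$cl, v = p_i$vc, ka = p_i$ka), de, times)
    } else {
      simulate_pk_ode(design$model, p_i, de, times)
    }
    eps_p <- if (design$sigma_prop > 0)
      stats::rnorm(length(f), 0, design$sigma_prop) else 0
    eps_a <- if (design$sigma_add > 0)
      stats::rnorm(length(f), 0, design$sigma_add) else 0
    dv <- pmax(0, f * (1 + eps_p) + eps_a)

    rows[[length(rows) + 1L]] <- data.frame(
      ID = i, TIME = dose_times, AMT = design$dose_amount, RATE = rate,
      EVID = 1L, CMT = dose_cmt, DV = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      ID = i, TIME = times, AMT = 0, RATE = 0, EVID = 0L, CMT = obs_cmt,
      DV = dv)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$TIME, out$EVID == 0), , drop = FALSE]
  rownames(out) <- NULL
  out
}
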