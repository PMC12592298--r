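#' Run the full initial-estimates pipeline
#'
#' End-to-end orchestration: parse and annotate the dataset, build the
#' pooled profiles and the pooled half-life, run the three
#' one-compartment methods (adaptive single-point, pooled NCA, graphical),
#' select the recommended parameter set by rRMSE (including per-parameter
#' hybrids), run any requested parameter sweeps for Michaelis-Menten or
#' multi-compartment models, and initialize the residual-error and IIV
#' components. Each method may be individually unavailable on a given
#' design; the report records why.
#'
#' @param dataset path to a delimited NONMEM-convention file, or a data
#'   frame, or a `pk_records` object.
#' @param models character vector of extended models to sweep:
#'   any of `"mm"`, `"2cpt"`, `"3cpt"` (default none; the one-compartment
#'   recommendation is always produced).
#' @param route route override passed to [annotate_doses()].
#' @param n_bins number of pooling bins (default 10).
#' @param metric selection metric, see [rrmse()].
#' @param config optional named list overriding tuning knobs:
#'   `sweep.km_ratios`, `sweep.c_fractions`, `sweep.vp_ratios`,
#'   `sweep.q_folds`, `error.cv_fallback`, `error.n_terminal_points`,
#'   `error.omega2`.
#' @return an object of class `pkinit_report`: `selected` (the winning
#'   `scored_candidate`), `methods` (the per-method estimates), `sweeps`
#'   (per requested model), `error_init`, `terminal`, `warnings` and
#'   `provenance`.
#' @examples
#' d <- generate_pk_dataset(pk_design("bolus", sampling = "rich",
#'                                    n_subjects = 6, iiv_omega2 = list(),
#'                                    sigma_add = 0, sigma_prop = 0))
#' run_pipeline(d)
#' @export
run_pipeline <- function(dataset, models = character(0),
                         route = "auto", n_bins = 10,
                         metric = "rrmse_pairwise", config = list()) {
  cfg <- function(key, default) config[[key]] %||% default
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  records <- if (inherits(dataset, "pk_records")) dataset
             else read_pk_dataset(dataset)
  ann <- withCallingHandlers(
    annotate_doses(records, route),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  hl <- pooled_halflife(ann, n_bins)
  t_half <- hl$halflife$t_half
  if (is.null(hl$fit)) {
    note("terminal phase not estimable by best-fit regression")
  }
  if (is.na(t_half)) {
    note("no pooled half-life available")
  } else {
    ann <- update_ss_flags(ann, t_half)
  }

  peak_tad <- if (nrow(hl$profile$bins)) {
    hl$profile$bins$tad[which.max(hl$profile$bins$conc)]
  } else NA_real_

  methods <- list(single_point = NULL, nca = NULL, graphical = NULL)
  methods$single_point <- tryCatch(
    single_point_estimate(ann, t_half, peak_tad),
    error = function(e) { note(paste("single-point:", conditionMessage(e))); NULL })
  methods$nca <- tryCatch(
    nca_estimate(ann, hl$profiles, hl$fit),
    error = function(e) { note(paste("nca:", conditionMessage(e))); NULL })
  if (is.null(methods$nca)) note("nca: method unavailable")
  fit_fd <- if (identical(hl$profile_group, "first_dose")) hl$fit
            else fit_lambda_z(hl$profiles$first_dose)
  methods$graphical <- tryCatch(
    graphical_estimate(ann, hl$profiles, fit_fd),
    error = function(e) { note(paste("graphical:", conditionMessage(e))); NULL })
  if (is.null(methods$graphical)) note("graphical: method unavailable")
  if (!is.null(methods$nca) && length(methods$nca$warnings)) {
    warnings <- c(warnings, paste("nca:", methods$nca$warnings))
  }

  selected <- select_base_params(methods, ann, metric)

  sweeps <- list()
  for (model in models) {
    sweeps[[model]] <- tryCatch({
      fixed <- list(ka = selected$params$ka, v = selected$params$v)
      if (model == "mm") {
        c_max <- max(ann$observations$dv, na.rm = TRUE)
        grid <- build_mm_grid(selected$params$cl, c_max,
                              km_ratios = cfg("sweep.km_ratios",
                                              c(4, 2, 1, 1/2, 1/4, 1/10, 1/20)),
                              c_fractions = cfg("sweep.c_fractions",
                                                c(0.05, 0.1, 0.25, 0.5, 0.75)))
      } else {
        v_cand <- unique(stats::na.omit(c(
          selected$params$v,
          methods$single_point$vc %||% NA_real_)))
        grid <- build_cpt_grid(selected$params$cl, v_cand,
                               n_compartments = if (model == "3cpt") 3 else 2,
                               vp_ratios = cfg("sweep.vp_ratios",
                                               c(10, 5, 2, 1, 1/2, 1/5, 1/10)),
                               q_folds = cfg("sweep.q_folds",
                                             c(0.25, 0.5, 1, 2)))
      }
      run_sweep(grid, ann, fixed, metric)
    }, error = function(e) {
      note(paste0("sweep(", model, "): ", conditionMessage(e)))
      NULL
    })
  }

  iiv_params <- c("cl", "v",
                  if (is.finite(selected$params$ka %||% NA_real_)) "ka")
  error_init <- error_model_init(
    ann, parameters = iiv_params,
    n_terminal_points = cfg("error.n_terminal_points", 3),
    cv = cfg("error.cv_fallback", 0.20),
    omega2 = cfg("error.omega2", 0.1))
  if (error_init$source == "fallback") {
    note("residual error: regression insufficient, fixed-fraction fallback used")
  }

  structure(list(
    selected = selected,
    methods = methods,
    sweeps = sweeps,
    error_init = error_init,
    terminal = hl$fit,
    pooled = hl$profiles,
    annotated = ann,
    warnings = warnings,
    provenance = list(metric = metric, n_bins = n_bins, route = route,
                      models = models, config = config,
                      package_version = as.character(
                        utils::packageVersion("pkautoinit")))
  ), class = "pkinit_report")
}

#' @export
print.pkinit_report <- function(x, ...) {
  cat("== Initial-estimates report ==\n")
  if (!is.null(x$terminal)) print(x$terminal)
  print(x$selected)
  for (m in names(x$methods)) {
    e <- x$methods[[m]]
    if (is.null(e)) cat(sprintf("  %s: unavailable\n", m)) else print(e)
  }
  for (s in names(x$sweeps)) if (!is.null(x$sweeps[[s]])) print(x$sweeps[[s]])
  print(x$error_init)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Serialize an initial-estimates report
#'
#' Writes the machine-readable report as JSON (losslessly re-readable) or
#' as a flat parameter/value/source CSV.
#'
#' @param report a `pkinit_report`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  flat <- report_parameters(report)
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      selected = list(params = report$selected$params,
                      source = report$selected$source,
                      rrmse_pct = report$selected$rrmse_pct),
      methods = lapply(report$methods, function(e) {
        if (is.null(e)) return(NULL)
        list(cl = e$cl, v = e$v, ka = e$ka, vc = e$vc %||% NA_real_)
      }),
      sweeps = lapply(report$sweeps, function(s) {
        if (is.null(s)) return(NULL)
        list(params = s$params, rrmse_pct = s$rrmse_pct)
      }),
      error_init = list(sigma_add = report$error_init$sigma_add,
                        sigma_prop = report$error_init$sigma_prop,
                        source = report$error_init$source,
                        omega2 = report$error_init$omega2),
      warnings = report$warnings,
      provenance = report$provenance
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Flat parameter table of a report
#'
#' @param report a `pkinit_report`.
#' @return data frame with columns `parameter`, `value`, `source`.
#' @export
report_parameters <- function(report) {
  sel <- report$selected
  rows <- list(
    data.frame(parameter = "cl", value = sel$params$cl,
               source = sel$source$cl),
    data.frame(parameter = "v", value = sel$params$v, source = sel$source$v)
  )
  if (is.finite(sel$params$ka %||% NA_real_)) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "ka", value = sel$params$ka, source = sel$source$ka)
  }
  for (s in names(report$sweeps)) {
    sw <- report$sweeps[[s]]
    if (is.null(sw)) next
    for (nm in setdiff(names(sw$params), c("ka", "cl"))) {
      v <- sw$params[[nm]]
      if (is.null(v) || !is.finite(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, value = v, source = paste0("sweep_", s))
    }
  }
  ei <- report$error_init
  rows[[length(rows) + 1L]] <- data.frame(parameter = "sigma_add",
                                          value = ei$sigma_add,
                                          source = ei$source)
  rows[[length(rows) + 1L]] <- data.frame(parameter = "sigma_prop",
                                          value = ei$sigma_prop,
                                          source = ei$source)
  for (nm in names(ei$omega2)) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("omega2_", nm), value = ei$omega2[[nm]],
      source = "default")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
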