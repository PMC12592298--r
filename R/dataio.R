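#' Read a PK dataset in the NONMEM/nlmixr2 column convention
#'
#' Parses a comma- or tab-delimited concentration-time dataset with the
#' usual NONMEM columns (`ID`, `TIME`, `AMT`, `RATE`, `EVID`, `CMT`, `DV`,
#' `ADDL`, `II`, optionally `DUR` and `ROUTE`). Headers are matched
#' case-insensitively. `ADDL`/`II` dosing shorthand is expanded into
#' explicit dose records, and records are returned ordered by subject and
#' time.
#'
#' When no `EVID` column is present, rows with a positive `AMT` are taken
#' to be dose records and all other rows observation records.
#'
#' @param source path to a delimited text file, or a `data.frame` already
#'   holding the columns above.
#' @return a `data.frame` of class `pk_records` with columns `id`, `time`,
#'   `amt`, `rate`, `evid`, `cmt`, `dv`, `dur`, `route` (the last two may be
#'   `NA` throughout), one row per event, ordered by (`id`, `time`) with dose
#'   records before observations at tied times.
#' @examples
#' d <- data.frame(ID = 1, TIME = c(0, 1, 2), AMT = c(100, 0, 0),
#'                 EVID = c(1, 0, 0), DV = c(NA, 8, 6))
#' read_pk_dataset(d)
#' @export
read_pk_dataset <- function(source) {
  if (is.character(source)) {
    stopifnot(length(source) == 1L, file.exists(source))
    header <- readLines(source, n = 1L)
    if (!length(header)) stop("empty dataset file: ", source)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    raw <- utils::read.table(source, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE,
                             na.strings = c("NA", ".", ""))
  } else if (is.data.frame(source)) {
    raw <- source
  } else {
    stop("`source` must be a file path or a data.frame")
  }
  names(raw) <- toupper(names(raw))

  need <- c("ID", "TIME", "DV")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!any(c("AMT", "EVID") %in% names(raw))) {
    stop("missing mandatory column(s): AMT or EVID")
  }

  col <- function(nm, default = NA_real_) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    id    = as.character(raw$ID),
    time  = as.numeric(raw$TIME),
    amt   = as_num0(col("AMT")),
    rate  = as_num0(col("RATE")),
    evid  = col("EVID"),
    cmt   = as.numeric(col("CMT")),
    dv    = as.numeric(raw$DV),
    addl  = as_num0(col("ADDL")),
    ii    = as_num0(col("II")),
    dur   = as.numeric(col("DUR")),
    route = as.character(col("ROUTE", NA_character_)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(rec$time) | rec$time < 0)) {
    stop("negative or missing TIME in record(s) ",
         paste(utils::head(which(!is.finite(rec$time) | rec$time < 0), 5L),
               collapse = ", "))
  }
  if (all(is.na(rec$evid))) {
    rec$evid <- ifelse(rec$amt > 0, 1, 0)
  }
  rec$evid <- as_num0(rec$evid)
  rec <- rec[rec$evid %in% c(0, 1, 4), , drop = FALSE]
  if (any(rec$amt < 0, na.rm = TRUE) || any(rec$rate < 0, na.rm = TRUE)) {
    stop("negative AMT or RATE encountered")
  }
  # infusion duration given as DUR instead of RATE
  has_dur <- is.finite(rec$dur) & rec$dur > 0 & rec$evid != 0 & rec$rate == 0
  rec$rate[has_dur] <- rec$amt[has_dur] / rec$dur[has_dur]

  # expand ADDL/II shorthand into explicit dose records
  exp_idx <- which(rec$evid != 0 & rec$addl > 0 & rec$ii > 0)
  if (length(exp_idx)) {
    extra <- do.call(rbind, lapply(exp_idx, function(i) {
      k <- seq_len(rec$addl[i])
      out <- rec[rep(i, length(k)), , drop = FALSE]
      out$time <- rec$time[i] + k * rec$ii[i]
      out
    }))
    rec$addl <- 0
    extra$addl <- 0
    rec <- rbind(rec, extra)
  }
  rec$dv[rec$evid != 0] <- NA_real_

  ord <- order(rec$id, rec$time, rec$evid == 0)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("pk_records", "data.frame")
  rec
}

as_num0 <- function(x) {
  x <- as.numeric(x)
  x[is.na(x)] <- 0
  x
}

#' Annotate observations with dose context
#'
#' Assigns to every observation record its time after the most recent dose
#' (TAD), the amount and ordinal of that dose, the administration route,
#' the dosing occasion (first dose vs. multiple dose) and a steady-state
#' flag, and extracts the dose events themselves with their inter-dose
#' intervals.
#'
#' Route detection: a dose with `rate > 0` (or `DUR > 0`) is an infusion; a
#' dose administered into a compartment different from the one observed
#' (depot dosing), or labelled by an explicit `ROUTE` column, is
#' extravascular; all other doses are boluses.
#'
#' Steady state is flagged when the regimen preceding an observation
#' consists of at least five doses (or, once a half-life is known, spans at
#' least five half-lives -- see [update_ss_flags()]) with both dose amounts
#' and dose intervals within +/- 25% of their respective medians.
#'
#' Subjects without any dose record are dropped with a warning, and
#' observations occurring before the first dose are excluded from TAD-based
#' analyses (returned in `$predose`).
#'
#' @param records a `pk_records` data frame from [read_pk_dataset()].
#' @param route optional route override: `"auto"` (default), `"iv"` (force
#'   bolus unless `rate > 0`), or `"oral"` (force extravascular).
#' @return a list of class `pk_annotated` with elements `doses`
#'   (one row per dose event: `id`, `time`, `amount`, `rate`, `t_inf`,
#'   `route`, `tau`, `dose_number`), `observations` (one row per retained
#'   observation: `id`, `time`, `dv`, `tad`, `dose_amount`, `dose_number`,
#'   `route`, `occasion`, `at_steady_state`, `tau`), and `predose`
#'   (excluded pre-first-dose observations).
#' @export
annotate_doses <- function(records, route = c("auto", "iv", "oral")) {
  route <- match.arg(route)
  stopifnot(is.data.frame(records))
  doses_raw <- records[records$evid %in% c(1, 4), , drop = FALSE]
  obs_raw <- records[records$evid == 0, , drop = FALSE]

  dosed_ids <- unique(doses_raw$id)
  no_dose <- setdiff(unique(obs_raw$id), dosed_ids)
  if (length(no_dose)) {
    warning("dropping subject(s) with no dose record: ",
            paste(no_dose, collapse = ", "))
    obs_raw <- obs_raw[obs_raw$id %in% dosed_ids, , drop = FALSE]
  }
  if (!nrow(doses_raw)) stop("no dose records in dataset")
  if (!nrow(obs_raw)) stop("no observation records in dataset")

  # per-subject modal observation compartment, for depot detection
  obs_cmt_by_id <- tapply(obs_raw$cmt, obs_raw$id, function(z) {
    z <- z[is.finite(z)]
    if (!length(z)) NA_real_ else as.numeric(names(sort(table(z), decreasing = TRUE))[1])
  })

  dose_list <- list()
  obs_list <- list()
  pre_list <- list()
  for (sid in dosed_ids) {
    d <- doses_raw[doses_raw$id == sid, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    o <- obs_raw[obs_raw$id == sid, , drop = FALSE]
    nd <- nrow(d)

    ocmt <- obs_cmt_by_id[[sid]]
    rt <- vapply(seq_len(nd), function(i) {
      if (route == "oral") return("extravascular")
      if (d$rate[i] > 0) return("infusion")
      if (route == "iv") return("bolus")
      if (!is.na(d$route[i])) {
        r <- tolower(d$route[i])
        if (r %in% c("oral", "po", "ev", "extravascular", "depot")) return("extravascular")
        if (r %in% c("infusion", "inf")) return("infusion")
        return("bolus")
      }
      if (is.finite(d$cmt[i]) && is.finite(ocmt) && d$cmt[i] != ocmt) {
        return("extravascular")
      }
      "bolus"
    }, character(1))

    tau_next <- c(diff(d$time), NA_real_)
    # active interval for observations after the final dose: carry the last
    # observed inter-dose interval forward
    tau_active <- tau_next
    if (nd > 1) tau_active[nd] <- tau_next[nd - 1L]

    dose_df <- data.frame(
      id = sid, time = d$time, amount = d$amt, rate = d$rate,
      t_inf = ifelse(d$rate > 0, d$amt / d$rate, 0),
      route = rt, tau = tau_next, dose_number = seq_len(nd),
      stringsAsFactors = FALSE
    )
    dose_list[[sid]] <- dose_df

    if (!nrow(o)) next
    last_dose <- findInterval(o$time, d$time)
    pre <- last_dose == 0L
    if (any(pre)) pre_list[[sid]] <- o[pre, , drop = FALSE]
    o <- o[!pre, , drop = FALSE]
    last_dose <- last_dose[!pre]
    if (!nrow(o)) next

    intervals <- diff(d$time)
    ss <- vapply(last_dose, function(k) {
      regimen_regular(d$amt[seq_len(k)], intervals[seq_len(max(0L, k - 1L))]) &&
        k >= 5L
    }, logical(1))

    obs_list[[sid]] <- data.frame(
      id = sid, time = o$time, dv = o$dv,
      tad = o$time - d$time[last_dose],
      dose_amount = d$amt[last_dose],
      dose_number = last_dose,
      route = rt[last_dose],
      t_inf = dose_df$t_inf[last_dose],
      occasion = ifelse(last_dose == 1L, "first_dose", "multi_dose"),
      at_steady_state = ss,
      tau = tau_active[last_dose],
      stringsAsFactors = FALSE
    )
  }

  out <- list(
    doses = do.call(rbind, c(dose_list, list(make.row.names = FALSE))),
    observations = do.call(rbind, c(obs_list, list(make.row.names = FALSE))),
    predose = if (length(pre_list))
      do.call(rbind, c(pre_list, list(make.row.names = FALSE))) else NULL
  )
  if (is.null(out$observations) || !nrow(out$observations)) {
    stop("no observation occurs after a dose for any subject")
  }
  class(out) <- "pk_annotated"
  out
}

# regimen-regularity rule: dose amounts and inter-dose intervals both within
# +/- 25% of their respective medians
regimen_regular <- function(amounts, intervals) {
  ok_band <- function(x) {
    if (!length(x)) return(TRUE)
    m <- stats::median(x)
    if (m <= 0) return(FALSE)
    all(abs(x - m) <= 0.25 * m)
  }
  ok_band(amounts) && ok_band(intervals)
}

#' Re-evaluate steady-state flags once a half-life is known
#'
#' The steady-state rule accepts a regimen covering at least five doses
#' *or* at least five elimination half-lives. The half-life is only
#' available after terminal-phase regression, so the flag is recomputed
#' lazily: observations preceded by a regular regimen whose total duration
#' since the first dose is at least `5 * t_half` are flagged even when
#' fewer than five doses were given.
#'
#' @param annotated a `pk_annotated` object.
#' @param t_half elimination half-life in hours.
#' @return the `pk_annotated` object with updated `at_steady_state` flags.
#' @export
update_ss_flags <- function(annotated, t_half) {
  stopifnot(inherits(annotated, "pk_annotated"), is.finite(t_half), t_half > 0)
  obs <- annotated$observations
  doses <- annotated$doses
  for (sid in unique(obs$id)) {
    d <- doses[doses$id == sid, , drop = FALSE]
    oi <- which(obs$id == sid)
    intervals <- diff(d$time)
    for (j in oi) {
      k <- obs$dose_number[j]
      if (obs$at_steady_state[j]) next
      if (k < 2L) next
      elapsed <- d$time[k] - d$time[1L]
      if (elapsed >= 5 * t_half &&
          regimen_regular(d$amount[seq_len(k)], intervals[seq_len(k - 1L)])) {
        obs$at_steady_state[j] <- TRUE
      }
    }
  }
  annotated$observations <- obs
  annotated
}

#' Build a naive pooled, binned concentration-time profile
#'
#' Dose-normalizes the observed concentrations (`dv / dose_amount`), pools
#' them across subjects by time after dose, and bins them into
#' approximately equal groups of unique TADs using type-7 quantiles. Each
#' bin is represented by the median TAD and the median normalized
#' concentration of the points it holds. When fewer unique TADs than
#' requested bins exist, the number of bins shrinks to match.
#'
#' @param annotated a `pk_annotated` object, or its `observations` data
#'   frame.
#' @param group pooling group: `"first_dose"`, `"multi_dose"` or `"mixed"`.
#' @param n_bins requested number of bins (default 10).
#' @return an object of class `pooled_profile`: a list with `group`, a
#'   `bins` data frame (`tad`, `conc` dose-normalized, `n_points`),
#'   `n_bins_requested`, and the dominant `route` of the pooled
#'   observations. Empty groups give a profile with zero bins.
#' @export
pool_observations <- function(annotated,
                              group = c("mixed", "first_dose", "multi_dose"),
                              n_bins = 10) {
  group <- match.arg(group)
  obs <- if (inherits(annotated, "pk_annotated")) annotated$observations else annotated
  stopifnot(is.data.frame(obs), n_bins >= 1)
  if (group != "mixed") obs <- obs[obs$occasion == group, , drop = FALSE]
  obs <- obs[is.finite(obs$dv) & is.finite(obs$tad) & obs$dose_amount > 0, ,
             drop = FALSE]

  if (!nrow(obs)) {
    return(structure(list(group = group,
                          bins = data.frame(tad = numeric(0), conc = numeric(0),
                                            n_points = integer(0)),
                          n_bins_requested = n_bins, route = NA_character_),
                     class = "pooled_profile"))
  }

  norm_conc <- obs$dv / obs$dose_amount
  u <- sort(unique(obs$tad))
  k <- min(n_bins, length(u))
  if (k == 1L) {
    bin_of_tad <- rep(1L, length(u))
  } else {
    brks <- stats::quantile(u, probs = seq(0, 1, length.out = k + 1L),
                            type = 7, names = FALSE)
    interior <- brks[-c(1L, k + 1L)]
    # ties on a break go to the lower bin
    bin_of_tad <- 1L + vapply(u, function(t) sum(t > interior), integer(1))
  }
  bin_idx <- bin_of_tad[match(obs$tad, u)]

  bins <- do.call(rbind, lapply(sort(unique(bin_idx)), function(b) {
    sel <- bin_idx == b
    data.frame(tad = stats::median(obs$tad[sel]),
               conc = stats::median(norm_conc[sel]),
               n_points = sum(sel))
  }))
  bins <- bins[order(bins$tad), , drop = FALSE]
  rownames(bins) <- NULL

  route <- names(sort(table(obs$route), decreasing = TRUE))[1]
  structure(list(group = group, bins = bins, n_bins_requested = n_bins,
                 route = route),
            class = "pooled_profile")
}

#' @export
print.pooled_profile <- function(x, ...) {
  cat(sprintf("Naive pooled profile (%s group, %s route): %d bin(s), %d point(s)\n",
              x$group, x$route %||% "?", nrow(x$bins), sum(x$bins$n_points)))
  if (nrow(x$bins)) print(x$bins, ...)
  invisible(x)
}

#' @export
print.pk_annotated <- function(x, ...) {
  cat(sprintf("Annotated PK dataset: %d subject(s), %d dose(s), %d observation(s)\n",
              length(unique(x$observations$id)), nrow(x$doses),
              nrow(x$observations)))
  cat(sprintf("  routes: %s; first-dose obs: %d; multi-dose obs: %d; steady-state obs: %d\n",
              paste(unique(x$doses$route), collapse = "/"),
              sum(x$observations$occasion == "first_dose"),
              sum(x$observations$occasion == "multi_dose"),
              sum(x$observations$at_steady_state)))
  invisible(x)
}

#' Write an annotated dataset as delimited text
#'
#' Exports the observation records with the derived `TAD`, `ROUTE`,
#' `OCCASION` and `SS_FLAG` columns appended.
#'
#' @param annotated a `pk_annotated` object.
#' @param path output file path; `","` separated.
#' @return the written data frame, invisibly.
#' @export
write_annotated <- function(annotated, path) {
  obs <- annotated$observations
  out <- data.frame(ID = obs$id, TIME = obs$time, DV = obs$dv, TAD = obs$tad,
                    DOSE = obs$dose_amount, ROUTE = toupper(obs$route),
                    OCCASION = toupper(obs$occasion),
                    SS_FLAG = as.integer(obs$at_steady_state))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
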