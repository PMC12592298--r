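test_that("parsing maps rows to dose and observation records", {
  d <- data.frame(ID = 1, TIME = c(0, 1, 2), AMT = c(100, 0, 0),
                  EVID = c(1, 0, 0), DV = c(NA, 8, 6))
  rec <- read_pk_dataset(d)
  expect_equal(nrow(rec), 3L)
  expect_equal(sum(rec$evid == 1), 1L)
  expect_equal(sum(rec$evid == 0), 2L)
  expect_true(all(is.na(rec$dv[rec$evid == 1])))
  expect_equal(rec$dv[rec$evid == 0], c(8, 6))
})

test_that("ADDL/II shorthand expands to explicit dose records", {
  d <- data.frame(ID = 1, TIME = c(0, 30), AMT = c(100, 0),
                  EVID = c(1, 0), DV = c(NA, 2), ADDL = c(2, 0),
                  II = c(12, 0))
  rec <- read_pk_dataset(d)
  doses <- rec[rec$evid == 1, ]
  expect_equal(doses$time, c(0, 12, 24))
  expect_equal(doses$amt, rep(100, 3))
  expect_true(all(doses$addl == 0))
})

test_that("parsing enforces mandatory columns and record validity", {
  expect_error(read_pk_dataset(data.frame(ID = 1, TIME = 0, AMT = 100)),
               "DV")
  expect_error(read_pk_dataset(data.frame(ID = 1, DV = 1, AMT = 0)),
               "TIME")
  expect_error(
    read_pk_dataset(data.frame(ID = 1, TIME = -1, AMT = 100, EVID = 1,
                               DV = NA)),
    "negative")
  # headers are case-insensitive and delimiter is sniffed from the file
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c("id,time,amt,evid,dv", "1,0,100,1,.", "1,2,0,0,4.5"), path)
  rec <- read_pk_dataset(path)
  expect_equal(rec$dv[rec$evid == 0], 4.5)
})

test_that("dose annotation assigns TAD, occasion and route", {
  d <- data.frame(ID = 1, TIME = c(0, 2), AMT = c(100, 0), EVID = c(1, 0),
                  DV = c(NA, 5))
  ann <- annotated_from(d)
  expect_equal(ann$observations$tad, 2)
  expect_equal(ann$observations$occasion, "first_dose")
  expect_equal(ann$observations$route, "bolus")

  # depot dosing (different compartments) is detected as extravascular,
  # a positive rate as infusion
  d$CMT <- c(1, 2)
  expect_equal(annotated_from(d)$observations$route, "extravascular")
  d$CMT <- NULL
  d$RATE <- c(50, 0)
  ann_inf <- annotated_from(d)
  expect_equal(ann_inf$observations$route, "infusion")
  expect_equal(ann_inf$doses$t_inf, 2)
})

test_that("steady state needs five regular doses; irregular regimens fail", {
  q12x6 <- data.frame(ID = 1, TIME = c(seq(0, 60, by = 12), 62),
                      AMT = c(rep(100, 6), 0), EVID = c(rep(1, 6), 0),
                      DV = c(rep(NA, 6), 4))
  expect_true(annotated_from(q12x6)$observations$at_steady_state)

  irregular <- data.frame(ID = 1, TIME = c(0, 12, 30, 42, 54, 66, 68),
                          AMT = c(rep(100, 6), 0), EVID = c(rep(1, 6), 0),
                          DV = c(rep(NA, 6), 4))
  expect_false(annotated_from(irregular)$observations$at_steady_state)

  # the five-half-life arm only opens once a half-life is supplied
  q12x3 <- data.frame(ID = 1, TIME = c(0, 12, 24, 26),
                      AMT = c(rep(100, 3), 0), EVID = c(rep(1, 3), 0),
                      DV = c(rep(NA, 3), 4))
  ann <- annotated_from(q12x3)
  expect_false(ann$observations$at_steady_state)
  expect_true(update_ss_flags(ann, t_half = 4)$observations$at_steady_state)
  expect_false(update_ss_flags(ann, t_half = 8)$observations$at_steady_state)
})

test_that("pre-dose observations are excluded and dose-less subjects dropped", {
  d <- data.frame(ID = c(1, 1, 1, 2), TIME = c(1, 2, 4, 3),
                  AMT = c(0, 100, 0, 0), EVID = c(0, 1, 0, 0),
                  DV = c(9, NA, 5, 7))
  expect_warning(ann <- annotated_from(d), "no dose")
  expect_equal(nrow(ann$observations), 1L)
  expect_equal(ann$predose$time, 1)
})

test_that("pooling builds quantile bins over unique TADs with median summaries", {
  # 20 unique TADs at the default 10 bins -> 2 unique TADs per bin
  tads <- 1:20
  obs <- data.frame(id = "1", time = tads, dv = exp(-0.05 * tads),
                    tad = tads, dose_amount = 1, dose_number = 1,
                    route = "bolus", occasion = "first_dose",
                    at_steady_state = FALSE, tau = NA_real_)
  prof <- pool_observations(obs, "mixed", n_bins = 10)
  expect_equal(nrow(prof$bins), 10L)
  expect_equal(prof$bins$n_points, rep(2L, 10))

  # fewer unique TADs than requested bins shrink the bin count
  obs5 <- obs[1:5, ]
  expect_equal(nrow(pool_observations(obs5, "mixed", 10)$bins), 5L)

  # representative = (median TAD, median normalized concentration)
  obs2 <- obs[1:2, ]
  obs2$tad <- c(2, 2.5); obs2$dv <- c(8, 6)
  bin <- pool_observations(obs2, "mixed", 1)$bins
  expect_equal(bin$tad, 2.25)
  expect_equal(bin$conc, 7)
})

test_that("pooling is idempotent and invariant to common dose scaling", {
  set.seed(42)
  tads <- sort(sample(seq(0.5, 24, by = 0.5), 12))
  obs <- data.frame(id = "1", time = tads, dv = 5 * exp(-0.1 * tads),
                    tad = tads, dose_amount = 100, dose_number = 1,
                    route = "bolus", occasion = "first_dose",
                    at_steady_state = FALSE, tau = NA_real_)
  prof <- pool_observations(obs, "mixed", n_bins = 12)
  # re-pooling the single-point-per-bin profile returns it unchanged
  obs2 <- obs
  obs2$tad <- prof$bins$tad
  obs2$dv <- prof$bins$conc
  obs2$dose_amount <- 1
  prof2 <- pool_observations(obs2, "mixed", n_bins = 12)
  expect_equal(prof2$bins$tad, prof$bins$tad)
  expect_equal(prof2$bins$conc, prof$bins$conc)

  # scaling doses and concentrations together changes nothing
  obs3 <- obs
  obs3$dv <- obs$dv * 7.5
  obs3$dose_amount <- obs$dose_amount * 7.5
  expect_equal(pool_observations(obs3, "mixed", 6)$bins,
               pool_observations(obs, "mixed", 6)$bins)

  # observation count is conserved across bins
  expect_equal(sum(pool_observations(obs, "mixed", 6)$bins$n_points),
               nrow(obs))
})
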