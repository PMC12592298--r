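test_that("linear-up log-down AUC applies the right rule per segment", {
  # rising segment linear, falling segment logarithmic
  expect_equal(auc_linuplogdown(c(0, 1, 2), c(0, 10, 5)),
               5 + 5 / log(2), tolerance = 1e-10)
  expect_equal(auc_linuplogdown(c(0, 3), c(4, 4)), 12)
  expect_true(is.na(auc_linuplogdown(1, 5)))
  expect_error(auc_linuplogdown(c(1, 1), c(2, 1)), "increasing")
  # exact on mono-exponential decay
  t <- seq(0, 24, by = 2)
  expect_equal(auc_linuplogdown(t, 10 * exp(-0.1 * t)),
               10 / 0.1 * (1 - exp(-2.4)), tolerance = 1e-12)
})

test_that("lin-up/log-down lies between pure log and pure linear rules", {
  t <- c(0, 1, 2, 3, 4)
  conc <- c(8, 3, 1, 2.5, 6)  # falling then rising
  lin <- sum((conc[-5] + conc[-1]) / 2 * diff(t))
  logt <- sum(ifelse(conc[-1] != conc[-5],
                     (conc[-5] - conc[-1]) / log(conc[-5] / conc[-1]),
                     conc[-1]) * diff(t))
  mixed <- auc_linuplogdown(t, conc)
  expect_gte(mixed, logt)
  expect_lte(mixed, lin)
})

test_that("pooled NCA recovers clearance and volume of an IV bolus", {
  # closed-form oracle: AUC(0-Inf) per unit dose = 1/CL
  t <- exp(seq(log(0.05), log(48), length.out = 50))
  prof <- make_profile(t, (1 / 20) * exp(-0.1 * t))  # dose-normalized
  fit <- fit_lambda_z(prof)
  res <- nca_onecpt(prof, "single", fit)
  expect_equal(res$cl, 2, tolerance = 0.02)
  expect_equal(res$v, 20, tolerance = 0.02)
  expect_lt(res$auc$extrapolated_fraction, 0.5)

  # doubling all concentrations halves CL
  prof2 <- make_profile(t, 2 * (1 / 20) * exp(-0.1 * t))
  res2 <- nca_onecpt(prof2, "single", fit_lambda_z(prof2))
  expect_equal(res2$cl, res$cl / 2, tolerance = 1e-8)
})

test_that("multiple-dose NCA integrates over one interval", {
  # steady-state bolus, tau = 12, ke = 0.1: AUC(0-tau) = Dose/CL exactly
  tau <- 12
  ke <- 0.1
  cmax <- (1 / 20) / (1 - exp(-ke * tau))
  t <- seq(0.5, 12, by = 0.5)
  prof <- make_profile(t, cmax * exp(-ke * t))
  fit <- fit_lambda_z(prof)
  res <- nca_onecpt(prof, "multiple", fit, tau = tau)
  expect_equal(res$cl, 2, tolerance = 0.01)
})

test_that("the modal dosing interval is chosen by frequency", {
  mk <- function(id, tau, n) data.frame(
    ID = id, TIME = c((0:(n - 1)) * tau, (n - 1) * tau + 1),
    AMT = c(rep(100, n), 0), EVID = c(rep(1, n), 0),
    DV = c(rep(NA, n), 1))
  d <- do.call(rbind, c(lapply(1:9, mk, tau = 12, n = 3),
                        lapply(10:11, mk, tau = 24, n = 3)))
  expect_equal(modal_tau(annotated_from(d)), 12)
})

test_that("Wagner-Nelson recovers Ka from a dense noise-free oral profile", {
  ka <- 1.5; ke <- 0.1
  t <- seq(0.05, 48, by = 0.05)
  conc <- simulate_onecpt(list(cl = 2, v = 20, ka = ka),
                          single_dose(1, "extravascular"), t)
  prof <- make_profile(t, conc, route = "extravascular")
  wn <- wagner_nelson_ka(prof, ke)
  expect_equal(wn$ka, ka, tolerance = 0.02)

  # fraction absorbed is non-decreasing; fraction remaining positive pre-peak
  expect_true(all(diff(wn$points$frac_remaining) <= 1e-12))

  # Ka is invariant to dose scaling (F(t) is a ratio)
  prof10 <- make_profile(t, 10 * conc, route = "extravascular")
  expect_equal(wagner_nelson_ka(prof10, ke)$ka, wn$ka, tolerance = 1e-10)

  # a single usable pre-peak point cannot support the slope
  sparse <- make_profile(c(2, 20, 24),
                         simulate_onecpt(list(cl = 2, v = 20, ka = ka),
                                         single_dose(1, "extravascular"),
                                         c(2, 20, 24)),
                         route = "extravascular")
  expect_null(wagner_nelson_ka(sparse, ke))
})
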