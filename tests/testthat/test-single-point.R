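test_that("elimination fraction follows 1 - exp(-ln2 * f)", {
  expect_equal(elimination_fraction(0), 0)
  expect_equal(elimination_fraction(1), 0.5)
  # the eligibility-window justification: ~13% eliminated at 0.2 half-lives
  expect_equal(round(100 * elimination_fraction(0.2)), 13)
  expect_error(elimination_fraction(-0.1), "non-negative")
})

test_that("first-point volume honors the 20%-of-half-life IV window", {
  expect_equal(sp_vd_first_point(100, 5, 0.5, 10, "bolus"), 20)
  expect_true(is.na(sp_vd_first_point(100, 5, 3, 10, "bolus")))
  expect_true(is.na(sp_vd_first_point(100, 5, 0.5, 10, "extravascular")))
  expect_true(is.na(sp_vd_first_point(100, 5, 0.5, NA, "bolus")))
})

test_that("steady-state clearance from both or reconstructed extremes", {
  # both extremes observed
  expect_equal(
    sp_cl_steady_state(list(c_ss_max = 10, c_ss_min = 6, tau = 12,
                            t_inf = 0, route = "bolus"), 100),
    100 / (8 * 12))
  # bolus, only the peak: trough = peak * exp(-ke tau)
  ke <- log(2) / 12
  cl_b <- sp_cl_steady_state(list(c_ss_max = 10, c_ss_min = NA, tau = 12,
                                  t_inf = 0, route = "bolus"), 100, ke)
  expect_equal(cl_b, 100 / (7.5 * 12))
  # infusion, only the peak: decay over tau - t_inf
  cmin_i <- 10 * exp(-ke * 10)
  cl_i <- sp_cl_steady_state(list(c_ss_max = 10, c_ss_min = NA, tau = 12,
                                  t_inf = 2, route = "infusion"), 100, ke)
  expect_equal(cl_i, 100 / ((10 + cmin_i) / 2 * 12))
  # symmetric inversion from the trough alone matches the peak-based chain
  cl_min <- sp_cl_steady_state(list(c_ss_max = NA, c_ss_min = 5, tau = 12,
                                    t_inf = 0, route = "bolus"), 100, ke)
  expect_equal(cl_min, cl_b)
  # extravascular with one extreme is ineligible
  expect_true(is.na(
    sp_cl_steady_state(list(c_ss_max = 10, c_ss_min = NA, tau = 12,
                            t_inf = 0, route = "extravascular"), 100, ke)))
})

test_that("half-life relations for volume and the accumulation ratio", {
  expect_equal(sp_vd_from_halflife(1, log(2)), 1)
  expect_equal(sp_vd_from_halflife(2, 10 * log(2) / 2), 10, tolerance = 1e-9)
  expect_equal(accumulation_ratio(log(2) / 12, 12), 2)
  expect_equal(accumulation_ratio(0.1, 200), 1, tolerance = 1e-8)
  expect_equal(accumulation_ratio(0.1, 12), 1 / (1 - exp(-1.2)))
})

test_that("Cmax-based central volume applies the accumulation correction", {
  expect_equal(sp_vc_from_cmax(100, 5, "first_dose", tad_at_cmax = 1,
                               t_half = 10), 20)
  # multi-dose: Cmax = Cmax,ss / Rac
  ke <- log(2) / 12
  rac <- accumulation_ratio(ke, 12)
  expect_equal(
    sp_vc_from_cmax(100, 10, "multi_dose", ke, 12, tad_at_cmax = 1,
                    t_half = 12),
    100 / (10 / rac))
  expect_true(is.na(sp_vc_from_cmax(100, 5, "first_dose", tad_at_cmax = 5,
                                    t_half = 10)))
})

test_that("Ka root-finding inverts the forward simulation", {
  # single dose: concentration generated with ka = 1
  conc <- simulate_onecpt(list(cl = 2, v = 20, ka = 1),
                          single_dose(100, "extravascular"), 1)
  expect_equal(conc, 2.9831, tolerance = 1e-4)
  expect_equal(solve_ka_onecpt(conc, 1, 100, 2, 20), 1, tolerance = 1e-6)

  # multiple-dose (steady-state) equation, ka = 0.3, tau = 12
  p <- list(cl = 2, v = 20, ka = 0.3)
  de <- data.frame(time = seq(0, 60) * 12, amount = 100, rate = 0,
                   route = "extravascular")
  c_ss <- simulate_onecpt(p, de, 60 * 12 + 3)
  expect_equal(solve_ka_onecpt(c_ss, 3, 100, 2, 20, tau = 12), 0.3,
               tolerance = 1e-4)

  # unreachable concentration: no sign change, no root
  expect_true(is.na(solve_ka_onecpt(1000, 1, 100, 2, 20)))
})

test_that("trimmed geometric mean drops floor(n*trim/2) per side", {
  expect_equal(trimmed_geomean(rep(3.7, 10)), 3.7)
  expect_equal(trimmed_geomean(c(1, 100), trim = 0), 10)
  vals <- c(rep(2, 40), 0.001, 5000)  # floor(42 * 0.025) = 1 per side
  expect_equal(trimmed_geomean(vals, trim = 0.05), 2)
  expect_warning(trimmed_geomean(c(1, 4, -2)), "non-positive")
  # positive homogeneity
  set.seed(1)
  x <- rlnorm(30)
  expect_equal(trimmed_geomean(5 * x), 5 * trimmed_geomean(x),
               tolerance = 1e-12)
})

test_that("noise-free one-compartment parameters are recovered end to end", {
  # IV bolus, first samples within the eligibility window
  d <- noise_free_data("bolus", "rich", n_subjects = 5)
  ann <- annotated_from(d)
  hl <- pooled_halflife(ann)
  est <- single_point_estimate(ann, hl$halflife$t_half)
  expect_equal(est$v, 70, tolerance = 0.02)
  expect_equal(est$cl, 4, tolerance = 0.02)

  # oral multiple-dose: CL via observed extremes, Ka via root-finding
  d2 <- noise_free_data("extravascular", "sparse1", n_subjects = 5)
  ann2 <- annotated_from(d2)
  hl2 <- pooled_halflife(ann2)
  ann2 <- update_ss_flags(ann2, hl2$halflife$t_half)
  peak <- hl2$profile$bins$tad[which.max(hl2$profile$bins$conc)]
  est2 <- single_point_estimate(ann2, hl2$halflife$t_half, peak)
  expect_equal(est2$cl, 4, tolerance = 0.1)
  expect_equal(est2$ka, 1, tolerance = 0.2)
})
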