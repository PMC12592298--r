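test_that("closed-form bolus and oral solutions match hand values", {
  p <- list(cl = 2, v = 20)
  expect_equal(simulate_onecpt(p, single_dose(100), 0), 5)
  expect_equal(simulate_onecpt(p, single_dose(100), c(1, 5)),
               5 * exp(-0.1 * c(1, 5)))
  # oral: 100 * 1 / (20 * 0.9) * (exp(-0.1) - exp(-1))
  po <- list(cl = 2, v = 20, ka = 1)
  expect_equal(
    simulate_onecpt(po, single_dose(100, "extravascular"), 1),
    100 * 1 / (20 * (1 - 0.1)) * (exp(-0.1) - exp(-1)),
    tolerance = 1e-12)
  # ka == ke limiting form stays finite and continuous
  pk_lim <- list(cl = 2, v = 20, ka = 0.1)
  pk_near <- list(cl = 2, v = 20, ka = 0.1 * (1 + 1e-9))
  t <- c(1, 5, 10)
  expect_equal(simulate_onecpt(pk_lim, single_dose(100, "extravascular"), t),
               simulate_onecpt(pk_near, single_dose(100, "extravascular"), t),
               tolerance = 1e-6)
})

test_that("multi-dose superposition equals summed shifted single doses", {
  p <- list(cl = 3, v = 40, ka = 0.8)
  for (route in c("bolus", "extravascular")) {
    de <- data.frame(time = c(0, 12, 24), amount = 100, rate = 0,
                     route = route)
    t <- c(1, 13, 25, 30)
    multi <- simulate_onecpt(p, de, t)
    manual <- Reduce(`+`, lapply(c(0, 12, 24), function(td)
      simulate_onecpt(p, single_dose(100, route, time = td), t)))
    expect_equal(multi, manual, tolerance = 1e-10)
  }
})

test_that("steady-state peak over single-dose peak equals the accumulation ratio", {
  p <- list(cl = 2, v = 20)  # ke = 0.1
  tau <- 12
  de <- data.frame(time = seq(0, 40) * tau, amount = 100, rate = 0,
                   route = "bolus")
  c_ss_max <- simulate_onecpt(p, de, 40 * tau)
  c_single <- simulate_onecpt(p, single_dose(100), 0)
  expect_equal(c_ss_max / c_single, accumulation_ratio(0.1, tau),
               tolerance = 1e-6)
})

test_that("ODE engine agrees with the closed form on linear 1-compartment cases", {
  t <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  cases <- list(
    list(de = single_dose(100), p = list(cl = 2, vc = 20)),
    list(de = single_dose(100, "infusion", rate = 50),
         p = list(cl = 2, vc = 20)),
    list(de = single_dose(100, "extravascular"),
         p = list(cl = 2, vc = 20, ka = 1.3)),
    list(de = data.frame(time = c(0, 12), amount = 100, rate = 0,
                         route = "bolus"),
         p = list(cl = 2, vc = 20))
  )
  for (cs in cases) {
    spec <- pk_model_spec(1, "linear")
    ode <- simulate_pk_ode(spec, cs$p, cs$de, t)
    cf <- simulate_onecpt(list(cl = cs$p$cl, v = cs$p$vc, ka = cs$p$ka),
                          cs$de, t)
    expect_equal(ode, cf, tolerance = 1e-6)
  }
})

test_that("a 2-compartment model with vanishing Q degenerates to 1-compartment", {
  t <- c(0.5, 1, 2, 4, 8, 16, 24)
  p <- list(cl = 2, vc = 20, vp = 10, q = 1e-9)
  ode <- simulate_pk_ode(pk_model_spec(2), p, single_dose(100), t)
  cf <- simulate_onecpt(list(cl = 2, v = 20), single_dose(100), t)
  expect_equal(ode, cf, tolerance = 1e-6)
})

test_that("Michaelis-Menten with Km >> C linearizes to CL = Vmax/Km", {
  t <- c(0.5, 1, 2, 4, 8, 16, 24)
  # Cmax = 5; Km = 100 * Cmax
  p <- list(vmax = 200, km = 500, vc = 20)
  mm <- simulate_pk_ode(pk_model_spec(1, "michaelis_menten"), p,
                        single_dose(100), t)
  lin <- simulate_onecpt(list(cl = 200 / 500, v = 20), single_dose(100), t)
  expect_lt(max(abs(mm - lin) / lin), 0.01)
})

test_that("mass balance: numeric AUC of a linear 2-compartment bolus is Dose/CL", {
  tgrid <- exp(seq(log(0.01), log(400), length.out = 400))
  p <- list(cl = 2, vc = 20, vp = 40, q = 3)
  conc <- simulate_pk_ode(pk_model_spec(2), p, single_dose(100), tgrid)
  auc0 <- auc_linuplogdown(c(0, tgrid), c(5, conc))  # C(0+) = Dose/Vc = 5
  expect_equal(auc0, 100 / 2, tolerance = 0.005)
  expect_true(all(conc >= 0))
})
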