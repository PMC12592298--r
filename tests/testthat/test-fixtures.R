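test_that("semi-sparse design yields three groups of two samples each", {
  d <- generate_pk_dataset(pk_design("bolus", sampling = "semi_sparse",
                                     n_subjects = 30, seed = 5))
  obs <- d[d$EVID == 0, ]
  counts <- table(obs$ID)
  expect_equal(length(counts), 30L)
  expect_true(all(counts == 2))
  # times fall in the final dosing interval, drawn from the template set
  last_dose <- 5 * 24
  tads <- obs$TIME - last_dose
  expect_true(all(tads %in% c(2, 4, 6, 8, 12, 24)))
  # round-robin groups: subjects 1, 4, 7, ... share a time pair
  tad1 <- sort(tads[obs$ID == 1])
  tad4 <- sort(tads[obs$ID == 4])
  expect_equal(tad1, tad4)
})

test_that("sparse templates follow their sampling definitions", {
  d_iv <- generate_pk_dataset(pk_design("bolus", sampling = "sparse2",
                                        n_subjects = 4, seed = 2))
  obs <- d_iv[d_iv$EVID == 0, ]
  expect_true(all(tapply(obs$TIME, obs$ID, function(x)
    identical(sort(x), c(20, 24)))))
  expect_equal(sum(d_iv$EVID == 1), 4L)  # single dose

  d_oral <- generate_pk_dataset(pk_design("extravascular",
                                          sampling = "sparse1",
                                          n_subjects = 3, seed = 2))
  obs_o <- d_oral[d_oral$EVID == 0, ]
  last_dose <- 5 * 24
  expect_true(all(tapply(obs_o$TIME - last_dose, obs_o$ID, function(x)
    identical(sort(x), c(2, 20, 24)))))
  expect_equal(sum(d_oral$EVID == 1), 18L)  # six doses each
  # depot dosing is encoded via distinct compartments
  expect_true(all(d_oral$CMT[d_oral$EVID == 1] == 1))
  expect_true(all(d_oral$CMT[d_oral$EVID == 0] == 2))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- pk_design("extravascular", sampling = "rich", n_subjects = 8,
                    seed = 99)
  expect_identical(generate_pk_dataset(spec), generate_pk_dataset(spec))
  spec2 <- pk_design("extravascular", sampling = "rich", n_subjects = 8,
                     seed = 100)
  expect_false(identical(generate_pk_dataset(spec),
                         generate_pk_dataset(spec2)))
})

test_that("a degenerate spec collapses to the deterministic simulation", {
  d <- noise_free_data("bolus", "rich", n_subjects = 3)
  obs <- d[d$EVID == 0, ]
  per_subj <- split(obs$DV, obs$ID)
  expect_equal(per_subj[[1]], per_subj[[2]])
  expect_equal(per_subj[[1]],
               simulate_onecpt(list(cl = 4, v = 70), single_dose(100),
                               sort(unique(obs$TIME))))
})

test_that("log-parameter variance across many subjects matches omega2", {
  d <- generate_pk_dataset(pk_design(
    "bolus", sampling = "custom", sample_times = 0.001, n_subjects = 1e4,
    iiv_omega2 = list(vc = 0.1), sigma_add = 0, sigma_prop = 0, seed = 31))
  obs <- d[d$EVID == 0, ]
  # C(0+) = Dose / Vc, so log-concentration variance equals Var(log Vc)
  v_emp <- var(log(obs$DV))
  expect_equal(v_emp, 0.1, tolerance = 0.05)
})

test_that("unknown sampling templates are rejected with the valid list", {
  expect_error(pk_design("bolus", sampling = "weekly"), "valid templates")
})
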