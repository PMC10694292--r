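test_that("objective is zero on self-consistent data and matches hand values", {
  m <- mdz_model()
  g <- generate_observations(m, mdz_dose(), sampling_design(), noise_free(),
                             n_subjects = 1, group = "control", seed = 1)
  expect_lt(pk_objective(m, g$observations, mdz_dose(),
                         loq = noise_free()$loq), 1e-10)
  # a single observation at half the prediction contributes (log 2)^2
  m1 <- one_compartment_model()
  tc <- simulate_model(build_ode_system(m1), list(dose_event("drug", 100)), 30)
  pred <- tc_concentration(tc, "plasma", "drug")
  obs <- data.frame(subject_id = "s1", group = "control", species = "drug",
                    kind = "plasma_conc", time_min = 30, value = pred / 2,
                    below_loq = FALSE)
  expect_equal(pk_objective(m1, obs, list(dose_event("drug", 100)),
                            loq = c(plasma_conc = 0, urine_cumulative = 0,
                                    bile_cumulative = 0)),
               log(2)^2, tolerance = 1e-9)
  # unknown species is a mapping error
  obs$species <- "X"
  expect_error(pk_objective(m1, obs, list(dose_event("drug", 100))), "unknown")
})

test_that("objective is invariant under permutation of observations", {
  m <- mdz_model()
  g <- generate_observations(m, mdz_dose(), n_subjects = 2, group = "control",
                             seed = 2)
  obs <- g$observations
  set.seed(1)
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(pk_objective(m, obs, mdz_dose()),
               pk_objective(m, shuffled, mdz_dose()), tolerance = 1e-12)
})

test_that("reference fitting recovers a first-order clearance", {
  m <- mdz_model()
  ugt_id <- "enzymatic_first_order:Ugt.OH-MDZ>hepatocyte"
  true_cl <- get_model_param(m, ugt_id, "cl")
  # noise-free: recovery to high precision from a perturbed start
  g0 <- generate_observations(m, mdz_dose(), sampling_design(), noise_free(),
                              n_subjects = 1, group = "control", seed = 1)
  fit0 <- fit_reference(m, list(parameter_spec(ugt_id, "cl", start = true_cl * 5,
                                               bounds = true_cl * c(0.01, 100))),
                        g0$observations, mdz_dose(), seed = 1,
                        loq = noise_free()$loq)
  expect_true(fit0$converged)
  expect_equal(unname(fit0$estimates[1]), true_cl, tolerance = 1e-3)
  # noisy data, 5 subjects: recovery within 25 percent
  g <- generate_observations(m, mdz_dose(), sampling_design(),
                             noise_model(cv = 0.1, iiv_cv = 0),
                             n_subjects = 5, group = "control", seed = 4)
  fit <- fit_reference(m, list(parameter_spec(ugt_id, "cl", start = true_cl * 5,
                                              bounds = true_cl * c(0.01, 100))),
                       g$observations, mdz_dose(), seed = 1)
  expect_lt(abs(fit$estimates[[1]] - true_cl) / true_cl, 0.25)
  # preconditions
  expect_error(fit_reference(m, list(), g$observations, mdz_dose(), seed = 1),
               "at least one free parameter")
  expect_error(
    fit_reference(m, list(parameter_spec(ugt_id, "cl", 1e-3)),
                  g$observations[0, ], mdz_dose(), seed = 1),
    "at least as many observations"
  )
})

test_that("multi-start never beats fewer starts on the same seed prefix", {
  m <- mdz_model()
  ids <- c("enzymatic_first_order:Cyp3a11.MDZ>hepatocyte",
           "enzymatic_first_order:Ugt.OH-MDZ>hepatocyte")
  params <- lapply(ids, function(id) {
    tr <- get_model_param(m, id, "cl")
    parameter_spec(id, "cl", start = tr * 3, bounds = tr * c(0.1, 10))
  })
  g <- generate_observations(m, mdz_dose(),
                             sampling_design(plasma_times = c(15, 30, 60, 120)),
                             noise_model(cv = 0.15, iiv_cv = 0),
                             n_subjects = 2, group = "control", seed = 8)
  obs <- plasma_only(g$observations)
  f1 <- fit_reference(m, params, obs, mdz_dose(), seed = 11, n_starts = 1)
  f3 <- fit_reference(m, params, obs, mdz_dose(), seed = 11, n_starts = 3)
  expect_lte(f3$objective, f1$objective + 1e-9)
})

test_that("joint fitting recovers the true export fold and the null", {
  m <- mdz_model()
  sc <- default_scenario()
  b <- generate_paired_cohorts(m, sc, hypothesis_spec("H3", 10), mdz_dose(),
                               n_per_group = 5, seed = 11)
  fit <- fit_joint_hypothesis(m, sc, hypothesis_spec("H3"), b$control,
                              b$cirrhosis, mdz_dose(), seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta - 10) / 10, 0.3)
  expect_equal(fit$n_obs, nrow(b$control) + nrow(b$cirrhosis))
  # true fold 1: the estimator must not invent an effect
  b0 <- generate_paired_cohorts(m, sc, hypothesis_spec("H3", 1), mdz_dose(),
                                n_per_group = 5, seed = 12)
  fit0 <- fit_joint_hypothesis(m, sc, hypothesis_spec("H3"), b0$control,
                               b0$cirrhosis, mdz_dose(), seed = 1)
  expect_gt(fit0$theta, 0.8)
  expect_lt(fit0$theta, 1.25)
  expect_error(
    fit_joint_hypothesis(m, sc, hypothesis_spec("H3"), b$control,
                         b$cirrhosis[0, ], mdz_dose(), seed = 1),
    "empty cirrhosis"
  )
})

test_that("hypothesis comparison tabulates fits and needs at least two specs", {
  m <- mdz_model()
  sc <- default_scenario()
  b <- generate_paired_cohorts(m, sc, hypothesis_spec("H3", 10), mdz_dose(),
                               n_per_group = 5, seed = 11)
  expect_error(
    compare_hypotheses(m, sc, list(hypothesis_spec("H1")), b$control,
                       b$cirrhosis, mdz_dose(), seed = 1),
    "at least 2"
  )
  cmp <- compare_hypotheses(m, sc, list(hypothesis_spec("H2"), hypothesis_spec("H3")),
                            b$control, b$cirrhosis, mdz_dose(), seed = 1,
                            ugt_ratio_obs = 1)
  expect_equal(cmp$hypothesis, c("H2", "H3"))
  expect_equal(min(cmp$obj_ratio), 1)
  expect_equal(cmp$sinusoidal_export_fold[1], 1)
  expect_equal(cmp$sinusoidal_export_fold[2], cmp$theta[2])
  expect_equal(cmp$biliary_clearance_ratio[1], cmp$theta[1])
  expect_s3_class(attr(cmp, "fits")[[1]], "fit_result")
})
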