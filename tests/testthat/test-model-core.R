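test_that("one-compartment reduction matches the analytic exponential", {
  m <- one_compartment_model(cl = 0.01, v_plasma = 1)
  t_eval <- seq(5, 240, by = 5)
  tc <- simulate_model(build_ode_system(m), list(dose_event("drug", 100)), t_eval)
  expected <- 100 * exp(-0.01 * t_eval)
  expect_equal(tc_concentration(tc, "plasma", "drug"), unname(expected),
               tolerance = 1e-6)
  # concentration at t = 100 min equals C0 * e^-1
  tc100 <- simulate_model(build_ode_system(m), list(dose_event("drug", 100)), 100)
  expect_equal(tc_concentration(tc100, "plasma", "drug"), 100 * exp(-1),
               tolerance = 1e-6)
})

test_that("parent-equivalent moles are conserved in every family model", {
  t_eval <- c(5, 15, 30, 60, 120, 180, 240)
  for (drug in cocktail_drugs()) {
    m <- get_family_model(drug)
    d <- list(family_dose(drug, 0.025))
    tc <- simulate_model(build_ode_system(m), d, t_eval)
    bal <- mass_balance_report(tc, d)
    expect_lt(max(abs(bal$rel_deviation)), 1e-6, label = drug)
    expect_false(any(bal$inconsistent), label = drug)
  }
})

test_that("dose conversion follows nmol = mg/kg * kg * 1e6 / MW", {
  expect_equal(mgkg_to_nmol(2, 0.025, 325.77), 0.05 * 1e6 / 325.77)
  expect_equal(mgkg_to_nmol(2, 0.025, 325.77), 153.48, tolerance = 1e-4)
  expect_equal(mgkg_to_nmol(5, 0.025, 194.19), 643.70, tolerance = 1e-4)
  expect_error(mgkg_to_nmol(0, 0.025, 300), "dose")
  expect_error(mgkg_to_nmol(2, -1, 300), "body weight")
  expect_error(mgkg_to_nmol(2, 0.025, 0), "molecular weight")
})

test_that("definition errors name the offending reference", {
  phys <- mouse_physiology()
  sp <- list(chem_species("A", 300, 1), chem_species("B", 300, 1))
  expect_error(
    model_definition(phys, sp, list(p_enzymatic("Cyp1a2", "X", "B", 0.1))),
    "undeclared species 'X'"
  )
  expect_error(
    model_definition(phys, sp, list(
      p_enzymatic("Cyp1a2", "A", "B", 0.1),
      p_enzymatic("Cyp3a11", "B", "A", 0.1)
    )),
    "cyclic"
  )
  expect_error(
    chem_species("G", 500, 0.9, passive_exchange_cl = 0.01, is_glucuronide = TRUE),
    "passive_exchange_cl"
  )
  expect_error(p_mm_transport("Abcc2", "A", "canal", vmax = 1, km = 0), "km")
})

test_that("Michaelis-Menten transport reduces to vmax*C/km far below Km", {
  phys <- physiology(0.025,
    c(plasma = 1, liver_blood = 1, hepatocyte = 1, kidney = 1, rest_of_body = 1),
    c(liver = 0, kidney = 0, rest_of_body = 0), gfr = 0, bile_flow = 0)
  m <- model_definition(phys, list(chem_species("A", 300, 1)),
                        list(p_mm_transport("Slco1b2", "A", "sinusoidal_in",
                                            vmax = 10, km = 1000)))
  sys <- build_ode_system(m)
  y <- stats::setNames(numeric(sys$n_states), sys$state_names)
  y["A.liver_blood"] <- 1  # Cu = 1 nmol/L at the source
  dy <- sys$rhs(0, y, NULL)[[1]]
  expect_equal(dy[match("A.hepatocyte", sys$state_names)], 10 * 1 / 1001,
               tolerance = 1e-12)
  expect_equal(dy[match("A.liver_blood", sys$state_names)], -10 * 1 / 1001,
               tolerance = 1e-12)
})

test_that("empty dose list yields an all-zero time course", {
  tc <- simulate_model(build_ode_system(mdz_model()), list(), c(15, 30, 60))
  expect_true(all(tc$amounts == 0))
  bal <- mass_balance_report(tc, list())
  expect_false(any(bal$inconsistent))
})

test_that("sequential boluses restart integration and track cumulative dose", {
  m <- one_compartment_model(cl = 0.01, v_plasma = 1)
  doses <- list(dose_event("drug", 100, time = 0), dose_event("drug", 50, time = 60))
  t_eval <- c(15, 30, 59, 61, 90, 120)
  tc <- simulate_model(build_ode_system(m), doses, t_eval)
  k <- 0.01
  piecewise <- function(t) {
    if (t < 60) 100 * exp(-k * t)
    else (100 * exp(-k * 60) + 50) * exp(-k * (t - 60))
  }
  expect_equal(tc_concentration(tc, "plasma", "drug"),
               vapply(t_eval, piecewise, 0), tolerance = 1e-6)
  bal <- mass_balance_report(tc, doses)
  expect_equal(bal$cum_dose_nmol, c(100, 100, 100, 150, 150, 150))
  expect_lt(max(abs(bal$rel_deviation)), 1e-6)
})

test_that("dose-linearity holds below saturation and fails above it", {
  # caffeine family: all processes linear at these concentrations
  m <- get_family_model("caffeine")
  sys <- build_ode_system(m)
  t_eval <- c(15, 30, 60, 120)
  tc1 <- simulate_model(sys, list(dose_event("CAF", 100)), t_eval)
  tc2 <- simulate_model(sys, list(dose_event("CAF", 200)), t_eval)
  expect_equal(2 * tc1$amounts, tc2$amounts, tolerance = 1e-4)
  # talinolol: canalicular Abcb1a transport saturates, linearity must fail
  mt <- get_family_model("talinolol")
  syst <- build_ode_system(mt)
  b1 <- tc_amount(simulate_model(syst, list(dose_event("TAL", 1e4)), t_eval),
                  "bile", "TAL")
  b2 <- tc_amount(simulate_model(syst, list(dose_event("TAL", 2e4)), t_eval),
                  "bile", "TAL")
  expect_true(any(abs(b2 - 2 * b1) / pmax(b1, 1e-12) > 1e-3))
})

test_that("sink amounts never decrease and repeat runs are bit-identical", {
  t_eval <- seq(10, 240, by = 10)
  for (drug in c("midazolam", "codeine", "pravastatin")) {
    m <- get_family_model(drug)
    d <- list(family_dose(drug, 0.025))
    tc <- simulate_model(build_ode_system(m), d, t_eval)
    for (s in names(m$species)) {
      expect_true(all(diff(tc_amount(tc, "urine", s)) >= -1e-8), label = paste(drug, s))
      expect_true(all(diff(tc_amount(tc, "bile", s)) >= -1e-8), label = paste(drug, s))
      expect_true(all(diff(tc_amount(tc, "unknown_sink", s)) >= -1e-8),
                  label = paste(drug, s))
    }
    tc2 <- simulate_model(build_ode_system(m), d, t_eval)
    expect_identical(tc$amounts, tc2$amounts)
  }
})

test_that("time-course export is tidy and JSON round-trips preserve dynamics", {
  m <- mdz_model()
  tc <- simulate_model(build_ode_system(m), mdz_dose(), c(15, 60))
  df <- as.data.frame(tc)
  expect_named(df, c("time_min", "compartment", "species", "amount_nmol",
                     "conc_nmol_per_L"))
  expect_equal(nrow(df), 2 * 8 * 3)
  expect_true(all(is.na(df$conc_nmol_per_L[df$compartment == "urine"])))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(tc, path)
  expect_equal(nrow(utils::read.delim(path)), nrow(df))

  jpath <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, jpath)
  m2 <- read_model_json(jpath)
  tc2 <- simulate_model(build_ode_system(m2), mdz_dose(), c(15, 60))
  expect_equal(tc$amounts, tc2$amounts, tolerance = 1e-12)
  # version guard
  doc <- jsonlite::read_json(jpath)
  doc$schema_version <- "99"
  jsonlite::write_json(doc, jpath, auto_unbox = TRUE)
  expect_error(read_model_json(jpath), "schema version")
})
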