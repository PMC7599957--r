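## small analytic motifs used throughout
motifSynthDeg <- function() {
  cfg <- list(
    species = list(list(id = "src", role = "boundary", initial_value = 1),
                   list(id = "A", role = "dynamic", initial_value = 0),
                   list(id = "snk", role = "boundary", initial_value = 0)),
    reactions = list(
      list(id = "Rsyn", substrates = list(list(species = "src")),
           products = list(list(species = "A")),
           rate_law = "mass_action_1st_order", params = list(k = "k_s")),
      list(id = "Rdeg", substrates = list(list(species = "A")),
           products = list(list(species = "snk")),
           rate_law = "mass_action_1st_order", params = list(k = "k_d"))))
  k <- c(k_s = 0.3, k_d = 0.12)
  params <- new("ParameterSet", constants = k,
                provenance = setNames(rep("calibrated", 2), names(k)),
                initial = c(src = 1, A = 0, snk = 0))
  list(model = buildModel(cfg), params = params)
}

motifMM <- function(vmax = 0.4, km = 2) {
  cfg <- list(
    species = list(list(id = "src", role = "boundary", initial_value = 1),
                   list(id = "A", role = "dynamic", initial_value = 0),
                   list(id = "snk", role = "boundary", initial_value = 0)),
    reactions = list(
      list(id = "Rin", substrates = list(list(species = "src")),
           products = list(list(species = "A")),
           rate_law = "mass_action_1st_order", params = list(k = "k_in")),
      list(id = "Rmm", substrates = list(list(species = "A")),
           products = list(list(species = "snk")),
           rate_law = "michaelis_menten_irreversible",
           params = list(vmax = "vm", km = "km"))))
  ## influx vmax/2 puts the steady state exactly at A = Km
  k <- c(k_in = vmax / 2, vm = vmax, km = km)
  params <- new("ParameterSet", constants = k,
                provenance = setNames(rep("calibrated", 3), names(k)),
                initial = c(src = 1, A = 0, snk = 0))
  list(model = buildModel(cfg), params = params)
}

test_that("elasticities reproduce their analytic values", {
  ## first-order step: elasticity exactly 1
  f <- motifSynthDeg()
  ss <- findSteadyState(f$model, f$params)
  E <- elasticityMatrix(f$model, f$params, ss)
  expect_equal(unname(E["Rdeg", "A"]), 1, tolerance = 1e-6)
  expect_equal(unname(E["Rsyn", "A"]), 0, tolerance = 1e-9)
  ## Michaelis-Menten step probed at S = Km: elasticity 1/2
  g <- motifMM()
  ssg <- findSteadyState(g$model, g$params)
  expect_equal(unname(ssg@state["A"]), 2, tolerance = 1e-6)
  Eg <- elasticityMatrix(g$model, g$params, ssg)
  expect_equal(unname(Eg["Rmm", "A"]), 0.5, tolerance = 1e-5)
  ## finite-difference and closed-form elasticities agree on the baseline
  ssb <- findSteadyState(base$model, base$params)
  Eb <- elasticityMatrix(base$model, base$params, ssb)
  Ea <- elasticityMatrix(base$model, base$params, ssb, method = "analytic")
  expect_equal(Eb, Ea, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("control coefficients recover classic analytic results", {
  ## committed first step of an irreversible chain holds all flux control
  ss <- findSteadyState(tiny$model, tiny$params)
  cc <- fluxControlCoefficients(tiny$model, tiny$params, ss)
  expect_equal(unname(cc@flux_cc[, "Rin"]), rep(1, 4), tolerance = 1e-6)
  expect_equal(unname(cc@flux_cc[, "Rab"]), rep(0, 4), tolerance = 1e-6)
  ## synthesis/degradation motif: C^S = +1 / -1
  f <- motifSynthDeg()
  ssf <- findSteadyState(f$model, f$params)
  ccf <- concentrationControlCoefficients(f$model, f$params, ssf)
  expect_equal(unname(ccf@conc_cc["A", ]), c(1, -1), tolerance = 1e-6)
})

test_that("summation theorems hold on the baseline steady state", {
  ss <- findSteadyState(base$model, base$params)
  cc <- fluxControlCoefficients(base$model, base$params, ss)
  expect_false(any(cc@flags$failed))
  ## per flux: sum_i C_i^J = 1; includes the LDL-C sink flux R18
  expect_true(all(abs(rowSums(cc@flux_cc) - 1) < 1e-3))
  expect_lt(abs(sum(cc@flux_cc["R18", ]) - 1), 1e-3)
  ## per species: sum_i C_i^S = 0; includes free cholesterol
  expect_true(all(abs(rowSums(cc@conc_cc)) < 1e-3))
  expect_lt(abs(sum(cc@conc_cc["FC", ])), 1e-3)
  ## raising acetyl-CoA synthesis raises free cholesterol
  expect_gt(cc@conc_cc["FC", "R1"], 0)
})

test_that("finite-difference and matrix-method coefficients agree", {
  ss <- findSteadyState(base$model, base$params)
  fd <- fluxControlCoefficients(base$model, base$params, ss)
  mm <- fluxControlCoefficients(base$model, base$params, ss, method = "matrix")
  expect_lt(max(abs(fd@flux_cc - mm@flux_cc)), 1e-3)
  expect_lt(max(abs(fd@conc_cc - mm@conc_cc)), 1e-3)
})

test_that("coefficients are robust to the perturbation size", {
  ss <- findSteadyState(base$model, base$params)
  c3 <- fluxControlCoefficients(base$model, base$params, ss, delta = 1e-3)
  c4 <- fluxControlCoefficients(base$model, base$params, ss, delta = 1e-4)
  ## 3 significant figures wherever the coefficient is non-negligible
  big <- abs(c3@conc_cc) > 1e-4
  expect_lt(max(abs((c3@conc_cc[big] - c4@conc_cc[big]) / c3@conc_cc[big])),
            1e-3)
})

test_that("zero steady-state fluxes are flagged, not silently zeroed", {
  cfg <- list(
    species = list(list(id = "src", role = "boundary", initial_value = 1),
                   list(id = "A", role = "dynamic", initial_value = 0),
                   list(id = "B", role = "dynamic", initial_value = 0),
                   list(id = "snk", role = "boundary", initial_value = 0)),
    reactions = list(
      list(id = "Rsyn", substrates = list(list(species = "src")),
           products = list(list(species = "A")),
           rate_law = "mass_action_1st_order", params = list(k = "k_s")),
      list(id = "Rdeg", substrates = list(list(species = "A")),
           products = list(list(species = "snk")),
           rate_law = "mass_action_1st_order", params = list(k = "k_d")),
      ## dead-end equilibrium branch: zero net flux at steady state
      list(id = "Req", substrates = list(list(species = "A")),
           products = list(list(species = "B")), reversible = TRUE,
           rate_law = "reversible_mass_action",
           params = list(kf = "kf", kr = "kr"))))
  k <- c(k_s = 0.3, k_d = 0.12, kf = 0.05, kr = 0.1)
  params <- new("ParameterSet", constants = k,
                provenance = setNames(rep("calibrated", 4), names(k)),
                initial = c(src = 1, A = 0, B = 0, snk = 0))
  model <- buildModel(cfg)
  ss <- findSteadyState(model, params)
  expect_lt(abs(ss@fluxes[["Req"]]), 1e-9)
  E <- elasticityMatrix(model, params, ss)
  expect_true(all(is.na(E["Req", ])))
  expect_true(all(attr(E, "undefined")["Req", ]))
})

test_that("the MCA report ranks steps and recomputes theorem residuals", {
  ss <- findSteadyState(base$model, base$params)
  cc <- fluxControlCoefficients(base$model, base$params, ss)
  dir <- tempfile()
  rep <- mcaReport(cc, dir)
  ## acetyl-CoA synthesis carries the largest mean concentration control
  expect_identical(rep$top_steps[1], "R1")
  ## every ranking block is sorted by |coefficient|
  fc <- rep$conc_ranking[rep$conc_ranking$target == "FC", ]
  expect_identical(fc$coefficient, fc$coefficient[order(-abs(fc$coefficient))])
  expect_true(all(abs(rep$theorem_residuals$flux) < 1e-3))
  expect_true(all(abs(rep$theorem_residuals$concentration) < 1e-3))
  expect_true(all(file.exists(file.path(dir, c("flux_control.csv",
                                               "concentration_control.csv",
                                               "theorem_residuals.json")))))
  ## empty coefficients: empty report, no error
  ssT <- findSteadyState(tiny$model, tiny$params)
  empty <- new("ControlCoefficients",
               flux_cc = matrix(numeric(), 0, 0),
               conc_cc = matrix(numeric(), 0, 0),
               elasticities = matrix(numeric(), 0, 0),
               flags = list(failed = logical(0),
                            undefined = matrix(logical(), 0, 0)),
               reference = ssT, delta = 1e-3, method = "finite_difference")
  repE <- mcaReport(empty)
  expect_identical(nrow(repE$flux_ranking), 0L)
  expect_length(repE$theorem_residuals$flux, 0L)
})
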