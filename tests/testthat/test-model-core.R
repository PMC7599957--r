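test_that("baseline config builds the full network", {
  m <- base$model
  expect_s4_class(m, "CholModel")
  expect_length(m@reactions, 30L)
  expect_identical(sum(m@species$role == "dynamic"), 22L)
  expect_identical(dim(stoichiometryMatrix(m)), c(22L, 30L))
  expect_identical(reactionIds(m), paste0("R", 1:30))
  ## reversibility exactly where the reaction list prints an equilibrium
  rev <- vapply(m@reactions, function(r) r$reversible, logical(1))
  expect_identical(reactionIds(m)[rev], c("R2", "R6", "R8"))
})

test_that("invalid configs are rejected with informative errors", {
  path <- system.file("extdata", "baseline_model.yaml", package = "cholsim")
  cfg <- yaml::read_yaml(path)
  ## omit R15
  drop15 <- cfg
  drop15$reactions <- Filter(function(r) r$id != "R15", drop15$reactions)
  expect_error(buildModel(drop15, required_reactions = paste0("R", 1:30)),
               "R15")
  ## duplicated species id
  dup <- cfg
  dup$species <- c(dup$species, dup$species[1])
  expect_error(buildModel(dup), "duplicated species id")
  ## unknown species referenced by a reaction
  bad <- cfg
  bad$reactions[[1]]$products[[1]]$species <- "NOPE"
  expect_error(buildModel(bad), "NOPE")
  ## missing parameter binding
  expect_error(
    buildModel(cfg, params = setConstants(tiny$params, dummy = 1)),
    "missing parameter")
  ## negative constants never validate
  expect_error(loadBaseline(local({
    tf <- tempfile(fileext = ".yaml")
    doc <- yaml::read_yaml(system.file("extdata", "baseline_params.yaml",
                                       package = "cholsim"))
    doc$constants$vmax_r15$value <- -1
    yaml::write_yaml(doc, tf)
    tf
  })), "positive")
})

test_that("stoichiometry matrix carries the printed net coefficients", {
  N <- stoichiometryMatrix(base$model)
  ## condensation of acetyl-CoA with acetoacetyl-CoA
  expect_identical(N[c("ACoA", "AACoA", "HMGCoA"), "R3"], c(ACoA = -1, AACoA = -1, HMGCoA = 1))
  ## prenyl chain extension consumes IPP alongside DMAPP
  expect_identical(N[c("DMAPP", "IPP", "GPP"), "R9"], c(DMAPP = -1, IPP = -1, GPP = 1))
  ## two further IPP consumed across R9 + R10
  expect_equal(sum(N["IPP", c("R9", "R10")]), -2)
  ## boundary species are excluded
  expect_false(any(c("CoAS", "LDLCs") %in% rownames(N)))
  ## an empty model yields a 0 x 0 matrix
  empty <- buildModel(list(species = list(list(id = "Z", role = "dynamic",
                                               initial_value = 0)),
                           reactions = list()))
  expect_identical(dim(stoichiometryMatrix(empty)), c(0L, 0L))
})

test_that("rates at an all-zero dynamic state isolate the synthesis steps", {
  m <- base$model
  v <- reactionRates(m, setNames(rep(0, 22), speciesIds(m, "dynamic")),
                     base$params)
  synth <- c("R1", "R19", "R22", "R24", "R25", "R27", "R29")
  expect_true(all(v[synth] > 0))
  expect_true(all(v[setdiff(names(v), synth)] == 0))
})

test_that("the HMGCR step saturates at its Vmax", {
  m <- base$model
  st <- setNames(rep(0, 22), speciesIds(m, "dynamic"))
  st["HMGCoA"] <- 1e9
  v <- reactionRates(m, st, base$params)
  expect_equal(unname(v["R4"]), 1.43, tolerance = 1e-6)
  ## and never exceeds it along a trajectory state
  st["HMGCoA"] <- 5
  expect_lt(reactionRates(m, st, base$params)[["R4"]], 1.43)
})

test_that("acetyl-CoA synthesis is first order in its rate constant", {
  m <- base$model
  st <- setNames(stats::runif(22, 0, 2), speciesIds(m, "dynamic"))
  v1 <- reactionRates(m, st, base$params)
  v2 <- reactionRates(m, st, setConstants(base$params, k1 = 2 * getConstants(base$params)[["k1"]]))
  expect_equal(unname(v2["R1"]), 2 * unname(v1["R1"]), tolerance = 1e-12)
  expect_equal(v2[setdiff(names(v2), "R1")], v1[setdiff(names(v1), "R1")])
})

test_that("the right-hand side is the stoichiometry matrix times the rates", {
  m <- base$model
  set.seed(7)
  for (i in 1:5) {
    st <- setNames(stats::runif(22, 0, 3), speciesIds(m, "dynamic"))
    st["LDLR"] <- stats::runif(1, 1e4, 4e4)
    v <- reactionRates(m, st, base$params)
    expect_equal(odeRHS(m, st, base$params),
                 setNames(as.numeric(stoichiometryMatrix(m) %*% v),
                          speciesIds(m, "dynamic")))
    ## d[HMG-CoA]/dt = v(R3) - v(R4)
    expect_equal(unname(odeRHS(m, st, base$params)["HMGCoA"]),
                 unname(v["R3"] - v["R4"]))
  }
})

test_that("negative concentrations raise a domain error", {
  m <- base$model
  st <- setNames(rep(0, 22), speciesIds(m, "dynamic"))
  st["FC"] <- -0.5
  expect_error(reactionRates(m, st, base$params), "negative concentration.*FC")
  expect_error(odeRHS(m, st, base$params), "FC")
})

test_that("finite differences of a trajectory match the right-hand side", {
  f <- tiny
  tr <- simulateModel(f$model, f$params, 50, record_times = seq(0, 50, 0.5))
  i <- c(20, 50, 80)
  for (j in i) {
    fd <- (tr@states[j + 1, ] - tr@states[j - 1, ]) / (tr@times[j + 1] - tr@times[j - 1])
    rhs <- odeRHS(f$model, tr@states[j, ], f$params)
    expect_equal(fd, rhs, tolerance = 1e-3)
  }
})

test_that("trajectories stay non-negative and boundary pools constant", {
  tr <- simulateModel(base$model, base$params, 3000,
                      record_times = seq(0, 3000, 100))
  expect_true(all(tr@states >= 0))
  expect_identical(tr@states[1, ], initialConcentrations(base$params)[colnames(tr@states)])
  ## boundary species are not part of the dynamic state at all, and their
  ## pool values feed the rates unchanged at every time
  expect_false(any(speciesIds(base$model, "boundary") %in% colnames(tr@states)))
})
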