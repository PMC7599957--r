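table2spec <- list(axes = list(vmax_r15 = seq(0.01, 0.05, by = 0.01),
                               vmax_r4 = 1:5),
                   observables = c("FC", "CE", "LDLC", "LDLR"))

test_that("the combined-modulation grid reproduces printed readouts", {
  sc <- runScan(base$model, base$params, table2spec)
  g <- sc@grid
  expect_identical(nrow(g), 25L)
  expect_true(all(g$ok))
  cell <- function(r15, r4) g[g$vmax_r15 == r15 & g$vmax_r4 == r4, ]
  ## two spot cells of the printed grid, 1% relative tolerance
  expect_equal(cell(0.04, 1)$FC, 2.83914, tolerance = 0.01)
  expect_equal(cell(0.01, 5)$FC, 22.2705, tolerance = 0.01)
})

test_that("a one-point scan equals the plain simulation readout", {
  sc <- runScan(base$model, base$params,
                list(axes = list(vmax_r4 = 1.43),
                     observables = c("FC", "ACoA")))
  tr <- simulateModel(base$model, base$params, 3000)
  end <- tr@states[nrow(tr@states), ]
  expect_equal(sc@grid$FC, unname(end["FC"]), tolerance = 1e-10)
  expect_equal(sc@grid$ACoA, unname(end["ACoA"]), tolerance = 1e-10)
})

test_that("scan cells are independent of grid order", {
  spec1 <- list(axes = list(vmax_r15 = c(0.01, 0.03, 0.05)),
                observables = c("FC", "CE"))
  spec2 <- list(axes = list(vmax_r15 = c(0.05, 0.01, 0.03)),
                observables = c("FC", "CE"))
  g1 <- runScan(base$model, base$params, spec1)@grid
  g2 <- runScan(base$model, base$params, spec2)@grid
  g2 <- g2[match(g1$vmax_r15, g2$vmax_r15), ]
  expect_equal(g1$FC, g2$FC, tolerance = 1e-12)
  expect_equal(g1$CE, g2$CE, tolerance = 1e-12)
})

test_that("HMGCR activation sweep shows the expected directions", {
  sc <- hmgcrScan(base$model, base$params)
  g <- sc@grid[order(sc@grid$vmax_r4), ]
  expect_identical(nrow(g), 10L)
  expect_true(all(diff(g$HMGCoA) < 0))  # HMG-CoA falls monotonically
  expect_true(all(diff(g$FC) > 0))      # free cholesterol accumulates
  ## single-point sweep degenerates to one row
  expect_identical(nrow(hmgcrScan(base$model, base$params, values = 1.43)@grid), 1L)
})

test_that("ACAT2 decline raises FC and depresses CE, LDL-C and LDLr", {
  sc <- acat2Scan(base$model, base$params)
  g <- sc@grid[order(sc@grid$vmax_r15), ]  # ascending Vmax
  expect_identical(nrow(g), 6L)
  expect_true(all(diff(g$FC) < 0))    # FC increases as Vmax(R15) decreases
  expect_true(all(diff(g$CE) > 0))
  expect_true(all(diff(g$LDLC) > 0))
  expect_true(all(diff(g$LDLR) > 0))
  ## the 0.04 point is consistent with the combined grid's baseline row
  comb <- runScan(base$model, base$params,
                  list(axes = list(vmax_r15 = 0.04, vmax_r4 = 1.43),
                       observables = c("FC", "CE", "LDLC", "LDLR")))
  expect_equal(g$FC[g$vmax_r15 == 0.04], comb@grid$FC, tolerance = 1e-10)
})

test_that("grid monotonicity matches the printed table cell-wise", {
  g <- runScan(base$model, base$params, table2spec)@grid
  for (r4 in 1:5) {
    col <- g[g$vmax_r4 == r4, ]
    col <- col[order(col$vmax_r15), ]
    expect_true(all(diff(col$FC) < 0))    # FC falls as Vmax(R15) rises
    expect_true(all(diff(col$CE) > 0))
    expect_true(all(diff(col$LDLC) > 0))
    expect_true(all(diff(col$LDLR) > 0))
  }
  for (r15 in seq(0.01, 0.05, by = 0.01)) {
    row <- g[g$vmax_r15 == r15, ]
    row <- row[order(row$vmax_r4), ]
    expect_true(all(diff(row$FC) >= 0))   # FC non-decreasing in Vmax(R4)
  }
})

test_that("scenario readouts hit the acetyl-CoA anchors", {
  bl <- runScenario(base$model, base$params, "baseline")
  expect_equal(bl$ACoA, 32.13, tolerance = 0.005)
  t1 <- runScenario(base$model, base$params, "t1dm")
  expect_equal(t1$ACoA, 57.52, tolerance = 0.005)
  expect_error(runScenario(base$model, base$params, "immortal"),
               "baseline.*aging.*high_fat")
})

test_that("ageing shifts the acetyl-CoA scenarios as hypothesised", {
  for (nm in c("high_fat", "t2dm", "t1dm")) {
    young <- runScenario(base$model, base$params, nm)
    aged <- runScenario(base$model, base$params, paste0("aging+", nm))
    expect_gt(aged$FC, young$FC)    # more hepatic free cholesterol with age
    expect_lt(aged$LDLC, young$LDLC)  # less circulating LDL-C with age
  }
  ## acetyl-CoA synthesis drives FC, CE and LDL-C up
  sc <- runScan(base$model, base$params,
                list(axes = list(k1 = c(0.1, 0.115, 0.175, 0.2)),
                     observables = c("FC", "CE", "LDLC")))
  g <- sc@grid[order(sc@grid$k1), ]
  expect_true(all(diff(g$FC) > 0))
  expect_true(all(diff(g$CE) > 0))
  expect_true(all(diff(g$LDLC) > 0))
})

test_that("scan validation and failure flagging behave as documented", {
  expect_error(runScan(base$model, base$params,
                       list(axes = list(vmax_r4 = c(1, -2)))), "finite")
  expect_error(runScan(base$model, base$params,
                       list(axes = list(nosuch = 1))), "nosuch")
  expect_error(runScan(base$model, base$params,
                       list(axes = list(vmax_r4 = 1),
                            observables = "XX")), "XX")
  ## a pathological grid point is flagged and the scan continues
  sc <- runScan(base$model, base$params,
                list(axes = list(k3 = c(0.01, 1e200)),
                     observables = "ACoA"))
  g <- sc@grid[order(sc@grid$k3), ]
  expect_identical(g$ok, c(TRUE, FALSE))
  expect_false(is.na(g$ACoA[1]))
  expect_true(is.na(g$ACoA[2]))
})
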