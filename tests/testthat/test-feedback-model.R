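refP <- referenceParams()

test_that("one step from the all-off state matches the hand computation", {
  p <- refP
  st <- cytograd:::initState(p)
  out <- simStep(st, p)
  drive <- cytograd:::sourceDrive(p)
  n0 <- st$n[1]; B0 <- st$B[1]
  expected <- p@uptake * B0 * n0 * drive * p@contact$deliver_prob
  expect_equal(out$state$C, expected, tolerance = 1e-12)
  expect_equal(out$delivered, sum(expected), tolerance = 1e-12)
})

test_that("with feedback off the fixed point is the geometric closed form", {
  p <- simParams(cytoneme = list(alpha = 0, beta = 0, gamma = 0),
                 receptor = list(alpha = 0, beta = 0, gamma = 0))
  res <- runToSteadyState(p)
  expect_true(converged(res))
  st <- steadyStates(res)
  drive <- cytograd:::sourceDrive(p)
  closedForm <- p@uptake * st$B[1] * st$n[1] * drive *
    p@contact$deliver_prob / p@deltaC
  expect_equal(st$C, closedForm, tolerance = 1e-6)
  # a pure exponential in distance: per-cell ratio is constant
  expect_equal(diff(log(st$C)),
               rep(-10 / p@contact$rho_um, p@nCells - 1),
               tolerance = 1e-6)
})

test_that("without a source the ligand dies and repressors take over", {
  p <- refP
  p@sources$strength <- 0
  res <- runToSteadyState(p)
  st <- steadyStates(res)
  expect_true(all(st$C < 1e-6))
  expect_true(all(st$P < 1e-3))
  expect_true(all(st$K > 0.9))
  expect_true(all(st$Y > 0.9))
  expect_true(all(st$n == p@cytoneme$n_floor))
  dom <- expressionDomains(res)
  expect_equal(dom$n_on[dom$gene == "sty"], 0)  # empty domain, no error
})

test_that("two-sided sources give a mirror-symmetric steady state", {
  p <- refP
  L <- p@nCells * p@cellDiameter
  p@sources <- data.frame(pos_um = c(0, L), strength = c(10, 10))
  st <- steadyStates(runToSteadyState(p))
  for (f in c("C", "P", "K", "Y", "n", "B")) {
    expect_equal(st[[f]], rev(st[[f]]), tolerance = 1e-9)
  }
})

test_that("the unperturbed steady gradient is monotone non-increasing", {
  st <- steadyStates(runToSteadyState(refP))
  expect_true(all(diff(st$C) <= 1e-12))
  expect_true(all(diff(st$n) <= 1e-9))
})

test_that("mass bookkeeping balances to 1e-9 in finite-pool mode", {
  p <- refP
  p@finitePool <- TRUE
  p@poolProduction <- 30
  res <- runToSteadyState(p)
  led <- res@ledger
  expect_lt(abs(led$produced - led$delivered - led$undelivered),
            1e-9 * max(led$produced, 1))
})

test_that("no cell co-expresses PntP1 and Cut above 0.9 at steady state", {
  st <- steadyStates(runToSteadyState(refP))
  expect_false(any(st$P > 0.9 & st$K > 0.9))
})

test_that("feedback gains act with the stated signs", {
  base <- steadyStates(runToSteadyState(refP))
  dom <- expressionDomains(runToSteadyState(refP))
  cutCells <- seq(dom$first_on_cell[dom$gene == "cut"],
                  dom$last_on_cell[dom$gene == "cut"])
  yanCells <- seq(dom$first_on_cell[dom$gene == "yan"],
                  dom$last_on_cell[dom$gene == "yan"])
  up <- function(block, field, by) {
    p <- refP
    slot(p, block)[[field]] <- slot(p, block)[[field]] + by
    steadyStates(runToSteadyState(p))
  }
  # stronger positive feedback raises tip ligand
  pa <- refP
  pa@cytoneme$alpha <- pa@cytoneme$alpha * 1.3
  stA <- steadyStates(runToSteadyState(pa))
  expect_gt(stA$C[1], base$C[1])
  # stronger Cut-mediated negative feedback lowers cut-domain ligand
  pb <- refP
  pb@cytoneme$beta <- pb@cytoneme$beta * 1.3
  pb@receptor$beta <- pb@receptor$beta * 1.3
  stB <- steadyStates(runToSteadyState(pb))
  expect_lt(sum(stB$C[cutCells]), sum(base$C[cutCells]))
  # stronger Yan-mediated negative feedback lowers ligand where Yan is
  # active and production is not already pinned at the clamp floors
  # (fully suppressed stalk cells are saturated and cannot drop further)
  pg <- refP
  pg@cytoneme$gamma <- pg@cytoneme$gamma * 1.5
  pg@receptor$gamma <- pg@receptor$gamma * 1.5
  stG <- steadyStates(runToSteadyState(pg))
  yanActive <- which(base$Y > 0.01 & base$B > refP@receptor$B_floor)
  expect_gt(length(yanActive), 0)
  expect_lt(sum(stG$C[yanActive]), sum(base$C[yanActive]))
  expect_true(all(stG$C <= base$C + 1e-9))
})

test_that("stochastic mode is reproducible under a fixed seed", {
  p <- refP
  p@mode <- "stochastic"
  a <- steadyStates(runToSteadyState(p, seed = 5, stochSteps = 50L))
  b <- steadyStates(runToSteadyState(p, seed = 5, stochSteps = 50L))
  d <- steadyStates(runToSteadyState(p, seed = 6, stochSteps = 50L))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("clone overrides pin the right quantities and check conflicts", {
  p <- applyClone(refP, 1:3, "cut_GOF")
  st <- steadyStates(runToSteadyState(p))
  expect_true(all(st$K[1:3] == 1))
  expect_error(applyClone(p, 3:4, "cut_GOF"), "conflict")
  # different pinned fields may coexist on one cell
  expect_silent(p2 <- applyClone(p, 1:2, "btl_GOF"))
  expect_error(applyClone(refP, 10:20, "pnt_GOF"), "outside")
  expect_error(applyClone(refP, integer(), "pnt_GOF"), "target cells")
  expect_error(applyClone(refP, override = "ectopic_source"), "position")
  pb <- applyClone(refP, 5:6, "btl_LOF")
  stb <- steadyStates(runToSteadyState(pb))
  expect_true(all(stb$B[5:6] == 0))
})

test_that("a period-2 oscillation is detected and reported", {
  p <- simParams(relax = 1,
                 thresholds = c(pnt = 0.92, cut = 0.91),
                 inhibition = c(w_KP = 40, w_PK = 40),
                 hillN = c(pnt = 4, cut = 4),
                 maxSteps = 4000L)
  res <- suppressWarnings(runToSteadyState(p))
  expect_true(res@oscillating || res@converged)
  if (res@oscillating) expect_false(res@converged)
})

test_that("a 4-cell minimal axis still converges", {
  p <- refP
  p@nCells <- 4L
  res <- runToSteadyState(p)
  expect_true(converged(res))
})

test_that("scene export closes the loop and respects clones", {
  res <- runToSteadyState(refP)
  ex <- exportScene(res, sceneDefaults = list(seed = 9))
  expect_s4_class(ex$config, "SceneConfig")
  expect_equal(ex$config@nCells, 14L)
  expect_equal(length(ex$perCellIntensity), 14L)
  # zero-ligand result exports an empty-ligand scene
  p0 <- refP
  p0@sources$strength <- 0
  ex0 <- exportScene(runToSteadyState(p0))
  expect_true(all(ex0$perCellIntensity == 0))
  sc0 <- renderScene(ex0$config, perCellIntensity = ex0$perCellIntensity)
  expect_equal(nrow(groundTruth(sc0)@puncta), 0)
  # clone cells propagate into the scene config
  pc <- applyClone(refP, 4:5, "cut_GOF")
  exc <- exportScene(runToSteadyState(pc))
  expect_equal(exc$config@clones[[1]]$cells, 4:5)
})

test_that("expression domains require convergence and report structure", {
  p <- refP
  p@maxSteps <- 3L
  res <- runToSteadyState(p)
  expect_false(converged(res))
  expect_error(expressionDomains(res), "converged")
  dom <- expressionDomains(runToSteadyState(refP))
  expect_true(all(dom$contiguous, na.rm = TRUE))
  # sty domain nested in the pntP1 domain
  expect_lte(dom$last_on_cell[dom$gene == "sty"],
             dom$last_on_cell[dom$gene == "pntP1"])
})
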