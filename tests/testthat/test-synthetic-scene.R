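test_that("straight-tube geometry places cells at cell-diameter spacing", {
  geo <- buildGeometry(sceneConfig(nCells = 12, curvature = 0))
  d <- distancesToSource(geo)
  expect_length(d, 12)
  expect_equal(diff(d), rep(10, 11))
  expect_equal(axisLength(geo), 120)
  geo14 <- buildGeometry(sceneConfig(nCells = 14, cellDiameter = 10))
  expect_equal(axisLength(geo14), 140)
})

test_that("curved geometry: arc spacing preserved, chords shorter than arcs", {
  cfg <- sceneConfig(nCells = 12, curvature = 0.02)
  geo <- buildGeometry(cfg)
  # numeric arc-length integration along the midline as oracle
  seg <- diff(geo@midline)
  arcNumeric <- sum(sqrt(rowSums(seg^2)))
  expect_equal(arcNumeric, 120, tolerance = 1e-4)
  expect_equal(diff(geo@cellArc), rep(10, 11))
  chord <- distancesToSource(geo)
  expect_true(all(chord < geo@cellArc))
  # chord oracle: (2/k) * sin(k * s / 2)
  expect_equal(chord, (2 / 0.02) * sin(0.02 * geo@cellArc / 2),
               tolerance = 1e-9)
  expect_true(all(diff(chord) > 0))
})

test_that("self-intersecting curvature is rejected", {
  expect_error(buildGeometry(sceneConfig(nCells = 14, curvature = 0.05)),
               "self-intersect")
})

test_that("identical config and seed give a bit-identical scene", {
  s1 <- tinyScene(seed = 42)
  s2 <- tinyScene(seed = 42)
  expect_identical(sceneStack(s1), sceneStack(s2))
  expect_identical(groundTruth(s1)@puncta, groundTruth(s2)@puncta)
  expect_identical(groundTruth(s1)@traces, groundTruth(s2)@traces)
  s3 <- tinyScene(seed = 43)
  expect_false(identical(sceneStack(s1), sceneStack(s3)))
})

test_that("punctum channel flags follow the configured probabilities", {
  sc <- tinyScene(seed = 2, puncta = list(receptor_binding_prob = 1))
  gt <- groundTruth(sc)@puncta
  expect_true(all(gt$receptor))        # every ligand punctum has a partner
  expect_true(all(gt$endosome <= !gt$surface))  # endosome => internalized
  sc0 <- tinyScene(seed = 2, puncta = list(receptor_binding_prob = 0))
  expect_true(!any(groundTruth(sc0)@puncta$receptor))
})

test_that("EIF channel contains only surface-flagged puncta", {
  sc <- renderScene(recoveryConfig(seed = 5))
  gt <- groundTruth(sc)@puncta
  surface <- gt[gt$surface, ]
  internal <- gt[!gt$surface, ]
  eif <- getChannel(sc, "eif")
  p <- cytograd:::physToPix(gt$x_um, gt$y_um, sc@origin, sc@pixelSize)
  vals <- eif[cbind(round(p$row), round(p$col))]
  # surface puncta leave signal at their position; a purely internal
  # punctum far from any surface one does not
  d2surf <- sapply(which(!gt$surface), function(i) {
    if (!nrow(surface)) return(Inf)
    min((surface$x_um - gt$x_um[i])^2 + (surface$y_um - gt$y_um[i])^2)
  })
  lonely <- which(!gt$surface)[d2surf > 4]
  expect_true(mean(vals[gt$surface]) > 10 * mean(vals[lonely]))
})

test_that("a zero-uptake clone has no ligand puncta inside its mask", {
  sc <- renderScene(cloneConfig(seed = 3, uptake = 0))
  gt <- groundTruth(sc)@puncta
  msk <- sceneCloneMask(sc, marginUm = 0)
  p <- cytograd:::physToPix(gt$x_um, gt$y_um, sc@origin, sc@pixelSize)
  inClone <- msk[cbind(pmin(pmax(round(p$row), 1), nrow(msk)),
                       pmin(pmax(round(p$col), 1), ncol(msk)))]
  expect_equal(sum(inClone), 0)
})

test_that("mean per-cell punctum counts match expectation over seeds", {
  cfg <- tinyConfig(seed = 1, puncta = list(density_scale = 0.4))
  expected <- groundTruth(renderScene(cfg))@cells$expected_count
  counts <- sapply(1:100, function(s) {
    cfg@seed <- s + 1000L
    gt <- groundTruth(renderScene(cfg))
    tabulate(gt@puncta$cell, nbins = cfg@nCells)
  })
  m <- rowMeans(counts)
  se <- apply(counts, 1, sd) / sqrt(ncol(counts))
  expect_true(all(abs(m - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("cytoneme placement honours per-cell counts and contact rule", {
  geo <- buildGeometry(sceneConfig(nCells = 5))
  cfg <- sceneConfig(nCells = 5)
  set.seed(9)
  cy <- placeCytonemes(geo, cfg, perCellCounts = c(5, 3, 1, 0, 2))
  expect_equal(as.vector(table(factor(cy$stats$cell_index,
                                      levels = 1:5))),
               c(5, 3, 1, 0, 2))
  # contact iff reach >= distance to source
  expect_equal(cy$stats$contact,
               cy$stats$length_um >= geo@distances[cy$stats$cell_index])
  # forced long lengths from cell 1 (d = 5 um) always reach the source
  cfgL <- sceneConfig(nCells = 5, cytonemes = list(
    length_mixture = c(short = 0, mid = 0, long = 1), kappa = 100))
  cyL <- placeCytonemes(geo, cfgL, perCellCounts = c(8, 0, 0, 0, 0))
  expect_true(all(cyL$stats$contact))
  expect_true(all(cyL$stats$contact_count >= 1))
})

test_that("kappa = 0 gives uniform orientations (chi-square GOF)", {
  set.seed(11)
  ang <- wrapAngle(cytograd:::rvonmises(10000, 0, 0) * 180 / pi)
  rt <- roseHistogram(ang, binDeg = 20, stratify = FALSE)
  expect_gt(chisq.test(rt$count)$p.value, 0.01)
})

test_that("scene files round-trip through the written TIFF/JSON/CSV", {
  dir <- withr::local_tempdir()
  sc <- tinyScene(seed = 6)
  writeScene(sc, dir)
  back <- readSceneDir(dir)
  expect_equal(back$channels, sc@channelNames)
  expect_equal(back$pixelSize, sc@pixelSize)
  # negative read-noise excursions are clamped at zero on write
  expect_equal(back$stack[, , "ligand"],
               pmax(unname(sceneStack(sc)[, , "ligand"]), 0),
               tolerance = 1e-6)
  expect_equal(nrow(back$traces), nrow(groundTruth(sc)@traces))
})

test_that("oversized punctum demands are rejected", {
  cfg <- tinyConfig(seed = 1, puncta = list(density_scale = 1e6))
  expect_error(renderScene(cfg), "1e6|10\\^6|puncta")
})
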