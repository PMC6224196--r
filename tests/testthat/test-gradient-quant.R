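test_that("midline through collinear anchors is straight with exact arc", {
  ml <- fitMidline(cbind(seq(0, 100, 10), 0))
  expect_equal(midlineArcLength(ml), 100, tolerance = 1e-6)
  expect_lt(max(abs(ml@points[, 2])), 1e-6)
})

test_that("semicircle anchors give arc length within 1% of pi*R", {
  R <- 50
  th <- seq(0, pi, length.out = 20)
  ml <- fitMidline(cbind(R * cos(th), R * sin(th)), tol = 0.5)
  expect_equal(midlineArcLength(ml), pi * R, tolerance = 0.01)
})

test_that("midline fitted to a curved tube mask is within 1 px RMS", {
  cfg <- sceneConfig(nCells = 12, seed = 1, curvature = 0.02)
  sc <- renderScene(cfg)
  d <- dim(sceneStack(sc))
  gx <- matrix(sc@origin[1] + (0:(d[2] - 1)) * sc@pixelSize,
               d[1], d[2], byrow = TRUE)
  gy <- matrix(sc@origin[2] + (0:(d[1] - 1)) * sc@pixelSize, d[1], d[2])
  tc <- cytograd:::tubeCoords(gx, gy, cfg)
  mask <- abs(tc$dist) <= 5 & tc$s >= 0 & tc$s <= 120
  ml <- fitMidline(mask, tol = 0.3, pixelSize = sc@pixelSize,
                   origin = sc@origin, distalEnd = c(0, 0))
  devs <- cytograd:::pointPolylineDist(ml@points[, 1], ml@points[, 2],
                                       sceneGeometry(sc)@midline)
  expect_lt(sqrt(mean(devs^2)), sc@pixelSize)  # 1 px RMS
})

test_that("self-intersecting anchor sets are rejected", {
  # a loop that crosses its own earlier path
  t <- seq(0, 2.4 * pi, length.out = 25)
  loops <- cbind((20 - 4 * t) * cos(t), (20 - 4 * t) * sin(t))
  expect_error(fitMidline(loops, tol = 0.5), "self-intersect")
})

test_that("band profile of a uniform image is constant", {
  img <- matrix(7, 60, 200)
  pr <- extractProfile(img, rbind(c(10, 6), c(30, 6)), bandWidthPx = 10)
  expect_true(all(abs(profileValues(pr) - 7) < 1e-9))
})

test_that("straight-tube scenes: midline and axis extraction agree", {
  sc <- renderScene(recoveryConfig(seed = 4))
  pm <- sceneProfile(sc, useMidline = TRUE)
  pa <- sceneProfile(sc, useMidline = FALSE)
  expect_equal(profileValues(pm), profileValues(pa), tolerance = 1e-12)
})

test_that("band clipping at the image border warns and is recorded", {
  img <- matrix(1, 20, 100)
  expect_warning(
    pr <- extractProfile(img, rbind(c(1, 2), c(18, 2)),
                         bandWidthPx = 30),
    "clipped")
  expect_gt(pr@clipped, 0)
})

test_that("exponential fits recover closed-form slope on noiseless data", {
  x <- seq(0, 120, by = 1)
  f20 <- fitExponential(intensityProfile(x, 100 * exp(-x / 20)),
                        fitBackground = FALSE)
  expect_equal(slopeStat(f20), 100 / (2 * 20 * log(2)),
               tolerance = 1e-6)
  expect_equal(decayLength(f20), 20, tolerance = 1e-6)
  f100 <- fitExponential(intensityProfile(x, 100 * exp(-x / 100)),
                         fitBackground = FALSE)
  expect_equal(slopeStat(f100), 100 / (2 * 100 * log(2)),
               tolerance = 1e-6)
  expect_equal(slopeStat(f100), 0.7213475, tolerance = 1e-6)
  # with a background term the slope uses the amplitude above baseline
  fb <- fitExponential(intensityProfile(x, 5 + 80 * exp(-x / 30)))
  expect_equal(fb@background, 5, tolerance = 1e-4)
  expect_equal(slopeStat(fb), 80 / (2 * 30 * log(2)), tolerance = 1e-4)
  expect_equal(fb@xHalf - fb@xMax, 30 * log(2), tolerance = 1e-4)
})

test_that("non-decaying profiles are flagged with undefined slope", {
  x <- seq(0, 50, 1)
  fc <- fitExponential(intensityProfile(x, rep(3, length(x))))
  expect_true(isFlagged(fc))
  expect_true(is.na(slopeStat(fc)))
  fr <- fitExponential(intensityProfile(x, x))  # rising profile
  expect_true(isFlagged(fr))
})

test_that("slope-length correlation behaves at the extremes", {
  len <- c(60, 80, 100, 120, 140)
  r <- correlateSlopeLength(len, 10 - 0.05 * len)
  expect_equal(r$r, -1, tolerance = 1e-12)
  set.seed(123)
  rn <- correlateSlopeLength(runif(100), runif(100))
  expect_lt(abs(rn$r), 0.3)
  expect_error(correlateSlopeLength(rep(1, 5), 1:5), "variance")
})

test_that("clone ratio is exact on constructed images", {
  img <- matrix(10, 50, 50)
  m1 <- matrix(FALSE, 50, 50); m1[10:20, 10:20] <- TRUE
  m2 <- matrix(FALSE, 50, 50); m2[30:40, 10:20] <- TRUE
  expect_equal(ratioOutIn(cloneRatio(img, m1, m2)), 1)
  img2 <- img; img2[m1] <- 5  # inside intensities exactly halved
  expect_equal(ratioOutIn(cloneRatio(img2, m1, m2)), 2)
  img3 <- img; img3[m1] <- 0
  m0 <- cloneRatio(img3, m1, m2)
  expect_true(m0@infiniteFlag)
  expect_equal(ratioOutIn(m0), Inf)
  expect_error(cloneRatio(img, m1, m1), "disjoint")
  mBig <- matrix(FALSE, 50, 50); mBig[25:48, 2:48] <- TRUE
  expect_error(cloneRatio(img, m1, mBig), "area")
})

test_that("auto-mirrored control ROI matches the explicit one", {
  img <- matrix(runif(50 * 200), 50, 200)
  ml <- rbind(c(0, 25), c(200, 25))
  m1 <- matrix(FALSE, 50, 200); m1[5:20, 50:90] <- TRUE
  auto <- cloneRatio(img, m1, midline = ml)
  mirrored <- matrix(FALSE, 50, 200); mirrored[32:47, 50:90] <- TRUE
  explicit <- cloneRatio(img, m1, mirrored)
  expect_equal(auto@outsideDensity, explicit@outsideDensity,
               tolerance = 0.05)
  expect_equal(auto@insideArea, auto@outsideArea, tolerance = 0.05)
})

test_that("clone ratios on rendered scenes recover 1/uptake_factor", {
  for (uf in c(0.5, 1)) {
    ratios <- vapply(1:12, measuredCloneRatio, numeric(1), uptake = uf)
    expect_lt(abs(mean(ratios) - 1 / uf) * uf, 0.1)
  }
})

test_that("punctum detection finds sparse spots on a quiet background", {
  cfg <- sceneConfig(nCells = 8, seed = 3,
                     gradient = list(Cmax = 100, lambda = 30,
                                     background = 0),
                     puncta = list(density_scale = 0.05,
                                   film_intensity = 0, intensity = 50),
                     noise = list(gaussian_sd = 0.5, poisson = FALSE,
                                  psf_sigma = 0.3))
  sc <- renderScene(cfg)
  det <- detectPuncta(getChannel(sc, "ligand"),
                      pixelSize = sc@pixelSize, origin = sc@origin)
  gt <- groundTruth(sc)@puncta
  matched <- colocalizationFraction(gt, det, 0.5)
  expect_gte(matched, 0.8)
  expect_lt(nrow(det), 2 * nrow(gt))
})

test_that("colocalization fraction honours its invariants", {
  a <- data.frame(x_um = runif(30, 0, 50), y_um = runif(30, 0, 50))
  expect_equal(colocalizationFraction(a, a, 0.5), 1)
  far <- data.frame(x_um = a$x_um + 1000, y_um = a$y_um)
  expect_equal(colocalizationFraction(a, far, 0.5), 0)
  b <- data.frame(x_um = runif(25, 0, 50), y_um = runif(25, 0, 50))
  fr <- sapply(c(0.1, 0.5, 2, 10), function(d) {
    colocalizationFraction(a, b, d)
  })
  expect_true(all(diff(fr) >= 0))          # monotone in max_dist
  expect_true(all(fr >= 0 & fr <= 1))
  expect_warning(fr0 <- colocalizationFraction(a[0, ], b, 0.5),
                 "undefined")
  expect_true(is.na(fr0))
  expect_error(colocalizationFraction(a, b, 0), "> 0")
})

test_that("welch t and ANOVA/Tukey behave on degenerate and powered data", {
  x <- c(1, 2, 3, 4)
  tt <- welchT(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  set.seed(21)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 1, 1)
  expect_lt(welchT(a, b)$p, 0.01)
  gconst <- list(g1 = rep(1, 3), g2 = rep(2, 3), g3 = rep(5, 3))
  expect_error(anovaTukey(gconst), "zero within-group variance")
  # three identical groups: F ~ 0, no significant HSD pairs
  gid <- list(g1 = x, g2 = x, g3 = x)
  rid <- anovaTukey(gid)
  expect_equal(rid$F, 0, tolerance = 1e-12)
  expect_true(all(rid$hsd$p_adj > 0.99))
  set.seed(22)
  gg <- list(tip = rnorm(10, 5), mid = rnorm(10, 5),
             stalk = rnorm(10, 5))
  res <- anovaTukey(gg)
  expect_gt(res$p, 0.001)
  expect_equal(nrow(res$hsd), 3)
  gg$tip <- gg$tip + 10
  res2 <- anovaTukey(gg)
  expect_lt(res2$p, 1e-6)
  expect_true(any(res2$hsd$p_adj < 0.01))
})
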