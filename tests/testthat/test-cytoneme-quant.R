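test_that("trace measurement matches vector arithmetic", {
  m <- measureTrace(rbind(c(0, 0), c(20, 0)), sourcePos = c(30, 0))
  expect_equal(m$length_um, 20)
  expect_equal(m$angle_deg, 0)
  # right-angle L of two 10 um segments, source on the +x axis
  mL <- measureTrace(rbind(c(0, 0), c(10, 0), c(10, 10)),
                     sourcePos = c(50, 0))
  expect_equal(mL$length_um, 20)
  expect_equal(mL$angle_deg, 45)  # net displacement (10, 10)
  d0 <- measureTrace(rbind(c(1, 1), c(1, 1)), sourcePos = c(5, 5))
  expect_true(d0$degenerate)
  expect_equal(d0$length_um, 0)
})

test_that("generated trace tables measure back to their ground truth", {
  sc <- renderScene(recoveryConfig(seed = 7))
  gt <- groundTruth(sc)
  meas <- measureTraces(gt@traces, sceneGeometry(sc)@sourcePos)
  m <- merge(meas, gt@traceStats, by = "trace_id")
  expect_lt(max(abs(m$length_um.x - m$length_um.y)), 1e-6)
  expect_lt(max(abs(wrapAngle(m$angle_deg.x - m$angle_deg.y))), 1e-6)
  expect_equal(as.character(m$length_bin.x), m$length_bin.y)
})

test_that("length bins follow the <15 / 15-30 / >30 um rule", {
  expect_equal(classifyBins(c(5, 14.9, 15, 29, 31)),
               c(short = 2, mid = 2, long = 1))
  expect_equal(classifyBins(c(30)), c(short = 0, mid = 1, long = 0))
  expect_equal(classifyBins(numeric(0)),
               c(short = 0, mid = 0, long = 0))
  expect_error(classifyBins(-1), "negative")
})

test_that("bin counts from a configured mixture sit in multinomial CI", {
  set.seed(32)
  geo <- buildGeometry(sceneConfig(nCells = 5))
  cfg <- sceneConfig(nCells = 5, cytonemes = list(
    length_mixture = c(short = 0.5, mid = 0.3, long = 0.2)))
  cy <- placeCytonemes(geo, cfg, perCellCounts = rep(200, 5))
  counts <- classifyBins(cy$stats$length_um)
  n <- sum(counts)
  for (cls in names(counts)) {
    p <- c(short = 0.5, mid = 0.3, long = 0.2)[cls]
    half <- 2.576 * sqrt(p * (1 - p) / n)
    expect_lt(abs(counts[cls] / n - p), half + 1e-12)
  }
  expect_equal(n, 1000)  # count conservation
})

test_that("rose histograms partition the circle and conserve counts", {
  rt0 <- roseHistogram(rep(0, 25), binDeg = 20, stratify = FALSE)
  expect_equal(sum(rt0$count), 25)
  nz <- rt0[rt0$count > 0, ]
  expect_equal(nrow(nz), 1)
  expect_true(nz$bin_lo < 0 && nz$bin_hi > 0)  # the 0-centred sector
  expect_error(roseHistogram(1:5, binDeg = 25), "divide")
  # concentrated orientations put the mode in the sector containing 0
  set.seed(33)
  a4 <- wrapAngle(cytograd:::rvonmises(5000, 0, 4) * 180 / pi)
  rt4 <- roseHistogram(a4, binDeg = 20, stratify = FALSE)
  mode <- which.max(rt4$count)
  expect_true(rt4$bin_lo[mode] <= 0 && rt4$bin_hi[mode] >= 0)
  expect_equal(sum(rt4$count), 5000)
})

test_that("region assignment maps tip/mid/stalk and rejects bad indices", {
  expect_equal(assignRegion(2), "tip")
  expect_equal(assignRegion(5), "mid")
  expect_equal(assignRegion(9), "stalk")
  expect_equal(assignRegion(c(1, 3, 4, 7, 8, 12)),
               c("tip", "tip", "mid", "mid", "stalk", "stalk"))
  expect_error(assignRegion(0), "out of range")
  expect_error(assignRegion(13, axisCells = 12), "out of range")
  # every valid index maps to exactly one region
  expect_true(all(assignRegion(1:12) %in% c("tip", "mid", "stalk")))
})

test_that("contact counting assigns puncta to the nearest trace", {
  traces <- data.frame(
    trace_id = rep(1:2, each = 2), cell_index = 1,
    vertex = rep(1:2, 2),
    x_um = c(0, 10, 0, 10), y_um = c(0, 0, 5, 5))
  puncta <- data.frame(x_um = c(2, 5, 8), y_um = c(0.2, 0.1, -0.3))
  cc <- countContacts(traces, puncta, maxDistUm = 1)
  expect_equal(cc$contact_count[cc$trace_id == 1], 3)
  expect_equal(cc$contact_count[cc$trace_id == 2], 0)
  cc0 <- countContacts(traces, puncta[0, ], maxDistUm = 1)
  expect_true(all(cc0$contact_count == 0))
  # monotone in the assignment radius
  far <- data.frame(x_um = c(5, 5), y_um = c(2, 3.2))
  n1 <- sum(countContacts(traces, far, 0.5)$contact_count)
  n2 <- sum(countContacts(traces, far, 2.5)$contact_count)
  n3 <- sum(countContacts(traces, far, 6)$contact_count)
  expect_true(n1 <= n2 && n2 <= n3)
  # ground-truth recovery on a generated scene: every punctum is
  # assigned (totals conserved); near the source, traces from one cell
  # overlap, so the nearest-trace proxy may swap puncta between
  # neighbouring traces occasionally
  sc <- renderScene(recoveryConfig(seed = 7))
  gt <- groundTruth(sc)
  cc2 <- countContacts(gt@traces, gt@grasp, maxDistUm = 1)
  m <- merge(cc2, gt@traceStats, by = "trace_id")
  expect_equal(sum(m$contact_count.x), sum(m$contact_count.y))
  expect_gte(mean(m$contact_count.x == m$contact_count.y), 0.85)
})

test_that("contacting cytonemes carry more puncta (two-group test)", {
  set.seed(41)
  contact <- rep(c(TRUE, FALSE), each = 7)   # 14 traces
  loads <- c(rpois(7, 5), rpois(7, 0.5))
  res <- compareContacting(contact, loads)
  expect_lt(res$p, 0.01)
  expect_gt(res$mean_contacting, res$mean_noncontacting)
})
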