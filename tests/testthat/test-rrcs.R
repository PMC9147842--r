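test_that("distance kernel closed forms and shape", {
  expect_identical(deltaScore(3.23), 1)
  expect_identical(deltaScore(4.63), 0)
  expect_equal(deltaScore(3.93), 0.5)
  expect_identical(deltaScore(10.0), 0)
  expect_identical(deltaScore(0), 1)
  # continuous, non-increasing over a fine grid
  r <- seq(0, 8, by = 0.001)
  d <- deltaScore(r)
  expect_true(all(diff(d) <= 0))
  expect_lt(max(abs(diff(d))), 0.002 / (4.63 - 3.23) + 1e-12)
  expect_error(deltaScore(-1), "non-negative")
  expect_error(deltaScore(NaN), "finite")
  # custom bounds
  p <- RRCSParams(rMin = 2, rMax = 4)
  expect_equal(deltaScore(3, p), 0.5)
  expect_error(RRCSParams(rMin = 5, rMax = 4), "rMin < rMax")
})

test_that("single-frame pair scores follow the unweighted heavy-atom sum", {
  a <- list(chain = "A", resno = 10L)
  # two single-heavy-atom residues 3.0 apart
  topo <- pairTopology("CB", "CB")
  b <- list(chain = "A", resno = 20L)
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(rrcsPairFrame(xyz, topo, a, b), 1.0)
  # two side-chain atoms each at 3.0 from a single atom: unweighted sum
  topo2 <- pairTopology(c("CB", "CG"), "CB")
  xyz2 <- rbind(c(3, 0, 0), c(3, 1, 0), c(0, 0, 0))
  expect_equal(rrcsPairFrame(xyz2, topo2, a, b), 2.0)
  # adjacent residues whose only proximal atoms are backbone score zero
  topo3 <- pairTopology(c("N", "CA", "C", "O"), c("N", "CA", "C", "O"),
                        sep = 1L)
  xyz3 <- rbind(matrix(rnorm(12, sd = 0.5), ncol = 3),
                matrix(rnorm(12, sd = 0.5), ncol = 3) +
                  matrix(rep(c(3, 0, 0), each = 4), ncol = 3))
  expect_equal(rrcsPairFrame(xyz3, topo3, a, list(chain = "A", resno = 11L)), 0)
  # identical residues rejected
  expect_error(rrcsPairFrame(xyz, topo, a, a), "distinct")
})

test_that("engine matches the brute-force all-pairs oracle on random systems", {
  set.seed(42)
  for (i in 1:220) {
    sys <- randomTwoResidueSystem()
    got <- rrcsPairFrame(sys$xyz, sys$topo, sys$a, sys$b)
    want <- oracleRRCSPair(sys$topo, sys$xyz, sys$a, sys$b)
    expect_lt(abs(got - want), 1e-9)
    # symmetry is exact
    expect_identical(got, rrcsPairFrame(sys$xyz, sys$topo, sys$b, sys$a))
  }
})

test_that("scores are invariant under rigid motion and monotone in retreat", {
  set.seed(43)
  for (i in 1:25) {
    sys <- randomTwoResidueSystem()
    base <- rrcsPairFrame(sys$xyz, sys$topo, sys$a, sys$b)
    tf <- randomRigidTransform()
    moved <- rrcsPairFrame(applyRigid(sys$xyz, tf), sys$topo, sys$a, sys$b)
    expect_lt(abs(base - moved), 1e-9)
  }
  # moving one atom of B radially away from all of A never raises the score
  topo <- pairTopology(c("CB", "CG"), c("CB", "CG"))
  a <- list(chain = "A", resno = 10L)
  b <- list(chain = "A", resno = 20L)
  xyzA <- rbind(c(0, 0, 0), c(0.5, 1, 0))
  fixedB <- c(3.2, 0.4, 0)
  centroid <- colMeans(xyzA)
  dirs <- seq(0, 6, by = 0.25)
  scores <- vapply(dirs, function(t) {
    movingB <- c(3.5, -0.4, 0) + t * c(1, -0.1, 0.2) / sqrt(1.05)
    rrcsPairFrame(rbind(xyzA, fixedB, movingB), topo, a, b)
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("saturated geometries give the exact atom-count product", {
  # all inter-residue distances <= rMin: score is |A| * |B| after exclusions
  topo <- pairTopology(c("N", "CA", "CB", "CG", "HB1"), c("CB", "CG", "OG"))
  a <- list(chain = "A", resno = 10L)
  b <- list(chain = "A", resno = 20L)  # separation 10: backbone kept
  xyz <- rbind(matrix(runif(15, 0, 0.8), ncol = 3),
               matrix(runif(9, 0.2, 1.0), ncol = 3))
  expect_identical(rrcsPairFrame(xyz, topo, a, b), 4 * 3)
  # near pair: backbone of both excluded -> 2 * 3
  topoNear <- pairTopology(c("N", "CA", "CB", "CG", "HB1"), c("CB", "CG", "OG"),
                           sep = 4L)
  expect_identical(
    rrcsPairFrame(xyz, topoNear, a, list(chain = "A", resno = 14L)), 2 * 3)
})

test_that("series respect stride, replicates and determinism", {
  g <- generatePairSystem(syntheticSpec(nFrames = 100, seed = 3, f = 0.5))
  s <- rrcsSeries(g$trajectory, g$pairs, g$bwMap, stride = 10L)
  expect_equal(nrow(s), 10L)
  expect_equal(s$frame_index, seq(0L, 90L, by = 10L))
  expect_error(rrcsSeries(g$trajectory, g$pairs, g$bwMap, stride = 100L),
               "stride")
  # two replicates in, two series per pair out
  g2 <- generatePairSystem(syntheticSpec(nFrames = 100, seed = 4, f = 0.5))
  g2$trajectory@replicateId <- "rep2"
  s2 <- rrcsSeries(list(g$trajectory, g2$trajectory), g$pairs, g$bwMap)
  expect_equal(length(unique(s2$replicate)), 2L)
  expect_equal(nrow(s2), 200L)
  # a static trajectory yields a constant series
  tr <- g$trajectory
  tr@coords <- array(rep(tr@coords[, , 1], 5), dim = c(atomCount(tr), 3, 5))
  s3 <- rrcsSeries(tr, g$pairs, g$bwMap)
  expect_equal(length(unique(s3$rrcs)), 1L)
})

test_that("histograms conserve counts in left-closed bins from zero", {
  g <- generatePairSystem(syntheticSpec(nFrames = 150, seed = 9, f = 0.7,
                                        nPairs = 2))
  s <- rrcsSeries(g$trajectory, g$pairs, g$bwMap)
  h <- rrcsHistogram(s, binWidth = 0.25)
  expect_equal(sum(h$count), nrow(s))
  expect_equal(h$binStart[1], 0)
  # all-zero series land in the first bin
  s0 <- data.frame(pair_label = "p", replicate = "r", frame_index = 0:9,
                   rrcs = 0)
  h0 <- rrcsHistogram(s0, binWidth = 0.25)
  expect_equal(h0$count[1], 10L)
  expect_equal(sum(h0$count), 10L)
  # doubling the bin width never increases the bin count
  for (bw in c(0.1, 0.25, 0.5)) {
    expect_gte(nrow(rrcsHistogram(s, binWidth = bw)),
               nrow(rrcsHistogram(s, binWidth = 2 * bw)))
  }
  expect_error(rrcsHistogram(s, binWidth = 0), "positive")
})

test_that("verdicts follow the mean difference against the threshold", {
  mkSeries <- function(label, rep, vals) {
    data.frame(pair_label = label, replicate = rep,
               frame_index = seq_along(vals) - 1L, rrcs = vals)
  }
  apo <- rbind(mkSeries("p1", "r1", rep(0, 10)),
               mkSeries("p2", "r1", rep(2, 10)),
               mkSeries("p3", "r1", rep(1, 10)))
  lig <- rbind(mkSeries("p1", "r1", rep(1.5, 10)),
               mkSeries("p2", "r1", rep(1, 10)),
               mkSeries("p3", "r1", rep(1, 10)))
  v <- classifyPairs(apo, lig, threshold = 0.2)
  expect_equal(v$verdict[v$pair_label == "p1"], "increased")
  expect_equal(v$verdict[v$pair_label == "p2"], "decreased")
  expect_equal(v$verdict[v$pair_label == "p3"], "unaffected")
  expect_equal(v$delta[v$pair_label == "p1"], 1.5)
  # condition mean is the mean of per-replicate means, not the pooled mean
  apoR <- rbind(mkSeries("p1", "r1", rep(0, 10)),
                mkSeries("p1", "r2", rep(1, 30)))
  ligR <- mkSeries("p1", "r1", rep(0.5, 10))
  vR <- classifyPairs(apoR, ligR, threshold = 0.2)
  expect_equal(vR$meanApo, 0.5)  # (0 + 1) / 2, not 0.75
  # pair present in only one condition
  expect_error(classifyPairs(apo, lig[lig$pair_label != "p2", ], 0.2),
               "same pair labels")
})
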