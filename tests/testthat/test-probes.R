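test_that("minimum ligand-residue distances ignore hydrogens", {
  topo <- Topology(data.frame(
    serial = 1:5,
    name = c("C1", "C2", "H1", "CB", "CG"),
    element = c("C", "C", "H", "C", "C"),
    chain = c("L", "L", "L", "A", "A"),
    resno = c(1L, 1L, 1L, 71L, 71L),
    resname = c("LIG", "LIG", "LIG", "ASP", "ASP"),
    stringsAsFactors = FALSE))
  lig <- selectAtoms(topo, chain = "L", resno = 1L)
  target <- selectAtoms(topo, chain = "A", resno = 71L)
  # 3-4-5 triangle; the closer ligand atom wins; the 1.0-A hydrogen is unseen
  xyz <- rbind(c(0, 0, 0),      # C1
               c(1, 4, 0),      # C2: 2.0 from CB
               c(3, 3, 0),      # H1: would be 1.0 away, ignored
               c(3, 4, 0),      # CB
               c(30, 0, 0))     # CG far
  tr <- .probeTraj(list(xyz), topo)
  expect_equal(minDistanceSeries(tr, lig, target), 2.0)
  # drop C2: classic 3-4-5 gives 5.0
  xyz2 <- xyz; xyz2[2, ] <- c(100, 0, 0)
  expect_equal(minDistanceSeries(.probeTraj(list(xyz2), topo), lig, target), 5.0)
  # symmetric under swapping the selections; rigid-motion invariant
  tf <- randomRigidTransform()
  trR <- .probeTraj(list(applyRigid(xyz, tf)), topo)
  expect_equal(minDistanceSeries(tr, target, lig),
               minDistanceSeries(tr, lig, target))
  expect_lt(abs(minDistanceSeries(trR, lig, target) -
                minDistanceSeries(tr, lig, target)), 1e-9)
  expect_error(minDistanceSeries(tr, integer(0), target), "empty")
})


test_that("occupancy clouds pool superposed ligand positions", {
  fx <- .cloudFixture()
  tr <- .probeTraj(fx$frames, fx$topo)
  lig <- selectAtoms(fx$topo, chain = "L", resno = 9L)
  cloud <- occupancyCloud(tr, lig, refXYZ = fx$base)
  expect_equal(dim(cloud), c(10 * 4, 3))  # frames x ligand atoms
  # rigid per-frame motion is removed: points scatter only by the jitter
  expect_lt(max(abs(cloud - do.call(rbind, rep(list(fx$base[5:8, ]), 10)))),
            0.3)
  # static trajectory: every atom's pooled positions coincide across frames
  trS <- .probeTraj(rep(list(fx$base), 6), fx$topo)
  cloudS <- occupancyCloud(trS, lig)
  perFrame <- split.data.frame(cloudS, attr(cloudS, "frame"))
  expect_lt(max(vapply(perFrame, function(m) max(abs(m - perFrame[[1]])),
                       numeric(1))), 1e-6)
  # whole-trajectory rotation leaves the cloud invariant after alignment
  tf <- randomRigidTransform()
  trR <- .probeTraj(lapply(fx$frames, applyRigid, tf = tf), fx$topo)
  expect_lt(max(abs(occupancyCloud(trR, lig, refXYZ = fx$base) - cloud)), 1e-6)
  # degenerate (collinear) alignment selection
  topoLin <- fx$topo
  linBase <- fx$base
  linBase[1:4, ] <- cbind(0:3, 0, 0)
  trL <- .probeTraj(list(linBase), topoLin)
  expect_error(occupancyCloud(trL, lig), "collinear")
})

test_that("axis-sweep bottleneck matches the analytic cylinder", {
  ch <- generateChannelSystem(3.0, nRings = 10, atomsPerRing = 8)
  start <- list(chain = "C", resno = 1L)
  prof <- bottleneckSeries(ch$trajectory, start, direction = c(0, 0, 1),
                           pathLength = 9)
  step <- prof@step
  bound <- step^2 / (2 * 3.0)  # worst-case axial discretisation error
  expect_lt(abs(bottleneckRadii(prof) - ch$manifest$trueBottleneck), bound + 1e-9)
  expect_equal(ch$manifest$trueBottleneck, 1.30)
  # 1.30 A: not water permissive at the 1.4 A threshold
  expect_equal(permissiveFraction(prof), 0)
  expect_true(all(prof@closed == FALSE))  # still above the 0.9 A probe

  ch2 <- generateChannelSystem(3.2)
  prof2 <- bottleneckSeries(ch2$trajectory, start, direction = c(0, 0, 1),
                            pathLength = 9)
  expect_lt(abs(bottleneckRadii(prof2) - 1.50), bound + 1e-9)
  expect_equal(permissiveFraction(prof2), 1)

  # no atoms within reach of the swept path: capped maximum
  farTopo <- Topology(data.frame(serial = 1:2, name = c("CB", "CB"),
                                 element = "C", chain = "F", resno = c(1L, 9L),
                                 resname = "UNK", stringsAsFactors = FALSE))
  farTr <- new("Trajectory", topology = farTopo,
               coords = array(c(0, 0, 0, 0, -50, 50), dim = c(2, 3, 1)),
               replicateId = "far")
  profFar <- bottleneckSeries(farTr, list(chain = "F", resno = 1L),
                              direction = c(0, 0, -1), pathLength = 10)
  expect_equal(bottleneckRadii(profFar), 5.0)
  expect_error(bottleneckSeries(ch$trajectory, start, direction = c(0, 0, 0)),
               "zero-length")
  expect_error(bottleneckSeries(ch$trajectory, start, direction = c(0, 0, 1),
                                step = 0), "positive")
  expect_error(bottleneckSeries(ch$trajectory,
                                list(chain = "Z", resno = 1L),
                                direction = c(0, 0, 1)), "not found")
})

test_that("permissive fraction counts strict exceedances and is monotone", {
  prof <- new("ChannelProfile", radii = c(1.3, 1.5, 1.5, 1.2),
              closed = rep(FALSE, 4), probeRadius = 0.9, step = 0.5,
              cap = 5, startLabel = "C:1")
  expect_equal(permissiveFraction(prof), 0.5)
  expect_equal(permissiveFraction(prof, rWater = 1.5), 0)  # strict >
  prof0 <- new("ChannelProfile", radii = rep(0, 5), closed = rep(TRUE, 5),
               probeRadius = 0.9, step = 0.5, cap = 5, startLabel = "C:1")
  expect_equal(permissiveFraction(prof0), 0)
  profCap <- new("ChannelProfile", radii = rep(5, 5), closed = rep(FALSE, 5),
                 probeRadius = 0.9, step = 0.5, cap = 5, startLabel = "C:1")
  expect_equal(permissiveFraction(profCap), 1)
  # monotone non-increasing in the water radius
  rs <- seq(0, 6, by = 0.25)
  fr <- vapply(rs, function(r) permissiveFraction(prof, r), numeric(1))
  expect_true(all(diff(fr) <= 0))
})
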