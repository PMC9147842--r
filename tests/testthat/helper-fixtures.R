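# Shared trajectory fixtures for probe and acceptance tests.

.probeTraj <- function(xyzList, topo) {
  co <- array(unlist(lapply(xyzList, t)), dim = c(3, nrow(xyzList[[1]]),
                                                  length(xyzList)))
  co <- aperm(co, c(2, 1, 3))
  new("Trajectory", topology = topo, coords = co, replicateId = "r1")
}

.cloudFixture <- function(nFrames = 10, seed = 5) {
  set.seed(seed)
  topo <- Topology(data.frame(
    serial = 1:8,
    name = c(rep("CA", 4), paste0("C", 1:4)),
    element = "C",
    chain = c(rep("A", 4), rep("L", 4)),
    resno = c(1:4, rep(9L, 4)),
    resname = c(rep("ALA", 4), rep("LIG", 4)),
    stringsAsFactors = FALSE))
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
                c(2, 2, 2), c(3, 2, 2), c(2, 3, 2), c(2, 2, 3))
  frames <- lapply(seq_len(nFrames), function(f) {
    tf <- randomRigidTransform()
    applyRigid(base + rbind(matrix(0, 4, 3),
                            matrix(rnorm(12, sd = 0.05), 4, 3)), tf)
  })
  list(topo = topo, base = base, frames = frames)
}
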