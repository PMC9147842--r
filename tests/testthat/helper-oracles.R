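# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, own constants.

ORACLE_BACKBONE <- c("N", "CA", "C", "O", "OXT")

oracleDelta <- function(r, rmin = 3.23, rmax = 4.63) {
  if (r <= rmin) return(1)
  if (r >= rmax) return(0)
  (rmax - r) / (rmax - rmin)
}

# naive all-pairs contact score: hydrogens always out; backbone of both
# residues out when same chain and |dresno| <= 4
oracleRRCSPair <- function(topo, xyz, a, b, nearThreshold = 4) {
  at <- atoms(topo)
  near <- identical(a$chain, b$chain) &&
    abs(a$resno - b$resno) <= nearThreshold
  keep <- function(r) {
    idx <- which(at$chain == r$chain & at$resno == r$resno)
    idx <- idx[!(at$element[idx] %in% c("H", "D"))]
    if (near) idx <- idx[!(at$name[idx] %in% ORACLE_BACKBONE)]
    idx
  }
  ia <- keep(a); ib <- keep(b)
  s <- 0
  for (i in ia) for (j in ib) {
    s <- s + oracleDelta(sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  s
}

# naive summation oracle for the global-effect metric
oracleGE <- function(acfA, acfB, labels) {
  s <- 0
  for (l in labels) s <- s + (acfA[[l]] - acfB[[l]])^2
  s
}

SIDE_NAMES <- c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE", "CZ",
                "OG", "OD1", "OE1", "SD", "SG", "NE", "NZ", "ND1")
H_NAMES <- c("H", "HA", "HB1", "HB2", "HB3", "HG1", "HG2", "HD1")

elementFromName <- function(nm) {
  if (substr(nm, 1, 1) == "H") "H"
  else if (nm %in% c("SD", "SG")) "S"
  else if (substr(nm, 1, 1) == "O") "O"
  else if (substr(nm, 1, 1) == "N") "N"
  else "C"
}

# random two-residue system: <= 25 atoms per residue (incl. hydrogens),
# random sequence separation so both near and far cases occur
randomTwoResidueSystem <- function() {
  nA <- sample(1:12, 1); nB <- sample(1:12, 1)
  draw <- function(n) {
    pool <- c(ORACLE_BACKBONE, SIDE_NAMES, H_NAMES)
    sample(pool, n)
  }
  namesA <- draw(nA); namesB <- draw(nB)
  sep <- sample(1:10, 1)
  mk <- function(nms, resno, serial0) data.frame(
    serial = serial0 + seq_along(nms), name = nms,
    element = vapply(nms, elementFromName, ""), chain = "A",
    resno = resno, resname = "UNK", stringsAsFactors = FALSE)
  topo <- Topology(rbind(mk(namesA, 10L, 0L), mk(namesB, 10L + sep, nA)))
  # coordinates clustered so distances span the kernel's sensitive range
  xyz <- rbind(matrix(rnorm(3 * nA, sd = 1.5), ncol = 3),
               matrix(rnorm(3 * nB, sd = 1.5), ncol = 3) +
                 matrix(rep(c(runif(1, 2, 6), 0, 0), each = nB), ncol = 3))
  list(topo = topo, xyz = xyz,
       a = list(chain = "A", resno = 10L),
       b = list(chain = "A", resno = 10L + sep))
}

# random proper rotation + translation
randomRigidTransform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

applyRigid <- function(xyz, tf) {
  sweep(xyz %*% t(tf$R), 2, -tf$t)
}

# standard error of the empirical occupancy of a two-state Markov chain with
# stationary fraction f and mean contact dwell `dwell` frames
seMarkov <- function(f, n, dwell = 20) {
  b <- 1 / dwell
  a <- f / (1 - f) * b
  rho <- 1 - a - b
  sqrt(f * (1 - f) / n * (1 + rho) / (1 - rho))
}

# minimal two-residue topology builder for hand-placed geometries
pairTopology <- function(namesA, namesB, sep = 10L, chainB = "A",
                         elementsA = NULL, elementsB = NULL) {
  if (is.null(elementsA)) elementsA <- vapply(namesA, elementFromName, "")
  if (is.null(elementsB)) elementsB <- vapply(namesB, elementFromName, "")
  Topology(rbind(
    data.frame(serial = seq_along(namesA), name = namesA, element = elementsA,
               chain = "A", resno = 10L, resname = "UNK",
               stringsAsFactors = FALSE),
    data.frame(serial = length(namesA) + seq_along(namesB), name = namesB,
               element = elementsB, chain = chainB,
               resno = if (chainB == "A") 10L + sep else 10L, resname = "UNK",
               stringsAsFactors = FALSE)))
}

writeTempPDB <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        occ = 1, elem = substr(name, 1, 1), rec = "ATOM  ",
                        alt = " ") {
  sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, if (nchar(name) >= 4) name else paste0(" ", formatC(name, width = -3)),
          alt, resname, chain, resno, x, y, z, occ, 0, elem)
}
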