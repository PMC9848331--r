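# Independent oracles used across tests.

# brute-force rigid-superposition RMSD: centre both point sets, then search
# rotations (Rodrigues axis-angle) with many grid starts + local refinement.
# Independent of the SVD path in superpose().
oracleSuperposeRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) {
    R <- rotmat(v)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  grid <- seq(-pi, pi, length.out = 5)
  for (a in grid) for (b in grid) for (c in grid) {
    o <- stats::optim(c(a, b, c), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  best
}

# build per-tool P/N call columns realising given confusion counts on a
# labelled 27 + 3 benchmark (first TP pathogenic called P, etc.)
callsFromCounts <- function(counts, labels) {
  isP <- labels == "Pathogenic"
  out <- character(length(labels))
  names(out) <- names(labels)
  pv <- names(labels)[isP]; bv <- names(labels)[!isP]
  out[pv] <- rep(c("P", "N"), c(counts$TP, counts$FN))
  out[bv] <- rep(c("N", "P"), c(counts$TN, counts$FP))
  out
}

# a labelled benchmark with the study's 27:3 imbalance and fixed ids
benchLabels27_3 <- function() {
  ids <- c(sprintf("A%dV", 1:27), sprintf("L%dF", 28:30))
  stats::setNames(rep(c("Pathogenic", "Benign"), c(27, 3)), ids)
}

# tiny hand-built ensembles for geometric tests
miniEnsemble <- function(coords, atoms) {
  TrajectoryEnsemble(atoms = atoms, xyz = coords)
}
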