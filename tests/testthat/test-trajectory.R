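rigid <- function(P, theta = 0.9, axis = c(0, 0, 1), shift = c(5, 0, 0)) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(P %*% t(R), 2, shift, `+`)
}

test_that("superposition is exact for identity and rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(24), ncol = 3)
  sp <- superpose(P, P)
  expect_equal(sp$fitRmsd, 0, tolerance = 1e-10)
  expect_equal(sp$coords, P, tolerance = 1e-10)
  Q <- rigid(P, theta = pi / 2)
  expect_equal(superpose(P, Q)$fitRmsd, 0, tolerance = 1e-10)
})

test_that("superposition matches the brute-force rotation-search oracle", {
  set.seed(5)
  for (i in 1:4) {
    n <- sample(4:6, 1)
    P <- matrix(rnorm(3 * n), ncol = 3)
    Q <- P + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
    expect_equal(superpose(P, Q)$fitRmsd, oracleSuperposeRmsd(P, Q),
                 tolerance = 1e-3)
  }
  # 4-atom toy with a single displaced atom
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  Q <- P; Q[4, 3] <- Q[4, 3] + 1
  expect_equal(superpose(P, Q)$fitRmsd, oracleSuperposeRmsd(P, Q),
               tolerance = 1e-3)
})

test_that("superposition rejects degenerate fits", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  P <- matrix(rnorm(12), ncol = 3)
  expect_error(superpose(P, P, fit = 1:2), "3 fit atoms")
})

test_that("RMSD series is zero for static and rigidly moving trajectories", {
  ref <- buildToyDimer(nRes = 6)
  co <- frameCoords(ref, 1)
  static <- TrajectoryEnsemble(atoms(ref), rbind(as.vector(t(co)),
                                                 as.vector(t(co)),
                                                 as.vector(t(co))))
  expect_equal(rmsdSeries(static, fit = "A:*:CA"), rep(0, 3),
               tolerance = 1e-10)
  moving <- TrajectoryEnsemble(atoms(ref), rbind(
    as.vector(t(co)),
    as.vector(t(rigid(co, 0.5))),
    as.vector(t(rigid(co, 1.1, axis = c(0, 1, 0), shift = c(0, 3, 3))))))
  expect_equal(rmsdSeries(moving, fit = "A:*:CA", measure = "B:*:CA"),
               rep(0, 3), tolerance = 1e-10)
})

test_that("RMSD matches a hand computation on a 2-frame toy", {
  # 2 measured atoms displaced by 1 A each under an identity fit
  at <- data.frame(eleno = 1:6, elety = c("CA", "CA", "CA", "CA", "CA", "CA"),
                   resid = "ALA", chain = c("A", "A", "A", "A", "B", "B"),
                   resno = 1:6, elesy = "C")
  f1 <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(4, 4, 4),
              c(10, 0, 0), c(10, 4, 0))
  f2 <- f1; f2[5, ] <- f2[5, ] + c(1, 0, 0); f2[6, ] <- f2[6, ] + c(0, 1, 0)
  ens <- TrajectoryEnsemble(at, rbind(as.vector(t(f1)), as.vector(t(f2))))
  rs <- rmsdSeries(ens, fit = 1:4, measure = 5:6)
  expect_equal(rs, c(0, 1), tolerance = 1e-10)
})

test_that("RMSF is zero for static frames and d for a +/-d alternation", {
  ref <- buildToyDimer(nRes = 5)
  co <- as.vector(t(frameCoords(ref, 1)))
  static <- TrajectoryEnsemble(atoms(ref), rbind(co, co, co, co))
  pr <- rmsfProfile(static, sel = "A:*:CA")
  expect_equal(pr$rmsf, rep(0, 5), tolerance = 1e-10)
  # one atom alternating x0 +/- d about its mean, fit on the rest
  at <- data.frame(eleno = 1:5, elety = "CA", resid = "ALA", chain = "A",
                   resno = 1:5, elesy = "C")
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(8, 8, 8))
  d <- 0.7
  up <- base; up[5, 1] <- up[5, 1] + d
  dn <- base; dn[5, 1] <- dn[5, 1] - d
  ens <- TrajectoryEnsemble(at, rbind(as.vector(t(up)), as.vector(t(dn)),
                                      as.vector(t(up)), as.vector(t(dn))))
  pr2 <- rmsfProfile(ens, sel = 1:5, fit = 1:4)
  expect_equal(pr2$rmsf[5], d, tolerance = 1e-10)
  expect_equal(pr2$rmsf[1:4], rep(0, 4), tolerance = 1e-10)
  expect_error(rmsfProfile(ens, sel = 1:5, window = 1L), "at least 2")
})

test_that("RMSD/RMSF are invariant under a global rigid motion of all frames", {
  sim <- makeEnsemble(nFrames = 40, sigma = 0.4, seed = 9)
  e <- sim$ensemble
  moved <- e
  for (f in seq_len(nFrames(e)))
    moved@xyz[f, ] <- as.vector(t(rigid(frameCoords(e, f), theta = 0.8,
                                        shift = c(3, -2, 7))))
  r1 <- rmsdSeries(e, fit = "B:*:CA", measure = "A:*:CA")
  r2 <- rmsdSeries(moved, fit = "B:*:CA", measure = "A:*:CA",
                   reference = frameCoords(e, 1))
  expect_equal(r1, r2, tolerance = 1e-8)
  p1 <- rmsfProfile(e, sel = "A:*:CA", fit = "B:*:CA")
  p2 <- rmsfProfile(moved, sel = "A:*:CA", fit = "B:*:CA")
  expect_equal(p1$rmsf, p2$rmsf, tolerance = 1e-8)
})

test_that("second-half mean uses the last ceiling(N/2) frames", {
  expect_equal(secondHalfMeanRmsd(c(9, 9, 1, 3)), 2)
  expect_equal(secondHalfMeanRmsd(c(9, 9, 3)), 6)  # frames 2..3 for N = 3
})

test_that("average structure returns frame 0 for static input and the midpoint of a 2-frame oscillation", {
  ref <- buildToyDimer(nRes = 4)
  co <- frameCoords(ref, 1)
  static <- TrajectoryEnsemble(atoms(ref),
                               rbind(as.vector(t(co)), as.vector(t(co))))
  av <- averageStructure(static, window = 1:2)
  expect_equal(unclass(av), co, tolerance = 1e-10, ignore_attr = TRUE)
  expect_false(attr(av, "minimised"))
  d <- c(0.5, 0, 0)
  up <- sweep(co, 2, d, `+`); dn <- sweep(co, 2, d, `-`)
  osc <- TrajectoryEnsemble(atoms(ref),
                            rbind(as.vector(t(up)), as.vector(t(dn))))
  av2 <- averageStructure(osc, window = 1:2)
  # rigid-body translation is removed by the fit: mean equals frame 1 shape
  expect_equal(superpose(unclass(av2), co)$fitRmsd, 0, tolerance = 1e-8)
})

test_that("selection mini-language resolves chains, ranges and atom names", {
  e <- buildToyDimer(nRes = 10)
  at <- atoms(e)
  i1 <- atomSelect(e, "A:2-4:CA")
  expect_equal(at$resno[i1], 2:4)
  expect_true(all(at$elety[i1] == "CA" & at$chain[i1] == "A"))
  i2 <- atomSelect(e, "B:*:CA")
  expect_equal(length(i2), 10)
  i3 <- atomSelect(e, "A:2:OG,HG")
  expect_equal(sort(at$elety[i3]), c("HG", "OG"))
  i4 <- atomSelect(e, "A:1-2:CA;B:1:CA")
  expect_equal(length(i4), 3)
  expect_error(atomSelect(e, "A:99:CA"), "empty")
  expect_error(atomSelect(e, "A:CA"), "malformed")
})
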