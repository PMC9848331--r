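# two residues with an explicit donor (N-H) / acceptor (O) geometry we can
# place at will, plus an optional water
hbToy <- function(NO_dist, NHO_angle, waterAt = NULL) {
  # donor N at origin, H along +x; acceptor O placed to realise the
  # requested N-O distance and N-H-O angle
  H <- c(1, 0, 0)
  th <- NHO_angle * pi / 180
  ct <- cos(th)
  r <- ct + sqrt(ct^2 - 1 + NO_dist^2)   # |H-O| from the angle at H
  O <- H + r * c(-ct, sin(th), 0)        # -ct: away from N for obtuse angles
  at <- data.frame(
    eleno = 1:6,
    elety = c("N", "H", "CA", "CA", "O", "C"),
    resid = c("ALA", "ALA", "ALA", "ALA", "ALA", "ALA"),
    chain = "A", resno = c(1, 1, 1, 2, 2, 2),
    elesy = c("N", "H", "C", "C", "O", "C"))
  co <- rbind(c(0, 0, 0), H, c(-1.5, 0, 1), O + c(1.5, 1, 0), O,
              O + c(0.5, -1, 0))
  if (!is.null(waterAt)) {
    at <- rbind(at, data.frame(eleno = 7, elety = "O", resid = "HOH",
                               chain = "W", resno = 99, elesy = "O"))
    co <- rbind(co, waterAt)
  }
  TrajectoryEnsemble(at, co)
}

test_that("hydrogen bonds require both the distance and the angle criterion", {
  hit <- detectHBonds(hbToy(2.9, 170))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$dist, 2.9, tolerance = 1e-6)
  expect_equal(hit$angle, 170, tolerance = 1e-6)
  expect_equal(nrow(detectHBonds(hbToy(4.0, 170))), 0)   # too far
  expect_equal(nrow(detectHBonds(hbToy(3.2, 100))), 0)   # angle rejection
  # boundary: exactly at the defaults counts
  expect_equal(nrow(detectHBonds(hbToy(3.5, 135))), 1)
})

test_that("intra-residue pairs are excluded and criteria are configurable", {
  e <- hbToy(2.9, 170)
  hb <- detectHBonds(e)
  at <- atoms(e)
  expect_true(all(at$resno[hb$donor] != at$resno[hb$acceptor]))
  strict <- hbondCriteria(distMax = 2.5)
  expect_equal(nrow(detectHBonds(e, criteria = strict)), 0)
  expect_error(hbondCriteria(angleMin = 200), "angleMin")
})

test_that("occupancy equals the constructed bonded-frame fraction", {
  bonded <- hbToy(2.9, 170); free <- hbToy(5.5, 170)
  xyz <- rbind(matrix(rep(bonded@xyz, 8), nrow = 8, byrow = TRUE),
               matrix(rep(free@xyz, 2), nrow = 2, byrow = TRUE))
  e <- TrajectoryEnsemble(atoms(bonded), xyz)
  rec <- hbondOccupancy(e, list(chain = "A", resno = 1),
                        list(chain = "A", resno = 2))
  expect_equal(rec$occupancy, 0.8)
  expect_equal(rec$n_frames, 10)
  expect_equal(rec$class, "direct")
  # zero bonded frames
  e0 <- TrajectoryEnsemble(atoms(free),
                           matrix(rep(free@xyz, 3), nrow = 3, byrow = TRUE))
  expect_equal(hbondOccupancy(e0, list(chain = "A", resno = 1),
                              list(chain = "A", resno = 2))$occupancy, 0)
  expect_error(hbondOccupancy(e0, list(chain = "A", resno = 1),
                              list(chain = "Q", resno = 7)), "Q:7")
})

test_that("occupancy is invariant to frame order and self-concatenation", {
  sim <- makeEnsemble(nFrames = 60, sigma = 0.3, seed = 4,
                      bonds = data.frame(chain1 = "A", resno1 = 2,
                                         chain2 = "A", resno2 = 6,
                                         target = 0.6, class = "direct"))
  e <- sim$ensemble
  a <- list(chain = "A", resno = 2); b <- list(chain = "A", resno = 6)
  o1 <- hbondOccupancy(e, a, b)$occupancy
  shuf <- e; set.seed(1); shuf@xyz <- e@xyz[sample(nFrames(e)), ]
  expect_equal(hbondOccupancy(shuf, a, b)$occupancy, o1)
  dbl <- TrajectoryEnsemble(atoms(e), rbind(e@xyz, e@xyz))
  expect_equal(hbondOccupancy(dbl, a, b)$occupancy, o1)
})

test_that("a single water must bridge both partners in the same frame", {
  # partners ~5.9 A apart: N1 at origin, O5 at (5.94, 0, 0) when built with
  # NO_dist 5.94 -- water exactly between them bridges, one-sided does not
  mid <- hbToy(5.94, 170, waterAt = c(2.95, 0.3, 0))
  rec <- waterBridgeOccupancy(mid, list(chain = "A", resno = 1),
                              list(chain = "A", resno = 2))
  expect_equal(rec$occupancy, 1)
  expect_equal(rec$class, "water_mediated")
  oneSide <- hbToy(5.94, 170, waterAt = c(-2.0, 0, 0))
  expect_equal(waterBridgeOccupancy(oneSide, list(chain = "A", resno = 1),
                                    list(chain = "A", resno = 2))$occupancy,
               0)
  expect_warning(
    rec0 <- waterBridgeOccupancy(hbToy(5.94, 170),
                                 list(chain = "A", resno = 1),
                                 list(chain = "A", resno = 2)),
    "no water")
  expect_equal(rec0$occupancy, 0)
})

test_that("two waters each near one partner do not count as a bridge", {
  e <- hbToy(5.94, 170, waterAt = c(-2.0, 0, 0))
  at <- rbind(atoms(e), data.frame(eleno = 8, elety = "O", resid = "HOH",
                                   chain = "W", resno = 100, elesy = "O"))
  co <- rbind(frameCoords(e, 1), c(7.9, 0, 0))   # near the acceptor side
  e2 <- TrajectoryEnsemble(at, co)
  expect_equal(waterBridgeOccupancy(e2, list(chain = "A", resno = 1),
                                    list(chain = "A", resno = 2))$occupancy,
               0)
})

test_that("side-chain contact occupancy counts frames within the cutoff", {
  ref <- buildToyDimer(nRes = 8)
  a <- list(chain = "A", resno = 2); b <- list(chain = "A", resno = 4)
  # SER OG (res 2) and LYS NZ (res 4) are side-chain atoms
  co <- frameCoords(ref, 1)
  at <- atoms(ref)
  iOG <- which(at$chain == "A" & at$resno == 2 & at$elety == "OG")
  iNZ <- which(at$chain == "A" & at$resno == 4 & at$elety == "NZ")
  near <- co; near[iNZ, ] <- co[iOG, ] + c(4.0, 0, 0)
  far <- co; far[iNZ, ] <- co[iOG, ] + c(20, 0, 0)
  mk <- function(frames) TrajectoryEnsemble(at, do.call(rbind,
    lapply(frames, function(f) as.vector(t(f)))))
  expect_equal(contactOccupancy(mk(list(near, near)), a, b)$occupancy, 1)
  expect_equal(contactOccupancy(mk(list(far, far)), a, b)$occupancy, 0)
  expect_equal(contactOccupancy(mk(list(near, far)), a, b)$occupancy, 0.5)
  expect_equal(contactOccupancy(mk(list(near, far)), a, b)$class,
               "hydrophobic_contact")
})

test_that("native interactions are direct contacts at or above the threshold", {
  rec <- data.frame(
    chain1 = "A", resno1 = c(303, 373, 400),
    resname1 = c("LYS", "ASN", "THR"),
    chain2 = "A", resno2 = c(401, 322, 396),
    resname2 = c("ILE", "GLY", "CYS"),
    class = c("direct", "water_mediated", "direct"),
    occupancy = c(0.99, 0.80, 0.50), n_frames = 100)
  nat <- nativeInteractions(rec)
  # water-mediated excluded even at high occupancy; 0.50 boundary included
  expect_equal(nat$resno2, c(401, 396))
  expect_equal(nrow(nativeInteractions(rec, nativeMin = 0.6)), 1)
})
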