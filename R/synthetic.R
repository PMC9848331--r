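# Synthetic inputs with known ground truth: labelled benchmarks with
# controlled per-tool error rates, and coordinate ensembles with controlled
# per-residue fluctuations and hydrogen-bond occupancies.

.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a labelled benchmark and a prediction matrix
#'
#' Emulates a benchmark of known variants with the study's class imbalance
#' (27 pathogenic : 3 benign by default). Each tool's call for each variant
#' is drawn independently: Pathogenic with probability = the tool's
#' sensitivity for pathogenic variants and 1 - specificity for benign ones.
#' Identical seeds give identical output.
#'
#' @param nPathogenic,nBenign class sizes (defaults 27 and 3).
#' @param tools data.frame with columns \code{tool}, \code{sensitivity},
#'   \code{specificity}. Default: 19 generic tools at sensitivity 0.90 and
#'   specificity 0.67, the regime typical of the selected predictor panel.
#' @param seed RNG seed (sets the global RNG).
#' @return list with \code{labels} (named \code{"Pathogenic"}/\code{"Benign"}
#'   vector), \code{matrix} (binary [PredictionMatrix-class]) and
#'   \code{spec} (the generating parameters).
#' @examples
#' b <- makeBenchmark(seed = 7)
#' head(benchmarkTools(b$matrix, b$labels))
#' @export
makeBenchmark <- function(nPathogenic = 27, nBenign = 3,
                          tools = data.frame(
                            tool = sprintf("tool%02d", 1:19),
                            sensitivity = 0.90, specificity = 0.67),
                          seed = 1) {
  stopifnot(nPathogenic >= 0, nBenign >= 0,
            all(tools$sensitivity >= 0 & tools$sensitivity <= 1),
            all(tools$specificity >= 0 & tools$specificity <= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- nPathogenic + nBenign
  pos <- seq_len(n) * 3L + 100L
  wt <- sample(.AA1, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(.AA1, a), 1L), "")
  ids <- paste0(wt, pos, mut)
  labels <- stats::setNames(
    rep(c("Pathogenic", "Benign"), c(nPathogenic, nBenign)), ids)
  cl <- matrix(NA_character_, n, nrow(tools),
               dimnames = list(ids, tools$tool))
  isP <- labels == "Pathogenic"
  for (j in seq_len(nrow(tools))) {
    p <- ifelse(isP, tools$sensitivity[j], 1 - tools$specificity[j])
    cl[, j] <- ifelse(stats::runif(n) < p, "P", "N")
  }
  list(labels = labels, matrix = PredictionMatrix(calls = cl),
       spec = list(nPathogenic = nPathogenic, nBenign = nBenign,
                   tools = tools, seed = seed))
}

# residue templates: atom name, element, coordinates relative to CA
.RES_TEMPLATES <- list(
  ALA = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB"),
    elesy = c("N", "H", "C", "C", "O", "C"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0)),
  SER = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB", "OG", "HG"),
    elesy = c("N", "H", "C", "C", "O", "C", "O", "H"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0, 0, 0),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50, -2.90, -3.86),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0, 0, 0)),
  LYS = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB", "NZ", "HZ1"),
    elesy = c("N", "H", "C", "C", "O", "C", "N", "H"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0, 0, 0),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50, -3.50, -4.50),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0, 0, 0)),
  GLU = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB", "OE1", "OE2"),
    elesy = c("N", "H", "C", "C", "O", "C", "O", "O"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0, -0.60, 0.60),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50, -3.20, -3.20),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0, 0, 0)),
  ASN = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB", "OD1", "ND2", "HD21"),
    elesy = c("N", "H", "C", "C", "O", "C", "O", "N", "H"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0, -0.70, 0.70, 0.70),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50, -2.90, -2.90, -3.90),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0, 0, 0, 0)),
  THR = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB", "OG1", "HG1"),
    elesy = c("N", "H", "C", "C", "O", "C", "O", "H"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0, 0, 0),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50, -2.80, -3.76),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0, 0, 0)),
  TRP = data.frame(
    elety = c("N", "H", "CA", "C", "O", "CB", "NE1", "HE1"),
    elesy = c("N", "H", "C", "C", "O", "C", "N", "H"),
    x = c(-1.20, -1.20, 0, 1.20, 1.20, 0, 0, 0),
    y = c(0.80, 1.80, 0, 0.80, 2.03, -1.50, -3.40, -4.40),
    z = c(0.10, 0.10, 0, -0.10, -0.10, 0, 0, 0))
)

.DEFAULT_SEQ <- c("ALA", "SER", "ALA", "LYS", "ALA",
                  "GLU", "ALA", "ASN", "ALA", "THR")

#' Build the toy two-chain dimer reference structure
#'
#' A minimal two-chain construct (default 30 residues per chain) whose
#' residues carry full backbones (N, H, CA, C, O), a CB, and -- on the polar
#' residue types -- hydrogen-bond capable side chains (SER, LYS, GLU, ASN,
#' THR, TRP). Chains A and B run antiparallel offset by ~9 Angstrom, so
#' inter-chain prescriptions (e.g. a serine/glutamate/tryptophan interface
#' bridge) are geometrically reachable. Geometry is schematic, not
#' physically relaxed: it exists to exercise selection, superposition and
#' hydrogen-bond code paths with unambiguous ground truth.
#'
#' @param nRes residues per chain.
#' @param sequence residue-name vector recycled along each chain (subset of
#'   names of the built-in templates).
#' @return a single-frame [TrajectoryEnsemble-class].
#' @export
buildToyDimer <- function(nRes = 30, sequence = .DEFAULT_SEQ) {
  bad <- setdiff(sequence, names(.RES_TEMPLATES))
  if (length(bad)) stop("no template for residue(s): ",
                        paste(bad, collapse = ", "))
  resnames <- rep_len(sequence, nRes)
  rows <- list(); k <- 0L
  for (chain in c("A", "B")) {
    for (i in seq_len(nRes)) {
      tpl <- .RES_TEMPLATES[[resnames[i]]]
      # CA positions along x, alternating z pucker; chain B offset in y,
      # side chains of both chains facing the interface (templates grow
      # toward negative y, so chain A is mirrored)
      flip <- if (chain == "B") 1 else -1
      ca <- c(3.8 * i + ifelse(chain == "B", 1.9, 0),
              ifelse(chain == "B", 11.0, 0),
              0.3 * (-1)^i)
      df <- data.frame(
        eleno = k + seq_len(nrow(tpl)), elety = tpl$elety,
        resid = resnames[i], chain = chain, resno = i,
        elesy = tpl$elesy,
        x = ca[1] + tpl$x, y = ca[2] + flip * tpl$y, z = ca[3] + tpl$z)
      k <- k + nrow(tpl)
      rows[[length(rows) + 1L]] <- df
    }
  }
  all <- do.call(rbind, rows)
  TrajectoryEnsemble(
    atoms = all[c("eleno", "elety", "resid", "chain", "resno", "elesy")],
    xyz = as.matrix(all[c("x", "y", "z")]))
}

.unitPerp <- function(u) {
  # any unit vector perpendicular to u
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- v - sum(v * u) * u
  p / sqrt(sum(p^2))
}

# place acceptor A given donor D, hydrogen H, target D-A distance d and
# D-H-A angle theta (deg), azimuth phi
.placeAcceptor <- function(D, H, d, theta, phi) {
  hd <- D - H
  L <- sqrt(sum(hd^2))
  a1 <- hd / L
  ct <- cos(theta * pi / 180)
  r <- L * ct + sqrt(L^2 * ct^2 - L^2 + d^2)
  p1 <- .unitPerp(a1)
  p2 <- c(a1[2] * p1[3] - a1[3] * p1[2],
          a1[3] * p1[1] - a1[1] * p1[3],
          a1[1] * p1[2] - a1[2] * p1[1])
  w <- ct * a1 + sin(theta * pi / 180) * (cos(phi) * p1 + sin(phi) * p2)
  H + r * w
}

# preferred donor (heavy atom with attached H) / acceptor atoms of a residue:
# side-chain first, then backbone
.pickDonor <- function(x, res) {
  at <- atoms(x)
  att <- .hydrogenAttachment(x)
  idx <- .residueAtoms(x, res)
  cand <- att[att$heavy %in% idx, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  side <- cand[at$elety[cand$heavy] != "N", , drop = FALSE]
  if (nrow(side)) side[1, ] else cand[1, ]
}

.pickAcceptor <- function(x, res) {
  at <- atoms(x)
  idx <- .residueAtoms(x, res)
  pol <- idx[.isPolar(at[idx, ]) & !.isHydrogen(at[idx, ])]
  if (!length(pol)) return(NULL)
  side <- pol[!(at$elety[pol] %in% c("N", "O"))]
  if (length(side)) return(side[1])
  bbO <- pol[at$elety[pol] == "O"]
  if (length(bbO)) bbO[1] else pol[1]
}

#' Simulate a coordinate ensemble with controlled ground truth
#'
#' Frames are the reference structure plus independent rigid per-residue
#' Gaussian displacements scaled so that each residue's expected RMSF equals
#' its target sigma. For every prescribed bond, each frame is independently
#' placed in bonded geometry with probability equal to the target occupancy
#' (donor-acceptor distance uniform in 2.7-3.3 Angstrom, angle uniform in
#' 150-180 degrees -- safely inside the default criteria) and otherwise
#' clearly outside them (distance 4.5-6.0 Angstrom). Water-mediated
#' prescriptions add one bridging water each, whose oxygen is placed within
#' the distance criterion of both partners in bonded frames and far from
#' them otherwise. Frames are independent (no autocorrelation); occupancy
#' and RMSF estimators do not depend on frame order.
#'
#' @param reference a single-frame [TrajectoryEnsemble-class] (default
#'   [buildToyDimer()]).
#' @param nFrames number of frames.
#' @param sigma target per-residue RMSF: a single number for all residues,
#'   or a data.frame with \code{chain}, \code{resno}, \code{sigma} (residues
#'   not listed get \code{sigmaDefault}).
#' @param sigmaDefault fallback sigma when \code{sigma} is a data.frame.
#' @param bonds \code{NULL} or data.frame with \code{chain1}, \code{resno1},
#'   \code{chain2}, \code{resno2}, \code{target} (occupancy in 0..1) and
#'   \code{class} (\code{"direct"} or \code{"water_mediated"}).
#' @param seed RNG seed (sets the global RNG).
#' @return list with \code{ensemble} (a [TrajectoryEnsemble-class]) and
#'   \code{manifest} (generating parameters: per-residue sigma table and the
#'   bond prescriptions).
#' @examples
#' sim <- makeEnsemble(nFrames = 50, sigma = 0.3, seed = 1,
#'   bonds = data.frame(chain1 = "A", resno1 = 2, chain2 = "A", resno2 = 6,
#'                      target = 0.8, class = "direct"))
#' hbondOccupancy(sim$ensemble, list(chain = "A", resno = 2),
#'                list(chain = "A", resno = 6))$occupancy
#' @export
makeEnsemble <- function(reference = buildToyDimer(), nFrames = 100,
                         sigma = 0.3, sigmaDefault = 0.3, bonds = NULL,
                         seed = 1) {
  stopifnot(nFrames >= 1)
  if (!is.null(seed)) set.seed(seed)
  at <- atoms(reference)
  ref <- frameCoords(reference, 1L)
  reskey <- .resKey(at$chain, at$resno)
  ures <- unique(reskey)
  # per-residue sigma table
  if (is.data.frame(sigma)) {
    sg <- stats::setNames(rep(sigmaDefault, length(ures)), ures)
    sg[.resKey(sigma$chain, sigma$resno)] <- sigma$sigma
  } else {
    sg <- stats::setNames(rep(sigma, length(ures)), ures)
  }
  if (any(sg < 0)) stop("sigma must be non-negative")

  # resolve bond prescriptions up-front; waters appended for bridges
  plans <- list()
  used <- integer()
  watAtoms <- NULL
  if (!is.null(bonds) && nrow(bonds)) {
    if (any(bonds$target < 0 | bonds$target > 1))
      stop("bond targets must be occupancies in [0, 1]")
    nextEleno <- max(at$eleno) + 1L
    for (b in seq_len(nrow(bonds))) {
      r1 <- list(chain = bonds$chain1[b], resno = bonds$resno1[b])
      r2 <- list(chain = bonds$chain2[b], resno = bonds$resno2[b])
      cls <- bonds$class[b]
      if (cls == "direct") {
        don <- .pickDonor(reference, r1)
        acc <- .pickAcceptor(reference, r2)
        if (is.null(don) || is.null(acc)) {
          don <- .pickDonor(reference, r2)
          acc <- .pickAcceptor(reference, r1)
        }
        if (is.null(don) || is.null(acc))
          stop("no donor/acceptor atoms available for bond ", b)
        if (acc %in% used || don$heavy %in% used)
          stop("conflicting prescriptions on one atom (bond ", b, ")")
        used <- c(used, acc)
        plans[[b]] <- list(class = "direct", donor = don$heavy,
                           h = don$h, acceptor = acc,
                           target = bonds$target[b])
      } else if (cls == "water_mediated") {
        p1 <- .pickAcceptor(reference, r1)
        p2 <- .pickAcceptor(reference, r2)
        if (is.null(p1) || is.null(p2))
          stop("no polar partner atoms for water bridge (bond ", b, ")")
        wid <- 9000L + b
        watAtoms <- rbind(watAtoms, data.frame(
          eleno = nextEleno, elety = "O", resid = "HOH", chain = "W",
          resno = wid, elesy = "O"))
        plans[[b]] <- list(class = "water_mediated", p1 = p1, p2 = p2,
                           wat = nrow(at) + nrow(watAtoms),
                           target = bonds$target[b])
        nextEleno <- nextEleno + 1L
      } else stop("unknown bond class: ", cls)
    }
  }
  if (!is.null(watAtoms)) at <- rbind(at, watAtoms)
  natom <- nrow(at)
  refAll <- rbind(ref, matrix(0, natom - nrow(ref), 3))

  # per-coordinate sd sigma/sqrt(3) gives an expected 3-D RMSF of sigma
  xyz <- matrix(0, nFrames, 3L * natom)
  for (f in seq_len(nFrames)) {
    co <- refAll
    # rigid per-residue displacement
    disp <- matrix(stats::rnorm(length(ures) * 3), ncol = 3) *
      unname(sg[ures]) / sqrt(3)
    co[seq_len(nrow(ref)), ] <- ref +
      disp[match(reskey, ures), , drop = FALSE]
    for (pl in plans) {
      if (pl$class == "direct") {
        bonded <- stats::runif(1) < pl$target
        D <- co[pl$donor, ]; H <- co[pl$h, ]
        if (bonded) {
          co[pl$acceptor, ] <- .placeAcceptor(
            D, H, d = stats::runif(1, 2.7, 3.3),
            theta = stats::runif(1, 150, 180),
            phi = stats::runif(1, 0, 2 * pi))
        } else {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          co[pl$acceptor, ] <- D + u * stats::runif(1, 4.5, 6.0)
        }
      } else {
        bonded <- stats::runif(1) < pl$target
        p1 <- co[pl$p1, ]; p2 <- co[pl$p2, ]
        v <- p2 - p1; L <- sqrt(sum(v^2)); u <- v / L
        if (bonded) {
          if (L > 6.2)
            stop("water-bridge partners too far apart (", round(L, 1),
                 " A) to satisfy the criteria; bring the residues closer ",
                 "or lower their sigma")
          co[pl$wat, ] <- p1 + u * min(2.9, L / 2)
        } else {
          co[pl$wat, ] <- p1 - u * stats::runif(1, 4.5, 6.0)
        }
      }
    }
    xyz[f, ] <- as.vector(t(co))
  }
  ens <- TrajectoryEnsemble(atoms = at, xyz = xyz)
  manifest <- list(
    sigma = data.frame(chain = sub(":.*", "", ures),
                       resno = as.integer(sub(".*:", "", ures)),
                       sigma = unname(sg[ures])),
    bonds = bonds, nFrames = nFrames, seed = seed)
  list(ensemble = ens, manifest = manifest)
}
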