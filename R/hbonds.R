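# Hydrogen-bond geometry over coordinate ensembles.
#
# Donors are N/O heavy atoms with an attached hydrogen (attachment inferred
# from frame-1 geometry: H within 1.2 A of a same-residue N/O); acceptors are
# any N/O. A residue-level bond is counted once per frame no matter how many
# atom pairs qualify, so bidentate contacts are not double counted.

.isHydrogen <- function(at) {
  ifelse(!is.na(at$elesy) & nzchar(at$elesy), at$elesy == "H",
         grepl("^[0-9]*H", at$elety))
}

.isPolar <- function(at) {
  sy <- ifelse(!is.na(at$elesy) & nzchar(at$elesy), at$elesy,
               substr(at$elety, 1, 1))
  sy %in% c("N", "O")
}

# map each hydrogen to its bonded heavy N/O (frame-1 geometry); returns
# data.frame(h, heavy) of atom indices
.hydrogenAttachment <- function(x) {
  at <- atoms(x)
  co <- frameCoords(x, 1L)
  hs <- which(.isHydrogen(at))
  if (!length(hs)) return(data.frame(h = integer(), heavy = integer()))
  rows <- lapply(hs, function(h) {
    cand <- which(.isPolar(at) & at$resno == at$resno[h] &
                    at$chain == at$chain[h] & at$resid == at$resid[h])
    if (!length(cand)) return(NULL)
    d2 <- rowSums(sweep(co[cand, , drop = FALSE], 2, co[h, ])^2)
    j <- cand[which.min(d2)]
    if (d2[which.min(d2)] > 1.2^2) return(NULL)
    data.frame(h = h, heavy = j)
  })
  do.call(rbind, rows)
}

.angleDeg <- function(a, b, c) {
  # angle at b, degrees; a, b, c are matrices of row-vectors
  u <- a - b; v <- c - b
  cosang <- rowSums(u * v) / sqrt(rowSums(u * u) * rowSums(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' All donor/acceptor atom pairs satisfying the geometric criteria
#' (donor-acceptor distance and donor-H-acceptor angle); intra-residue pairs
#' are excluded. When the topology carries no hydrogens and the criteria
#' allow it, a heavy-atom-only fallback (distance-only, tighter cutoff) is
#' used with a warning.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param frame frame index.
#' @param criteria an [HBondCriteria-class] (default [hbondCriteria()]).
#' @param donorAtoms,acceptorAtoms optional integer index vectors restricting
#'   the candidate donor heavy atoms / acceptor atoms.
#' @return data.frame with atom indices \code{donor}, \code{h} (\code{NA} in
#'   fallback mode), \code{acceptor}, plus \code{dist} and \code{angle}.
#' @export
detectHBonds <- function(x, frame = 1L, criteria = hbondCriteria(),
                         donorAtoms = NULL, acceptorAtoms = NULL) {
  at <- atoms(x)
  co <- frameCoords(x, frame)
  polar <- which(.isPolar(at))
  if (is.null(acceptorAtoms)) acceptorAtoms <- polar
  acceptorAtoms <- intersect(acceptorAtoms, polar)
  att <- .hydrogenAttachment(x)
  empty <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      dist = numeric(), angle = numeric())
  if (!nrow(att)) {
    if (!criteria@allowHeavyFallback)
      stop("no hydrogens in topology and heavy-atom fallback disabled")
    warning("no hydrogens in topology; using heavy-atom distance criterion (",
            criteria@heavyDistMax, " A)")
    don <- if (is.null(donorAtoms)) polar else intersect(donorAtoms, polar)
    pairs <- expand.grid(donor = don, acceptor = acceptorAtoms)
    pairs <- pairs[!(at$resno[pairs$donor] == at$resno[pairs$acceptor] &
                       at$chain[pairs$donor] == at$chain[pairs$acceptor]), ]
    if (!nrow(pairs)) return(empty)
    d <- sqrt(rowSums((co[pairs$donor, , drop = FALSE] -
                         co[pairs$acceptor, , drop = FALSE])^2))
    keep <- d <= criteria@heavyDistMax
    return(data.frame(donor = pairs$donor[keep], h = NA_integer_,
                      acceptor = pairs$acceptor[keep], dist = d[keep],
                      angle = NA_real_))
  }
  if (!is.null(donorAtoms)) att <- att[att$heavy %in% donorAtoms, , drop = FALSE]
  if (!nrow(att)) return(empty)
  grid <- expand.grid(k = seq_len(nrow(att)), acceptor = acceptorAtoms)
  don <- att$heavy[grid$k]; hyd <- att$h[grid$k]; acc <- grid$acceptor
  keep <- !(at$resno[don] == at$resno[acc] & at$chain[don] == at$chain[acc])
  don <- don[keep]; hyd <- hyd[keep]; acc <- acc[keep]
  if (!length(don)) return(empty)
  d <- sqrt(rowSums((co[don, , drop = FALSE] - co[acc, , drop = FALSE])^2))
  ang <- .angleDeg(co[don, , drop = FALSE], co[hyd, , drop = FALSE],
                   co[acc, , drop = FALSE])
  keep <- d <= criteria@distMax & ang >= criteria@angleMin
  data.frame(donor = don[keep], h = hyd[keep], acceptor = acc[keep],
             dist = d[keep], angle = ang[keep])
}

.residueAtoms <- function(x, res) {
  # res: list(chain=, resno=)
  at <- atoms(x)
  idx <- which(at$chain == res$chain & at$resno == res$resno &
                 !(at$resid %in% c("HOH", "WAT")))
  if (!length(idx))
    stop("unknown residue ", res$chain, ":", res$resno)
  idx
}

.pairRecord <- function(x, resA, resB, class, occ, nFrames, pairs = NULL) {
  at <- atoms(x)
  ia <- .residueAtoms(x, resA)[1]; ib <- .residueAtoms(x, resB)[1]
  out <- data.frame(
    chain1 = resA$chain, resno1 = resA$resno, resname1 = at$resid[ia],
    chain2 = resB$chain, resno2 = resB$resno, resname2 = at$resid[ib],
    class = class, occupancy = occ, n_frames = nFrames)
  if (!is.null(pairs)) attr(out, "atom_pairs") <- pairs
  out
}

# charged side-chain N/O atom names: contacts between two of these are
# tagged as salt bridges (charge-assisted)
.CHARGED_ATOMS <- c("NZ", "NH1", "NH2", "NE", "OD1", "OD2", "OE1", "OE2")

#' Hydrogen-bond occupancy of a residue pair over an ensemble
#'
#' Occupancy is the fraction of frames in which at least one donor/acceptor
#' atom pair between the two residues (either direction) satisfies the
#' criteria; multiple simultaneous atom pairs count once. Contacts whose
#' atoms on both sides belong to charged side-chain groups are tagged
#' \code{"salt_bridge"}; the alert logic treats them like any direct
#' hydrogen bond.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param resA,resB residues as \code{list(chain =, resno =)}.
#' @param criteria an [HBondCriteria-class].
#' @return one-row data.frame (\code{chain1,resno1,resname1,chain2,resno2,
#'   resname2,class,occupancy,n_frames}) with an \code{atom_pairs} attribute
#'   giving the per-atom-pair frame counts.
#' @export
hbondOccupancy <- function(x, resA, resB, criteria = hbondCriteria()) {
  ia <- .residueAtoms(x, resA); ib <- .residueAtoms(x, resB)
  n <- nFrames(x)
  at <- atoms(x)
  att <- .hydrogenAttachment(x)
  polar <- .isPolar(at)
  triples <- rbind(.donorAcceptorTriples(att, ia, ib, polar),
                   .donorAcceptorTriples(att, ib, ia, polar))
  if (!nrow(triples)) {
    if (!criteria@allowHeavyFallback && !nrow(att))
      stop("no hydrogens in topology and heavy-atom fallback disabled")
    if (!nrow(att)) {
      warning("no hydrogens in topology; using heavy-atom distance ",
              "criterion (", criteria@heavyDistMax, " A)")
      pp <- expand.grid(d = ia[polar[ia]], a = ib[polar[ib]])
      bonded <- rep(FALSE, n)
      for (k in seq_len(nrow(pp)))
        bonded <- bonded |
          (.pairDistFrames(x, pp$d[k], pp$a[k]) <= criteria@heavyDistMax)
      return(.pairRecord(x, resA, resB, "direct", mean(bonded), n))
    }
    return(.pairRecord(x, resA, resB, "direct", 0, n))
  }
  bonded <- rep(FALSE, n)
  tally <- list(); saltOnly <- TRUE; sawAny <- FALSE
  for (k in seq_len(nrow(triples))) {
    d <- triples$donor[k]; h <- triples$h[k]; a <- triples$acceptor[k]
    ok <- (.pairDistFrames(x, d, a) <= criteria@distMax) &
      (.angleFrames(x, d, h, a) >= criteria@angleMin)
    if (any(ok)) {
      sawAny <- TRUE
      if (!(at$elety[d] %in% .CHARGED_ATOMS &&
              at$elety[a] %in% .CHARGED_ATOMS)) saltOnly <- FALSE
      key <- paste0(at$elety[d], "->", at$elety[a])
      tally[[key]] <- (tally[[key]] %||% 0L) + sum(ok)
    }
    bonded <- bonded | ok
  }
  cls <- if (sawAny && saltOnly) "salt_bridge" else "direct"
  pairs <- if (length(tally))
    data.frame(atom_pair = names(tally), frames = unlist(tally),
               row.names = NULL) else NULL
  .pairRecord(x, resA, resB, cls, mean(bonded), n, pairs)
}

# candidate donor(in 'from')/acceptor(in 'to') triples given the hydrogen
# attachment table
.donorAcceptorTriples <- function(att, from, to, polar) {
  att <- att[att$heavy %in% from, , drop = FALSE]
  acc <- to[polar[to]]
  if (!nrow(att) || !length(acc))
    return(data.frame(donor = integer(), h = integer(),
                      acceptor = integer()))
  g <- expand.grid(k = seq_len(nrow(att)), acceptor = acc)
  data.frame(donor = att$heavy[g$k], h = att$h[g$k], acceptor = g$acceptor)
}

# per-frame distance between two atoms, vectorised over frames
.pairDistFrames <- function(x, i, j) {
  ci <- (3L * (i - 1L) + 1L):(3L * i)
  cj <- (3L * (j - 1L) + 1L):(3L * j)
  sqrt(rowSums((x@xyz[, ci, drop = FALSE] - x@xyz[, cj, drop = FALSE])^2))
}

# per-frame donor-H-acceptor angle (degrees), vectorised over frames
.angleFrames <- function(x, d, h, a) {
  cd <- (3L * (d - 1L) + 1L):(3L * d)
  ch <- (3L * (h - 1L) + 1L):(3L * h)
  ca <- (3L * (a - 1L) + 1L):(3L * a)
  u <- x@xyz[, cd, drop = FALSE] - x@xyz[, ch, drop = FALSE]
  v <- x@xyz[, ca, drop = FALSE] - x@xyz[, ch, drop = FALSE]
  cosang <- rowSums(u * v) / sqrt(rowSums(u * u) * rowSums(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Water-bridge occupancy of a residue pair
#'
#' Fraction of frames in which a single water molecule bridges the two
#' residues: its oxygen lies within the distance criterion of at least one
#' polar (N/O) atom of each residue in the same frame. Two different waters
#' each near one partner do not count.
#'
#' @inheritParams hbondOccupancy
#' @return one-row record as in [hbondOccupancy()], class
#'   \code{"water_mediated"}.
#' @export
waterBridgeOccupancy <- function(x, resA, resB, criteria = hbondCriteria()) {
  at <- atoms(x)
  wat <- which(at$resid %in% c("HOH", "WAT") & .isPolar(at) &
                 !.isHydrogen(at))
  n <- nFrames(x)
  if (!length(wat)) {
    warning("ensemble contains no water molecules; occupancy 0")
    return(.pairRecord(x, resA, resB, "water_mediated", 0, n))
  }
  pa <- intersect(.residueAtoms(x, resA), which(.isPolar(at)))
  pb <- intersect(.residueAtoms(x, resB), which(.isPolar(at)))
  if (!length(pa) || !length(pb))
    stop("no polar atoms in one of the residues")
  dmax <- criteria@distMax
  minDistFrames <- function(w, grp) {
    d <- sapply(grp, function(g) .pairDistFrames(x, w, g))
    if (is.null(dim(d))) d else apply(d, 1, min)
  }
  bridged <- rep(FALSE, n)
  for (w in wat)
    bridged <- bridged | (minDistFrames(w, pa) <= dmax &
                            minDistFrames(w, pb) <= dmax)
  .pairRecord(x, resA, resB, "water_mediated", mean(bridged), n)
}

#' Side-chain contact occupancy (hydrophobic-contact report)
#'
#' Fraction of frames with any side-chain heavy-atom pair of the two
#' residues within \code{distMax}. Purely informational: packing contacts
#' never feed the interaction alert, which is hydrogen-bond based.
#'
#' @inheritParams hbondOccupancy
#' @param distMax contact cutoff in Angstrom (default 4.5).
#' @return one-row record, class \code{"hydrophobic_contact"}.
#' @export
contactOccupancy <- function(x, resA, resB, distMax = 4.5) {
  at <- atoms(x)
  bb <- c("N", "CA", "C", "O", "OXT")
  side <- function(idx) idx[!(at$elety[idx] %in% bb) &
                              !.isHydrogen(at[idx, ])]
  ia <- side(.residueAtoms(x, resA))
  ib <- side(.residueAtoms(x, resB))
  n <- nFrames(x)
  if (!length(ia) || !length(ib))
    return(.pairRecord(x, resA, resB, "hydrophobic_contact", 0, n))
  hit <- rep(FALSE, n)
  for (i in ia)
    for (j in ib)
      hit <- hit | (.pairDistFrames(x, i, j) <= distMax)
  .pairRecord(x, resA, resB, "hydrophobic_contact", mean(hit), n)
}

#' Native interactions of a wild-type ensemble
#'
#' Direct (including salt-bridge) contact records with occupancy at or above
#' \code{nativeMin} -- the stable interactions whose maintenance is assessed
#' in the mutants. Water-mediated and packing contacts are never native under
#' this rule.
#'
#' @param records data.frame of occupancy records (rows as returned by
#'   [hbondOccupancy()] and friends, rbind-ed).
#' @param nativeMin inclusive occupancy threshold (default 0.5: maintained
#'   for at least half of the trajectory).
#' @return the qualifying rows, keyed by residue pair.
#' @export
nativeInteractions <- function(records, nativeMin = 0.5) {
  keep <- records$class %in% c("direct", "salt_bridge") &
    records$occupancy >= nativeMin
  records[keep, , drop = FALSE]
}
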