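#' Select atoms of a TrajectoryEnsemble
#'
#' Selections are written \code{"chain:resno-range:atom-names"}, e.g.
#' \code{"A:70-125:CA"} (alpha carbons of chain A residues 70..125,
#' inclusive), \code{"B:*:CA"}, \code{"A:303:NZ,HZ1"} or \code{"*:*:CA"}.
#' Several triplets may be joined with \code{";"}; the union is returned.
#' Waters are excluded unless addressed by residue name \code{"HOH"} in the
#' chain field.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param selection selection string (see above), or \code{NULL} together
#'   with the explicit \code{chain}/\code{resno}/\code{elety} arguments.
#' @param chain,resno,elety explicit filters (each \code{NULL} = no filter).
#' @return integer vector of atom indices (row numbers of \code{atoms(x)}).
#' @export
atomSelect <- function(x, selection = NULL, chain = NULL, resno = NULL,
                       elety = NULL) {
  at <- atoms(x)
  if (!is.null(selection)) {
    parts <- strsplit(selection, ";", fixed = TRUE)[[1]]
    idx <- sort(unique(unlist(lapply(parts, function(p) {
      f <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
      if (length(f) != 3L)
        stop("malformed selection '", p, "' (expect chain:resids:atoms)")
      ch <- if (f[1] == "*") NULL else f[1]
      rn <- if (f[2] == "*") NULL else {
        rr <- strsplit(f[2], "-", fixed = TRUE)[[1]]
        if (length(rr) == 2L) seq(as.integer(rr[1]), as.integer(rr[2]))
        else as.integer(rr)
      }
      an <- if (f[3] == "*") NULL else strsplit(f[3], ",", fixed = TRUE)[[1]]
      atomSelect(x, chain = ch, resno = rn, elety = an)
    }))))
    return(idx)
  }
  keep <- rep(TRUE, nrow(at))
  iswat <- at$resid %in% c("HOH", "WAT")
  if (!is.null(chain)) {
    if (chain %in% c("HOH", "WAT")) keep <- keep & iswat
    else keep <- keep & at$chain == chain & !iswat
  } else keep <- keep & !iswat
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  idx <- which(keep)
  if (!length(idx)) stop("empty atom selection")
  idx
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of \code{mobile} onto \code{reference} over the fit
#' atoms: the returned rotation + translation minimises the RMSD of the fit
#' atoms, with the reflection branch excluded.
#'
#' @param mobile,reference n x 3 coordinate matrices (same atom order).
#' @param fit integer indices of the fit atoms (default: all). At least 3
#'   non-collinear atoms are required.
#' @return list with \code{R} (3x3 rotation), \code{t} (length-3
#'   translation), \code{coords} (all mobile atoms transformed:
#'   \code{coords = mobile \%*\% R + t}) and \code{fitRmsd}.
#' @export
superpose <- function(mobile, reference, fit = seq_len(nrow(mobile))) {
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (length(fit) < 3L)
    stop("superposition needs at least 3 fit atoms")
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity guard: centred fit atoms must span a plane
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L)
    stop("degenerate (collinear) fit selection")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # rotation, no reflection
  # x_new = R x + t  with row-vector convention: X %*% t(R) + t
  tvec <- cq - as.vector(R %*% cp)
  moved <- sweep(mobile %*% t(R), 2, tvec, `+`)
  fr <- sqrt(mean(rowSums((moved[fit, , drop = FALSE] - Q)^2)))
  list(R = R, t = tvec, coords = moved, fitRmsd = fr)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series after superposition
#'
#' Each frame is superposed on the reference over \code{fit} and the RMSD is
#' then measured over \code{measure} without refitting -- mirroring the
#' restrained-frame analysis where external residues define the frame of
#' reference and the dimer-interface alpha carbons are measured.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param fit,measure selection strings or integer atom indices. Both must
#'   be non-empty; \code{measure} defaults to \code{fit}.
#' @param reference reference frame index (default 1) or an n_atoms x 3
#'   coordinate matrix.
#' @return numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsdSeries <- function(x, fit, measure = fit, reference = 1L) {
  fit <- .resolveSel(x, fit)
  measure <- .resolveSel(x, measure)
  ref <- if (is.matrix(reference)) reference else frameCoords(x, reference)
  vapply(seq_len(nFrames(x)), function(i) {
    sp <- superpose(frameCoords(x, i), ref, fit)
    .rmsd(sp$coords[measure, , drop = FALSE], ref[measure, , drop = FALSE])
  }, numeric(1))
}

.resolveSel <- function(x, sel) {
  if (is.character(sel)) atomSelect(x, sel) else as.integer(sel)
}

#' Mean RMSD over the second half of a series
#'
#' The "second half" is frames \code{(N/2, N]} (1-based), i.e. the last
#' \code{ceiling(N/2)} frames.
#'
#' @param rmsd numeric RMSD series.
#' @return mean of the second-half values.
#' @export
secondHalfMeanRmsd <- function(rmsd) {
  n <- length(rmsd)
  mean(rmsd[seq.int(floor(n / 2) + 1L, n)])
}

#' Per-residue RMSF profile
#'
#' All window frames are superposed on the fit selection (reference = first
#' window frame), then each selected atom's root-mean-square deviation from
#' its window-mean position is computed. With a Calpha selection this is the
#' per-residue fluctuation profile.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param sel atoms to profile (selection string or indices); typically
#'   \code{"A:*:CA"}.
#' @param fit atoms used for the superposition (default: \code{sel});
#'   \code{NULL} skips the superposition entirely (a "nofit" analysis for
#'   frames already sharing a common frame of reference).
#' @param window frame indices (default: all); at least 2 frames.
#' @param offset residue-numbering offset added for reporting (see
#'   [toHrpe65()]); default 0 keeps model numbering.
#' @return data.frame with \code{chain}, \code{resno} (offset applied),
#'   \code{elety}, \code{rmsf} (Angstrom), one row per selected atom.
#' @export
rmsfProfile <- function(x, sel, fit = sel, window = seq_len(nFrames(x)),
                        offset = 0L) {
  if (length(window) < 2L) stop("RMSF needs a window of at least 2 frames")
  sel <- .resolveSel(x, sel)
  if (!is.null(fit)) fit <- .resolveSel(x, fit)
  ref <- frameCoords(x, window[1])
  n <- length(sel)
  acc <- matrix(0, n, 3)
  frames <- vector("list", length(window))
  for (k in seq_along(window)) {
    co <- frameCoords(x, window[k])
    if (!is.null(fit)) co <- superpose(co, ref, fit)$coords
    frames[[k]] <- co[sel, , drop = FALSE]
    acc <- acc + frames[[k]]
  }
  mu <- acc / length(window)
  ssq <- Reduce(`+`, lapply(frames, function(f) rowSums((f - mu)^2)))
  at <- atoms(x)[sel, ]
  data.frame(chain = at$chain, resno = toHrpe65(at$resno, offset),
             elety = at$elety, rmsf = sqrt(ssq / length(window)),
             row.names = NULL)
}

#' Average structure over a frame window
#'
#' Plain per-atom coordinate mean of the superposed window frames. The
#' result is a geometric average, not an energy-minimised structure, and is
#' flagged as such.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param window frame indices (default: final third of the trajectory,
#'   the conventional late-window for averaged conformations).
#' @param fit fit selection for the superposition (default: all non-water
#'   atoms).
#' @return n_atoms x 3 matrix of mean coordinates with attribute
#'   \code{minimised = FALSE}.
#' @export
averageStructure <- function(x, window = NULL, fit = NULL) {
  n <- nFrames(x)
  if (is.null(window)) window <- seq.int(max(1L, floor(2 * n / 3) + 1L), n)
  if (!length(window)) stop("empty frame window")
  if (is.null(fit)) fit <- which(!(atoms(x)$resid %in% c("HOH", "WAT")))
  fit <- .resolveSel(x, fit)
  ref <- frameCoords(x, window[1])
  acc <- matrix(0, nrow(atoms(x)), 3)
  for (k in window)
    acc <- acc + superpose(frameCoords(x, k), ref, fit)$coords
  out <- acc / length(window)
  attr(out, "minimised") <- FALSE
  out
}

#' Summary structural metrics of an ensemble
#'
#' Convenience wrapper computing the RMSD series over the measured
#' selection, its second-half mean, and the Calpha RMSF profile -- the three
#' quantities the structural alert compares between mutant and wild type.
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param fit restrained/fit selection string (frame of reference).
#' @param measure measured selection (e.g. interface Calpha atoms).
#' @param rmsfSel selection profiled for RMSF (e.g. \code{"A:*:CA"}).
#' @param offset residue-numbering offset for the RMSF report.
#' @return list with \code{rmsd_series}, \code{second_half_mean_rmsd},
#'   \code{rmsf} (data.frame from [rmsfProfile()]).
#' @export
structuralMetrics <- function(x, fit, measure, rmsfSel = "A:*:CA",
                              offset = 0L) {
  rs <- rmsdSeries(x, fit = fit, measure = measure)
  list(rmsd_series = rs,
       second_half_mean_rmsd = secondHalfMeanRmsd(rs),
       rmsf = rmsfProfile(x, sel = rmsfSel, fit = fit, offset = offset))
}
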