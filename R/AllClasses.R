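#' @import methods
NULL

#' PredictionMatrix: variants x predictor-tool calls and/or raw scores
#'
#' Container for the predictions of a panel of variant-effect predictors over
#' a set of protein missense variants. Each tool is declared either
#' \code{"binary"} (cells are Pathogenic/Neutral calls, stored as \code{"P"} /
#' \code{"N"}) or \code{"scored"} (cells are raw numeric scores awaiting
#' binarisation against a cutoff). Empty cells are missing predictions.
#'
#' @slot calls character matrix (variants x tools) with entries \code{"P"},
#'   \code{"N"} or \code{NA}.
#' @slot scores numeric matrix of the same dimensions; \code{NA} for binary
#'   tools and for missing cells.
#' @slot toolType named character vector, one of \code{"binary"} or
#'   \code{"scored"} per tool.
#'
#' @seealso [PredictionMatrix()], [binarizeCalls()], [conPath()]
#' @exportClass PredictionMatrix
setClass("PredictionMatrix",
  representation(
    calls = "matrix",
    scores = "matrix",
    toolType = "character"
  )
)

setValidity("PredictionMatrix", function(object) {
  msg <- character()
  cl <- object@calls; sc <- object@scores; tt <- object@toolType
  if (!identical(dim(cl), dim(sc)))
    msg <- c(msg, "calls and scores must have identical dimensions")
  if (is.null(rownames(cl)) || is.null(colnames(cl)))
    msg <- c(msg, "calls must have variant rownames and tool colnames")
  if (anyDuplicated(rownames(cl)))
    msg <- c(msg, "duplicate variant ids")
  if (anyDuplicated(colnames(cl)))
    msg <- c(msg, "duplicate tool names")
  if (!identical(sort(names(tt)), sort(colnames(cl))))
    msg <- c(msg, "toolType must be named by the tools of the matrix")
  if (!all(tt %in% c("binary", "scored")))
    msg <- c(msg, "toolType entries must be 'binary' or 'scored'")
  bad <- cl[!is.na(cl) & !(cl %in% c("P", "N"))]
  if (length(bad))
    msg <- c(msg, sprintf("invalid call value(s): %s",
                          paste(unique(bad), collapse = ", ")))
  # a binary tool never carries raw scores
  bintools <- names(tt)[tt == "binary"]
  if (length(bintools) && any(!is.na(sc[, bintools, drop = FALSE])))
    msg <- c(msg, "binary tools must not carry raw scores")
  # invalid variant ids
  vv <- rownames(cl)
  ok <- grepl("^[A-Y][0-9]+[A-Y]$", vv) &
    substr(vv, 1, 1) != substring(vv, nchar(vv))
  if (any(!ok))
    msg <- c(msg, sprintf("invalid variant id(s): %s",
                          paste(vv[!ok], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionMatrix
#'
#' @param calls character matrix (variants x tools) of \code{"P"}/\code{"N"}
#'   calls (\code{NA} where the tool is scored or the cell missing). May be
#'   \code{NULL} when only scores are supplied.
#' @param scores numeric matrix of raw scores (\code{NA} for binary tools).
#'   May be \code{NULL} when only calls are supplied.
#' @param toolType named character vector "binary"/"scored"; by default every
#'   tool with any non-\code{NA} score is "scored", the rest "binary".
#' @return a [PredictionMatrix-class] object.
#' @examples
#' m <- matrix(c("P", "N", "P", "P"), nrow = 2,
#'             dimnames = list(c("K303N", "N373S"), c("toolA", "toolB")))
#' pm <- PredictionMatrix(calls = m)
#' conPath(pm)
#' @export
PredictionMatrix <- function(calls = NULL, scores = NULL, toolType = NULL) {
  if (is.null(calls) && is.null(scores))
    stop("supply at least one of 'calls' and 'scores'")
  if (is.null(calls)) {
    calls <- matrix(NA_character_, nrow(scores), ncol(scores),
                    dimnames = dimnames(scores))
  }
  if (is.null(scores)) {
    scores <- matrix(NA_real_, nrow(calls), ncol(calls),
                     dimnames = dimnames(calls))
  }
  storage.mode(scores) <- "double"
  if (is.null(toolType)) {
    scored <- apply(scores, 2, function(x) any(!is.na(x)))
    toolType <- ifelse(scored, "scored", "binary")
    names(toolType) <- colnames(calls)
  }
  new("PredictionMatrix", calls = calls, scores = scores,
      toolType = toolType[colnames(calls)])
}

#' TrajectoryEnsemble: a multi-frame coordinate ensemble of a protein system
#'
#' Holds the topology (one row per atom) and the Cartesian coordinates of an
#' ordered set of frames, e.g. snapshots sampled from a molecular-dynamics
#' production run and stored as a multi-model PDB. Coordinates are in
#' Angstrom. Chains identify the two monomers of a dimer; water residues are
#' recognised by residue name HOH/WAT.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety} (atom
#'   name), \code{resid} (residue name), \code{chain}, \code{resno},
#'   \code{elesy} (element symbol).
#' @slot xyz numeric matrix, frames x (3 * n_atoms), each row the
#'   concatenated x,y,z coordinates of one frame (bio3d convention).
#' @slot frameSpacing numeric scalar, time per frame; metadata only.
#'
#' @seealso [readPdbEnsemble()], [rmsdSeries()], [hbondOccupancy()]
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  representation(
    atoms = "data.frame",
    xyz = "matrix",
    frameSpacing = "numeric"
  )
)

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("eleno", "elety", "resid", "chain", "resno", "elesy")
  if (!all(need %in% names(at)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@xyz) != 3L * nrow(at))
    msg <- c(msg, "xyz must have 3 * n_atoms columns")
  if (nrow(object@xyz) < 1L)
    msg <- c(msg, "at least one frame required")
  if (any(!is.finite(object@xyz)))
    msg <- c(msg, "non-finite coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct a TrajectoryEnsemble
#'
#' @param atoms atom table (see [TrajectoryEnsemble-class]).
#' @param xyz frames x (3 * n_atoms) coordinate matrix, or an n_atoms x 3
#'   matrix for a single frame.
#' @param frameSpacing time per frame (arbitrary units, metadata only).
#' @return a [TrajectoryEnsemble-class] object.
#' @export
TrajectoryEnsemble <- function(atoms, xyz, frameSpacing = 1) {
  if (ncol(xyz) == 3L && nrow(xyz) == nrow(atoms))
    xyz <- matrix(t(xyz), nrow = 1L)
  atoms$chain[is.na(atoms$chain)] <- ""
  new("TrajectoryEnsemble", atoms = atoms, xyz = xyz,
      frameSpacing = frameSpacing)
}

#' Geometric hydrogen-bond criteria
#'
#' A donor/acceptor pair is counted as hydrogen-bonded in a frame when the
#' donor--acceptor heavy-atom distance is at most \code{distMax} and the
#' donor--H--acceptor angle is at least \code{angleMin}. When the ensemble
#' carries no hydrogens, a heavy-atom-only fallback (distance at most
#' \code{heavyDistMax}) can be enabled. A water bridge requires a single
#' water oxygen within \code{distMax} of one polar (N/O) atom of each
#' residue in the same frame.
#'
#' @slot distMax maximum donor-acceptor heavy-atom distance (Angstrom).
#' @slot angleMin minimum donor-H-acceptor angle (degrees).
#' @slot heavyDistMax distance cutoff for the hydrogen-free fallback.
#' @slot allowHeavyFallback logical; permit the fallback (with a warning).
#' @exportClass HBondCriteria
setClass("HBondCriteria",
  representation(
    distMax = "numeric",
    angleMin = "numeric",
    heavyDistMax = "numeric",
    allowHeavyFallback = "logical"
  )
)

setValidity("HBondCriteria", function(object) {
  msg <- character()
  if (object@distMax <= 0) msg <- c(msg, "distMax must be positive")
  if (object@angleMin <= 0 || object@angleMin > 180)
    msg <- c(msg, "angleMin must lie in (0, 180]")
  if (object@heavyDistMax <= 0) msg <- c(msg, "heavyDistMax must be positive")
  if (length(msg)) msg else TRUE
})

#' @param distMax,angleMin,heavyDistMax,allowHeavyFallback see slots.
#' @return an [HBondCriteria-class] object.
#' @rdname HBondCriteria-class
#' @export
hbondCriteria <- function(distMax = 3.5, angleMin = 135,
                          heavyDistMax = 3.3, allowHeavyFallback = TRUE) {
  new("HBondCriteria", distMax = distMax, angleMin = angleMin,
      heavyDistMax = heavyDistMax, allowHeavyFallback = allowHeavyFallback)
}
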