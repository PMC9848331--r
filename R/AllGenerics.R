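#' @rdname PredictionMatrix-class
#' @param x,object a \code{PredictionMatrix} or \code{TrajectoryEnsemble}.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname PredictionMatrix-class
#' @export
setGeneric("toolNames", function(x) standardGeneric("toolNames"))

#' @rdname PredictionMatrix-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname PredictionMatrix-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PredictionMatrix-class
#' @export
setGeneric("toolType", function(x) standardGeneric("toolType"))

#' @rdname TrajectoryEnsemble-class
#' @param x a \code{TrajectoryEnsemble}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname TrajectoryEnsemble-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname TrajectoryEnsemble-class
#' @param frame frame index.
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

setMethod("variantIds", "PredictionMatrix", function(x) rownames(x@calls))
setMethod("toolNames", "PredictionMatrix", function(x) colnames(x@calls))
setMethod("calls", "PredictionMatrix", function(x) x@calls)
setMethod("scores", "PredictionMatrix", function(x) x@scores)
setMethod("toolType", "PredictionMatrix", function(x) x@toolType)

setMethod("nFrames", "TrajectoryEnsemble", function(x) nrow(x@xyz))
setMethod("atoms", "TrajectoryEnsemble", function(x) x@atoms)

#' @describeIn TrajectoryEnsemble-class coordinates of one frame as an
#'   n_atoms x 3 matrix.
setMethod("frameCoords", "TrajectoryEnsemble", function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= nrow(x@xyz))
  matrix(x@xyz[frame, ], ncol = 3L, byrow = TRUE)
})

setMethod("show", "PredictionMatrix", function(object) {
  tt <- object@toolType
  cat(sprintf("PredictionMatrix: %d variants x %d tools (%d binary, %d scored)\n",
              nrow(object@calls), ncol(object@calls),
              sum(tt == "binary"), sum(tt == "scored")))
  nmiss <- sum(is.na(object@calls) & is.na(object@scores))
  if (nmiss) cat(sprintf("  %d missing cell(s)\n", nmiss))
  cat("  variants:", paste(utils::head(rownames(object@calls), 6), collapse = ", "),
      if (nrow(object@calls) > 6) "..." else "", "\n")
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  at <- object@atoms
  wat <- at$resid %in% c("HOH", "WAT")
  cat(sprintf("TrajectoryEnsemble: %d frames, %d atoms (%d water), chains: %s\n",
              nrow(object@xyz), nrow(at), sum(wat),
              paste(unique(at$chain[!wat]), collapse = ", ")))
})

setMethod("show", "HBondCriteria", function(object) {
  cat(sprintf(
    "HBondCriteria: D-A <= %.2f A, D-H-A >= %.0f deg (heavy-only fallback %s, <= %.2f A)\n",
    object@distMax, object@angleMin,
    if (object@allowHeavyFallback) "on" else "off", object@heavyDistMax))
})
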