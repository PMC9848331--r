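#' Default score cutoffs for scored predictor tools
#'
#' Raw-score predictors are converted to binary Pathogenic/Neutral calls with
#' the convention score >= cutoff => Pathogenic. The defaults are: 0 for the
#' raw coding scores of Eigen and Eigen-PC and for SNPs3D, INPS-sequence and
#' PROST; 0.4 for Integrated FitCons; 0.5 for REVEL, VEST4, DANN, MutPred2
#' and PON-P2; 0.75 for MVP; 20 for CADD and CADD_hg19; 50 for SuSPect.
#'
#' @return named numeric vector of cutoffs (canonical tool names).
#' @export
defaultCutoffs <- function() {
  c("Eigen" = 0, "Eigen-PC" = 0, "SNPs3D" = 0, "INPS-sequence" = 0,
    "PROST" = 0,
    "Integrated FitCons" = 0.4,
    "REVEL" = 0.5, "VEST4" = 0.5, "DANN" = 0.5, "MutPred2" = 0.5,
    "PON-P2" = 0.5,
    "MVP" = 0.75,
    "CADD" = 20, "CADD_hg19" = 20,
    "SuSPect" = 50)
}

#' Binarise raw predictor scores into Pathogenic/Neutral calls
#'
#' Cells of binary tools pass through unchanged; cells of scored tools are
#' mapped by score >= cutoff => Pathogenic (or strictly > for tools listed in
#' \code{strict}). Missing cells stay missing. Binarisation is idempotent: a
#' matrix whose tools are all binary is returned as-is.
#'
#' @param x a [PredictionMatrix-class].
#' @param cutoffs named numeric vector, tool -> cutoff ([defaultCutoffs()]).
#' @param strict character vector of tools for which the tie at the cutoff
#'   counts as Neutral (score > cutoff required for Pathogenic).
#' @return a [PredictionMatrix-class] with every tool binary.
#' @examples
#' sc <- matrix(c(25, 15), ncol = 1, dimnames = list(c("K303N","N373S"), "CADD"))
#' binarizeCalls(PredictionMatrix(scores = sc))
#' @export
binarizeCalls <- function(x, cutoffs = defaultCutoffs(), strict = character()) {
  stopifnot(is(x, "PredictionMatrix"))
  tt <- toolType(x)
  scored <- names(tt)[tt == "scored"]
  nocut <- setdiff(scored, names(cutoffs))
  if (length(nocut))
    stop("no cutoff configured for scored tool(s): ",
         paste(nocut, collapse = ", "))
  cl <- calls(x)
  sc <- scores(x)
  for (tool in scored) {
    s <- sc[, tool]
    hit <- if (tool %in% strict) s > cutoffs[[tool]] else s >= cutoffs[[tool]]
    cl[, tool] <- ifelse(is.na(s), NA_character_, ifelse(hit, "P", "N"))
  }
  sc[] <- NA_real_
  tt[] <- "binary"
  new("PredictionMatrix", calls = cl, scores = sc, toolType = tt)
}

#' Confusion counts of one tool's calls against a labelled benchmark
#'
#' TP and TN are pathogenic and benign variants correctly called; FP is a
#' benign variant called Pathogenic; FN a pathogenic variant called Neutral.
#' Missing predictions are excluded from the counts and reported in
#' \code{n_missing}.
#'
#' @param predictions named character vector of \code{"P"}/\code{"N"} calls
#'   (names are variant ids), possibly with \code{NA} for missing.
#' @param labels named character vector of \code{"Pathogenic"}/\code{"Benign"}
#'   truth labels covering every predicted variant.
#' @return list with integer \code{TP}, \code{TN}, \code{FP}, \code{FN},
#'   \code{n_missing} and character \code{missing} (variant ids).
#' @export
confusionCounts <- function(predictions, labels) {
  if (is.null(names(predictions)))
    stop("'predictions' must be named by variant id")
  unl <- setdiff(names(predictions), names(labels))
  if (length(unl))
    stop("unlabelled variant(s): ", paste(unl, collapse = ", "))
  lab <- labels[names(predictions)]
  if (!all(lab %in% c("Pathogenic", "Benign")))
    stop("labels must be 'Pathogenic' or 'Benign'")
  miss <- names(predictions)[is.na(predictions)]
  keep <- !is.na(predictions)
  p <- predictions[keep] == "P"
  truthP <- lab[keep] == "Pathogenic"
  list(TP = sum(p & truthP), TN = sum(!p & !truthP),
       FP = sum(p & !truthP), FN = sum(!p & truthP),
       n_missing = length(miss), missing = miss)
}

#' Performance metrics from confusion counts
#'
#' Precision = TP/(TP+FP); Specificity = TN/(TN+FP); Recall = TP/(TP+FN);
#' Accuracy = (TP+TN)/(TP+TN+FP+FN). Metrics are kept in full precision; a
#' zero denominator yields \code{NA} and the metric name is listed in the
#' \code{undefined} attribute rather than being silently reported as 0.
#'
#' @param counts list with \code{TP}, \code{TN}, \code{FP}, \code{FN}
#'   (see [confusionCounts()]).
#' @return list with \code{precision}, \code{specificity}, \code{recall},
#'   \code{accuracy} (raw fractions, \code{NA} when undefined), the counts,
#'   and \code{undefined} (character vector of undefined metric names).
#' @examples
#' toolMetrics(list(TP = 27, TN = 2, FP = 1, FN = 0))
#' @export
toolMetrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop("negative confusion counts")
    frac <- function(num, den) if (den == 0) NA_real_ else num / den
    out <- list(
      precision = frac(TP, TP + FP),
      specificity = frac(TN, TN + FP),
      recall = frac(TP, TP + FN),
      accuracy = frac(TP + TN, TP + TN + FP + FN),
      TP = TP, TN = TN, FP = FP, FN = FN)
    out$undefined <- names(out)[1:4][vapply(out[1:4], is.na, TRUE)]
    out
  })
}

#' Benchmark every tool of a binary prediction matrix
#'
#' @param x a binary [PredictionMatrix-class] (run [binarizeCalls()] first).
#' @param labels named \code{"Pathogenic"}/\code{"Benign"} vector.
#' @param digits decimal places for the rounded report columns (half-up
#'   rounding; raw fractions are kept in the \code{*_raw} columns).
#' @return data.frame, one row per tool: confusion counts, raw and rounded
#'   recall/precision/specificity/accuracy, and \code{n_missing}.
#' @export
benchmarkTools <- function(x, labels, digits = 2) {
  stopifnot(is(x, "PredictionMatrix"))
  if (any(toolType(x) == "scored"))
    stop("matrix contains scored tools; binarise first")
  cl <- calls(x)
  rows <- lapply(colnames(cl), function(tool) {
    m <- toolMetrics(confusionCounts(cl[, tool], labels))
    data.frame(tool = tool, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               recall_raw = m$recall, precision_raw = m$precision,
               specificity_raw = m$specificity, accuracy_raw = m$accuracy,
               n_missing = sum(is.na(cl[, tool])))
  })
  out <- do.call(rbind, rows)
  for (f in c("recall", "precision", "specificity", "accuracy"))
    out[[f]] <- roundHalfUp(out[[paste0(f, "_raw")]], digits)
  out
}

#' Confusion counts implied by reported recall and specificity
#'
#' On a benchmark of known size (27 pathogenic + 3 benign by default) the
#' printed recall and specificity determine the full confusion table:
#' TP = round(recall * nPos), TN = round(specificity * nNeg).
#'
#' @param recall,specificity reported fractions (2-decimal rounding is fine).
#' @param nPos,nNeg benchmark class sizes.
#' @return list(TP, TN, FP, FN), vector-safe for length-1 inputs only.
#' @export
impliedConfusionCounts <- function(recall, specificity, nPos = 27, nNeg = 3) {
  TP <- as.integer(round(recall * nPos))
  TN <- as.integer(round(specificity * nNeg))
  list(TP = TP, TN = TN, FP = nNeg - TN, FN = nPos - TP)
}

#' Select reliable tools by recall and specificity thresholds
#'
#' Thresholds are quoted on the 2-decimal reported scale and are applied to
#' the rounded metrics: on the 27 + 3 benchmark, a tool finding 21 of 27
#' pathogenic variants (21/27 = 0.777...) reports recall 0.78 and passes the
#' default filter, and 2 of 3 benign variants reports specificity 0.67.
#'
#' @param perf data.frame from [benchmarkTools()] (needs \code{tool},
#'   \code{recall_raw}, \code{specificity_raw}; rounded columns are used
#'   when the raw ones are absent).
#' @param recallMin,specificityMin inclusive thresholds (defaults 0.78 and
#'   0.67, the panel-selection filter).
#' @return character vector of retained tool names, input order preserved.
#' @export
selectTools <- function(perf, recallMin = 0.78, specificityMin = 0.67) {
  rec <- if ("recall_raw" %in% names(perf)) perf$recall_raw else perf$recall
  spe <- if ("specificity_raw" %in% names(perf)) perf$specificity_raw else
    perf$specificity
  if (anyNA(rec) || anyNA(spe))
    stop("recall/specificity undefined for tool(s): ",
         paste(perf$tool[is.na(rec) | is.na(spe)], collapse = ", "))
  keep <- roundHalfUp(rec) >= recallMin - 1e-9 &
    roundHalfUp(spe) >= specificityMin - 1e-9
  if (!any(keep))
    message("no tool passes the selection thresholds")
  as.character(perf$tool[keep])
}

#' ConPath consensus score and call
#'
#' The ConPath score of a variant is the number of panel tools calling it
#' Pathogenic. With the 19-tool panel a score >= 10 is a pathogenic
#' consensus call and <= 9 a neutral one; for other panel sizes the default
#' threshold is the strict majority floor(n/2) + 1 (which equals 10 at
#' n = 19).
#'
#' @param x a binary [PredictionMatrix-class].
#' @param panel tools to aggregate (default: all tools of the matrix).
#' @param pathogenicMin minimal score for a Pathogenic call; default
#'   floor(panel size / 2) + 1.
#' @param missingPolicy \code{"strict"} (default) errors on any missing
#'   (variant, panel tool) prediction, naming it; \code{"neutral"} counts
#'   missing predictions as Neutral with a warning (conservative toward
#'   non-pathogenicity).
#' @return data.frame with \code{variant}, \code{votes}, \code{panel_size},
#'   \code{call} (\code{"Pathogenic"}/\code{"Neutral"}), rows in input
#'   variant order.
#' @examples
#' d <- hrpe65DmsData()
#' conPath(d$matrix1)
#' @export
conPath <- function(x, panel = toolNames(x), pathogenicMin = NULL,
                    missingPolicy = c("strict", "neutral")) {
  stopifnot(is(x, "PredictionMatrix"))
  missingPolicy <- match.arg(missingPolicy)
  bad <- setdiff(panel, toolNames(x))
  if (length(bad))
    stop("panel tool(s) absent from matrix: ", paste(bad, collapse = ", "))
  if (any(toolType(x)[panel] == "scored"))
    stop("panel contains scored tools; binarise first")
  cl <- calls(x)[, panel, drop = FALSE]
  if (anyNA(cl)) {
    idx <- which(is.na(cl), arr.ind = TRUE)
    where <- paste0(rownames(cl)[idx[, 1]], "/", panel[idx[, 2]])
    if (missingPolicy == "strict")
      stop("missing panel prediction(s): ", paste(where, collapse = ", "))
    warning("missing prediction(s) counted as Neutral: ",
            paste(where, collapse = ", "))
  }
  if (is.null(pathogenicMin))
    pathogenicMin <- floor(length(panel) / 2) + 1L
  votes <- rowSums(cl == "P", na.rm = TRUE)
  data.frame(
    variant = rownames(cl),
    votes = as.integer(votes),
    panel_size = length(panel),
    call = ifelse(votes >= pathogenicMin, "Pathogenic", "Neutral"),
    row.names = NULL)
}
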