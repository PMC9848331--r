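#' Bundled hRPE65 dimer-region VUS study data
#'
#' Machine-readable transcriptions of the published evaluation of 13 hRPE65
#' missense variants of uncertain significance located in the
#' dimer-mediating region:
#' \describe{
#' \item{matrix1, matrix2}{[PredictionMatrix-class] objects with the 19
#'   selected tools' Pathogenic/Neutral calls for the first (9-variant) and
#'   second (4-variant) VUS sets; tool names canonicalised.}
#' \item{toolStats}{data.frame of the 19 selected tools' reported
#'   recall/precision/specificity/accuracy on the 27 pathogenic + 3 benign
#'   ClinVar benchmark, plus the confusion counts those fractions imply
#'   (\code{TP = round(recall * 27)}, \code{TN = round(specificity * 3)}).}
#' \item{occupancies}{long data.frame of wild-type and mutant residue-pair
#'   contact occupancies around each mutated residue (direct, salt-bridge,
#'   water-mediated and packing contacts). Reported percentages were partly
#'   qualitative ("more than 50\%", "85--90\%"); the file fixes concrete
#'   values consistent with the reported text.}
#' \item{structural}{per-variant second-half mean RMSD and RMSF-peak
#'   summaries. RMSD/RMSF curves were published as figures, not numbers;
#'   this synthetic summary carries the values the accompanying text states
#'   (second-half mean RMSD above 1.5 vs around 1.0 Angstrom; an RMSF peak
#'   of almost 3 Angstrom over hRPE65 residues 375--379 vs below 1.0 for
#'   the wild type).}
#' \item{alerts}{the 13 published alert triples (structural, interaction,
#'   ConPath) as logicals plus the published class.}
#' }
#'
#' @return a named list (see above).
#' @examples
#' d <- hrpe65DmsData()
#' conPath(d$matrix1)
#' @export
hrpe65DmsData <- function() {
  path <- function(f) system.file("extdata", f, package = "ConPathDMS",
                                  mustWork = TRUE)
  m1 <- readPredictionMatrix(path("consensus_calls_set1.tsv"))$matrix
  m2 <- readPredictionMatrix(path("consensus_calls_set2.tsv"))$matrix
  ts <- .readTable(path("tool_benchmark_stats.csv"))
  ts$tool <- canonicalToolName(ts$tool)
  cc <- impliedConfusionCounts(ts$recall, ts$specificity)
  ts$TP <- cc$TP; ts$TN <- cc$TN; ts$FP <- cc$FP; ts$FN <- cc$FN
  occ <- .readTable(path("hbond_occupancies.csv"))
  struct <- utils::read.csv(path("structural_summaries_synthetic.csv"),
                            na.strings = "NA")
  al <- .readTable(path("alert_annotations.csv"))
  for (f in c("structural", "interaction", "conpath"))
    al[[f]] <- al[[f]] == "+"
  list(matrix1 = m1, matrix2 = m2, toolStats = ts, occupancies = occ,
       structural = struct, alerts = al)
}
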