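#' Parse a protein-change variant id
#'
#' Variant ids follow the one-letter convention \code{<WT><position><mutant>},
#' e.g. \code{"K303N"}: lysine 303 replaced by asparagine, with 1-based
#' hRPE65 residue numbering.
#'
#' @param id character vector of variant ids.
#' @return data.frame with columns \code{id}, \code{wt}, \code{pos},
#'   \code{mut}.
#' @examples parseVariant(c("K303N", "T306I"))
#' @export
parseVariant <- function(id) {
  m <- regmatches(id, regexec("^([A-Y])([0-9]+)([A-Y])$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed variant id(s): ", paste(id[bad], collapse = ", "))
  wt <- vapply(m, `[`, "", 2L)
  mut <- vapply(m, `[`, "", 4L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  if (any(wt == mut))
    stop("wild-type and mutant residue identical in: ",
         paste(id[wt == mut], collapse = ", "))
  if (any(pos < 1L))
    stop("residue positions must be positive")
  data.frame(id = id, wt = wt, pos = pos, mut = mut)
}

#' Round half away from zero
#'
#' Reported two-decimal metrics use conventional half-up rounding (24/27
#' prints as 0.89), not the round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# alias map: published tables use several spellings per tool
.TOOL_ALIASES <- c(
  "Mut. Assessor" = "MutationAssessor",
  "Mut. Assesor" = "MutationAssessor",
  "MutationAssessor" = "MutationAssessor",
  "NEI Mut. Search" = "NEI Mutation Search",
  "NEI commons Mutation Search" = "NEI Mutation Search",
  "NEI Mutation Search" = "NEI Mutation Search",
  "SusPect" = "SuSPect",
  "SuSPect" = "SuSPect"
)

#' Canonical predictor-tool names
#'
#' Published tables spell some tools in more than one way (e.g.
#' "Mut. Assessor" / "Mut. Assesor" / "MutationAssessor"); all analyses key
#' tools by one canonical spelling.
#'
#' @param tool character vector of tool names as found in input files.
#' @param extra optional named character vector of additional alias -> name
#'   mappings (applied after the built-in map).
#' @return character vector of canonical names (unknown names pass through
#'   unchanged, whitespace-trimmed).
#' @export
canonicalToolName <- function(tool, extra = NULL) {
  tool <- trimws(tool)
  map <- c(extra, .TOOL_ALIASES)
  hit <- match(tool, names(map))
  ifelse(is.na(hit), tool, unname(map[hit]))
}

#' Map model residue numbering to hRPE65 numbering
#'
#' The dimer-focussed structural models renumber residues from 1; hRPE65
#' positions are recovered by a constant offset (model residue 98 is hRPE65
#' residue 375, i.e. offset 277).
#'
#' @param resno integer vector of model residue numbers.
#' @param offset numbering offset (default 277).
#' @return hRPE65 residue numbers.
#' @export
toHrpe65 <- function(resno, offset = 277L) resno + as.integer(offset)

#' @rdname toHrpe65
#' @export
fromHrpe65 <- function(resno, offset = 277L) resno - as.integer(offset)

# shared residue-key helper: "A:303"
.resKey <- function(chain, resno) paste0(chain, ":", resno)
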