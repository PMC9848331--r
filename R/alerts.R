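# Alert derivation and the four-level pathogenic-potential classification.

.pairKey <- function(df) {
  # order-independent residue-pair key
  a <- .resKey(df$chain1, df$resno1)
  b <- .resKey(df$chain2, df$resno2)
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Pairwise-interaction alert: are native contacts maintained in a mutant?
#'
#' A native wild-type contact (see [nativeInteractions()]) is considered
#' maintained when some mutant direct contact between the same residue pair
#' has occupancy of at least \code{max(floor, wt_occupancy - dropPoints)};
#' i.e. a contact may weaken by up to \code{dropPoints} occupancy points but
#' never below the \code{floor}. The alert fires when at least one native
#' pair involving the mutated residue is not maintained.
#'
#' @param wtNative data.frame of native wild-type records (output of
#'   [nativeInteractions()]).
#' @param mutRecords data.frame of mutant contact records over the same
#'   residue numbering (occupancy 0 or an absent row both mean "lost").
#' @param mutatedResno residue number of the mutation; only native pairs
#'   involving this residue are assessed. \code{NULL} assesses every native
#'   pair.
#' @param mutatedChain chain of the mutated monomer (default \code{"A"}).
#' @param dropPoints tolerated occupancy drop (default 0.20).
#' @param floor minimal occupancy for a maintained contact (default 0.50).
#' @return list with \code{alert} (logical) and \code{disrupted} (data.frame
#'   of lost pairs with \code{wt_occupancy}, \code{mut_occupancy},
#'   \code{required}).
#' @export
interactionAlert <- function(wtNative, mutRecords, mutatedResno = NULL,
                             mutatedChain = "A", dropPoints = 0.20,
                             floor = 0.50) {
  if (is.null(wtNative) || !nrow(wtNative))
    return(list(alert = FALSE, disrupted = .emptyDisrupted()))
  wt <- wtNative
  if (!is.null(mutatedResno)) {
    key <- .resKey(mutatedChain, mutatedResno)
    inv <- .resKey(wt$chain1, wt$resno1) == key |
      .resKey(wt$chain2, wt$resno2) == key
    wt <- wt[inv, , drop = FALSE]
  }
  if (!nrow(wt)) return(list(alert = FALSE, disrupted = .emptyDisrupted()))
  mut <- mutRecords[mutRecords$class %in% c("direct", "salt_bridge"), ,
                    drop = FALSE]
  mutKey <- if (nrow(mut)) .pairKey(mut) else character()
  rows <- lapply(seq_len(nrow(wt)), function(i) {
    k <- .pairKey(wt[i, ])
    mo <- if (k %in% mutKey) max(mut$occupancy[mutKey == k]) else 0
    req <- max(floor, wt$occupancy[i] - dropPoints)
    if (mo >= req) return(NULL)
    cbind(wt[i, c("chain1", "resno1", "resname1",
                  "chain2", "resno2", "resname2")],
          data.frame(wt_occupancy = wt$occupancy[i], mut_occupancy = mo,
                     required = req))
  })
  disrupted <- do.call(rbind, rows)
  if (is.null(disrupted)) disrupted <- .emptyDisrupted()
  list(alert = nrow(disrupted) > 0L, disrupted = disrupted)
}

.emptyDisrupted <- function() {
  data.frame(chain1 = character(), resno1 = integer(), resname1 = character(),
             chain2 = character(), resno2 = integer(), resname2 = character(),
             wt_occupancy = numeric(), mut_occupancy = numeric(),
             required = numeric())
}

#' Structural alert: conformational deviation of a mutant versus wild type
#'
#' Fires when either (a) the mutant's second-half mean RMSD reaches
#' \code{rmsdMin}, or (b) some run of at least \code{rmsfWindow} consecutive
#' profiled residues has mutant RMSF of at least \code{rmsfMin} while the
#' wild type stays below \code{wtRmsfMax} there -- a localised flexibility
#' peak absent from the wild type.
#'
#' @param mutMetrics,wtMetrics lists as returned by [structuralMetrics()]
#'   (elements \code{second_half_mean_rmsd} and \code{rmsf}, the latter a
#'   data.frame with \code{resno} and \code{rmsf} over identical residue
#'   sets).
#' @param rmsdMin second-half mean RMSD threshold (default 1.5 Angstrom).
#' @param rmsfMin mutant RMSF peak threshold (default 2.0 Angstrom).
#' @param rmsfWindow minimal run length in residues (default 3).
#' @param wtRmsfMax wild-type RMSF ceiling inside the run (default 1.0).
#' @return list with \code{alert}, and \code{evidence} (list: which
#'   criterion fired, the mutant and wild-type second-half RMSD, the peak
#'   residues).
#' @export
structuralAlert <- function(mutMetrics, wtMetrics, rmsdMin = 1.5,
                            rmsfMin = 2.0, rmsfWindow = 3L,
                            wtRmsfMax = 1.0) {
  mr <- mutMetrics$rmsf; wr <- wtMetrics$rmsf
  if (!is.null(mr) && !is.null(wr)) {
    if (!identical(mr$resno, wr$resno))
      stop("mutant and wild-type RMSF profiles cover different residues")
  }
  rmsdHit <- isTRUE(mutMetrics$second_half_mean_rmsd >= rmsdMin)
  peakRes <- integer()
  if (!is.null(mr)) {
    flag <- mr$rmsf >= rmsfMin & wr$rmsf < wtRmsfMax
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= rmsfWindow)) {
      run <- seq.int(ends[k] - r$lengths[k] + 1L, ends[k])
      peakRes <- c(peakRes, mr$resno[run])
    }
  }
  rmsfHit <- length(peakRes) > 0L
  list(
    alert = rmsdHit || rmsfHit,
    evidence = list(
      criterion = c("rmsd", "rmsf")[c(rmsdHit, rmsfHit)],
      second_half_mean_rmsd_mut = mutMetrics$second_half_mean_rmsd,
      second_half_mean_rmsd_wt = wtMetrics$second_half_mean_rmsd,
      peak_residues = peakRes))
}

.PP_CLASSES <- c("LPPV", "MLPPV", "MHPPV", "HPPV")

#' Four-level pathogenic-potential class from the three alerts
#'
#' The class is a pure function of the number of alerts that fire:
#' 3 = HPPV (high), 2 = MHPPV (moderate/high), 1 = MLPPV (moderate/low),
#' 0 = LPPV (low pathogenic potential). Which alerts fire is irrelevant.
#'
#' @param structural,interaction,conpath logical vectors (recycled to a
#'   common length); \code{NA} is an error -- partial profiles are reported,
#'   never classified.
#' @return factor with levels LPPV < MLPPV < MHPPV < HPPV.
#' @examples classifyVariant(FALSE, TRUE, TRUE)  # MHPPV
#' @export
classifyVariant <- function(structural, interaction, conpath) {
  n <- max(length(structural), length(interaction), length(conpath))
  s <- rep_len(structural, n); i <- rep_len(interaction, n)
  c_ <- rep_len(conpath, n)
  if (anyNA(s) || anyNA(i) || anyNA(c_))
    stop("alert flags must be TRUE/FALSE; partial profiles cannot be classified")
  factor(.PP_CLASSES[s + i + c_ + 1L], levels = .PP_CLASSES, ordered = TRUE)
}

#' Cohort report over a set of alert profiles
#'
#' @param profiles data.frame with columns \code{variant},
#'   \code{structural}, \code{interaction}, \code{conpath} (logical), and
#'   optionally \code{conpath_votes}.
#' @return list with \code{table} (profiles plus \code{n_alerts} and
#'   \code{class}), \code{classCounts} (named integer vector over the four
#'   classes), and \code{highConfidence} (variants with 0 or 3 alerts, i.e.
#'   the LPPV and HPPV sets -- consensus-supported neutral or pathogenic
#'   predictions).
#' @examples
#' d <- hrpe65DmsData()
#' cohortReport(d$alerts)$classCounts
#' @export
cohortReport <- function(profiles) {
  if (anyDuplicated(profiles$variant))
    stop("duplicate variant(s): ",
         paste(unique(profiles$variant[duplicated(profiles$variant)]),
               collapse = ", "))
  tab <- profiles
  if (nrow(tab)) {
    tab$class <- classifyVariant(tab$structural, tab$interaction, tab$conpath)
    tab$n_alerts <- tab$structural + tab$interaction + tab$conpath
  } else {
    tab$class <- factor(character(), levels = .PP_CLASSES, ordered = TRUE)
    tab$n_alerts <- integer()
  }
  counts <- table(factor(tab$class, levels = .PP_CLASSES))
  hc <- tab$variant[tab$n_alerts %in% c(0L, 3L)]
  list(table = tab,
       classCounts = stats::setNames(as.integer(counts), .PP_CLASSES),
       highConfidence = as.character(hc))
}

#' Assemble alert profiles from the three evidence tracks
#'
#' @param conpath data.frame from [conPath()].
#' @param structural named logical vector of structural alerts per variant.
#' @param interaction named logical vector of interaction alerts per
#'   variant.
#' @param pathogenicMin ConPath score threshold used for the ConPath alert
#'   (default: the strict majority of the panel recorded in \code{conpath}).
#' @return profiles data.frame suitable for [cohortReport()].
#' @export
alertProfiles <- function(conpath, structural, interaction,
                          pathogenicMin = NULL) {
  v <- conpath$variant
  if (is.null(pathogenicMin))
    pathogenicMin <- floor(conpath$panel_size[1] / 2) + 1L
  missS <- setdiff(v, names(structural))
  missI <- setdiff(v, names(interaction))
  if (length(missS) || length(missI))
    stop("missing alert flag(s) for variant(s): ",
         paste(unique(c(missS, missI)), collapse = ", "))
  data.frame(variant = v,
             structural = unname(structural[v]),
             interaction = unname(interaction[v]),
             conpath = conpath$votes >= pathogenicMin,
             conpath_votes = conpath$votes)
}
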