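# File I/O: prediction matrices and benchmarks (CSV/TSV), multi-model PDB
# ensembles (via bio3d), run configuration (YAML) and result writers.

.readTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}

#' Read a prediction matrix from CSV/TSV
#'
#' Expected layout: header \code{variant,<tool1>,<tool2>,...}; binary cells
#' \code{P}/\code{N} (case-insensitive, \code{Pathogenic}/\code{Neutral}
#' also accepted); scored cells numeric; empty cells missing. Matrices may
#' also be tool-per-row (first column \code{Method}/\code{tool}, one column
#' per variant), the layout of published consensus tables; this is detected
#' from the header and transposed. A companion tool-metadata table
#' (\code{tool,type,cutoff,alias}) can declare tool types, per-tool cutoffs
#' and alternate spellings.
#'
#' @param path matrix file.
#' @param toolMeta optional path to the tool-metadata CSV.
#' @return list with \code{matrix} (a [PredictionMatrix-class], tools under
#'   canonical names) and \code{cutoffs} (named vector: [defaultCutoffs()]
#'   overridden by the metadata).
#' @export
readPredictionMatrix <- function(path, toolMeta = NULL) {
  df <- .readTable(path)
  first <- tolower(names(df)[1])
  extra <- NULL
  cutoffs <- defaultCutoffs()
  types <- NULL
  if (!is.null(toolMeta)) {
    meta <- .readTable(toolMeta)
    if (!all(c("tool", "type") %in% names(meta)))
      stop("tool metadata needs at least columns 'tool' and 'type'")
    if ("alias" %in% names(meta)) {
      has <- !is.na(meta$alias) & nzchar(meta$alias)
      extra <- stats::setNames(meta$tool[has], meta$alias[has])
    }
    if ("cutoff" %in% names(meta)) {
      has <- !is.na(meta$cutoff)
      cutoffs[meta$tool[has]] <- meta$cutoff[has]
    }
    types <- stats::setNames(meta$type, meta$tool)
  }
  if (first %in% c("method", "tool", "software")) {
    tools <- canonicalToolName(df[[1]], extra)
    variants <- names(df)[-1]
    cells <- t(as.matrix(df[, -1, drop = FALSE]))
    dimnames(cells) <- list(variants, tools)
  } else {
    variants <- df[[1]]
    tools <- canonicalToolName(names(df)[-1], extra)
    cells <- as.matrix(df[, -1, drop = FALSE])
    dimnames(cells) <- list(variants, tools)
  }
  cells[!nzchar(trimws(cells))] <- NA
  low <- tolower(trimws(cells))
  isP <- low %in% c("p", "pathogenic")
  isN <- low %in% c("n", "neutral", "benign")
  num <- suppressWarnings(as.numeric(cells))
  isScore <- !is.na(num) & !isP & !isN
  bad <- !is.na(cells) & !isP & !isN & !isScore
  if (any(bad))
    stop("unparseable cell(s), e.g. '", cells[which(bad)[1]], "'")
  callsM <- matrix(NA_character_, nrow(cells), ncol(cells),
                   dimnames = dimnames(cells))
  callsM[isP] <- "P"; callsM[isN] <- "N"
  scoresM <- matrix(NA_real_, nrow(cells), ncol(cells),
                    dimnames = dimnames(cells))
  scoresM[isScore] <- num[isScore]
  tt <- apply(scoresM, 2, function(x) any(!is.na(x)))
  toolType <- ifelse(tt, "scored", "binary")
  names(toolType) <- colnames(cells)
  if (!is.null(types)) {
    known <- intersect(names(types), names(toolType))
    mismatch <- known[types[known] != toolType[known] &
                        toolType[known] != "binary"]
    if (length(mismatch))
      stop("tool(s) declared binary but carrying scores: ",
           paste(mismatch, collapse = ", "))
    toolType[known] <- types[known]
  }
  mixed <- colnames(cells)[apply(callsM, 2, function(x) any(!is.na(x))) &
                             apply(scoresM, 2, function(x) any(!is.na(x)))]
  if (length(mixed))
    stop("tool(s) mix binary calls and raw scores: ",
         paste(mixed, collapse = ", "))
  list(matrix = PredictionMatrix(callsM, scoresM, toolType),
       cutoffs = cutoffs)
}

#' Read a labelled benchmark (variant,label CSV/TSV)
#'
#' @param path file with columns \code{variant} and \code{label}
#'   (\code{Pathogenic}/\code{Benign}).
#' @return named character vector of labels.
#' @export
readBenchmark <- function(path) {
  df <- .readTable(path)
  if (!all(c("variant", "label") %in% names(df)))
    stop("benchmark file needs columns 'variant' and 'label'")
  lab <- df$label
  if (!all(lab %in% c("Pathogenic", "Benign")))
    stop("labels must be 'Pathogenic' or 'Benign'")
  stats::setNames(lab, df$variant)
}

#' Read a multi-model PDB file as a TrajectoryEnsemble
#'
#' MODEL/ENDMDL blocks become frames; a file without MODEL records is a
#' single-frame ensemble (valid for static analyses only). Atom counts must
#' match across models and insertion codes are rejected.
#'
#' @param path PDB file.
#' @param frameSpacing time per frame (metadata only).
#' @return a [TrajectoryEnsemble-class].
#' @export
readPdbEnsemble <- function(path, frameSpacing = 1) {
  lines <- readLines(path)
  atomLn <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atomLn)) stop("no ATOM/HETATM records in ", path)
  icode <- substr(lines[atomLn], 27, 27)
  if (any(icode != " " & icode != ""))
    stop("insertion codes are not supported; renumber residues in ", path)
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(modelStarts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(atomLn[s:e]), modelStarts, ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop("inconsistent atom count at MODEL ", bad, " (", counts[bad],
           " atoms vs ", counts[1], " in MODEL 1)")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain), resno = at$resno,
    elesy = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                   substr(trimws(at$elety), 1, 1), trimws(at$elesy)))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  TrajectoryEnsemble(atoms = atoms, xyz = unclass(xyz),
                     frameSpacing = frameSpacing)
}

#' Write a TrajectoryEnsemble as a multi-model PDB file
#'
#' @param x a [TrajectoryEnsemble-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePdbEnsemble <- function(x, path) {
  at <- atoms(x)
  bio3d::write.pdb(file = path, xyz = x@xyz, eleno = at$eleno,
                   elety = at$elety, resid = at$resid, chain = at$chain,
                   resno = at$resno, elesy = at$elesy)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Thresholds outside their documented ranges and unknown top-level keys are
#' rejected. See [runFullEvaluation()] for the schema.
#'
#' @param path YAML file.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("consensus", "alerts", "output_dir", "seed", "offset",
             "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  chk <- function(x, lo, hi, name) {
    if (!is.null(x) && (x < lo || x > hi))
      stop("config threshold out of range: ", name, " = ", x)
  }
  cc <- cfg$consensus
  chk(cc$recall_min, 0, 1, "recall_min")
  chk(cc$specificity_min, 0, 1, "specificity_min")
  al <- cfg$alerts
  chk(al$native_min, 0, 1, "native_min")
  chk(al$drop_points, 0, 1, "drop_points")
  chk(al$floor, 0, 1, "floor")
  chk(al$rmsd_min, 0, Inf, "rmsd_min")
  chk(al$rmsf_min, 0, Inf, "rmsf_min")
  cfg
}

#' Run the full two-track evaluation
#'
#' Executes the consensus track (binarise, optionally benchmark and select
#' tools, ConPath scores), then -- where structural evidence is configured --
#' the alert track, and finally the four-level classification. Structural
#' evidence comes either from per-variant coordinate ensembles (computing
#' RMSD/RMSF and hydrogen-bond occupancies) or from a precomputed occupancy
#' table plus structural summaries.
#'
#' Config schema (a list, or a YAML file read by [readRunConfig()]):
#' \describe{
#' \item{consensus}{\code{matrices} (character vector of matrix files),
#'   optional \code{tool_metadata}, optional \code{benchmark} (labelled CSV;
#'   enables tool selection with \code{recall_min}/\code{specificity_min}),
#'   optional \code{panel} (tool names), \code{pathogenic_min},
#'   \code{missing_policy}.}
#' \item{alerts}{either \code{occupancy_table} + \code{structural_summaries}
#'   (precomputed route; file schemas as the bundled data, see
#'   [hrpe65DmsData()]) or \code{ensembles} (list: \code{wt} = PDB path,
#'   \code{variants} = named list of PDB paths, \code{fit_selection},
#'   \code{measure_selection}, \code{rmsf_selection}); thresholds
#'   \code{native_min}, \code{drop_points}, \code{floor}, \code{rmsd_min},
#'   \code{rmsf_min}, \code{rmsf_window}, \code{wt_rmsf_max}.}
#' \item{output_dir}{optional; intermediate and final tables are written
#'   there as CSV/JSON.}
#' \item{offset}{residue-numbering offset for reports (default 0).}
#' }
#'
#' @param config list or path to a YAML file.
#' @return list with \code{conpath} (data.frame), \code{performance}
#'   (data.frame or NULL), \code{panel}, \code{profiles},
#'   \code{classification} (cohort report, or NULL when no alert track is
#'   configured) and \code{log} (character vector of decisions taken).
#' @export
runFullEvaluation <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  cc <- config$consensus
  if (is.null(cc)) stop("stage consensus: no configuration")

  mats <- lapply(cc$matrices, function(p)
    readPredictionMatrix(p, toolMeta = cc$tool_metadata))
  cutoffs <- mats[[1]]$cutoffs
  pms <- lapply(mats, function(m)
    binarizeCalls(m$matrix, cutoffs = cutoffs))
  say("consensus: ", length(pms), " matrix file(s) read and binarised")

  performance <- NULL
  panel <- cc$panel
  if (!is.null(cc$benchmark)) {
    labels <- readBenchmark(cc$benchmark)
    bench <- readPredictionMatrix(cc$benchmark_matrix,
                                  toolMeta = cc$tool_metadata)
    bpm <- binarizeCalls(bench$matrix, cutoffs = cutoffs)
    performance <- benchmarkTools(bpm, labels)
    panel <- selectTools(performance,
                         recallMin = cc$recall_min %||% 0.78,
                         specificityMin = cc$specificity_min %||% 0.67)
    say("consensus: ", length(panel), " tool(s) selected at recall >= ",
        cc$recall_min %||% 0.78, ", specificity >= ",
        cc$specificity_min %||% 0.67)
  }

  cpList <- lapply(pms, function(pm) {
    p <- if (is.null(panel)) toolNames(pm) else panel
    tryCatch(
      conPath(pm, panel = p, pathogenicMin = cc$pathogenic_min,
              missingPolicy = cc$missing_policy %||% "strict"),
      error = function(e) stop("stage conpath: ", conditionMessage(e),
                               call. = FALSE))
  })
  conpath <- do.call(rbind, cpList)
  if (anyDuplicated(conpath$variant))
    stop("stage conpath: duplicate variant across matrices")
  say("conpath: panel size ", conpath$panel_size[1], ", threshold ",
      cc$pathogenic_min %||% (floor(conpath$panel_size[1] / 2) + 1L))

  al <- config$alerts
  classification <- NULL
  profiles <- NULL
  if (!is.null(al)) {
    thr <- list(native_min = al$native_min %||% 0.5,
                drop_points = al$drop_points %||% 0.2,
                floor = al$floor %||% 0.5,
                rmsd_min = al$rmsd_min %||% 1.5,
                rmsf_min = al$rmsf_min %||% 2.0,
                rmsf_window = al$rmsf_window %||% 3L,
                wt_rmsf_max = al$wt_rmsf_max %||% 1.0)
    if (!is.null(al$occupancy_table)) {
      occ <- .readTable(al$occupancy_table)
      ints <- .interactionAlertsFromTable(occ, conpath$variant, thr)
      struct <- .structuralAlertsFromSummaries(
        .readTable(al$structural_summaries), conpath$variant, thr)
    } else if (!is.null(al$ensembles)) {
      res <- .alertsFromEnsembles(al$ensembles, conpath$variant, thr,
                                  offset = config$offset %||% 0L)
      ints <- res$interaction; struct <- res$structural
    } else stop("stage alerts: configure occupancy_table or ensembles")
    say("alerts: floor ", thr$floor, ", drop ", thr$drop_points,
        ", rmsd_min ", thr$rmsd_min, ", rmsf_min ", thr$rmsf_min)
    profiles <- alertProfiles(conpath, structural = struct,
                              interaction = ints,
                              pathogenicMin = cc$pathogenic_min)
    classification <- cohortReport(profiles)
  }

  out <- list(conpath = conpath, performance = performance, panel = panel,
              profiles = profiles, classification = classification,
              log = log)
  if (!is.null(config$output_dir)) .writeEvaluation(out, config$output_dir)
  out
}

# interaction alerts for each variant from a long occupancy table
# (columns variant, chain1, resno1, ..., class, wt_occupancy, mut_occupancy)
.interactionAlertsFromTable <- function(occ, variants, thr) {
  need <- c("variant", "chain1", "resno1", "chain2", "resno2", "class",
            "wt_occupancy", "mut_occupancy")
  if (!all(need %in% names(occ)))
    stop("occupancy table lacks column(s): ",
         paste(setdiff(need, names(occ)), collapse = ", "))
  flags <- logical(0)
  for (v in variants) {
    sub <- occ[occ$variant == v, , drop = FALSE]
    pv <- parseVariant(v)
    wt <- sub; wt$occupancy <- wt$wt_occupancy
    mut <- sub; mut$occupancy <- mut$mut_occupancy
    ia <- interactionAlert(
      nativeInteractions(wt, nativeMin = thr$native_min), mut,
      mutatedResno = pv$pos, dropPoints = thr$drop_points,
      floor = thr$floor)
    flags[v] <- ia$alert
  }
  flags
}

# structural alerts from a per-variant summary table: second-half mean RMSD
# plus the RMSF peak (height, residue run, WT level at the peak)
.structuralAlertsFromSummaries <- function(ss, variants, thr) {
  flags <- logical(0)
  for (v in variants) {
    row <- ss[ss$variant == v, , drop = FALSE]
    if (!nrow(row)) stop("no structural summary for variant ", v)
    runlen <- if (is.na(row$rmsf_peak_first)) 0L else
      row$rmsf_peak_last - row$rmsf_peak_first + 1L
    flags[v] <- row$second_half_mean_rmsd >= thr$rmsd_min ||
      (runlen >= thr$rmsf_window &&
         !is.na(row$rmsf_peak_max) && row$rmsf_peak_max >= thr$rmsf_min &&
         row$wt_rmsf_at_peak < thr$wt_rmsf_max)
  }
  flags
}

# full trajectory route: WT + per-variant ensembles
.alertsFromEnsembles <- function(ens, variants, thr, offset = 0L) {
  wt <- readPdbEnsemble(ens$wt)
  fitSel <- ens$fit_selection
  measSel <- ens$measure_selection %||% fitSel
  rmsfSel <- ens$rmsf_selection %||% "A:*:CA"
  wtMetrics <- structuralMetrics(wt, fit = fitSel, measure = measSel,
                                 rmsfSel = rmsfSel, offset = offset)
  struct <- logical(0); ints <- logical(0)
  for (v in variants) {
    path <- ens$variants[[v]]
    if (is.null(path))
      stop("stage alerts: no ensemble configured for variant ", v)
    mut <- readPdbEnsemble(path)
    mm <- structuralMetrics(mut, fit = fitSel, measure = measSel,
                            rmsfSel = rmsfSel, offset = offset)
    struct[v] <- structuralAlert(mm, wtMetrics, rmsdMin = thr$rmsd_min,
                                 rmsfMin = thr$rmsf_min,
                                 rmsfWindow = thr$rmsf_window,
                                 wtRmsfMax = thr$wt_rmsf_max)$alert
    pv <- parseVariant(v)
    mres <- list(chain = "A", resno = fromHrpe65(pv$pos, offset))
    wtRec <- .scanResidueContacts(wt, mres)
    mutRec <- .scanResidueContacts(mut, mres)
    # report in offset numbering
    for (col in c("resno1", "resno2")) {
      wtRec[[col]] <- toHrpe65(wtRec[[col]], offset)
      mutRec[[col]] <- toHrpe65(mutRec[[col]], offset)
    }
    ia <- interactionAlert(
      nativeInteractions(wtRec, nativeMin = thr$native_min), mutRec,
      mutatedResno = pv$pos, dropPoints = thr$drop_points,
      floor = thr$floor)
    ints[v] <- ia$alert
  }
  list(structural = struct, interaction = ints)
}

# all direct-contact occupancy records of one residue against every residue
# with any heavy atom within `cutoff` of it in frame 1
.scanResidueContacts <- function(x, res, cutoff = 6.0,
                                 criteria = hbondCriteria()) {
  at <- atoms(x)
  co <- frameCoords(x, 1L)
  idx <- .residueAtoms(x, res)
  prot <- !(at$resid %in% c("HOH", "WAT")) & !.isHydrogen(at)
  d2 <- rep(Inf, nrow(at))
  for (i in idx)
    d2 <- pmin(d2, rowSums(sweep(co, 2, co[i, ])^2))
  near <- unique(.resKey(at$chain, at$resno)[prot & d2 <= cutoff^2])
  near <- setdiff(near, .resKey(res$chain, res$resno))
  rows <- lapply(near, function(k) {
    other <- list(chain = sub(":.*", "", k),
                  resno = as.integer(sub(".*:", "", k)))
    hbondOccupancy(x, res, other, criteria)
  })
  do.call(rbind, rows)
}

.writeEvaluation <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(out$conpath, "conpath.csv")
  if (!is.null(out$performance)) wr(out$performance, "tool_performance.csv")
  if (!is.null(out$classification)) {
    wr(out$classification$table, "classification.csv")
    jsonlite::write_json(
      list(classCounts = as.list(out$classification$classCounts),
           highConfidence = out$classification$highConfidence,
           log = out$log),
      file.path(dir, "evidence.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  writeLines(out$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
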