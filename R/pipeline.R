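#' @include seqio.R motif_scan.R bgc_context.R corepep.R mge.R ssn.R
NULL

# proteome of a genome: CDS translations named by locus tag
.annotation_proteome <- function(annotation) {
  feat <- features(annotation)
  is_cds <- as.character(feat$type) == "CDS"
  tr <- feat$translation[is_cds]
  setNames(as.character(tr), feat$locus_tag[is_cds])
}

#' Run the nBGC discovery pipeline on a cohort directory
#'
#' End-to-end analysis of a directory of annotated genomes (one
#' \code{<id>.gff3} + \code{<id>.fna} pair per genome, with optional
#' \code{metadata.tsv}, \code{is_elements.tsv} and \code{mge_intervals.tsv}
#' as written by \code{\link{generateCohort}} or by external predictors):
#' core-peptide detection by the sequence pattern, neighborhood extraction
#' and machinery classification, leader cleavage, deduplication,
#' composite-transposon detection, MGE co-localization, cargo census,
#' sequence similarity network and genus-sharing table.
#'
#' @param cohortDir Directory of genomes.
#' @param outDir Optional output directory; when given, every result table
#'   is written as TSV.
#' @param refs Machinery references for \code{\link{classifyMachinery}}.
#' @param windowKb,maxCdsEachSide Neighborhood parameters.
#' @param ssnThreshold SSN edge identity threshold (percent).
#' @return List with \code{hits}, \code{contexts} (per-hit machinery calls,
#'   one row each), \code{core_peptides}, \code{unique_precursors},
#'   \code{bgc_intervals}, \code{composite_transposons},
#'   \code{colocalization}, \code{cargo_census}, \code{ssn},
#'   \code{sharing_table}, \code{metadata}.
#' @export
runNisinPipeline <- function(cohortDir, outDir = NULL,
                             refs = machineryReferences(),
                             windowKb = 30, maxCdsEachSide = 25,
                             ssnThreshold = 70) {
  gffs <- sort(list.files(cohortDir, pattern = "\\.gff3$",
                          full.names = TRUE))
  if (length(gffs) == 0) .stopf("no .gff3 files in %s", cohortDir)
  md_path <- file.path(cohortDir, "metadata.tsv")
  metadata <- if (file.exists(md_path)) readFlatTable(md_path) else NULL
  is_path <- file.path(cohortDir, "is_elements.tsv")
  is_df <- if (file.exists(is_path)) readISElements(is_path) else NULL
  mge_path <- file.path(cohortDir, "mge_intervals.tsv")
  mge_df <- if (file.exists(mge_path)) readMGEIntervals(mge_path) else
    data.frame(contig = character(), start = integer(), end = integer(),
               type = character(), evidence = character(),
               stringsAsFactors = FALSE)

  annotations <- list()
  hit_rows <- list()
  ctx_rows <- list()
  pep_rows <- list()
  bgc_rows <- list()
  comp_rows <- list()
  for (gff in gffs) {
    gid <- sub("\\.gff3$", "", basename(gff))
    fna <- file.path(cohortDir, paste0(gid, ".fna"))
    md <- character()
    if (!is.null(metadata) && gid %in% metadata$genome_id) {
      row <- metadata[metadata$genome_id == gid, , drop = FALSE]
      md <- setNames(as.character(row[1, .metadata_keys()]),
                     .metadata_keys())
    }
    ga <- readGenomeAnnotations(gff, fna, md)
    annotations[[gid]] <- ga
    proteome <- .annotation_proteome(ga)
    hits <- suppressMessages(scanProteome(proteome))
    if (nrow(hits)) hits <- cbind(genome_id = gid, hits)
    hit_rows[[gid]] <- hits
    for (locus in unique(hits$protein_id)) {
      ctx <- extractContext(ga, locus, windowKb = windowKb,
                            maxCdsEachSide = maxCdsEachSide, genomeId = gid)
      ctx <- classifyMachinery(ctx, refs = refs)
      fl <- machineryFlags(ctx)
      ctg <- as.character(GenomicRanges::seqnames(ctx@focal))
      cls_feats <- ctx@windowFeatures[!is.na(ctx@windowFeatures$machinery_class)]
      bgc_start <- min(GenomicRanges::start(ctx@focal),
                       if (length(cls_feats))
                         min(GenomicRanges::start(cls_feats)) else Inf)
      bgc_end <- max(GenomicRanges::end(ctx@focal),
                     if (length(cls_feats))
                       max(GenomicRanges::end(cls_feats)) else -Inf)
      ctx_rows[[length(ctx_rows) + 1]] <- data.frame(
        genome_id = gid, contig = ctg, locus_tag = locus,
        t(as.data.frame(fl)), orphan = isOrphan(ctx),
        complete_BCI = completeBCI(ctx), stringsAsFactors = FALSE)
      bgc_rows[[length(bgc_rows) + 1]] <- data.frame(
        bgc_id = paste0(gid, ":", locus), genome_id = gid, contig = ctg,
        start = as.integer(bgc_start), end = as.integer(bgc_end),
        stringsAsFactors = FALSE)
      prec <- proteome[[locus]]
      cp <- if (nchar(prec) >= 30) {
        cleaveLeader(prec)
      } else {
        NULL
      }
      genus <- if (length(md)) md[["genus"]] else "missing"
      pep_rows[[length(pep_rows) + 1]] <- data.frame(
        genome_id = gid, locus_tag = locus, precursor = prec,
        leader = if (is.null(cp)) "" else leaderSeq(cp),
        core = if (is.null(cp)) prec else coreSeq(cp),
        cut_rule = if (is.null(cp)) "unassigned" else cutRule(cp),
        genus = genus, stringsAsFactors = FALSE)
    }
    if (!is.null(is_df)) {
      bgc_here <- do.call(rbind, c(bgc_rows[vapply(
        bgc_rows, function(r) r$genome_id == gid, logical(1))],
        list(make.row.names = FALSE)))
      if (!is.null(bgc_here) && nrow(bgc_here)) {
        comp <- findCompositeTransposons(ga, is_df, bgc_here)
        if (nrow(comp)) comp_rows[[gid]] <- cbind(genome_id = gid, comp)
      }
    }
  }

  hits <- do.call(rbind, c(hit_rows, list(make.row.names = FALSE)))
  contexts <- do.call(rbind, c(ctx_rows, list(make.row.names = FALSE)))
  peps <- do.call(rbind, c(pep_rows, list(make.row.names = FALSE)))
  bgc <- do.call(rbind, c(bgc_rows, list(make.row.names = FALSE)))
  composite <- if (length(comp_rows)) {
    do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(genome_id = character(), contig = character(),
               start = integer(), end = integer(), type = character(),
               evidence = character(), is_family = character(),
               bgc_start = integer(), bgc_end = integer(),
               stringsAsFactors = FALSE)
  }

  all_mge <- rbind(
    mge_df[, c("contig", "start", "end", "type", "evidence")],
    if (nrow(composite)) {
      composite[, c("contig", "start", "end", "type", "evidence")]
    } else {
      NULL
    })
  coloc <- if (!is.null(bgc) && nrow(bgc)) {
    colocalize(bgc[, c("bgc_id", "contig", "start", "end")], all_mge)
  } else {
    colocalize(data.frame(contig = character(), start = integer(),
                          end = integer()), all_mge)
  }
  census <- cargoCensus(annotations, coloc, all_mge)

  uniq <- if (!is.null(peps) && nrow(peps)) {
    dedup <- suppressMessages(dedupExact(
      setNames(peps$precursor, paste0(peps$genome_id, ":", peps$locus_tag))))
    dedup
  } else {
    dedupExact(character())
  }
  ssn <- NULL
  sharing <- genusSharingTable(NULL)
  if (!is.null(peps) && nrow(peps)) {
    core_dedup <- suppressMessages(dedupExact(
      setNames(peps$core, paste0(peps$genome_id, ":", peps$locus_tag))))
    ssn <- buildSSN(setNames(core_dedup$sequence, core_dedup$representative),
                    edgeThresholdIdentity = ssnThreshold)
    core_ids <- core_dedup$representative[match(toupper(peps$core),
                                                core_dedup$sequence)]
    sharing <- genusSharingTable(data.frame(core_id = core_ids,
                                            genus = peps$genus,
                                            stringsAsFactors = FALSE))
  }

  out <- list(hits = hits, contexts = contexts, core_peptides = peps,
              unique_precursors = uniq, bgc_intervals = bgc,
              composite_transposons = composite, colocalization = coloc,
              cargo_census = census, ssn = ssn, sharing_table = sharing,
              metadata = metadata)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name, keys) {
      if (is.null(df) || !nrow(df)) {
        writeFlatTable(list(), file.path(outDir, name), keys = keys)
      } else {
        writeFlatTable(df, file.path(outDir, name))
      }
    }
    wr(hits, "hits.tsv",
       c("genome_id", "protein_id", "start", "end", "pattern_name",
         "matched_text"))
    wr(contexts, "contexts.tsv",
       c("genome_id", "contig", "locus_tag", machineryClasses(), "orphan",
         "complete_BCI"))
    wr(peps, "corepeptides.tsv",
       c("genome_id", "locus_tag", "precursor", "leader", "core",
         "cut_rule", "genus"))
    wr(uniq, "unique_precursors.tsv",
       c("representative", "sequence", "members", "n_members"))
    wr(bgc, "bgc_intervals.tsv",
       c("bgc_id", "genome_id", "contig", "start", "end"))
    wr(composite, "composite_transposons.tsv",
       c("genome_id", "contig", "start", "end", "type", "evidence",
         "is_family", "bgc_start", "bgc_end"))
    wr(coloc, "colocalization.tsv",
       c("bgc_id", "contig", "bgc_start", "bgc_end", "mge_type",
         "mge_start", "mge_end", "evidence"))
    wr(census, "cargo_census.tsv",
       c("mge_type", "product", "n_mge_with", "n_mge_total", "pct"))
    if (!is.null(ssn)) {
      wr(ssn$nodes, "ssn_nodes.tsv", c("id", "sequence", "component"))
      wr(ssn$edges, "ssn_edges.tsv", c("from", "to", "identity_pct"))
    }
    wr(sharing, "sharing_table.tsv", c("core_id", "genus", "count"))
  }
  out
}

.prf <- function(n_tp, n_fp, n_fn) {
  precision <- if (n_tp + n_fp == 0) 1 else n_tp / (n_tp + n_fp)
  recall <- if (n_tp + n_fn == 0) 1 else n_tp / (n_tp + n_fn)
  c(precision = precision, recall = recall)
}

#' Score pipeline results against planted truth
#'
#' Compares a \code{\link{runNisinPipeline}} result with the
#' \code{truth.json} of the cohort it ran on: precision/recall of core-gene
#' detection, machinery presence-flag accuracy, orphan-call accuracy,
#' composite-transposon precision/recall (exact span match), and MGE
#' co-localization accuracy (the planted interval type must be recovered
#' for labelled genomes and \code{"none"}-only for unlabelled ones).
#'
#' @param cohortDir Cohort directory containing \code{truth.json}.
#' @param results Result list of \code{\link{runNisinPipeline}}.
#' @return Named list of metrics.
#' @export
evaluateAgainstTruth <- function(cohortDir, results) {
  truth <- jsonlite::read_json(file.path(cohortDir, "truth.json"),
                               simplifyVector = FALSE)
  true_cores <- character()
  for (tr in truth) {
    if (!is.null(tr$cluster)) {
      true_cores <- c(true_cores,
                      paste0(tr$genome_id, ":", tr$cluster$locus_tag))
    }
  }
  pred_cores <- if (!is.null(results$hits) && nrow(results$hits)) {
    unique(paste0(results$hits$genome_id, ":", results$hits$protein_id))
  } else {
    character()
  }
  core_pr <- .prf(length(intersect(pred_cores, true_cores)),
                  length(setdiff(pred_cores, true_cores)),
                  length(setdiff(true_cores, pred_cores)))

  flag_ok <- 0L
  flag_total <- 0L
  orphan_ok <- 0L
  orphan_total <- 0L
  ctx <- results$contexts
  for (tr in truth) {
    if (is.null(tr$cluster)) next
    row <- ctx[ctx$genome_id == tr$genome_id &
               ctx$locus_tag == tr$cluster$locus_tag, , drop = FALSE]
    planted <- names(tr$cluster$machinery)
    for (cls in machineryClasses()) {
      flag_total <- flag_total + 1L
      pred <- nrow(row) == 1 && isTRUE(row[[cls]][1])
      if (pred == (cls %in% planted)) flag_ok <- flag_ok + 1L
    }
    orphan_total <- orphan_total + 1L
    pred_orphan <- nrow(row) == 1 && isTRUE(row$orphan[1])
    if (pred_orphan == isTRUE(tr$cluster$orphan)) {
      orphan_ok <- orphan_ok + 1L
    }
  }

  true_tn <- list()
  for (tr in truth) {
    if (isTRUE(tr$composite$is_composite)) {
      true_tn[[length(true_tn) + 1]] <- paste(
        tr$contig, tr$composite$span_start, tr$composite$span_end)
    }
  }
  true_tn <- unlist(true_tn)
  comp <- results$composite_transposons
  pred_tn <- if (!is.null(comp) && nrow(comp)) {
    unique(paste(comp$contig, comp$start, comp$end))
  } else {
    character()
  }
  tn_pr <- .prf(length(intersect(pred_tn, true_tn)),
                length(setdiff(pred_tn, true_tn)),
                length(setdiff(true_tn, pred_tn)))

  coloc_ok <- 0L
  coloc_total <- 0L
  coloc <- results$colocalization
  for (tr in truth) {
    if (is.null(tr$cluster)) next
    coloc_total <- coloc_total + 1L
    bid <- paste0(tr$genome_id, ":", tr$cluster$locus_tag)
    types <- if (!is.null(coloc) && nrow(coloc)) {
      coloc$mge_type[coloc$bgc_id == bid]
    } else {
      character()
    }
    expected <- character()
    if (tr$mge$type != "none") expected <- tr$mge$type
    if (isTRUE(tr$composite$is_composite)) {
      expected <- c(expected, "composite_transposon")
    }
    got <- setdiff(types, "none")
    if (setequal(got, expected)) coloc_ok <- coloc_ok + 1L
  }

  list(
    core_detection_precision = unname(core_pr["precision"]),
    core_detection_recall = unname(core_pr["recall"]),
    machinery_flag_accuracy = if (flag_total) flag_ok / flag_total else NA,
    orphan_accuracy = if (orphan_total) orphan_ok / orphan_total else NA,
    composite_tn_precision = unname(tn_pr["precision"]),
    composite_tn_recall = unname(tn_pr["recall"]),
    mge_colocalization_accuracy =
      if (coloc_total) coloc_ok / coloc_total else NA,
    n_genomes = length(truth),
    n_true_cores = length(true_cores),
    n_true_composites = length(true_tn)
  )
}
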