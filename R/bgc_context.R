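#' @include AllClasses.R align.R fixtures.R
NULL

#' Extract the gene neighborhood around a core-peptide gene
#'
#' Collects the CDS whose spans intersect a window of \code{windowKb}
#' kilobases on each side of the focal gene (same contig), keeping at most
#' \code{maxCdsEachSide} nearest neighbors per side. The window clips at the
#' contig boundaries without error. Machinery flags are left unset;
#' run \code{\link{classifyMachinery}} next.
#'
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param focal The focal feature: a one-element \code{GRanges} from
#'   \code{features(annotation)}, or a locus tag.
#' @param windowKb Window half-width in kb (default 30, the span used for
#'   cross-cluster synteny comparisons).
#' @param maxCdsEachSide Cap on neighbors per side (default 25).
#' @param genomeId Genome identifier to record.
#' @return A \linkS4class{BGCContext} with unclassified machinery flags.
#' @export
extractContext <- function(annotation, focal, windowKb = 30,
                           maxCdsEachSide = 25, genomeId = "genome") {
  feat <- features(annotation)
  if (is.character(focal)) {
    idx <- which(feat$locus_tag == focal)
    if (length(idx) != 1) {
      .stopf("focal locus tag '%s' matches %d feature(s)", focal, length(idx))
    }
    focal <- feat[idx]
  }
  hit <- which(feat$locus_tag == focal$locus_tag &
               as.character(GenomicRanges::seqnames(feat)) ==
                 as.character(GenomicRanges::seqnames(focal)) &
               GenomicRanges::start(feat) == GenomicRanges::start(focal))
  if (length(hit) == 0) .stopf("focal feature not found in the annotation")
  w <- as.integer(round(windowKb * 1000))
  lo <- max(1L, GenomicRanges::start(focal) - w)
  hi <- GenomicRanges::end(focal) + w
  same_contig <- as.character(GenomicRanges::seqnames(feat)) ==
    as.character(GenomicRanges::seqnames(focal))
  is_cds <- if (!is.null(feat$type)) as.character(feat$type) == "CDS" else
    rep(TRUE, length(feat))
  cand <- feat[same_contig & is_cds &
               GenomicRanges::end(feat) >= lo &
               GenomicRanges::start(feat) <= hi]
  # drop the focal gene itself from the neighborhood
  cand <- cand[!(cand$locus_tag == focal$locus_tag &
                 GenomicRanges::start(cand) == GenomicRanges::start(focal))]
  up <- cand[GenomicRanges::end(cand) < GenomicRanges::start(focal)]
  down <- cand[GenomicRanges::start(cand) > GenomicRanges::end(focal)]
  over <- cand[GenomicRanges::end(cand) >= GenomicRanges::start(focal) &
               GenomicRanges::start(cand) <= GenomicRanges::end(focal)]
  if (length(up) > maxCdsEachSide) {
    up <- utils::tail(up, maxCdsEachSide) # nearest = highest starts
  }
  if (length(down) > maxCdsEachSide) {
    down <- utils::head(down, maxCdsEachSide)
  }
  win <- c(up, over, down)
  win <- win[order(GenomicRanges::start(win), GenomicRanges::end(win))]
  methods::new("BGCContext", genomeId = genomeId, focal = focal,
               windowFeatures = win,
               machineryFlags = setNames(
                 rep(NA, length(machineryClasses())), machineryClasses()),
               orphan = NA, completeBCI = NA)
}

# best machinery class for one protein under reference-sequence mode;
# returns NA when nothing passes the identity/coverage floors
.assign_machinery_class <- function(translation, refs, minIdentity,
                                    minCoverage) {
  best_class <- NA_character_
  best_id <- -Inf
  for (cls in names(refs)) {
    ref <- as.character(refs[[cls]])
    al <- globalAlign(translation, ref)
    cols_a <- strsplit(al$aligned_a, "")[[1]]
    cols_b <- strsplit(al$aligned_b, "")[[1]]
    aligned_pairs <- sum(cols_a != "-" & cols_b != "-")
    coverage <- aligned_pairs / nchar(ref)
    if (al$identity_pct >= minIdentity && coverage >= minCoverage &&
        al$identity_pct > best_id) {
      best_id <- al$identity_pct
      best_class <- cls
    }
  }
  best_class
}

#' Classify the machinery genes in a neighborhood
#'
#' Assigns each neighborhood protein to the machinery class whose bundled
#' reference it matches at or above the homology floors (global identity >=
#' \code{minIdentity} percent with aligned coverage >= \code{minCoverage} of
#' the reference length), then sets the presence flags, the orphan call (no
#' LanB) and the LanB/LanC/LanI completeness call.
#'
#' @param context A \linkS4class{BGCContext} from \code{\link{extractContext}}.
#' @param refs Machinery references (\code{AAStringSet} named by class);
#'   default the bundled synthetic set.
#' @param minIdentity Identity floor in percent (default 30).
#' @param minCoverage Reference-coverage floor as a fraction (default 0.7).
#' @return The context with flags, \code{orphan} and \code{completeBCI} set;
#'   per-gene assignments are kept in
#'   \code{windowFeatures(context)$machinery_class}.
#' @export
classifyMachinery <- function(context, refs = machineryReferences(),
                              minIdentity = 30, minCoverage = 0.7) {
  win <- context@windowFeatures
  tr <- win$translation
  if (length(win) && (is.null(tr) || anyNA(tr) || any(!nzchar(tr)))) {
    missing <- win$locus_tag[is.null(tr) | is.na(tr) | !nzchar(tr)]
    .stopf("window feature(s) lack translations: %s",
           paste(missing, collapse = ", "))
  }
  classes <- if (length(win)) {
    vapply(tr, .assign_machinery_class, character(1), refs = refs,
           minIdentity = minIdentity, minCoverage = minCoverage,
           USE.NAMES = FALSE)
  } else {
    character(0)
  }
  if (length(win)) win$machinery_class <- classes
  flags <- setNames(machineryClasses() %in% classes, machineryClasses())
  context@windowFeatures <- win
  context@machineryFlags <- flags
  context@orphan <- unname(!flags["lanB"])
  context@completeBCI <- unname(flags["lanB"] && flags["lanC"] &&
                                  flags["lanI"])
  methods::validObject(context)
  context
}

#' Shared-protein links between two gene neighborhoods
#'
#' All-vs-all global alignment of the proteins of two contexts, reporting
#' the pairs whose identity reaches the floor (default 20 percent, the
#' conventional display floor for cross-cluster synteny comparisons), sorted
#' by identity descending.
#'
#' @param contextA,contextB \linkS4class{BGCContext} objects with
#'   translations.
#' @param minIdentityPct Identity floor in percent.
#' @return Data frame with \code{locus_a}, \code{locus_b},
#'   \code{identity_pct}.
#' @export
operonSyntenyLinks <- function(contextA, contextB, minIdentityPct = 20) {
  fa <- c(contextA@focal, contextA@windowFeatures)
  fb <- c(contextB@focal, contextB@windowFeatures)
  rows <- list()
  for (i in seq_along(fa)) {
    for (j in seq_along(fb)) {
      ta <- fa$translation[i]
      tb <- fb$translation[j]
      if (is.na(ta) || is.na(tb) || !nzchar(ta) || !nzchar(tb)) next
      pid <- globalAlign(ta, tb)$identity_pct
      if (pid >= minIdentityPct) {
        rows[[length(rows) + 1]] <- data.frame(
          locus_a = fa$locus_tag[i], locus_b = fb$locus_tag[j],
          identity_pct = pid, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_a = character(), locus_b = character(),
                      identity_pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$identity_pct, out$locus_a, out$locus_b), , drop = FALSE]
}
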