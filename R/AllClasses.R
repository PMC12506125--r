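#' @include nisinscan-package.R
NULL

setOldClass("data.frame")

#' Genome annotation container
#'
#' Holds one genome: its contig sequences, its gene features (a
#' \link[GenomicRanges]{GRanges} with \code{locus_tag}, \code{product} and
#' \code{translation} metadata columns, 1-based inclusive coordinates), and an
#' assembly metadata record. Metadata always carries the keys \code{source},
#' \code{host}, \code{country}, \code{collection_date} and \code{genus};
#' unknown values hold the explicit marker \code{"missing"}, so missingness
#' is a first-class category rather than an \code{NA}.
#'
#' @slot contigs A \link[Biostrings]{DNAStringSet}, one entry per contig.
#' @slot features A \code{GRanges} of gene features on those contigs.
#' @slot genomeMetadata Named character vector of assembly metadata.
#' @export
setClass("GenomeAnnotation",
  representation(
    contigs = "DNAStringSet",
    features = "GRanges",
    genomeMetadata = "character"
  )
)

.metadata_keys <- function() {
  c("source", "host", "country", "collection_date", "genus")
}

setValidity("GenomeAnnotation", function(object) {
  msgs <- character()
  feat <- object@features
  ctg <- names(object@contigs)
  if (length(feat)) {
    chr <- as.character(GenomicRanges::seqnames(feat))
    if (!all(chr %in% ctg)) {
      msgs <- c(msgs, sprintf("features reference unknown contigs: %s",
                              paste(unique(setdiff(chr, ctg)), collapse = ", ")))
    } else {
      lens <- Biostrings::width(object@contigs)[match(chr, ctg)]
      bad <- GenomicRanges::start(feat) < 1 | GenomicRanges::end(feat) > lens
      if (any(bad)) {
        msgs <- c(msgs, sprintf("%d feature(s) extend beyond contig bounds",
                                sum(bad)))
      }
    }
    if (!all(as.character(GenomicRanges::strand(feat)) %in% c("+", "-"))) {
      msgs <- c(msgs, "all features must be stranded (+ or -)")
    }
  }
  miss <- setdiff(.metadata_keys(), names(object@genomeMetadata))
  if (length(miss)) {
    msgs <- c(msgs, sprintf("metadata keys absent: %s",
                            paste(miss, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param contigs A \code{DNAStringSet} (or named character vector) of contig
#'   sequences.
#' @param features A \code{GRanges} of gene features; metadata columns
#'   \code{type}, \code{locus_tag}, \code{product} and \code{translation} are
#'   used by downstream stages.
#' @param genomeMetadata Named character vector; keys from
#'   \code{source, host, country, collection_date, genus}. Missing keys are
#'   filled with the marker \code{"missing"}.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(contigs, features = GenomicRanges::GRanges(),
                             genomeMetadata = character()) {
  if (!methods::is(contigs, "DNAStringSet")) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  md <- setNames(rep("missing", length(.metadata_keys())), .metadata_keys())
  if (length(genomeMetadata)) {
    keep <- intersect(names(genomeMetadata), .metadata_keys())
    md[keep] <- as.character(genomeMetadata[keep])
  }
  md[is.na(md) | md == ""] <- "missing"
  if (length(features)) {
    o <- order(as.character(GenomicRanges::seqnames(features)),
               GenomicRanges::start(features), GenomicRanges::end(features))
    features <- features[o]
  }
  methods::new("GenomeAnnotation", contigs = contigs, features = features,
               genomeMetadata = md)
}

#' @describeIn GenomeAnnotation Contig sequences.
#' @param x A \code{GenomeAnnotation}.
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname GenomeAnnotation
#' @export
setMethod("contigs", "GenomeAnnotation", function(x) x@contigs)

#' @describeIn GenomeAnnotation Gene features, sorted by start then end.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname GenomeAnnotation
#' @export
setMethod("features", "GenomeAnnotation", function(x) x@features)

#' @describeIn GenomeAnnotation Assembly metadata record.
#' @export
setGeneric("genomeMetadata", function(x) standardGeneric("genomeMetadata"))

#' @rdname GenomeAnnotation
#' @export
setMethod("genomeMetadata", "GenomeAnnotation", function(x) x@genomeMetadata)

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@contigs), "contig(s) and",
      length(object@features), "feature(s)\n")
  cat("  total length:", sum(Biostrings::width(object@contigs)), "bp\n")
  md <- object@genomeMetadata
  cat("  metadata:", paste(sprintf("%s=%s", names(md), md), collapse = ", "),
      "\n")
})

#' Position-specific log-odds profile model
#'
#' An ungapped position-specific scoring model over the 20 amino-acid
#' alphabet, built from an alignment of seed core peptides and scored in
#' bits against a background residue distribution. An empirical decoy
#' threshold (set by \code{\link{calibrateThreshold}}) plays the role an
#' E-value cutoff plays for a database profile search.
#'
#' @slot logOdds Numeric matrix, model columns x 20 residues, in bits.
#' @slot background Named numeric vector of 20 background frequencies.
#' @slot pseudocountWeight Positive pseudocount weight (alpha).
#' @slot scoreThreshold Bit-score threshold; \code{NA} until calibrated.
#' @slot provenance Ids of the training sequences.
#' @export
setClass("ProfileModel",
  representation(
    logOdds = "matrix",
    background = "numeric",
    pseudocountWeight = "numeric",
    scoreThreshold = "numeric",
    provenance = "character"
  )
)

setValidity("ProfileModel", function(object) {
  msgs <- character()
  lo <- object@logOdds
  bg <- object@background
  if (ncol(lo) != 20 || !identical(colnames(lo), aminoAcids())) {
    msgs <- c(msgs, "logOdds must have the 20 amino acids as columns")
  }
  if (nrow(lo) < 10) {
    msgs <- c(msgs, "model must have at least 10 columns")
  }
  if (length(bg) != 20 || abs(sum(bg) - 1) > 1e-9 || any(bg <= 0)) {
    msgs <- c(msgs, "background must be 20 positive frequencies summing to 1")
  }
  if (length(msgs) == 0) {
    # every column's probabilities must reconstruct to a distribution
    probs <- sweep(2^lo, 2, bg, "*")
    if (any(abs(rowSums(probs) - 1) > 1e-9)) {
      msgs <- c(msgs, "column probabilities do not sum to 1")
    }
  }
  if (object@pseudocountWeight <= 0) {
    msgs <- c(msgs, "pseudocountWeight must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProfileModel Number of model columns.
#' @param x A \code{ProfileModel}.
#' @export
setGeneric("modelLength", function(x) standardGeneric("modelLength"))

#' @rdname ProfileModel
#' @export
setMethod("modelLength", "ProfileModel", function(x) nrow(x@logOdds))

#' @describeIn ProfileModel Calibrated bit-score threshold (NA before
#'   calibration).
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))

#' @rdname ProfileModel
#' @export
setMethod("scoreThreshold", "ProfileModel", function(x) x@scoreThreshold)

setMethod("show", "ProfileModel", function(object) {
  cat("ProfileModel:", nrow(object@logOdds), "columns,",
      length(object@provenance), "training sequence(s)\n")
  if (is.na(object@scoreThreshold)) {
    cat("  uncalibrated (run calibrateThreshold before searching)\n")
  } else {
    cat(sprintf("  score threshold: %.3f bits\n", object@scoreThreshold))
  }
})

#' Classified gene neighborhood around a core-peptide gene
#'
#' The focal precursor gene plus the coding genes within a configured window,
#' with per-class machinery flags once \code{\link{classifyMachinery}} has
#' run. \code{orphan} is \code{TRUE} exactly when no LanB dehydratase gene is
#' present in the neighborhood; \code{completeBCI} requires LanB, LanC and
#' LanI jointly.
#'
#' @slot genomeId Genome identifier.
#' @slot focal One-element \code{GRanges}: the core-peptide gene.
#' @slot windowFeatures \code{GRanges} of neighborhood CDS, ordered by start.
#' @slot machineryFlags Named logical vector over the machinery classes
#'   (\code{NA} until classified).
#' @slot orphan Logical; no LanB in the neighborhood.
#' @slot completeBCI Logical; LanB, LanC and LanI all present.
#' @export
setClass("BGCContext",
  representation(
    genomeId = "character",
    focal = "GRanges",
    windowFeatures = "GRanges",
    machineryFlags = "logical",
    orphan = "logical",
    completeBCI = "logical"
  )
)

machineryClasses <- function() {
  c("lanB", "lanC", "lanI", "lanT", "lanF", "lanE", "lanG",
    "lanP", "lanR", "lanK")
}

setValidity("BGCContext", function(object) {
  msgs <- character()
  if (length(object@focal) != 1) {
    msgs <- c(msgs, "focal must contain exactly one feature")
  }
  if (!identical(sort(names(object@machineryFlags)), sort(machineryClasses()))) {
    msgs <- c(msgs, "machineryFlags must cover every machinery class")
  }
  fl <- object@machineryFlags
  if (!anyNA(fl)) {
    if (!identical(object@orphan, unname(!fl["lanB"]))) {
      msgs <- c(msgs, "orphan must equal absence of lanB")
    }
    if (!identical(object@completeBCI,
                   unname(fl["lanB"] && fl["lanC"] && fl["lanI"]))) {
      msgs <- c(msgs, "completeBCI must equal joint presence of lanB/lanC/lanI")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BGCContext Machinery presence/absence flags.
#' @param x A \code{BGCContext}.
#' @export
setGeneric("machineryFlags", function(x) standardGeneric("machineryFlags"))

#' @rdname BGCContext
#' @export
setMethod("machineryFlags", "BGCContext", function(x) x@machineryFlags)

#' @describeIn BGCContext Orphan-core call (no LanB in context).
#' @export
setGeneric("isOrphan", function(x) standardGeneric("isOrphan"))

#' @rdname BGCContext
#' @export
setMethod("isOrphan", "BGCContext", function(x) x@orphan)

#' @describeIn BGCContext Joint LanB/LanC/LanI completeness call.
#' @export
setGeneric("completeBCI", function(x) standardGeneric("completeBCI"))

#' @rdname BGCContext
#' @export
setMethod("completeBCI", "BGCContext", function(x) x@completeBCI)

setMethod("show", "BGCContext", function(object) {
  cat("BGCContext in genome", object@genomeId, "\n")
  cat("  focal:", object@focal$locus_tag, "at",
      GenomicRanges::start(object@focal), "-",
      GenomicRanges::end(object@focal), "\n")
  cat("  neighborhood:", length(object@windowFeatures), "CDS\n")
  fl <- object@machineryFlags
  if (anyNA(fl)) {
    cat("  machinery: unclassified\n")
  } else {
    cat("  machinery present:",
        paste(names(fl)[fl], collapse = ", "), "\n")
    cat("  orphan:", object@orphan, " completeBCI:", object@completeBCI, "\n")
  }
})

#' Leader/core split of a precursor peptide
#'
#' A precursor peptide split into leader and core at a cleavage site, with
#' the rule that produced the cut. Rules, in precedence order, are the
#' canonical \code{GASPR} and \code{PQ} sites and the \code{PK} site, then
#' transfer from the nearest characterized reference; \code{unassigned}
#' leaves the whole precursor as core, flagged for manual review.
#'
#' @slot precursor Full precursor sequence.
#' @slot leader Leader segment (may be empty when unassigned).
#' @slot core Core segment.
#' @slot cutRule One of GASPR, PQ, PK, nearest_reference, unassigned.
#' @slot cutAfter 1-based index of the last leader residue (0 if none).
#' @slot referenceUsed Reference id when the cut was transferred, else NA.
#' @export
setClass("CorePeptide",
  representation(
    precursor = "character",
    leader = "character",
    core = "character",
    cutRule = "character",
    cutAfter = "integer",
    referenceUsed = "character"
  )
)

setValidity("CorePeptide", function(object) {
  msgs <- character()
  if (!identical(paste0(object@leader, object@core), object@precursor)) {
    msgs <- c(msgs, "leader + core must reconstruct the precursor")
  }
  if (object@cutAfter != nchar(object@leader)) {
    msgs <- c(msgs, "cutAfter must equal the leader length")
  }
  if (!object@cutRule %in%
      c("GASPR", "PQ", "PK", "nearest_reference", "unassigned")) {
    msgs <- c(msgs, "unknown cutRule")
  }
  if (object@cutRule == "unassigned" && nchar(object@leader) != 0) {
    msgs <- c(msgs, "unassigned cuts must leave the leader empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CorePeptide Core (mature peptide) segment.
#' @param x A \code{CorePeptide}.
#' @export
setGeneric("coreSeq", function(x) standardGeneric("coreSeq"))

#' @rdname CorePeptide
#' @export
setMethod("coreSeq", "CorePeptide", function(x) x@core)

#' @describeIn CorePeptide Leader segment.
#' @export
setGeneric("leaderSeq", function(x) standardGeneric("leaderSeq"))

#' @rdname CorePeptide
#' @export
setMethod("leaderSeq", "CorePeptide", function(x) x@leader)

#' @describeIn CorePeptide Rule that produced the cut.
#' @export
setGeneric("cutRule", function(x) standardGeneric("cutRule"))

#' @rdname CorePeptide
#' @export
setMethod("cutRule", "CorePeptide", function(x) x@cutRule)

setMethod("show", "CorePeptide", function(object) {
  cat("CorePeptide (rule:", object@cutRule, ")\n")
  cat("  leader:", if (nchar(object@leader)) object@leader else "<none>", "\n")
  cat("  core:  ", object@core, "\n")
  if (!is.na(object@referenceUsed)) {
    cat("  reference:", object@referenceUsed, "\n")
  }
})
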