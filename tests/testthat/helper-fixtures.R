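# Shared helpers: in-code fixture builders and an independent alignment
# oracle used to cross-check the C++ aligner.

aa20 <- aminoAcids()

random_protein <- function(n) {
  paste0("M", paste(sample(aa20, n - 1, replace = TRUE), collapse = ""))
}

# Build a GenomeAnnotation from a compact gene table.
# genes: data.frame(start, end, strand, type, locus_tag, product, translation)
make_annotation <- function(genes, contig_len = NULL, contig = "c1",
                            metadata = character()) {
  if (is.null(contig_len)) contig_len <- max(genes$end) + 1000L
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = if (!is.null(genes$strand)) genes$strand else "+")
  gr$type <- if (!is.null(genes$type)) genes$type else "CDS"
  gr$locus_tag <- genes$locus_tag
  gr$product <- if (!is.null(genes$product)) genes$product else
    "hypothetical protein"
  gr$translation <- if (!is.null(genes$translation)) genes$translation else
    NA_character_
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  GenomeAnnotation(
    contigs = Biostrings::DNAStringSet(setNames(
      paste(rep("A", contig_len), collapse = ""), contig)),
    features = gr, genomeMetadata = metadata)
}

# Independent affine-gap global alignment oracle: top-down recursion over
# (position in a, position in b, previous move), maximizing over every gap
# placement. Shares no code with the package's aligner.
oracle_align_score <- function(a, b, submat, gap_open, gap_extend) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra)
  m <- length(rb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[ra[i], rb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) { # gap in b
      cost <- if (prev == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) { # gap in a
      cost <- if (prev == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "start")
}

# Fully exhaustive variant (no memo): enumerates every alignment path.
# Only viable for very short sequences; used to validate the oracle itself.
exhaustive_align_score <- function(a, b, submat, gap_open, gap_extend) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra)
  m <- length(rb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[ra[i], rb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (prev == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (prev == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "start")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# score an emitted alignment from its gapped strings (affine gaps)
score_from_alignment <- function(aligned_a, aligned_b, submat, gap_open,
                                 gap_extend) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  s <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      s <- s - (if (in_gap_a) gap_extend else gap_open + gap_extend)
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      s <- s - (if (in_gap_b) gap_extend else gap_open + gap_extend)
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      s <- s + submat[ca[k], cb[k]]
      in_gap_a <- FALSE
      in_gap_b <- FALSE
    }
  }
  s
}
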