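#' @include AllClasses.R align.R
NULL

.mge_types <- function() c("ICE", "plasmid", "prophage", "composite_transposon")

#' Read an insertion-sequence element table
#'
#' TSV with columns \code{contig}, \code{start}, \code{end}, \code{family}
#' and optionally \code{sequence}. IS elements shorter than 200 bp are
#' rejected.
#'
#' @param path Input TSV path.
#' @return Data frame of IS elements.
#' @export
readISElements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "family")
  if (!all(need %in% names(df))) {
    .stopf("IS table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$end - df$start + 1 < 200)) {
    .stopf("IS element(s) shorter than 200 bp")
  }
  df
}

#' Read an MGE interval table
#'
#' TSV with columns \code{contig}, \code{start}, \code{end}, \code{type},
#' \code{evidence}; \code{type} must come from the closed set ICE, plasmid,
#' prophage, composite_transposon. These intervals are produced by external
#' predictors; this package only consumes them (and adds its own
#' composite-transposon calls).
#'
#' @param path Input TSV path.
#' @return Data frame of MGE intervals.
#' @export
readMGEIntervals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "type", "evidence")
  if (!all(need %in% names(df))) {
    .stopf("MGE table must have columns: %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$type), .mge_types())
  if (length(bad)) {
    .stopf("unknown MGE type(s): %s", paste(bad, collapse = ", "))
  }
  if (any(df$start > df$end)) .stopf("MGE interval(s) with start > end")
  df
}

# two IS elements count as "the same IS" when their family labels agree, or,
# when sequences are available, at >= 95% identity over >= 90% mutual coverage
.same_is <- function(is1, is2, minIdentity = 95, minCoverage = 0.9) {
  if (!is.null(is1$family) && !is.null(is2$family) &&
      !is.na(is1$family) && !is.na(is2$family)) {
    if (identical(is1$family, is2$family)) return(TRUE)
  }
  s1 <- is1$sequence
  s2 <- is2$sequence
  if (is.null(s1) || is.null(s2) || is.na(s1) || is.na(s2)) return(FALSE)
  if (nchar(s1) / nchar(s2) < minCoverage ||
      nchar(s2) / nchar(s1) < minCoverage) {
    return(FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  al <- nw_align_cpp(toupper(s1), toupper(s2), mat, 5, 2)
  cols_a <- strsplit(al$aligned_a, "")[[1]]
  cols_b <- strsplit(al$aligned_b, "")[[1]]
  pairs <- sum(cols_a != "-" & cols_b != "-")
  al$identity_pct >= minIdentity &&
    pairs / nchar(s1) >= minCoverage && pairs / nchar(s2) >= minCoverage
}

#' Detect composite transposons around nisin BGCs
#'
#' Implements the composite-transposon rule: two copies of the same IS
#' element on one contig flanking an nBGC, an outer span (first IS start to
#' second IS end) of 10-130 kb inclusive, curated to require at least one
#' CDS whose product mentions a transposase within the outer span.
#' Overlapping candidates deduplicate to the shortest qualifying span per
#' BGC.
#'
#' @param annotation A \linkS4class{GenomeAnnotation} (for the transposase
#'   CDS check).
#' @param isElements Data frame of IS elements (\code{contig}, \code{start},
#'   \code{end}, \code{family}, optional \code{sequence}).
#' @param bgcIntervals Data frame with \code{contig}, \code{start},
#'   \code{end} of candidate nBGCs.
#' @param minSpan,maxSpan Outer-span bounds in bp (default 10,000 and
#'   130,000, both inclusive).
#' @return Data frame of composite-transposon intervals (\code{contig},
#'   \code{start}, \code{end}, \code{type}, \code{evidence},
#'   \code{is_family}, \code{bgc_start}, \code{bgc_end}).
#' @export
findCompositeTransposons <- function(annotation, isElements, bgcIntervals,
                                     minSpan = 10000, maxSpan = 130000) {
  feat <- features(annotation)
  is_cds <- if (!is.null(feat$type)) as.character(feat$type) == "CDS" else
    rep(TRUE, length(feat))
  tpase <- feat[is_cds & !is.na(feat$product) &
                grepl("transposase", feat$product, ignore.case = TRUE)]
  out <- list()
  for (ctg in unique(isElements$contig)) {
    is_ctg <- isElements[isElements$contig == ctg, , drop = FALSE]
    is_ctg <- is_ctg[order(is_ctg$start), , drop = FALSE]
    n <- nrow(is_ctg)
    if (n < 2) next
    bgc_ctg <- bgcIntervals[bgcIntervals$contig == ctg, , drop = FALSE]
    if (nrow(bgc_ctg) == 0) next
    tp_ctg <- tpase[as.character(GenomicRanges::seqnames(tpase)) == ctg]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!.same_is(as.list(is_ctg[i, ]), as.list(is_ctg[j, ]))) next
        span_start <- is_ctg$start[i]
        span_end <- is_ctg$end[j]
        span <- span_end - span_start + 1
        if (span < minSpan || span > maxSpan) next
        has_tp <- length(tp_ctg) > 0 &&
          any(GenomicRanges::start(tp_ctg) >= span_start &
              GenomicRanges::end(tp_ctg) <= span_end)
        if (!has_tp) next
        for (b in seq_len(nrow(bgc_ctg))) {
          # the nBGC must lie strictly between the two IS copies
          if (bgc_ctg$start[b] > is_ctg$end[i] &&
              bgc_ctg$end[b] < is_ctg$start[j]) {
            out[[length(out) + 1]] <- data.frame(
              contig = ctg, start = span_start, end = span_end,
              type = "composite_transposon", evidence = "in_package_rule",
              is_family = is_ctg$family[i],
              bgc_start = bgc_ctg$start[b], bgc_end = bgc_ctg$end[b],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), type = character(),
                      evidence = character(), is_family = character(),
                      bgc_start = integer(), bgc_end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # shortest qualifying span per BGC
  key <- paste(res$contig, res$bgc_start, res$bgc_end)
  keep <- unlist(lapply(split(seq_len(nrow(res)), key), function(idx) {
    spans <- res$end[idx] - res$start[idx]
    idx[which.min(spans)]
  }))
  res <- res[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign BGCs to the MGE intervals that contain them
#'
#' A BGC is assigned to an MGE interval only when fully contained in it
#' (containment, not overlap). A BGC contained in several intervals is
#' reported once per containing interval; a BGC contained in none gets one
#' row with type \code{"none"}.
#'
#' @param bgcIntervals Data frame with \code{contig}, \code{start},
#'   \code{end} (one row per BGC); an optional \code{bgc_id} column is
#'   carried through.
#' @param mgeIntervals Data frame with \code{contig}, \code{start},
#'   \code{end}, \code{type}, \code{evidence}.
#' @return Data frame with one row per (BGC, containing MGE) pair plus
#'   \code{"none"} rows; columns \code{bgc_id}, \code{contig},
#'   \code{bgc_start}, \code{bgc_end}, \code{mge_type}, \code{mge_start},
#'   \code{mge_end}, \code{evidence}.
#' @export
colocalize <- function(bgcIntervals, mgeIntervals) {
  if (is.null(bgcIntervals$bgc_id)) {
    bgcIntervals$bgc_id <- sprintf("bgc%03d", seq_len(nrow(bgcIntervals)))
  }
  rows <- list()
  for (b in seq_len(nrow(bgcIntervals))) {
    hit <- which(mgeIntervals$contig == bgcIntervals$contig[b] &
                 mgeIntervals$start <= bgcIntervals$start[b] &
                 mgeIntervals$end >= bgcIntervals$end[b])
    if (length(hit) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        bgc_id = bgcIntervals$bgc_id[b], contig = bgcIntervals$contig[b],
        bgc_start = bgcIntervals$start[b], bgc_end = bgcIntervals$end[b],
        mge_type = "none", mge_start = NA_integer_, mge_end = NA_integer_,
        evidence = NA_character_, stringsAsFactors = FALSE)
    } else {
      for (h in hit) {
        rows[[length(rows) + 1]] <- data.frame(
          bgc_id = bgcIntervals$bgc_id[b], contig = bgcIntervals$contig[b],
          bgc_start = bgcIntervals$start[b], bgc_end = bgcIntervals$end[b],
          mge_type = mgeIntervals$type[h], mge_start = mgeIntervals$start[h],
          mge_end = mgeIntervals$end[h],
          evidence = mgeIntervals$evidence[h], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(bgc_id = character(), contig = character(),
                      bgc_start = integer(), bgc_end = integer(),
                      mge_type = character(), mge_start = integer(),
                      mge_end = integer(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cargo gene census of nBGC-bearing MGEs
#'
#' Restricts the MGE intervals to those containing at least one BGC (per the
#' co-localization table) and counts, per MGE type and product label, how
#' many intervals contain at least one CDS with that product. Percentages
#' are per type: 100 x containing / total nBGC-bearing intervals of the
#' type.
#'
#' @param annotations A named list of \linkS4class{GenomeAnnotation}
#'   objects, names = contig prefixes is not required; CDS are matched to
#'   intervals by contig name.
#' @param colocalization Output of \code{\link{colocalize}}.
#' @param mgeIntervals The MGE interval table used for co-localization.
#' @param labels Optional character vector restricting the census to given
#'   product labels; default: all labeled products observed inside the
#'   intervals.
#' @return Data frame with \code{mge_type}, \code{product},
#'   \code{n_mge_with}, \code{n_mge_total}, \code{pct}.
#' @export
cargoCensus <- function(annotations, colocalization, mgeIntervals,
                        labels = NULL) {
  if (methods::is(annotations, "GenomeAnnotation")) {
    annotations <- list(annotations)
  }
  occupied <- unique(colocalization[colocalization$mge_type != "none",
                                    c("contig", "mge_start", "mge_end",
                                      "mge_type")])
  if (nrow(occupied) == 0) {
    return(data.frame(mge_type = character(), product = character(),
                      n_mge_with = integer(), n_mge_total = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  all_feat <- suppressWarnings(
    do.call(c, unname(lapply(annotations, features))))
  is_cds <- if (!is.null(all_feat$type)) {
    as.character(all_feat$type) == "CDS"
  } else {
    rep(TRUE, length(all_feat))
  }
  cds <- all_feat[is_cds & !is.na(all_feat$product)]
  # products inside each occupied interval
  per_interval <- lapply(seq_len(nrow(occupied)), function(k) {
    inside <- as.character(GenomicRanges::seqnames(cds)) ==
      occupied$contig[k] &
      GenomicRanges::start(cds) >= occupied$mge_start[k] &
      GenomicRanges::end(cds) <= occupied$mge_end[k]
    unique(cds$product[inside])
  })
  if (is.null(labels)) {
    labels <- sort(setdiff(unique(unlist(per_interval)),
                           c("hypothetical protein")))
  }
  rows <- list()
  for (tp in unique(occupied$mge_type)) {
    sel <- which(occupied$mge_type == tp)
    total <- length(sel)
    for (lb in labels) {
      with_lb <- sum(vapply(per_interval[sel], function(p) lb %in% p,
                            logical(1)))
      if (with_lb == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        mge_type = tp, product = lb, n_mge_with = with_lb,
        n_mge_total = total, pct = roundHalfUp(100 * with_lb / total, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mge_type = character(), product = character(),
                      n_mge_with = integer(), n_mge_total = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$mge_type, -out$n_mge_with, out$product), , drop = FALSE]
}
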