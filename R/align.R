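#' @include utils.R
NULL

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length k costs \code{gapOpen + k * gapExtend}). Traceback is
#' deterministic: ties prefer the diagonal move, then a gap in \code{b},
#' then a gap in \code{a}. Percent identity uses the full alignment length as
#' denominator, gap columns included, so it is symmetric in its arguments
#' and never flattered by a short sequence.
#'
#' @param a,b Protein sequences (non-empty).
#' @param substitutionMatrix Scoring matrix with residue dimnames; defaults
#'   to BLOSUM62.
#' @param gapOpen,gapExtend Affine gap parameters (default 10 and 0.5).
#' @return List with \code{aligned_a}, \code{aligned_b} (gapped strings),
#'   \code{score} and \code{identity_pct}.
#' @examples
#' globalAlign("ITSIS", "ITSVS")$identity_pct  # 80
#' @export
globalAlign <- function(a, b, substitutionMatrix = NULL,
                        gapOpen = 10, gapExtend = 0.5) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) .stopf("sequences must be non-empty")
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  nw_align_cpp(a, b, substitutionMatrix, gapOpen, gapExtend)
}

#' Pairwise percent-identity matrix
#'
#' All-vs-all global alignment identities under the default alignment
#' parameters. The matrix is symmetric with 100 on the diagonal.
#'
#' @param seqs Named character vector or \code{AAStringSet} (at least 2).
#' @param ... Passed to \code{\link{globalAlign}}.
#' @return Symmetric numeric matrix of percent identities, dimnames = ids.
#' @export
identityMatrix <- function(seqs, ...) {
  seqs <- .as_chr_seqs(seqs)
  n <- length(seqs)
  if (n < 2) .stopf("identityMatrix needs at least 2 sequences")
  ids <- names(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- globalAlign(seqs[[i]], seqs[[j]], ...)$identity_pct
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  m
}

# Center-star multiple alignment: the center is the sequence with maximal
# summed pairwise identity; all others are aligned to it pairwise and merged
# under "once a gap, always a gap". Deterministic (first index wins ties).
# Returns equal-length gapped strings, named as the input.
centerStarAlign <- function(seqs, ...) {
  seqs <- .as_chr_seqs(seqs)
  n <- length(seqs)
  if (n == 1) return(seqs)
  idm <- identityMatrix(seqs, ...)
  center <- which.max(rowSums(idm))
  master <- strsplit(seqs[[center]], "")[[1]] # center residues, no gaps yet
  # aligned[[k]]: character vector over current master columns
  aligned <- vector("list", n)
  aligned[[center]] <- master
  master_cols <- master # center residue (or "-") per master column
  for (k in seq_len(n)) {
    if (k == center) next
    al <- globalAlign(seqs[[center]], seqs[[k]], ...)
    ac <- strsplit(al$aligned_a, "")[[1]] # center with gaps
    ak <- strsplit(al$aligned_b, "")[[1]]
    # merge: walk master columns and pairwise columns in center coordinates
    i <- 1L # master column pointer
    j <- 1L # pairwise column pointer
    nm <- length(master_cols)
    np <- length(ac)
    out_cols <- list()
    while (i <= nm || j <= np) {
      m_gap <- i <= nm && master_cols[i] == "-"
      p_gap <- j <= np && ac[j] == "-"
      if (m_gap && p_gap) {
        # insertion columns on both sides: merge into one column
        out_cols[[length(out_cols) + 1]] <- list(m = i, p = j)
        i <- i + 1L
        j <- j + 1L
      } else if (m_gap) {
        # gap column contributed by an earlier sequence: carry it, k gets '-'
        out_cols[[length(out_cols) + 1]] <- list(m = i, p = NA)
        i <- i + 1L
      } else if (p_gap) {
        # new insertion relative to the center: new gap column for the rest
        out_cols[[length(out_cols) + 1]] <- list(m = NA, p = j)
        j <- j + 1L
      } else if (i <= nm && j <= np) {
        out_cols[[length(out_cols) + 1]] <- list(m = i, p = j)
        i <- i + 1L
        j <- j + 1L
      } else if (i <= nm) {
        out_cols[[length(out_cols) + 1]] <- list(m = i, p = NA)
        i <- i + 1L
      } else {
        out_cols[[length(out_cols) + 1]] <- list(m = NA, p = j)
        j <- j + 1L
      }
    }
    ncol_new <- length(out_cols)
    new_master_cols <- character(ncol_new)
    for (c_idx in seq_len(ncol_new)) {
      mc <- out_cols[[c_idx]]$m
      pc <- out_cols[[c_idx]]$p
      new_master_cols[c_idx] <- if (!is.na(mc)) master_cols[mc] else "-"
    }
    # re-map all previously aligned sequences onto the new columns
    for (t in seq_len(n)) {
      if (is.null(aligned[[t]])) next
      old <- aligned[[t]]
      aligned[[t]] <- vapply(out_cols, function(col) {
        if (!is.na(col$m)) old[col$m] else "-"
      }, character(1))
    }
    aligned[[k]] <- vapply(out_cols, function(col) {
      if (!is.na(col$p)) ak[col$p] else "-"
    }, character(1))
    master_cols <- new_master_cols
  }
  setNames(vapply(aligned, paste, character(1), collapse = ""), names(seqs))
}
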