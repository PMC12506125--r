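#' @include AllClasses.R align.R
NULL

#' Build a position-specific log-odds profile
#'
#' Builds a \linkS4class{ProfileModel} from an alignment of seed sequences.
#' Columns with a gap fraction of 0.5 or more are dropped (majority
#' occupancy). Per retained column the residue probabilities are
#' \eqn{p_a = (c_a + \alpha b_a) / (N + \alpha)} over the non-gap counts
#' \eqn{c_a} (\eqn{N} = non-gap sequences in that column), and the scores are
#' \eqn{s_a = \log_2(p_a / b_a)} bits.
#'
#' @param alignedSeqs Character vector of equal-length gapped sequences
#'   (gap = \code{-}), at least 2.
#' @param pseudocountWeight Positive pseudocount weight alpha (default 1).
#' @param background Named 20-vector of background frequencies summing to 1;
#'   default uniform. In pipeline use, pass the residue frequencies of the
#'   searched proteome (see \code{\link{proteomeBackground}}).
#' @return An uncalibrated \linkS4class{ProfileModel}.
#' @export
buildProfile <- function(alignedSeqs, pseudocountWeight = 1,
                         background = NULL) {
  seq_ids <- names(.as_chr_seqs(alignedSeqs))
  alignedSeqs <- toupper(unname(.as_chr_seqs(alignedSeqs)))
  if (length(alignedSeqs) < 2) .stopf("need at least 2 aligned sequences")
  if (length(unique(nchar(alignedSeqs))) != 1) {
    .stopf("aligned sequences must share one length")
  }
  aa <- aminoAcids()
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), aa)
  }
  background <- background[aa]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    .stopf("background must cover the 20 amino acids and sum to 1")
  }
  chars <- do.call(rbind, strsplit(alignedSeqs, ""))
  L <- ncol(chars)
  gap_frac <- colMeans(chars == "-")
  keep <- gap_frac < 0.5
  if (sum(!keep) > 0) {
    message(sprintf("buildProfile: dropped %d column(s) with >= 50%% gaps",
                    sum(!keep)))
  }
  if (!any(keep)) .stopf("all columns dropped (gap fraction >= 0.5)")
  cols <- which(keep)
  lo <- matrix(0, length(cols), 20, dimnames = list(NULL, aa))
  for (r in seq_along(cols)) {
    col <- chars[, cols[r]]
    col <- col[col != "-"]
    col[col == "X"] <- NA # unknowns contribute no counts
    cnt <- table(factor(col[!is.na(col)], levels = aa))
    n <- sum(cnt)
    p <- (as.numeric(cnt) + pseudocountWeight * background) /
      (n + pseudocountWeight)
    lo[r, ] <- unname(log2(p / background))
  }
  methods::new("ProfileModel", logOdds = lo,
               background = setNames(as.numeric(background), aa),
               pseudocountWeight = pseudocountWeight,
               scoreThreshold = NA_real_,
               provenance = if (is.null(seq_ids)) character() else seq_ids)
}

#' Build a profile from unaligned seed peptides
#'
#' Convenience wrapper: aligns the seeds with the deterministic center-star
#' aligner (center = maximal summed pairwise identity; gaps merged under
#' "once a gap, always a gap") and calls \code{\link{buildProfile}}.
#'
#' @param seqs Named character vector or \code{AAStringSet} of seed peptides.
#' @inheritParams buildProfile
#' @return An uncalibrated \linkS4class{ProfileModel}; provenance records the
#'   seed ids.
#' @export
buildProfileFromSeeds <- function(seqs, pseudocountWeight = 1,
                                  background = NULL) {
  seqs <- .as_chr_seqs(seqs)
  aligned <- centerStarAlign(seqs)
  model <- buildProfile(unname(aligned), pseudocountWeight, background)
  model@provenance <- names(seqs)
  model
}

#' Amino-acid background frequencies of a proteome
#'
#' @param proteins An \code{AAStringSet} or character vector.
#' @return Named 20-vector of residue frequencies (X ignored), smoothed so no
#'   frequency is zero.
#' @export
proteomeBackground <- function(proteins) {
  seqs <- paste(.as_chr_seqs(proteins), collapse = "")
  cnt <- table(factor(strsplit(seqs, "")[[1]], levels = aminoAcids()))
  cnt <- as.numeric(cnt) + 1 # avoid zero frequencies
  setNames(cnt / sum(cnt), aminoAcids())
}

#' Score one window against a profile
#'
#' Sum of the column log-odds for the window's residues; \code{X} scores 0
#' at every column (neutral residue).
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param window Sequence of length \code{modelLength(model)}.
#' @return Score in bits.
#' @export
scoreWindow <- function(model, window) {
  window <- toupper(as.character(window))
  L <- modelLength(model)
  if (nchar(window) != L) {
    .stopf("window length %d does not match model length %d",
           nchar(window), L)
  }
  res <- strsplit(window, "")[[1]]
  idx <- match(res, aminoAcids())
  s <- vapply(seq_len(L), function(i) {
    if (is.na(idx[i])) 0 else model@logOdds[i, idx[i]]
  }, numeric(1))
  sum(s)
}

# all window scores for one protein; returns numeric(0) when too short
.window_scores <- function(model, residues) {
  L <- modelLength(model)
  res <- strsplit(residues, "")[[1]]
  n <- length(res)
  if (n < L) return(numeric(0))
  idx <- match(res, aminoAcids()) # NA for X -> scores 0
  nw <- n - L + 1L
  acc <- numeric(nw)
  for (j in seq_len(L)) {
    pos <- idx[j:(j + nw - 1L)]
    sc <- ifelse(is.na(pos), 0, model@logOdds[j, ][pos])
    acc <- acc + sc
  }
  acc
}

#' Calibrate the profile score threshold on decoys
#'
#' Sets the empirical decoy threshold that stands in for a database-search
#' E-value cutoff. In \code{max_decoy} mode the threshold is the strict
#' maximum per-decoy window score plus a small epsilon (1e-6 bits), so a
#' subsequent search of the calibration decoys returns nothing by
#' construction. In \code{quantile} mode the threshold is the \eqn{(1-q)}
#' quantile of the per-decoy maximum window scores.
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param decoyProteins Non-empty \code{AAStringSet} or character vector.
#' @param fdrMode \code{"max_decoy"} or \code{"quantile"}.
#' @param q Quantile parameter in (0, 1], used in quantile mode.
#' @return The model with \code{scoreThreshold} set.
#' @export
calibrateThreshold <- function(model, decoyProteins,
                               fdrMode = c("max_decoy", "quantile"),
                               q = 0.05) {
  fdrMode <- match.arg(fdrMode)
  seqs <- .as_chr_seqs(decoyProteins)
  if (length(seqs) == 0) .stopf("decoy set must be non-empty")
  maxima <- vapply(seqs, function(s) {
    sc <- .window_scores(model, toupper(s))
    if (length(sc)) max(sc) else -Inf
  }, numeric(1))
  maxima <- maxima[is.finite(maxima)]
  if (length(maxima) == 0) {
    .stopf("no decoy is long enough to hold one model window")
  }
  thr <- if (fdrMode == "max_decoy") {
    max(maxima) + 1e-6
  } else {
    if (q <= 0 || q > 1) .stopf("q must be in (0, 1]")
    unname(stats::quantile(maxima, 1 - q))
  }
  model@scoreThreshold <- thr
  model
}

#' Search a proteome with a calibrated profile
#'
#' Slides the profile over every protein and emits maximal-scoring
#' non-overlapping windows with score at or above the calibrated threshold
#' (equal-scoring overlapping windows resolve to the leftmost). Results are
#' sorted by protein (input order) then start.
#'
#' @param model A calibrated \linkS4class{ProfileModel}.
#' @param proteins An \code{AAStringSet} or named character vector.
#' @return Data frame with \code{protein_id}, \code{start}, \code{end},
#'   \code{score}.
#' @export
searchProteome <- function(model, proteins) {
  if (is.na(model@scoreThreshold)) {
    .stopf("model is uncalibrated; run calibrateThreshold first")
  }
  seqs <- .as_chr_seqs(proteins)
  L <- modelLength(model)
  rows <- list()
  for (i in seq_along(seqs)) {
    sc <- .window_scores(model, toupper(seqs[[i]]))
    cand <- which(sc >= model@scoreThreshold)
    if (length(cand) == 0) next
    # greedy by score (ties leftmost), rejecting overlaps
    ord <- cand[order(-sc[cand], cand)]
    taken <- integer(0)
    for (s0 in ord) {
      if (!any(abs(taken - s0) < L)) taken <- c(taken, s0)
    }
    taken <- sort(taken)
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = names(seqs)[i], start = taken, end = taken + L - 1L,
      score = sc[taken], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Serialize a profile model to JSON
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeProfileModel <- function(model, path) {
  obj <- list(
    log_odds = unname(model@logOdds),
    residues = aminoAcids(),
    background = as.list(model@background),
    pseudocount_weight = model@pseudocountWeight,
    score_threshold = if (is.na(model@scoreThreshold)) NULL else
      model@scoreThreshold,
    provenance = model@provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile model serialized by \code{writeProfileModel}
#'
#' @param path Input path.
#' @return A \linkS4class{ProfileModel}.
#' @export
readProfileModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- as.matrix(obj$log_odds)
  dimnames(lo) <- list(NULL, aminoAcids())
  thr <- if (is.null(obj$score_threshold)) NA_real_ else obj$score_threshold
  methods::new("ProfileModel", logOdds = lo,
               background = unlist(obj$background)[aminoAcids()],
               pseudocountWeight = obj$pseudocount_weight,
               scoreThreshold = thr,
               provenance = as.character(obj$provenance))
}
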