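#' @include corepep.R
NULL

#' Bundled characterized nisin-family peptides
#'
#' Reference precursor/leader/core sequences with literature cleavage rules,
#' used to seed the profile model and as cut-transfer references. The set
#' mixes three canonical, experimentally characterized family members
#' (nisin A, nisin Z, subtilin) with synthetic nisin-like variants that obey
#' the core pattern; the \code{synthetic} column distinguishes them, and the
#' file name of the underlying fixture marks the set as partly synthetic.
#'
#' @return Data frame with columns \code{name}, \code{precursor},
#'   \code{leader}, \code{core}, \code{cut_rule}, \code{cut_after},
#'   \code{fully_modified_n}, \code{synthetic}.
#' @export
characterizedPeptides <- function() {
  if (is.null(.pkg_cache$characterized)) {
    path <- system.file("extdata", "characterized_peptides_partly_synthetic.tsv",
                        package = "nisinscan", mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$cut_after <- nchar(df$leader)
    .pkg_cache$characterized <- df
  }
  .pkg_cache$characterized
}

#' Bundled machinery reference proteins (synthetic)
#'
#' One synthetic reference protein per nisin machinery class
#' (lanB, lanC, lanI, lanT, lanF, lanE, lanG, lanP, lanR, lanK), used for
#' reference-sequence machinery classification and as the source proteins
#' the synthetic-genome generator reverse-translates. They are synthetic
#' stand-ins with realistic lengths, not database sequences. NisT-, NisFEG-
#' and NisP-like classes are the least specific in real genomes (their
#' domains recur across many protein families); treat those flags with
#' caution on real data.
#'
#' @return An \code{AAStringSet} named by machinery class.
#' @export
machineryReferences <- function() {
  if (is.null(.pkg_cache$machinery)) {
    path <- system.file("extdata", "machinery_refs_synthetic.faa",
                        package = "nisinscan", mustWork = TRUE)
    refs <- readProteinFasta(path)
    missing <- setdiff(machineryClasses(), names(refs))
    if (length(missing)) {
      .stopf("machinery reference set lacks class(es): %s",
             paste(missing, collapse = ", "))
    }
    .pkg_cache$machinery <- refs
  }
  .pkg_cache$machinery
}

#' Bundled decoy source proteins (synthetic)
#'
#' A pool of synthetic proteins unrelated to the nisin machinery. The
#' synthetic-genome generator shuffles these to produce decoy CDS, which
#' stresses profile search and machinery classification with
#' realistic-composition negatives.
#'
#' @return An \code{AAStringSet}.
#' @export
decoyProteinPool <- function() {
  if (is.null(.pkg_cache$decoys)) {
    path <- system.file("extdata", "decoy_proteins_synthetic.faa",
                        package = "nisinscan", mustWork = TRUE)
    .pkg_cache$decoys <- readProteinFasta(path)
  }
  .pkg_cache$decoys
}
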