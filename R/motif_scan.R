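#' @include seqio.R
NULL

#' The nisin-like core-peptide sequence pattern
#'
#' Regular expression describing the spacing of the conserved Ser/Thr and
#' Cys residues that form the lanthionine ring scaffold of nisin-family core
#' peptides. Matches are 22 to 34 residues long by construction.
#'
#' @return The pattern as a single string (PCRE syntax).
#' @export
nisinCorePattern <- function() {
  "..S.S.CT..C.[TS].{1,6}C.{1,4}[TS].{1,2}[TS]C.{1,3}C"
}

.lanp_motifs <- function() {
  c(lanP_D = "HGTHVAG", lanP_H = "[IV]D[ST]G", lanP_S = "G[TN]S.A")
}

#' Find nisin-like core matches in one protein
#'
#' Scans a protein for the core pattern, returning all non-overlapping
#' left-to-right matches (standard leftmost, greedy regex semantics). Spans
#' are 1-based inclusive residue indices.
#'
#' @param residues Protein sequence (character scalar, or an element of an
#'   \code{AAStringSet}).
#' @param proteinId Id to report in the output.
#' @return Data frame with columns \code{protein_id}, \code{start},
#'   \code{end}, \code{pattern_name}, \code{matched_text}; zero rows when
#'   nothing matches.
#' @examples
#' matchCorePattern("ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK", "nisinA")
#' @export
matchCorePattern <- function(residues, proteinId = "protein") {
  residues <- toupper(as.character(residues))
  .check_residues(residues, sprintf("protein '%s'", proteinId))
  m <- gregexpr(nisinCorePattern(), residues, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), pattern_name = character(),
                      matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    protein_id = proteinId,
    start = starts,
    end = starts + lens - 1L,
    pattern_name = "nisin_core",
    matched_text = substring(residues, starts, starts + lens - 1L),
    stringsAsFactors = FALSE
  )
}

#' Scan a proteome for nisin-like core peptides
#'
#' Applies \code{\link{matchCorePattern}} to every protein, preserving input
#' order, and logs the total hit count.
#'
#' @param proteins An \code{AAStringSet} or named character vector.
#' @return Data frame as in \code{\link{matchCorePattern}}, rows concatenated
#'   across proteins.
#' @export
scanProteome <- function(proteins) {
  seqs <- .as_chr_seqs(proteins)
  hits <- lapply(seq_along(seqs), function(i) {
    matchCorePattern(seqs[[i]], names(seqs)[i])
  })
  out <- if (length(hits)) {
    do.call(rbind, c(hits, list(make.row.names = FALSE)))
  } else {
    matchCorePattern("A", "x")[0, ]
  }
  message(sprintf("scanProteome: %d hit(s) in %d protein(s)",
                  nrow(out), length(seqs)))
  out
}

#' Find candidate LanP-type serine proteases
#'
#' A protein is a LanP candidate only when it contains at least one match to
#' each of the three subtilisin-like protease motifs: the D-motif
#' \code{HGTHVAG}, the H-motif \code{[IV]D[ST]G} and the S-motif
#' \code{G[TN]S.A}. Requiring the three jointly is the stringent reading;
#' the motifs cover the catalytic triad of this peptidase class.
#'
#' @param proteins An \code{AAStringSet} or named character vector.
#' @return Character vector of protein ids, in input order.
#' @export
findLanPCandidates <- function(proteins) {
  seqs <- .as_chr_seqs(proteins)
  motifs <- .lanp_motifs()
  keep <- vapply(seqs, function(s) {
    all(vapply(motifs, function(p) grepl(p, s, perl = TRUE), logical(1)))
  }, logical(1))
  names(seqs)[keep]
}

#' Classify the lipid II binding motif of a core peptide
#'
#' Looks for the first ring A/B 5-mer of the form \code{[CG]T[PA]GC} and
#' classifies it as the canonical \code{CTPGC}, the \code{CTAGC} variant, or
#' the rombocin-like \code{GTAGC} variant. When no such 5-mer exists, the
#' residues aligned to scaffold positions 7-11 of the nisin A core are
#' inspected: a Cys-x-x-x-Cys arrangement there is reported as \code{other};
#' otherwise the call is \code{absent}. The alignment anchor prevents false
#' 5-mer calls elsewhere in the core.
#'
#' @param core Core-peptide sequence.
#' @return List with elements \code{core}, \code{motif} (the 5-mer or
#'   \code{NA}), and \code{category}.
#' @export
classifyLipid2Motif <- function(core) {
  core <- toupper(as.character(core))
  if (!nzchar(core)) .stopf("core must be non-empty")
  m <- regexpr("[CG]T[PA]GC", core, perl = TRUE)
  if (m[1] != -1) {
    motif <- substring(core, m, m + 4L)
    category <- switch(motif,
      CTPGC = "canonical_CTPGC",
      CTAGC = "variant_CTAGC",
      GTAGC = "variant_GTAGC",
      "other")
    return(list(core = core, motif = motif, category = category))
  }
  # anchor by scaffold alignment: ring A/B closing pattern C...C at 7-11
  if (nchar(core) >= 20 && nchar(core) <= 45) {
    sa <- alignToScaffold(core)
    cols <- .scaffold_column_residues(sa)
    five <- cols[7:11]
    if (!anyNA(five) && five[1] == "C" && five[5] == "C") {
      return(list(core = core, motif = paste(five, collapse = ""),
                  category = "other"))
    }
  }
  list(core = core, motif = NA_character_, category = "absent")
}
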