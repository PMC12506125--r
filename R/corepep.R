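#' @include motif_scan.R align.R
NULL

#' The canonical nisin A core peptide
#'
#' The 34-residue mature nisin A sequence, used as the scaffold for ring
#' feasibility, hinge extraction and position-composition summaries.
#' Scaffold ring-closing cysteines sit at positions 7, 11, 19, 26 and 28;
#' the hinge occupies positions 20-22.
#'
#' @return Character scalar.
#' @export
nisinACore <- function() "ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK"

# ring name -> c(opening S/T column, closing Cys column) on the scaffold
.scaffold_rings <- function() {
  list(A = c(3L, 7L), B = c(8L, 11L), C = c(13L, 19L),
       D = c(23L, 26L), E = c(25L, 28L))
}

# average residue masses (Da) and the mass of one water; average (not
# monoisotopic) masses are the default because the family's MALDI ladders
# are reported on the average-mass scale
.residue_avg_masses <- function() {
  c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
}

.residue_mono_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
}

.water_mass <- function(monoisotopic = FALSE) {
  if (monoisotopic) 18.01056 else 18.0153
}

#' Split a precursor peptide into leader and core
#'
#' Applies the canonical cleavage rules in precedence order GASPR > PQ > PK.
#' For each motif the rightmost occurrence is taken whose downstream segment
#' is 20-45 residues long and matches the nisin core pattern; the cut falls
#' immediately after the motif's last residue. When no motif qualifies, the
#' precursor is globally aligned to every reference precursor with a known
#' cut and the best reference's cut column is transferred; if the best
#' identity is below 30 percent the peptide is returned \code{unassigned}
#' (whole precursor as core, flagged for manual review).
#'
#' @param precursor Precursor sequence, at least 30 residues.
#' @param references Data frame of characterized precursors with known cuts
#'   (columns \code{name}, \code{precursor}, \code{cut_after}); defaults to
#'   the bundled characterized set.
#' @return A \linkS4class{CorePeptide}.
#' @examples
#' cp <- cleaveLeader(paste0("MSTKDFNLDLVSVSKKDSGASPR",
#'                           "ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK"))
#' cutRule(cp)
#' coreSeq(cp)
#' @export
cleaveLeader <- function(precursor, references = characterizedPeptides()) {
  precursor <- toupper(as.character(precursor))
  if (nchar(precursor) < 30) {
    .stopf("precursor must have at least 30 residues (got %d)",
           nchar(precursor))
  }
  for (motif in c("GASPR", "PQ", "PK")) {
    hits <- gregexpr(motif, precursor, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    ends <- rev(as.integer(hits) + nchar(motif) - 1L) # rightmost first
    for (e in ends) {
      core <- substring(precursor, e + 1L)
      if (nchar(core) < 20 || nchar(core) > 45) next
      if (nrow(matchCorePattern(core, "candidate")) == 0) next
      return(methods::new("CorePeptide", precursor = precursor,
                          leader = substring(precursor, 1, e), core = core,
                          cutRule = motif, cutAfter = e,
                          referenceUsed = NA_character_))
    }
  }
  # fall back to the nearest characterized reference
  if (!is.null(references) && nrow(references) > 0) {
    best_id <- -Inf
    best <- NULL
    for (i in seq_len(nrow(references))) {
      al <- globalAlign(references$precursor[i], precursor)
      if (al$identity_pct > best_id) {
        best_id <- al$identity_pct
        best <- list(al = al, i = i)
      }
    }
    if (best_id >= 30) {
      ref_cut <- references$cut_after[best$i]
      ra <- strsplit(best$al$aligned_a, "")[[1]]
      rb <- strsplit(best$al$aligned_b, "")[[1]]
      ref_count <- cumsum(ra != "-")
      cut_col <- match(ref_cut, ref_count) # first column reaching the cut
      cut_after <- sum(rb[seq_len(cut_col)] != "-")
      if (cut_after >= 1 && cut_after < nchar(precursor)) {
        return(methods::new("CorePeptide", precursor = precursor,
                            leader = substring(precursor, 1, cut_after),
                            core = substring(precursor, cut_after + 1L),
                            cutRule = "nearest_reference",
                            cutAfter = as.integer(cut_after),
                            referenceUsed = references$name[best$i]))
      }
    }
  }
  methods::new("CorePeptide", precursor = precursor, leader = "",
               core = precursor, cutRule = "unassigned", cutAfter = 0L,
               referenceUsed = NA_character_)
}

#' Collapse sequences that are exactly identical
#'
#' Groups sequences by exact (case-insensitive) equality; the representative
#' is the first-seen id and groups are returned in order of first
#' occurrence. This is the non-redundancy step that turns raw precursor hits
#' into unique prepropeptides.
#'
#' @param seqs Named character vector or \code{AAStringSet}.
#' @return Data frame with \code{representative}, \code{sequence},
#'   \code{members} (comma-joined member ids) and \code{n_members}.
#' @export
dedupExact <- function(seqs) {
  seqs <- .as_chr_seqs(seqs)
  if (length(seqs) == 0) {
    return(data.frame(representative = character(), sequence = character(),
                      members = character(), n_members = integer(),
                      stringsAsFactors = FALSE))
  }
  up <- toupper(seqs)
  grp <- match(up, unique(up))
  reps <- !duplicated(grp)
  message(sprintf("dedupExact: %d sequence(s) -> %d unique",
                  length(seqs), sum(reps)))
  data.frame(
    representative = names(seqs)[reps],
    sequence = unname(up[reps]),
    members = vapply(unique(grp), function(g) {
      paste(names(seqs)[grp == g], collapse = ",")
    }, character(1)),
    n_members = as.integer(table(grp)[as.character(unique(grp))]),
    stringsAsFactors = FALSE
  )
}

# residues of the query aligned to each scaffold column (NA where the query
# has a gap); insertion columns relative to the scaffold are dropped
.scaffold_column_residues <- function(scaffoldAlignment) {
  sa <- strsplit(scaffoldAlignment$aligned_scaffold, "")[[1]]
  qa <- strsplit(scaffoldAlignment$aligned_core, "")[[1]]
  keep <- sa != "-"
  res <- qa[keep]
  res[res == "-"] <- NA
  res
}

#' Align a core peptide to the nisin A scaffold
#'
#' Globally aligns the core to the canonical nisin A core and reads off ring
#' feasibility and the hinge. A ring is feasible iff the core supplies a Cys
#' at the scaffold's ring-closing Cys column and a Ser/Thr at the
#' ring-opening column. The hinge is the residues aligned to scaffold
#' positions 20-22, reported only when all three columns are occupied.
#'
#' @param core Core sequence of length 20-45.
#' @param ... Alignment parameters passed to \code{\link{globalAlign}}.
#' @return List with \code{core}, \code{aligned_core},
#'   \code{aligned_scaffold}, \code{ring_feasibility} (named logical over
#'   rings A-E) and \code{hinge} (3-residue string or \code{NA}).
#' @export
alignToScaffold <- function(core, ...) {
  core <- toupper(as.character(core))
  if (nchar(core) < 20 || nchar(core) > 45) {
    .stopf("core length %d outside [20, 45]", nchar(core))
  }
  al <- globalAlign(core, nisinACore(), ...)
  out <- list(core = core, aligned_core = al$aligned_a,
              aligned_scaffold = al$aligned_b)
  res <- .scaffold_column_residues(out)
  rings <- .scaffold_rings()
  feas <- vapply(rings, function(rc) {
    open <- res[rc[1]]
    close <- res[rc[2]]
    !is.na(open) && !is.na(close) && open %in% c("S", "T") && close == "C"
  }, logical(1))
  hinge_res <- res[20:22]
  out$ring_feasibility <- feas
  out$hinge <- if (anyNA(hinge_res)) NA_character_ else
    paste(hinge_res, collapse = "")
  out
}

#' Dehydration mass ladder of a core peptide
#'
#' Computes the unmodified average mass of the core (sum of residue masses
#' plus one water) and the ladder of masses after n dehydrations, each
#' removing one water (18.0153 Da average). Masses are reported rounded to
#' the nearest integer Da, matching how MALDI ladders are printed.
#'
#' @param core Core sequence.
#' @param nValues Non-negative integers; each must not exceed the Ser/Thr
#'   count of the core.
#' @param fullyModifiedN Optional annotation: the dehydration count of the
#'   fully modified peptide. This is peptide-specific knowledge supplied by
#'   the caller, never inferred.
#' @param monoisotopic Use monoisotopic masses instead of average masses.
#' @return List with \code{core}, \code{unmodified_avg_mass} (unrounded),
#'   \code{entries} (data frame \code{n_dehydrations}, \code{mass}) and
#'   \code{fully_modified_n}.
#' @examples
#' massLadder(nisinACore(), 6:8)$entries  # 3390, 3372, 3354
#' @export
massLadder <- function(core, nValues, fullyModifiedN = NA_integer_,
                       monoisotopic = FALSE) {
  core <- toupper(as.character(core))
  .check_residues(core, "core")
  if (grepl("X", core)) .stopf("cannot compute mass for a core containing X")
  nValues <- as.integer(nValues)
  if (any(nValues < 0)) .stopf("n values must be non-negative")
  st <- sum(strsplit(core, "")[[1]] %in% c("S", "T"))
  if (any(nValues > st)) {
    .stopf("n = %d exceeds the Ser/Thr count (%d) of the core",
           max(nValues), st)
  }
  masses <- if (monoisotopic) .residue_mono_masses() else
    .residue_avg_masses()
  water <- .water_mass(monoisotopic)
  unmod <- sum(masses[strsplit(core, "")[[1]]]) + water
  entries <- data.frame(
    n_dehydrations = nValues,
    mass = floor(unmod - nValues * water + 0.5),
    stringsAsFactors = FALSE
  )
  if (!is.na(fullyModifiedN) && fullyModifiedN > st) {
    .stopf("fullyModifiedN exceeds the Ser/Thr count of the core")
  }
  list(core = core, unmodified_avg_mass = unmod, entries = entries,
       fully_modified_n = as.integer(fullyModifiedN))
}

#' Per-position residue composition of scaffold-aligned cores
#'
#' Aligns every core to the nisin A scaffold and summarizes each scaffold
#' column: residue counts, distinct-residue count, and information content
#' \eqn{\log_2 20 - H} in bits, where \eqn{H} is the Shannon entropy of the
#' column's residue frequencies (non-gap residues only).
#'
#' @param cores Character vector of at least 2 core sequences.
#' @return List with \code{counts} (20 x 34 matrix), \code{n_distinct},
#'   \code{information_bits} and \code{aligned} (residue matrix, cores x
#'   scaffold columns).
#' @export
positionComposition <- function(cores) {
  cores <- .as_chr_seqs(cores)
  if (length(cores) < 2) .stopf("need at least 2 cores")
  L <- nchar(nisinACore())
  aligned <- t(vapply(cores, function(cc) {
    .scaffold_column_residues(alignToScaffold(cc))
  }, character(L)))
  aa <- aminoAcids()
  counts <- matrix(0L, 20, L, dimnames = list(aa, NULL))
  n_distinct <- integer(L)
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- aligned[, j]
    col <- col[!is.na(col) & col != "X"]
    cnt <- table(factor(col, levels = aa))
    counts[, j] <- as.integer(cnt)
    n_distinct[j] <- sum(cnt > 0)
    if (sum(cnt) > 0) {
      p <- as.numeric(cnt[cnt > 0]) / sum(cnt)
      info[j] <- log2(20) + sum(p * log2(p))
    } else {
      info[j] <- NA_real_
    }
  }
  list(counts = counts, n_distinct = n_distinct,
       information_bits = info, aligned = aligned)
}
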