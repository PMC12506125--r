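#' @include seqio.R motif_scan.R fixtures.R
NULL

#' Configuration for the synthetic genome generator
#'
#' Collects the knobs of the synthetic cohort: how many genomes, which
#' operon gene order, how often clusters/orphans/composite transposons are
#' planted, the MGE label mix, the per-position core mutation rate, and the
#' metadata missingness rate. Defaults mirror a real nBGC survey cohort:
#' every genome carries a cluster, orphans and composite transposons are
#' rare, ICEs dominate the MGE mix, and about 5 percent of records lack
#' both isolation source and host.
#'
#' @param seed Master seed (integer).
#' @param nGenomes Number of genomes (>= 1).
#' @param plantedClusterRate Probability a genome carries an nBGC.
#' @param operonOrder \code{"canonical"} (nisABTCIPRKFEG),
#'   \code{"lanFEGPBCT"}, or a custom character vector of machinery classes
#'   (the core gene is always emitted first).
#' @param orphanRate Probability a planted cluster lacks its lanB gene.
#' @param compositeTnRate Probability a planted cluster is flanked by an
#'   identical IS pair with an internal transposase.
#' @param mgeTypeMix Named probabilities over ICE, plasmid, prophage, none;
#'   must sum to 1.
#' @param coreMutationRate Per-position substitution rate applied to the
#'   unconstrained positions of the core template.
#' @param metadataMissingRate Probability that both source and host are the
#'   explicit \code{"missing"} marker.
#' @param decoyRange Range (min, max) of decoy CDS per genome.
#' @param compositeTnSpanBp Optional fixed outer span (bp) for planted IS
#'   pairs; spans outside 10-130 kb plant labelled negative controls.
#' @return A list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(seed = 42L,
                            nGenomes = 20L,
                            plantedClusterRate = 1,
                            operonOrder = "canonical",
                            orphanRate = 2 / 915,
                            compositeTnRate = 34 / 915,
                            mgeTypeMix = c(ICE = 187 / 915,
                                           plasmid = 54 / 915,
                                           prophage = 5 / 915,
                                           none = 669 / 915),
                            coreMutationRate = 0.1,
                            metadataMissingRate = 49 / 915,
                            decoyRange = c(30L, 80L),
                            compositeTnSpanBp = NULL) {
  probs <- c(plantedClusterRate, orphanRate, compositeTnRate,
             coreMutationRate, metadataMissingRate)
  if (any(probs < 0 | probs > 1)) .stopf("rates must lie in [0, 1]")
  if (nGenomes < 1) .stopf("nGenomes must be >= 1")
  need <- c("ICE", "plasmid", "prophage", "none")
  if (!all(need %in% names(mgeTypeMix)) ||
      abs(sum(mgeTypeMix) - 1) > 1e-6) {
    .stopf("mgeTypeMix must cover ICE/plasmid/prophage/none and sum to 1")
  }
  if (is.character(operonOrder) && length(operonOrder) == 1) {
    operonOrder <- switch(operonOrder,
      canonical = c("lanB", "lanT", "lanC", "lanI", "lanP", "lanR", "lanK",
                    "lanF", "lanE", "lanG"),
      lanFEGPBCT = c("lanF", "lanE", "lanG", "lanP", "lanB", "lanC", "lanT"),
      .stopf("unknown operonOrder '%s'", operonOrder))
  }
  if (!all(operonOrder %in% machineryClasses())) {
    .stopf("operonOrder contains unknown machinery classes")
  }
  structure(list(
    seed = as.integer(seed), nGenomes = as.integer(nGenomes),
    plantedClusterRate = plantedClusterRate, operonOrder = operonOrder,
    orphanRate = orphanRate, compositeTnRate = compositeTnRate,
    mgeTypeMix = mgeTypeMix[need], coreMutationRate = coreMutationRate,
    metadataMissingRate = metadataMissingRate,
    decoyRange = as.integer(decoyRange),
    compositeTnSpanBp = compositeTnSpanBp
  ), class = "SyntheticConfig")
}

# variable (mutable) positions of a core that matches the pattern: the
# pattern's literal S/C/T and [TS] positions stay fixed; everything matched
# by a dot or a quantified gap, and any residues outside the match, may vary
.core_variable_positions <- function(core) {
  grouped <- paste0("(..)(S)(.)(S)(.)(C)(T)(..)(C)(.)([TS])(.{1,6})(C)",
                    "(.{1,4})([TS])(.{1,2})([TS])(C)(.{1,3})(C)")
  m <- regexec(grouped, core, perl = TRUE)[[1]]
  if (m[1] == -1) .stopf("template does not match the nisin core pattern")
  starts <- m[-1]
  lens <- attr(m, "match.length")[-1]
  fixed_groups <- c(2, 4, 6, 7, 9, 11, 13, 15, 17, 18, 20)
  fixed_pos <- unlist(lapply(fixed_groups, function(g) {
    seq.int(starts[g], length.out = lens[g])
  }))
  setdiff(seq_len(nchar(core)), fixed_pos)
}

#' Generate a nisin-like variant core peptide
#'
#' Substitutes the unconstrained positions of the template (those matched by
#' a dot or a quantified gap of the core pattern, and any residues outside
#' the match) with residues drawn uniformly from the 20 amino acids at the
#' given per-position rate. The pattern's literal Ser/Thr/Cys positions are
#' never touched, so the output always matches the core pattern. Uses R's
#' RNG; seed with \code{set.seed} for reproducibility.
#'
#' @param template Core template (default the canonical nisin A core); must
#'   itself match the core pattern.
#' @param mutationRate Per-position substitution probability.
#' @return A variant core sequence.
#' @export
generateVariantCore <- function(template = nisinACore(), mutationRate = 0.1) {
  template <- toupper(as.character(template))
  if (nrow(matchCorePattern(template, "template")) == 0) {
    .stopf("template does not match the nisin core pattern")
  }
  varpos <- .core_variable_positions(template)
  res <- strsplit(template, "")[[1]]
  mutate <- varpos[stats::runif(length(varpos)) < mutationRate]
  if (length(mutate)) {
    res[mutate] <- sample(aminoAcids(), length(mutate), replace = TRUE)
  }
  out <- paste(res, collapse = "")
  stopifnot(nrow(matchCorePattern(out, "variant")) > 0)
  out
}

# --- low-level assembly helpers -------------------------------------------

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_protein <- function(n) {
  paste0("M", paste(sample(aminoAcids(), n - 1, replace = TRUE),
                    collapse = ""))
}

# codons per amino acid under the standard code (computed once)
.codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons
}

#' Reverse-translate a protein with uniform synonymous codons
#'
#' Each residue gets a codon drawn uniformly from its synonymous set; a stop
#' codon is appended. Re-translating the result reproduces the protein
#' exactly.
#'
#' @param protein Protein sequence (no X).
#' @return Nucleotide CDS string, length \code{3 * (nchar(protein) + 1)}.
#' @export
reverseTranslate <- function(protein) {
  protein <- toupper(as.character(protein))
  if (grepl("X", protein)) .stopf("cannot reverse-translate X")
  tab <- .codon_table()
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  stop_codon <- tab[["*"]][sample.int(3, 1)]
  paste(c(codons, stop_codon), collapse = "")
}

# mutable builder for one contig
.new_builder <- function(genomeId) {
  env <- new.env(parent = emptyenv())
  env$chunks <- list()
  env$pos <- 1L
  env$features <- list()
  env$counter <- 0L
  env$genomeId <- genomeId
  env$contig <- paste0(genomeId, "_c1")
  env
}

.bld_dna <- function(b, seq) {
  start <- b$pos
  b$chunks[[length(b$chunks) + 1]] <- seq
  b$pos <- b$pos + nchar(seq)
  c(start, b$pos - 1L)
}

.bld_gene <- function(b, protein, product, strand = "+") {
  nt <- reverseTranslate(protein)
  if (strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(nt)))
  }
  span <- .bld_dna(b, nt)
  b$counter <- b$counter + 1L
  locus <- sprintf("%s_%04d", b$genomeId, b$counter)
  b$features[[length(b$features) + 1]] <- list(
    contig = b$contig, start = span[1], end = span[2], strand = strand,
    type = "CDS", locus_tag = locus, product = product,
    translation = protein)
  list(locus_tag = locus, start = span[1], end = span[2])
}

.bld_spacer <- function(b, len = NULL) {
  if (is.null(len)) len <- sample(20:200, 1)
  if (len > 0) .bld_dna(b, .random_dna(len))
  invisible(len)
}

.bld_is <- function(b, seq, family) {
  span <- .bld_dna(b, seq)
  b$counter <- b$counter + 1L
  locus <- sprintf("%s_%04d", b$genomeId, b$counter)
  b$features[[length(b$features) + 1]] <- list(
    contig = b$contig, start = span[1], end = span[2], strand = "+",
    type = "repeat_region", locus_tag = locus, product = family,
    translation = NA_character_)
  list(start = span[1], end = span[2], family = family)
}

.bld_decoys <- function(b, n, pool) {
  for (k in seq_len(n)) {
    src <- as.character(pool[[sample.int(length(pool), 1)]])
    res <- strsplit(src, "")[[1]]
    shuffled <- paste(c(res[1], sample(res[-1])), collapse = "")
    strand <- sample(c("+", "-"), 1)
    .bld_gene(b, shuffled, "hypothetical protein", strand)
    .bld_spacer(b)
  }
}

.leaders <- function() {
  # canonical-style leaders ending in each recognized cut motif
  c(GASPR = "MSTKDFNLDLVSVSKKDSGASPR",
    PQ = "MSKFDDFDLDVVKVSKQDSKITPQ",
    PK = "MNNEDFNLDLIKISKENNSGASPK")
}

#' Generate one synthetic genome with planted ground truth
#'
#' Emits a single-contig genome: decoy CDS (shuffled pool proteins on random
#' strands), optionally one nisin-like operon in the configured gene order
#' (core gene = leader with a sampled canonical cut motif plus a mutated
#' core; machinery genes reverse-translated from the bundled references),
#' intergenic spacers of 20-200 bp, optionally an identical-IS-flanked
#' composite-transposon region with an internal transposase, optional MGE
#' interval labels with planted cargo genes, and a metadata record with
#' configured missingness. Uses R's RNG; seed with \code{set.seed}.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @param genomeId Genome identifier (used in contig and locus names).
#' @return List with \code{annotation} (a
#'   \linkS4class{GenomeAnnotation}), \code{truth} (planted coordinates,
#'   sequences and labels), \code{is_elements} and \code{mge_intervals}
#'   (data frames, possibly empty).
#' @export
generateGenome <- function(config, genomeId = "g001") {
  pool <- decoyProteinPool()
  refs <- machineryReferences()
  b <- .new_builder(genomeId)
  truth <- list(genome_id = genomeId, contig = b$contig)
  is_rows <- list()
  mge_rows <- list()

  has_cluster <- stats::runif(1) < config$plantedClusterRate
  orphan <- has_cluster && stats::runif(1) < config$orphanRate
  composite <- has_cluster && stats::runif(1) < config$compositeTnRate
  mge_type <- if (has_cluster && !composite) {
    sample(names(config$mgeTypeMix), 1, prob = config$mgeTypeMix)
  } else {
    "none"
  }

  n_decoys <- sample(config$decoyRange[1]:config$decoyRange[2], 1)
  n_lead <- sample.int(n_decoys, 1)
  .bld_decoys(b, n_lead, pool)

  if (has_cluster) {
    order_used <- config$operonOrder
    if (orphan) order_used <- setdiff(order_used, "lanB")

    is_seq <- NULL
    negative_reason <- NA_character_
    span_target <- NA_real_
    is1 <- NULL
    if (composite) {
      is_seq <- .random_dna(1200)
      if (!is.null(config$compositeTnSpanBp)) {
        span_target <- config$compositeTnSpanBp
        if (span_target < 10000 || span_target > 130000) {
          negative_reason <- "span_out_of_range"
        }
      } else {
        span_target <- stats::runif(1, 15000, 45000)
      }
      is1 <- .bld_is(b, is_seq, "ISsyn1")
      .bld_spacer(b)
    }

    # the operon: core gene first, then machinery in the configured order
    cut_rule <- sample(names(.leaders()), 1)
    leader <- .leaders()[[cut_rule]]
    core <- generateVariantCore(nisinACore(), config$coreMutationRate)
    precursor <- paste0(leader, core)
    core_gene <- .bld_gene(b, precursor, "hypothetical protein")
    operon_start <- core_gene$start
    machinery <- list()
    for (cls in order_used) {
      .bld_spacer(b)
      g <- .bld_gene(b, as.character(refs[[cls]]), "hypothetical protein")
      machinery[[cls]] <- g
    }
    operon_end <- if (length(machinery)) {
      max(vapply(machinery, function(g) g$end, numeric(1)))
    } else {
      core_gene$end
    }

    cargo <- character()
    cargo_loci <- list()
    if (mge_type != "none") {
      n_cargo <- sample.int(2, 1)
      cargo <- sample(c("Tet(O)", "Erm(B)", "APH(3')-IIIa", "BcrA", "MobC",
                        "T4SS protein"), n_cargo)
      for (lb in cargo) {
        .bld_spacer(b)
        cargo_loci[[lb]] <- .bld_gene(b, .random_protein(sample(100:250, 1)),
                                      lb)
      }
    }

    tn_span <- NULL
    if (composite) {
      if (is.na(negative_reason) && stats::runif(1) < 0.3) {
        # negative controls: break the rule on purpose
        negative_reason <- sample(c("different_is_family",
                                    "no_transposase"), 1)
      }
      if (is.na(negative_reason) || negative_reason != "no_transposase") {
        .bld_spacer(b)
        .bld_gene(b, .random_protein(sample(220:320, 1)),
                  "IS200-like transposase")
      }
      content_end <- b$pos - 1L
      used <- content_end - is1$start + 1L
      min_span <- used + 1200L + 40L
      if (span_target < min_span) {
        if (!is.null(config$compositeTnSpanBp)) {
          .stopf("requested composite span %d bp below the minimum %d bp",
                 round(span_target), min_span)
        }
        span_target <- min_span
      }
      filler <- round(span_target) - used - 1200L
      .bld_spacer(b, max(filler, 20L))
      fam2_final <- if (!is.na(negative_reason) &&
                        negative_reason == "different_is_family") "ISsyn2"
        else "ISsyn1"
      seq2 <- if (fam2_final == "ISsyn1") is_seq else .random_dna(1200)
      is2 <- .bld_is(b, seq2, fam2_final)
      tn_span <- c(is1$start, is2$end)
      is_rows[[1]] <- data.frame(contig = b$contig, start = is1$start,
                                 end = is1$end, family = "ISsyn1",
                                 stringsAsFactors = FALSE)
      is_rows[[2]] <- data.frame(contig = b$contig, start = is2$start,
                                 end = is2$end, family = fam2_final,
                                 stringsAsFactors = FALSE)
    }

    truth$cluster <- list(
      locus_tag = core_gene$locus_tag,
      precursor = precursor, leader = leader, core = core,
      cut_rule = cut_rule,
      start = core_gene$start, end = core_gene$end,
      operon_start = operon_start, operon_end = operon_end,
      operon_order = order_used, orphan = orphan,
      machinery = lapply(machinery, function(g) {
        list(locus_tag = g$locus_tag, start = g$start, end = g$end)
      })
    )
    truth$composite <- if (composite) {
      list(planted = TRUE,
           is_composite = is.na(negative_reason),
           negative_reason = negative_reason,
           span_start = tn_span[1], span_end = tn_span[2],
           span_len = tn_span[2] - tn_span[1] + 1)
    } else {
      list(planted = FALSE, is_composite = FALSE)
    }
    truth$mge <- list(type = mge_type, cargo = as.list(cargo))
    if (mge_type != "none") {
      pad1 <- sample(500:2000, 1)
      pad2 <- sample(500:2000, 1)
      last_end <- if (length(cargo_loci)) {
        max(vapply(cargo_loci, function(g) g$end, numeric(1)))
      } else {
        operon_end
      }
      mge_start <- max(1L, operon_start - pad1)
      mge_end <- last_end + pad2 # trailing decoys extend the contig past it
      mge_rows[[1]] <- data.frame(
        contig = b$contig, start = mge_start, end = mge_end,
        type = mge_type, evidence = "simulated", stringsAsFactors = FALSE)
      truth$mge$start <- mge_start
      truth$mge$end <- mge_end
    }
  } else {
    truth$cluster <- NULL
    truth$composite <- list(planted = FALSE, is_composite = FALSE)
    truth$mge <- list(type = "none", cargo = list())
  }

  .bld_spacer(b, 2500L) # guarantees trailing MGE pad stays on the contig
  .bld_decoys(b, n_decoys - n_lead, pool)
  .bld_spacer(b)

  contig_seq <- paste(unlist(b$chunks), collapse = "")
  feats <- b$features
  gr <- GenomicRanges::GRanges(
    seqnames = b$contig,
    ranges = IRanges::IRanges(
      start = vapply(feats, function(f) f$start, numeric(1)),
      end = vapply(feats, function(f) f$end, numeric(1))),
    strand = vapply(feats, function(f) f$strand, character(1)))
  gr$type <- vapply(feats, function(f) f$type, character(1))
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  gr$locus_tag <- vapply(feats, function(f) f$locus_tag, character(1))
  gr$product <- vapply(feats, function(f) f$product, character(1))
  gr$translation <- vapply(feats, function(f) f$translation, character(1))

  sources <- c("gut", "oral", "blood", "milk", "soil")
  hosts <- c("human", "pig", "cow", "chicken")
  countries <- c("China", "USA", "UK", "Netherlands", "Ireland")
  genera <- c("Streptococcus", "Lactococcus", "Blautia", "Bacillus",
              "Staphylococcus", "Enterococcus", "Bifidobacterium",
              "Velocimicrobium")
  md <- c(source = sample(sources, 1), host = sample(hosts, 1),
          country = sample(countries, 1),
          collection_date = as.character(sample(2015:2023, 1)),
          genus = sample(genera, 1))
  if (stats::runif(1) < config$metadataMissingRate) {
    md["source"] <- "missing"
    md["host"] <- "missing"
  }
  truth$metadata <- as.list(md)

  annotation <- GenomeAnnotation(
    contigs = Biostrings::DNAStringSet(setNames(contig_seq, b$contig)),
    features = gr, genomeMetadata = md)

  list(
    annotation = annotation,
    truth = truth,
    is_elements = if (length(is_rows)) {
      do.call(rbind, c(is_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(contig = character(), start = integer(), end = integer(),
                 family = character(), stringsAsFactors = FALSE)
    },
    mge_intervals = if (length(mge_rows)) {
      do.call(rbind, c(mge_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(contig = character(), start = integer(), end = integer(),
                 type = character(), evidence = character(),
                 stringsAsFactors = FALSE)
    }
  )
}

#' Generate a synthetic cohort on disk
#'
#' Writes \code{nGenomes} independent genomes (GFF3 + FASTA per genome),
#' the aggregated \code{is_elements.tsv} and \code{mge_intervals.tsv},
#' a \code{metadata.tsv} with the per-genome assembly metadata, and a
#' \code{truth.json} recording everything that was planted. Per-genome
#' seeds are derived deterministically from the master seed
#' (\code{master + index * 1000003 mod 2^31 - 1}), so a cohort regenerates
#' byte-identically and individual genomes can be regenerated in isolation.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the output paths and the cohort truth.
#' @export
generateCohort <- function(config, outDir) {
  if (!inherits(config, "SyntheticConfig")) {
    .stopf("config must come from syntheticConfig()")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  truths <- list()
  md_rows <- list()
  is_all <- list()
  mge_all <- list()
  for (i in seq_len(config$nGenomes)) {
    gid <- sprintf("g%03d", i)
    set.seed(deriveSeed(config$seed, i))
    g <- generateGenome(config, gid)
    writeGenomeAnnotation(g$annotation,
                          file.path(outDir, paste0(gid, ".gff3")),
                          file.path(outDir, paste0(gid, ".fna")))
    truths[[gid]] <- g$truth
    md_rows[[gid]] <- data.frame(
      genome_id = gid, t(genomeMetadata(g$annotation)),
      stringsAsFactors = FALSE)
    if (nrow(g$is_elements)) is_all[[gid]] <- g$is_elements
    if (nrow(g$mge_intervals)) mge_all[[gid]] <- g$mge_intervals
  }
  md <- do.call(rbind, c(md_rows, list(make.row.names = FALSE)))
  writeFlatTable(md, file.path(outDir, "metadata.tsv"))
  is_df <- if (length(is_all)) {
    do.call(rbind, c(is_all, list(make.row.names = FALSE)))
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               family = character(), stringsAsFactors = FALSE)
  }
  writeFlatTable(is_df, file.path(outDir, "is_elements.tsv"),
                 keys = c("contig", "start", "end", "family"))
  mge_df <- if (length(mge_all)) {
    do.call(rbind, c(mge_all, list(make.row.names = FALSE)))
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               type = character(), evidence = character(),
               stringsAsFactors = FALSE)
  }
  writeFlatTable(mge_df, file.path(outDir, "mge_intervals.tsv"),
                 keys = c("contig", "start", "end", "type", "evidence"))
  jsonlite::write_json(truths, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(dir = outDir, truth = truths))
}
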