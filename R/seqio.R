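#' @include AllClasses.R
NULL

#' Read a protein FASTA file with strict validation
#'
#' Parses a protein FASTA file into an \link[Biostrings]{AAStringSet}.
#' Unlike a permissive reader, every sequence is checked against the
#' amino-acid alphabet (20 standard letters plus \code{X}); any other
#' character, a record with no sequence, or a duplicated id is an error that
#' names the offending line.
#'
#' @param path Path to a FASTA file.
#' @return An \code{AAStringSet}; names are record ids, descriptions (text
#'   after the first whitespace in the header) are kept in
#'   \code{mcols(x)$description}.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "ITSIS", ">b", "WKSES"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  descs <- character()
  seqs <- character()
  cur <- NULL
  cur_line <- 0L
  flush <- function() {
    if (is.null(cur)) return(invisible())
    if (!nzchar(cur$seq)) {
      .stopf("record '%s' (line %d) has an empty sequence", cur$id, cur$line)
    }
    ids <<- c(ids, cur$id)
    descs <<- c(descs, cur$desc)
    seqs <<- c(seqs, cur$seq)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      hdr <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", hdr)
      if (!nzchar(id)) .stopf("malformed FASTA header at line %d", i)
      desc <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else ""
      cur <- list(id = id, desc = desc, seq = "", line = i)
    } else {
      if (is.null(cur)) {
        .stopf("sequence data before any FASTA header at line %d", i)
      }
      chunk <- toupper(gsub("\\s", "", ln))
      if (grepl(sprintf("[^%s]", paste(.aa_alphabet(), collapse = "")), chunk)) {
        bad <- regmatches(chunk, regexpr(
          sprintf("[^%s]", paste(.aa_alphabet(), collapse = "")), chunk))
        .stopf("invalid residue '%s' at line %d (record '%s')",
               bad, i, cur$id)
      }
      cur$seq <- paste0(cur$seq, chunk)
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    .stopf("duplicate record id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = descs)
  out
}

#' Write protein sequences as FASTA
#'
#' @param proteins An \code{AAStringSet} or named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeProteinFasta <- function(proteins, path) {
  if (!methods::is(proteins, "AAStringSet")) {
    proteins <- Biostrings::AAStringSet(.as_chr_seqs(proteins))
  }
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

# translate CDS spans in one batched call, strand-aware, dropping one
# trailing stop if present (per-span translate calls are far too slow)
.translate_spans <- function(contigs, chr, starts, ends, strands) {
  nts <- Biostrings::DNAStringSet(lapply(seq_along(chr), function(i) {
    Biostrings::subseq(contigs[[chr[i]]], starts[i], ends[i])
  }))
  neg <- strands == "-"
  if (any(neg)) nts[neg] <- Biostrings::reverseComplement(nts[neg])
  aa <- as.character(suppressWarnings(
    Biostrings::translate(nts, if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

#' Read a genome annotation from GFF3 + FASTA
#'
#' Imports features with \code{rtracklayer} and contig sequences with
#' \code{Biostrings}, producing a \linkS4class{GenomeAnnotation}. Coordinates
#' are 1-based inclusive throughout. CDS features carry translations: the
#' GFF3 \code{translation} attribute wins when present; otherwise the span is
#' translated from the nucleotide sequence with the standard code,
#' strand-aware. When both exist and disagree, the attribute wins and a
#' warning is issued.
#'
#' @param gffPath Path to a GFF3 file.
#' @param fastaPath Path to the matching nucleotide FASTA.
#' @param genomeMetadata Optional named character vector of assembly metadata
#'   (keys \code{source, host, country, collection_date, genus}).
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
readGenomeAnnotations <- function(gffPath, fastaPath, genomeMetadata = character()) {
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gffPath)
  if (length(gr)) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chr), names(contigs))
    if (length(unknown)) {
      .stopf("GFF3 references contig(s) absent from the FASTA: %s",
             paste(unknown, collapse = ", "))
    }
    lens <- Biostrings::width(contigs)[match(chr, names(contigs))]
    bad <- GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > lens
    if (any(bad)) {
      .stopf("feature(s) beyond contig bounds: %s",
             paste(utils::head(gr$locus_tag[bad], 5), collapse = ", "))
    }
    strands <- as.character(GenomicRanges::strand(gr))
    if (any(strands == "*")) {
      .stopf("feature(s) with unknown strand; '+' or '-' required")
    }
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$locus_tag)) mc$locus_tag <- NA_character_
    if (is.null(mc$product)) mc$product <- NA_character_
    if (is.null(mc$translation)) mc$translation <- NA_character_
    is_cds <- which(as.character(mc$type) == "CDS")
    if (length(is_cds)) {
      derived <- .translate_spans(contigs, chr[is_cds],
                                  GenomicRanges::start(gr)[is_cds],
                                  GenomicRanges::end(gr)[is_cds],
                                  strands[is_cds])
      for (k in seq_along(is_cds)) {
        i <- is_cds[k]
        attr_tr <- mc$translation[i]
        if (is.na(attr_tr) || !nzchar(attr_tr)) {
          mc$translation[i] <- derived[k]
        } else if (!identical(attr_tr, derived[k])) {
          warning(sprintf(
            "CDS %s: translation attribute disagrees with the nucleotide-derived translation; keeping the attribute",
            mc$locus_tag[i]), call. = FALSE)
        }
      }
    }
    S4Vectors::mcols(gr) <- mc
  }
  GenomeAnnotation(contigs = contigs, features = gr,
                   genomeMetadata = genomeMetadata)
}

#' Write a genome annotation as GFF3 + FASTA
#'
#' Inverse of \code{\link{readGenomeAnnotations}} (assembly metadata travels
#' separately, e.g. in a cohort metadata table).
#'
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param gffPath Output GFF3 path.
#' @param fastaPath Output FASTA path.
#' @return Invisibly, the two paths.
#' @export
writeGenomeAnnotation <- function(annotation, gffPath, fastaPath) {
  Biostrings::writeXStringSet(contigs(annotation), fastaPath)
  rtracklayer::export(features(annotation), gffPath, format = "gff3")
  invisible(c(gffPath, fastaPath))
}

.escape_tsv <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.unescape_tsv <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- character()
    k <- 1L
    n <- nchar(s)
    while (k <= n) {
      ch <- substr(s, k, k)
      if (ch == "\\" && k < n) {
        nxt <- substr(s, k + 1, k + 1)
        res <- c(res, switch(nxt, t = "\t", n = "\n", "\\" = "\\",
                             paste0("\\", nxt)))
        k <- k + 2L
      } else {
        res <- c(res, ch)
        k <- k + 1L
      }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

#' Write a flat table as TSV or JSON
#'
#' TSV output is UTF-8, tab-delimited with a header row; missing values are
#' written as the empty string; embedded tabs, newlines and backslashes are
#' backslash-escaped so that \code{\link{readFlatTable}} round-trips every
#' value. JSON output is an array of objects.
#'
#' @param rows A data frame, or a list of named lists sharing one key set.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param keys Optional character vector of column names; required to write a
#'   header-only TSV when \code{rows} is empty.
#' @return Invisibly, the path.
#' @export
writeFlatTable <- function(rows, path, format = c("tsv", "json"), keys = NULL) {
  format <- match.arg(format)
  if (is.data.frame(rows)) {
    df <- rows
  } else if (is.list(rows)) {
    if (length(rows) == 0) {
      if (is.null(keys)) {
        .stopf("empty row list: supply `keys` to write a header-only table")
      }
      df <- as.data.frame(setNames(
        replicate(length(keys), character(0), simplify = FALSE), keys))
    } else {
      keysets <- lapply(rows, function(r) sort(names(r)))
      ref <- keysets[[1]]
      for (i in seq_along(keysets)) {
        if (!identical(keysets[[i]], ref)) {
          .stopf("row %d has keys {%s}; expected {%s}",
                 i, paste(keysets[[i]], collapse = ","),
                 paste(ref, collapse = ","))
        }
      }
      df <- do.call(rbind, lapply(rows, function(r) {
        as.data.frame(r[names(rows[[1]])], stringsAsFactors = FALSE)
      }))
    }
  } else {
    .stopf("rows must be a data frame or a list of named lists")
  }
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
    return(invisible(path))
  }
  chr <- as.data.frame(lapply(df, function(col) {
    out <- as.character(col)
    out[is.na(col)] <- ""
    .escape_tsv(out)
  }), stringsAsFactors = FALSE, optional = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(chr)) {
    writeLines(do.call(paste, c(unname(chr), sep = "\t")), con,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Read a table written by \code{writeFlatTable}
#'
#' Reverses the TSV escaping and re-types columns with
#' \code{utils::type.convert}, so numeric columns round-trip as numerics and
#' empty strings come back as \code{NA}.
#'
#' @param path Input path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return A data frame.
#' @export
readFlatTable <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)))
  }
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1) {
    return(as.data.frame(setNames(
      replicate(length(header), character(0), simplify = FALSE), header)))
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  mat <- t(vapply(cells, function(x) {
    length(x) <- length(header)
    x[is.na(x)] <- ""
    x
  }, character(length(header))))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  for (j in seq_along(df)) {
    col <- .unescape_tsv(df[[j]])
    col[col == ""] <- NA
    df[[j]] <- utils::type.convert(col, as.is = TRUE)
  }
  df
}
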