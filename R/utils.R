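# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals (printed percentages use
# half-up, not banker's rounding).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_residues <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(.aa_alphabet(), collapse = "")), x)
  if (any(bad)) {
    .stopf("%s contains characters outside the amino-acid alphabet: %s",
           what, paste(unique(x[bad]), collapse = ", "))
  }
  invisible(x)
}

# Deterministic per-genome seed derived from a master seed; exact in double
# arithmetic and always a valid 32-bit R seed.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) + as.numeric(index) * 1000003) %% 2147483647)
}

.as_chr_seqs <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- as.character(seq_along(out))
    out
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- as.character(seq_along(x))
    x
  } else {
    .stopf("expected a character vector or an XStringSet")
  }
}
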