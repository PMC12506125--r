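# annotation with a transposase CDS; IS tables are built per test
tn_annotation <- function(tpase_at = 30000L, contig_len = 200000L) {
  genes <- data.frame(
    start = c(20000L, tpase_at),
    end = c(20120L, tpase_at + 900L),
    strand = "+", type = "CDS",
    locus_tag = c("core1", "tp1"),
    product = c("hypothetical protein", "IS200-like transposase"),
    translation = c("MAAA", "MCCC"), stringsAsFactors = FALSE)
  make_annotation(genes, contig_len = contig_len)
}

is_pair <- function(s1, e1, s2, e2, fam1 = "IS3", fam2 = "IS3") {
  data.frame(contig = "c1", start = c(s1, s2), end = c(e1, e2),
             family = c(fam1, fam2), stringsAsFactors = FALSE)
}

bgc <- data.frame(contig = "c1", start = 20000L, end = 25000L,
                  stringsAsFactors = FALSE)

test_that("the composite-transposon rule fires on the worked layout", {
  ga <- tn_annotation()
  res <- findCompositeTransposons(ga, is_pair(1000, 2200, 45000, 46200), bgc)
  expect_identical(nrow(res), 1L)
  expect_identical(res$start, 1000)
  expect_identical(res$end, 46200)
  expect_identical(res$type, "composite_transposon")
  expect_identical(res$end - res$start + 1, 45201)
})

test_that("span bounds are inclusive at 10 kb and 130 kb, exact to 1 bp", {
  ga <- tn_annotation(tpase_at = 6000L)
  b <- data.frame(contig = "c1", start = 3000L, end = 5000L)
  # span exactly 10,000: IS1 1000-2200, IS2 ends at 10999
  ok10 <- findCompositeTransposons(ga, is_pair(1000, 2200, 9800, 10999), b)
  expect_identical(nrow(ok10), 1L)
  # one bp shorter: rejected
  no10 <- findCompositeTransposons(ga, is_pair(1000, 2200, 9799, 10998), b)
  expect_identical(nrow(no10), 0L)

  ga2 <- tn_annotation(tpase_at = 60000L)
  # span exactly 130,000: 1000 .. 130999
  ok130 <- findCompositeTransposons(ga2, is_pair(1000, 2200, 129800, 130999),
                                    bgc)
  expect_identical(nrow(ok130), 1L)
  # one bp longer: rejected
  no130 <- findCompositeTransposons(ga2, is_pair(1000, 2200, 129801, 131000),
                                    bgc)
  expect_identical(nrow(no130), 0L)
})

test_that("the curation clause requires a transposase inside the span", {
  ga_out <- tn_annotation(tpase_at = 60000L) # transposase beyond IS2
  res <- findCompositeTransposons(ga_out, is_pair(1000, 2200, 45000, 46200),
                                  bgc)
  expect_identical(nrow(res), 0L)
})

test_that("different IS families never pair; same sequences do", {
  ga <- tn_annotation()
  res <- findCompositeTransposons(
    ga, is_pair(1000, 2200, 45000, 46200, "IS3", "IS6"), bgc)
  expect_identical(nrow(res), 0L)

  # family labels absent: fall back to sequence identity
  set.seed(3)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  seq2 <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  is_seq <- data.frame(contig = "c1", start = c(1000, 45000),
                       end = c(2200, 46200), family = NA_character_,
                       sequence = c(seq1, seq1), stringsAsFactors = FALSE)
  expect_identical(nrow(findCompositeTransposons(ga, is_seq, bgc)), 1L)
  is_seq$sequence[2] <- seq2
  expect_identical(nrow(findCompositeTransposons(ga, is_seq, bgc)), 0L)
})

test_that("the shortest qualifying span wins per BGC", {
  ga <- tn_annotation()
  is3 <- data.frame(contig = "c1", start = c(1000, 45000, 60000),
                    end = c(2200, 46200, 61200), family = "IS3",
                    stringsAsFactors = FALSE)
  res <- findCompositeTransposons(ga, is3, bgc)
  expect_identical(nrow(res), 1L)
  expect_identical(res$end, 46200)
})

test_that("co-localization requires containment and reports multiplicity", {
  mge <- data.frame(contig = "c1",
                    start = c(1L, 1L, 100000L),
                    end = c(40000L, 39000L, 150000L),
                    type = c("plasmid", "prophage", "ICE"),
                    evidence = "tool", stringsAsFactors = FALSE)
  b1 <- data.frame(bgc_id = "b1", contig = "c1", start = 20000L,
                   end = 25000L, stringsAsFactors = FALSE)
  res <- colocalize(b1, mge)
  expect_setequal(res$mge_type, c("plasmid", "prophage"))

  # straddling an MGE boundary is not containment
  b2 <- data.frame(bgc_id = "b2", contig = "c1", start = 24000L,
                   end = 41000L, stringsAsFactors = FALSE)
  res2 <- colocalize(b2, mge)
  expect_identical(res2$mge_type, "none")

  # enlarging an interval never removes an assignment (monotonicity)
  mge_big <- mge
  mge_big$end[1] <- 60000L
  res3 <- colocalize(b2, mge_big)
  expect_true("plasmid" %in% res3$mge_type)
  res1b <- colocalize(b1, mge_big)
  expect_true(all(res$mge_type %in% res1b$mge_type))
})

test_that("the cargo census counts label-bearing intervals per type", {
  # 4 ICEs, 3 carrying a Tet(O)-labelled CDS
  genes <- do.call(rbind, lapply(1:4, function(k) {
    base <- k * 20000L
    data.frame(start = c(base, base + 2000L), end = c(base + 120L,
                                                      base + 2900L),
               strand = "+", type = "CDS",
               locus_tag = paste0(c("core", "cargo"), k),
               product = c("hypothetical protein",
                           if (k < 4) "Tet(O)" else "hypothetical protein"),
               translation = "MAAA", stringsAsFactors = FALSE)
  }))
  ga <- make_annotation(genes, contig_len = 120000L)
  mge <- data.frame(contig = "c1", start = (1:4) * 20000L - 1000L,
                    end = (1:4) * 20000L + 4000L, type = "ICE",
                    evidence = "tool", stringsAsFactors = FALSE)
  b <- data.frame(contig = "c1", start = (1:4) * 20000L,
                  end = (1:4) * 20000L + 120L, stringsAsFactors = FALSE)
  coloc <- colocalize(b, mge)
  census <- cargoCensus(ga, coloc, mge)
  teto <- census[census$product == "Tet(O)", ]
  expect_identical(teto$n_mge_with, 3L)
  expect_identical(teto$n_mge_total, 4L)
  expect_equal(teto$pct, 75.0)

  # no occupied MGEs -> empty census
  empty <- cargoCensus(ga, colocalize(b, mge[0, ]), mge[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("IS and MGE table readers enforce their schemas", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFlatTable(data.frame(contig = "c1", start = 1L, end = 100L,
                            family = "IS3"), f)
  expect_error(readISElements(f), "200 bp")
  writeFlatTable(data.frame(contig = "c1", start = 1L, end = 1200L,
                            family = "IS3"), f)
  expect_identical(nrow(readISElements(f)), 1L)

  writeFlatTable(data.frame(contig = "c1", start = 1L, end = 5000L,
                            type = "megaplasmid", evidence = "x"), f)
  expect_error(readMGEIntervals(f), "unknown MGE type")
})
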