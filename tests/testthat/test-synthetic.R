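test_that("variant cores always respect the pattern's fixed positions", {
  set.seed(1)
  expect_identical(generateVariantCore(nisinACore(), 0), nisinACore())

  # full mutation leaves the pattern literals (incl. ring cysteines) intact
  set.seed(2)
  v <- generateVariantCore(nisinACore(), 1)
  lit <- c(3, 5, 7, 8, 11, 13, 19, 23, 25, 26, 28)
  expect_identical(strsplit(v, "")[[1]][lit],
                   strsplit(nisinACore(), "")[[1]][lit])
  expect_identical(nrow(matchCorePattern(v, "v")), 1L)

  # cross-module contract: many seeded variants all match the pattern
  set.seed(3)
  for (k in 1:200) {
    vk <- generateVariantCore(nisinACore(), runif(1))
    expect_gte(nrow(matchCorePattern(vk, "vk")), 1L)
  }

  expect_error(generateVariantCore(strrep("A", 30), 0.5),
               "does not match")
})

test_that("variant generation is seed-reproducible with rate-consistent drift", {
  set.seed(10)
  v1 <- generateVariantCore(nisinACore(), 0.5)
  set.seed(10)
  v2 <- generateVariantCore(nisinACore(), 0.5)
  expect_identical(v1, v2)

  # over many draws the per-variable-position substitution fraction tracks
  # the rate (a substitution can redraw the same residue: rate * 19/20)
  set.seed(11)
  varpos <- nisinscan:::.core_variable_positions(nisinACore())
  tmpl <- strsplit(nisinACore(), "")[[1]]
  n_draws <- 1000
  changed <- 0
  for (k in seq_len(n_draws)) {
    v <- strsplit(generateVariantCore(nisinACore(), 0.3), "")[[1]]
    changed <- changed + sum(v[varpos] != tmpl[varpos])
  }
  rate_hat <- changed / (n_draws * length(varpos))
  expect_gt(rate_hat, 0.3 * 19 / 20 - 0.03)
  expect_lt(rate_hat, 0.3 * 19 / 20 + 0.03)
})

test_that("reverse translation round-trips through the standard code", {
  set.seed(21)
  for (k in 1:10) {
    prot <- random_protein(sample(20:200, 1))
    nt <- reverseTranslate(prot)
    expect_identical(nchar(nt), (nchar(prot) + 1L) * 3L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_identical(sub("\\*$", "", aa), prot)
  }
})

test_that("generated genomes honor the planted-cluster and orphan switches", {
  cfg <- syntheticConfig(nGenomes = 1, orphanRate = 0)
  set.seed(100)
  g <- generateGenome(cfg, "gA")
  expect_false(is.null(g$truth$cluster))
  expect_false(g$truth$cluster$orphan)
  expect_true("lanB" %in% names(g$truth$cluster$machinery))
  # the planted precursor is a real CDS whose translation carries the core
  feat <- features(g$annotation)
  row <- feat[feat$locus_tag == g$truth$cluster$locus_tag]
  expect_identical(row$translation, g$truth$cluster$precursor)

  cfg_orphan <- syntheticConfig(nGenomes = 1, orphanRate = 1)
  set.seed(101)
  g2 <- generateGenome(cfg_orphan, "gB")
  expect_true(g2$truth$cluster$orphan)
  expect_false("lanB" %in% names(g2$truth$cluster$machinery))

  cfg_none <- syntheticConfig(nGenomes = 1, plantedClusterRate = 0)
  set.seed(102)
  g3 <- generateGenome(cfg_none, "gC")
  expect_null(g3$truth$cluster)
})

test_that("alternative operon orders are emitted as configured", {
  cfg <- syntheticConfig(nGenomes = 1, operonOrder = "lanFEGPBCT",
                         orphanRate = 0)
  set.seed(103)
  g <- generateGenome(cfg, "gD")
  expect_identical(unlist(g$truth$cluster$operon_order),
                   c("lanF", "lanE", "lanG", "lanP", "lanB", "lanC", "lanT"))
  # gene coordinates follow that order on the contig
  starts <- vapply(g$truth$cluster$machinery, function(m) m$start,
                   numeric(1))
  expect_identical(names(sort(starts)),
                   c("lanF", "lanE", "lanG", "lanP", "lanB", "lanC", "lanT"))
})

test_that("a sub-10 kb IS span is planted as a labelled negative control", {
  cfg <- syntheticConfig(nGenomes = 1, compositeTnRate = 1,
                         compositeTnSpanBp = 9500)
  set.seed(104)
  g <- generateGenome(cfg, "gE")
  expect_true(g$truth$composite$planted)
  expect_false(g$truth$composite$is_composite)
  expect_identical(g$truth$composite$negative_reason, "span_out_of_range")
  expect_lt(g$truth$composite$span_len, 10000)
  # the rule-based caller agrees with the truth label
  bgc <- data.frame(contig = g$truth$contig,
                    start = g$truth$cluster$operon_start,
                    end = g$truth$cluster$operon_end)
  found <- findCompositeTransposons(g$annotation, g$is_elements, bgc)
  expect_identical(nrow(found), 0L)
})

test_that("cohorts are deterministic and carry configured missingness", {
  cfg <- syntheticConfig(seed = 7, nGenomes = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateCohort(cfg, d1)
  generateCohort(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }

  expect_error(generateCohort(syntheticConfig(nGenomes = 0), d1),
               "nGenomes")

  # missing-both fraction within the binomial 99% CI at n = 1000
  cfg_many <- syntheticConfig(seed = 13, nGenomes = 1000,
                              plantedClusterRate = 0,
                              decoyRange = c(2L, 3L),
                              metadataMissingRate = 0.054)
  miss <- 0L
  for (i in seq_len(cfg_many$nGenomes)) {
    set.seed(nisinscan:::deriveSeed(cfg_many$seed, i))
    g <- generateGenome(cfg_many, sprintf("g%04d", i))
    md <- g$truth$metadata
    if (md$source == "missing" && md$host == "missing") miss <- miss + 1L
  }
  p_hat <- miss / 1000
  half <- 2.576 * sqrt(0.054 * (1 - 0.054) / 1000)
  expect_gt(p_hat, 0.054 - half)
  expect_lt(p_hat, 0.054 + half)
})

test_that("truth JSON round-trips losslessly", {
  cfg <- syntheticConfig(seed = 5, nGenomes = 2, compositeTnRate = 1)
  d <- withr::local_tempdir()
  out <- generateCohort(cfg, d)
  back <- jsonlite::read_json(file.path(d, "truth.json"),
                              simplifyVector = FALSE)
  expect_identical(names(back), names(out$truth))
  expect_identical(back$g001$cluster$precursor,
                   out$truth$g001$cluster$precursor)
  expect_identical(back$g001$composite$span_start,
                   out$truth$g001$composite$span_start)
})
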