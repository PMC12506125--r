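nisA_precursor <- paste0("MSTKDFNLDLVSVSKKDSGASPR", nisinACore())
subtilin_core <- "WKSESLCTPGCVTGALQTCFLQTLTCNCKISK"
subtilin_precursor <- paste0("MSKFDDFDLDVVKVSKQDSKITPQ", subtilin_core)

test_that("canonical cut sites are applied with GASPR > PQ > PK precedence", {
  cp <- cleaveLeader(nisA_precursor)
  expect_identical(cutRule(cp), "GASPR")
  expect_identical(coreSeq(cp), nisinACore())
  expect_true(startsWith(coreSeq(cp), "ITSIS"))
  expect_identical(paste0(leaderSeq(cp), coreSeq(cp)), nisA_precursor)

  cp2 <- cleaveLeader(subtilin_precursor)
  expect_identical(cutRule(cp2), "PQ")
  expect_identical(coreSeq(cp2), subtilin_core)

  pk_prec <- paste0("MNNEDFNLDLIKISKENNSGASPK", nisinACore())
  cp3 <- cleaveLeader(pk_prec)
  expect_identical(cutRule(cp3), "PK")
  expect_identical(coreSeq(cp3), nisinACore())
})

test_that("motifs with unusable downstream segments fall through", {
  # GASPR present but downstream too short and too dissimilar to references
  prec <- paste0(strrep("M", 25), "GASPR", strrep("W", 10))
  cp <- cleaveLeader(prec)
  expect_identical(cutRule(cp), "unassigned")
  expect_identical(coreSeq(cp), prec)
  expect_identical(leaderSeq(cp), "")

  expect_error(cleaveLeader(strrep("M", 29)), "at least 30")
})

test_that("cut transfer from the nearest reference works for motif-free leaders", {
  # nisin A-like precursor whose leader lost its GASPR motif
  prec <- paste0("MSTKDFNLDLVSVSKKDSGAWTR", nisinACore())
  cp <- cleaveLeader(prec)
  expect_identical(cutRule(cp), "nearest_reference")
  expect_identical(coreSeq(cp), nisinACore())
  expect_false(is.na(cp@referenceUsed))
  expect_identical(paste0(leaderSeq(cp), coreSeq(cp)), prec)
})

test_that("exact dedup groups case-insensitively and is idempotent", {
  d <- dedupExact(c(a = "X", b = "x", c = "Y"))
  expect_identical(d$representative, c("a", "c"))
  expect_identical(d$n_members, c(2L, 1L))
  expect_identical(d$members[1], "a,b")

  expect_identical(nrow(dedupExact(character())), 0L)

  set.seed(77)
  base <- vapply(1:900, function(i) random_protein(25), character(1))
  dups <- sample(base, 100)
  all_seqs <- setNames(c(base, dups), paste0("s", 1:1000))
  d2 <- dedupExact(all_seqs)
  expect_identical(nrow(d2), 900L)

  # idempotence
  d3 <- dedupExact(setNames(d2$sequence, d2$representative))
  expect_identical(d3$sequence, d2$sequence)
})

test_that("scaffold alignment reads rings and hinge off the nisin A frame", {
  sa <- alignToScaffold(nisinACore())
  expect_true(all(sa$ring_feasibility))
  expect_identical(sa$hinge, "NMK")

  # breaking the ring E cysteine (position 28) spoils only ring E
  noE <- nisinACore()
  substr(noE, 28, 28) <- "A"
  sa2 <- alignToScaffold(noE)
  expect_false(sa2$ring_feasibility[["E"]])
  expect_true(all(sa2$ring_feasibility[c("A", "B", "C", "D")]))

  # C-terminal truncation removes rings D and E and the result aligns with
  # trailing gaps
  trunc <- substr(nisinACore(), 1, 22)
  sa3 <- alignToScaffold(trunc)
  expect_false(sa3$ring_feasibility[["D"]])
  expect_false(sa3$ring_feasibility[["E"]])

  expect_error(alignToScaffold("SHORT"), "outside")
})

test_that("mass ladders step by one water per dehydration", {
  ml <- massLadder(nisinACore(), 6:8)
  expect_identical(ml$entries$mass, c(3390, 3372, 3354))

  # n = 0 returns the unmodified mass
  ml0 <- massLadder(nisinACore(), 0)
  expect_identical(ml0$entries$mass, floor(ml0$unmodified_avg_mass + 0.5))

  # hand sum for the dipeptide ST with one dehydration
  expect_identical(massLadder("ST", 1)$entries$mass, 188)

  # strictly decreasing with constant step before rounding
  masses <- ml$unmodified_avg_mass - (6:8) * 18.0153
  expect_equal(unique(round(diff(masses), 4)), -18.0153)

  expect_error(massLadder("ST", 3), "exceeds")
  expect_error(massLadder("AAA", 1), "exceeds")
})

test_that("position composition measures conservation in bits", {
  pos <- positionComposition(rep(nisinACore(), 3))
  expect_true(all(abs(pos$information_bits - log2(20)) < 1e-9))
  expect_true(all(pos$n_distinct == 1))

  # two cores differing at one unconstrained position: that column carries
  # log2(20) - 1 bits (fair-coin entropy), the rest are untouched
  variant <- nisinACore()
  substr(variant, 4, 4) <- "V"
  pos2 <- positionComposition(c(nisinACore(), variant))
  expect_identical(sum(pos2$n_distinct == 2), 1L)
  expect_equal(pos2$information_bits[4], log2(20) - 1, tolerance = 1e-9)

  # column counts account for every non-gap sequence
  expect_true(all(colSums(pos2$counts) <= 2))
  expect_error(positionComposition("ITSIS"), "at least 2")
})
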