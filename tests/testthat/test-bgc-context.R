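# a small genome: focal core gene at 10 kb with machinery genes nearby and
# decoys further out
context_fixture <- function(include = c("lanB", "lanC", "lanI"),
                            fragment_lanB = FALSE) {
  refs <- machineryReferences()
  rows <- list(list(start = 10000L, end = 10120L, locus_tag = "core1",
                    translation = paste0("MSTKDFNLDLVSVSKKDSGASPR",
                                         nisinACore()),
                    product = "hypothetical protein"))
  pos <- 11000L
  for (cls in include) {
    prot <- as.character(refs[[cls]])
    if (cls == "lanB" && fragment_lanB) {
      half <- nchar(prot) %/% 2
      for (part in c(substr(prot, 1, half),
                     substr(prot, half + 1, nchar(prot)))) {
        len <- nchar(part) * 3L
        rows[[length(rows) + 1]] <- list(start = pos, end = pos + len - 1L,
                                         locus_tag = paste0(cls, "_frag", pos),
                                         translation = part,
                                         product = "hypothetical protein")
        pos <- pos + len + 100L
      }
      next
    }
    len <- nchar(prot) * 3L
    rows[[length(rows) + 1]] <- list(start = pos, end = pos + len - 1L,
                                     locus_tag = cls, translation = prot,
                                     product = "hypothetical protein")
    pos <- pos + len + 100L
  }
  set.seed(123)
  for (k in 1:5) {
    prot <- random_protein(150)
    rows[[length(rows) + 1]] <- list(start = pos, end = pos + 449L,
                                     locus_tag = paste0("decoy", k),
                                     translation = prot,
                                     product = "hypothetical protein")
    pos <- pos + 600L
  }
  genes <- do.call(rbind, lapply(rows, function(r) {
    data.frame(start = r$start, end = r$end, strand = "+", type = "CDS",
               locus_tag = r$locus_tag, product = r$product,
               translation = r$translation, stringsAsFactors = FALSE)
  }))
  make_annotation(genes, contig_len = 100000L)
}

test_that("neighborhood extraction respects window and side caps", {
  ga <- context_fixture()
  ctx <- extractContext(ga, "core1", windowKb = 30)
  expect_s4_class(ctx, "BGCContext")
  expect_true(all(is.na(machineryFlags(ctx))))
  # everything in the fixture lies within 30 kb
  expect_identical(length(ctx@windowFeatures), 8L)

  # a 1 kb window drops the distant decoys
  ctx_small <- extractContext(ga, "core1", windowKb = 1)
  expect_lt(length(ctx_small@windowFeatures), 8L)

  # side cap: keep only the nearest CDS downstream
  ctx_cap <- extractContext(ga, "core1", maxCdsEachSide = 1)
  expect_identical(length(ctx_cap@windowFeatures), 1L)
  expect_identical(ctx_cap@windowFeatures$locus_tag, "lanB")

  expect_error(extractContext(ga, "nope"), "matches 0")
})

test_that("window clips at the contig start without error", {
  genes <- data.frame(start = c(50L, 500L), end = c(250L, 700L),
                      strand = "+", type = "CDS",
                      locus_tag = c("edge", "nbr"),
                      product = "hypothetical protein",
                      translation = c("MAAAA", "MCCCC"),
                      stringsAsFactors = FALSE)
  ga <- make_annotation(genes, contig_len = 10000L)
  ctx <- extractContext(ga, "edge", windowKb = 5)
  expect_identical(ctx@windowFeatures$locus_tag, "nbr")
})

test_that("machinery classification recovers planted genes exactly", {
  ga <- context_fixture(include = c("lanB", "lanC", "lanI", "lanT", "lanP"))
  ctx <- classifyMachinery(extractContext(ga, "core1"))
  fl <- machineryFlags(ctx)
  expect_true(all(fl[c("lanB", "lanC", "lanI", "lanT", "lanP")]))
  expect_false(any(fl[c("lanF", "lanE", "lanG", "lanR", "lanK")]))
  expect_false(isOrphan(ctx))
  expect_true(completeBCI(ctx))
  # per-gene assignments recorded, decoys unassigned
  cls <- ctx@windowFeatures$machinery_class
  expect_identical(sum(!is.na(cls)), 5L)

  # determinism: flags identical across runs
  ctx2 <- classifyMachinery(extractContext(ga, "core1"))
  expect_identical(machineryFlags(ctx2), fl)
})

test_that("a context of decoys only is an orphan", {
  ga <- context_fixture(include = character())
  ctx <- classifyMachinery(extractContext(ga, "core1"))
  expect_true(isOrphan(ctx))
  expect_false(completeBCI(ctx))
  expect_false(any(machineryFlags(ctx)))
})

test_that("an interrupted lanB gene drops below the coverage floor", {
  ga <- context_fixture(include = c("lanB", "lanC", "lanI"),
                        fragment_lanB = TRUE)
  ctx <- classifyMachinery(extractContext(ga, "core1"))
  fl <- machineryFlags(ctx)
  expect_false(fl[["lanB"]])
  expect_true(fl[["lanC"]])
  expect_true(isOrphan(ctx))
  expect_false(completeBCI(ctx))
})

test_that("synteny links report shared proteins above the identity floor", {
  ga <- context_fixture(include = c("lanB", "lanC"))
  ctx <- classifyMachinery(extractContext(ga, "core1"))
  links_self <- operonSyntenyLinks(ctx, ctx)
  self_pairs <- links_self[links_self$locus_a == links_self$locus_b, ]
  expect_true(all(self_pairs$identity_pct == 100))
  expect_setequal(self_pairs$locus_a,
                  c("core1", "lanB", "lanC", paste0("decoy", 1:5)))

  # an impossible threshold empties the table
  expect_identical(nrow(operonSyntenyLinks(ctx, ctx,
                                           minIdentityPct = 101)), 0L)
})
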