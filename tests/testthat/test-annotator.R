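suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Small hand-built feature set: miRNA (tier 1), CDS + collinear (tier 1),
## gene - antisense (tier 2), intron (tier 3).
toyIndex <- function() {
  f <- GRanges("chr1",
               IRanges(c(100L, 150L, 100L, 400L), c(130L, 260L, 500L, 500L)),
               strand = c("+", "+", "+", "+"))
  mcols(f) <- S4Vectors::DataFrame(
    feature_id = c("mir1", "g1", "g1", "g1"),
    class_label = c("miRNA", "CDS (+)", "gene (-)", "intron"),
    origin = c("primary", "primary", "primary", "intron"),
    tier = c(1L, 1L, 2L, 3L),
    orientation = c("any", "collinear", "antisense", "any"))
  buildIndex(f, binWidth = 256L)
}

test_that("annotateHit keeps only the minimal tier and applies orientation", {
  idx <- toyIndex()
  ## miRNA (tier 1) beats intron (tier 3)
  a <- annotateHit(idx, "chr1", 420L, 440L, "+")
  expect_equal(a$tier, 3L)   # only intron overlaps here
  a <- annotateHit(idx, "chr1", 120L, 160L, "+")
  expect_equal(a$tier, 1L)
  expect_setequal(a$matches$class_label, c("miRNA", "CDS (+)"))  # same tier: ambiguous hit
  ## antisense read: CDS + fails orientation, gene - qualifies
  a <- annotateHit(idx, "chr1", 200L, 220L, "-")
  expect_equal(a$tier, 2L)
  expect_equal(a$matches$class_label, "gene (-)")
  ## intergenic
  a <- annotateHit(idx, "chr1", 900L, 920L, "+")
  expect_true(is.na(a$tier))
  expect_equal(nrow(a$matches), 0L)
})

test_that("annotateHit honours the overlap threshold", {
  idx <- toyIndex()
  ## read overlaps miRNA by 6 nt
  a <- annotateHit(idx, "chr1", 125L, 144L, "+", readLength = 20L,
                   threshold = "10nt")
  expect_false("miRNA" %in% a$matches$class_label)
  a <- annotateHit(idx, "chr1", 125L, 144L, "+", readLength = 20L,
                   threshold = "5nt")
  expect_true("miRNA" %in% a$matches$class_label)
})

test_that("mergeLabel canonicalizes independently of input order", {
  expect_equal(mergeLabel(c("miRNA", "CDS (+)")), "CDS (+)--miRNA")
  expect_equal(mergeLabel(c("a", "b")), mergeLabel(c("b", "a")))
  set.seed(51)
  for (i in 1:20) {
    labs <- sample(letters, sample(2:6, 1L))
    ref <- mergeLabel(labs)
    for (j in 1:5) expect_equal(mergeLabel(sample(labs)), ref)
  }
})

hitAnn <- function(tier, ...) {
  m <- list(...)
  list(tier = tier,
       matches = data.frame(class_label = vapply(m, `[`, character(1), 1L),
                            feature_id = vapply(m, `[`, character(1), 2L),
                            stringsAsFactors = FALSE))
}
intergenic <- list(tier = NA_integer_,
                   matches = data.frame(class_label = character(0),
                                        feature_id = character(0)))

test_that("resolveRead covers rescue, merging and intergenic-hit dropping", {
  ## both hits on miRNA copies: rescued
  r <- resolveRead(list(hitAnn(1L, c("miRNA", "mirD1")),
                        hitAnn(1L, c("miRNA", "mirD2"))))
  expect_equal(r$label, "miRNA")
  expect_equal(r$status, "rescued")
  expect_equal(r$features, c("mirD1", "mirD2"))

  ## hits on 3'UTR and miRNA at the same tier: merged, ambiguous
  r <- resolveRead(list(hitAnn(1L, c("3'UTR (+)", "g1")),
                        hitAnn(1L, c("miRNA", "mirF"))))
  expect_equal(r$label, "3'UTR (+)--miRNA")
  expect_equal(r$status, "ambiguous")

  ## one annotated hit plus an intergenic hit: rescued to the annotation
  r <- resolveRead(list(hitAnn(1L, c("5'UTR", "g1")), intergenic))
  expect_equal(r$label, "5'UTR")
  expect_equal(r$status, "rescued")

  ## all hits intergenic: unannotated
  r <- resolveRead(list(intergenic, intergenic))
  expect_equal(r$label, "unannotated")
  expect_equal(r$status, "unannotated")

  ## single unambiguous hit: unique
  r <- resolveRead(list(hitAnn(1L, c("miRNA", "mir1"))))
  expect_equal(r$status, "unique")
})

test_that("cross-hit tier minimization resolves to the higher class as rescued", {
  r <- resolveRead(list(hitAnn(1L, c("miRNA", "mir1")),
                        hitAnn(3L, c("intron", "g1"))))
  expect_equal(r$label, "miRNA")
  expect_equal(r$status, "rescued")
})

test_that("a read hitting the same feature twice counts it once", {
  r <- resolveRead(list(hitAnn(1L, c("miRNA", "mir1")),
                        hitAnn(1L, c("miRNA", "mir1"))))
  expect_equal(r$label, "miRNA")
  expect_equal(r$features, "mir1")
})

test_that("an ambiguous single hit yields a merged label regardless of n", {
  r <- resolveRead(list(hitAnn(1L, c("CDS (+)", "g1"), c("miRNA", "mirE"))))
  expect_equal(r$label, "CDS (+)--miRNA")
  expect_equal(r$status, "ambiguous")
})

test_that("strategies weight reads as specified", {
  two <- list(hitAnn(1L, c("miRNA", "m1")), hitAnn(1L, c("snoRNA", "s1")))

  d <- applyStrategy("default", two)
  expect_equal(d$weight, 1)
  expect_equal(d$label, "miRNA--snoRNA")

  u <- applyStrategy("unique", two)
  expect_equal(u$label, "multi-mapping (discarded)")
  expect_equal(u$weight, 1)
  u1 <- applyStrategy("unique", two[1], n = 1L)
  expect_equal(u1$label, "miRNA")

  rt <- applyStrategy("ratio", two)
  expect_equal(rt$weight, c(0.5, 0.5))
  expect_setequal(rt$label, c("miRNA", "snoRNA"))
  rt <- applyStrategy("ratio", list(two[[1]], intergenic))
  expect_equal(sum(rt$weight), 1)   # intergenic share lost to unannotated
  expect_setequal(rt$label, c("miRNA", "unannotated"))

  expect_error(applyStrategy("best", two), "unknown counting strategy")
})

test_that("random strategy draws hits uniformly", {
  two <- list(hitAnn(1L, c("miRNA", "m1")), hitAnn(1L, c("snoRNA", "s1")))
  set.seed(52)
  picks <- vapply(1:10000, function(i) applyStrategy("random", two)$label,
                  character(1))
  k <- sum(picks == "miRNA")
  ## binomial(10000, 1/2): 5000 +/- 3 sigma = 150
  expect_true(abs(k - 5000) <= 150)
  ## an intergenic draw yields unannotated
  set.seed(53)
  picks <- vapply(1:200, function(i)
    applyStrategy("random", list(two[[1]], intergenic))$label, character(1))
  expect_setequal(unique(picks), c("miRNA", "unannotated"))
})

test_that("every strategy conserves one unit of weight per read", {
  set.seed(54)
  for (i in 1:50) {
    n <- sample(1:4, 1L)
    anns <- lapply(seq_len(n), function(j) {
      if (stats::runif(1) < 0.3) intergenic
      else hitAnn(sample(1:3, 1L),
                  c(sample(c("miRNA", "snoRNA", "tRNA"), 1L),
                    paste0("f", sample(1:5, 1L))))
    })
    for (s in c("default", "unique", "random", "ratio")) {
      cb <- applyStrategy(s, anns)
      expect_equal(sum(cb$weight), 1, tolerance = 1e-12)
    }
  }
})

test_that("duplicated-feature rescue never discards or splits under default", {
  set.seed(55)
  for (i in 1:20) {
    k <- sample(2:4, 1L)
    anns <- lapply(seq_len(k), function(j)
      hitAnn(1L, c("miRNA", paste0("copy", j))))
    cb <- applyStrategy("default", anns)
    expect_equal(cb$label, "miRNA")
    expect_equal(cb$weight, 1)
    expect_equal(cb$status, "rescued")
  }
})
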