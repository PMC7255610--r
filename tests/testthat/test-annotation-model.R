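suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

test_that("readGtf maps GTF fields and attributes onto records", {
  p <- writeTemp('chr1\t.\tmiRNA\t100\t120\t.\t+\t.\tgene_id "mirA";', ".gtf")
  r <- readGtf(p)
  expect_length(r, 1L)
  expect_equal(as.character(seqnames(r)), "chr1")
  expect_equal(start(r), 100L)
  expect_equal(end(r), 120L)
  expect_equal(as.character(strand(r)), "+")
  expect_equal(mcols(r)$source, ".")
  expect_equal(mcols(r)$feature, "miRNA")
  expect_equal(mcols(r)$gene_id, "mirA")
})

test_that("readGtf handles empty files and rejects malformed lines by number", {
  expect_length(readGtf(writeTemp(character(0), ".gtf")), 0L)
  expect_length(readGtf(writeTemp("# only a comment", ".gtf")), 0L)

  bad <- c('chr1\t.\texon\t100\t200\t.\t+\t.\tgene_id "g";',
           'chr1\t.\texon\t300\t200\t.\t+\t.\tgene_id "g";')
  expect_error(readGtf(writeTemp(bad, ".gtf")), "line 2.*start")
  expect_error(readGtf(writeTemp("chr1\t.\texon\t1\t2", ".gtf")), "line 1.*9")
  expect_error(readGtf(writeTemp('chr1\t.\texon\tx\t2\t.\t+\t.\ta "b";', ".gtf")),
               "line 1.*integer")
  expect_error(readGtf(writeTemp('chr1\t.\texon\t1\t2\t.\t.\t.\ta "b";', ".gtf")),
               "line 1.*strand")
})

test_that("GTF records survive a write/read round trip", {
  gtf <- c('chr1\t.\texon\t100\t200\t.\t+\t.\tgene_id "g1";',
           'chr1\t.\texon\t300\t400\t.\t+\t.\tgene_id "g1";',
           'chr1\t.\tCDS\t150\t200\t.\t+\t.\tgene_id "g1";',
           'chr2\thavana\tmiRNA\t50\t70\t.\t-\t.\tgene_id "m1";',
           'chr2\t.\tsnoRNA\t500\t600\t.\t+\t.\tgene_id "s1";')
  r1 <- readGtf(writeTemp(gtf, ".gtf"))
  expect_length(r1, 5L)
  p2 <- tempfile(fileext = ".gtf")
  writeGtf(r1, p2)
  r2 <- readGtf(p2)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("reconstructGenes groups, merges and validates exons", {
  gtf <- c('chr1\t.\texon\t100\t200\t.\t+\t.\tgene_id "g1";',
           'chr1\t.\texon\t300\t400\t.\t+\t.\tgene_id "g1";',
           'chr1\t.\texon\t150\t250\t.\t+\t.\tgene_id "g2";',
           'chr1\t.\texon\t100\t200\t.\t+\t.\tgene_id "g2";')
  g <- reconstructGenes(readGtf(writeTemp(gtf, ".gtf")))
  expect_setequal(names(g), c("g1", "g2"))
  expect_equal(start(g$g1$exons), c(100L, 300L))
  ## overlapping exons merged
  expect_equal(as.data.frame(g$g2$exons)[, c("start", "end")],
               data.frame(start = 100L, end = 250L))

  mixed <- c('chr1\t.\texon\t100\t200\t.\t+\t.\tgene_id "g1";',
             'chr1\t.\texon\t300\t400\t.\t-\t.\tgene_id "g1";')
  expect_error(reconstructGenes(readGtf(writeTemp(mixed, ".gtf"))),
               "mixed strands")

  noid <- 'chr1\t.\texon\t100\t200\t.\t+\t.\tName "x";'
  expect_error(reconstructGenes(readGtf(writeTemp(noid, ".gtf"))), "gene_id")
})

test_that("gene exon unions equal a brute-force per-id union on random records", {
  set.seed(11)
  for (rep in 1:5) {
    ids <- sample(paste0("g", 1:5), 50, replace = TRUE)
    s <- sample.int(5000L, 50, replace = TRUE)
    e <- s + sample.int(300L, 50, replace = TRUE) - 1L
    gtf <- sprintf('chr1\t.\texon\t%d\t%d\t.\t+\t.\tgene_id "%s";', s, e, ids)
    g <- reconstructGenes(readGtf(writeTemp(gtf, ".gtf")))
    for (id in unique(ids)) {
      expected <- sort(unique(unlist(mapply(function(a, b) a:b,
                                            s[ids == id], e[ids == id],
                                            SIMPLIFY = FALSE))))
      expect_identical(basesOf(g[[id]]$exons), expected)
    }
  }
})

test_that("introns are the gaps between merged exons", {
  g <- list(gene_id = "g", strand = "+",
            exons = GRanges("chr1", IRanges(c(100L, 301L), c(200L, 400L)), "+"),
            cds = GRanges())
  intr <- inferIntrons(g)
  expect_equal(as.data.frame(intr)[, c("start", "end")],
               data.frame(start = 201L, end = 300L))

  single <- list(gene_id = "g", strand = "+",
                 exons = GRanges("chr1", IRanges(100L, 400L), "+"),
                 cds = GRanges())
  expect_length(inferIntrons(single), 0L)
})

test_that("intron/exon complementarity holds per base on random genes", {
  set.seed(12)
  for (i in 1:100) {
    g <- randomGeneModel()
    intr <- inferIntrons(g)
    exB <- basesOf(g$exons)
    inB <- basesOf(intr)
    expect_length(intersect(exB, inB), 0L)
    span <- min(exB):max(exB)
    expect_identical(sort(c(exB, inB)), span)
  }
})

test_that("UTR inference is strand-aware and partitions the exon union", {
  plus <- list(gene_id = "g", strand = "+",
               exons = GRanges("chr1", IRanges(100L, 400L), "+"),
               cds = GRanges("chr1", IRanges(150L, 350L), "+"))
  u <- inferUtrs(plus)
  expect_equal(c(start(u$five_utr), end(u$five_utr)), c(100L, 149L))
  expect_equal(c(start(u$three_utr), end(u$three_utr)), c(351L, 400L))

  minus <- plus
  minus$strand <- "-"
  strand(minus$exons) <- "-"; strand(minus$cds) <- "-"
  u <- inferUtrs(minus)
  expect_equal(c(start(u$five_utr), end(u$five_utr)), c(351L, 400L))
  expect_equal(c(start(u$three_utr), end(u$three_utr)), c(100L, 149L))

  bad <- plus
  bad$cds <- GRanges("chr1", IRanges(150L, 500L), "+")
  expect_error(inferUtrs(bad), "outside its exon union")
  noncoding <- plus; noncoding$cds <- GRanges()
  expect_error(inferUtrs(noncoding), "no CDS")
})

test_that("5'UTR + CDS + 3'UTR partition matches per-base classification on random genes", {
  set.seed(13)
  for (i in 1:60) {
    g <- randomGeneModel(withCds = TRUE)
    u <- inferUtrs(g)
    exB <- basesOf(g$exons)
    cdB <- basesOf(g$cds)
    ## brute-force: classify each exonic base by position vs CDS extremes
    lo <- min(cdB); hi <- max(cdB)
    left <- exB[exB < lo]; right <- exB[exB > hi]
    if (g$strand == "+") {
      expect_identical(basesOf(u$five_utr), left)
      expect_identical(basesOf(u$three_utr), right)
    } else {
      expect_identical(basesOf(u$five_utr), right)
      expect_identical(basesOf(u$three_utr), left)
    }
    expect_identical(sort(c(basesOf(u$five_utr), cdB, basesOf(u$three_utr))),
                     exB)
  }
})

test_that("vicinity regions abut the feature, mirror with strand, and clip", {
  gp <- GRanges("chr1", IRanges(5000L, 6000L), "+")
  v <- makeVicinity(gp, 3000L)
  expect_equal(c(start(v$upstream), end(v$upstream)), c(2000L, 4999L))
  expect_equal(c(start(v$downstream), end(v$downstream)), c(6001L, 9000L))

  gm <- GRanges("chr1", IRanges(5000L, 6000L), "-")
  v <- makeVicinity(gm, 3000L)
  expect_equal(c(start(v$upstream), end(v$upstream)), c(6001L, 9000L))
  expect_equal(c(start(v$downstream), end(v$downstream)), c(2000L, 4999L))

  near <- GRanges("chr1", IRanges(100L, 300L), "+")
  v <- makeVicinity(near, 3000L)
  expect_equal(c(start(v$upstream), end(v$upstream)), c(1L, 99L))

  v <- makeVicinity(gp, 3000L, seqlengths = c(chr1 = 7000L))
  expect_equal(end(v$downstream), 7000L)
})

test_that("buildFeatureSet assembles primary and derived features for the worked example", {
  fx <- fig9Fixture()
  rec <- readGtf(writeTemp(fx$gtf, ".gtf"))
  cfg <- parseConfig(fx$config)
  fs <- buildFeatureSet(rec, cfg)
  lab <- mcols(fs)$class_label
  expect_equal(sum(lab == "miRNA"), 5L)
  expect_equal(sum(lab == "CDS (+)"), 2L)     # split CDS: two intervals
  expect_equal(sum(lab == "5'UTR"), 1L)
  expect_equal(sum(lab == "3'UTR (+)"), 1L)
  expect_equal(sum(lab == "gene (-)"), 1L)
  expect_equal(sum(lab == "intron"), 1L)
  expect_equal(sum(lab == "upstream"), 1L)
  expect_equal(sum(lab == "downstream"), 1L)
  ## derived features carry the parent gene id
  expect_true(all(mcols(fs)$feature_id[mcols(fs)$origin != "primary"] == "g1"))
  ## top tier shares rank 1
  expect_setequal(mcols(fs)$tier[lab %in% c("miRNA", "CDS (+)", "5'UTR", "3'UTR (+)")],
                  1L)
})

test_that("empty Introns/Vicinity sections yield only primary features", {
  fx <- fig9Fixture()
  rec <- readGtf(writeTemp(fx$gtf, ".gtf"))
  cfg <- parseConfig("Order:\nmiRNA .:CDS +\n")
  fs <- buildFeatureSet(rec, cfg)
  expect_setequal(unique(mcols(fs)$origin), "primary")
  expect_setequal(unique(mcols(fs)$class_label), c("miRNA", "CDS (+)"))
})

test_that("buildFeatureSet is invariant under record order", {
  fx <- fig9Fixture()
  rec <- readGtf(writeTemp(fx$gtf, ".gtf"))
  cfg <- parseConfig(fx$config)
  ref <- buildFeatureSet(rec, cfg)
  set.seed(14)
  for (i in 1:5) {
    shuf <- buildFeatureSet(rec[sample(length(rec))], cfg)
    expect_equal(as.data.frame(ref), as.data.frame(shuf))
  }
})

test_that("an Order selector matching nothing warns instead of failing", {
  rec <- readGtf(writeTemp('chr1\t.\tmiRNA\t100\t120\t.\t+\t.\tgene_id "m";', ".gtf"))
  expect_warning(fs <- buildFeatureSet(rec, parseConfig("Order:\nmiRNA\npiRNA\n")),
                 "piRNA")
  expect_equal(unique(mcols(fs)$class_label), "miRNA")
})
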