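## Shared helpers: temp-file plumbing, independent oracles and small random
## generators used across the suite.

writeTemp <- function(text, ext) {
  p <- tempfile(fileext = ext)
  writeLines(text, p)
  p
}

## Materialize the worked-example fixture on disk.
fig9OnDisk <- function() {
  fx <- fig9Fixture()
  list(fx = fx,
       gtf = writeTemp(fx$gtf, ".gtf"),
       cfg = writeTemp(fx$config, ".cfg"),
       sam = writeTemp(fx$sam, ".sam"))
}

simOnDisk <- function(...) {
  sim <- simulateDataset(...)
  list(sim = sim,
       gtf = writeTemp(sim$gtf, ".gtf"),
       cfg = writeTemp(sim$config, ".cfg"),
       sam = writeTemp(sim$sam, ".sam"))
}

## Independent CIGAR reference-consumed length: M/D/N/=/X consume reference.
cigarRefLenOracle <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## Random feature set for index tests.
randomFeatures <- function(n, chroms = c("chr1", "chr2"), maxPos = 50000L,
                           maxLen = 400L) {
  s <- sample.int(maxPos, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(s, s + sample.int(maxLen, n, replace = TRUE) - 1L),
                         strand = sample(c("+", "-"), n, replace = TRUE))
}

## All-pairs overlap oracle, independent of the binned index.
bruteOverlaps <- function(features, chrom, start, end) {
  fc <- as.character(GenomicRanges::seqnames(features))
  fs <- GenomicRanges::start(features)
  fe <- GenomicRanges::end(features)
  ov <- pmin(fe, end) - pmax(fs, start) + 1L
  keep <- fc == chrom & ov >= 1L
  data.frame(index = which(keep), overlap = ov[keep])
}

## Random gene model (reduced exons + optional CDS inside the exon union).
randomGeneModel <- function(id = "g", minExons = 2L, maxExons = 6L,
                            withCds = FALSE) {
  k <- sample(minExons:maxExons, 1L)
  starts <- cumsum(sample(50:300, k)) + cumsum(c(0L, rep(0L, k - 1L)))
  lens <- sample(30:200, k, replace = TRUE)
  s <- 1000L + cumsum(sample(100:400, k))
  e <- s + lens - 1L
  ## force gaps: shift each exon after the previous end
  for (i in seq_len(k)[-1]) {
    if (s[i] <= e[i - 1] + 1L) {
      shift <- e[i - 1] + 2L + sample.int(200L, 1L) - s[i]
      s[i] <- s[i] + shift
      e[i] <- e[i] + shift
    }
  }
  strand <- sample(c("+", "-"), 1L)
  exons <- GenomicRanges::reduce(GenomicRanges::GRanges("chrT",
                                                        IRanges::IRanges(s, e),
                                                        strand))
  cds <- GenomicRanges::GRanges()
  if (withCds) {
    ## CDS: exonic bases between two cut points of the exon union
    bases <- unlist(lapply(seq_along(exons), function(i)
      GenomicRanges::start(exons)[i]:GenomicRanges::end(exons)[i]))
    cuts <- sort(sample(seq_along(bases), 2L))
    if (cuts[1] == 1L) cuts[1] <- 2L           # leave room for a 5' UTR
    if (cuts[2] == length(bases)) cuts[2] <- length(bases) - 1L
    cdsBases <- bases[cuts[1]:cuts[2]]
    r <- IRanges::reduce(IRanges::IRanges(cdsBases, cdsBases))
    cds <- GenomicRanges::GRanges("chrT", r, strand)
  }
  list(gene_id = id, strand = strand, exons = exons, cds = cds)
}

## Integer base set of a GRanges (small test genes only).
basesOf <- function(gr) {
  if (length(gr) == 0L) return(integer(0))
  sort(unlist(lapply(seq_along(gr), function(i)
    GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i])))
}

## Name-grouped random SAM without NH tags (bowtie-style), plus the expected
## per-read hit counts.
makeRandomSam <- function(nReads, maxHits = 4L, chromLength = 100000L,
                          readLength = 20L, unmappedFraction = 0) {
  ids <- sprintf("q%04d", sample(seq_len(nReads)))  # random read order
  recs <- character(0)
  counts <- integer(0)
  for (id in ids) {
    if (stats::runif(1) < unmappedFraction) {
      recs <- c(recs, paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                            strrep("A", readLength), "*", sep = "\t"))
      counts[id] <- 0L
      next
    }
    k <- sample.int(maxHits, 1L)
    pos <- sample.int(chromLength - readLength, k)
    fl <- c(0L, rep(256L, k - 1L)) + sample(c(0L, 16L), k, replace = TRUE)
    recs <- c(recs, paste(id, fl, "chrS", pos, 255L,
                          paste0(readLength, "M"), "*", 0L, 0L,
                          strrep("A", readLength), "*", sep = "\t"))
    counts[id] <- k
  }
  list(lines = c("@HD\tVN:1.6", sprintf("@SQ\tSN:chrS\tLN:%d", chromLength),
                 recs),
       counts = counts)
}
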