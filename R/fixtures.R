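## Synthetic inputs for testing and benchmarking: a hand-laid worked example
## covering every resolution case (unique, antisense, priority, rescue via
## duplication, same-locus ambiguity, cross-hit ambiguity, rescue via an
## intergenic hit), and a parameterized simulator with ground truth.

.samHeader <- function(chromLengths) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths), chromLengths))
}

.samRecord <- function(qname, flag, chrom, pos, cigar, seq, nh) {
  paste(qname, flag, chrom, pos, 255L, cigar, "*", 0L, 0L, seq, "*",
        paste0("NH:i:", nh), sep = "\t")
}

.randSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

#' Worked-example fixture: one coding gene and five miRNAs
#'
#' Builds a small scenario exercising every branch of the read-resolution
#' method on one `+`-strand coding gene (two exons, split CDS, hence inferred
#' 5'/3' UTRs, one intron, and ±3 kb vicinity regions) and five miRNAs, with
#' seven reads:
#'
#' * `A` maps once, only on the gene's upstream region;
#' * `B` maps once, antisense within the CDS (caught by the `gene -` class);
#' * `C` maps once on a miRNA inside the intron (priority resolves it);
#' * `D` maps twice, both hits on duplicated miRNA copies (rescued);
#' * `E` maps once where a miRNA overlaps the CDS (equal priority: merged);
#' * `F` maps twice, once on the 3' UTR and once on a miRNA (merged);
#' * `G` maps twice, once on the 5' UTR and once intergenic (rescued).
#'
#' The configuration puts miRNA, `.:CDS +`, `5'UTR` and `3'UTR +` on the top
#' tier, then `gene -`, `intron`, `upstream`, `downstream`.
#'
#' @return list with elements `gtf`, `config`, `sam` (input texts),
#'   `expected` (data frame `read_id`, `label`, `status`),
#'   `expectedClassCounts` (named numeric), `expectedRescued` (integer) and
#'   `chromLength`.
#' @export
fig9Fixture <- function() {
  gtf <- c(
    'chr1\t.\texon\t1001\t3000\t.\t+\t.\tgene_id "g1";',
    'chr1\t.\texon\t4001\t6000\t.\t+\t.\tgene_id "g1";',
    'chr1\t.\tCDS\t1501\t3000\t.\t+\t.\tgene_id "g1";',
    'chr1\t.\tCDS\t4001\t5500\t.\t+\t.\tgene_id "g1";',
    'chr1\t.\tmiRNA\t2001\t2100\t.\t+\t.\tgene_id "mirE";',
    'chr1\t.\tmiRNA\t3201\t3300\t.\t+\t.\tgene_id "mirC";',
    'chr1\t.\tmiRNA\t9501\t9600\t.\t+\t.\tgene_id "mirD1";',
    'chr1\t.\tmiRNA\t10501\t10600\t.\t+\t.\tgene_id "mirD2";',
    'chr1\t.\tmiRNA\t12001\t12100\t.\t+\t.\tgene_id "mirF";')

  config <- c("Introns:", "gene", "",
              "Vicinity:", "gene", "",
              "Order:",
              "miRNA .:CDS + 5'UTR 3'UTR +",
              "gene -",
              "intron",
              "upstream",
              "downstream")

  chromLength <- c(chr1 = 20000L)
  seq20 <- strrep("ACGTA", 4L)
  sam <- c(.samHeader(chromLength),
           .samRecord("A", 0L, "chr1", 501L, "20M", seq20, 1L),
           .samRecord("B", 16L, "chr1", 2401L, "20M", seq20, 1L),
           .samRecord("C", 0L, "chr1", 3221L, "20M", seq20, 1L),
           .samRecord("D", 0L, "chr1", 9541L, "20M", seq20, 2L),
           .samRecord("D", 256L, "chr1", 10541L, "20M", seq20, 2L),
           .samRecord("E", 0L, "chr1", 2021L, "20M", seq20, 1L),
           .samRecord("F", 0L, "chr1", 5601L, "20M", seq20, 2L),
           .samRecord("F", 256L, "chr1", 12021L, "20M", seq20, 2L),
           .samRecord("G", 0L, "chr1", 1101L, "20M", seq20, 2L),
           .samRecord("G", 256L, "chr1", 15001L, "20M", seq20, 2L))

  expected <- data.frame(
    read_id = c("A", "B", "C", "D", "E", "F", "G"),
    label = c("upstream", "gene (-)", "miRNA", "miRNA",
              "CDS (+)--miRNA", "3'UTR (+)--miRNA", "5'UTR"),
    status = c("unique", "unique", "unique", "rescued",
               "ambiguous", "ambiguous", "rescued"),
    stringsAsFactors = FALSE)

  expectedClassCounts <- c("upstream" = 1, "gene (-)" = 1, "miRNA" = 2,
                           "CDS (+)--miRNA" = 1, "3'UTR (+)--miRNA" = 1,
                           "5'UTR" = 1)

  list(gtf = paste(gtf, collapse = "\n"),
       config = paste(config, collapse = "\n"),
       sam = paste(sam, collapse = "\n"),
       expected = expected,
       expectedClassCounts = expectedClassCounts,
       expectedRescued = 2L,
       chromLength = chromLength)
}

#' Simulate an annotated genome and a perfectly mapped read set
#'
#' Generates a toy genome layout with non-overlapping loci for several
#' small-RNA classes, duplicates a configurable subset of loci verbatim
#' elsewhere on the chromosome (so reads drawn from them multi-map to all
#' copies at the same offset), and emits reads with correct NH tags plus a
#' ground-truth table. Reads map perfectly (no mismatches): the method is
#' mapping-agnostic, so error models are deliberately out of scope. Output
#' is deterministic given `seed`.
#'
#' @param nReads number of reads.
#' @param classes character vector of class names (GTF feature values).
#' @param nLociPerClass base (pre-duplication) loci per class.
#' @param dupFraction fraction of base loci duplicated verbatim.
#' @param dupCopies integer vector of total copy numbers drawn for duplicated
#'   loci (e.g. `2:3`).
#' @param readLength read length (nt).
#' @param intergenicFraction fraction of reads drawn from unannotated gaps.
#' @param antisenseFraction fraction of locus reads drawn antisense.
#' @param seed RNG seed.
#' @return list with elements `gtf`, `config`, `sam` (texts), `truth` (data
#'   frame `read_id`, `true_class`, `true_feature`, `n_hits`; intergenic
#'   reads have class `"intergenic"`), and `chromLength`.
#' @export
simulateDataset <- function(nReads = 1000L,
                            classes = c("miRNA", "snoRNA", "snRNA", "tRNA"),
                            nLociPerClass = 25L,
                            dupFraction = 0.3,
                            dupCopies = 2:3,
                            readLength = 21L,
                            intergenicFraction = 0.05,
                            antisenseFraction = 0,
                            seed = 1L) {
  stopifnot(nReads >= 1L, length(classes) >= 1L, readLength >= 1L)
  set.seed(as.integer(seed))

  nBase <- length(classes) * nLociPerClass
  lociClass <- rep(classes, each = nLociPerClass)
  lociLen <- sample(60:150, nBase, replace = TRUE)
  lociStrand <- sample(c("+", "-"), nBase, replace = TRUE)
  baseId <- sprintf("L%04d_%s", seq_len(nBase), lociClass)

  nDup <- floor(dupFraction * nBase)
  dupIdx <- if (nDup) sort(sample.int(nBase, nDup)) else integer(0)
  copies <- rep(1L, nBase)
  if (nDup) copies[dupIdx] <- dupCopies[sample.int(length(dupCopies), nDup,
                                                   replace = TRUE)]

  ## sequential placement with random gaps: collisions are impossible
  placements <- data.frame(base = rep(seq_len(nBase), copies))
  ord <- sample(nrow(placements))          # interleave copies along the genome
  placements <- placements[ord, , drop = FALSE]
  gaps <- sample(300:1000, nrow(placements), replace = TRUE)
  len <- lociLen[placements$base]
  placements$start <- cumsum(gaps) + cumsum(c(0L, utils::head(len, -1L)))
  placements$end <- placements$start + len - 1L
  copyOrd <- stats::ave(placements$base, placements$base, FUN = seq_along)
  placements$id <- ifelse(copies[placements$base] == 1L,
                          baseId[placements$base],
                          sprintf("%s_copy%d", baseId[placements$base], copyOrd))
  chromLength <- max(placements$end) + 1000L

  gtf <- sprintf('sim1\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                 lociClass[placements$base], placements$start, placements$end,
                 lociStrand[placements$base], placements$id)

  config <- c("Order:", classes)

  ## intergenic gap segments with a read-length margin away from any locus
  po <- order(placements$start)
  gapStart <- c(1L, placements$end[po] + readLength)
  gapEnd <- c(placements$start[po] - readLength, chromLength) - readLength + 1L
  okGap <- gapEnd >= gapStart
  gapStart <- gapStart[okGap]; gapEnd <- gapEnd[okGap]

  placByBase <- split(seq_len(nrow(placements)), placements$base)

  isInter <- stats::runif(nReads) < intergenicFraction
  srcLocus <- sample.int(nBase, nReads, replace = TRUE)
  samRec <- vector("list", nReads)
  truth <- data.frame(read_id = sprintf("r%05d", seq_len(nReads)),
                      true_class = ifelse(isInter, "intergenic",
                                          lociClass[srcLocus]),
                      true_feature = ifelse(isInter, NA_character_,
                                            baseId[srcLocus]),
                      n_hits = 1L, stringsAsFactors = FALSE)

  for (i in seq_len(nReads)) {
    rid <- truth$read_id[i]
    seq <- .randSeq(readLength)
    if (isInter[i]) {
      g <- sample.int(length(gapStart), 1L)
      pos <- gapStart[g] + sample.int(gapEnd[g] - gapStart[g] + 1L, 1L) - 1L
      samRec[[i]] <- .samRecord(rid, 0L, "sim1", pos,
                                paste0(readLength, "M"), seq, 1L)
      next
    }
    b <- srcLocus[i]
    offset <- sample.int(lociLen[b] - readLength + 1L, 1L) - 1L
    anti <- stats::runif(1) < antisenseFraction
    rs <- if (anti) setdiff(c("+", "-"), lociStrand[b]) else lociStrand[b]
    flagBase <- if (rs == "-") 16L else 0L
    pl <- placByBase[[as.character(b)]]
    truth$n_hits[i] <- length(pl)
    samRec[[i]] <- vapply(seq_along(pl), function(k) {
      .samRecord(rid,
                 flagBase + if (k > 1L) 256L else 0L,
                 "sim1", placements$start[pl[k]] + offset,
                 paste0(readLength, "M"), seq, length(pl))
    }, character(1))
  }

  sam <- c(.samHeader(c(sim1 = chromLength)), unlist(samRec))
  list(gtf = paste(gtf, collapse = "\n"),
       config = paste(config, collapse = "\n"),
       sam = paste(sam, collapse = "\n"),
       truth = truth,
       chromLength = chromLength)
}

#' Score read annotations against simulation ground truth
#'
#' A read is a true positive when its true class is among the classes named
#' by its label (single or merged; orientation qualifiers are ignored for
#' the comparison), a false positive when it is annotated but its true class
#' is absent, and a false negative when it is unannotated although the truth
#' assigns it a class. Reads drawn from intergenic regions count as false
#' positives when annotated and are otherwise ignored.
#'
#' @param readAnnotations data frame with columns `read_id`, `label` (one
#'   element of [readAnnotations()]).
#' @param truth truth table from [simulateDataset()].
#' @return named numeric vector with elements `tp`, `fp`, `fn`.
#' @export
scoreAgainstTruth <- function(readAnnotations, truth) {
  if (!setequal(readAnnotations$read_id, truth$read_id))
    stop("read universes of annotations and truth differ", call. = FALSE)
  m <- match(truth$read_id, readAnnotations$read_id)
  label <- readAnnotations$label[m]
  classesOf <- strsplit(label, .MERGE_SEP, fixed = TRUE)
  classesOf <- lapply(classesOf, function(x) sub(" \\([+-]\\)$", "", x))
  annotated <- label != .LABEL_UNANNOTATED & label != .LABEL_DISCARDED
  hasTruth <- truth$true_class != "intergenic"
  tp <- sum(annotated & hasTruth &
              mapply(function(cl, tc) tc %in% cl, classesOf, truth$true_class))
  fp <- sum(annotated &
              !mapply(function(cl, tc) tc %in% cl, classesOf, truth$true_class))
  fn <- sum(!annotated & hasTruth)
  c(tp = tp, fp = fp, fn = fn)
}
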