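## Binned genomic interval index. Annotation intervals are sorted and
## registered into fixed-width bins; an overlap query inspects only the bins
## its interval spans. Bins are the 1-based closed ranges
## [k*w + 1, (k+1)*w]; an interval is registered in every bin it overlaps,
## found by integer division of its endpoints.

#' Build a binned interval index
#'
#' Registers every feature into each fixed-width genomic bin its interval
#' overlaps. The build is deterministic: features are stored in their input
#' order and queries report candidates in feature order.
#'
#' @param features `GRanges` of annotation features (typically from
#'   [buildFeatureSet()]); metadata columns are kept and travel with query
#'   results.
#' @param binWidth bin width in nucleotides (`>= 1`). The default, 16384 nt,
#'   balances small-RNA read size against vicinity-region size.
#' @return a [BinnedIndex-class].
#' @seealso [queryOverlaps()], [overlapPasses()]
#' @export
buildIndex <- function(features, binWidth = 16384L) {
  binWidth <- as.integer(binWidth)
  stopifnot(binWidth >= 1L)
  chrom <- as.character(seqnames(features))
  s <- start(features)
  e <- end(features)
  b0 <- (s - 1L) %/% binWidth
  b1 <- (e - 1L) %/% binWidth
  n <- b1 - b0 + 1L
  featIdx <- rep(seq_along(features), n)
  bin <- unlist(lapply(seq_along(features), function(i) b0[i]:b1[i]),
                use.names = FALSE)
  if (length(featIdx)) {
    keys <- paste0(chrom[featIdx], ":", bin)
    bins <- list2env(split(featIdx, keys), hash = TRUE)
  } else {
    bins <- new.env(hash = TRUE)
  }
  new("BinnedIndex", binWidth = binWidth, features = features, bins = bins,
      featChrom = chrom, featStart = s, featEnd = e)
}

## Fast path shared by queryOverlaps() and the annotator: plain-vector
## arguments, returns list(index =, overlap =).
.queryIndex <- function(index, chrom, start, end) {
  w <- index@binWidth
  keys <- paste0(chrom, ":", ((start - 1L) %/% w):((end - 1L) %/% w))
  idx <- unique(unlist(mget(keys, envir = index@bins,
                            ifnotfound = list(integer(0))),
                       use.names = FALSE))
  if (length(idx) == 0L)
    return(list(index = integer(0), overlap = integer(0)))
  idx <- sort(idx)
  ov <- pmin(index@featEnd[idx], end) - pmax(index@featStart[idx], start) + 1L
  keep <- ov >= 1L
  list(index = idx[keep], overlap = ov[keep])
}

#' Query a binned index for overlapping features
#'
#' Returns exactly the indexed features overlapping the query interval by at
#' least one nucleotide on the same chromosome, each once, with the overlap
#' length in nucleotides. Strand is deliberately not filtered here:
#' orientation requirements are a class-level rule applied during hit
#' annotation. Querying an unknown chromosome yields an empty result.
#'
#' @param index a [BinnedIndex-class].
#' @param interval a length-1 `GRanges`, or a chromosome name when `start`
#'   and `end` are given.
#' @param start,end 1-based closed query coordinates (used when `interval`
#'   is a chromosome name).
#' @return data frame with columns `index` (row in `indexedFeatures(index)`)
#'   and `overlap` (nt), ordered by feature index.
#' @export
queryOverlaps <- function(index, interval, start = NULL, end = NULL) {
  if (methods::is(interval, "GRanges")) {
    stopifnot(length(interval) == 1L)
    chrom <- as.character(seqnames(interval))
    start <- GenomicRanges::start(interval)
    end <- GenomicRanges::end(interval)
  } else {
    chrom <- as.character(interval)
    stopifnot(!is.null(start), !is.null(end))
  }
  stopifnot(start >= 1L, start <= end)
  hit <- .queryIndex(index, chrom, as.integer(start), as.integer(end))
  data.frame(index = hit$index, overlap = hit$overlap)
}

#' Apply the minimal-overlap rule
#'
#' An annotation whose overlap with the hit is lower than the threshold is
#' not considered; equality passes. A nucleotide threshold `t` requires
#' `overlap >= t`; a percentage threshold `p` requires
#' `overlap >= ceiling(p/100 * readLength)`.
#'
#' @param overlap overlap length(s) in nucleotides (`>= 0`).
#' @param readLength read length(s) in nucleotides (`>= 1`).
#' @param threshold `list(type, value)` from [parseOverlapThreshold()] (or
#'   anything that function accepts).
#' @return logical vector.
#' @examples
#' overlapPasses(5, 20, "10nt")   # FALSE
#' overlapPasses(10, 20, "50%")   # TRUE: 10 >= ceiling(0.5 * 20)
#' @export
overlapPasses <- function(overlap, readLength, threshold) {
  threshold <- parseOverlapThreshold(threshold)
  stopifnot(all(overlap >= 0), all(readLength >= 1))
  if (threshold$type == "nt")
    overlap >= threshold$value
  else
    overlap >= ceiling(threshold$value / 100 * readLength)
}
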