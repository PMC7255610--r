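## Alignment input. The complete hit set of each read is reconstructed either
## from multi-record output carrying the NH tag (one SAM record per hit,
## records of one read consecutive) or from BWA-style output where a primary
## record compresses its alternative hits into an XA tag
## ("chr,(+|-)pos,CIGAR,NM;" repeated; the sign is the hit's strand).

#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamHeader
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
#'   cigarWidthAlongQuerySpace
NULL

.FLAG_PAIRED <- 1L
.FLAG_UNMAPPED <- 4L
.FLAG_REVERSE <- 16L
.FLAG_SECONDARY <- 256L
.FLAG_SUPPLEMENTARY <- 2048L

.hasFlag <- function(flag, bit) bitwAnd(flag, bit) != 0L

## Path to a BAM for scanBam(): SAM input is converted to a temporary BAM.
.asBamPath <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  asBam(path, tempfile(), indexDestination = FALSE, overwrite = TRUE)
}

.parseXa <- function(xa) {
  entries <- strsplit(xa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, ",", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  posTok <- vapply(parts, `[`, character(1), 2L)
  cig <- vapply(parts, `[`, character(1), 3L)
  strand <- substr(posTok, 1L, 1L)
  if (!all(strand %in% c("+", "-")))
    stop("malformed XA entry: '", xa, "'", call. = FALSE)
  pos <- as.integer(substring(posTok, 2L))
  data.frame(chrom = chrom, start = pos,
             end = pos + cigarWidthAlongReferenceSpace(cig) - 1L,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read the complete hit sets of single-end reads from SAM/BAM
#'
#' Streams a mapped single-end SAM or BAM file and reconstructs one alignment
#' set per read: all its `n` hits (the NH value), whether they are encoded as
#' one record per hit or as a primary record plus an XA tag. Unmapped
#' (`0x4`) and supplementary (`0x800`) records are skipped; secondary
#' (`0x100`) records count as hits. Each hit's reference span is computed
#' from POS and the reference-consuming CIGAR length; the read length is
#' taken from the primary record's SEQ (or its query-consuming CIGAR length
#' when SEQ is `*`).
#'
#' Records of one read must be consecutive (mapper output order); a QNAME
#' reappearing after another QNAME raises an error suggesting name-grouped
#' sorting or the NH companion tool ([setNhTags()]). When an NH tag disagrees
#' with the number of hits actually present, the observed hits are trusted
#' and a single summary warning is emitted. Paired-end input is rejected.
#'
#' @param path SAM or BAM file.
#' @return list with elements `reads` (data frame: `read_id`, `read_length`,
#'   `n`) and `hits` (data frame: `read` (row index into `reads`), `chrom`,
#'   `start`, `end`, `strand`, `from_xa`), so that
#'   `sum(reads$n) == nrow(hits)`.
#' @export
readAlignmentSets <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- .asBamPath(path)
  p <- ScanBamParam(what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
                    tag = c("NH", "XA"))
  x <- scanBam(bam, param = p)[[1]]
  flag <- x$flag
  if (any(.hasFlag(flag, .FLAG_PAIRED)))
    stop("paired-end records found; this method is defined for single-end sRNA-seq",
         call. = FALSE)
  keep <- !.hasFlag(flag, .FLAG_UNMAPPED) & !.hasFlag(flag, .FLAG_SUPPLEMENTARY)
  if (!any(keep))
    return(list(reads = data.frame(read_id = character(0),
                                   read_length = integer(0), n = integer(0)),
                hits = data.frame(read = integer(0), chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  strand = character(0), from_xa = logical(0))))
  qname <- x$qname[keep]
  flag <- flag[keep]
  chrom <- as.character(x$rname)[keep]
  pos <- x$pos[keep]
  cigar <- x$cigar[keep]
  seqw <- BiocGenerics::width(x$seq)[keep]
  nh <- x$tag$NH[keep]
  xa <- x$tag$XA[keep]

  grp <- rle(qname)
  if (anyDuplicated(grp$values))
    stop("records of read '", grp$values[duplicated(grp$values)][1],
         "' are not consecutive; sort the file by name or run the NH companion tool",
         call. = FALSE)
  readOf <- rep(seq_along(grp$values), grp$lengths)

  strand <- ifelse(.hasFlag(flag, .FLAG_REVERSE), "-", "+")
  refw <- cigarWidthAlongReferenceSpace(cigar)
  hits <- data.frame(read = readOf, chrom = chrom, start = pos,
                     end = pos + refw - 1L, strand = strand,
                     from_xa = FALSE, stringsAsFactors = FALSE)

  hasXa <- which(!is.na(xa))
  if (length(hasXa)) {
    extra <- lapply(hasXa, function(i) cbind(read = readOf[i], .parseXa(xa[i]),
                                             from_xa = TRUE))
    hits <- rbind(hits, do.call(rbind, extra))
    hits <- hits[order(hits$read), , drop = FALSE]
    rownames(hits) <- NULL
  }

  ## read length from the primary record; CIGAR query length when SEQ is '*'
  nReads <- length(grp$values)
  primary <- !.hasFlag(flag, .FLAG_SECONDARY)
  firstPrim <- rep(NA_integer_, nReads)
  primIdx <- which(primary)
  firstPrim[rev(readOf[primIdx])] <- rev(primIdx)  # reversed, so the first wins
  firstOfGroup <- cumsum(c(1L, utils::head(grp$lengths, -1L)))
  firstPrim[is.na(firstPrim)] <- firstOfGroup[is.na(firstPrim)]
  rlen <- seqw[firstPrim]
  noSeq <- rlen == 0L
  if (any(noSeq))
    rlen[noSeq] <- cigarWidthAlongQuerySpace(cigar[firstPrim[noSeq]],
                                             after.soft.clipping = FALSE)

  nHits <- tabulate(hits$read, nbins = nReads)
  reads <- data.frame(read_id = grp$values, read_length = as.integer(rlen),
                      n = nHits, stringsAsFactors = FALSE)

  nhFirst <- nh[firstPrim]
  bad <- !is.na(nhFirst) & nhFirst != nHits
  if (any(bad))
    warning(sum(bad), " read(s) have an NH tag disagreeing with the hits present",
            " (e.g. '", reads$read_id[bad][1], "': NH=", nhFirst[bad][1],
            ", hits=", nHits[bad][1], "); the observed hits are used",
            call. = FALSE)
  list(reads = reads, hits = hits)
}

#' Add NH tags to name-grouped SAM output (bowtie companion tool)
#'
#' bowtie emits one record per hit but no NH tag. This companion reads a SAM
#' file whose mapped records of one read are consecutive (bowtie output
#' property), counts the mapped records of each QNAME, and writes every
#' mapped record back with `NH:i:<count>`. The header and all other fields
#' are byte-identical; an existing NH tag is replaced, which makes the
#' operation idempotent. A QNAME reappearing after another QNAME raises an
#' error.
#'
#' @param samIn input SAM path.
#' @param samOut output SAM path.
#' @return named integer vector of per-read hit counts, invisibly.
#' @export
setNhTags <- function(samIn, samOut) {
  lines <- readLines(samIn)
  isHeader <- startsWith(lines, "@")
  rec <- lines[!isHeader]
  if (length(rec) == 0L) {
    writeLines(lines, samOut)
    return(invisible(structure(integer(0), names = character(0))))
  }
  fields <- strsplit(rec, "\t", fixed = TRUE)
  qn <- vapply(fields, `[`, character(1), 1L)
  fl <- as.integer(vapply(fields, `[`, character(1), 2L))
  mapped <- !.hasFlag(fl, .FLAG_UNMAPPED)

  grp <- rle(qn)
  if (anyDuplicated(grp$values))
    stop("records of read '", grp$values[duplicated(grp$values)][1],
         "' are not consecutive; sort the SAM file by name first", call. = FALSE)
  readOf <- rep(seq_along(grp$values), grp$lengths)
  counts <- vapply(split(mapped, readOf), sum, integer(1))

  out <- rec
  nhOf <- counts[readOf]
  upd <- which(mapped)
  stripped <- gsub("\tNH:i:[0-9]+", "", out[upd])
  out[upd] <- paste0(stripped, "\tNH:i:", nhOf[upd])

  final <- character(length(lines))
  final[isHeader] <- lines[isHeader]
  final[!isHeader] <- out
  writeLines(final, samOut)
  invisible(structure(as.integer(counts), names = grp$values))
}
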