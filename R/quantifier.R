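## Accumulation of per-read contributions into the three output tables:
## class-level counts (including merged annotations), feature-level counts
## (canonical feature-id combinations), and per-read annotations; plus
## per-file summary statistics. Accumulation is order-independent and
## associative, so files (or file chunks) can be processed independently and
## merged.

## Process one alignment file against a built index. Returns the per-file
## pieces consumed by annotateReads().
.annotateFile <- function(path, index, config, strategy, seed, ordinal) {
  als <- readAlignmentSets(path)
  reads <- als$reads
  hits <- als$hits
  nReads <- nrow(reads)
  hitAnns <- .annotateHits(index, hits, reads$read_length[hits$read],
                           config@overlapThreshold)
  hitsOfRead <- split(seq_len(nrow(hits)),
                      factor(hits$read, levels = seq_len(nReads)))
  ## one RNG stream per input file: deterministic for any thread count
  set.seed(seed + ordinal)
  resolutions <- vector("list", nReads)
  contribs <- vector("list", nReads)
  for (i in seq_len(nReads)) {
    ha <- hitAnns[hitsOfRead[[i]]]
    resolutions[[i]] <- resolveRead(ha, reads$n[i])
    contribs[[i]] <- applyStrategy(strategy, ha, reads$n[i])
  }
  cb <- if (nReads) do.call(rbind, contribs) else
    data.frame(label = character(0), weight = numeric(0),
               status = character(0), features = character(0))

  classCounts <- if (nrow(cb))
    rowsum(cb$weight, cb$label) else matrix(numeric(0), 0, 1)
  classCounts <- structure(as.numeric(classCounts),
                           names = rownames(classCounts))

  fk <- cb$features
  fsel <- nzchar(fk)
  featCounts <- if (any(fsel)) {
    m <- rowsum(cb$weight[fsel], fk[fsel])
    structure(as.numeric(m), names = rownames(m))
  } else structure(numeric(0), names = character(0))

  status <- vapply(resolutions, `[[`, character(1), "status")
  ra <- data.frame(read_id = reads$read_id,
                   status = status,
                   label = vapply(resolutions, `[[`, character(1), "label"),
                   features = vapply(resolutions, function(r)
                     paste(r$features, collapse = ";"), character(1)),
                   stringsAsFactors = FALSE)

  annotated <- sum(cb$weight[!cb$label %in% c(.LABEL_UNANNOTATED, .LABEL_DISCARDED)])
  stats <- data.frame(
    reads_seen = nReads,
    reads_annotated = annotated,
    reads_rescued = sum(status == "rescued"),
    reads_ambiguous = sum(status == "ambiguous"),
    reads_unannotated = sum(cb$weight[cb$label == .LABEL_UNANNOTATED]),
    reads_discarded = sum(cb$weight[cb$label == .LABEL_DISCARDED]),
    annotation_rate = if (nReads) annotated / nReads else NA_real_)

  list(classCounts = classCounts, featureCounts = featCounts,
       readAnnotations = ra, stats = stats)
}

## Named per-file vectors -> labels x files matrix, absent labels filled 0.
.bindCounts <- function(vecs, fileNames) {
  labels <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0, nrow = length(labels), ncol = length(vecs),
              dimnames = list(labels, fileNames))
  for (j in seq_along(vecs)) m[names(vecs[[j]]), j] <- vecs[[j]]
  m
}

#' Annotate and quantify small-RNA classes in alignment files
#'
#' The full pipeline: parse the configuration, build the in-memory feature
#' set (primary records plus derived introns, UTRs and vicinity regions),
#' build the binned interval index, then annotate every read of every input
#' file and accumulate class-level counts, feature-level counts, per-read
#' annotations and summary statistics.
#'
#' Files are processed independently (optionally in parallel); each file uses
#' its own RNG stream seeded `seed + file ordinal`, so results are
#' byte-identical for any thread count.
#'
#' @param alignmentFiles one or more SAM/BAM files (single-end).
#' @param annotation GTF path or a record `GRanges` from [readGtf()].
#' @param config configuration path/text or a [PriorityConfig-class].
#' @param strategy counting strategy: `"default"` (multi-mapping aware, with
#'   rescue and merged annotations), `"unique"`, `"random"` or `"ratio"`.
#' @param overlapThreshold optional override of the minimal-overlap rule
#'   (e.g. `"10nt"`, `"50%"`).
#' @param vicinitySize optional override of the upstream/downstream width
#'   (nt).
#' @param binWidth bin width of the interval index.
#' @param seed base seed for the `random` strategy.
#' @param threads number of files processed concurrently.
#' @param idAttribute GTF attribute grouping exons into genes.
#' @return a [SmallRNAQuant-class].
#' @examples
#' fx <- fig9Fixture()
#' dir <- tempfile(); dir.create(dir)
#' writeLines(fx$gtf, file.path(dir, "a.gtf"))
#' writeLines(fx$sam, file.path(dir, "r.sam"))
#' q <- annotateReads(file.path(dir, "r.sam"), file.path(dir, "a.gtf"),
#'                    fx$config)
#' classCounts(q)
#' @export
annotateReads <- function(alignmentFiles, annotation, config,
                          strategy = c("default", "unique", "random", "ratio"),
                          overlapThreshold = NULL, vicinitySize = NULL,
                          binWidth = 16384L, seed = 0L, threads = 1L,
                          idAttribute = "gene_id") {
  strategy <- match.arg(strategy)
  if (!methods::is(config, "PriorityConfig"))
    config <- parseConfig(config)
  if (!is.null(overlapThreshold))
    config@overlapThreshold <- parseOverlapThreshold(overlapThreshold)
  if (!is.null(vicinitySize))
    config@vicinitySize <- as.integer(vicinitySize)
  records <- if (methods::is(annotation, "GRanges")) annotation
             else readGtf(annotation)

  seqlens <- tryCatch(.seqlengthsOf(alignmentFiles[1]), error = function(e) NULL)
  features <- buildFeatureSet(records, config, seqlengths = seqlens,
                              idAttribute = idAttribute)
  index <- buildIndex(features, binWidth)

  worker <- function(j) .annotateFile(alignmentFiles[j], index, config,
                                      strategy, seed, j)
  per <- if (threads > 1L)
    parallel::mclapply(seq_along(alignmentFiles), worker,
                       mc.cores = as.integer(threads))
  else
    lapply(seq_along(alignmentFiles), worker)

  fileNames <- make.unique(basename(alignmentFiles))
  counts <- .bindCounts(lapply(per, `[[`, "classCounts"), fileNames)
  fcounts <- .bindCounts(lapply(per, `[[`, "featureCounts"), fileNames)
  stats <- do.call(rbind, lapply(per, `[[`, "stats"))
  rownames(stats) <- fileNames
  ra <- lapply(per, `[[`, "readAnnotations")
  names(ra) <- fileNames

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(label = rownames(counts),
                        merged = grepl(.MERGE_SEP, rownames(counts), fixed = TRUE)))
  new("SmallRNAQuant", se, featureCounts = fcounts, readAnnotations = ra,
      summaryStats = stats, strategy = strategy)
}

## Chromosome lengths from a SAM/BAM header (for vicinity right-clipping).
.seqlengthsOf <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE))
    return(scanBamHeader(path)[[1]]$targets)
  lines <- readLines(path, n = 5000L)
  sq <- lines[startsWith(lines, "@SQ")]
  if (length(sq) == 0L) return(NULL)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  structure(ln, names = sn)
}

.writeTsv <- function(df, path, digits6 = FALSE) {
  if (digits6) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the class-level count table
#'
#' One row per class label (merged annotations included), one count column
#' per input file, tab-separated, rows sorted by label. Under the `ratio`
#' strategy weights are printed with 6 decimal places; otherwise counts are
#' integers.
#'
#' @param x a [SmallRNAQuant-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path) {
  m <- classCounts(x)
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$label), , drop = FALSE]
  .writeTsv(df, path, digits6 = countStrategy(x) == "ratio")
}

#' Write the feature-level count table
#'
#' One row per canonical feature-id combination (single id, or the sorted
#' `;`-joined ids supporting a merged or multi-copy assignment), one column
#' per input file.
#'
#' @inheritParams writeCounts
#' @export
writeFeatureCounts <- function(x, path) {
  m <- featureCounts(x)
  df <- data.frame(features = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$features), , drop = FALSE]
  .writeTsv(df, path, digits6 = countStrategy(x) == "ratio")
}

#' Write the per-read annotation table
#'
#' One row per read with columns `read_id`, `status`, `label` and the
#' `;`-joined supporting feature ids. With several input files a leading
#' `file` column is added and files are concatenated in input order.
#'
#' @inheritParams writeCounts
#' @export
writeReadAnnotations <- function(x, path) {
  ra <- readAnnotations(x)
  if (length(ra) == 1L) {
    df <- ra[[1]]
  } else {
    df <- do.call(rbind, lapply(names(ra), function(f)
      cbind(file = f, ra[[f]], stringsAsFactors = FALSE)))
  }
  .writeTsv(df, path)
}
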