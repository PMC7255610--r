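#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Annotation-class priorities and derivation rules
#'
#' A `PriorityConfig` holds the parsed content of a configuration file: which
#' annotation classes are quantified, in which priority order, with which
#' strand-orientation requirement, and for which classes introns and vicinity
#' regions (upstream/downstream, plus inferred UTRs) are derived from the gene
#' models.
#'
#' Each priority tier is a data frame of class selectors with columns `source`
#' (GTF column 2, `"."` matches any source), `feature` (GTF column 3, or one of
#' the reserved derived-class words `intron`, `upstream`, `downstream`,
#' `5'UTR`, `3'UTR`), `orientation` (`"collinear"`, `"antisense"` or `"any"`)
#' and `label` (the display label used in count tables, e.g. `"CDS (+)"`).
#' Tier 1 (the first element of `priorityTiers()`) is the highest priority.
#'
#' @slot tiers list of data frames, one per priority tier (first = highest).
#' @slot intronSelectors data frame of selectors naming the classes whose
#'   introns are derived.
#' @slot vicinitySelectors data frame of selectors naming the classes whose
#'   upstream/downstream regions (and, for coding genes, UTRs) are derived.
#' @slot vicinitySize integer width in nucleotides of the upstream and
#'   downstream regions.
#' @slot overlapThreshold list with elements `type` (`"nt"` or `"pct"`) and
#'   `value`; the minimal hit/annotation overlap below which a candidate
#'   annotation is discarded.
#'
#' @seealso [parseConfig()], [serializeConfig()], [reversePriorities()]
#' @export
setClass("PriorityConfig",
  representation(
    tiers             = "list",
    intronSelectors   = "data.frame",
    vicinitySelectors = "data.frame",
    vicinitySize      = "integer",
    overlapThreshold  = "list"
  )
)

.selectorCols <- c("source", "feature", "orientation", "label")

setValidity("PriorityConfig", function(object) {
  msg <- character(0)
  if (length(object@tiers) == 0L)
    msg <- c(msg, "at least one priority tier is required")
  for (t in object@tiers) {
    if (!is.data.frame(t) || !all(.selectorCols %in% names(t)))
      msg <- c(msg, "each tier must be a selector data frame")
    else if (!all(t$orientation %in% c("collinear", "antisense", "any")))
      msg <- c(msg, "orientation must be collinear, antisense or any")
  }
  all <- do.call(rbind, object@tiers)
  if (!is.null(all)) {
    key <- paste(all$source, all$feature, all$orientation)
    if (anyDuplicated(key))
      msg <- c(msg, paste0("class selector appears in more than one tier: ",
                           key[duplicated(key)][1]))
  }
  if (length(object@vicinitySize) != 1L || object@vicinitySize < 1L)
    msg <- c(msg, "vicinitySize must be a single integer >= 1")
  thr <- object@overlapThreshold
  if (!is.list(thr) || !all(c("type", "value") %in% names(thr)) ||
      !thr$type %in% c("nt", "pct"))
    msg <- c(msg, "overlapThreshold must be list(type = 'nt'|'pct', value = )")
  if (length(msg)) msg else TRUE
})

#' @describeIn PriorityConfig list of per-tier selector data frames (first
#'   element = highest priority).
#' @param x,object a `PriorityConfig`.
#' @export
priorityTiers <- function(x) x@tiers

#' @describeIn PriorityConfig selectors whose introns are derived.
#' @export
intronSelectors <- function(x) x@intronSelectors

#' @describeIn PriorityConfig selectors whose vicinity regions are derived.
#' @export
vicinitySelectors <- function(x) x@vicinitySelectors

#' @describeIn PriorityConfig width (nt) of derived upstream/downstream
#'   regions.
#' @export
vicinitySize <- function(x) x@vicinitySize

#' @describeIn PriorityConfig minimal-overlap rule, `list(type, value)`.
#' @export
overlapThreshold <- function(x) x@overlapThreshold

setMethod("show", "PriorityConfig", function(object) {
  cat("PriorityConfig with", length(object@tiers), "priority tiers\n")
  for (i in seq_along(object@tiers)) {
    t <- object@tiers[[i]]
    cat(sprintf("  tier %d: %s\n", i, paste(t$label, collapse = ", ")))
  }
  cat("  introns derived for:",
      if (nrow(object@intronSelectors)) paste(object@intronSelectors$label, collapse = ", ")
      else "(none)", "\n")
  cat("  vicinity derived for:",
      if (nrow(object@vicinitySelectors)) paste(object@vicinitySelectors$label, collapse = ", ")
      else "(none)", "\n")
  thr <- object@overlapThreshold
  cat(sprintf("  vicinity size: %d nt; overlap threshold: %g%s\n",
              object@vicinitySize, thr$value, ifelse(thr$type == "nt", " nt", "%")))
  invisible(NULL)
})

#' Binned interval index over an annotation feature set
#'
#' Annotation intervals are registered into fixed-width genomic bins, one bin
#' list per chromosome; an overlap query touches only the bins spanned by the
#' query interval, so query time scales with local bin occupancy rather than
#' with the total number of features.
#'
#' @slot binWidth bin width in nucleotides.
#' @slot features the indexed [GenomicRanges::GRanges] (with its feature
#'   metadata columns).
#' @slot bins environment mapping `"chrom:bin"` keys to integer vectors of
#'   feature indices.
#' @slot featChrom,featStart,featEnd cached plain vectors of feature
#'   coordinates, used on the query fast path.
#'
#' @seealso [buildIndex()], [queryOverlaps()]
#' @export
setClass("BinnedIndex",
  representation(
    binWidth  = "integer",
    features  = "GRanges",
    bins      = "environment",
    featChrom = "character",
    featStart = "integer",
    featEnd   = "integer"
  )
)

setValidity("BinnedIndex", function(object) {
  n <- length(object@features)
  if (length(object@featStart) != n || length(object@featEnd) != n ||
      length(object@featChrom) != n)
    return("cached coordinate vectors out of step with features")
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    return("binWidth must be a single integer >= 1")
  TRUE
})

#' @describeIn BinnedIndex the indexed feature set as a `GRanges`.
#' @param x a `BinnedIndex`.
#' @export
indexedFeatures <- function(x) x@features

#' @describeIn BinnedIndex bin width in nucleotides.
#' @export
binWidth <- function(x) x@binWidth

setMethod("show", "BinnedIndex", function(object) {
  cat(sprintf("BinnedIndex: %d features on %d chromosome(s), bin width %d nt, %d occupied bins\n",
              length(object@features),
              length(unique(object@featChrom)),
              object@binWidth,
              length(ls(object@bins))))
  invisible(NULL)
})

#' Small-RNA class quantification result
#'
#' `SmallRNAQuant` extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' rows are annotation-class labels (including merged labels such as
#' `"CDS (+)--miRNA"`, plus `"unannotated"` and, under the `unique` strategy,
#' `"multi-mapping (discarded)"`), columns are input alignment files, and the
#' `"counts"` assay holds the per-file weights. Additional slots carry the
#' feature-level count table, the per-read annotations and per-file summary
#' statistics.
#'
#' @slot featureCounts numeric matrix of counts per canonical feature-id
#'   combination (rownames are single ids or `;`-joined sorted id tuples).
#' @slot readAnnotations list (one element per input file) of data frames with
#'   columns `read_id`, `status`, `label`, `features`.
#' @slot summaryStats data frame, one row per input file, with columns
#'   `reads_seen`, `reads_annotated`, `reads_rescued`, `reads_ambiguous`,
#'   `reads_unannotated`, `reads_discarded`, `annotation_rate`.
#' @slot strategy the counting strategy used (`default`, `unique`, `random`
#'   or `ratio`).
#'
#' @seealso [annotateReads()], [classCounts()], [featureCounts()],
#'   [readAnnotations()], [summaryStats()]
#' @export
setClass("SmallRNAQuant",
  contains = "SummarizedExperiment",
  representation(
    featureCounts   = "matrix",
    readAnnotations = "list",
    summaryStats    = "data.frame",
    strategy        = "character"
  )
)

setValidity("SmallRNAQuant", function(object) {
  nf <- ncol(object)
  if (ncol(object@featureCounts) && ncol(object@featureCounts) != nf)
    return("featureCounts columns must match input files")
  if (length(object@readAnnotations) != nf)
    return("one readAnnotations element per input file is required")
  if (nrow(object@summaryStats) != nf)
    return("one summaryStats row per input file is required")
  if (!object@strategy %in% c("default", "unique", "random", "ratio"))
    return("unknown counting strategy")
  if (any(SummarizedExperiment::assay(object, "counts") < 0))
    return("counts must be non-negative")
  TRUE
})

#' @describeIn SmallRNAQuant class-level count matrix (labels x files).
#' @export
classCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn SmallRNAQuant feature-level count matrix (feature-id
#'   combinations x files).
#' @export
featureCounts <- function(x) x@featureCounts

#' @describeIn SmallRNAQuant per-read annotations, one data frame per file.
#' @export
readAnnotations <- function(x) x@readAnnotations

#' @describeIn SmallRNAQuant per-file summary statistics.
#' @export
summaryStats <- function(x) x@summaryStats

#' @describeIn SmallRNAQuant counting strategy used.
#' @export
countStrategy <- function(x) x@strategy

setMethod("show", "SmallRNAQuant", function(object) {
  cat(sprintf("SmallRNAQuant: %d class labels x %d file(s), strategy '%s'\n",
              nrow(object), ncol(object), object@strategy))
  st <- object@summaryStats
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %s: %d reads, %.6g annotated (%.1f%%), %d rescued, %d ambiguous\n",
                rownames(st)[i], st$reads_seen[i], st$reads_annotated[i],
                100 * st$annotation_rate[i], st$reads_rescued[i],
                st$reads_ambiguous[i]))
  }
  tot <- rowSums(classCounts(object))
  top <- head(sort(tot, decreasing = TRUE), 8L)
  cat("  top labels:", paste(sprintf("%s=%g", names(top), top), collapse = ", "), "\n")
  invisible(NULL)
})
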