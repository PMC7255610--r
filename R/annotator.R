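## The core method. Read annotation proceeds in two steps:
##
## 1. Hit annotation: the candidate annotations of a hit are the indexed
##    features it overlaps (passing the minimal-overlap rule and the class's
##    strand-orientation rule); among candidates only those on the minimal
##    (highest-priority) tier survive. More than one distinct class on that
##    tier makes the hit itself ambiguous; no candidate makes it intergenic.
##
## 2. Read resolution: intergenic (orphan) hits are dropped; the surviving
##    matches of all hits are pooled and again reduced to the minimal tier.
##    One remaining class annotates the read (status "unique" for a single
##    hit, "rescued" for a multi-mapper); several remaining classes yield a
##    merged annotation, a new class label concatenating the matching classes,
##    and status "ambiguous". A read with no surviving match is unannotated.

.LABEL_UNANNOTATED <- "unannotated"
.LABEL_DISCARDED <- "multi-mapping (discarded)"
.MERGE_SEP <- "--"

#' Annotate one hit against the indexed feature set
#'
#' Finds the candidate features overlapping the hit, applies the
#' minimal-overlap rule ([overlapPasses()]) and each feature's
#' strand-orientation rule ([orientationOk()]), and keeps only candidates on
#' the minimal (highest-priority) tier. Matches are deduplicated on
#' (class, feature id), so a hit spanning the same feature twice counts it
#' once.
#'
#' @param index a [BinnedIndex-class] built from [buildFeatureSet()] output.
#' @param chrom,start,end the hit's reference span (1-based, closed).
#' @param readStrand `"+"` or `"-"`.
#' @param readLength read length in nucleotides (used by percentage
#'   thresholds).
#' @param threshold overlap threshold (anything [parseOverlapThreshold()]
#'   accepts); default: any overlap counts.
#' @return list with elements `tier` (integer, `NA` for an intergenic hit)
#'   and `matches` (data frame `class_label`, `feature_id`, deduplicated,
#'   all on `tier`).
#' @export
annotateHit <- function(index, chrom, start, end, readStrand,
                        readLength = end - start + 1L, threshold = "1nt") {
  threshold <- parseOverlapThreshold(threshold)
  mc <- mcols(index@features)
  hit <- .queryIndex(index, chrom, as.integer(start), as.integer(end))
  .annotateFromCandidates(hit$index, hit$overlap, readStrand, readLength,
                          threshold, mc,
                          as.character(strand(index@features)))
}

.emptyMatches <- data.frame(class_label = character(0),
                            feature_id = character(0),
                            stringsAsFactors = FALSE)

.annotateFromCandidates <- function(idx, overlap, readStrand, readLength,
                                    threshold, featMeta, featStrand) {
  if (length(idx)) {
    pass <- overlapPasses(overlap, readLength, threshold) &
      orientationOk(featMeta$orientation[idx], readStrand, featStrand[idx])
    idx <- idx[pass]
  }
  if (length(idx) == 0L)
    return(list(tier = NA_integer_, matches = .emptyMatches))
  tiers <- featMeta$tier[idx]
  tmin <- min(tiers)
  idx <- idx[tiers == tmin]
  m <- data.frame(class_label = featMeta$class_label[idx],
                  feature_id = featMeta$feature_id[idx],
                  stringsAsFactors = FALSE)
  m <- m[!duplicated(paste(m$class_label, m$feature_id)), , drop = FALSE]
  list(tier = as.integer(tmin), matches = m)
}

## Annotate a whole hit table at once; returns one hit-annotation per row.
.annotateHits <- function(index, hits, readLengths, threshold) {
  mc <- mcols(index@features)
  featMeta <- list(orientation = as.character(mc$orientation),
                   tier = as.integer(mc$tier),
                   class_label = as.character(mc$class_label),
                   feature_id = as.character(mc$feature_id))
  featStrand <- as.character(strand(index@features))
  lapply(seq_len(nrow(hits)), function(i) {
    h <- .queryIndex(index, hits$chrom[i], hits$start[i], hits$end[i])
    .annotateFromCandidates(h$index, h$overlap, hits$strand[i],
                            readLengths[i], threshold, featMeta, featStrand)
  })
}

#' Build the canonical merged-annotation label
#'
#' A merged annotation concatenates the class labels an ambiguous read
#' matches. Labels are sorted (the classes of a merged label always share a
#' tier, so the order is lexicographic) and joined with `"--"`, making the
#' label independent of input order.
#'
#' @param classLabels character vector of two or more distinct class labels.
#' @return a single merged label, e.g. `"CDS (+)--miRNA"`.
#' @export
mergeLabel <- function(classLabels) {
  paste(sort(unique(classLabels)), collapse = .MERGE_SEP)
}

#' Resolve a read from its per-hit annotations
#'
#' Implements the read-level resolution: intergenic hits are dropped (a read
#' mapping one annotation plus intergenic regions still belongs to that
#' annotation); the surviving matches are pooled and only the minimal
#' (highest-priority) tier is kept. One remaining class gives status
#' `"unique"` (single hit) or `"rescued"` (multi-mapper); several give a
#' merged label with status `"ambiguous"`; none gives `"unannotated"`.
#'
#' @param hitAnnotations list of hit annotations from [annotateHit()], one
#'   per hit of the read.
#' @param n number of hits of the read (defaults to
#'   `length(hitAnnotations)`).
#' @return list with elements `label`, `status` (`unique`, `rescued`,
#'   `ambiguous` or `unannotated`) and `features` (sorted feature ids
#'   supporting the label).
#' @export
resolveRead <- function(hitAnnotations, n = length(hitAnnotations)) {
  tiers <- vapply(hitAnnotations, function(a) a$tier, integer(1))
  keep <- !is.na(tiers)
  if (!any(keep))
    return(list(label = .LABEL_UNANNOTATED, status = "unannotated",
                features = character(0)))
  tmin <- min(tiers[keep])
  sel <- which(keep & tiers == tmin)
  classes <- unlist(lapply(sel, function(i) hitAnnotations[[i]]$matches$class_label))
  feats <- unlist(lapply(sel, function(i) hitAnnotations[[i]]$matches$feature_id))
  classes <- unique(classes)
  feats <- sort(unique(feats))
  if (length(classes) == 1L)
    list(label = classes,
         status = if (n > 1L) "rescued" else "unique",
         features = feats)
  else
    list(label = mergeLabel(classes), status = "ambiguous", features = feats)
}

## One contribution row: label, weight, status, featureKey.
.contrib <- function(label, weight, status, features) {
  data.frame(label = label, weight = weight, status = status,
             features = paste(features, collapse = ";"),
             stringsAsFactors = FALSE)
}

.resolveToContrib <- function(res, weight = 1) {
  .contrib(res$label, weight, res$status, res$features)
}

#' Apply a counting strategy to one read
#'
#' Turns the per-hit annotations of a read into count contributions:
#'
#' * `default`: the full resolution ([resolveRead()]) contributes weight 1.
#' * `unique`: only uniquely mapping reads (`n = 1`) are resolved;
#'   multi-mappers contribute weight 1 to the
#'   `"multi-mapping (discarded)"` bucket.
#' * `random`: one hit is drawn uniformly among all `n` hits (using the
#'   current RNG state) and resolved on its own; an intergenic draw yields
#'   `"unannotated"`.
#' * `ratio`: every hit contributes `1/n` to its own hit-level resolution;
#'   intergenic hits contribute `1/n` to `"unannotated"`, so the read's total
#'   weight is still 1.
#'
#' @param strategy `"default"`, `"unique"`, `"random"` or `"ratio"`.
#' @param hitAnnotations list of hit annotations from [annotateHit()].
#' @param n number of hits (defaults to `length(hitAnnotations)`).
#' @return data frame of contributions with columns `label`, `weight`,
#'   `status`, `features`; weights always sum to 1 per read.
#' @export
applyStrategy <- function(strategy, hitAnnotations, n = length(hitAnnotations)) {
  switch(strategy,
    default = .resolveToContrib(resolveRead(hitAnnotations, n)),
    unique = {
      if (n == 1L) .resolveToContrib(resolveRead(hitAnnotations, n))
      else .contrib(.LABEL_DISCARDED, 1, "discarded", character(0))
    },
    random = {
      k <- if (n == 1L) 1L else sample.int(n, 1L)
      .resolveToContrib(resolveRead(hitAnnotations[k], 1L))
    },
    ratio = {
      do.call(rbind, lapply(hitAnnotations, function(a)
        .resolveToContrib(resolveRead(list(a), 1L), weight = 1 / n)))
    },
    stop("unknown counting strategy '", strategy, "'", call. = FALSE)
  )
}
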