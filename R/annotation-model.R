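## Annotation model: GTF records, gene models reconstructed from exons, and
## the derived features (introns, UTRs, vicinity regions) that standard
## annotation files do not contain.
##
## All coordinates are 1-based inclusive (GTF native; SAM POS is already
## 1-based), and all interval arithmetic uses closed intervals.

#' @importFrom GenomicRanges GRanges mcols mcols<- strand start end seqnames
#'   reduce setdiff flank resize findOverlaps pintersect granges sort shift
#' @importFrom IRanges IRanges restrict subsetByOverlaps
#' @importFrom BiocGenerics width unlist "end<-"
NULL

.validateGtfLines <- function(lines) {
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f), call. = FALSE)
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-integer coordinates", call. = FALSE)
    if (s < 1L || s > e)
      stop("malformed GTF line ", i, ": start must satisfy 1 <= start <= end",
           call. = FALSE)
    if (!f[7] %in% c("+", "-"))
      stop("malformed GTF line ", i, ": strand must be '+' or '-'", call. = FALSE)
    if (!nzchar(f[2]) || !nzchar(f[3]))
      stop("malformed GTF line ", i, ": empty source or feature field",
           call. = FALSE)
  }
  invisible(TRUE)
}

.emptyRecords <- function()
  GRanges(seqnames = character(0), ranges = IRanges(),
          strand = character(0),
          source = character(0), feature = character(0))

#' Read annotation records from a GTF file
#'
#' Parses a 9-column Ensembl/TAIR-dialect GTF (attributes as `key "value";`
#' pairs, `#` comment lines skipped) into a [GenomicRanges::GRanges] whose
#' metadata columns are `source` (column 2, `.` preserved), `feature`
#' (column 3) and one column per attribute key. The input file is never
#' modified. Malformed lines (wrong field count, non-integer coordinates,
#' `start > end`, strand other than `+`/`-`) raise an error naming the line
#' number.
#'
#' @param path path to a GTF file.
#' @return `GRanges` with one range per non-comment line.
#' @seealso [writeGtf()], [reconstructGenes()], [buildFeatureSet()]
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  .validateGtfLines(lines)
  if (!any(nzchar(trimws(lines)) & !startsWith(lines, "#")))
    return(.emptyRecords())
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- mcols(gr)
  src <- as.character(mc$source)
  src[is.na(src)] <- "."
  feat <- as.character(mc$type)
  keep <- setdiff(colnames(mc), c("source", "type", "score", "phase"))
  mcols(gr) <- cbind(DataFrame(source = src, feature = feat),
                     mc[, keep, drop = FALSE])
  gr
}

#' Write annotation records as GTF text
#'
#' Inverse of [readGtf()]: serializes a record `GRanges` (metadata columns
#' `source`, `feature`, plus attribute columns) back to 9-column GTF.
#' `NA` attributes are omitted per record.
#'
#' @param records a `GRanges` as returned by [readGtf()].
#' @param path output path; when `NULL` the GTF text is returned instead.
#' @return `path` invisibly, or the GTF text when `path` is `NULL`.
#' @export
writeGtf <- function(records, path = NULL) {
  mc <- mcols(records)
  attrCols <- setdiff(colnames(mc), c("source", "feature"))
  lines <- vapply(seq_along(records), function(i) {
    attrs <- character(0)
    for (k in attrCols) {
      v <- mc[[k]][i]
      if (!is.na(v)) attrs <- c(attrs, sprintf('%s "%s";', k, v))
    }
    paste(as.character(seqnames(records))[i], mc$source[i], mc$feature[i],
          start(records)[i], end(records)[i], ".",
          as.character(strand(records))[i], ".",
          paste(attrs, collapse = " "), sep = "\t")
  }, character(1))
  txt <- paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  if (is.null(path)) return(txt)
  writeLines(lines, path)
  invisible(path)
}

## First available of the ID / gene_id / Name attributes, else coordinates.
.featureIds <- function(records) {
  mc <- mcols(records)
  out <- rep(NA_character_, length(records))
  for (k in c("ID", "gene_id", "Name")) {
    if (k %in% colnames(mc)) {
      v <- as.character(mc[[k]])
      out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
    }
  }
  miss <- is.na(out)
  out[miss] <- paste0(as.character(seqnames(records))[miss], ":",
                      start(records)[miss], "-", end(records)[miss])
  out
}

#' Reconstruct gene models from exon records
#'
#' Groups `exon` records by a grouping attribute (default `gene_id`), merges
#' overlapping exons within each gene, and attaches the (merged) `CDS`
#' records sharing the same id. Genes whose exons lie on mixed strands or
#' chromosomes are rejected.
#'
#' @param records annotation records from [readGtf()].
#' @param idAttribute attribute key used to group exons into genes.
#' @return named list of gene models; each model is a list with elements
#'   `gene_id`, `strand`, `exons` (reduced `GRanges`) and `cds` (reduced
#'   `GRanges`, possibly empty).
#' @export
reconstructGenes <- function(records, idAttribute = "gene_id") {
  ex <- records[mcols(records)$feature == "exon"]
  if (length(ex) == 0L) return(structure(list(), names = character(0)))
  mc <- mcols(ex)
  if (!idAttribute %in% colnames(mc))
    stop("exon records carry no '", idAttribute, "' attribute", call. = FALSE)
  ids <- as.character(mc[[idAttribute]])
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop("exon record at ", seqnames(ex)[bad], ":", start(ex)[bad], "-",
         end(ex)[bad], " is missing the '", idAttribute, "' attribute",
         call. = FALSE)
  }
  cds <- records[mcols(records)$feature == "CDS"]
  cdsIds <- if (length(cds) && idAttribute %in% colnames(mcols(cds)))
    as.character(mcols(cds)[[idAttribute]]) else character(0)

  out <- lapply(unique(ids), function(id) {
    e <- ex[ids == id]
    st <- unique(as.character(strand(e)))
    if (length(st) != 1L)
      stop("gene '", id, "' has exons on mixed strands", call. = FALSE)
    if (length(unique(as.character(seqnames(e)))) != 1L)
      stop("gene '", id, "' has exons on several chromosomes", call. = FALSE)
    cd <- if (length(cdsIds)) cds[!is.na(cdsIds) & cdsIds == id] else cds[0]
    list(gene_id = id, strand = st,
         exons = reduce(granges(e)), cds = reduce(granges(cd)))
  })
  names(out) <- unique(ids)
  out
}

#' Infer introns of a gene model
#'
#' Introns are the maximal gaps between consecutive merged exons: the
#' set-complement of the exon union within the gene span. A single-exon gene
#' has no introns.
#'
#' @param gene a gene model from [reconstructGenes()].
#' @return `GRanges` of introns (strand of the gene), disjoint from the
#'   exons; exons and introns together tile the gene span contiguously.
#' @export
inferIntrons <- function(gene) {
  stopifnot(length(gene$exons) >= 1L)
  GenomicRanges::setdiff(range(gene$exons), gene$exons)
}

#' Infer 5' and 3' UTRs of a coding gene model
#'
#' The 5' UTR is the exonic sequence strictly upstream (strand-aware) of the
#' first CDS base, the 3' UTR the exonic sequence strictly downstream of the
#' last CDS base; 5'UTR, CDS and 3'UTR partition the exon union exactly.
#'
#' @param gene a gene model from [reconstructGenes()] with at least one CDS
#'   interval.
#' @return `list(five_utr = GRanges, three_utr = GRanges)`.
#' @export
inferUtrs <- function(gene) {
  if (length(gene$cds) == 0L)
    stop("gene '", gene$gene_id, "' has no CDS; UTRs are only inferred for coding genes",
         call. = FALSE)
  if (sum(width(GenomicRanges::setdiff(gene$cds, gene$exons))) > 0L)
    stop("gene '", gene$gene_id, "' has CDS outside its exon union", call. = FALSE)
  cdsMin <- min(start(gene$cds))
  cdsMax <- max(end(gene$cds))
  ## restrict() can leave zero-width stubs when an exon boundary coincides
  ## with a CDS end; closed-interval features have no zero-width ranges
  left  <- restrict(gene$exons, end = cdsMin - 1L)
  left  <- left[width(left) > 0L]
  right <- restrict(gene$exons, start = cdsMax + 1L)
  right <- right[width(right) > 0L]
  if (gene$strand == "+") list(five_utr = left, three_utr = right)
  else                    list(five_utr = right, three_utr = left)
}

#' Derive upstream and downstream vicinity regions
#'
#' The upstream region abuts the 5' end of each feature and the downstream
#' region its 3' end (strand-aware), each of the requested width. Regions are
#' clipped at position 1, and at the chromosome end when sequence lengths are
#' supplied (e.g. from a BAM header); clipping may shorten or drop a region.
#'
#' @param features `GRanges` (metadata columns are preserved).
#' @param size region width in nucleotides (`>= 1`).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return `list(upstream = GRanges, downstream = GRanges)`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000), "+")
#' makeVicinity(gr, 3000)
#' @export
makeVicinity <- function(features, size, seqlengths = NULL) {
  stopifnot(size >= 1L)
  clip <- function(x) {
    x <- restrict(x, start = 1L)
    x <- x[width(x) > 0L]
    if (!is.null(seqlengths)) {
      sl <- seqlengths[as.character(seqnames(x))]
      known <- !is.na(sl)
      if (any(known)) {
        newEnd <- ifelse(known, pmin(end(x), sl), end(x))
        keep <- start(x) <= newEnd
        x <- x[keep]
        end(x) <- newEnd[keep]
      }
    }
    x
  }
  list(upstream   = clip(flank(features, size, start = TRUE)),
       downstream = clip(flank(features, size, start = FALSE)))
}

## Dedupe a derived-feature GRanges on (feature_id, interval, strand).
.dedupeDerived <- function(gr) {
  if (length(gr) < 2L) return(gr)
  key <- paste(mcols(gr)$feature_id, seqnames(gr), start(gr), end(gr), strand(gr))
  gr[!duplicated(key)]
}

#' Build the in-memory annotation feature set
#'
#' Assembles every annotation interval the quantification will use, leaving
#' the input annotation untouched:
#'
#' * every primary record whose `source:feature` matches a selector of the
#'   configuration's `Order` section, labeled with that selector's class
#'   label and priority tier;
#' * gene models reconstructed from `exon` records (grouped by
#'   `idAttribute`), registered as feature `"gene"` when the GTF carries no
#'   explicit gene line;
#' * introns of every class listed in the `Introns` section;
#' * upstream/downstream regions (width `vicinitySize`) and, for coding
#'   genes, inferred 5'/3' UTRs, for every class listed in the `Vicinity`
#'   section.
#'
#' Derived classes only enter the feature set when their reserved word
#' (`intron`, `upstream`, `downstream`, `5'UTR`, `3'UTR`) appears in the
#' `Order` section. Feature ids are taken from the first present of the
#' attributes `ID`, `gene_id`, `Name`, else `chrom:start-end`; derived
#' features carry the id of their parent gene/feature.
#'
#' @param records annotation records from [readGtf()].
#' @param config a [PriorityConfig-class].
#' @param vicinitySize override of the configuration's vicinity width (nt).
#' @param seqlengths optional named chromosome lengths for right-clipping of
#'   vicinity regions.
#' @param idAttribute grouping attribute for gene reconstruction.
#' @return `GRanges` with metadata columns `feature_id`, `class_label`,
#'   `origin` (`primary`, `intron`, `five_utr`, `three_utr`, `upstream`,
#'   `downstream`), `tier` (1 = highest priority) and `orientation`.
#' @export
buildFeatureSet <- function(records, config, vicinitySize = NULL,
                            seqlengths = NULL, idAttribute = "gene_id") {
  vs <- if (is.null(vicinitySize)) config@vicinitySize else as.integer(vicinitySize)
  fid <- .featureIds(records)
  genes <- reconstructGenes(records, idAttribute)

  ## universe of matchable primary entries: records + synthesized gene spans
  uni <- granges(records)
  mcols(uni) <- DataFrame(source = mcols(records)$source,
                          feature = mcols(records)$feature,
                          feature_id = fid)
  explicitGeneIds <- fid[mcols(records)$feature == "gene"]
  synthIds <- setdiff(names(genes), explicitGeneIds)
  if (length(synthIds)) {
    synth <- do.call(c, lapply(synthIds, function(id) {
      g <- genes[[id]]
      span <- range(g$exons)
      mcols(span) <- DataFrame(source = ".", feature = "gene", feature_id = id)
      span
    }))
    uni <- c(uni, synth)
  }

  hasModel <- mcols(uni)$feature_id %in% names(genes) &
              mcols(uni)$feature == "gene"

  derived <- function(gr, ids, origin) {
    if (length(gr) == 0L) {
      gr <- GRanges()
    }
    mcols(gr) <- DataFrame(feature_id = ids, origin = origin)
    gr
  }

  emptyDerived <- GRanges()
  mcols(emptyDerived) <- DataFrame(feature_id = character(0), origin = character(0))
  pools <- list("intron" = emptyDerived, "upstream" = emptyDerived,
                "downstream" = emptyDerived, "5'UTR" = emptyDerived,
                "3'UTR" = emptyDerived)

  matchRows <- function(sel)
    which(matchSelector(sel, mcols(uni)$source, mcols(uni)$feature))

  intronSel <- config@intronSelectors
  for (i in seq_len(nrow(intronSel))) {
    for (r in matchRows(intronSel[i, ])) {
      if (!hasModel[r]) next
      g <- genes[[mcols(uni)$feature_id[r]]]
      intr <- inferIntrons(g)
      if (length(intr))
        pools[["intron"]] <- c(pools[["intron"]],
                               derived(intr, g$gene_id, "intron"))
    }
  }

  vicSel <- config@vicinitySelectors
  for (i in seq_len(nrow(vicSel))) {
    rows <- matchRows(vicSel[i, ])
    if (length(rows) == 0L) next
    ent <- uni[rows]
    ## raw (unclipped) flanks stay aligned with ent, so parent ids can be
    ## attached before clipping drops or shortens anything
    upRaw <- flank(granges(ent), vs, start = TRUE)
    dnRaw <- flank(granges(ent), vs, start = FALSE)
    mcols(upRaw) <- DataFrame(feature_id = mcols(ent)$feature_id, origin = "upstream")
    mcols(dnRaw) <- DataFrame(feature_id = mcols(ent)$feature_id, origin = "downstream")
    clipOne <- function(x) {
      x <- restrict(x, start = 1L)
      x <- x[width(x) > 0L]
      if (!is.null(seqlengths)) {
        sl <- seqlengths[as.character(seqnames(x))]
        ok <- is.na(sl) | start(x) <= sl
        x <- x[ok]
        sl <- sl[ok]
        end(x) <- ifelse(is.na(sl), end(x), pmin(end(x), sl))
      }
      x
    }
    pools[["upstream"]] <- c(pools[["upstream"]], clipOne(upRaw))
    pools[["downstream"]] <- c(pools[["downstream"]], clipOne(dnRaw))
    for (r in rows) {
      if (!hasModel[r]) next
      g <- genes[[mcols(uni)$feature_id[r]]]
      if (length(g$cds) == 0L) next
      utr <- inferUtrs(g)
      if (length(utr$five_utr))
        pools[["5'UTR"]] <- c(pools[["5'UTR"]],
                              derived(utr$five_utr,
                                      rep(g$gene_id, length(utr$five_utr)), "five_utr"))
      if (length(utr$three_utr))
        pools[["3'UTR"]] <- c(pools[["3'UTR"]],
                              derived(utr$three_utr,
                                      rep(g$gene_id, length(utr$three_utr)), "three_utr"))
    }
  }
  pools <- lapply(pools, .dedupeDerived)

  originOf <- c("intron" = "intron", "upstream" = "upstream",
                "downstream" = "downstream", "5'UTR" = "five_utr",
                "3'UTR" = "three_utr")

  out <- list()
  for (tier in seq_along(config@tiers)) {
    specs <- config@tiers[[tier]]
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      if (s$source == "." && s$feature %in% .derivedWords) {
        gr <- pools[[s$feature]]
        if (length(gr) == 0L) {
          warning("Order selector '", s$label, "' matches no features",
                  call. = FALSE)
          next
        }
        mcols(gr) <- DataFrame(feature_id = mcols(gr)$feature_id,
                               class_label = s$label,
                               origin = originOf[[s$feature]],
                               tier = tier, orientation = s$orientation)
      } else {
        rows <- matchRows(s)
        if (length(rows) == 0L) {
          warning("Order selector '", s$label, "' matches no annotation records",
                  call. = FALSE)
          next
        }
        gr <- uni[rows]
        mcols(gr) <- DataFrame(feature_id = mcols(gr)$feature_id,
                               class_label = s$label,
                               origin = "primary",
                               tier = tier, orientation = s$orientation)
      }
      out[[length(out) + 1L]] <- gr
    }
  }
  if (length(out) == 0L) {
    res <- GRanges()
    mcols(res) <- DataFrame(feature_id = character(0), class_label = character(0),
                            origin = character(0), tier = integer(0),
                            orientation = character(0))
    return(res)
  }
  res <- do.call(c, out)
  o <- order(mcols(res)$tier, as.character(seqnames(res)), start(res), end(res),
             mcols(res)$class_label, mcols(res)$feature_id)
  res[o]
}
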