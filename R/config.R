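## Configuration file parsing.
##
## Three sections: "Introns:", "Vicinity:" and "Order:". Order is mandatory
## and lists the quantified classes by decreasing priority, one tier per line;
## whitespace-separated selectors on one line share a tier. A selector is
## either `source:feature` (GTF columns 2 and 3; source "." matches any) or a
## bare feature word; the reserved bare words intron / upstream / downstream /
## 5'UTR / 3'UTR name in-memory derived features rather than GTF rows. A
## selector may be followed by a lone "+" (count collinear reads only) or "-"
## (count antisense reads only).

.derivedWords <- c("intron", "upstream", "downstream", "5'UTR", "3'UTR")

.emptySelectors <- function()
  data.frame(source = character(0), feature = character(0),
             orientation = character(0), label = character(0),
             stringsAsFactors = FALSE)

## Turn the whitespace-separated tokens of one config line into a selector
## data frame; lone +/- tokens qualify the preceding selector.
.parseSelectorLine <- function(line, lineno) {
  tokens <- strsplit(trimws(line), "[ \t]+")[[1]]
  out <- .emptySelectors()
  for (tok in tokens) {
    if (tok %in% c("+", "-")) {
      if (nrow(out) == 0L)
        stop("config line ", lineno, ": orientation qualifier '", tok,
             "' without a preceding class selector", call. = FALSE)
      i <- nrow(out)
      out$orientation[i] <- if (tok == "+") "collinear" else "antisense"
      out$label[i] <- paste0(out$feature[i], if (tok == "+") " (+)" else " (-)")
    } else {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (length(parts) > 2L)
        stop("config line ", lineno, ": selector '", tok,
             "' contains more than one colon", call. = FALSE)
      src <- if (length(parts) == 2L) parts[1] else "."
      feat <- parts[length(parts)]
      if (!nzchar(feat))
        stop("config line ", lineno, ": empty feature in selector '", tok, "'",
             call. = FALSE)
      out <- rbind(out, data.frame(source = src, feature = feat,
                                   orientation = "any", label = feat,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Parse an annotation-priority configuration file
#'
#' Reads the three-section plain-text configuration (`Introns:`, `Vicinity:`,
#' `Order:`) that selects the annotation classes to quantify, their priority
#' ordering and their strand-orientation requirements. Blank lines and lines
#' starting with `#` are ignored. The `Order:` section is mandatory; each of
#' its lines becomes one priority tier (first line = highest priority), and
#' selectors sharing a line share a tier.
#'
#' @param config path to a configuration file, or the configuration text
#'   itself (any string containing a newline is taken as text).
#' @param vicinitySize width in nucleotides of the derived upstream and
#'   downstream regions (default 3000, i.e. +/- 3 kb around the feature).
#' @param overlapThreshold minimal hit/annotation overlap below which a
#'   candidate annotation is discarded: a number (nucleotides), `"Nnt"`, or
#'   `"P%"` (percentage of the read length). Default `"1nt"`: any overlap
#'   counts.
#' @return a [PriorityConfig-class] object.
#' @examples
#' cfg <- parseConfig("Order:\nmiRNA .:CDS +\nintron\n")
#' priorityTiers(cfg)
#' @export
parseConfig <- function(config, vicinitySize = 3000L, overlapThreshold = "1nt") {
  txt <- if (length(config) == 1L && !grepl("\n", config) && file.exists(config))
    readLines(config) else unlist(strsplit(config, "\n", fixed = TRUE))
  txt <- sub("#.*$", "", txt)

  sections <- list(Introns = .emptySelectors(), Vicinity = .emptySelectors(),
                   Order = list())
  current <- NA_character_
  for (i in seq_along(txt)) {
    line <- trimws(txt[i])
    if (!nzchar(line)) next
    if (line %in% c("Introns:", "Vicinity:", "Order:")) {
      current <- sub(":$", "", line)
      next
    }
    if (is.na(current))
      stop("config line ", i, ": content before any section header", call. = FALSE)
    sel <- .parseSelectorLine(line, i)
    if (current == "Order")
      sections$Order[[length(sections$Order) + 1L]] <- sel
    else
      sections[[current]] <- rbind(sections[[current]], sel)
  }
  if (length(sections$Order) == 0L)
    stop("configuration has no Order section (or it is empty)", call. = FALSE)

  all <- do.call(rbind, sections$Order)
  key <- paste(all$source, all$feature, all$orientation)
  if (anyDuplicated(key))
    stop("class selector '", all$label[duplicated(key)][1],
         "' appears in more than one Order tier", call. = FALSE)

  new("PriorityConfig",
      tiers = sections$Order,
      intronSelectors = sections$Introns,
      vicinitySelectors = sections$Vicinity,
      vicinitySize = as.integer(vicinitySize),
      overlapThreshold = parseOverlapThreshold(overlapThreshold))
}

#' Parse an overlap-threshold specification
#'
#' @param x a number (nucleotides if `>= 1`, fraction of the read length if
#'   `< 1`), a string `"Nnt"` (nucleotides) or `"P%"` (percentage of the read
#'   length), or an already-parsed `list(type, value)`.
#' @return `list(type = "nt"|"pct", value = numeric)`.
#' @examples
#' parseOverlapThreshold("10nt")
#' parseOverlapThreshold("50%")
#' @export
parseOverlapThreshold <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("type", "value") %in% names(x)))
    return(x[c("type", "value")])
  }
  if (is.numeric(x)) {
    if (x < 1) return(list(type = "pct", value = 100 * x))
    return(list(type = "nt", value = as.numeric(x)))
  }
  x <- trimws(x)
  if (grepl("^[0-9.]+nt$", x))
    return(list(type = "nt", value = as.numeric(sub("nt$", "", x))))
  if (grepl("^[0-9.]+%$", x))
    return(list(type = "pct", value = as.numeric(sub("%$", "", x))))
  stop("cannot parse overlap threshold '", x, "'; use e.g. '10nt' or '50%'",
       call. = FALSE)
}

.serializeSelector <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    tok <- if (df$source[i] == ".") df$feature[i]
           else paste0(df$source[i], ":", df$feature[i])
    qual <- switch(df$orientation[i], collinear = " +", antisense = " -", "")
    paste0(tok, qual)
  }, character(1))
}

#' Serialize a PriorityConfig back to configuration text
#'
#' Inverse of [parseConfig()]: `parseConfig(serializeConfig(cfg))` recovers an
#' identical configuration (used for round-trip testing and to persist derived
#' configurations such as [reversePriorities()] output).
#'
#' @param config a [PriorityConfig-class].
#' @return a single string of configuration text.
#' @export
serializeConfig <- function(config) {
  out <- c("Introns:", .serializeSelector(config@intronSelectors), "",
           "Vicinity:", .serializeSelector(config@vicinitySelectors), "",
           "Order:",
           vapply(config@tiers,
                  function(t) paste(.serializeSelector(t), collapse = " "),
                  character(1)))
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Test whether a class selector matches an annotation record
#'
#' A selector matches when its source pattern is `"."` (any source) or equals
#' the record's source, and its feature pattern equals the record's feature.
#'
#' @param selector one-row selector data frame (or any list with `source` and
#'   `feature`).
#' @param source,feature character vectors of record source/feature fields
#'   (recycled together).
#' @return logical vector.
#' @examples
#' matchSelector(list(source = ".", feature = "CDS"), "havana", "CDS")
#' @export
matchSelector <- function(selector, source, feature) {
  (selector$source == "." | selector$source == source) &
    selector$feature == feature
}

#' Test a strand-orientation requirement
#'
#' `collinear` requires the read strand to equal the feature strand,
#' `antisense` requires them to differ, `any` always passes.
#'
#' @param orientation `"collinear"`, `"antisense"` or `"any"` (scalar or
#'   vector).
#' @param readStrand,featureStrand strand characters `"+"` or `"-"`.
#' @return logical vector.
#' @examples
#' orientationOk("antisense", "-", "+")
#' @export
orientationOk <- function(orientation, readStrand, featureStrand) {
  stopifnot(all(readStrand %in% c("+", "-")), all(featureStrand %in% c("+", "-")))
  ifelse(orientation == "any", TRUE,
         ifelse(orientation == "collinear",
                readStrand == featureStrand,
                readStrand != featureStrand))
}

#' Reverse the priority ordering of a configuration
#'
#' Produces a configuration in which the order of the priority tiers is
#' reversed, while tiers consisting solely of untranscribed derived classes
#' (intron, upstream, downstream) are kept at the bottom. Used to check that
#' the number of annotated reads is invariant under the (arbitrary) priority
#' ordering.
#'
#' @param config a [PriorityConfig-class].
#' @param keepDerivedLast keep all-derived (intron/upstream/downstream) tiers
#'   at the lowest priorities (default `TRUE`).
#' @return a [PriorityConfig-class] with permuted tiers.
#' @export
reversePriorities <- function(config, keepDerivedLast = TRUE) {
  tiers <- config@tiers
  if (keepDerivedLast) {
    low <- c("intron", "upstream", "downstream")
    isLow <- vapply(tiers, function(t) all(t$feature %in% low), logical(1))
    tiers <- c(rev(tiers[!isLow]), tiers[isLow])
  } else {
    tiers <- rev(tiers)
  }
  initialize(config, tiers = tiers)
}
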