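#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   GENETIC_CODE
#' @importFrom stats setNames rpois runif rbinom
#' @importFrom utils read.delim write.table combn head tail
NULL

#' Gapped multiple alignment of plastid genomes
#'
#' Holds equal-length gapped sequences over \code{A,C,G,T,N,-} together with
#' the name of a reference taxon whose ungapped coordinates (1-based) anchor
#' all reported variant positions.
#'
#' @slot seqs Named character vector of equal-length gapped sequences.
#' @slot reference Name of the reference taxon (must be one of the rows).
#' @export
setClass("PlastomeAlignment",
  representation(seqs = "character", reference = "character"))

setValidity("PlastomeAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("sequences must carry unique taxon names")
  if (length(unique(nchar(s))) != 1L)
    return("ragged alignment: all rows must have equal length")
  if (length(object@reference) != 1L || !object@reference %in% names(s))
    return("reference must name one of the aligned taxa")
  bad <- grepl("[^ACGTN-]", s)
  if (any(bad))
    return(paste0("illegal characters (alphabet is A,C,G,T,N,-) in: ",
                  paste(names(s)[bad], collapse = ", ")))
  TRUE
})

#' Marker panel of plastid typing loci
#'
#' A set of length-polymorphism (SSR/indel), gel-scored and CAPS loci with
#' dye labels, expected allele size ranges and repeat-count anchors.
#'
#' @slot loci data.frame with columns \code{id}, \code{kind} (one of
#'   \code{ssr}, \code{indel}, \code{caps}, \code{mixed}, \code{unknown}),
#'   \code{dye} (\code{HEX}, \code{6-FAM}, \code{NED} or \code{none}),
#'   \code{size_min}, \code{size_max}, \code{motif}, \code{anchor_size},
#'   \code{anchor_count}, \code{indel_size}, \code{multiplex},
#'   \code{gel_scored}.
#' @export
setClass("MarkerPanel", representation(loci = "data.frame"))

setValidity("MarkerPanel", function(object) {
  df <- object@loci
  need <- c("id", "kind", "dye", "size_min", "size_max", "motif",
            "anchor_size", "anchor_count", "indel_size", "multiplex",
            "gel_scored")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("panel table lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$id)) return("duplicate locus ids")
  if (nrow(df)) {
    bad <- !is.na(df$size_min) & !is.na(df$size_max) & df$size_min > df$size_max
    if (any(bad))
      return(paste("inverted size range at locus",
                   paste(df$id[bad], collapse = ", ")))
    if (!all(df$kind %in% c("ssr", "indel", "caps", "mixed", "unknown")))
      return("unknown locus kind")
  }
  TRUE
})

#' Genotype table of individuals typed at panel loci
#'
#' Raw or binned calls for a set of individuals. Cells hold fragment sizes in
#' bp (possibly fractional before binning), CAPS states (\code{cut}/
#' \code{uncut}), gel states, or \code{NA} for missing data.
#'
#' @slot calls character matrix, individuals x loci.
#' @slot groups character vector of population/group tags, one per individual.
#' @export
setClass("CpGenotypes",
  representation(calls = "matrix", groups = "character"))

setValidity("CpGenotypes", function(object) {
  m <- object@calls
  if (!is.character(m)) return("calls must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("individuals must carry unique row names")
  if (is.null(colnames(m))) return("loci must carry column names")
  if (length(object@groups) != nrow(m))
    return("one group tag per individual required")
  if (any(is.na(object@groups) | object@groups == ""))
    return("group tags must be nonempty")
  TRUE
})

#' Catalog of distinct multilocus haplotypes
#'
#' @slot profiles character matrix, haplotypes x loci; rownames are haplotype
#'   names (lineage prefix + ordinal, e.g. \code{E1.1}).
#' @slot diagnostics data.frame with columns \code{lineage}, \code{locus},
#'   \code{value}: a profile whose call at \code{locus} equals \code{value}
#'   is assigned that lineage prefix (first match wins).
#' @export
setClass("HaplotypeCatalog",
  representation(profiles = "matrix", diagnostics = "data.frame"))

setValidity("HaplotypeCatalog", function(object) {
  m <- object@profiles
  if (nrow(m) && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    return("haplotype names must be unique")
  if (nrow(m) > 1L) {
    key <- apply(m, 1L, paste, collapse = "\r")
    if (anyDuplicated(key)) return("catalogued profiles must be distinct")
  }
  TRUE
})

#' Character-coded haplotype matrix for network construction
#'
#' Ordered (integer repeat count) and binary (indel presence) characters.
#'
#' @slot states integer matrix, haplotypes x characters.
#' @slot kind character vector per character: \code{ordered} or \code{binary}.
#' @slot weights positive numeric weight per character.
#' @slot frequencies observed haplotype frequencies (tie-breaking).
#' @export
setClass("CodedMatrix",
  representation(states = "matrix", kind = "character",
                 weights = "numeric", frequencies = "numeric"))

setValidity("CodedMatrix", function(object) {
  m <- object@states
  k <- ncol(m)
  if (length(object@kind) != k || length(object@weights) != k)
    return("kind and weights must have one entry per character")
  if (!all(object@kind %in% c("ordered", "binary")))
    return("character kind must be 'ordered' or 'binary'")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (any(object@kind == "binary")) {
    b <- m[, object@kind == "binary", drop = FALSE]
    if (!all(b %in% c(0L, 1L, NA_integer_)))
      return("binary characters must be 0/1")
  }
  if (length(object@frequencies) != nrow(m))
    return("one frequency per haplotype required")
  TRUE
})

#' Reduced-median haplotype network
#'
#' Observed haplotypes plus inferred median vectors, with edges labelled by
#' the character(s) changing along them.
#'
#' @slot graph igraph object; vertex attributes \code{name}, \code{observed},
#'   \code{frequency}; edge attribute \code{character}.
#' @slot vectors integer matrix of node state vectors (expanded binary space).
#' @slot expansion the \code{binaryExpand} map used, for decoding edges.
#' @export
setClass("MedianNetwork",
  representation(graph = "ANY", vectors = "matrix", expansion = "list"))

#' @describeIn PlastomeAlignment Taxon names of the alignment rows.
#' @param x,object a \code{PlastomeAlignment}.
#' @export
setMethod("names", "PlastomeAlignment", function(x) names(x@seqs))

setMethod("show", "PlastomeAlignment", function(object) {
  cat("PlastomeAlignment:", length(object@seqs), "taxa x",
      nchar(object@seqs[[1L]]), "columns (reference:",
      object@reference, ")\n")
})

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel:", nrow(object@loci), "loci (",
      sum(object@loci$kind == "ssr"), "ssr,",
      sum(object@loci$kind == "caps"), "caps )\n")
})

setMethod("show", "CpGenotypes", function(object) {
  cat("CpGenotypes:", nrow(object@calls), "individuals x",
      ncol(object@calls), "loci;",
      length(unique(object@groups)), "groups\n")
})

setMethod("show", "HaplotypeCatalog", function(object) {
  cat("HaplotypeCatalog:", nrow(object@profiles), "haplotypes over",
      ncol(object@profiles), "loci\n")
})

setMethod("show", "CodedMatrix", function(object) {
  cat("CodedMatrix:", nrow(object@states), "haplotypes x",
      ncol(object@states), "characters (",
      sum(object@kind == "ordered"), "ordered,",
      sum(object@kind == "binary"), "binary )\n")
})

setMethod("show", "MedianNetwork", function(object) {
  g <- object@graph
  cat("MedianNetwork:", igraph::vcount(g), "nodes (",
      sum(igraph::V(g)$observed), "observed ),",
      igraph::ecount(g), "edges\n")
})
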