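## Marker-panel logic: locus definitions, fragment-size binning, repeat-count
## coding, dye-aware multiplex validation and design.

.panelColumns <- c("id", "kind", "dye", "size_min", "size_max", "motif",
                   "anchor_size", "anchor_count", "indel_size", "multiplex",
                   "gel_scored")

.completePanelFrame <- function(df) {
  for (col in .panelColumns)
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  df$id <- as.character(df$id)
  df$kind[is.na(df$kind)] <- "unknown"
  df$dye[is.na(df$dye)] <- "none"
  df$gel_scored <- !is.na(df$gel_scored) & as.logical(df$gel_scored)
  for (col in c("size_min", "size_max", "anchor_size", "anchor_count",
                "indel_size"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df[, .panelColumns]
}

#' Load marker locus definitions
#'
#' Reads a panel configuration from TSV, JSON or YAML into a validated
#' \code{\linkS4class{MarkerPanel}}. Recognised fields: \code{id},
#' \code{kind} (ssr/indel/caps/mixed/unknown), \code{dye}, \code{size_min},
#' \code{size_max}, \code{motif}, \code{anchor_size}, \code{anchor_count}
#' (the size-to-repeat-count anchor of SSR loci), \code{indel_size} (for
#' mixed loci), \code{multiplex} and \code{gel_scored}.
#'
#' @param config path to a TSV/JSON/YAML file, or a data.frame.
#' @return a \code{\linkS4class{MarkerPanel}}.
#' @export
loadLocusDefinitions <- function(config) {
  df <- if (is.data.frame(config)) config
  else {
    ext <- tolower(tools::file_ext(config))
    switch(ext,
      tsv = , txt = read.delim(config, stringsAsFactors = FALSE,
                               na.strings = c("NA", "")),
      json = as.data.frame(jsonlite::fromJSON(config),
                           stringsAsFactors = FALSE),
      yaml = , yml = {
        lst <- yaml::read_yaml(config)
        rows <- lapply(lst, function(x) {
          x <- as.list(x)
          for (col in setdiff(.panelColumns, names(x))) x[[col]] <- NA
          as.data.frame(x[.panelColumns], stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
      },
      stop("unsupported panel config format: ", ext))
  }
  if (!nrow(df) && is.null(df$id))
    df <- data.frame(id = character(0))
  methods::new("MarkerPanel", loci = .completePanelFrame(df))
}

#' The olive tree cpDNA marker panel
#'
#' The packaged 64-locus olive plastome typing system: 62 length-polymorphism
#' loci (51 with microsatellite motifs) plus the CAPS-XapI and CAPS-EcoRI
#' restriction-site loci. The 35 loci recommended for rapid germplasm
#' characterisation carry their multiplex group, fluorescent dye and allele
#' size range; loci outside the published multiplexes are range-unknown.
#' Loci 8 and 61 are the gel-scored 225-bp and 342-bp diagnostic indels,
#' modelled as binary presence/absence calls.
#'
#' @return a \code{\linkS4class{MarkerPanel}} of 66 loci.
#' @export
olivePanel <- function() {
  loadLocusDefinitions(system.file("extdata", "olive_panel.tsv",
                                   package = "plastotype", mustWork = TRUE))
}

#' Panel loci as a data.frame
#' @param panel a \code{\linkS4class{MarkerPanel}}.
#' @export
panelLoci <- function(panel) panel@loci

.locusRow <- function(panel, id) {
  i <- match(as.character(id), panel@loci$id)
  if (is.na(i)) stop("unknown locus id: ", id)
  panel@loci[i, ]
}

#' Bin raw fragment sizes into integer allele calls
#'
#' Sizes are rounded to the nearest integer bp with half-up ties
#' (\code{158.5 -> 159}); calls falling outside the locus size range by more
#' than \code{tolerance} bp are flagged off-ladder.
#'
#' @param sizes numeric vector of raw fragment sizes (bp).
#' @param locus locus id, looked up in \code{panel}, or a one-row locus
#'   data.frame.
#' @param panel a \code{\linkS4class{MarkerPanel}} (when \code{locus} is an
#'   id).
#' @param tolerance off-ladder slack in bp beyond the size range (default 1).
#' @return data.frame with \code{size}, \code{allele}, \code{off_ladder}.
#' @export
binFragmentSizes <- function(sizes, locus, panel = NULL, tolerance = 1) {
  if (any(sizes < 0, na.rm = TRUE)) stop("negative fragment size")
  row <- if (is.data.frame(locus)) locus else .locusRow(panel, locus)
  allele <- floor(sizes + 0.5)  # half-up
  off <- rep(FALSE, length(sizes))
  if (!is.na(row$size_min) && !is.na(row$size_max))
    off <- allele < row$size_min - tolerance |
           allele > row$size_max + tolerance
  data.frame(size = sizes, allele = as.integer(allele), off_ladder = off)
}

#' Convert an allele size to a repeat count
#'
#' Uses the locus anchor (a known size/repeat-count pair) and motif length:
#' \code{count = anchor_count + (size - anchor_size) / nchar(motif)}. A
#' non-integer step means the size is inconsistent with the motif and raises
#' an error.
#'
#' @param size integer allele size(s) in bp.
#' @param locus locus id or one-row locus data.frame (must carry
#'   \code{motif}, \code{anchor_size}, \code{anchor_count}).
#' @param panel a \code{\linkS4class{MarkerPanel}} (when \code{locus} is an
#'   id).
#' @return integer repeat count(s).
#' @examples
#' loc <- data.frame(motif = "T", anchor_size = 158, anchor_count = 12)
#' sizeToRepeatCount(159, loc)  # 13
#' @export
sizeToRepeatCount <- function(size, locus, panel = NULL) {
  row <- if (is.data.frame(locus)) locus else .locusRow(panel, locus)
  if (is.na(row$motif) || is.na(row$anchor_size) || is.na(row$anchor_count))
    stop("locus ", row$id %||% "?", " carries no motif/anchor")
  step <- (size - row$anchor_size) / nchar(row$motif)
  if (any(abs(step - round(step)) > 1e-9, na.rm = TRUE))
    stop("allele size inconsistent with a whole number of ",
         row$motif, " motifs")
  cnt <- row$anchor_count + round(step)
  if (any(cnt < 0, na.rm = TRUE)) stop("negative repeat count implied")
  as.integer(cnt)
}

#' Repeat count back to allele size (anchor arithmetic inverse)
#' @inheritParams sizeToRepeatCount
#' @param count integer repeat count(s).
#' @export
repeatCountToSize <- function(count, locus, panel = NULL) {
  row <- if (is.data.frame(locus)) locus else .locusRow(panel, locus)
  as.integer(row$anchor_size + (count - row$anchor_count) * nchar(row$motif))
}

#' Validate a multiplex panel assignment
#'
#' An assignment passes when, within each dye (pooled across all
#' co-electrophoresed groups), the allele size ranges of the assigned loci
#' are pairwise disjoint, and no group exceeds \code{max_group_size} loci —
#' the constraints under which fragments from different loci can never be
#' confused on one capillary run.
#'
#' @param assignment data.frame with columns \code{locus}, \code{group},
#'   \code{dye} (a \code{PanelAssignment}).
#' @param panel a \code{\linkS4class{MarkerPanel}} providing size ranges.
#' @param max_group_size maximum loci per multiplex group (default 6).
#' @return list with \code{pass} (logical) and \code{violations}
#'   (data.frame describing each offending pair or oversized group).
#' @export
validatePanel <- function(assignment, panel, max_group_size = 6L) {
  unknown <- setdiff(assignment$locus, panel@loci$id)
  if (length(unknown))
    stop("unknown locus id(s): ", paste(unknown, collapse = ", "))
  viol <- list()
  for (g in unique(assignment$group)) {
    sz <- sum(assignment$group == g)
    if (sz > max_group_size)
      viol[[length(viol) + 1L]] <- data.frame(
        kind = "group_size", dye = NA, a = g, b = NA,
        detail = sprintf("%d loci > max %d", sz, max_group_size))
  }
  for (d in unique(assignment$dye)) {
    ids <- assignment$locus[assignment$dye == d]
    rows <- panel@loci[match(ids, panel@loci$id), ]
    rows <- rows[!is.na(rows$size_min) & !is.na(rows$size_max), ]
    if (nrow(rows) < 2L) next
    for (i in seq_len(nrow(rows) - 1L)) for (j in (i + 1L):nrow(rows)) {
      if (rows$size_min[i] <= rows$size_max[j] &&
          rows$size_min[j] <= rows$size_max[i])
        viol[[length(viol) + 1L]] <- data.frame(
          kind = "range_overlap", dye = d, a = rows$id[i], b = rows$id[j],
          detail = sprintf("[%g,%g] overlaps [%g,%g]",
                           rows$size_min[i], rows$size_max[i],
                           rows$size_min[j], rows$size_max[j]))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(kind = character(0), dye = character(0), a = character(0),
               b = character(0), detail = character(0))
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Design a dye-aware multiplex assignment
#'
#' Greedy interval-graph colouring: loci are taken in ascending order of
#' range start (ties by range end, then id) and placed first-fit onto the
#' first dye whose already-assigned ranges they do not overlap; each dye
#' track is then split into groups of at most \code{max_group_size} loci in
#' size order. Loci that fit no dye are reported unassignable. The result is
#' deterministic and always passes \code{\link{validatePanel}}; optimality
#' is not claimed.
#'
#' @param panel a \code{\linkS4class{MarkerPanel}}; loci without a size
#'   range are skipped (reported unassignable).
#' @param dyes dye names to use.
#' @param max_group_size maximum loci per multiplex group.
#' @param loci optional subset of locus ids to assign.
#' @return list with \code{assignment} (data.frame locus/group/dye) and
#'   \code{unassignable} (locus ids).
#' @export
designMultiplex <- function(panel, dyes = c("NED", "HEX", "6-FAM"),
                            max_group_size = 6L, loci = NULL) {
  df <- panel@loci
  if (!is.null(loci)) df <- df[df$id %in% as.character(loci), ]
  ranged <- df[!is.na(df$size_min) & !is.na(df$size_max), ]
  unassignable <- setdiff(df$id, ranged$id)
  ranged <- ranged[order(ranged$size_min, ranged$size_max, ranged$id), ]
  track <- setNames(vector("list", length(dyes)), dyes)
  assigned_dye <- character(0); assigned_id <- character(0)
  for (i in seq_len(nrow(ranged))) {
    placed <- FALSE
    for (d in dyes) {
      clash <- any(vapply(track[[d]], function(r)
        ranged$size_min[i] <= r[2L] && r[1L] <= ranged$size_max[i],
        logical(1L)))
      if (!clash) {
        track[[d]] <- c(track[[d]],
                        list(c(ranged$size_min[i], ranged$size_max[i])))
        assigned_dye <- c(assigned_dye, d)
        assigned_id <- c(assigned_id, ranged$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) unassignable <- c(unassignable, ranged$id[i])
  }
  rows <- list()
  for (d in dyes) {
    ids <- assigned_id[assigned_dye == d]
    if (!length(ids)) next
    ngrp <- ceiling(length(ids) / max_group_size)
    grp <- rep(seq_len(ngrp), each = max_group_size)[seq_along(ids)]
    rows[[length(rows) + 1L]] <- data.frame(
      locus = ids, group = sprintf("%s-%d", d, grp), dye = d,
      stringsAsFactors = FALSE)
  }
  assignment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), group = character(0),
               dye = character(0))
  list(assignment = assignment, unassignable = unassignable)
}

#' Replicate concordance report
#'
#' For genotyping reproducibility checks: given replicate sets of
#' individuals typed independently, reports per locus the fraction of sets
#' whose calls are identical, the overall concordance, and the loci with at
#' least one discordant set.
#'
#' @param genotypes a \code{\linkS4class{CpGenotypes}}.
#' @param replicate_map named list: set name -> individual ids.
#' @return list with \code{per_locus}, \code{overall}, \code{flagged}.
#' @export
replicateConcordance <- function(genotypes, replicate_map) {
  calls <- genotypes@calls
  if (!length(replicate_map))
    return(list(per_locus = data.frame(locus = character(0),
                                       concordance = numeric(0)),
                overall = NA_real_, flagged = character(0)))
  loci <- colnames(calls)
  conc <- vapply(loci, function(l) {
    ok <- vapply(replicate_map, function(ids) {
      v <- calls[ids, l]
      length(unique(v[!is.na(v)])) <= 1L
    }, logical(1L))
    mean(ok)
  }, numeric(1L))
  per_locus <- data.frame(locus = loci, concordance = unname(conc),
                          stringsAsFactors = FALSE)
  list(per_locus = per_locus, overall = mean(conc),
       flagged = loci[conc < 1])
}
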