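## Haplotype calling from multilocus profiles, frequency tables,
## discriminating power D = 1 - sum(p_i^2), and sharing summaries.

.profileKey <- function(v) paste(ifelse(is.na(v), "\033", v), collapse = "\r")

#' Collapse genotyped individuals into haplotypes
#'
#' Individuals with identical complete multilocus profiles share a
#' haplotype. Individuals with missing calls are assigned to an existing
#' haplotype only if exactly one catalogued profile is consistent with their
#' non-missing calls (the conservative policy); otherwise they are left
#' unassigned. New complete profiles are added to the catalog and named via
#' \code{\link{nameHaplotype}}.
#'
#' @param genotypes a \code{\linkS4class{CpGenotypes}} (typed and binned).
#' @param catalog optional existing \code{\linkS4class{HaplotypeCatalog}};
#'   ordinals already in the catalog are never renamed.
#' @param diagnostics optional lineage-diagnostic rule table (columns
#'   \code{lineage}, \code{locus}, \code{value}) used to name new profiles.
#' @param max_missing individuals missing more than this fraction of calls
#'   are never assigned (default 0.5).
#' @return list: \code{assignment} (data.frame individual/group/haplotype,
#'   \code{NA} = unassigned), \code{catalog} (updated).
#' @export
assignHaplotypes <- function(genotypes, catalog = NULL, diagnostics = NULL,
                             max_missing = 0.5) {
  calls <- genotypes@calls
  if (is.null(catalog))
    catalog <- methods::new("HaplotypeCatalog",
      profiles = matrix(character(0), 0L, ncol(calls),
                        dimnames = list(NULL, colnames(calls))),
      diagnostics = diagnostics %||%
        data.frame(lineage = character(0), locus = character(0),
                   value = character(0)))
  if (!is.null(diagnostics)) catalog@diagnostics <- diagnostics
  profiles <- catalog@profiles

  complete <- rowSums(is.na(calls)) == 0L
  ## register new complete profiles, most frequent first so ordinals follow
  ## descending observed frequency at catalog build time
  if (any(complete)) {
    keys <- apply(calls[complete, , drop = FALSE], 1L, .profileKey)
    known <- if (nrow(profiles)) apply(profiles, 1L, .profileKey)
             else character(0)
    tab <- sort(table(keys[!keys %in% known]), decreasing = TRUE)
    for (key in names(tab)) {
      prof <- calls[complete, , drop = FALSE][match(key, keys), ]
      nm <- nameHaplotype(prof, catalog)
      profiles <- rbind(profiles, matrix(prof, 1L,
        dimnames = list(nm, colnames(calls))))
      catalog@profiles <- profiles
    }
  }
  known_keys <- if (nrow(profiles)) apply(profiles, 1L, .profileKey)
                else character(0)
  hap <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    if (mean(is.na(v)) > max_missing) next
    if (!anyNA(v)) {
      hap[i] <- rownames(profiles)[match(.profileKey(v), known_keys)]
    } else if (nrow(profiles)) {
      ok <- which(apply(profiles, 1L, function(p)
        all(p[!is.na(v)] == v[!is.na(v)])))
      if (length(ok) == 1L) hap[i] <- rownames(profiles)[ok]
    }
  }
  list(assignment = data.frame(individual = rownames(calls),
                               group = genotypes@groups, haplotype = hap,
                               stringsAsFactors = FALSE),
       catalog = catalog)
}

#' Name a haplotype profile
#'
#' The lineage prefix comes from the first matching diagnostic rule (e.g. a
#' profile carrying the locus-61 deletion state belongs to lineage E3); with
#' no matching rule the prefix is \code{"U"} (unassigned lineage). The
#' ordinal is the next free integer within that lineage.
#'
#' @param profile named character vector of calls over the locus set.
#' @param catalog a \code{\linkS4class{HaplotypeCatalog}} (supplies the
#'   diagnostics and the already-used names).
#' @return haplotype name, e.g. \code{"E3.2"}.
#' @export
nameHaplotype <- function(profile, catalog) {
  diag <- catalog@diagnostics
  prefix <- "U"
  if (!is.null(diag) && nrow(diag)) {
    for (i in seq_len(nrow(diag))) {
      v <- profile[[as.character(diag$locus[i])]]
      if (!is.null(v) && !is.na(v) && v == as.character(diag$value[i])) {
        prefix <- diag$lineage[i]
        break
      }
    }
  }
  used <- rownames(catalog@profiles) %||% character(0)
  used <- used[startsWith(used, paste0(prefix, "."))]
  ords <- suppressWarnings(as.integer(sub(".*\\.", "", used)))
  nxt <- if (length(ords)) max(ords, na.rm = TRUE) + 1L else 1L
  sprintf("%s.%d", prefix, nxt)
}

#' Haplotype frequency table by group
#'
#' @param assignment data.frame with \code{group} and \code{haplotype}
#'   columns (unassigned \code{NA} rows are dropped with a warning).
#' @param pooled also include a pooled column over all groups.
#' @return list with matrices \code{count} and \code{proportion}
#'   (haplotypes x groups) and \code{n} per group.
#' @export
haplotypeFrequencies <- function(assignment, pooled = TRUE) {
  drop <- is.na(assignment$haplotype)
  if (any(drop)) {
    warning(sum(drop), " unassigned individual(s) excluded")
    assignment <- assignment[!drop, ]
  }
  tab <- table(assignment$haplotype, assignment$group)
  empty <- colSums(tab) == 0L
  if (any(empty)) {
    warning("empty group(s) excluded: ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  cnt <- unclass(tab)
  if (pooled) cnt <- cbind(cnt, pooled = rowSums(cnt))
  storage.mode(cnt) <- "integer"
  prop <- sweep(cnt, 2L, colSums(cnt), "/")
  list(count = cnt, proportion = prop, n = colSums(cnt))
}

#' Discriminating power D
#'
#' The probability that two individuals sampled at random carry different
#' haplotypes: \code{D = 1 - sum(p_i^2)} with plug-in frequencies (no
#' small-sample correction). Pooled D must be computed from pooled counts,
#' never by averaging per-group values.
#'
#' @param p haplotype frequencies (proportions summing to 1 within 1e-6) or,
#'   with \code{counts = TRUE}, nonnegative integer counts.
#' @param counts interpret \code{p} as counts.
#' @return D in \code{[0, 1 - 1/n]}.
#' @examples
#' discriminatingPower(c(0.5, 0.5))  # 0.5
#' @export
discriminatingPower <- function(p, counts = FALSE) {
  if (counts) {
    if (any(p < 0) || sum(p) == 0) stop("counts must be nonnegative, not all zero")
    p <- p / sum(p)
  } else if (abs(sum(p) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  1 - sum(p^2)
}

#' Haplotype sharing between two pools
#'
#' Counts haplotypes present on each side of a group partition (e.g.
#' cultivated vs wild) and in both.
#'
#' @param freqs result of \code{\link{haplotypeFrequencies}}, or a count
#'   matrix (haplotypes x groups).
#' @param partition named list of two character vectors of group names.
#' @return named integer vector: per-side totals (using the partition
#'   names), \code{shared}, and \code{total}.
#' @export
sharingSummary <- function(freqs, partition) {
  cnt <- if (is.list(freqs) && !is.null(freqs$count)) freqs$count else freqs
  cnt <- cnt[, colnames(cnt) != "pooled", drop = FALSE]
  stopifnot(length(partition) == 2L)
  miss <- setdiff(colnames(cnt), unlist(partition))
  if (length(miss))
    stop("partition does not cover group(s): ", paste(miss, collapse = ", "))
  side <- lapply(partition, function(g)
    rownames(cnt)[rowSums(cnt[, colnames(cnt) %in% g, drop = FALSE]) > 0L])
  out <- c(lengths(side),
           shared = length(intersect(side[[1L]], side[[2L]])),
           total = length(union(side[[1L]], side[[2L]])))
  names(out)[1:2] <- names(partition)
  out
}

#' The published olive haplotype frequency survey
#'
#' Packaged haplotype frequency percentages for 186 Mediterranean olive
#' cultivars and five wild (oleaster) populations surveyed with the
#' \code{\link{olivePanel}} loci.
#'
#' @return data.frame with columns \code{haplotype}, \code{group},
#'   \code{pool} (\code{cultivated}/\code{wild}) and \code{percent}.
#' @export
oliveFrequencies <- function() {
  read.delim(system.file("extdata", "olive_haplotype_freqs.tsv",
                         package = "plastotype", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Infer a sample size from printed percentages
#'
#' Finds the smallest n (at least the number of nonzero classes) such that
#' every percentage equals \code{round(100 * c / n, 1)} for some integer
#' count c. Useful for reconstructing counts from published frequency tables.
#'
#' @param percents numeric percentages (one decimal).
#' @param n_max search bound.
#' @return integer sample size, or \code{NA} if none fits.
#' @export
inferSampleSize <- function(percents, n_max = 1000L) {
  percents <- percents[percents > 0]
  for (n in seq.int(max(2L, length(percents)), n_max)) {
    cnt <- round(percents / 100 * n)
    if (all(cnt >= 1) && all(round(100 * cnt / n, 1L) == percents))
      return(n)
  }
  NA_integer_
}

#' Reconstruct integer counts from percentages at a known sample size
#'
#' Counts are \code{round(percent / 100 * n)}; if they do not sum to n
#' (a rounding or typographic inconsistency in the source table), the
#' largest count is adjusted by the difference.
#'
#' @param percents numeric percentages.
#' @param n sample size.
#' @return integer counts summing to \code{n}.
#' @export
countsFromPercent <- function(percents, n) {
  cnt <- round(percents / 100 * n)
  excess <- sum(cnt) - n
  if (excess != 0) {
    i <- which.max(cnt)
    cnt[i] <- cnt[i] - excess
  }
  as.integer(cnt)
}
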