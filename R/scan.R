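## Polymorphism scanning of aligned plastid genomes: substitutions, indels,
## SSR tracts, pairwise divergence and substitution-rate arithmetic.

#' Scan an alignment for nucleotide substitutions
#'
#' One record is emitted per alignment column that contains at least two
#' distinct bases among non-gap, non-N rows. Columns containing any gap are
#' excluded from substitution calling (indels are scanned separately by
#' \code{\link{scanIndels}}), so substitution and indel events never double
#' count a column.
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @return data.frame with columns \code{ref_position}, \code{column},
#'   \code{type}, \code{informative}, and one state column per taxon.
#' @export
scanSubstitutions <- function(aln) {
  m <- alignmentMatrix(aln)
  pos <- referencePositions(aln)
  no_gap <- colSums(m == "-") == 0L
  cand <- which(no_gap)
  recs <- lapply(cand, function(j) {
    st <- m[, j]
    obs <- st[st != "N"]
    if (length(unique(obs)) < 2L) return(NULL)
    j
  })
  cols <- unlist(recs)
  out <- data.frame(
    ref_position = if (length(cols)) pos$position[cols] else integer(0),
    column = cols %||% integer(0),
    type = rep("substitution", length(cols)),
    stringsAsFactors = FALSE)
  states <- if (length(cols)) t(m[, cols, drop = FALSE]) else
    matrix(character(0), 0L, nrow(m), dimnames = list(NULL, rownames(m)))
  colnames(states) <- rownames(m)
  out <- cbind(out, as.data.frame(states, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out$informative <- informativeSites(out, names(aln))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag parsimony-informative sites
#'
#' A site is parsimony-informative when at least two distinct states are each
#' carried by at least two taxa (gaps and N treated as missing).
#'
#' @param records data.frame from \code{\link{scanSubstitutions}} (or any
#'   frame holding per-taxon state columns).
#' @param taxa names of the per-taxon state columns.
#' @return logical vector, one per record.
#' @export
informativeSites <- function(records, taxa) {
  if (!nrow(records)) return(logical(0))
  st <- as.matrix(records[, taxa, drop = FALSE])
  apply(st, 1L, function(s) {
    s <- s[!is.na(s) & !s %in% c("N", "-", "?")]
    sum(table(s) >= 2L) >= 2L
  })
}

#' Scan an alignment for insertion/deletion events
#'
#' Maximal runs of adjacent gap columns sharing an identical presence/absence
#' pattern across taxa are merged into a single event. Each event reports its
#' length, the reference position of the base preceding it (insertions
#' relative to the reference anchor to that base) and per-taxon presence
#' (1 = sequence present, 0 = gapped).
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @return data.frame with \code{ref_position}, \code{col_start},
#'   \code{col_end}, \code{length}, \code{type}, and presence columns
#'   (one per taxon, named \code{present.<taxon>}).
#' @export
scanIndels <- function(aln) {
  m <- alignmentMatrix(aln)
  pos <- referencePositions(aln)
  gap <- m == "-"
  has_gap <- colSums(gap) > 0L
  ncolm <- ncol(m)
  pat <- apply(gap, 2L, function(g) paste(as.integer(g), collapse = ""))
  ## run boundaries: gap column whose pattern differs from its left neighbour
  events <- list()
  j <- 1L
  while (j <= ncolm) {
    if (!has_gap[j]) { j <- j + 1L; next }
    k <- j
    while (k < ncolm && has_gap[k + 1L] && pat[k + 1L] == pat[j]) k <- k + 1L
    events[[length(events) + 1L]] <- c(j, k)
    j <- k + 1L
  }
  if (!length(events)) {
    out <- data.frame(ref_position = integer(0), col_start = integer(0),
                      col_end = integer(0), length = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
    pres <- matrix(integer(0), 0L, nrow(m),
                   dimnames = list(NULL, paste0("present.", rownames(m))))
    return(cbind(out, as.data.frame(pres)))
  }
  ev <- do.call(rbind, events)
  ## deletions: first deleted reference base; insertions (reference gapped):
  ## preceding reference base — both equal the cumulative count at col_start
  anchor <- pos$position[ev[, 1L]]
  out <- data.frame(ref_position = anchor,
                    col_start = ev[, 1L], col_end = ev[, 2L],
                    length = ev[, 2L] - ev[, 1L] + 1L,
                    type = "indel", stringsAsFactors = FALSE)
  pres <- t(vapply(seq_len(nrow(ev)), function(i)
    as.integer(!gap[, ev[i, 1L]]), integer(nrow(m))))
  colnames(pres) <- paste0("present.", rownames(m))
  cbind(out, as.data.frame(pres))
}

#' Classify an indel event
#'
#' Classes follow the olive plastome survey convention: an event inside an
#' annotated SSR tract whose length is a multiple of the motif is an SSR
#' length step (\code{ssr_motif}); a 7-12 bp event whose inserted/deleted
#' block duplicates the immediately adjacent flanking sequence is a
#' \code{repeated_motif_7_12} duplication; events longer than 12 bp are
#' \code{long} (e.g. the diagnostic 225-bp and 342-bp deletions); anything
#' else is \code{other_short}.
#'
#' @param event one row of the \code{\link{scanIndels}} result.
#' @param aln the alignment the event was called on.
#' @param ssr optional SSR annotation frame from \code{\link{detectSSR}}
#'   (columns \code{ref_start}, \code{ref_end}, \code{motif}).
#' @return one of \code{"ssr_motif"}, \code{"repeated_motif_7_12"},
#'   \code{"other_short"}, \code{"long"}.
#' @export
classifyIndel <- function(event, aln, ssr = NULL) {
  len <- event$length
  if (!is.null(ssr) && nrow(ssr)) {
    hit <- ssr$ref_start <= event$ref_position + 1L &
           ssr$ref_end >= event$ref_position
    for (i in which(hit)) {
      if (len %% nchar(ssr$motif[i]) == 0L) return("ssr_motif")
    }
  }
  if (len > 12L) return("long")
  if (len >= 7L) {
    ## duplication test: gapped block equals the adjacent upstream or
    ## downstream block in a taxon carrying the sequence
    m <- alignmentMatrix(aln)
    carrier <- which(m[, event$col_start] != "-")[1L]
    if (!is.na(carrier)) {
      row <- m[carrier, ]
      block <- paste(row[event$col_start:event$col_end], collapse = "")
      up_start <- event$col_start - len
      if (up_start >= 1L) {
        up <- paste(row[up_start:(event$col_start - 1L)], collapse = "")
        if (up == block) return("repeated_motif_7_12")
      }
      dn_end <- event$col_end + len
      if (dn_end <= ncol(m)) {
        dn <- paste(row[(event$col_end + 1L):dn_end], collapse = "")
        if (dn == block) return("repeated_motif_7_12")
      }
    }
  }
  "other_short"
}

#' Detect microsatellite (SSR) tracts
#'
#' Finds maximal non-overlapping tracts of a tandemly repeated primitive
#' motif (1-6 bp) meeting per-motif-length minimum repeat counts. On an
#' alignment, detection runs on the ungapped reference and per-taxon repeat
#' counts are read through the alignment columns spanning the tract
#' (including adjacent insertion columns).
#'
#' @param x a sequence (character scalar) or a
#'   \code{\linkS4class{PlastomeAlignment}}.
#' @param thresholds minimum repeat count by motif length 1-6. Defaults:
#'   mononucleotide >= 8, dinucleotide >= 5, tri- to hexanucleotide >= 4.
#' @return data.frame with \code{motif}, \code{ref_start}, \code{ref_end},
#'   \code{repeat_count}, and (for alignments) \code{count.<taxon>} columns.
#' @export
detectSSR <- function(x, thresholds = c(8L, 5L, 4L, 4L, 4L, 4L)) {
  stopifnot(length(thresholds) == 6L)
  if (methods::is(x, "PlastomeAlignment")) return(.detectSSRAln(x, thresholds))
  seq <- toupper(as.character(x))
  .detectSSRSeq(seq, thresholds)
}

.smallestPeriod <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p) next
    motif <- substr(s, 1L, p)
    if (strrep(motif, n %/% p) == s) return(p)
  }
  n
}

.detectSSRSeq <- function(seq, thresholds) {
  hits <- list()
  for (m in 1:6) {
    ## maximal tandem runs of any m-mer; primitivity filtered afterwards
    re <- sprintf("([ACGT]{%d})\\1+", m)
    g <- gregexpr(re, seq, perl = TRUE)[[1L]]
    if (g[1L] == -1L) next
    for (i in seq_along(g)) {
      start <- g[i]
      len <- attr(g, "match.length")[i]
      tract <- substr(seq, start, start + len - 1L)
      if (.smallestPeriod(substr(tract, 1L, m)) != m) next
      motif <- substr(tract, 1L, m)
      ## regex may leave a partial trailing motif unmatched; keep whole copies
      count <- len %/% m
      ## extend by any further full copies missed due to greedy anchoring
      while (substr(seq, start + count * m, start + (count + 1L) * m - 1L)
             == motif && start + (count + 1L) * m - 1L <= nchar(seq))
        count <- count + 1L
      if (count < thresholds[m]) next
      hits[[length(hits) + 1L]] <-
        data.frame(motif = motif, ref_start = start,
                   ref_end = start + count * m - 1L, repeat_count = count,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(0), ref_start = integer(0),
                      ref_end = integer(0), repeat_count = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$ref_start, -(out$ref_end - out$ref_start)), ,
             drop = FALSE]
  ## resolve overlaps: keep longer tract, then earlier start
  span <- out$ref_end - out$ref_start
  ord <- order(-span, out$ref_start)
  sel <- rep(FALSE, nrow(out))
  occupied <- integer(0)
  for (i in ord) {
    rng <- out$ref_start[i]:out$ref_end[i]
    if (!any(rng %in% occupied)) {
      sel[i] <- TRUE
      occupied <- c(occupied, rng)
    }
  }
  out <- out[sel, , drop = FALSE]
  out <- out[order(out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.detectSSRAln <- function(aln, thresholds) {
  refseq <- ungappedSequence(aln)
  ann <- .detectSSRSeq(refseq, thresholds)
  if (!nrow(ann)) return(ann)
  pos <- referencePositions(aln)
  m <- alignmentMatrix(aln)
  n_aln <- ncol(m)
  counts <- matrix(0L, nrow(ann), nrow(m),
                   dimnames = list(NULL, paste0("count.", rownames(m))))
  for (i in seq_len(nrow(ann))) {
    c1 <- which(pos$is_ref & pos$position == ann$ref_start[i])[1L]
    c2 <- which(pos$is_ref & pos$position == ann$ref_end[i])[1L]
    ## absorb adjacent insertion columns (reference-gapped) after the tract
    while (c2 < n_aln && !pos$is_ref[c2 + 1L]) c2 <- c2 + 1L
    motif <- ann$motif[i]
    for (t in seq_len(nrow(m))) {
      s <- gsub("-", "", paste(m[t, c1:c2], collapse = ""), fixed = TRUE)
      cnt <- 0L
      while (substr(s, cnt * nchar(motif) + 1L,
                    (cnt + 1L) * nchar(motif)) == motif)
        cnt <- cnt + 1L
      counts[i, t] <- cnt
    }
  }
  cbind(ann, as.data.frame(counts))
}

#' Pairwise substitution counts and divergence
#'
#' For every taxon pair, counts alignment columns where both taxa carry
#' differing non-gap, non-N bases; the divergence proportion divides by the
#' pair's shared ungapped (and unambiguous) column count.
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @return list with symmetric matrices \code{count}, \code{shared_length}
#'   and \code{proportion}.
#' @export
pairwiseSubstitutions <- function(aln) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("at least two taxa required")
  ok <- m != "-" & m != "N"
  cnt <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  len <- cnt
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    d <- sum(both & m[i, ] != m[j, ])
    cnt[i, j] <- cnt[j, i] <- d
    len[i, j] <- len[j, i] <- sum(both)
  }
  prop <- ifelse(len > 0L, cnt / len, 0)
  diag(prop) <- 0
  list(count = cnt, shared_length = len, proportion = prop)
}

#' Percent divergence
#'
#' @param count substitution count.
#' @param length aligned ungapped length in bp (> 0).
#' @return percentage, rounded to two decimals.
#' @examples
#' percentDivergence(106, 155531)  # 0.07
#' @export
percentDivergence <- function(count, length) {
  if (any(length <= 0)) stop("length must be positive")
  round(100 * count / length, 2L)
}

#' Per-site per-year substitution rate
#'
#' Divides total pairwise divergence by the divergence time T (a
#' \code{(substitutions / genome_length) / T} convention).
#'
#' @param substitutions substitution count (>= 0).
#' @param genome_length genome length in bp (> 0).
#' @param divergence_time divergence time in years (> 0).
#' @return list with the exact \code{rate} and \code{rate_2sf} (two
#'   significant figures, as conventionally reported).
#' @examples
#' substitutionRate(417, 155896, 22e6)$rate_2sf  # 1.2e-10
#' @export
substitutionRate <- function(substitutions, genome_length, divergence_time) {
  if (substitutions < 0) stop("substitutions must be nonnegative")
  if (genome_length <= 0 || divergence_time <= 0)
    stop("genome length and divergence time must be positive")
  rate <- (substitutions / genome_length) / divergence_time
  list(substitutions = substitutions, genome_length = genome_length,
       divergence_time = divergence_time, rate = rate,
       rate_2sf = signif(rate, 2L))
}

#' Coding effect of a substitution
#'
#' Translates the codon containing the site under each observed state and
#' classifies the change as synonymous, non-synonymous, or non-coding when
#' the position falls outside every annotated interval.
#'
#' @param ref_position 1-based position on the reference sequence.
#' @param states character vector of observed bases at the site.
#' @param annotation data.frame of gene intervals with columns \code{start},
#'   \code{end}, \code{strand} (\code{+}/\code{-}), \code{frame} (0-2 offset
#'   of the first complete codon) and \code{name}.
#' @param refseq ungapped reference sequence (character scalar).
#' @return list with \code{effect}, \code{gene} and the amino acids per state.
#' @export
codingEffect <- function(ref_position, states, annotation, refseq) {
  states <- unique(toupper(states))
  states <- states[states %in% c("A", "C", "G", "T")]
  hit <- which(annotation$start <= ref_position &
               annotation$end >= ref_position)
  if (!length(hit))
    return(list(effect = "non-coding", gene = NA_character_, aa = NULL))
  g <- annotation[hit[1L], ]
  code <- Biostrings::GENETIC_CODE
  aa <- vapply(states, function(b) {
    s <- strsplit(toupper(refseq), "", fixed = TRUE)[[1L]]
    s[ref_position] <- b
    if (identical(g$strand, "-")) {
      gene <- rev(chartr("ACGT", "TGCA", s[g$start:g$end]))
      off <- (g$end - ref_position) - g$frame
    } else {
      gene <- s[g$start:g$end]
      off <- (ref_position - g$start) - g$frame
    }
    cidx <- off %/% 3L
    cod <- paste(gene[(g$frame + cidx * 3L + 1L):(g$frame + cidx * 3L + 3L)],
                 collapse = "")
    unname(code[cod])
  }, character(1L))
  effect <- if (length(unique(aa)) > 1L) "non-synonymous" else "synonymous"
  list(effect = effect, gene = g$name, aa = aa)
}

#' Full variant scan of an alignment
#'
#' Convenience wrapper running \code{\link{scanSubstitutions}},
#' \code{\link{scanIndels}} (with classification) and \code{\link{detectSSR}}.
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @param thresholds SSR detection thresholds, see \code{\link{detectSSR}}.
#' @return list with \code{substitutions}, \code{indels}, \code{ssr} and a
#'   \code{summary} of counts.
#' @export
scanAlignment <- function(aln, thresholds = c(8L, 5L, 4L, 4L, 4L, 4L)) {
  ssr <- detectSSR(aln, thresholds)
  subs <- scanSubstitutions(aln)
  ind <- scanIndels(aln)
  if (nrow(ind))
    ind$class <- vapply(seq_len(nrow(ind)), function(i)
      classifyIndel(ind[i, ], aln, ssr), character(1L))
  else ind$class <- character(0)
  list(substitutions = subs, indels = ind, ssr = ssr,
       summary = c(n_substitutions = nrow(subs),
                   n_informative = sum(subs$informative),
                   n_indels = nrow(ind), n_ssr = nrow(ssr)))
}
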