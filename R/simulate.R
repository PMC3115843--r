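## Synthetic plastome and population-genotype generator. Every downstream
## stage (scanner, typing, haplotyping, network, parsimony) is validated
## against the truth tables these functions emit.
##
## RNG discipline: each entry point takes one integer seed and restores the
## caller's RNG state on exit. Draw order is fixed and documented per
## function, so identical seeds give byte-identical outputs.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build a root plastome-like genome with planted features
#'
#' Generates a seeded random nucleotide sequence and plants microsatellite
#' tracts verbatim at the stated positions. The single base flanking each
#' tract on either side is forced off-motif so a planted \code{(T)12} is
#' exactly 12 repeats, never accidentally extended. Designated long-deletion
#' sites and gene intervals are carried as annotation for the evolver.
#'
#' @param length genome length in bp.
#' @param ssr_loci data.frame with columns \code{position} (1-based tract
#'   start), \code{motif} (1-6 bp) and \code{repeat_count}; may be NULL.
#' @param gene_intervals optional data.frame (\code{start}, \code{end},
#'   \code{strand}, \code{frame}, \code{name}).
#' @param long_indel_sites optional data.frame (\code{position},
#'   \code{length}) of designated long-deletion sites.
#' @param seed integer seed.
#' @return list of class \code{RootGenome}: \code{sequence}, \code{length},
#'   \code{ssr} (with \code{ref_start}/\code{ref_end}), \code{genes},
#'   \code{long_indel_sites}, \code{seed}.
#' @examples
#' g <- buildRootGenome(2000,
#'   ssr_loci = data.frame(position = 500, motif = "T", repeat_count = 12),
#'   seed = 1)
#' substr(g$sequence, 500, 511)  # "TTTTTTTTTTTT"
#' @export
buildRootGenome <- function(length, ssr_loci = NULL, gene_intervals = NULL,
                            long_indel_sites = NULL, seed = 1L) {
  stopifnot(length >= 1L)
  ssr <- ssr_loci
  if (!is.null(ssr) && nrow(ssr)) {
    if (any(nchar(ssr$motif) < 1L | nchar(ssr$motif) > 6L))
      stop("SSR motif length must be 1-6 bp")
    ssr$ref_start <- as.integer(ssr$position)
    ssr$ref_end <- ssr$ref_start + nchar(ssr$motif) * ssr$repeat_count - 1L
    if (any(ssr$ref_start < 1L) || any(ssr$ref_end > length))
      stop("SSR placement outside [1, length]")
    o <- order(ssr$ref_start)
    ssr <- ssr[o, , drop = FALSE]
    if (nrow(ssr) > 1L &&
        any(ssr$ref_start[-1L] <= ssr$ref_end[-nrow(ssr)] + 1L))
      stop("SSR placements overlap or touch")
  }
  if (!is.null(gene_intervals) && nrow(gene_intervals) &&
      (any(gene_intervals$start < 1L) || any(gene_intervals$end > length)))
    stop("gene interval outside [1, length]")
  bases <- c("A", "C", "G", "T")
  seq <- .withSeed(seed, sample(bases, length, replace = TRUE))
  if (!is.null(ssr) && nrow(ssr)) {
    for (i in seq_len(nrow(ssr))) {
      mot <- strsplit(ssr$motif[i], "", fixed = TRUE)[[1L]]
      tract <- rep(mot, ssr$repeat_count[i])
      seq[ssr$ref_start[i]:ssr$ref_end[i]] <- tract
      ## break the repeat phase at both flanks
      p <- ssr$ref_start[i] - 1L
      if (p >= 1L && seq[p] == mot[base::length(mot)])
        seq[p] <- setdiff(bases, mot[base::length(mot)])[1L]
      p <- ssr$ref_end[i] + 1L
      if (p <= length && seq[p] == mot[1L])
        seq[p] <- setdiff(bases, mot[1L])[1L]
    }
  }
  structure(list(sequence = paste(seq, collapse = ""), length = length,
                 ssr = ssr, genes = gene_intervals,
                 long_indel_sites = long_indel_sites, seed = seed),
            class = "RootGenome")
}

.tipsBelow <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .tipsBelow, tree = tree))
}

#' Evolve a root genome along a genealogy
#'
#' Simulates substitutions, single-step SSR mutations and indels along each
#' branch of a rooted tree, then assembles the gapped leaf alignment and a
#' truth table mapping every event to its alignment columns. Events are
#' drawn from Poisson counts (\code{rate x branch length}); overlapping
#' placements are rejected and redrawn so the truth-to-alignment mapping is
#' unambiguous, and non-SSR events avoid planted SSR tracts (padded by one
#' motif length) so every event has a single unambiguous class.
#'
#' Draw order per branch (branches in \code{tree$edge} row order):
#' substitution count and placements, SSR step counts and signs per locus
#' (locus order), indel count, types and placements.
#'
#' @param root a \code{RootGenome} from \code{\link{buildRootGenome}}.
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param model list with \code{sub_rate} (per site per branch-length unit),
#'   \code{ssr_step_rate} (per locus per unit), \code{indel_rate} (per genome
#'   per unit) and \code{indel_length_law}, a named weight vector over
#'   \code{c("dup7_12", "other_short", "long")}.
#' @param seed integer seed.
#' @return list: \code{alignment} (a \code{PlastomeAlignment} over the
#'   leaves, reference = first tip), \code{truth} (data.frame: branch, type,
#'   position, length, detail, col_start, col_end), \code{root}.
#' @export
evolveGenomes <- function(root, tree, model, seed = 1L) {
  stopifnot(inherits(root, "RootGenome"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  law <- model$indel_length_law %||%
    c(dup7_12 = 0.4, other_short = 0.4, long = 0.2)
  if (abs(sum(law) - 1) > 1e-9) stop("indel mixture weights must sum to 1")
  rates <- c(model$sub_rate %||% 0, model$ssr_step_rate %||% 0,
             model$indel_rate %||% 0)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("model rates must be finite and nonnegative")

  L <- root$length
  rootseq <- strsplit(root$sequence, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  ssr <- root$ssr
  n_ssr <- if (is.null(ssr)) 0L else nrow(ssr)
  ## positions barred to non-SSR events: tracts padded by one motif length
  protected <- rep(FALSE, L)
  if (n_ssr) for (i in seq_len(n_ssr)) {
    pad <- nchar(ssr$motif[i])
    protected[max(1L, ssr$ref_start[i] - pad):
              min(L, ssr$ref_end[i] + pad)] <- TRUE
  }
  occupied <- protected  # grows as events land
  long_sites <- root$long_indel_sites
  long_used <- if (is.null(long_sites)) logical(0) else
    rep(FALSE, nrow(long_sites))
  ## designated long-deletion intervals are reserved up front so no other
  ## event can ever land inside one
  if (length(long_used)) for (i in seq_along(long_used))
    occupied[long_sites$position[i]:
             min(L, long_sites$position[i] + long_sites$length[i] - 1L)] <-
      TRUE

  tips <- tree$tip.label
  edge_child <- tree$edge[, 2L]
  branch_name <- ifelse(edge_child <= length(tips), tips[edge_child],
                        paste0("node", edge_child))
  events <- list()
  .withSeed(seed, {
    for (e in seq_len(nrow(tree$edge))) {
      bl <- tree$edge.length[e]
      below <- .tipsBelow(tree, edge_child[e])
      ## substitutions
      n_sub <- rpois(1L, (model$sub_rate %||% 0) * L * bl)
      for (k in seq_len(n_sub)) {
        for (try in 1:1000) {
          p <- sample.int(L, 1L)
          if (!occupied[p]) break
          if (try == 1000L) stop("genome too saturated to place substitution")
        }
        occupied[p] <- TRUE
        newb <- sample(setdiff(bases, rootseq[p]), 1L)
        events[[length(events) + 1L]] <- list(
          branch = branch_name[e], tips = below, type = "substitution",
          position = p, length = 1L,
          detail = paste0(rootseq[p], ">", newb), base = newb)
      }
      ## SSR steps
      if (n_ssr) for (i in seq_len(n_ssr)) {
        n_step <- rpois(1L, (model$ssr_step_rate %||% 0) * bl)
        for (k in seq_len(n_step)) {
          delta <- sample(c(-1L, 1L), 1L)
          events[[length(events) + 1L]] <- list(
            branch = branch_name[e], tips = below, type = "ssr_step",
            position = ssr$ref_start[i], length = nchar(ssr$motif[i]),
            detail = sprintf("locus%d:%+d", i, delta),
            locus = i, delta = delta)
        }
      }
      ## indels
      n_ind <- rpois(1L, (model$indel_rate %||% 0) * bl)
      for (k in seq_len(n_ind)) {
        type <- sample(names(law), 1L, prob = law)
        if (type == "long" && (!length(long_used) || all(long_used)))
          type <- "other_short"
        if (type == "long") {
          i <- which(!long_used)[1L]
          long_used[i] <- TRUE
          p <- long_sites$position[i]; len <- long_sites$length[i]
          events[[length(events) + 1L]] <- list(
            branch = branch_name[e], tips = below, type = "indel",
            position = p, length = len, detail = "deletion:long",
            indel = "del", class = "long")
        } else if (type == "dup7_12") {
          len <- sample(7:12, 1L)
          for (try in 1:1000) {
            a <- sample(seq.int(len + 1L, L), 1L)  # anchor: block ends at a
            if (!any(occupied[(a - len + 1L):a])) break
            if (try == 1000L) stop("genome too saturated to place duplication")
          }
          occupied[(a - len + 1L):a] <- TRUE
          events[[length(events) + 1L]] <- list(
            branch = branch_name[e], tips = below, type = "indel",
            position = a, length = len, detail = "insertion:dup",
            indel = "ins", class = "repeated_motif_7_12",
            insert = paste(rootseq[(a - len + 1L):a], collapse = ""))
        } else {
          len <- sample(1:6, 1L)
          for (try in 1:1000) {
            p <- sample.int(L - len, 1L)
            if (!any(occupied[p:(p + len - 1L)])) break
            if (try == 1000L) stop("genome too saturated to place deletion")
          }
          occupied[p:(p + len - 1L)] <- TRUE
          events[[length(events) + 1L]] <- list(
            branch = branch_name[e], tips = below, type = "indel",
            position = p, length = len, detail = "deletion:short",
            indel = "del", class = "other_short")
        }
      }
    }
  })

  .assembleAlignment(rootseq, tips, events, ssr, root)
}

## Assemble the gapped leaf alignment from the root sequence and the global,
## pairwise-disjoint event list; returns alignment + truth table.
.assembleAlignment <- function(rootseq, tips, events, ssr, root) {
  L <- length(rootseq)
  ntip <- length(tips)
  n_ssr <- if (is.null(ssr)) 0L else nrow(ssr)

  ## per-leaf SSR repeat counts (floor 1: a step that would reach 0 flips)
  counts <- if (n_ssr)
    matrix(rep(ssr$repeat_count, each = ntip), ntip, n_ssr,
           dimnames = list(tips, NULL)) else
    matrix(0L, ntip, 0L, dimnames = list(tips, NULL))
  realized_delta <- integer(length(events))
  for (ei in seq_along(events)) {
    ev <- events[[ei]]
    if (ev$type != "ssr_step") next
    d <- ev$delta
    tt <- ev$tips
    if (d < 0L && any(counts[tt, ev$locus] + d < 1L)) d <- 1L  # flip at floor
    counts[tt, ev$locus] <- counts[tt, ev$locus] + d
    realized_delta[ei] <- d
    events[[ei]]$delta <- d
    events[[ei]]$detail <- sprintf("locus%d:%+d", ev$locus, d)
  }

  ## leaf base matrix on root coordinates
  M <- matrix(rep(rootseq, each = ntip), ntip, L, dimnames = list(tips, NULL))
  for (ev in events) {
    if (ev$type == "substitution") M[ev$tips, ev$position] <- ev$base
    else if (ev$type == "indel" && ev$indel == "del")
      M[ev$tips, ev$position:(ev$position + ev$length - 1L)] <- "-"
  }
  ## SSR contraction below root count: gap trailing motif copies
  if (n_ssr) for (i in seq_len(n_ssr)) {
    r0 <- ssr$repeat_count[i]; m <- nchar(ssr$motif[i])
    for (t in tips) {
      c_t <- counts[t, i]
      if (c_t < r0)
        M[t, (ssr$ref_start[i] + c_t * m):(ssr$ref_start[i] + r0 * m - 1L)] <-
          "-"
    }
  }

  ## insertion blocks keyed by anchor (columns appear after the anchor base)
  blocks <- list()  # each: list(anchor, width, fill = ntip x width matrix)
  if (n_ssr) for (i in seq_len(n_ssr)) {
    r0 <- ssr$repeat_count[i]; m <- nchar(ssr$motif[i])
    cmax <- max(counts[, i])
    if (cmax > r0) {
      w <- (cmax - r0) * m
      fill <- matrix("-", ntip, w, dimnames = list(tips, NULL))
      mot <- strsplit(ssr$motif[i], "", fixed = TRUE)[[1L]]
      for (t in tips) {
        extra <- counts[t, i] - r0
        if (extra > 0L) fill[t, seq_len(extra * m)] <- rep(mot, extra)
      }
      blocks[[length(blocks) + 1L]] <-
        list(anchor = ssr$ref_end[i], width = w, fill = fill)
    }
  }
  ins_idx <- which(vapply(events, function(e)
    e$type == "indel" && e$indel == "ins", logical(1L)))
  for (ei in ins_idx) {
    ev <- events[[ei]]
    w <- ev$length
    fill <- matrix("-", ntip, w, dimnames = list(tips, NULL))
    fill[ev$tips, ] <- matrix(rep(strsplit(ev$insert, "", fixed = TRUE)[[1L]],
                                  each = length(ev$tips)),
                              length(ev$tips), w)
    blocks[[length(blocks) + 1L]] <-
      list(anchor = ev$position, width = w, fill = fill)
  }

  ## column layout: root position p maps to p + width inserted at anchors < p
  ins_w <- integer(L + 1L)  # ins_w[a+1] = width anchored after root base a
  for (b in blocks) ins_w[b$anchor + 1L] <- ins_w[b$anchor + 1L] + b$width
  shift <- cumsum(ins_w)    # shift[p] = inserted columns at anchors < p...
  colof <- seq_len(L) + shift[seq_len(L)]  # column of root position p
  total <- L + sum(ins_w)
  A <- matrix("-", ntip, total, dimnames = list(tips, NULL))
  A[, colof] <- M
  offset_at <- integer(L + 1L)
  for (b in blocks) {
    a <- b$anchor
    start <- (if (a >= 1L) colof[a] else 0L) + offset_at[a + 1L] + 1L
    A[, start:(start + b$width - 1L)] <- b$fill
    b_cols <- c(start, start + b$width - 1L)
    offset_at[a + 1L] <- offset_at[a + 1L] + b$width
    ## remember columns for truth mapping
    for (ei in ins_idx) {
      ev <- events[[ei]]
      if (ev$indel == "ins" && ev$position == a &&
          is.null(events[[ei]]$col_start)) {
        events[[ei]]$col_start <- b_cols[1L]
        events[[ei]]$col_end <- b_cols[2L]
        break
      }
    }
  }

  truth <- do.call(rbind, lapply(events, function(ev) {
    cs <- ev$col_start %||% colof[ev$position]
    ce <- ev$col_end %||% (if (ev$type == "indel")
      colof[ev$position + ev$length - 1L] else colof[ev$position])
    data.frame(branch = ev$branch, type = ev$type, position = ev$position,
               length = ev$length, detail = ev$detail,
               class = if (ev$type == "indel") ev$class else NA_character_,
               col_start = cs, col_end = ce,
               carriers = paste(ev$tips, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(branch = character(0), type = character(0),
                        position = integer(0), length = integer(0),
                        detail = character(0), class = character(0),
                        col_start = integer(0), col_end = integer(0),
                        carriers = character(0), stringsAsFactors = FALSE)
  seqs <- setNames(apply(A, 1L, paste, collapse = ""), tips)
  list(alignment = PlastomeAlignment(seqs, reference = tips[1L]),
       truth = truth, root = root, ssr_counts = counts)
}

#' Draw a population genotype table from haplotype frequencies
#'
#' Samples a source haplotype per individual from the per-population
#' frequency simplex, copies its multilocus profile, then applies fragment
#' mis-sizing noise (+/- 1 bp on numeric cells, before binning) and missing
#' data. Draw order: for each population in row order, haplotype assignments,
#' then noise signs, then missing masks.
#'
#' @param catalog a \code{\linkS4class{HaplotypeCatalog}} or a named list of
#'   profiles (each a named character/numeric vector over the locus set).
#' @param populations data.frame with columns \code{name} and \code{size}.
#' @param frequencies matrix (populations x haplotypes, rows summing to 1)
#'   or a single named vector applied to all populations.
#' @param missing_rate per-cell missing probability.
#' @param size_noise per-cell probability of a +/-1 bp mis-sized fragment.
#' @param seed integer seed.
#' @return list: \code{genotypes} (a \code{CpGenotypes}), \code{truth}
#'   (data.frame individual/population/haplotype).
#' @export
genotypePopulation <- function(catalog, populations, frequencies,
                               missing_rate = 0, size_noise = 0, seed = 1L) {
  profs <- if (methods::is(catalog, "HaplotypeCatalog")) {
    m <- catalog@profiles
    setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]), rownames(m))
  } else lapply(catalog, function(p) setNames(as.character(p), names(p)))
  loci <- names(profs[[1L]])
  if (is.null(dim(frequencies))) {
    frequencies <- matrix(frequencies, nrow(populations),
                          length(frequencies), byrow = TRUE,
                          dimnames = list(populations$name,
                                          names(frequencies)))
  }
  if (any(abs(rowSums(frequencies) - 1) > 1e-9))
    stop("frequency rows must sum to 1")
  unknown <- setdiff(colnames(frequencies), names(profs))
  if (length(unknown))
    stop("haplotype(s) not in catalog: ", paste(unknown, collapse = ", "))
  stopifnot(all(populations$size >= 1L))

  .withSeed(seed, {
    rows <- list(); grp <- character(0); src <- character(0)
    for (pi in seq_len(nrow(populations))) {
      n <- populations$size[pi]
      hap <- sample(colnames(frequencies), n, replace = TRUE,
                    prob = frequencies[pi, ])
      for (k in seq_len(n)) {
        v <- profs[[hap[k]]]
        if (size_noise > 0) {
          num <- suppressWarnings(!is.na(as.numeric(v)))
          hitn <- runif(length(v)) < size_noise & num
          if (any(hitn)) {
            sign <- sample(c(-1, 1), sum(hitn), replace = TRUE)
            v[hitn] <- as.character(as.numeric(v[hitn]) + sign)
          }
        }
        if (missing_rate > 0) {
          v[runif(length(v)) < missing_rate] <- NA_character_
        }
        rows[[length(rows) + 1L]] <- v
      }
      grp <- c(grp, rep(populations$name[pi], n))
      src <- c(src, hap)
    }
    calls <- do.call(rbind, rows)
    colnames(calls) <- loci
    rownames(calls) <- sprintf("ind%04d", seq_len(nrow(calls)))
    gt <- methods::new("CpGenotypes", calls = calls, groups = grp)
    list(genotypes = gt,
         truth = data.frame(individual = rownames(calls), population = grp,
                            haplotype = src, stringsAsFactors = FALSE))
  })
}
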