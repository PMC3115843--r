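## Exact maximum parsimony on small nucleotide matrices: Fitch scoring,
## exhaustive enumeration of unrooted binary topologies, strict consensus,
## site-resampling bootstrap, outgroup rooting.
##
## Gaps, N and ? are treated as fully missing (any state). All characters
## are equally weighted.

.baseMask <- c(A = 1L, C = 2L, G = 4L, T = 8L,
               N = 15L, "-" = 15L, "?" = 15L)

#' Read a taxa-by-sites nucleotide matrix
#'
#' @param x character matrix (taxa x sites, rownames = taxa), a named
#'   character vector of equal-length sequences, or a path to an aligned
#'   FASTA or TSV file (first column taxon names).
#' @return character matrix with taxon rownames.
#' @export
characterMatrix <- function(x) {
  if (is.matrix(x)) m <- x
  else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
      s <- as.character(readDNAStringSet(x))
      m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
      rownames(m) <- names(s)
    } else {
      df <- read.delim(x, stringsAsFactors = FALSE)
      m <- as.matrix(df[, -1L, drop = FALSE])
      rownames(m) <- df[[1L]]
    }
  } else {
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  m[] <- toupper(m)
  if (is.null(rownames(m))) stop("taxa must be named")
  m
}

.maskMatrix <- function(m) {
  msk <- .baseMask[m]
  if (anyNA(msk)) stop("states must be A/C/G/T/N/-/?")
  matrix(as.integer(msk), nrow(m), ncol(m), dimnames = dimnames(m))
}

## --- topology representation -------------------------------------------
## An unrooted binary tree over n >= 3 leaves is built by stepwise addition:
## leaves 1..3 join at internal node n+1; leaf k (k >= 4) is attached to the
## a_k-th edge (1 <= a_k <= 2k-5) of the tree so far, creating internal node
## n+k-3. Every topology corresponds to exactly one choice vector.

.decodeTopology <- function(choices, n) {
  edges <- matrix(0L, 2L * n - 3L, 2L)
  root <- n + 1L
  edges[1L, ] <- c(root, 1L)
  edges[2L, ] <- c(root, 2L)
  edges[3L, ] <- c(root, 3L)
  ne <- 3L
  for (k in seq_len(n - 3L) + 3L) {
    a <- choices[k - 3L]
    w <- n + k - 2L  # internals: n+1 (initial join), n+2, ...
    u <- edges[a, 1L]; v <- edges[a, 2L]
    edges[a, ] <- c(u, w)
    edges[ne + 1L, ] <- c(w, v)
    edges[ne + 2L, ] <- c(w, k)
    ne <- ne + 2L
  }
  edges[seq_len(ne), , drop = FALSE]
}

## Fitch score of an unrooted binary topology, vectorised over site patterns.
## Rooted on the internal node adjacent to leaf 1 via a DFS; unrooted Fitch
## score is rooting-invariant for binary trees.
.fitchEdges <- function(edges, masks, weights = NULL) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nsite <- ncol(masks)
  weights <- weights %||% rep(1L, nsite)
  score <- numeric(nsite)
  ntip <- nrow(masks)
  dfs <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(masks[node, ])
    s <- dfs(kids[1L], node)
    for (k in kids[-1L]) {
      t <- dfs(k, node)
      inter <- bitwAnd(s, t)
      empty <- inter == 0L
      score <<- score + empty * weights
      s <- ifelse(empty, bitwOr(s, t), inter)
    }
    s
  }
  ## root along the pendant edge of tip 1: every internal node then has
  ## exactly two children, so pairwise intersection Fitch is exact
  start <- adj[[1L]][1L]
  s <- dfs(start, 1L)
  inter <- bitwAnd(s, masks[1L, ])
  score <- score + (inter == 0L) * weights
  sum(score)
}

#' Fitch parsimony length of a tree
#'
#' Sum over sites of the minimum number of state changes required on the
#' given topology; missing states (gap, N, ?) are unconstrained.
#'
#' @param tree an \code{ape::phylo} (rooted or unrooted; branch lengths
#'   ignored) whose tip labels match the matrix rows.
#' @param matrix character matrix from \code{\link{characterMatrix}}.
#' @return integer parsimony score.
#' @export
fitchLength <- function(tree, matrix) {
  if (!setequal(tree$tip.label, rownames(matrix)))
    stop("tree tips and matrix taxa differ")
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  masks <- .maskMatrix(matrix[tree$tip.label, , drop = FALSE])
  if (n == 2L) return(sum(bitwAnd(masks[1L, ], masks[2L, ]) == 0L))
  edges <- tree$edge
  ## ape numbers tips 1..n and internals n+1..; same convention as ours
  as.integer(.fitchEdges(edges, masks))
}

.topologyToNewick <- function(edges, n, tip_labels) {
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(tip_labels[node])
    paste0("(", paste(vapply(kids, rec, character(1L), parent = node),
                      collapse = ","), ")")
  }
  paste0(rec(n + 1L, 0L), ";")
}

## split key: sorted tip labels of the side not containing tip 1, per
## internal edge
.topologySplits <- function(edges, n, tip_labels) {
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  below <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(node)
    unlist(lapply(kids, below, parent = node))
  }
  internal <- edges[edges[, 1L] > n & edges[, 2L] > n, , drop = FALSE]
  vapply(seq_len(nrow(internal)), function(i) {
    tips <- below(internal[i, 2L], internal[i, 1L])
    if (1L %in% tips) tips <- setdiff(seq_len(n), tips)
    paste(sort(tip_labels[tips]), collapse = "|")
  }, character(1L))
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all \code{(2n-5)!!} unrooted binary topologies for n taxa
#' (refusing more than 10), scores each by Fitch length, and returns every
#' optimal topology together with their strict consensus.
#'
#' @param matrix character matrix (taxa x sites), 3-10 taxa.
#' @return list: \code{best_score}, \code{n_topologies}, \code{trees}
#'   (ape \code{multiPhylo} of all optimal topologies), \code{consensus}
#'   (strict consensus \code{phylo}), \code{best_splits} (splits present in
#'   every optimal tree).
#' @export
exhaustiveSearch <- function(matrix) {
  n <- nrow(matrix)
  if (n < 3L) stop("at least 3 taxa required")
  if (n > 10L) stop("exhaustive enumeration refused for > 10 taxa; ",
                    "use a heuristic search tool")
  tip_labels <- rownames(matrix)
  masks0 <- .maskMatrix(matrix)
  ## collapse duplicate site patterns with weights
  key <- apply(matrix, 2L, paste, collapse = "")
  patt <- !duplicated(key)
  weights <- as.integer(table(key)[key[patt]])
  masks <- masks0[, patt, drop = FALSE]

  dims <- if (n >= 4L) 2L * (4:n) - 5L else integer(0)
  n_topologies <- prod(dims)
  best <- Inf; best_edges <- list()
  choices <- rep(1L, length(dims))
  repeat {
    edges <- .decodeTopology(choices, n)
    s <- .fitchEdges(edges, masks, weights)
    if (s < best) { best <- s; best_edges <- list(edges) }
    else if (s == best) best_edges[[length(best_edges) + 1L]] <- edges
    ## odometer increment
    if (!length(dims)) break
    i <- length(dims)
    repeat {
      choices[i] <- choices[i] + 1L
      if (choices[i] <= dims[i]) break
      choices[i] <- 1L
      i <- i - 1L
      if (i == 0L) break
    }
    if (i == 0L) break
  }
  trees <- lapply(best_edges, function(e)
    ape::read.tree(text = .topologyToNewick(e, n, tip_labels)))
  class(trees) <- "multiPhylo"
  cons <- if (length(trees) > 1L) ape::consensus(trees, p = 1) else
    trees[[1L]]
  split_sets <- lapply(best_edges, .topologySplits, n = n,
                       tip_labels = tip_labels)
  best_splits <- Reduce(intersect, split_sets)
  list(best_score = as.integer(best), n_topologies = n_topologies,
       trees = trees, consensus = cons, best_splits = best_splits)
}

#' Site-resampling bootstrap for parsimony splits
#'
#' Resamples sites with replacement, reruns the exhaustive search on each
#' replicate, and counts how often each split appears in the replicate's
#' strict consensus of optimal trees (ties propagate as unresolved, so a
#' split ambiguous in a replicate earns no support from it).
#'
#' @param matrix character matrix (taxa x sites).
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame with \code{split} (taxon set, \code{|}-separated) and
#'   \code{support} (percent of replicates).
#' @export
parsimonyBootstrap <- function(matrix, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  nsite <- ncol(matrix)
  counts <- new.env(parent = emptyenv())
  .withSeed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(nsite, nsite, replace = TRUE)
      res <- exhaustiveSearch(matrix[, cols, drop = FALSE])
      for (sp in res$best_splits) {
        cur <- if (exists(sp, envir = counts, inherits = FALSE))
          get(sp, envir = counts) else 0L
        assign(sp, cur + 1L, envir = counts)
      }
    }
  })
  sp <- ls(counts)
  data.frame(split = sp,
             support = vapply(sp, function(s)
               100 * get(s, envir = counts) / replicates, numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Root a tree on an outgroup's pendant edge
#'
#' @param tree an \code{ape::phylo}.
#' @param outgroup tip label to root with.
#' @return rooted \code{phylo} with the outgroup sister to the rest.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("unknown taxon: ", outgroup)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' The informative-site nucleotide matrix of the olive plastome survey
#'
#' The packaged 9-site x 8-taxon matrix of parsimony-informative
#' substitutions among the Mediterranean/North African olive lineages plus
#' the O. woodiana outgroup, with columns named by 1-based position on the
#' 'Manzanilla de Sevilla' reference genome.
#'
#' @return character matrix (8 taxa x 9 sites).
#' @export
informativeSiteMatrix <- function() {
  characterMatrix(system.file("extdata", "informative_sites.tsv",
                              package = "plastotype", mustWork = TRUE))
}
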