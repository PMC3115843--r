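## Independent brute-force oracles and fixture builders used across the
## suite. These deliberately avoid the package's own code paths.

## quick alignment builder from equal-length strings
toyAln <- function(..., reference = NULL) {
  PlastomeAlignment(c(...), reference = reference)
}

## brute-force per-column classifier: invariant / substitution / gap
bruteColumnClass <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return("gap")
    obs <- col[col != "N"]
    if (length(unique(obs)) >= 2L) "substitution" else "invariant"
  }, character(1L))
}

## brute-force parsimony-informativeness of a state vector
bruteInformative <- function(states) {
  states <- states[!states %in% c("N", "-", "?")]
  sum(table(states) >= 2L) >= 2L
}

## brute-force pairwise substitution count
brutePairCount <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1L]]
  b <- strsplit(s2, "", fixed = TRUE)[[1L]]
  ok <- a != "-" & b != "-" & a != "N" & b != "N"
  sum(ok & a != b)
}

## Sankoff dynamic programme with unit costs on an ape tree (independent of
## the package's bitmask Fitch): min total changes over all internal
## labellings; missing leaf states cost 0 for every base
sankoffScore <- function(tree, matrix) {
  tree <- ape::unroot(tree)
  bases <- c("A", "C", "G", "T")
  n <- length(tree$tip.label)
  m <- matrix[tree$tip.label, , drop = FALSE]
  nn <- max(tree$edge)
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  root <- n + 1L
  total <- 0L
  for (s in seq_len(ncol(m))) {
    cost <- matrix(Inf, nn, 4L)
    rec <- function(v) {
      if (v <= n) {
        st <- m[v, s]
        cost[v, ] <<- if (st %in% bases) ifelse(bases == st, 0, Inf)
                      else rep(0, 4L)
        return(invisible())
      }
      for (k in kids[[v]]) rec(k)
      for (b in 1:4) {
        tot <- 0
        for (k in kids[[v]])
          tot <- tot + min(cost[k, ] + (seq_len(4L) != b))
        cost[v, b] <<- tot
      }
      invisible()
    }
    rec(root)
    total <- total + min(cost[root, ])
  }
  total
}

## perfect-phylogeny construction for compatible binary matrices
## (laminar-family argument): returns NULL if incompatible, else a list of
## node vectors and an edge list of (node_a, node_b) index pairs.
perfectPhylogeny <- function(b) {
  nh <- nrow(b)
  flip <- b[1L, ] == 1L
  b[, flip] <- 1L - b[, flip, drop = FALSE]
  keep <- colSums(b) > 0L
  b <- b[, keep, drop = FALSE]
  if (ncol(b)) {
    key <- apply(b, 2L, paste, collapse = "")
    b <- b[, !duplicated(key), drop = FALSE]
  }
  nc <- ncol(b)
  sets <- lapply(seq_len(nc), function(j) which(b[, j] == 1L))
  for (i in seq_len(max(0L, nc - 1L))) for (j in (i + 1L):nc) {
    inter <- intersect(sets[[i]], sets[[j]])
    if (length(inter) &&
        length(inter) != length(sets[[i]]) &&
        length(inter) != length(sets[[j]])) return(NULL)  # incompatible
  }
  ## node vector of character c: supersets of S_c get a 1
  nodevec <- function(cs) {
    v <- integer(nc)
    v[cs] <- 1L
    v
  }
  above <- lapply(seq_len(nc), function(j)
    which(vapply(seq_len(nc), function(k)
      all(sets[[j]] %in% sets[[k]]), logical(1L))))
  nodes <- c(list(integer(nc)), lapply(above, nodevec))
  parent_of <- vapply(seq_len(nc), function(j) {
    sup <- setdiff(above[[j]], j)
    if (!length(sup)) return(0L)  # root
    sup[which.min(lengths(sets)[sup])]
  }, integer(1L))
  edges <- cbind(parent_of + 1L, seq_len(nc) + 1L)
  key <- vapply(nodes, paste, character(1L), collapse = "")
  list(nodes = nodes, edges = edges, key = key)
}

## random compatible binary matrix: characters are edges of a random
## topology; haplotypes are the leaf vectors
randomCompatibleMatrix <- function(nh, nchar_, seed) {
  set.seed(seed)
  tr <- ape::rtree(nh)
  edge_id <- sample(nrow(tr$edge), nchar_, replace = TRUE)
  below <- function(node) {
    if (node <= nh) return(node)
    kk <- tr$edge[tr$edge[, 1L] == node, 2L]
    unlist(lapply(kk, below))
  }
  m <- vapply(edge_id, function(e) {
    v <- integer(nh)
    v[below(tr$edge[e, 2L])] <- 1L
    v
  }, integer(nh))
  rownames(m) <- paste0("H", seq_len(nh))
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

## small random nucleotide matrix with optional missing data
randomMatrix <- function(ntaxa, nsites, seed, p_missing = 0) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE),
              ntaxa, nsites)
  if (p_missing > 0)
    m[runif(length(m)) < p_missing] <- "N"
  rownames(m) <- paste0("t", seq_len(ntaxa))
  m
}
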