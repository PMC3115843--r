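## Character coding and reduced-median network construction.
##
## Microsatellite loci are coded as ordered integer repeat counts (single-
## step mutation assumption), indels as binary presence/absence; ordered
## characters are expanded to distance-preserving binary threshold
## indicators before the median construction.

#' Encode a haplotype catalog as a character matrix
#'
#' SSR loci (motif and anchor present) become ordered characters of repeat
#' counts; indel and gel-scored loci become binary; mixed loci emit one
#' ordered plus one binary character (the allele size is decomposed using
#' the locus \code{indel_size}); CAPS loci are excluded by default. Loci of
#' unknown kind with purely numeric calls are coded as ordered characters on
#' the integer step lattice of their observed sizes; two-state non-numeric
#' calls become binary.
#'
#' @param catalog a \code{\linkS4class{HaplotypeCatalog}}.
#' @param panel a \code{\linkS4class{MarkerPanel}}.
#' @param include_caps include CAPS loci as binary characters.
#' @param weights named numeric: per-locus weight (default 1 for all).
#' @param frequencies observed frequency per haplotype (for tie-breaking in
#'   the network stage); defaults to equal.
#' @return a \code{\linkS4class{CodedMatrix}}.
#' @export
encodeMatrix <- function(catalog, panel, include_caps = FALSE,
                         weights = NULL, frequencies = NULL) {
  profs <- catalog@profiles
  nh <- nrow(profs)
  cols <- list(); kinds <- character(0); wts <- numeric(0)
  for (locus in colnames(profs)) {
    row <- panel@loci[match(locus, panel@loci$id), ]
    if (is.na(row$id)) stop("locus ", locus, " not in panel")
    v <- profs[, locus]
    w <- if (!is.null(weights) && !is.na(weights[locus])) weights[[locus]]
         else 1
    kind <- row$kind
    if (kind == "caps" && !include_caps) next
    if (kind == "mixed") {
      if (is.na(row$motif) || is.na(row$indel_size))
        stop("mixed locus ", locus, " needs motif and indel_size")
      sz <- as.numeric(v)
      rel <- sz - row$anchor_size
      ml <- nchar(row$motif)
      ## indel carriers: residue class of indel_size modulo the motif
      present <- as.integer((rel %% ml) == (row$indel_size %% ml) &
                            rel %% ml != 0)
      if (row$indel_size %% ml == 0)
        stop("mixed locus ", locus,
             ": indel length indistinguishable from motif steps")
      cnt <- row$anchor_count + (rel - present * row$indel_size) / ml
      if (any(abs(cnt - round(cnt)) > 1e-9))
        stop("allele sizes at mixed locus ", locus,
             " inconsistent with motif/indel decomposition")
      cols <- c(cols, list(as.integer(round(cnt))), list(present))
      kinds <- c(kinds, "ordered", "binary")
      wts <- c(wts, w, w)
      names(cols)[length(cols) - 1:0] <- paste0(locus, c(".ssr", ".indel"))
      next
    }
    col <- if (!is.na(row$motif) && !is.na(row$anchor_size) &&
               !is.na(row$anchor_count)) {
      kinds <- c(kinds, "ordered")
      sizeToRepeatCount(as.numeric(v), row)
    } else if (kind %in% c("indel", "caps") ||
               length(unique(v)) <= 2L && anyNA(suppressWarnings(as.numeric(v)))) {
      lev <- sort(unique(v))
      if (length(lev) > 2L)
        stop("locus ", locus, " has >2 non-numeric states")
      kinds <- c(kinds, "binary")
      as.integer(v == lev[length(lev)])
    } else {
      sz <- as.numeric(v)
      if (anyNA(sz)) stop("cannot code locus ", locus)
      d <- diff(sort(unique(sz)))
      g <- if (length(d)) Reduce(.gcd, round(d)) else 1
      g <- max(1, g)
      kinds <- c(kinds, "ordered")
      as.integer((sz - min(sz)) / g)
    }
    cols <- c(cols, list(col))
    names(cols)[length(cols)] <- locus
    wts <- c(wts, w)
  }
  states <- do.call(cbind, cols)
  rownames(states) <- rownames(profs)
  freq <- frequencies %||% rep(1 / nh, nh)
  methods::new("CodedMatrix", states = states, kind = kinds,
               weights = setNames(wts, colnames(states)),
               frequencies = freq)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Expand ordered characters into binary threshold indicators
#'
#' Each ordered character with observed states spanning \code{[lo, hi]}
#' becomes \code{hi - lo} indicator characters ("state >= t" for
#' \code{t = lo+1 .. hi}); binary characters pass through unchanged. The
#' expansion preserves pairwise distances exactly: weighted Hamming distance
#' on the expansion equals the weighted sum of absolute state differences on
#' the originals.
#'
#' @param coded a \code{\linkS4class{CodedMatrix}}.
#' @return list: \code{matrix} (binary 0/1, haplotypes x expanded
#'   characters), \code{weights}, \code{map} (data.frame: expanded column,
#'   source character, threshold).
#' @export
binaryExpand <- function(coded) {
  m <- coded@states
  cols <- list(); map <- list(); wts <- numeric(0)
  for (j in seq_len(ncol(m))) {
    nm <- colnames(m)[j]
    if (coded@kind[j] == "binary") {
      cols[[length(cols) + 1L]] <- m[, j]
      names(cols)[length(cols)] <- nm
      map[[length(map) + 1L]] <- data.frame(column = nm, source = nm,
                                            threshold = NA_integer_)
      wts <- c(wts, coded@weights[j])
    } else {
      lo <- min(m[, j]); hi <- max(m[, j])
      for (t in seq_len(max(0L, hi - lo))) {
        thr <- lo + t
        cname <- sprintf("%s>=%d", nm, thr)
        cols[[length(cols) + 1L]] <- as.integer(m[, j] >= thr)
        names(cols)[length(cols)] <- cname
        map[[length(map) + 1L]] <- data.frame(column = cname, source = nm,
                                              threshold = thr)
        wts <- c(wts, coded@weights[j])
      }
    }
  }
  bm <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(0), nrow(m), 0L)
  rownames(bm) <- rownames(m)
  list(matrix = bm, weights = setNames(wts, colnames(bm)),
       map = do.call(rbind, map) %||%
         data.frame(column = character(0), source = character(0),
                    threshold = integer(0)))
}

## majority state per column over three binary vectors
.median3 <- function(a, b, c) as.integer(a + b + c >= 2L)

#' Build a reduced-median haplotype network
#'
#' Constructs a median network over binary characters: identical split
#' patterns are merged into one character of summed weight, haplotypes with
#' identical vectors merge into one node, and median (majority-rule) vectors
#' of unresolved triples are added until closure, so every observed
#' haplotype is connected through single-character steps. A frequency-guided
#' reduction then removes inferred median nodes that are redundant — nodes
#' whose deletion leaves the graph connected and all observed-pair distances
#' unchanged — whenever their frequency support falls below \code{1/r} of
#' the best-supported alternative (support = summed observed frequency of a
#' node's neighbours). For homoplasy-free (compatible) characters no node is
#' redundant and the result is exactly the perfect phylogeny tree. Scaling
#' all weights by a positive constant never changes the topology.
#'
#' @param binary binary matrix (haplotypes x characters) from
#'   \code{\link{binaryExpand}}, or a \code{\linkS4class{CodedMatrix}}
#'   (expanded automatically).
#' @param weights per-character weights (defaults to the expansion's).
#' @param frequencies observed haplotype frequencies (tie-breaking and
#'   reduction support); default equal.
#' @param r reduction parameter (>= 1); larger values prune harder. Default
#'   2.
#' @return a \code{\linkS4class{MedianNetwork}}.
#' @export
reducedMedian <- function(binary, weights = NULL, frequencies = NULL, r = 2) {
  stopifnot(r >= 1)
  expansion <- list()
  if (methods::is(binary, "CodedMatrix")) {
    freq0 <- binary@frequencies
    ex <- binaryExpand(binary)
    expansion <- ex
    weights <- weights %||% ex$weights
    binary <- ex$matrix
    frequencies <- frequencies %||% freq0
  }
  if (!all(binary %in% c(0, 1))) stop("matrix must be binary 0/1")
  storage.mode(binary) <- "integer"
  nh <- nrow(binary)
  if (is.null(rownames(binary))) rownames(binary) <- paste0("H", seq_len(nh))
  weights <- weights %||% rep(1, ncol(binary))
  frequencies <- frequencies %||% rep(1 / nh, nh)

  ## orient so the first row is all zero; drop invariant; merge identical
  flip <- binary[1L, ] == 1L
  b <- binary
  b[, flip] <- 1L - b[, flip, drop = FALSE]
  keep <- colSums(b) > 0L & colSums(b) < nh
  b <- b[, keep, drop = FALSE]
  w <- weights[keep]
  labs <- colnames(b) %||% paste0("c", which(keep))
  if (ncol(b)) {
    key <- apply(b, 2L, paste, collapse = "")
    grp <- split(seq_len(ncol(b)), key)
    grp <- grp[order(vapply(grp, min, integer(1L)))]  # stable order
    b2 <- vapply(grp, function(ix) b[, ix[1L]], integer(nh))
    w2 <- vapply(grp, function(ix) sum(w[ix]), numeric(1L))
    lab2 <- vapply(grp, function(ix) paste(labs[ix], collapse = "|"),
                   character(1L))
    b <- matrix(b2, nh); w <- unname(w2); labs <- unname(lab2)
  }

  ## merge identical haplotype vectors into one node
  vkey <- if (ncol(b)) apply(b, 1L, paste, collapse = "") else
    rep("", nh)
  vgrp <- split(seq_len(nh), vkey)
  vgrp <- vgrp[order(vapply(vgrp, min, integer(1L)))]
  nodes <- lapply(vgrp, function(ix) b[ix[1L], , drop = TRUE])
  node_name <- vapply(vgrp, function(ix)
    paste(rownames(binary)[ix], collapse = "/"), character(1L))
  node_freq <- vapply(vgrp, function(ix) sum(frequencies[ix]), numeric(1L))
  observed <- rep(TRUE, length(nodes))

  ## median closure over triples (majority per character)
  vec_key <- function(v) paste0("k", paste(v, collapse = ""))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(nodes)) assign(vec_key(nodes[[i]]), TRUE, envir = seen)
  repeat {
    added <- FALSE
    nn <- length(nodes)
    if (nn >= 3L) for (i in 1:(nn - 2L)) for (j in (i + 1L):(nn - 1L))
      for (k in (j + 1L):nn) {
        m <- .median3(nodes[[i]], nodes[[j]], nodes[[k]])
        kk <- vec_key(m)
        if (!exists(kk, envir = seen, inherits = FALSE)) {
          assign(kk, TRUE, envir = seen)
          nodes[[length(nodes) + 1L]] <- m
          node_name <- c(node_name, sprintf("mv%d",
                                            sum(!observed) + 1L))
          node_freq <- c(node_freq, 0)
          observed <- c(observed, FALSE)
          added <- TRUE
        }
      }
    if (!added) break
  }

  V <- do.call(rbind, nodes)
  edge_list <- .hammingEdges(V)
  g <- .networkGraph(V, edge_list, node_name, node_freq, observed, labs)

  ## frequency-guided reduction of redundant medians
  g <- .reduceMedians(g, V, observed, node_freq, r)
  keep_ix <- match(igraph::V(g)$name, node_name)
  methods::new("MedianNetwork", graph = g,
               vectors = V[keep_ix, , drop = FALSE],
               expansion = expansion)
}

.hammingEdges <- function(V) {
  n <- nrow(V)
  out <- list()
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- which(V[i, ] != V[j, ])
    if (length(d) == 1L)
      out[[length(out) + 1L]] <- c(i, j, d)
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0L, 3L)
}

.networkGraph <- function(V, edge_list, node_name, node_freq, observed,
                          char_labs) {
  g <- igraph::make_empty_graph(n = nrow(V), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_name)
  g <- igraph::set_vertex_attr(g, "observed", value = observed)
  g <- igraph::set_vertex_attr(g, "frequency", value = node_freq)
  if (nrow(edge_list))
    g <- igraph::add_edges(g, t(edge_list[, 1:2, drop = FALSE]),
                           character = char_labs[edge_list[, 3L]])
  g
}

.reduceMedians <- function(g, V, observed, node_freq, r) {
  repeat {
    nm <- igraph::V(g)$name
    obs <- igraph::V(g)$observed
    ## dead-end medians first
    deg <- igraph::degree(g)
    drop <- which(!obs & deg <= 1L)
    if (length(drop)) { g <- igraph::delete_vertices(g, drop[1L]); next }
    med <- which(!obs)
    if (!length(med)) break
    d0 <- igraph::distances(g, v = which(obs), to = which(obs))
    support <- vapply(med, function(v)
      sum(igraph::V(g)$frequency[igraph::neighbors(g, v)]), numeric(1L))
    ord <- med[order(support, nm[med])]
    sup <- support[order(support, nm[med])]
    best <- max(c(0, support))
    removed <- FALSE
    for (ii in seq_along(ord)) {
      v <- ord[ii]
      if (sup[ii] * r >= best && best > 0) next
      g2 <- igraph::delete_vertices(g, v)
      if (!igraph::is_connected(g2)) next
      obs2 <- which(igraph::V(g2)$observed)
      d2 <- igraph::distances(g2, v = obs2, to = obs2)
      if (all(d2 == d0)) { g <- g2; removed <- TRUE; break }
    }
    if (!removed) break
  }
  g
}

#' Export a network as GraphML or DOT
#'
#' @param net a \code{\linkS4class{MedianNetwork}}.
#' @param file output path.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @export
networkExport <- function(net, file, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- net@graph
  if (format == "dot")  # DOT has no boolean attribute type
    g <- igraph::set_vertex_attr(g, "observed",
                                 value = as.integer(igraph::V(g)$observed))
  igraph::write_graph(g, file, format = format)
  invisible(file)
}

#' Per-lineage connectivity report
#'
#' For each lineage, tests whether its observed haplotypes form a connected
#' subnetwork once other lineages' observed nodes are removed (inferred
#' median nodes are retained as potential through-points), and flags
#' characters labelling more than one edge (homoplasy).
#'
#' @param net a \code{\linkS4class{MedianNetwork}}.
#' @param lineages named character vector: haplotype name -> lineage.
#' @return list with \code{connected} (named logical per lineage) and
#'   \code{homoplastic_characters}.
#' @export
lineageClusters <- function(net, lineages) {
  g <- net@graph
  node_lin <- lapply(strsplit(igraph::V(g)$name, "/", fixed = TRUE),
                     function(h) unique(stats::na.omit(lineages[h])))
  lins <- sort(unique(unlist(node_lin)))
  connected <- setNames(logical(length(lins)), lins)
  for (l in lins) {
    mine <- vapply(node_lin, function(x) l %in% x, logical(1L))
    others <- igraph::V(g)$observed & !mine
    g2 <- igraph::delete_vertices(g, which(others))
    mine2 <- vapply(node_lin[!others], function(x) l %in% x, logical(1L))
    comp <- igraph::components(g2)$membership
    connected[l] <- length(unique(comp[mine2])) <= 1L
  }
  elab <- igraph::E(g)$character
  tab <- table(unlist(strsplit(elab %||% character(0), "|", fixed = TRUE)))
  list(connected = connected,
       homoplastic_characters = names(tab)[tab > 1L])
}
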