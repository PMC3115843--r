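mkCatalog <- function(profiles) {
  methods::new("HaplotypeCatalog", profiles = profiles,
               diagnostics = data.frame(lineage = character(0),
                                        locus = character(0),
                                        value = character(0)))
}

test_that("character coding follows locus kind", {
  panel <- loadLocusDefinitions(data.frame(
    id = c("s1", "d1", "x1", "m1"),
    kind = c("ssr", "indel", "caps", "mixed"),
    motif = c("T", NA, NA, "AT"),
    anchor_size = c(158, NA, NA, 200),
    anchor_count = c(12, NA, NA, 10),
    indel_size = c(NA, NA, NA, 5)))
  prof <- rbind(h1 = c(s1 = "158", d1 = "present", x1 = "cut", m1 = "200"),
                h2 = c(s1 = "159", d1 = "present", x1 = "uncut", m1 = "207"),
                h3 = c(s1 = "159", d1 = "absent", x1 = "cut", m1 = "202"))
  cm <- encodeMatrix(mkCatalog(prof), panel)
  ## SSR -> ordered repeat counts; indel -> binary; caps excluded; mixed ->
  ## one ordered + one binary
  expect_identical(colnames(cm@states), c("s1", "d1", "m1.ssr", "m1.indel"))
  expect_identical(cm@kind, c("ordered", "binary", "ordered", "binary"))
  expect_identical(unname(cm@states[, "s1"]), c(12L, 13L, 13L))
  expect_identical(unname(cm@states[, "d1"]), c(1L, 1L, 0L))
  ## mixed decomposition: 200 = anchor; 207 = anchor + 1 motif + 5 bp indel;
  ## 202 = anchor + 1 motif
  expect_identical(unname(cm@states[, "m1.ssr"]), c(10L, 11L, 11L))
  expect_identical(unname(cm@states[, "m1.indel"]), c(0L, 1L, 0L))
  ## mono-motif mixed loci are rejected: the indel is indistinguishable
  pmono <- loadLocusDefinitions(data.frame(
    id = "mm", kind = "mixed", motif = "A", anchor_size = 100,
    anchor_count = 8, indel_size = 5))
  pr <- rbind(h1 = c(mm = "100"), h2 = c(mm = "105"))
  expect_error(encodeMatrix(mkCatalog(pr), pmono), "indistinguishable")
  ## caps included on request
  cm2 <- encodeMatrix(mkCatalog(prof), panel, include_caps = TRUE)
  expect_true("x1" %in% colnames(cm2@states))
  expect_identical(cm2@kind[colnames(cm2@states) == "x1"], "binary")
  ## size off the motif lattice is an error
  bad <- prof; bad["h2", "s1"] <- "158.5"
  expect_error(encodeMatrix(mkCatalog(bad), panel), "inconsistent")
})

test_that("binary expansion is a distance-preserving ladder", {
  cm <- methods::new("CodedMatrix",
    states = cbind(ssrA = c(3L, 4L, 5L), del1 = c(0L, 0L, 1L)),
    kind = c("ordered", "binary"), weights = c(ssrA = 1, del1 = 1),
    frequencies = rep(1 / 3, 3))
  rownames(cm@states) <- c("h1", "h2", "h3")
  ex <- binaryExpand(cm)
  expect_identical(colnames(ex$matrix), c("ssrA>=4", "ssrA>=5", "del1"))
  expect_identical(unname(ex$matrix[, "ssrA>=4"]), c(0L, 1L, 1L))
  ## already-binary matrix expands to itself
  cb <- methods::new("CodedMatrix",
    states = cbind(a = c(0L, 1L), b = c(1L, 0L)),
    kind = c("binary", "binary"), weights = c(1, 1),
    frequencies = c(0.5, 0.5))
  expect_identical(binaryExpand(cb)$matrix, cb@states)
  ## exhaustive distance preservation on random ordered matrices
  for (s in 1:10) {
    set.seed(s)
    nh <- sample(3:8, 1L)
    st <- matrix(sample(0:5, nh * 4L, replace = TRUE), nh, 4L,
                 dimnames = list(paste0("h", 1:nh), paste0("c", 1:4)))
    w <- runif(4L, 0.5, 2)
    cmx <- methods::new("CodedMatrix", states = st,
                        kind = rep("ordered", 4L),
                        weights = setNames(w, colnames(st)),
                        frequencies = rep(1 / nh, nh))
    exx <- binaryExpand(cmx)
    for (i in seq_len(nh - 1L)) for (j in (i + 1L):nh) {
      orig <- sum(w * abs(st[i, ] - st[j, ]))
      expd <- sum(exx$weights * (exx$matrix[i, ] != exx$matrix[j, ]))
      expect_equal(expd, orig)
    }
  }
})

test_that("degenerate networks: one node, and a single-step pair", {
  n1 <- reducedMedian(matrix(0L, 1L, 2L, dimnames = list("A", NULL)))
  expect_equal(igraph::vcount(n1@graph), 1L)
  expect_equal(igraph::ecount(n1@graph), 0L)
  n2 <- reducedMedian(rbind(A = 0L, B = 1L))
  expect_equal(igraph::vcount(n2@graph), 2L)
  expect_equal(igraph::ecount(n2@graph), 1L)
})

test_that("compatible matrices give exactly the perfect phylogeny", {
  ## fixed 5-haplotype case
  b <- rbind(H1 = c(0L, 0L, 0L, 0L), H2 = c(1L, 0L, 0L, 0L),
             H3 = c(1L, 1L, 0L, 0L), H4 = c(0L, 0L, 1L, 0L),
             H5 = c(0L, 0L, 1L, 1L))
  colnames(b) <- paste0("c", 1:4)
  net <- reducedMedian(b)
  g <- net@graph
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 4L)
  expect_true(igraph::is_connected(g))
  ## exhaustive check against the laminar-construction oracle
  for (s in 1:30) {
    nh <- sample(3:8, 1L)
    nc <- sample(2:12, 1L)
    b <- randomCompatibleMatrix(nh, nc, seed = s)
    pp <- perfectPhylogeny(b)
    expect_false(is.null(pp))
    net <- reducedMedian(b)
    g <- net@graph
    ## trees match: same node count and edge count, all observed present,
    ## and the node vector sets coincide
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::ecount(g), igraph::vcount(g) - 1L)
    expect_equal(igraph::vcount(g), length(unique(pp$key)))
    obs <- igraph::V(g)$name[igraph::V(g)$observed]
    expect_setequal(unlist(strsplit(obs, "/", fixed = TRUE)), rownames(b))
  }
})

test_that("every observed haplotype appears exactly once and stays connected", {
  set.seed(99)
  for (s in 1:10) {
    nh <- sample(3:7, 1L)
    b <- matrix(sample(0:1, nh * 6L, replace = TRUE), nh, 6L,
                dimnames = list(paste0("H", 1:nh), paste0("c", 1:6)))
    net <- reducedMedian(b, frequencies = runif(nh))
    g <- net@graph
    expect_true(igraph::is_connected(g) || igraph::vcount(g) == 1L)
    obs <- unlist(strsplit(igraph::V(g)$name[igraph::V(g)$observed], "/",
                           fixed = TRUE))
    expect_setequal(obs, rownames(b))
    expect_identical(anyDuplicated(obs), 0L)
  }
})

test_that("weight scaling leaves the topology unchanged", {
  b <- rbind(H1 = c(0L, 0L, 1L), H2 = c(1L, 0L, 0L), H3 = c(1L, 1L, 0L),
             H4 = c(0L, 1L, 1L))
  colnames(b) <- paste0("c", 1:3)
  n1 <- reducedMedian(b, weights = c(1, 1, 1))
  n2 <- reducedMedian(b, weights = c(7, 7, 7))
  expect_identical(igraph::as_data_frame(n1@graph, "edges"),
                   igraph::as_data_frame(n2@graph, "edges"))
})

test_that("edges decode through the expansion to single steps", {
  cm <- methods::new("CodedMatrix",
    states = cbind(ssrA = c(12L, 13L, 14L), del1 = c(0L, 0L, 1L)),
    kind = c("ordered", "binary"), weights = c(ssrA = 1, del1 = 1),
    frequencies = rep(1 / 3, 3))
  rownames(cm@states) <- c("h1", "h2", "h3")
  net <- reducedMedian(cm)
  labs <- igraph::E(net@graph)$character
  parts <- unlist(strsplit(labs, "|", fixed = TRUE))
  expect_true(all(parts %in% net@expansion$map$column))
})

test_that("networks export to GraphML (round trip) and DOT", {
  b <- rbind(H1 = c(0L, 0L), H2 = c(1L, 0L), H3 = c(1L, 1L))
  colnames(b) <- c("c1", "c2")
  net <- reducedMedian(b)
  fg <- tempfile(fileext = ".graphml")
  networkExport(net, fg, "graphml")
  back <- igraph::read_graph(fg, format = "graphml")
  expect_true(igraph::isomorphic(back, net@graph))
  expect_setequal(igraph::V(back)$name, igraph::V(net@graph)$name)
  fd <- tempfile(fileext = ".dot")
  networkExport(net, fd, "dot")
  txt <- readLines(fd)
  expect_true(grepl("graph", txt[1L]))
  expect_equal(sum(grepl("--", txt, fixed = TRUE)),
               igraph::ecount(net@graph))
  expect_error(networkExport(net, tempfile(), "abc"))
})

test_that("lineage clusters are detected and homoplasy flagged", {
  ## three clades, each with a private diagnostic character
  b <- rbind(A1 = c(1L, 0L, 0L, 0L), A2 = c(1L, 0L, 0L, 1L),
             B1 = c(0L, 1L, 0L, 0L), B2 = c(0L, 1L, 0L, 1L),
             C1 = c(0L, 0L, 1L, 0L))
  colnames(b) <- c("dA", "dB", "dC", "hom")
  net <- reducedMedian(b)
  lin <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C")
  rep <- lineageClusters(net, lin)
  expect_true(all(rep$connected))
  ## the character shared across clades labels more than one edge
  expect_true("hom" %in% rep$homoplastic_characters)
  expect_false("dC" %in% rep$homoplastic_characters)
})
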