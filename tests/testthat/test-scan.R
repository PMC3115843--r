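test_that("substitution scan calls only fully ungapped polymorphic columns", {
  expect_identical(nrow(scanSubstitutions(toyAln(a = "ACGTACGTAC",
                                                 b = "ACGTACGTAC"))), 0L)
  ## mismatches at columns 3 and 7, gap at column 5
  aln <- toyAln(a = "ACGTACGTAC", b = "ACTT-CATAC")
  sub <- scanSubstitutions(aln)
  expect_identical(sub$column, c(3L, 7L))
  expect_identical(sub$ref_position, c(3L, 7L))
  ## N rows are ignored for polymorphism calling
  alnN <- toyAln(a = "ACGT", b = "ACGT", c = "NCGT")
  expect_identical(nrow(scanSubstitutions(alnN)), 0L)
})

test_that("the packaged informative-site matrix yields nine informative substitutions", {
  m <- informativeSiteMatrix()
  expect_identical(dim(m), c(8L, 9L))
  aln <- PlastomeAlignment(setNames(apply(m, 1L, paste, collapse = ""),
                                    rownames(m)))
  sub <- scanSubstitutions(aln)
  expect_identical(nrow(sub), 9L)
  expect_true(all(sub$informative))
})

test_that("informativeness matches a brute-force counter on all 3^4 state vectors", {
  states <- c("C", "T", "N")
  grid <- expand.grid(t1 = states, t2 = states, t3 = states, t4 = states,
                      stringsAsFactors = FALSE)
  got <- informativeSites(grid, c("t1", "t2", "t3", "t4"))
  want <- apply(as.matrix(grid), 1L, bruteInformative)
  expect_identical(unname(got), unname(want))
  ## a singleton is never informative
  expect_false(informativeSites(data.frame(a = "C", b = "C", c = "C",
                                           d = "T"), letters[1:4]))
})

test_that("indel events merge maximal gap runs by presence pattern", {
  one <- scanIndels(toyAln(a = "ACGTACGT", b = "AC---CGT"))
  expect_identical(nrow(one), 1L)
  expect_identical(one$length, 3L)
  expect_identical(one$ref_position, 3L)
  expect_identical(one$present.a, 1L)
  expect_identical(one$present.b, 0L)
  ## adjacent runs with different taxon patterns stay separate events
  two <- scanIndels(toyAln(a = "ACGTACGT", b = "AC--ACGT", c = "ACGT--GT"))
  expect_identical(nrow(two), 2L)
  expect_identical(two$col_start, c(3L, 5L))
  ## none at all
  expect_identical(nrow(scanIndels(toyAln(a = "ACGT", b = "ACGT"))), 0L)
})

test_that("indel classes follow tract membership, duplication and length rules", {
  ## 1-bp gap inside a (T)n tract
  aln <- toyAln(a = "GCTTTTTTTTTTGC", b = "GCTTTTTTTTT-GC")
  ssr <- detectSSR(aln)
  ev <- scanIndels(aln)
  expect_identical(classifyIndel(ev[1L, ], aln, ssr), "ssr_motif")
  ## 9-bp block equal to the 9 bp immediately upstream -> duplication
  blk <- "GATCCATGA"
  aln2 <- toyAln(a = paste0("ACGT", blk, blk, "ACGT"),
                 b = paste0("ACGT", blk, strrep("-", 9L), "ACGT"))
  ev2 <- scanIndels(aln2)
  expect_identical(classifyIndel(ev2[1L, ], aln2, detectSSR(aln2)),
                   "repeated_motif_7_12")
  ## >12 bp is long regardless of content
  aln3 <- toyAln(a = strrep("ACGT", 80L),
                 b = paste0(substr(strrep("ACGT", 80L), 1L, 40L),
                            strrep("-", 225L),
                            substr(strrep("ACGT", 80L), 266L, 320L)))
  ev3 <- scanIndels(aln3)
  expect_identical(ev3$length, 225L)
  expect_identical(classifyIndel(ev3[1L, ], aln3), "long")
  ## short non-duplicated, non-SSR
  aln4 <- toyAln(a = "ACGTGCAATTGC", b = "ACGT---ATTGC")
  expect_identical(classifyIndel(scanIndels(aln4)[1L, ], aln4),
                   "other_short")
})

test_that("SSR detection reports primitive canonical motifs above thresholds", {
  set.seed(42)
  ## random sequence screened to carry no qualifying tract
  rnd <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  hits <- detectSSR(rnd, thresholds = rep(30L, 6L))
  expect_identical(nrow(hits), 0L)
  ## planted (T)12
  g <- buildRootGenome(2000, ssr_loci = data.frame(position = 500,
                                                   motif = "T",
                                                   repeat_count = 12),
                       seed = 1)
  ann <- detectSSR(g$sequence)
  hit <- ann[ann$ref_start == 500, ]
  expect_identical(hit$motif, "T")
  expect_identical(hit$repeat_count, 12L)
  ## planted (AT)6 reported once as AT (primitive; not TA, not A)
  flank <- "GACTGCGATCCGATGCAACG"
  ann2 <- detectSSR(paste0(flank, strrep("AT", 6L), flank))
  expect_identical(nrow(ann2), 1L)
  expect_identical(ann2$motif, "AT")
  expect_identical(ann2$ref_start, nchar(flank) + 1L)
  expect_identical(ann2$repeat_count, 6L)
  ## a (TT)6 run is reported as its primitive motif T, not TT
  ann3 <- detectSSR(paste0(flank, strrep("T", 12L), flank))
  expect_identical(ann3$motif, "T")
  expect_identical(ann3$repeat_count, 12L)
})

test_that("pairwise matrix is symmetric with hand-checked counts", {
  aln <- toyAln(a = strrep("A", 100L),
                b = paste0("CC", strrep("A", 98L)),
                c = strrep("A", 100L))
  pw <- pairwiseSubstitutions(aln)
  expect_identical(pw$count["a", "b"], 2L)
  expect_identical(pw$count["a", "c"], 0L)
  expect_equal(pw$proportion["a", "b"], 0.02)
  expect_identical(pw$count, t(pw$count))
  expect_true(all(diag(pw$proportion) == 0))
  ## against the brute-force pair counter on random gapped alignments
  for (s in 1:5) {
    set.seed(s)
    seqs <- replicate(4, paste(sample(c("A", "C", "G", "T", "-", "N"), 60,
                                      replace = TRUE,
                                      prob = c(rep(0.22, 4), 0.06, 0.06)),
                               collapse = ""))
    names(seqs) <- paste0("t", 1:4)
    seqs[1] <- gsub("-", "A", seqs[1])  # reference must be mostly ungapped
    pw2 <- pairwiseSubstitutions(PlastomeAlignment(seqs))
    for (i in 1:3) for (j in (i + 1):4)
      expect_identical(pw2$count[i, j], brutePairCount(seqs[i], seqs[j]))
  }
})

test_that("column classification conserves the alignment length", {
  for (s in 1:10) {
    set.seed(s)
    seqs <- replicate(sample(3:6, 1), paste(
      sample(c("A", "C", "G", "T", "-"), 50, replace = TRUE,
             prob = c(rep(0.23, 4), 0.08)), collapse = ""))
    names(seqs) <- paste0("t", seq_along(seqs))
    aln <- PlastomeAlignment(seqs)
    cls <- bruteColumnClass(seqs)
    sub <- scanSubstitutions(aln)
    expect_identical(nrow(sub), sum(cls == "substitution"))
    expect_identical(sub$column, which(cls == "substitution"))
    ind <- scanIndels(aln)
    gap_cols <- if (nrow(ind)) sum(ind$length) else 0L
    expect_identical(gap_cols, sum(cls == "gap"))
    expect_identical(sum(cls == "invariant") + nrow(sub) + gap_cols, 50L)
  }
})

test_that("divergence and substitution-rate arithmetic match reported conventions", {
  expect_identical(percentDivergence(0, 1000), 0)
  expect_identical(percentDivergence(106, 155531), 0.07)
  expect_identical(percentDivergence(432, 155531), 0.28)
  expect_error(percentDivergence(1, 0), "positive")
  expect_equal(substitutionRate(417, 155896, 2.2e7)$rate_2sf, 1.2e-10)
  expect_equal(substitutionRate(432, 155531, 1.4e7)$rate_2sf, 2.0e-10)
  expect_identical(substitutionRate(0, 1e5, 1e7)$rate, 0)
  expect_error(substitutionRate(10, 0, 1e7), "positive")
  ## strict monotonicity
  r0 <- substitutionRate(100, 1e5, 1e7)$rate
  expect_lt(substitutionRate(100, 1e5, 2e7)$rate, r0)
  expect_lt(substitutionRate(100, 2e5, 1e7)$rate, r0)
  expect_gt(substitutionRate(200, 1e5, 1e7)$rate, r0)
})

test_that("coding effect classifies via codon translation on both strands", {
  ## toy gene ATG GAA TAA at 11..19 on the plus strand
  refseq <- paste0("ACGTACGTAC", "ATGGAATAA", "GGCCGGCC")
  ann <- data.frame(start = 11, end = 19, strand = "+", frame = 0,
                    name = "toy")
  expect_identical(codingEffect(5, c("A", "G"), ann, refseq)$effect,
                   "non-coding")
  ## GAA (Glu) -> GGA (Gly) at codon 2 position 2: non-synonymous
  ns <- codingEffect(15, c("A", "G"), ann, refseq)
  expect_identical(ns$effect, "non-synonymous")
  expect_setequal(unname(ns$aa), c("E", "G"))
  ## TTA -> TTG third-position change: synonymous (both Leu)
  refseq2 <- paste0("AAAA", "ATGTTATAA", "CCCC")
  ann2 <- data.frame(start = 5, end = 13, strand = "+", frame = 0,
                     name = "leu")
  syn <- codingEffect(10, c("A", "G"), ann2, refseq2)
  expect_identical(syn$effect, "synonymous")
  expect_true(all(syn$aa == "L"))
  ## minus strand: gene is reverse complement of ATGGAATAA
  refseq3 <- paste0("AAAA", "TTATTCCAT", "CCCC")
  ann3 <- data.frame(start = 5, end = 13, strand = "-", frame = 0,
                     name = "rev")
  rs <- codingEffect(9, c("T", "C"), ann3, refseq3)  # codon 2 pos 2 on rev
  expect_identical(rs$effect, "non-synonymous")
})
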