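sim_root <- function(seed = 3) {
  buildRootGenome(4000,
    ssr_loci = data.frame(position = c(400L, 1500L, 2600L),
                          motif = c("T", "AT", "A"),
                          repeat_count = c(12L, 6L, 10L)),
    long_indel_sites = data.frame(position = 3000L, length = 342L),
    seed = seed)
}
sim_tree <- function() ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
sim_model <- function() list(sub_rate = 5e-4, ssr_step_rate = 0.5,
                             indel_rate = 1.2,
                             indel_length_law = c(dup7_12 = 0.4,
                                                  other_short = 0.3,
                                                  long = 0.3))

test_that("root genome plants SSR tracts verbatim and validates placements", {
  g <- buildRootGenome(2000, ssr_loci = data.frame(position = 500,
                                                   motif = "T",
                                                   repeat_count = 12),
                       seed = 1)
  expect_identical(nchar(g$sequence), 2000L)
  expect_identical(substr(g$sequence, 500, 511), strrep("T", 12L))
  ## flanks are broken off-motif
  expect_false(substr(g$sequence, 499, 499) == "T")
  expect_false(substr(g$sequence, 512, 512) == "T")
  ## same spec + seed twice -> identical
  g2 <- buildRootGenome(2000, ssr_loci = data.frame(position = 500,
                                                    motif = "T",
                                                    repeat_count = 12),
                        seed = 1)
  expect_identical(g$sequence, g2$sequence)
  ## bounds and overlap rejection
  expect_error(buildRootGenome(100, ssr_loci = data.frame(
    position = 95, motif = "T", repeat_count = 12), seed = 1), "outside")
  expect_error(buildRootGenome(1000, ssr_loci = data.frame(
    position = c(100, 105), motif = c("T", "A"),
    repeat_count = c(10, 10)), seed = 1), "overlap")
  expect_error(buildRootGenome(1000, ssr_loci = data.frame(
    position = 10, motif = "ACGTACG", repeat_count = 4), seed = 1),
    "1-6")
})

test_that("zero-rate evolution returns the root at every leaf", {
  ev <- evolveGenomes(sim_root(), sim_tree(),
                      list(sub_rate = 0, ssr_step_rate = 0, indel_rate = 0),
                      seed = 1)
  expect_identical(nrow(ev$truth), 0L)
  expect_true(all(ev$alignment@seqs == sim_root()$sequence))
  expect_false(grepl("-", ev$alignment@seqs[[1L]], fixed = TRUE))
})

test_that("evolution is deterministic and conserves alignment columns", {
  ev1 <- evolveGenomes(sim_root(), sim_tree(), sim_model(), seed = 7)
  ev2 <- evolveGenomes(sim_root(), sim_tree(), sim_model(), seed = 7)
  expect_identical(ev1$alignment@seqs, ev2$alignment@seqs)
  expect_identical(ev1$truth, ev2$truth)
  ## columns = root length + inserted bases (dup insertions + SSR expansion
  ## above the root repeat count)
  ins <- sum(ev1$truth$length[ev1$truth$type == "indel" &
                                ev1$truth$detail == "insertion:dup"])
  root <- sim_root()
  expansion <- sum(vapply(seq_len(nrow(root$ssr)), function(i)
    max(0L, max(ev1$ssr_counts[, i]) - root$ssr$repeat_count[i]) *
      nchar(root$ssr$motif[i]), numeric(1L)))
  expect_equal(nchar(ev1$alignment@seqs[[1L]]),
               root$length + ins + expansion)
})

test_that("a single planted substitution yields exactly one differing column", {
  root <- buildRootGenome(800, seed = 5)
  tree <- ape::read.tree(text = "(A:0.001,B:10);")
  ## rate chosen so branch B expects ~4 events, branch A essentially none;
  ## draw seeds until the truth holds exactly one substitution, then check
  ## the alignment
  for (s in 1:50) {
    ev <- evolveGenomes(root, tree, list(sub_rate = 1 / 800 / 10.001,
                                         ssr_step_rate = 0, indel_rate = 0),
                        seed = s)
    if (nrow(ev$truth) == 1L && ev$truth$type == "substitution") break
  }
  expect_identical(nrow(ev$truth), 1L)
  m <- alignmentMatrix(ev$alignment)
  diffs <- which(m["A", ] != m["B", ])
  expect_identical(diffs, ev$truth$col_start)
})

test_that("substitution counts follow the Poisson law across seeds", {
  root <- buildRootGenome(2000, seed = 9)
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  rate <- 20 / (2000 * 4)  # 20 expected substitutions per run
  total <- 0L
  nrun <- 40L
  for (s in seq_len(nrun)) {
    ev <- evolveGenomes(root, star, list(sub_rate = rate, ssr_step_rate = 0,
                                         indel_rate = 0), seed = s)
    total <- total + sum(ev$truth$type == "substitution")
  }
  lambda <- 20 * nrun
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("every planted event is recovered by the scanner (recall 1)", {
  ev <- evolveGenomes(sim_root(), sim_tree(), sim_model(), seed = 7)
  res <- scanAlignment(ev$alignment)
  truth <- ev$truth
  ## substitutions: every truth column is called, with matching ref position
  tsub <- truth[truth$type == "substitution", ]
  expect_true(all(tsub$col_start %in% res$substitutions$column))
  ## events land in distinct columns, so precision is exact too
  expect_identical(nrow(res$substitutions), nrow(tsub))
  ## indels: each truth event matches a detected event by column range,
  ## length and class
  tind <- truth[truth$type == "indel", ]
  for (i in seq_len(nrow(tind))) {
    hit <- res$indels[res$indels$col_start == tind$col_start[i], ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$length, tind$length[i])
    expect_identical(hit$class, tind$class[i])
  }
  ## SSR repeat counts per taxon match the generator's bookkeeping
  root <- sim_root()
  counts <- ev$ssr_counts
  for (i in seq_len(nrow(root$ssr))) {
    hit <- res$ssr[res$ssr$motif == root$ssr$motif[i] &
                     abs(res$ssr$ref_start - root$ssr$ref_start[i]) < 100, ]
    expect_identical(nrow(hit), 1L)
    for (t in colnames(ev$alignment@seqs) %||% names(ev$alignment@seqs))
      expect_identical(hit[[paste0("count.", t)]], unname(counts[t, i]))
  }
})

test_that("population genotyping is exact when noiseless", {
  catalog <- list(H1 = c(l1 = "158", l2 = "200", d1 = "present"),
                  H2 = c(l1 = "159", l2 = "200", d1 = "present"),
                  H3 = c(l1 = "158", l2 = "202", d1 = "absent"))
  pops <- data.frame(name = c("p1", "p2"), size = c(40L, 20L))
  fr <- rbind(p1 = c(H1 = 0.6, H2 = 0.4, H3 = 0),
              p2 = c(H1 = 0.2, H2 = 0.3, H3 = 0.5))
  gp <- genotypePopulation(catalog, pops, fr, seed = 11)
  expect_identical(nrow(gp$genotypes@calls), 60L)
  for (i in seq_len(60L))
    expect_identical(unname(gp$genotypes@calls[i, ]),
                     unname(catalog[[gp$truth$haplotype[i]]]))
  ## frequency 1 on one haplotype -> all rows identical
  gp1 <- genotypePopulation(catalog, data.frame(name = "p", size = 10L),
                            c(H2 = 1), seed = 2)
  expect_identical(unique(gp1$truth$haplotype), "H2")
  expect_identical(nrow(unique(gp1$genotypes@calls)), 1L)
  ## unknown haplotype name is a configuration error
  expect_error(genotypePopulation(catalog,
                                  data.frame(name = "p", size = 5L),
                                  c(H9 = 1), seed = 1), "not in catalog")
  ## determinism
  gp2 <- genotypePopulation(catalog, pops, fr, seed = 11)
  expect_identical(gp$genotypes@calls, gp2$genotypes@calls)
})

test_that("noise and missingness behave as configured", {
  catalog <- list(H1 = c(l1 = "158", l2 = "200"))
  gp <- genotypePopulation(catalog, data.frame(name = "p", size = 200L),
                           c(H1 = 1), missing_rate = 0.2, size_noise = 0.3,
                           seed = 3)
  calls <- gp$genotypes@calls
  miss <- mean(is.na(calls))
  expect_lt(abs(miss - 0.2), 0.06)
  noised <- calls[!is.na(calls)]
  expect_true(all(noised %in% c("157", "158", "159", "199", "200", "201")))
  expect_gt(mean(noised %in% c("157", "159", "199", "201")), 0.1)
})

test_that("empirical haplotype frequencies converge to the spec", {
  catalog <- list(H1 = c(l1 = "1"), H2 = c(l1 = "2"), H3 = c(l1 = "3"))
  ## binomial check at n = 1000 for (0.77, 0.23)
  gp <- genotypePopulation(catalog[1:2],
                           data.frame(name = "p", size = 1000L),
                           c(H1 = 0.77, H2 = 0.23), seed = 21)
  k <- sum(gp$truth$haplotype == "H1")
  ci <- qbinom(c(0.005, 0.995), 1000L, 0.77)
  expect_gte(k, ci[1L]); expect_lte(k, ci[2L])
  ## law of large numbers at n = 10,000, tolerance 0.02
  p <- c(H1 = 0.6, H2 = 0.3, H3 = 0.1)
  gp2 <- genotypePopulation(catalog, data.frame(name = "p", size = 10000L),
                            p, seed = 22)
  emp <- table(gp2$truth$haplotype) / 10000
  expect_true(all(abs(emp[names(p)] - p) < 0.02))
})
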