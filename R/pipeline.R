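## End-to-end orchestration: simulate -> scan -> genotype -> haplotypes ->
## diversity -> network -> tree, with TSV/FASTA/GFF3/GraphML/newick
## artifacts and a checksummed JSON run manifest.

#' The published multiplex assignment of the olive panel
#'
#' @param panel a \code{\linkS4class{MarkerPanel}}, default
#'   \code{\link{olivePanel}}.
#' @return data.frame with \code{locus}, \code{group}, \code{dye} for the 35
#'   loci of the six published multiplex PCRs.
#' @export
olivePanelAssignment <- function(panel = olivePanel()) {
  df <- panel@loci
  df <- df[!is.na(df$multiplex) &
             df$multiplex %in% c("A-1", "A-2", "B-1", "B-2", "C-1", "C-2"), ]
  data.frame(locus = df$id, group = df$multiplex, dye = df$dye,
             stringsAsFactors = FALSE)
}

#' Loci of the rapid germplasm characterisation set
#'
#' The 35 multiplexed loci plus the separately amplified locus 10.
#'
#' @param panel a \code{\linkS4class{MarkerPanel}}.
#' @return character vector of locus ids (36 loci).
#' @export
rapidCharacterisationSet <- function(panel = olivePanel()) {
  c(olivePanelAssignment(panel)$locus, "10")
}

#' Per-group and pooled diversity report
#'
#' Computes haplotype counts, proportions and the discriminating power
#' \code{D = 1 - sum(p_i^2)} for each group and for the pooled sample
#' (pooled D always from pooled counts).
#'
#' @param assignment data.frame with \code{group} and \code{haplotype}
#'   columns (e.g. from \code{\link{assignHaplotypes}}), or a precomputed
#'   count matrix (haplotypes x groups).
#' @return list: \code{frequencies} (from
#'   \code{\link{haplotypeFrequencies}}), \code{D} (named, one per group
#'   plus \code{pooled}).
#' @export
diversityReport <- function(assignment) {
  freqs <- if (is.matrix(assignment)) {
    cnt <- cbind(assignment, pooled = rowSums(assignment))
    list(count = cnt, proportion = sweep(cnt, 2L, colSums(cnt), "/"),
         n = colSums(cnt))
  } else haplotypeFrequencies(assignment, pooled = TRUE)
  D <- apply(freqs$count, 2L, discriminatingPower, counts = TRUE)
  list(frequencies = freqs, D = D)
}

#' Reconstruct survey counts from a published percentage table
#'
#' Per group, the sample size is taken from \code{group_sizes} when given
#' and otherwise inferred as the smallest n under which every printed
#' percentage is an integer count (\code{\link{inferSampleSize}}); counts
#' follow via \code{\link{countsFromPercent}}.
#'
#' @param freq_df data.frame with \code{haplotype}, \code{group},
#'   \code{percent} (e.g. \code{\link{oliveFrequencies}}).
#' @param group_sizes optional named integer vector of known group sizes.
#' @return count matrix, haplotypes x groups.
#' @export
reconstructSurveyCounts <- function(freq_df, group_sizes = NULL) {
  groups <- unique(freq_df$group)
  haps <- unique(freq_df$haplotype)
  cnt <- matrix(0L, length(haps), length(groups),
                dimnames = list(haps, groups))
  for (g in groups) {
    sub <- freq_df[freq_df$group == g & freq_df$percent > 0, ]
    n <- if (!is.null(group_sizes) && g %in% names(group_sizes))
      group_sizes[[g]] else inferSampleSize(sub$percent)
    if (is.na(n)) stop("cannot infer sample size for group ", g)
    cnt[sub$haplotype, g] <- countsFromPercent(sub$percent, n)
  }
  cnt
}

.writeGFF3 <- function(root, file) {
  rows <- character(0)
  if (!is.null(root$ssr) && nrow(root$ssr))
    rows <- c(rows, sprintf(
      "root\tplastotype\tmicrosatellite\t%d\t%d\t.\t+\t.\tID=ssr%d;motif=%s;repeats=%d",
      root$ssr$ref_start, root$ssr$ref_end, seq_len(nrow(root$ssr)),
      root$ssr$motif, root$ssr$repeat_count))
  if (!is.null(root$genes) && nrow(root$genes))
    rows <- c(rows, sprintf(
      "root\tplastotype\tgene\t%d\t%d\t.\t%s\t%d\tID=%s",
      root$genes$start, root$genes$end, root$genes$strand,
      root$genes$frame, root$genes$name))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region root 1 %d", root$length), rows),
             file)
  invisible(file)
}

.stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Default pipeline configuration
#'
#' A desk-scale synthetic run: a 5 kb root genome with six planted SSR loci
#' and two designated long-deletion sites evolving along a four-taxon
#' genealogy, genotyped in two populations of 60 individuals.
#'
#' @param outdir output directory.
#' @param seed integer seed driving every stage.
#' @return config list accepted by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(outdir, seed = 1L) {
  list(
    seed = seed,
    outdir = outdir,
    stages = c("simulate", "scan", "genotype", "haplotypes", "diversity",
               "network", "tree"),
    simulate = list(
      genome_length = 5000L,
      ssr_loci = data.frame(
        position = c(400L, 1200L, 2100L, 2900L, 3700L, 4500L),
        motif = c("T", "A", "AT", "T", "TA", "A"),
        repeat_count = c(12L, 10L, 6L, 11L, 6L, 9L)),
      long_indel_sites = data.frame(position = c(1600L, 3200L),
                                    length = c(225L, 342L)),
      tree = "((A:1,B:1):0.5,(C:1,D:1):0.5);",
      model = list(sub_rate = 4e-4, ssr_step_rate = 0.6, indel_rate = 1.0,
                   indel_length_law = c(dup7_12 = 0.4, other_short = 0.3,
                                        long = 0.3))),
    genotype = list(
      populations = data.frame(name = c("pop1", "pop2"),
                               size = c(60L, 60L)),
      frequencies = rbind(pop1 = c(A = 0.70, B = 0.20, C = 0.10, D = 0),
                          pop2 = c(A = 0.10, B = 0.10, C = 0.40, D = 0.40)),
      missing_rate = 0, size_noise = 0))
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order and writes all artifacts
#' plus a run manifest (\code{manifest.json}) with per-artifact MD5
#' checksums; identical seeds and configs give byte-identical artifacts.
#' A failing stage stops downstream stages with a stage-tagged error while
#' preserving the artifacts already written.
#'
#' @param config list as produced by \code{\link{defaultPipelineConfig}}, or
#'   a path to a YAML/JSON config file.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      json = jsonlite::fromJSON(config),
      yaml = , yml = yaml::read_yaml(config),
      stop("unsupported config format: ", ext))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  seed <- as.integer(config$seed %||% 1L)
  art <- character(0)
  sim <- NULL; scan <- NULL; geno <- NULL; haplo <- NULL

  if ("simulate" %in% stages) {
    sim <- .stageError("simulate", {
      sc <- config$simulate
      root <- buildRootGenome(sc$genome_length,
                              ssr_loci = sc$ssr_loci,
                              long_indel_sites = sc$long_indel_sites,
                              seed = seed)
      tree <- ape::read.tree(text = sc$tree)
      ev <- evolveGenomes(root, tree, sc$model, seed = seed + 1L)
      writePlastomeAlignment(ev$alignment,
                             file.path(outdir, "alignment.fasta"))
      write.table(ev$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      .writeGFF3(root, file.path(outdir, "annotation.gff3"))
      art <- c(art, "alignment.fasta", "truth.tsv", "annotation.gff3")
      ev
    })
  }
  if ("scan" %in% stages) {
    scan <- .stageError("scan", {
      aln <- if (!is.null(sim)) sim$alignment else
        readPlastomeAlignment(config$scan$alignment)
      res <- scanAlignment(aln)
      write.table(res$substitutions, file.path(outdir, "substitutions.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(res$indels, file.path(outdir, "indels.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(res$ssr, file.path(outdir, "ssr.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      pw <- pairwiseSubstitutions(aln)
      write.table(pw$count, file.path(outdir, "pairwise_substitutions.tsv"),
                  sep = "\t", quote = FALSE)
      jsonlite::write_json(as.list(res$summary),
                           file.path(outdir, "scan_summary.json"),
                           auto_unbox = TRUE)
      art <- c(art, "substitutions.tsv", "indels.tsv", "ssr.tsv",
                "pairwise_substitutions.tsv", "scan_summary.json")
      res
    })
  }
  if ("genotype" %in% stages) {
    geno <- .stageError("genotype", {
      gc <- config$genotype
      catalog <- if (!is.null(sim)) .simCatalog(sim) else gc$catalog
      gp <- genotypePopulation(catalog$profiles, gc$populations,
                               gc$frequencies,
                               missing_rate = gc$missing_rate %||% 0,
                               size_noise = gc$size_noise %||% 0,
                               seed = seed + 2L)
      tab <- data.frame(individual = rownames(gp$genotypes@calls),
                        population = gp$genotypes@groups,
                        gp$genotypes@calls, check.names = FALSE)
      write.table(tab, file.path(outdir, "genotypes.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      art <- c(art, "genotypes.tsv")
      c(gp, list(panel = catalog$panel))
    })
  }
  if ("haplotypes" %in% stages) {
    haplo <- .stageError("haplotypes", {
      if (is.null(geno)) stop("haplotype stage requires genotypes")
      res <- assignHaplotypes(geno$genotypes)
      write.table(res$assignment, file.path(outdir, "haplotypes.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      art <- c(art, "haplotypes.tsv")
      res
    })
  }
  if ("diversity" %in% stages) {
    .stageError("diversity", {
      if (is.null(haplo)) stop("diversity stage requires haplotypes")
      rep <- diversityReport(haplo$assignment)
      write.table(data.frame(haplotype = rownames(rep$frequencies$count),
                             rep$frequencies$count, check.names = FALSE),
                  file.path(outdir, "haplotype_frequencies.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(as.list(round(rep$D, 4L)),
                           file.path(outdir, "diversity.json"),
                           auto_unbox = TRUE)
      art <- c(art, "haplotype_frequencies.tsv", "diversity.json")
    })
  }
  if ("network" %in% stages) {
    .stageError("network", {
      if (is.null(haplo) || is.null(geno))
        stop("network stage requires haplotypes")
      coded <- encodeMatrix(haplo$catalog, geno$panel)
      net <- reducedMedian(coded)
      networkExport(net, file.path(outdir, "network.graphml"), "graphml")
      art <- c(art, "network.graphml")
    })
  }
  if ("tree" %in% stages) {
    .stageError("tree", {
      if (is.null(scan)) stop("tree stage requires scan results")
      subs <- scan$substitutions
      aln_taxa <- setdiff(colnames(subs),
                          c("ref_position", "column", "type", "informative"))
      if (nrow(subs) < 1L || length(aln_taxa) < 3L)
        stop("too little substitution signal for tree inference")
      cm <- t(as.matrix(subs[, aln_taxa, drop = FALSE]))
      res <- exhaustiveSearch(cm)
      ape::write.tree(res$consensus, file.path(outdir, "tree.nwk"))
      art <- c(art, "tree.nwk")
    })
  }

  cfg_file <- file.path(outdir, "config.json")
  jsonlite::write_json(.serializableConfig(config), cfg_file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    tool = paste0("plastotype ",
                  as.character(utils::packageVersion("plastotype"))),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    artifacts = lapply(setNames(art, art), function(f)
      list(md5 = unname(tools::md5sum(file.path(outdir, f))))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.serializableConfig <- function(config) {
  rapply(config, function(x)
    if (is.data.frame(x)) as.list(x) else x, classes = "ANY",
    how = "replace")
}

## Catalog + panel derived from a simulation: per-leaf profiles of SSR
## fragment sizes (100 bp flank + repeats) and long-indel presence.
.simCatalog <- function(sim) {
  ssr <- sim$root$ssr
  counts <- sim$ssr_counts
  flank <- 100L
  loci <- sprintf("ssr%d", seq_len(nrow(ssr)))
  sizes <- sweep(counts * rep(nchar(ssr$motif), each = nrow(counts)),
                 2L, flank, "+")
  colnames(sizes) <- loci
  prof <- matrix(as.character(sizes), nrow(sizes),
                 dimnames = dimnames(sizes))
  truth_long <- sim$truth[sim$truth$type == "indel" &
                            !is.na(sim$truth$class) &
                            sim$truth$class == "long", , drop = FALSE]
  if (nrow(truth_long)) {
    for (i in seq_len(nrow(truth_long))) {
      id <- sprintf("del%d", i)
      carriers <- strsplit(truth_long$carriers[i], ",", fixed = TRUE)[[1L]]
      prof <- cbind(prof, setNames(
        data.frame(ifelse(rownames(prof) %in% carriers, "absent",
                          "present"), stringsAsFactors = FALSE), id))
      prof <- as.matrix(prof)
    }
  }
  panel <- loadLocusDefinitions(data.frame(
    id = colnames(prof),
    kind = c(rep("ssr", length(loci)),
             rep("indel", ncol(prof) - length(loci))),
    motif = c(ssr$motif, rep(NA, ncol(prof) - length(loci))),
    anchor_size = c(flank + ssr$repeat_count * nchar(ssr$motif),
                    rep(NA, ncol(prof) - length(loci))),
    anchor_count = c(ssr$repeat_count,
                     rep(NA, ncol(prof) - length(loci))),
    stringsAsFactors = FALSE))
  profiles <- setNames(lapply(seq_len(nrow(prof)), function(i) prof[i, ]),
                       rownames(prof))
  list(profiles = profiles, panel = panel)
}
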