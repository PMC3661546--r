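#' Configuration for the synthetic genotype generator
#'
#' The generator emulates multi-population SNP genotype panels of the kind
#' produced by large resequencing/genotyping consortia: several populations
#' with tunable differentiation (Balding-Nichols model), blockwise LD
#' created by sampling diploids from small per-block haplotype pools,
#' uniform missingness, and genes containing several SNPs.
#'
#' @param n_populations Number of populations (default 3).
#' @param samples_per_population Diploid samples per population
#'   (default 30).
#' @param n_genes Number of gene regions (default 20).
#' @param snps_per_gene SNPs per gene region (default 6).
#' @param balding_nichols_F Differentiation parameter F in \[0, 1); a single
#'   value shared by all populations or one per population (default 0.1).
#' @param block_length SNPs per LD block (default 3).
#' @param haplotypes_per_block Haplotype pool size per block and population;
#'   small pools give strong within-block LD (default 4).
#' @param missing_rate Probability a genotype call is missing (default
#'   0.02, must be in \[0, 0.5\]).
#' @param ascertain Emulate array ascertainment of common SNPs: haplotype
#'   pool columns that come out monomorphic are redrawn (up to 20 times),
#'   so SNPs stay polymorphic in every population, as genotyping-panel
#'   SNPs typically are (default TRUE). Set FALSE for unbiased
#'   Balding-Nichols sampling, e.g. when studying frequency-model
#'   recovery.
#' @param seed Integer seed; every draw is derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 3, samples_per_population = 30,
                       n_genes = 20, snps_per_gene = 6,
                       balding_nichols_F = 0.1, block_length = 3,
                       haplotypes_per_block = 4, missing_rate = 0.02,
                       ascertain = TRUE, seed = 1) {
  stopifnot(n_populations >= 2, samples_per_population >= 2,
            n_genes >= 1, snps_per_gene >= 2, block_length >= 1,
            haplotypes_per_block >= 2)
  if (any(balding_nichols_F < 0) || any(balding_nichols_F >= 1)) {
    stop("balding_nichols_F must be in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("missing_rate must be in [0, 0.5]")
  }
  F_vec <- rep(balding_nichols_F, length.out = n_populations)
  structure(list(n_populations = n_populations,
                 samples_per_population = samples_per_population,
                 n_genes = n_genes, snps_per_gene = snps_per_gene,
                 balding_nichols_F = F_vec, block_length = block_length,
                 haplotypes_per_block = haplotypes_per_block,
                 missing_rate = missing_rate, ascertain = isTRUE(ascertain),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ancestral and per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are drawn from Uniform(0.05, 0.95); each
#' population's frequency is drawn from
#' Beta(p (1-F)/F, (1-p)(1-F)/F), whose mean is p and variance
#' F p (1-p). F = 0 degenerates to the ancestral frequency exactly.
#'
#' @param config A [sim_config()].
#' @return A list: `ancestral` (length n_snps) and `pop_freq` (matrix
#'   n_snps x n_populations).
#' @export
simulate_frequencies <- function(config) {
  set.seed(config$seed)
  n_snps <- config$n_genes * config$snps_per_gene
  p <- stats::runif(n_snps, 0.05, 0.95)
  pop_freq <- sapply(seq_len(config$n_populations), function(i) {
    F <- config$balding_nichols_F[i]
    if (F == 0) return(p)
    stats::rbeta(n_snps, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  })
  list(ancestral = p, pop_freq = pop_freq)
}

#' Simulate genotypes with blockwise LD
#'
#' Within each gene, SNPs are grouped into blocks of `block_length`. For
#' each (block, population) a pool of `haplotypes_per_block` haplotypes is
#' drawn from that population's allele frequencies, and each diploid's two
#' block haplotypes are sampled with replacement from the pool. Small pools
#' induce strong within-block LD; blocks are drawn independently, so
#' between-block LD is at equilibrium. Missingness is applied uniformly at
#' random.
#'
#' @param frequencies Output of [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @return A list: `vt` (a [variant_table()]), `panel`
#'   (a [population_panel()]), `regions` (gene BED tibble, 0-based
#'   half-open), `sets` (a gene-set tibble when `n_genes >= 10`, else an
#'   empty tibble).
#' @export
simulate_genotypes <- function(frequencies, config) {
  set.seed(config$seed + 1L)
  n_snps <- config$n_genes * config$snps_per_gene
  n_tot <- config$n_populations * config$samples_per_population
  pops <- paste0("POP", seq_len(config$n_populations))
  sample_ids <- paste0(rep(pops, each = config$samples_per_population), "_",
                       rep(seq_len(config$samples_per_population),
                           config$n_populations))
  panel <- population_panel(sample_ids,
                            rep(pops, each = config$samples_per_population))

  gene_of <- rep(seq_len(config$n_genes), each = config$snps_per_gene)
  within <- sequence(rep(config$snps_per_gene, config$n_genes))
  block_of <- paste(gene_of, ceiling(within / config$block_length))

  geno <- matrix(NA_integer_, nrow = n_tot, ncol = n_snps)
  for (bi in unique(block_of)) {
    snps <- which(block_of == bi)
    for (pi in seq_len(config$n_populations)) {
      rows <- (pi - 1) * config$samples_per_population +
        seq_len(config$samples_per_population)
      pool <- matrix(
        stats::rbinom(config$haplotypes_per_block * length(snps), 1,
                      rep(frequencies$pop_freq[snps, pi],
                          each = config$haplotypes_per_block)),
        nrow = config$haplotypes_per_block)
      if (config$ascertain) {
        for (ci in seq_along(snps)) {
          tries <- 0L
          while (length(unique(pool[, ci])) == 1 && tries < 20L) {
            pool[, ci] <- stats::rbinom(config$haplotypes_per_block, 1,
                                        frequencies$pop_freq[snps[ci], pi])
            tries <- tries + 1L
          }
        }
      }
      h1 <- sample.int(config$haplotypes_per_block,
                       config$samples_per_population, replace = TRUE)
      h2 <- sample.int(config$haplotypes_per_block,
                       config$samples_per_population, replace = TRUE)
      geno[rows, snps] <- pool[h1, , drop = FALSE] +
        pool[h2, , drop = FALSE]
    }
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }

  gene_start <- (gene_of - 1L) * 100000L
  pos <- gene_start + (within - 1L) * 250L + 1L   # 1-based
  snp <- tibble::tibble(
    snp_id = sprintf("snp_g%03d_%02d", gene_of, within),
    chrom = "1", pos = pos, ref = "A", alt = "G")
  vt <- variant_table(snp, geno, sample_ids)
  regions <- tibble::tibble(
    gene_id = sprintf("GENE%03d", seq_len(config$n_genes)),
    chrom = "1",
    start = (seq_len(config$n_genes) - 1L) * 100000L,
    end = (seq_len(config$n_genes) - 1L) * 100000L +
      config$snps_per_gene * 250L)
  sets <- if (config$n_genes >= 10) {
    n_sets <- max(2L, config$n_genes %/% 10L)
    tibble::tibble(
      set_id = sprintf("SET%02d", seq_len(n_sets)),
      set_name = sprintf("synthetic set %d", seq_len(n_sets)),
      category = "pathway",
      gene_ids = lapply(seq_len(n_sets), function(s) {
        sort(sample(regions$gene_id, min(10L + s, config$n_genes)))
      }))
  } else {
    tibble::tibble(set_id = character(), set_name = character(),
                   category = character(), gene_ids = list())
  }
  if (nrow(sets) > 0) sets$n_genes <- lengths(sets$gene_ids)
  list(vt = vt, panel = panel, regions = regions, sets = sets)
}

#' One-call synthetic dataset
#'
#' @param config A [sim_config()] (or arguments passed to it via `...`).
#' @param ... Passed to [sim_config()] when `config` is missing.
#' @return As [simulate_genotypes()].
#' @export
simulate_dataset <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  simulate_genotypes(simulate_frequencies(config), config)
}

#' Write a variant table as a minimal VCF
#'
#' @param vt A `variant_table`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popgendiff-synthetic",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(vt$geno)),
                     collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (k in seq_len(n_snps(vt))) {
    g <- vt$geno[, k]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    writeLines(paste(c(vt$snp$chrom[k], vt$snp$pos[k], vt$snp$snp_id[k],
                       vt$snp$ref[k], vt$snp$alt[k], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the simple genotype TSV dialect
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(vt, path) {
  dos <- t(vt$geno)
  dos_chr <- matrix(as.character(dos), nrow = nrow(dos))
  dos_chr[is.na(dos_chr)] <- "."
  df <- cbind(vt$snp[, c("snp_id", "chrom", "pos", "ref", "alt")],
              stats::setNames(as.data.frame(dos_chr), rownames(vt$geno)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write synthetic fixtures to disk
#'
#' Emits the four input files the pipeline reads: a VCF, a two-column panel
#' TSV, a BED3+name gene file and a GMT gene-set file. The files round-trip
#' losslessly through [read_vcf()], [read_population_panel()],
#' [read_gene_regions()] and [read_gene_sets()].
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the paths written.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             panel = file.path(dir, "panel.tsv"),
             bed = file.path(dir, "genes.bed"),
             gmt = file.path(dir, "sets.gmt"))
  write_vcf(dataset$vt, paths[["vcf"]])
  utils::write.table(dataset$panel[, c("sample_id", "population")],
                     paths[["panel"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  reg <- dataset$regions
  writeLines(paste(reg$chrom, reg$start, reg$end, reg$gene_id, sep = "\t"),
             paths[["bed"]])
  if (nrow(dataset$sets) > 0) {
    writeLines(vapply(seq_len(nrow(dataset$sets)), function(i) {
      paste(c(dataset$sets$set_id[i], dataset$sets$set_name[i],
              dataset$sets$gene_ids[[i]]), collapse = "\t")
    }, character(1)), paths[["gmt"]])
  } else {
    writeLines(character(0), paths[["gmt"]])
  }
  paths
}
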