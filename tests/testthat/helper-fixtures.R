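# in-code fixtures shared across test files

# tiny variant table from a dosage matrix (samples x SNPs)
make_vt <- function(geno, pos = NULL, chrom = "1") {
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  snp <- data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                    pos = pos, ref = "A", alt = "G")
  variant_table(snp, geno, paste0("ind", seq_len(nrow(geno))))
}

# two-population panel over the samples of a variant table
make_panel <- function(vt, n_pops = 2) {
  ids <- rownames(vt$geno)
  pops <- paste0("P", rep(seq_len(n_pops), length.out = length(ids)))
  population_panel(ids, pops[order(rep(seq_len(n_pops),
                                       length.out = length(ids)))])
}

# a pairwise_ld-shaped tibble from a symmetric r2 matrix over snp_idx
ld_from_r2 <- function(snp_idx, r2m) {
  m <- length(snp_idx)
  rows <- list()
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        a = snp_idx[a], b = snp_idx[b], r2 = r2m[a, b],
        d_prime = r2m[a, b], n_gametes = 4L, fgt_pass = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

# default small synthetic dataset used by several suites
small_dataset <- function(seed = 1, missing_rate = 0, ...) {
  simulate_dataset(sim_config(n_populations = 2,
                              samples_per_population = 20,
                              n_genes = 4, snps_per_gene = 4,
                              balding_nichols_F = 0.1, block_length = 2,
                              haplotypes_per_block = 3,
                              missing_rate = missing_rate,
                              seed = seed, ...))
}
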