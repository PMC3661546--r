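test_that("closed-form LD statistics match hand evaluation", {
  # independence: D = 0
  f <- c("11" = 0.25, "10" = 0.25, "01" = 0.25, "00" = 0.25)
  st <- ld_stats(f)
  expect_equal(st$r2, 0); expect_equal(st$d_prime, 0)
  # one haplotype class absent -> D' = 1
  f <- c("11" = 0.5, "10" = 0.3, "01" = 0.2, "00" = 0)
  expect_equal(ld_stats(f)$d_prime, 1)
  # hand-evaluated: (0.4, 0.1, 0.1, 0.4)
  f <- c("11" = 0.4, "10" = 0.1, "01" = 0.1, "00" = 0.4)
  st <- ld_stats(f)
  expect_equal(st$r2, 0.36)
  expect_equal(st$d_prime, 0.6)
  # monomorphic marginal -> undefined
  f <- c("11" = 0, "10" = 0, "01" = 0.4, "00" = 0.6)
  expect_true(is.na(ld_stats(f)$r2))
})

test_that("unambiguous phase data give the counted spectrum and r2 = 1", {
  ga <- c(0L, 0L, 0L, 2L, 2L, 2L, 2L)
  gb <- c(0L, 0L, 0L, 2L, 2L, 2L, 2L)
  fit <- em_two_locus(ga, gb)
  expect_equal(fit$freqs[["11"]], 4 / 7, tolerance = 1e-7)
  expect_equal(fit$freqs[["00"]], 3 / 7, tolerance = 1e-7)
  expect_equal(ld_stats(fit$freqs)$r2, 1, tolerance = 1e-7)
})

test_that("EM equals direct phase counting when no double heterozygotes", {
  set.seed(8)
  for (i in 1:20) {
    n <- 30
    ga <- rbinom(n, 2, runif(1, 0.2, 0.8))
    gb <- ifelse(ga == 1L, sample(c(0L, 2L), n, replace = TRUE),
                 rbinom(n, 2, 0.5))     # never both het
    if (length(unique(ga)) == 1 || length(unique(gb)) == 1) next
    fit <- em_two_locus(ga, gb)
    # direct gamete counting: every genotype phases uniquely
    cnt <- c("11" = 0, "10" = 0, "01" = 0, "00" = 0)
    for (s in seq_len(n)) {
      a <- ga[s]; b <- gb[s]
      h1a <- ifelse(a >= 1, 1, 0); h2a <- ifelse(a == 2, 1, 0)
      h1b <- ifelse(b >= 1, 1, 0); h2b <- ifelse(b == 2, 1, 0)
      cnt[paste0(h1a, h1b)] <- cnt[paste0(h1a, h1b)] + 1
      cnt[paste0(h2a, h2b)] <- cnt[paste0(h2a, h2b)] + 1
    }
    expect_equal(unname(fit$freqs[names(cnt)]), unname(cnt / (2 * n)),
                 tolerance = 1e-6)
  }
})

test_that("EM log-likelihood dominates an exhaustive grid (two-locus)", {
  set.seed(19)
  done <- 0
  while (done < 8) {
    n <- sample(8:15, 1)
    ga <- rbinom(n, 2, runif(1, 0.25, 0.75))
    gb <- rbinom(n, 2, runif(1, 0.25, 0.75))
    if (length(unique(ga)) == 1 || length(unique(gb)) == 1) next
    fit <- em_two_locus(cbind(ga), cbind(gb))
    best <- grid_best_loglik(cbind(ga, gb), steps = 40)
    expect_gte(fit$loglik, best - 1e-6)
    done <- done + 1
  }
})

test_that("a lone double heterozygote converges to a stationary point", {
  ga <- c(0L, 2L, 1L, 0L, 2L)
  gb <- c(0L, 2L, 1L, 0L, 2L)
  fit <- em_two_locus(ga, gb)
  expect_equal(sum(fit$freqs), 1, tolerance = 1e-8)
  best <- grid_best_loglik(cbind(ga, gb), steps = 50)
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("linkage-equilibrium simulation gives near-zero r2", {
  set.seed(4)
  ga <- rbinom(500, 2, 0.5)
  gb <- rbinom(500, 2, 0.4)
  fit <- em_two_locus(ga, gb)
  expect_lt(ld_stats(fit$freqs)$r2, 0.05)
})

test_that("r2 and D' are invariant to locus order and allele relabeling", {
  set.seed(27)
  ds <- small_dataset(seed = 27)
  g <- ds$vt$geno[1:20, 1:2]
  f0 <- em_two_locus(g[, 1], g[, 2])
  s0 <- ld_stats(f0$freqs)
  s_swap <- ld_stats(em_two_locus(g[, 2], g[, 1])$freqs)
  s_flip <- ld_stats(em_two_locus(2L - g[, 1], g[, 2])$freqs)
  expect_equal(s0$r2, s_swap$r2, tolerance = 1e-6)
  expect_equal(s0$d_prime, s_swap$d_prime, tolerance = 1e-6)
  expect_equal(s0$r2, s_flip$r2, tolerance = 1e-6)
  expect_equal(s0$d_prime, s_flip$d_prime, tolerance = 1e-6)
})

test_that("r2 <= D' when both marginals are one half", {
  # forced algebraically at pA = pB = 0.5: r2 = D'^2 <= D'
  for (d in c(-0.2, -0.1, 0.05, 0.2, 0.25)) {
    f <- c("11" = 0.25 + d, "10" = 0.25 - d, "01" = 0.25 - d,
           "00" = 0.25 + d)
    st <- ld_stats(f)
    expect_lte(st$r2, st$d_prime + 1e-12)
  }
})

test_that("four-gamete test groups and splits two-SNP examples", {
  # 3 gametes only: block
  ga <- c(0L, 0L, 2L, 2L, 0L, 0L, 2L, 2L)
  gb <- c(0L, 0L, 2L, 2L, 2L, 2L, 2L, 2L)
  vt <- make_vt(cbind(ga, gb))
  blocks <- four_gamete_blocks(vt, rownames(vt$geno), 1:2)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_snps, 2)
  # all four gametes at high frequency: no block
  ga <- rep(c(0L, 0L, 2L, 2L), 3)
  gb <- rep(c(0L, 2L, 0L, 2L), 3)
  vt <- make_vt(cbind(ga, gb))
  expect_length(four_gamete_blocks(vt, rownames(vt$geno), 1:2), 0)
})

test_that("greedy partition equals the brute-force partitioner", {
  set.seed(61)
  for (rep in 1:25) {
    ds <- simulate_dataset(sim_config(
      n_populations = 2, samples_per_population = 25, n_genes = 1,
      snps_per_gene = 8, balding_nichols_F = 0.05,
      block_length = sample(2:4, 1), haplotypes_per_block = sample(2:6, 1),
      missing_rate = 0.05, seed = 6000 + rep))
    samples <- panel_samples(ds$panel, "POP1")
    ld <- pairwise_ld(ds$vt, samples, 1:8)
    blocks <- four_gamete_blocks(ds$vt, samples, 1:8, ld = ld)
    pass <- matrix(TRUE, 8, 8)
    for (r in seq_len(nrow(ld))) {
      pass[ld$a[r], ld$b[r]] <- isTRUE(ld$fgt_pass[r])
      pass[ld$b[r], ld$a[r]] <- isTRUE(ld$fgt_pass[r])
    }
    brute <- fgt_brute_partition(pass)
    expect_identical(lapply(blocks, function(b) b$snp_idx),
                     lapply(brute, as.integer))
    # partition property: disjoint, ordered, contiguous
    idx <- unlist(lapply(blocks, function(b) b$snp_idx))
    expect_false(any(duplicated(idx)))
    expect_identical(idx, sort(idx))
    for (b in blocks) expect_identical(b$snp_idx,
                                       seq(min(b$snp_idx), max(b$snp_idx)))
  }
})

test_that("block summary features compute spans, means and densities", {
  blocks <- list(list(snp_idx = 1:5, start_bp = 1, end_bp = 10000,
                      n_snps = 5))
  bf <- block_features(blocks)
  expect_equal(bf$block_number, 1)
  expect_equal(bf$mean_block_size, 10000)
  expect_equal(bf$snp_density, 0.5)
  two <- list(list(snp_idx = 1:2, start_bp = 1, end_bp = 1000, n_snps = 2),
              list(snp_idx = 4:5, start_bp = 2001, end_bp = 5000,
                   n_snps = 2))
  expect_equal(block_features(two)$mean_block_size, 2000)
  none <- block_features(list())
  expect_equal(none$block_number, 0)
  expect_true(is.na(none$mean_block_size))
  expect_true(is.na(none$snp_density))
})

test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotype_diversity(c(a = 1), 10), 0)
  expect_equal(haplotype_diversity(c(a = 0.5, b = 0.5), 10),
               (10 / 9) * 0.5)
  expect_equal(haplotype_diversity(c(a = 0.5, b = 0.5), 10,
                                   unbiased = FALSE), 0.5)
})

test_that("diversity grows when a haplotype class is split in half", {
  set.seed(13)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    p <- as.vector(stats::rmultinom(1, 50, rep(1, k))) / 50
    p <- p[p > 0]
    split <- c(p[-1], p[1] / 2, p[1] / 2)
    n <- 40
    expect_gt(haplotype_diversity(split, n) + 1e-12,
              haplotype_diversity(p, n))
    h <- haplotype_diversity(p, n)
    expect_gte(h, 0)
    expect_lt(h, n / (n - 1))
  }
})

test_that("block EM log-likelihood dominates a grid scan (3 SNPs)", {
  set.seed(77)
  done <- 0
  while (done < 3) {
    ds <- simulate_dataset(sim_config(
      n_populations = 2, samples_per_population = 10, n_genes = 1,
      snps_per_gene = 3, balding_nichols_F = 0.05, block_length = 3,
      haplotypes_per_block = 3, missing_rate = 0, seed = 700 + done))
    g <- ds$vt$geno[panel_samples(ds$panel, "POP1"), 1:3]
    fit <- em_block_haplotypes(g)
    best <- grid_best_loglik(g, steps = 8)
    expect_gte(fit$loglik, best - 1e-6)
    expect_equal(sum(fit$freqs), 1, tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("partition-ligation handles blocks longer than the threshold", {
  set.seed(55)
  ds <- simulate_dataset(sim_config(
    n_populations = 2, samples_per_population = 30, n_genes = 1,
    snps_per_gene = 10, balding_nichols_F = 0.05, block_length = 10,
    haplotypes_per_block = 4, missing_rate = 0, seed = 55))
  g <- ds$vt$geno[panel_samples(ds$panel, "POP1"), ]
  fit <- em_block_haplotypes(g, pl_threshold = 4L)
  expect_equal(sum(fit$freqs), 1, tolerance = 1e-6)
  expect_lte(sum(fit$freqs > 0.01), 16)   # few pool haplotypes dominate
  direct <- em_haplotypes(g)               # 10 SNPs is still tractable
  expect_gte(fit$loglik, direct$loglik - 2)  # PL is a restricted-space EM
})
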