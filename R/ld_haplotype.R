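#' Maximum-likelihood haplotype frequencies from unphased genotypes
#'
#' Expectation-Maximization over the haplotype space of a small window of
#' bi-allelic SNPs. Samples with any missing genotype in the window are
#' excluded. Initialization is deterministic at the linkage-equilibrium
#' product of marginal allele frequencies, so repeated runs are identical;
#' EM converges to a stationary point of the likelihood.
#'
#' @param g Integer matrix of dosages (samples x SNPs), values 0/1/2/NA.
#' @param tol Convergence tolerance on the max absolute frequency change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param candidates Optional character vector of haplotype strings (e.g.
#'   `"010"`) restricting the admissible haplotype space (used by
#'   partition-ligation); samples with no compatible pair among the
#'   candidates are dropped.
#' @return A list: `freqs` (named vector over haplotype strings, summing to
#'   1), `loglik`, `n_chromosomes` (2 x samples used), `n_iter`.
#' @export
em_haplotypes <- function(g, tol = 1e-8, max_iter = 1000L,
                          candidates = NULL) {
  g <- as.matrix(g)
  complete <- stats::complete.cases(g)
  g <- g[complete, , drop = FALSE]
  L <- ncol(g)
  if (nrow(g) < 2) stop("need >= 2 samples with complete genotypes")

  # unordered compatible haplotype pairs per sample
  hap_str <- function(v) paste(v, collapse = "")
  pairs_of <- function(geno) {
    het <- which(geno == 1L)
    base <- ifelse(geno == 2L, 1L, 0L)
    if (length(het) == 0) {
      h <- hap_str(base)
      return(list(c(h, h)))
    }
    # fix the first het site to 0 in hap1: enumerates unordered pairs once
    n_free <- length(het) - 1L
    combos <- if (n_free == 0) matrix(0L, 1, 0) else
      as.matrix(expand.grid(rep(list(0:1), n_free)))
    lapply(seq_len(nrow(combos)), function(r) {
      h1 <- base
      h1[het] <- c(0L, as.integer(combos[r, ]))
      h2 <- base
      h2[het] <- 1L - h1[het]
      c(hap_str(h1), hap_str(h2))
    })
  }
  sample_pairs <- lapply(seq_len(nrow(g)), function(i) {
    pr <- pairs_of(g[i, ])
    if (!is.null(candidates)) {
      pr <- Filter(function(p) all(p %in% candidates), pr)
    }
    pr
  })
  used <- lengths(sample_pairs) > 0
  sample_pairs <- sample_pairs[used]
  n_used <- sum(used)
  if (n_used < 2) stop("fewer than 2 samples compatible with haplotype set")

  haps <- sort(unique(unlist(sample_pairs)))
  H <- length(haps)
  # linkage-equilibrium initialization from marginal frequencies
  marg <- colMeans(g[used, , drop = FALSE]) / 2
  hap_mat <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  p <- apply(hap_mat, 1, function(a) prod(ifelse(a == 1, marg, 1 - marg)))
  p <- p / sum(p)
  names(p) <- haps

  pair_i1 <- lapply(sample_pairs, function(pr) match(vapply(pr, `[`, "", 1), haps))
  pair_i2 <- lapply(sample_pairs, function(pr) match(vapply(pr, `[`, "", 2), haps))

  loglik <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cnt <- numeric(H)
    ll <- 0
    for (s in seq_len(n_used)) {
      i1 <- pair_i1[[s]]
      i2 <- pair_i2[[s]]
      w <- ifelse(i1 == i2, p[i1]^2, 2 * p[i1] * p[i2])
      tot <- sum(w)
      if (tot <= 0) {
        w <- rep(1 / length(w), length(w))
        tot <- 1e-300
      } else {
        w <- w / tot
      }
      ll <- ll + log(tot)
      for (k in seq_along(w)) {
        cnt[i1[k]] <- cnt[i1[k]] + w[k]
        cnt[i2[k]] <- cnt[i2[k]] + w[k]
      }
    }
    p_new <- stats::setNames(cnt / (2 * n_used), haps)
    delta <- max(abs(p_new - p))
    p <- p_new
    loglik <- ll
    if (delta < tol || iter >= max_iter) break
  }
  list(freqs = p, loglik = loglik, n_chromosomes = 2L * n_used,
       n_iter = iter)
}

#' Two-locus EM haplotype frequencies
#'
#' @param ga,gb Integer dosage vectors for the two SNPs (same samples).
#' @inheritParams em_haplotypes
#' @return A list as in [em_haplotypes()] with `freqs` always the full
#'   length-4 vector named `"11"`, `"10"`, `"01"`, `"00"` (1 = alt allele).
#' @details Uses the closed-form two-locus EM on the 3 x 3 genotype class
#'   table: all classes except the double heterozygote phase unambiguously,
#'   and the double-heterozygote mass is split between the cis and trans
#'   phases in proportion to `p11 p00 : p10 p01` at each E-step.
#' @export
em_two_locus <- function(ga, gb, tol = 1e-8, max_iter = 1000L) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]
  gb <- gb[ok]
  n <- length(ga)
  if (n < 2) stop("need >= 2 samples with complete genotypes")
  cnt <- table(factor(ga, 0:2), factor(gb, 0:2))
  N <- 2 * n
  # fixed haplotype counts from unambiguous classes
  fix11 <- 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"]
  fix10 <- 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"]
  fix01 <- 2 * cnt["0", "2"] + cnt["1", "2"] + cnt["0", "1"]
  fix00 <- 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"]
  dh <- cnt["1", "1"]
  pA <- mean(ga) / 2
  pB <- mean(gb) / 2
  p <- c("11" = pA * pB, "10" = pA * (1 - pB), "01" = (1 - pA) * pB,
         "00" = (1 - pA) * (1 - pB))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cis <- p[["11"]] * p[["00"]]
    trans <- p[["10"]] * p[["01"]]
    x <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    p_new <- c(fix11 + dh * x, fix10 + dh * (1 - x),
               fix01 + dh * (1 - x), fix00 + dh * x) / N
    names(p_new) <- names(p)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol || iter >= max_iter) break
  }
  pr <- function(h) p[[h]]
  class_probs <- matrix(c(
    pr("00")^2, 2 * pr("00") * pr("01"), pr("01")^2,
    2 * pr("00") * pr("10"), 2 * (pr("11") * pr("00") + pr("10") * pr("01")),
    2 * pr("01") * pr("11"),
    pr("10")^2, 2 * pr("10") * pr("11"), pr("11")^2), nrow = 3,
    byrow = TRUE)
  obs <- matrix(as.numeric(cnt), 3, 3)
  nz <- obs > 0
  ll <- sum(obs[nz] * log(pmax(class_probs[nz], 1e-300)))
  list(freqs = p, loglik = ll, n_chromosomes = N, n_iter = iter)
}

#' r-squared and D-prime from two-locus haplotype frequencies
#'
#' D = p11 - pA * pB with pA, pB the alt-allele frequencies at the two loci;
#' r2 = D^2 / (pA (1-pA) pB (1-pB)); D' = |D| / Dmax where Dmax is
#' min(pA (1-pB), (1-pA) pB) for D > 0 and min(pA pB, (1-pA)(1-pB)) for
#' D < 0.
#'
#' @param hap_freqs Length-4 vector named `"11"`, `"10"`, `"01"`, `"00"`.
#' @return A list with `r2` and `d_prime`, both `NA` when either locus is
#'   monomorphic; both 0 exactly when D = 0.
#' @export
ld_stats <- function(hap_freqs) {
  pA <- hap_freqs[["11"]] + hap_freqs[["10"]]
  pB <- hap_freqs[["11"]] + hap_freqs[["01"]]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(list(r2 = NA_real_, d_prime = NA_real_))
  }
  D <- hap_freqs[["11"]] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  if (D > 0) {
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    dmax <- min(pA * pB, (1 - pA) * (1 - pB))
  } else {
    return(list(r2 = 0, d_prime = 0))
  }
  list(r2 = min(r2, 1), d_prime = min(abs(D) / dmax, 1))
}

#' All pairwise LD statistics within a gene region, one population
#'
#' Runs the two-locus EM for every SNP pair (optionally capped by physical
#' distance) and reports r2, D' and the number of gametes whose EM frequency
#' reaches the four-gamete threshold.
#'
#' @param vt A `variant_table`.
#' @param samples Sample ids defining the population.
#' @param snp_idx SNP column indices of the gene.
#' @param fgt_threshold A gamete "exists" if its EM frequency is at least
#'   this value (default 0.01, the HaploView convention).
#' @param max_pair_distance Skip pairs further apart than this many bp
#'   (default `Inf`).
#' @return A tibble: `a`, `b` (SNP column indices, a < b), `r2`, `d_prime`,
#'   `n_gametes`, `fgt_pass` (fewer than four gametes observed).
#' @export
pairwise_ld <- function(vt, samples, snp_idx, fgt_threshold = 0.01,
                        max_pair_distance = Inf) {
  g <- vt$geno[rownames(vt$geno) %in% samples, snp_idx, drop = FALSE]
  pos <- vt$snp$pos[snp_idx]
  m <- length(snp_idx)
  rows <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (pos[j] - pos[i] > max_pair_distance) next
      both <- !is.na(g[, i]) & !is.na(g[, j])
      if (sum(both) < 2) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          a = snp_idx[i], b = snp_idx[j], r2 = NA_real_,
          d_prime = NA_real_, n_gametes = NA_integer_, fgt_pass = NA)
        next
      }
      mono_i <- length(unique(g[both, i])) == 1 && g[both, i][1] != 1L
      mono_j <- length(unique(g[both, j])) == 1 && g[both, j][1] != 1L
      if (mono_i || mono_j) {
        # monomorphic locus: r2/D' undefined, at most two gametes
        rows[[length(rows) + 1]] <- tibble::tibble(
          a = snp_idx[i], b = snp_idx[j], r2 = NA_real_,
          d_prime = NA_real_, n_gametes = 2L, fgt_pass = TRUE)
        next
      }
      fit <- em_two_locus(g[, i], g[, j])
      st <- ld_stats(fit$freqs)
      ng <- sum(fit$freqs >= fgt_threshold)
      rows[[length(rows) + 1]] <- tibble::tibble(
        a = snp_idx[i], b = snp_idx[j], r2 = st$r2, d_prime = st$d_prime,
        n_gametes = as.integer(ng), fgt_pass = ng < 4L)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(a = integer(), b = integer(), r2 = numeric(),
                          d_prime = numeric(), n_gametes = integer(),
                          fgt_pass = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Four-gamete-test haplotype blocks
#'
#' Greedy left-to-right partition of a gene's SNPs into maximal contiguous
#' runs in which every SNP pair shows fewer than four gametes (a gamete
#' "exists" if its EM frequency reaches `fgt_threshold`). Runs of length 1
#' are not blocks: singleton SNPs between blocks are left unblocked.
#'
#' @param vt A `variant_table`.
#' @param samples Sample ids of the population.
#' @param snp_idx SNP column indices of the gene (increasing).
#' @param fgt_threshold Gamete existence threshold (default 0.01).
#' @param ld Optional precomputed [pairwise_ld()] tibble for these SNPs;
#'   computed if omitted.
#' @return A list of blocks, each a list with `snp_idx`, `start_bp`,
#'   `end_bp`, `n_snps`.
#' @export
four_gamete_blocks <- function(vt, samples, snp_idx, fgt_threshold = 0.01,
                               ld = NULL) {
  m <- length(snp_idx)
  if (m < 2) return(list())
  if (is.null(ld)) {
    ld <- pairwise_ld(vt, samples, snp_idx, fgt_threshold = fgt_threshold)
  }
  pass <- matrix(FALSE, m, m)
  for (r in seq_len(nrow(ld))) {
    i <- match(ld$a[r], snp_idx)
    j <- match(ld$b[r], snp_idx)
    ok <- isTRUE(ld$fgt_pass[r])
    pass[i, j] <- ok
    pass[j, i] <- ok
  }
  blocks <- list()
  s <- 1L
  while (s <= m) {
    e <- s
    while (e < m && all(pass[s:e, e + 1L])) e <- e + 1L
    if (e > s) {
      idx <- snp_idx[s:e]
      blocks[[length(blocks) + 1]] <- list(
        snp_idx = idx,
        start_bp = vt$snp$pos[idx[1]],
        end_bp = vt$snp$pos[idx[length(idx)]],
        n_snps = length(idx))
    }
    s <- e + 1L
  }
  blocks
}

#' Block-level summary features
#'
#' @param blocks Output of [four_gamete_blocks()].
#' @return A list: `block_number` (count of multi-SNP blocks),
#'   `mean_block_size` (mean of end - start + 1, bp), `snp_density` (mean
#'   over blocks of SNPs per kb of block span). All `NA` when no block
#'   exists.
#' @export
block_features <- function(blocks) {
  if (length(blocks) == 0) {
    return(list(block_number = 0L, mean_block_size = NA_real_,
                snp_density = NA_real_))
  }
  sizes <- vapply(blocks, function(b) b$end_bp - b$start_bp + 1, numeric(1))
  dens <- vapply(blocks, function(b) b$n_snps / ((b$end_bp - b$start_bp + 1) / 1000),
                 numeric(1))
  list(block_number = length(blocks), mean_block_size = mean(sizes),
       snp_density = mean(dens))
}

#' Haplotype frequencies of one block, with partition-ligation fallback
#'
#' Blocks of up to `pl_threshold` SNPs are fit by a single multi-locus EM;
#' longer blocks are split into chunks, each chunk is fit separately, the
#' most frequent chunk haplotypes are concatenated into a candidate set and
#' a final EM is run restricted to those candidates (partition-ligation).
#'
#' @param g Dosage matrix (samples x block SNPs).
#' @param pl_threshold Maximum SNPs for direct EM (default 8).
#' @param keep_per_chunk Chunk haplotypes retained for ligation (default 8).
#' @return As [em_haplotypes()].
#' @export
em_block_haplotypes <- function(g, pl_threshold = 8L, keep_per_chunk = 8L) {
  L <- ncol(g)
  if (L <= pl_threshold) return(em_haplotypes(g))
  chunks <- split(seq_len(L), ceiling(seq_len(L) / pl_threshold))
  cand_parts <- lapply(chunks, function(ix) {
    fit <- em_haplotypes(g[, ix, drop = FALSE])
    fr <- sort(fit$freqs, decreasing = TRUE)
    names(fr)[seq_len(min(keep_per_chunk, length(fr)))]
  })
  grid <- expand.grid(cand_parts, stringsAsFactors = FALSE)
  candidates <- apply(as.matrix(grid), 1, paste, collapse = "")
  em_haplotypes(g, candidates = candidates)
}

#' Haplotype diversity of a block
#'
#' Nei's unbiased gene diversity over the block's haplotype spectrum:
#' H = (n / (n - 1)) * (1 - sum p_h^2), with n the number of chromosomes.
#'
#' @param hap_freqs Named haplotype frequency vector (sums to 1).
#' @param n_chromosomes Number of chromosomes the spectrum was estimated
#'   from.
#' @param unbiased Apply the n/(n-1) correction (default TRUE); set FALSE
#'   for the plain 1 - sum p^2 form.
#' @return Diversity in \[0, n/(n-1)); 0 for a single-haplotype spectrum.
#' @export
haplotype_diversity <- function(hap_freqs, n_chromosomes, unbiased = TRUE) {
  h <- 1 - sum(hap_freqs^2)
  if (unbiased) h <- n_chromosomes / (n_chromosomes - 1) * h
  max(h, 0)
}
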