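#' Per-population allele counts at a set of SNPs
#'
#' @param vt A `variant_table`.
#' @param samples Sample ids defining the population.
#' @param snp_idx SNP column indices.
#' @return A list with `alt_count` (alt alleles observed), `n_chrom`
#'   (non-missing chromosomes) and `alt_freq` per SNP.
#' @keywords internal
allele_counts <- function(vt, samples, snp_idx) {
  g <- vt$geno[rownames(vt$geno) %in% samples, snp_idx, drop = FALSE]
  n_obs <- unname(colSums(!is.na(g)))
  alt <- unname(colSums(g, na.rm = TRUE))
  list(alt_count = alt, n_chrom = 2L * n_obs,
       alt_freq = ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_))
}

#' Reference-oriented allele frequencies for a gene region
#'
#' For each SNP of a gene, the tracked allele is the minor allele in the
#' reference population (ties broken toward the VCF alt allele); its
#' frequency is then reported in every population, so that frequency vectors
#' are directly comparable across populations.
#'
#' @param vt A `variant_table`.
#' @param panel A `population_panel`.
#' @param snp_idx SNP column indices of the gene.
#' @param reference_population Population whose minor allele defines the
#'   orientation.
#' @return A tibble with one row per (population, SNP): `population`,
#'   `snp_id`, `snp_idx`, `freq` (tracked-allele frequency), `n_chrom`
#'   (non-missing chromosomes), and a logical `tracked_is_alt`.
#' @export
orient_and_frequencies <- function(vt, panel, snp_idx,
                                   reference_population) {
  pops <- panel_populations(panel)
  if (!reference_population %in% pops) {
    stop("reference population not in panel: ", reference_population)
  }
  ref <- allele_counts(vt, panel_samples(panel, reference_population),
                       snp_idx)
  if (any(ref$n_chrom == 0)) {
    k <- which(ref$n_chrom == 0)[1]
    stop("SNP ", vt$snp$snp_id[snp_idx[k]],
         " has no called genotypes in population ", reference_population)
  }
  tracked_is_alt <- ref$alt_freq <= 0.5   # tie (0.5) -> alt
  purrr::map_dfr(pops, function(p) {
    ac <- allele_counts(vt, panel_samples(panel, p), snp_idx)
    if (any(ac$n_chrom == 0)) {
      k <- which(ac$n_chrom == 0)[1]
      stop("SNP ", vt$snp$snp_id[snp_idx[k]],
           " has no called genotypes in population ", p)
    }
    tibble::tibble(
      population = p,
      snp_id = vt$snp$snp_id[snp_idx],
      snp_idx = snp_idx,
      freq = ifelse(tracked_is_alt, ac$alt_freq, 1 - ac$alt_freq),
      n_chrom = ac$n_chrom,
      tracked_is_alt = tracked_is_alt
    )
  })
}

#' Mean absolute allele-frequency difference for a gene region
#'
#' The allele-frequency difference between two populations is the mean of
#' per-SNP absolute differences of the reference-oriented frequencies:
#' d = (1/m) * sum_k |p_ik - p_jk|.
#'
#' @param freq_i,freq_j Numeric vectors of tracked-allele frequencies for the
#'   same gene, same SNP order.
#' @return A value in \[0, 1\], symmetric in its arguments.
#' @export
maf_difference <- function(freq_i, freq_j) {
  if (length(freq_i) != length(freq_j)) {
    stop("frequency vectors differ in length")
  }
  mean(abs(freq_i - freq_j))
}

#' Weir-Cockerham variance components for one SNP, two populations
#'
#' Computes the a (among-population), b (among-individual) and c
#' (within-individual) variance components of the Weir-Cockerham theta
#' estimator from per-population sample sizes, alt-allele frequencies and
#' observed heterozygote proportions.
#'
#' @param n Numeric length-2: diploid sample sizes (non-missing individuals).
#' @param p Numeric length-2: alt-allele sample frequencies.
#' @param h Numeric length-2: observed heterozygote proportions.
#' @return A list with components `a`, `b`, `c`; all `NA` when the SNP is
#'   monomorphic across both populations (theta undefined) or a population
#'   has fewer than 2 individuals.
#' @export
wc_components <- function(n, p, h) {
  r <- 2
  if (any(n < 2)) return(list(a = NA_real_, b = NA_real_, c = NA_real_))
  if (all(p == p[1]) && (p[1] == 0 || p[1] == 1)) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_))
  }
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Per-SNP Weir-Cockerham theta between two populations
#'
#' @param vt A `variant_table`.
#' @param samples_i,samples_j Sample ids of the two populations.
#' @param snp_idx SNP column indices.
#' @return A tibble with one row per SNP: components `a`, `b`, `c` and
#'   `theta` = a / (a + b + c) (may be slightly negative; `NA` where
#'   undefined).
#' @export
fst_weir_cockerham_snp <- function(vt, samples_i, samples_j, snp_idx) {
  comp_one <- function(samples) {
    g <- vt$geno[rownames(vt$geno) %in% samples, snp_idx, drop = FALSE]
    n_obs <- colSums(!is.na(g))
    list(n = n_obs,
         p = ifelse(n_obs > 0, colSums(g, na.rm = TRUE) / (2 * n_obs),
                    NA_real_),
         h = ifelse(n_obs > 0, colSums(g == 1L, na.rm = TRUE) / n_obs,
                    NA_real_))
  }
  ci <- comp_one(samples_i)
  cj <- comp_one(samples_j)
  comps <- purrr::map(seq_along(snp_idx), function(k) {
    if (is.na(ci$p[k]) || is.na(cj$p[k])) {
      return(list(a = NA_real_, b = NA_real_, c = NA_real_))
    }
    wc_components(c(ci$n[k], cj$n[k]), c(ci$p[k], cj$p[k]),
                  c(ci$h[k], cj$h[k]))
  })
  a <- purrr::map_dbl(comps, "a")
  b <- purrr::map_dbl(comps, "b")
  cc <- purrr::map_dbl(comps, "c")
  denom <- a + b + cc
  tibble::tibble(snp_idx = snp_idx, a = a, b = b, c = cc,
                 theta = ifelse(!is.na(denom) & denom != 0, a / denom,
                                NA_real_))
}

#' Multi-locus theta for a gene region
#'
#' Combines per-SNP variance components with the ratio-of-sums estimator
#' theta = sum(a) / sum(a + b + c), which has lower bias than averaging
#' per-SNP ratios. `method = "average"` averages per-SNP ratios instead.
#'
#' @param components A tibble from [fst_weir_cockerham_snp()].
#' @param method `"ratio_of_sums"` (default) or `"average"`.
#' @return A single theta value, or `NA` if no SNP has defined components.
#' @export
gene_fst <- function(components, method = c("ratio_of_sums", "average")) {
  method <- match.arg(method)
  ok <- !is.na(components$a)
  if (!any(ok)) return(NA_real_)
  if (method == "ratio_of_sums") {
    denom <- sum(components$a[ok] + components$b[ok] + components$c[ok])
    if (denom == 0) return(NA_real_)
    sum(components$a[ok]) / denom
  } else {
    mean(components$theta[ok & !is.na(components$theta)])
  }
}
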