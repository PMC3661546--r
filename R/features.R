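#' The eleven per-gene population genetic features
#'
#' Feature names, in canonical order, grouped by aspect: allele frequency
#' (`maf`, `fst`), LD pattern (`r2`, `dprime`, `block_number`, `block_size`,
#' `snp_density`, `hap_diversity`) and tagSNP transferability
#' (`tag_percent`, `captured_percent`, `avg_max_r2`).
#'
#' @return Character vector of length 11.
#' @export
all_features <- function() {
  c("maf", "fst", "r2", "dprime", "block_number", "block_size",
    "snp_density", "hap_diversity", "tag_percent", "captured_percent",
    "avg_max_r2")
}

#' Per-population feature profiles for every gene
#'
#' For each (gene, population) this computes the building blocks from which
#' pairwise differences are formed: the reference-oriented allele-frequency
#' vector, the full pairwise r2/D' map, the four-gamete-test block summary
#' (block number, mean block size in bp, SNP density per kb, mean haplotype
#' diversity over blocks) and the greedy tagSNP set with its tag percent.
#'
#' @param vt A post-QC `variant_table`.
#' @param panel A `population_panel`.
#' @param catalogue A `gene_catalogue` from [assign_snps_to_genes()].
#' @param reference_population Population whose minor allele orients the
#'   frequency vectors (defaults to the first panel population).
#' @param r2_threshold Tagger coverage threshold (default 0.8).
#' @param fgt_threshold Four-gamete existence threshold (default 0.01).
#' @param max_pair_distance Cap on SNP pair distance for LD (default Inf).
#' @param pl_threshold Partition-ligation block-size threshold (default 8).
#' @return A tibble with one row per (gene_id, population): list-columns
#'   `freq` (named frequency vector), `ld` (pairwise LD tibble), `tag_idx`;
#'   scalar columns `block_number`, `block_size`, `snp_density`,
#'   `hap_diversity`, `tag_percent`, `n_snps`.
#' @export
compute_gene_features <- function(vt, panel, catalogue,
                                  reference_population = NULL,
                                  r2_threshold = 0.8,
                                  fgt_threshold = 0.01,
                                  max_pair_distance = Inf,
                                  pl_threshold = 8L) {
  pops <- panel_populations(panel)
  if (is.null(reference_population)) reference_population <- pops[1]
  purrr::map_dfr(seq_len(nrow(catalogue)), function(gi) {
    snp_idx <- catalogue$snp_idx[[gi]]
    gene_id <- catalogue$gene_id[gi]
    freqs <- orient_and_frequencies(vt, panel, snp_idx,
                                    reference_population)
    purrr::map_dfr(pops, function(p) {
      samples <- panel_samples(panel, p)
      ld <- pairwise_ld(vt, samples, snp_idx,
                        fgt_threshold = fgt_threshold,
                        max_pair_distance = max_pair_distance)
      blocks <- four_gamete_blocks(vt, samples, snp_idx,
                                   fgt_threshold = fgt_threshold, ld = ld)
      bf <- block_features(blocks)
      hd <- if (length(blocks) == 0) NA_real_ else {
        g <- vt$geno[rownames(vt$geno) %in% samples, , drop = FALSE]
        mean(vapply(blocks, function(b) {
          fit <- em_block_haplotypes(g[, b$snp_idx, drop = FALSE],
                                     pl_threshold = pl_threshold)
          haplotype_diversity(fit$freqs, fit$n_chromosomes)
        }, numeric(1)))
      }
      tags <- select_tags_greedy(snp_idx, ld, r2_threshold = r2_threshold)
      tp <- tag_percent(tags, length(snp_idx))
      fv <- freqs[freqs$population == p, ]
      tibble::tibble(
        gene_id = gene_id,
        population = p,
        n_snps = length(snp_idx),
        snp_idx = list(snp_idx),
        freq = list(stats::setNames(fv$freq, fv$snp_id)),
        ld = list(ld),
        block_number = bf$block_number,
        block_size = bf$mean_block_size,
        snp_density = bf$snp_density,
        hap_diversity = hd,
        tag_idx = list(tags$tag_idx),
        tag_percent = tp
      )
    })
  })
}

#' Pairwise-population difference records for every gene
#'
#' Turns per-population feature profiles into one difference value per
#' (gene, feature, unordered population pair), the atomic record of the
#' difference database:
#' \itemize{
#'   \item `maf`: mean absolute per-SNP difference of reference-oriented
#'     frequencies.
#'   \item `fst`: the gene-level Weir-Cockerham theta for that pair
#'     (ratio-of-sums over SNPs; already pairwise, so the record is theta
#'     itself). SNPs monomorphic across both populations are excluded.
#'   \item `r2`, `dprime`: mean absolute difference over SNP pairs with the
#'     statistic defined in both populations.
#'   \item `block_number`, `block_size`, `snp_density`, `hap_diversity`:
#'     absolute difference of the per-population scalars.
#'   \item `tag_percent`: absolute difference of tag fractions (percent
#'     difference divided by 100, keeping the value in \[0, 1\]).
#'   \item `captured_percent`, `avg_max_r2`: directed transferability is
#'     computed both ways and the two deviations from perfect transfer are
#'     averaged (see [directed_pair_difference()]).
#' }
#'
#' @param features Output of [compute_gene_features()].
#' @param vt The same post-QC `variant_table`.
#' @param panel The `population_panel`.
#' @param feature_subset Features to emit (default all 11).
#' @param r2_threshold Capture threshold for transferability (default 0.8,
#'   strict).
#' @return A tibble of difference records: `entity_id`, `entity_type`
#'   (`"gene"`), `feature`, `pop_i`, `pop_j` (pop_i before pop_j in panel
#'   order), `value`.
#' @export
gene_differences <- function(features, vt, panel,
                             feature_subset = all_features(),
                             r2_threshold = 0.8) {
  feature_subset <- match.arg(feature_subset, all_features(),
                              several.ok = TRUE)
  pops <- panel_populations(panel)
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  genes <- unique(features$gene_id)
  purrr::map_dfr(genes, function(g) {
    fg <- features[features$gene_id == g, ]
    prof <- stats::setNames(split(fg, seq_len(nrow(fg))), fg$population)
    purrr::map_dfr(pairs, function(pr) {
      pi <- prof[[pr[1]]]
      pj <- prof[[pr[2]]]
      vals <- list()
      if ("maf" %in% feature_subset) {
        vals$maf <- vector_feature_difference(pi$freq[[1]], pj$freq[[1]])
      }
      if ("fst" %in% feature_subset) {
        comp <- fst_weir_cockerham_snp(
          vt, panel_samples(panel, pr[1]), panel_samples(panel, pr[2]),
          snp_idx = gene_snp_idx(pi))
        vals$fst <- gene_fst(comp)
      }
      if ("r2" %in% feature_subset) {
        vals$r2 <- vector_feature_difference(ld_map(pi$ld[[1]], "r2"),
                                             ld_map(pj$ld[[1]], "r2"))
      }
      if ("dprime" %in% feature_subset) {
        vals$dprime <- vector_feature_difference(
          ld_map(pi$ld[[1]], "d_prime"), ld_map(pj$ld[[1]], "d_prime"))
      }
      for (f in intersect(c("block_number", "block_size", "snp_density",
                            "hap_diversity"), feature_subset)) {
        vals[[f]] <- scalar_feature_difference(pi[[f]], pj[[f]])
      }
      if ("tag_percent" %in% feature_subset) {
        vals$tag_percent <-
          scalar_feature_difference(pi$tag_percent, pj$tag_percent) / 100
      }
      if (any(c("captured_percent", "avg_max_r2") %in% feature_subset)) {
        snp_idx <- gene_snp_idx(pi)
        t_ij <- transferability(pj$tag_idx[[1]], snp_idx, pi$ld[[1]],
                                r2_threshold)  # B = j tags, evaluated in i
        t_ji <- transferability(pi$tag_idx[[1]], snp_idx, pj$ld[[1]],
                                r2_threshold)
        if ("captured_percent" %in% feature_subset) {
          vals$captured_percent <- directed_pair_difference(
            t_ij$captured_percent, t_ji$captured_percent, perfect = 100,
            scale = 100)
        }
        if ("avg_max_r2" %in% feature_subset) {
          vals$avg_max_r2 <- directed_pair_difference(
            t_ij$avg_max_r2, t_ji$avg_max_r2, perfect = 1, scale = 1)
        }
      }
      tibble::tibble(entity_id = g, entity_type = "gene",
                     feature = names(vals),
                     pop_i = pr[1], pop_j = pr[2],
                     value = unlist(vals, use.names = FALSE))
    })
  })
}

# snp column indices of the gene a feature-profile row describes
gene_snp_idx <- function(prof_row) prof_row$snp_idx[[1]]

# named per-pair LD vector keyed "a:b"
ld_map <- function(ld, stat) {
  stats::setNames(ld[[stat]], paste(ld$a, ld$b, sep = ":"))
}
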