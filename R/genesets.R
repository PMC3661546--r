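#' Equal-weight gene-set difference score
#'
#' The set score for one (feature, population pair) is the arithmetic mean
#' of the member genes' difference values: D = (1/g) * sum of gene values,
#' with every gene weighted equally. Genes with missing values are dropped
#' from the mean and counted in `n_genes_used`.
#'
#' @param gene_values Named numeric vector of gene difference values.
#' @param gene_ids Member gene ids of the set.
#' @return A list: `value` (the mean, `NA` when no usable gene) and
#'   `n_genes_used`.
#' @export
set_score <- function(gene_values, gene_ids) {
  v <- gene_values[intersect(gene_ids, names(gene_values))]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(list(value = NA_real_, n_genes_used = 0L))
  list(value = mean(v), n_genes_used = length(v))
}

#' Score every gene set for every feature and population pair
#'
#' @param gene_records Gene-level difference records from
#'   [gene_differences()].
#' @param sets A gene-set tibble from [read_gene_sets()] (or any tibble with
#'   `set_id`, `category`, `gene_ids` list-column).
#' @return A difference-record tibble with `entity_type` taken from each
#'   set's `category` and an extra `n_genes_used` column; one row per
#'   (set, feature, population pair).
#' @export
score_gene_sets <- function(gene_records, sets) {
  cells <- dplyr::distinct(gene_records, .data$feature, .data$pop_i,
                           .data$pop_j)
  purrr::map_dfr(seq_len(nrow(sets)), function(si) {
    members <- sets$gene_ids[[si]]
    purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
      rec <- gene_records[gene_records$feature == cells$feature[ci] &
                            gene_records$pop_i == cells$pop_i[ci] &
                            gene_records$pop_j == cells$pop_j[ci], ]
      sc <- set_score(stats::setNames(rec$value, rec$entity_id), members)
      tibble::tibble(entity_id = sets$set_id[si],
                     entity_type = sets$category[si],
                     feature = cells$feature[ci],
                     pop_i = cells$pop_i[ci], pop_j = cells$pop_j[ci],
                     value = sc$value, n_genes_used = sc$n_genes_used)
    })
  })
}

#' Expected difference-record count
#'
#' The difference database holds one record per (entity, feature, unordered
#' population pair), so a complete table has
#' `n_entities * n_features * choose(n_populations, 2)` records.
#'
#' @param n_entities Number of genes or gene sets.
#' @param n_features Number of features (11 for the full feature set).
#' @param n_populations Number of populations (>= 2).
#' @return The record count as a double (counts can exceed .Machine's
#'   integer range for large catalogues).
#' @examples
#' enumerate_difference_records(18158, 11, 11)  # 10,985,590
#' @export
enumerate_difference_records <- function(n_entities, n_features,
                                         n_populations) {
  stopifnot(n_entities >= 1, n_features >= 1)
  if (n_populations < 2) stop("need at least 2 populations")
  n_entities * n_features * choose(n_populations, 2)
}
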