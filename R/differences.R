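#' Mean absolute difference over shared units
#'
#' The vector-feature difference between two populations: per-unit values
#' (per-SNP frequencies, per-SNP-pair r2 or D') are aligned by name and the
#' mean of absolute differences is taken over units defined (non-missing) in
#' both populations.
#'
#' @param values_i,values_j Named numeric vectors on the same unit keys.
#' @return Mean absolute difference, or `NA` when no shared defined unit
#'   exists.
#' @export
vector_feature_difference <- function(values_i, values_j) {
  shared <- intersect(names(values_i), names(values_j))
  vi <- values_i[shared]
  vj <- values_j[shared]
  ok <- !is.na(vi) & !is.na(vj)
  if (!any(ok)) return(NA_real_)
  mean(abs(vi[ok] - vj[ok]))
}

#' Absolute difference of per-gene scalars
#'
#' The single-unit degenerate case of the mean-absolute-difference formula,
#' applied to scalar features (block number, block size, SNP density,
#' haplotype diversity, tag percent).
#'
#' @param x_i,x_j Scalar feature values.
#' @return `|x_i - x_j|`, or `NA` if either value is missing.
#' @export
scalar_feature_difference <- function(x_i, x_j) {
  if (is.na(x_i) || is.na(x_j)) return(NA_real_)
  abs(x_i - x_j)
}

#' Symmetrize directed transferability statistics into one difference
#'
#' Transferability is directed (tags from B evaluated in A and vice versa);
#' the pairwise difference averages the two deviations from perfect
#' transfer and rescales to \[0, 1\]:
#' `((perfect - x_fwd) + (perfect - x_rev)) / 2 / scale`. If one direction
#' is missing the other is used alone.
#'
#' @param x_fwd,x_rev The two directed statistics (captured percent on the
#'   0-100 scale, average maximum r2 on the 0-1 scale).
#' @param perfect Value of a perfect transfer (100 or 1).
#' @param scale Divisor bringing the result to \[0, 1\] (100 or 1).
#' @return Difference value in \[0, 1\]; `NA` when both directions are
#'   missing.
#' @export
directed_pair_difference <- function(x_fwd, x_rev, perfect = 100,
                                     scale = 100) {
  dev <- c(perfect - x_fwd, perfect - x_rev)
  dev <- dev[!is.na(dev)]
  if (length(dev) == 0) return(NA_real_)
  mean(dev) / scale
}

#' Symmetric difference matrix for one entity and feature
#'
#' @param records A difference-record tibble (as from [gene_differences()]
#'   or [score_gene_sets()]) filtered to one `entity_id` and `feature`, or
#'   a larger tibble together with `entity` and `feature` selectors.
#' @param panel A `population_panel` giving the label order.
#' @param entity,feature Optional selectors applied to `records`.
#' @return A `difference_matrix`: a symmetric numeric matrix with zero
#'   diagonal and population labels, with attributes `entity_id` and
#'   `feature`.
#' @export
build_matrix <- function(records, panel, entity = NULL, feature = NULL) {
  if (!is.null(entity)) records <- records[records$entity_id == entity, ]
  if (!is.null(feature)) records <- records[records$feature == feature, ]
  if (nrow(records) == 0) stop("no records for requested entity/feature")
  if (length(unique(records$entity_id)) > 1 ||
      length(unique(records$feature)) > 1) {
    stop("records must cover a single entity and feature")
  }
  key <- paste(records$pop_i, records$pop_j)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- !all(tapply(records$value, key, function(v)
      length(unique(v[!is.na(v)])) <= 1))
    if (conflict) stop("conflicting duplicate records")
    records <- records[!dup, ]
  }
  pops <- panel_populations(panel)
  mat <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  diag(mat) <- 0
  for (r in seq_len(nrow(records))) {
    mat[records$pop_i[r], records$pop_j[r]] <- records$value[r]
    mat[records$pop_j[r], records$pop_i[r]] <- records$value[r]
  }
  structure(mat, entity_id = records$entity_id[1],
            feature = records$feature[1], class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, ...) {
  cat("<difference_matrix> entity: ", attr(x, "entity_id"),
      ", feature: ", attr(x, "feature"), "\n", sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, 4))
  invisible(x)
}

#' Reference-distribution summary of a difference matrix
#'
#' Summarizes all pairwise differences of one entity/feature with five-number
#' boxplot statistics (quartiles by linear interpolation) and, optionally,
#' the percentile rank of a queried population pair: the fraction of all
#' values strictly below the query, times 100.
#'
#' @param mat A `difference_matrix` from [build_matrix()].
#' @param query_pair Optional character length-2: the population pair whose
#'   value should be ranked against the reference distribution.
#' @return A `reference_summary` list: `entity_id`, `feature`, `values`
#'   (the C(n,2) upper-triangle values, missing excluded), `boxplot`
#'   (named vector min/q1/median/q3/max), and when queried `query_value`
#'   and `percentile_rank`.
#' @export
summarize_differences <- function(mat, query_pair = NULL) {
  vals <- unclass(mat)[upper.tri(mat)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no non-missing pairwise values")
  q <- stats::quantile(vals, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  out <- list(entity_id = attr(mat, "entity_id"),
              feature = attr(mat, "feature"),
              values = vals,
              boxplot = stats::setNames(q, c("min", "q1", "median", "q3",
                                             "max")))
  if (!is.null(query_pair)) {
    qv <- unclass(mat)[query_pair[1], query_pair[2]]
    out$query_value <- qv
    out$percentile_rank <- 100 * mean(vals < qv)
  }
  structure(out, class = "reference_summary")
}

#' @export
print.reference_summary <- function(x, ...) {
  cat("<reference_summary> entity: ", x$entity_id, ", feature: ",
      x$feature, " (", length(x$values), " pairs)\n", sep = "")
  print(round(x$boxplot, 4))
  if (!is.null(x$percentile_rank)) {
    cat("query value ", signif(x$query_value, 4), " -> percentile rank ",
        round(x$percentile_rank, 1), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a reference summary into a one-row tibble
#'
#' @param x A `reference_summary`.
#' @param ... Unused.
#' @return A tibble with the entity, feature, five-number summary, number
#'   of pairs and (if queried) the percentile rank.
#' @method tidy reference_summary
#' @export
tidy.reference_summary <- function(x, ...) {
  tibble::tibble(entity_id = x$entity_id, feature = x$feature,
                 n_pairs = length(x$values),
                 min = x$boxplot[["min"]], q1 = x$boxplot[["q1"]],
                 median = x$boxplot[["median"]], q3 = x$boxplot[["q3"]],
                 max = x$boxplot[["max"]],
                 percentile_rank = x$percentile_rank %||% NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Heatmap of a pairwise-population difference matrix
#'
#' @param object A `difference_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot difference_matrix
#' @export
autoplot.difference_matrix <- function(object, ...) {
  pops <- rownames(object)
  df <- tidyr::expand_grid(pop_i = pops, pop_j = pops)
  df$value <- mapply(function(i, j) unclass(object)[i, j],
                     df$pop_i, df$pop_j)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$pop_j, levels = pops),
    y = factor(.data$pop_i, levels = rev(pops)),
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(object, "feature"),
                  title = paste0(attr(object, "entity_id"), ": pairwise ",
                                 attr(object, "feature"), " differences")) +
    ggplot2::theme_minimal()
}

#' Boxplot of an entity's reference distribution
#'
#' @param object A `reference_summary`.
#' @param ... Unused.
#' @return A ggplot object; the queried pair, if any, is drawn as a point.
#' @method autoplot reference_summary
#' @export
autoplot.reference_summary <- function(object, ...) {
  df <- tibble::tibble(value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.3, fill = "grey85") +
    ggplot2::labs(x = NULL, y = object$feature,
                  title = paste0(object$entity_id,
                                 ": reference distribution")) +
    ggplot2::theme_minimal()
  if (!is.null(object$query_value)) {
    p <- p + ggplot2::annotate("point", x = 1, y = object$query_value,
                               colour = "red", size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
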