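#' Construct a variant table
#'
#' A `variant_table` bundles SNP metadata with a samples-by-SNPs matrix of
#' alt-allele dosages. It is the in-memory genotype container used by every
#' downstream step: QC, allele-frequency features, LD features and tagging.
#'
#' @param snp A data frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `ref` and `alt` (single-base alleles), one row per SNP.
#' @param geno Integer matrix of alt-allele dosages in \{0, 1, 2, NA\}, one row
#'   per sample and one column per SNP (columns in `snp` row order).
#' @param sample_ids Character vector of sample identifiers, one per row of
#'   `geno`.
#'
#' @return An object of class `variant_table`: a list with elements `snp`
#'   (a tibble), `geno` (the dosage matrix, with `sample_ids` as rownames and
#'   `snp_id` as colnames).
#'
#' @details SNP columns are sorted by (chrom, pos) on construction. Duplicate
#'   (chrom, pos) pairs are an error: the pipeline assumes one bi-allelic
#'   record per site. Dosage is the count of alt alleles; half-calls and
#'   missing genotypes are `NA`.
#'
#' @examples
#' snp <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100, 200),
#'                   ref = "A", alt = "G")
#' geno <- matrix(c(0L, 1L, 2L, 0L), nrow = 2)
#' vt <- variant_table(snp, geno, c("s1", "s2"))
#' n_snps(vt)
#' @export
variant_table <- function(snp, geno, sample_ids) {
  snp <- tibble::as_tibble(snp)
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(snp))
  if (length(missing_cols) > 0) {
    stop("snp table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(snp) != ncol(geno)) {
    stop("geno must have one column per SNP (", nrow(snp), " SNPs, ",
         ncol(geno), " columns)")
  }
  if (length(sample_ids) != nrow(geno)) {
    stop("sample_ids length must equal nrow(geno)")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  key <- paste(snp$chrom, snp$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos) records: ", key[duplicated(key)][1])
  }
  ord <- order(snp$chrom, snp$pos)
  snp <- snp[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  dimnames(geno) <- list(as.character(sample_ids), snp$snp_id)
  structure(list(snp = snp, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$geno), " samples x ", ncol(x$geno),
      " SNPs\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat("  chrom: ", paste(unique(x$snp$chrom), collapse = ", "),
      "; missing dosage fraction: ", signif(miss, 3), "\n", sep = "")
  invisible(x)
}

#' Number of SNPs / samples in a variant table
#' @param vt A `variant_table`.
#' @return Integer count.
#' @export
n_snps <- function(vt) ncol(vt$geno)

#' @rdname n_snps
#' @export
n_samples <- function(vt) nrow(vt$geno)

#' Subset a variant table by SNP column index and/or sample id
#'
#' @param vt A `variant_table`.
#' @param snp_idx Integer vector of SNP column indices (in current order).
#' @param samples Optional character vector of sample ids to keep.
#' @return A `variant_table` restricted to the requested SNPs/samples.
#' @export
vt_subset <- function(vt, snp_idx = seq_len(n_snps(vt)), samples = NULL) {
  geno <- vt$geno[, snp_idx, drop = FALSE]
  snp <- vt$snp[snp_idx, , drop = FALSE]
  ids <- rownames(vt$geno)
  if (!is.null(samples)) {
    keep <- ids %in% samples
    geno <- geno[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  variant_table(snp, geno, ids)
}

#' Population panel constructor
#'
#' @param sample_id Character vector of sample ids.
#' @param population Character vector of population labels, parallel to
#'   `sample_id`.
#' @param populations Optional explicit population ordering; defaults to
#'   first-appearance order.
#' @return A `population_panel`: a tibble (`sample_id`, `population`) with a
#'   `populations` attribute giving the stable label order.
#' @details Every population must have at least two samples and at least two
#'   populations must be present; pairwise statistics are undefined otherwise.
#' @export
population_panel <- function(sample_id, population, populations = NULL) {
  if (anyDuplicated(sample_id)) {
    stop("sample listed twice in panel: ",
         sample_id[duplicated(sample_id)][1])
  }
  if (is.null(populations)) populations <- unique(population)
  if (!all(population %in% populations)) stop("population not in ordering")
  tab <- table(factor(population, levels = populations))
  if (length(populations) < 2) stop("need at least 2 populations")
  if (any(tab < 2)) {
    stop("population with fewer than 2 samples: ",
         names(tab)[tab < 2][1])
  }
  out <- tibble::tibble(sample_id = as.character(sample_id),
                        population = as.character(population))
  attr(out, "populations") <- populations
  class(out) <- c("population_panel", class(out))
  out
}

#' Population labels of a panel, in stable order
#' @param panel A `population_panel`.
#' @return Character vector of population labels.
#' @export
panel_populations <- function(panel) attr(panel, "populations")

#' Sample ids belonging to one population
#' @param panel A `population_panel`.
#' @param pop A population label.
#' @return Character vector of sample ids.
#' @export
panel_samples <- function(panel, pop) {
  panel$sample_id[panel$population == pop]
}
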