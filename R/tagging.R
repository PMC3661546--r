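#' Greedy pairwise tagSNP selection
#'
#' Re-implements pairwise tagger selection: repeatedly pick the SNP that
#' covers the most uncovered SNPs, where SNP u covers SNP v if their
#' pairwise r2 is at least `r2_threshold` (a SNP always covers itself).
#' Ties are broken toward the lower column index. Terminates when every SNP
#' is covered, so the coverage property holds by construction.
#'
#' @param snp_idx SNP column indices of the gene (increasing).
#' @param ld A [pairwise_ld()] tibble for these SNPs in one population;
#'   pairs with undefined r2 are treated as r2 = 0.
#' @param r2_threshold Coverage threshold (default 0.8, inclusive).
#' @return A list: `tag_idx` (selected SNP column indices), `r2_threshold`,
#'   `covered_by` (named integer vector mapping each SNP index to the tag
#'   that covers it).
#' @export
select_tags_greedy <- function(snp_idx, ld, r2_threshold = 0.8) {
  m <- length(snp_idx)
  r2m <- r2_matrix(snp_idx, ld)
  covers <- (r2m >= r2_threshold)
  diag(covers) <- TRUE
  uncovered <- rep(TRUE, m)
  tags <- integer(0)
  covered_by <- rep(NA_integer_, m)
  while (any(uncovered)) {
    gain <- colSums(covers & uncovered)   # column u covers rows
    pick <- which.max(gain)               # which.max: first max = lowest index
    newly <- which(uncovered & covers[, pick])
    covered_by[newly] <- snp_idx[pick]
    uncovered[newly] <- FALSE
    tags <- c(tags, snp_idx[pick])
  }
  list(tag_idx = sort(tags), r2_threshold = r2_threshold,
       covered_by = stats::setNames(covered_by, snp_idx))
}

# symmetric r2 matrix over snp_idx, NA pairs -> 0
r2_matrix <- function(snp_idx, ld) {
  m <- length(snp_idx)
  r2m <- matrix(0, m, m)
  diag(r2m) <- 1
  if (nrow(ld) > 0) {
    ia <- match(ld$a, snp_idx)
    ib <- match(ld$b, snp_idx)
    v <- ifelse(is.na(ld$r2), 0, ld$r2)
    keep <- !is.na(ia) & !is.na(ib)
    r2m[cbind(ia[keep], ib[keep])] <- v[keep]
    r2m[cbind(ib[keep], ia[keep])] <- v[keep]
  }
  r2m
}

#' Tag percent of a gene region
#'
#' @param tagset Output of [select_tags_greedy()].
#' @param n_snps Total SNPs in the gene region.
#' @return 100 * (number of tags) / n_snps.
#' @export
tag_percent <- function(tagset, n_snps) {
  if (n_snps == 0) stop("gene has no SNPs")
  100 * length(tagset$tag_idx) / n_snps
}

#' TagSNP transferability from one population to another
#'
#' Tags selected in population B are evaluated in population A: an A SNP is
#' captured if its r2 (computed in population A) with at least one B tag is
#' strictly greater than `r2_threshold`. `captured_percent` is the captured
#' fraction of A's SNPs times 100; `avg_max_r2` is the mean, over captured
#' SNPs, of the maximum r2 with any tag.
#'
#' @param tag_idx Tag SNP column indices selected in the source population.
#' @param snp_idx SNP column indices of the gene in the target population.
#' @param ld_target [pairwise_ld()] tibble computed in the target
#'   population.
#' @param r2_threshold Capture threshold (default 0.8, strict inequality).
#' @return A list: `captured_percent` in \[0, 100\] and `avg_max_r2` in
#'   \[0, 1\] (`NA` when no SNP is captured). A tag present among the target
#'   SNPs captures itself (self r2 = 1).
#' @export
transferability <- function(tag_idx, snp_idx, ld_target,
                            r2_threshold = 0.8) {
  tags_here <- intersect(tag_idx, snp_idx)
  if (length(tags_here) == 0) {
    return(list(captured_percent = 0, avg_max_r2 = NA_real_))
  }
  r2m <- r2_matrix(snp_idx, ld_target)
  tag_cols <- match(tags_here, snp_idx)
  max_r2 <- apply(r2m[, tag_cols, drop = FALSE], 1, max)
  captured <- max_r2 > r2_threshold
  list(
    captured_percent = 100 * mean(captured),
    avg_max_r2 = if (any(captured)) mean(max_r2[captured]) else NA_real_
  )
}
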