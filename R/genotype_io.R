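#' Read bi-allelic SNP genotypes from a VCF file
#'
#' Parses a VCF (only the GT field is used) into a [variant_table()].
#' Multi-allelic records and records whose REF or ALT is not a single base
#' are skipped; the skip count is reported as a message and stored in the
#' `skipped` attribute of the result.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param region_filter Optional data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open); only records whose `pos - 1` falls in a
#'   region are kept.
#' @return A `variant_table`. Dosage is the alt-allele count of the GT call;
#'   half-calls (e.g. `./1`) and missing calls become `NA`.
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  snv <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip,
            " non-SNP or multi-allelic record(s)")
  }
  if (!any(snv)) stop("zero usable bi-allelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  if (!is.null(region_filter)) {
    pos0 <- as.integer(fix$POS) - 1L
    keep <- vapply(seq_len(nrow(fix)), function(i) {
      any(region_filter$chrom == fix$CHROM[i] &
            region_filter$start <= pos0[i] & pos0[i] < region_filter$end)
    }, logical(1))
    gt <- gt[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
    if (nrow(fix) == 0) stop("no records left after region filter")
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  dos <- gt_to_dosage(gt)
  snp <- tibble::tibble(snp_id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT)
  vt <- variant_table(snp, t(dos), colnames(gt))
  attr(vt, "skipped") <- n_skip
  vt
}

# GT strings -> alt dosage; anything containing "." -> NA
gt_to_dosage <- function(gt) {
  clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  dos
}

#' Read genotypes from the simple TSV dialect
#'
#' Format: a header row `snp_id chrom pos ref alt <sample ids...>`, then one
#' row per SNP with dosages 0/1/2 and `.` for missing.
#'
#' @param path Path to a TSV file.
#' @return A `variant_table`.
#' @export
read_genotype_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  meta <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% names(df)[1:5])) {
    stop("genotype TSV must start with columns: ", paste(meta, collapse = ", "))
  }
  samples <- setdiff(names(df), meta)
  if (length(samples) == 0) stop("no sample columns in ", path)
  dos <- as.matrix(df[, samples])
  dos[dos == "."] <- NA
  dos <- matrix(as.integer(dos), nrow = nrow(df),
                dimnames = list(NULL, samples))
  snp <- tibble::tibble(snp_id = df$snp_id, chrom = df$chrom,
                        pos = as.integer(df$pos), ref = df$ref, alt = df$alt)
  variant_table(snp, t(dos), samples)
}

#' Read a sample-to-population panel
#'
#' @param path Two-column TSV without header: `sample_id<TAB>population`.
#' @param vt Optional `variant_table`; panel samples absent from it are
#'   dropped with a warning, and an error is raised if no overlap remains.
#' @return A [population_panel()] with population order = first appearance.
#' @export
read_population_panel <- function(path, vt = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample_id", "population"),
                          colClasses = "character")
  if (!is.null(vt)) {
    present <- df$sample_id %in% rownames(vt$geno)
    if (any(!present)) {
      warning(sum(!present), " panel sample(s) absent from genotypes; dropped")
      df <- df[present, , drop = FALSE]
    }
    if (nrow(df) == 0) stop("no panel samples present in genotype data")
  }
  population_panel(df$sample_id, df$population)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Non-negative integer genotype counts.
#' @return Exact p-value in (0, 1].
#' @details The conditional distribution of the heterozygote count given the
#'   allele counts is computed in closed form on the log scale; the test is
#'   exact, not a chi-square approximation, so it remains valid at thresholds
#'   as small as 1e-3 with modest sample sizes. Monomorphic samples return 1.
#' @examples
#' hwe_exact_test(100, 0, 0)   # monomorphic: 1
#' hwe_exact_test(0, 100, 0)   # extreme heterozygote excess: tiny
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  n_a <- n_Aa + 2 * n_aa           # minor-ish allele count (either is fine)
  n_A <- n_Aa + 2 * n_AA
  rare <- min(n_A, n_a)
  if (rare == 0) return(1.0)       # monomorphic
  # heterozygote count h has the same parity as `rare` and 0 <= h <= rare,
  # with (rare - h)/2 homozygotes of the rare allele
  h <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((n_A - h) / 2) - lfactorial(h) -
    lfactorial((n_a - h) / 2) + h * log(2) +
    lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[h == n_Aa]
  sum(p[p <= obs + 1e-12])
}

#' Default QC thresholds
#'
#' @param hwe_p_min Minimum HWE exact-test p-value (default 0.001).
#' @param call_rate_min Minimum fraction of non-missing genotypes
#'   (default 0.75).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(hwe_p_min = 0.001, call_rate_min = 0.75,
                          maf_min = 0.01) {
  if (!(hwe_p_min > 0 && hwe_p_min < 1)) stop("hwe_p_min must be in (0,1)")
  if (!(call_rate_min > 0 && call_rate_min <= 1)) {
    stop("call_rate_min must be in (0,1]")
  }
  if (!(maf_min >= 0 && maf_min < 0.5)) stop("maf_min must be in [0,0.5)")
  list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
       maf_min = maf_min)
}

#' Apply SNP quality control
#'
#' A SNP is retained only if, in every population (default) or in the pooled
#' sample (`scope = "pooled"`), its HWE exact p-value, call rate and minor
#' allele frequency all meet the thresholds.
#'
#' @param vt A `variant_table`.
#' @param panel A `population_panel` covering the samples of `vt`.
#' @param thresholds A list from [qc_thresholds()].
#' @param scope `"per_population"` (a SNP must pass in every population) or
#'   `"pooled"` (tests on the pooled sample).
#' @return A list with elements `vt` (the filtered `variant_table`) and
#'   `report`, a tibble with one row per SNP and logical columns
#'   `fail_hwe`, `fail_call_rate`, `fail_maf`, `retained`.
#' @export
apply_qc <- function(vt, panel, thresholds = qc_thresholds(),
                     scope = c("per_population", "pooled")) {
  scope <- match.arg(scope)
  thresholds <- do.call(qc_thresholds, thresholds)  # re-validate ranges
  groups <- if (scope == "per_population") {
    lapply(panel_populations(panel), function(p) panel_samples(panel, p))
  } else {
    list(panel$sample_id)
  }
  m <- n_snps(vt)
  fail_hwe <- fail_cr <- fail_maf <- rep(FALSE, m)
  for (samples in groups) {
    g <- vt$geno[rownames(vt$geno) %in% samples, , drop = FALSE]
    n_tot <- nrow(g)
    n_obs <- colSums(!is.na(g))
    cr <- n_obs / n_tot
    alt <- colSums(g, na.rm = TRUE)
    af <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
    maf <- pmin(af, 1 - af)
    n_het <- colSums(g == 1L, na.rm = TRUE)
    n_hom_alt <- colSums(g == 2L, na.rm = TRUE)
    n_hom_ref <- n_obs - n_het - n_hom_alt
    hwe_p <- vapply(seq_len(m), function(k) {
      if (n_obs[k] == 0) return(NA_real_)
      hwe_exact_test(n_hom_ref[k], n_het[k], n_hom_alt[k])
    }, numeric(1))
    fail_cr <- fail_cr | (cr < thresholds$call_rate_min)
    fail_maf <- fail_maf | is.na(maf) | (maf < thresholds$maf_min)
    fail_hwe <- fail_hwe | is.na(hwe_p) | (hwe_p < thresholds$hwe_p_min)
  }
  retained <- !(fail_hwe | fail_cr | fail_maf)
  report <- tibble::tibble(snp_id = vt$snp$snp_id,
                           fail_hwe = fail_hwe,
                           fail_call_rate = fail_cr,
                           fail_maf = fail_maf,
                           retained = retained)
  list(vt = vt_subset(vt, which(retained)), report = report)
}

#' Read gene regions from a BED file
#'
#' @param path BED3+name file: `chrom start end gene_id`, 0-based half-open.
#' @return A tibble (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gene_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path,
         " (need chrom, start, end, name)")
  }
  out <- tibble::tibble(
    gene_id = vapply(parts, `[`, "", 4),
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end = as.integer(vapply(parts, `[`, "", 3))
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    stop("non-numeric BED coordinates in ", path)
  }
  if (any(out$start >= out$end)) {
    stop("BED region with start >= end: ",
         out$gene_id[out$start >= out$end][1])
  }
  out
}

#' Assign SNPs to gene regions
#'
#' A SNP at 1-based position `pos` belongs to gene `[start, end)` (0-based
#' half-open) iff `start <= pos - 1 < end`. Genes retaining fewer than
#' `min_snps` SNPs are dropped with a message.
#'
#' @param vt A `variant_table` (typically post-QC).
#' @param regions A tibble from [read_gene_regions()].
#' @param min_snps Minimum SNPs for a gene to be retained (default 2).
#' @return A `gene_catalogue` tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `snp_idx` (list-column of strictly increasing SNP column indices).
#' @export
assign_snps_to_genes <- function(vt, regions, min_snps = 2) {
  pos0 <- vt$snp$pos - 1L
  snp_idx <- purrr::map(seq_len(nrow(regions)), function(i) {
    which(vt$snp$chrom == regions$chrom[i] &
            pos0 >= regions$start[i] & pos0 < regions$end[i])
  })
  out <- dplyr::mutate(tibble::as_tibble(regions), snp_idx = snp_idx)
  n_assigned <- lengths(out$snp_idx)
  dropped <- sum(n_assigned < min_snps)
  if (dropped > 0) {
    message("assign_snps_to_genes: dropped ", dropped,
            " gene(s) with fewer than ", min_snps, " SNPs")
  }
  out <- out[n_assigned >= min_snps, , drop = FALSE]
  class(out) <- c("gene_catalogue", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' Sets are pruned to genes present in the catalogue; sets retaining fewer
#' than `min_genes` members are dropped.
#'
#' @param path GMT file: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' @param catalogue A `gene_catalogue`; membership filter.
#' @param min_genes Minimum surviving genes per retained set (default 10).
#' @param category Category label for all sets in this file, one of
#'   `"pathway"`, `"BP"`, `"MF"`, `"CC"`, `"custom"`.
#' @return A tibble: `set_id`, `set_name`, `category`, `gene_ids`
#'   (list-column), `n_genes`.
#' @export
read_gene_sets <- function(path, catalogue, min_genes = 10,
                           category = c("pathway", "BP", "MF", "CC",
                                        "custom")) {
  category <- match.arg(category)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0) stop("no gene sets in ", path)
  # recover the description column for set_name
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  lines <- lines[lengths(lines) >= 3]
  names_map <- stats::setNames(vapply(lines, `[`, "", 2),
                               vapply(lines, `[`, "", 1))
  gene_ids <- purrr::map(sets, function(g) {
    unique(g[g %in% catalogue$gene_id])
  })
  out <- tibble::tibble(
    set_id = names(sets),
    set_name = unname(names_map[names(sets)]),
    category = category,
    gene_ids = unname(gene_ids),
    n_genes = lengths(gene_ids)
  )
  out[out$n_genes >= min_genes, , drop = FALSE]
}
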