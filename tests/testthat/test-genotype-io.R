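test_that("VCF round-trips through write and read, skipping non-SNP records", {
  ds <- small_dataset(seed = 11)
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "rt.vcf")
  write_vcf(ds$vt, vcf)
  vt2 <- read_vcf(vcf)
  expect_identical(unname(vt2$geno), unname(ds$vt$geno))
  expect_identical(vt2$snp$pos, ds$vt$snp$pos)
  expect_identical(colnames(vt2$geno), colnames(ds$vt$geno))

  # splice in an indel and a multi-allelic record: both skipped
  lines <- readLines(vcf)
  gts <- paste(rep("0/0", n_samples(ds$vt)), collapse = "\t")
  extra <- c(paste("1", 999991, "indel1", "AT", "A", ".", "PASS", ".",
                   "GT", gts, sep = "\t"),
             paste("1", 999992, "multi1", "A", "G,T", ".", "PASS", ".",
                   "GT", gts, sep = "\t"))
  writeLines(c(lines, extra), vcf)
  expect_message(vt3 <- read_vcf(vcf), "skipped 2")
  expect_identical(attr(vt3, "skipped"), 2L)
  expect_equal(n_snps(vt3), n_snps(ds$vt))
})

test_that("basic GT encodings map to dosages and missing", {
  gt <- matrix(c("0/0", "0/1", "1/1", "./.", "./1", "0|1"), ncol = 1)
  expect_identical(as.vector(popgendiff:::gt_to_dosage(gt)),
                   c(0L, 1L, 2L, NA, NA, 1L))
})

test_that("genotype TSV dialect round-trips including missing values", {
  ds <- small_dataset(seed = 3, missing_rate = 0.2)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "g.tsv")
  write_genotype_tsv(ds$vt, tsv)
  vt2 <- read_genotype_tsv(tsv)
  expect_identical(unname(vt2$geno), unname(ds$vt$geno))
})

test_that("population panel validates duplicates, sizes and VCF overlap", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.tsv")
  writeLines(c("a\tP1", "b\tP1", "c\tP2", "d\tP2"), p)
  panel <- read_population_panel(p)
  expect_identical(panel_populations(panel), c("P1", "P2"))
  expect_identical(panel_samples(panel, "P2"), c("c", "d"))

  writeLines(c("a\tP1", "a\tP1", "c\tP2", "d\tP2"), p)
  expect_error(read_population_panel(p), "twice")

  writeLines(c("a\tP1", "b\tP1", "c\tP2"), p)
  expect_error(read_population_panel(p), "fewer than 2")

  # sample absent from genotypes is dropped with a warning
  vt <- make_vt(matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L), ncol = 2))
  writeLines(c("ind1\tP1", "ind2\tP1", "ind3\tP2", "ind4\tP2",
               "ghost\tP2"), p)
  expect_warning(panel <- read_population_panel(p, vt), "absent")
  expect_equal(nrow(panel), 4)
})

test_that("HWE exact test matches trivial cases and fails extreme excess", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_lt(hwe_exact_test(0, 100, 0), 0.001)
  expect_error(hwe_exact_test(0, 0, 0), "must be >= 1")
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
})

test_that("HWE exact test equals the enumeration oracle for n <= 12", {
  # full sweep to n <= 30 runs in the acceptance suite; this is a spot sweep
  for (n in 1:12) {
    for (n_aa in 0:n) for (n_het in 0:(n - n_aa)) {
      n_AA <- n - n_aa - n_het
      expect_equal(hwe_exact_test(n_AA, n_het, n_aa),
                   hwe_oracle(n_AA, n_het, n_aa), tolerance = 1e-10)
    }
  }
})

test_that("QC retains a SNP only if it passes in every population", {
  set.seed(42)
  # SNP 1 fine everywhere; SNP 2 monomorphic in P2; SNP 3 low call in P1
  g <- cbind(rbinom(20, 2, 0.5),
             c(rbinom(10, 2, 0.5), rep(0L, 10)),
             c(rep(NA_integer_, 4), rbinom(6, 2, 0.5), rbinom(10, 2, 0.5)))
  g[1, 1] <- 1L  # ensure polymorphic in both halves
  g[11, 1] <- 1L
  vt <- make_vt(g)
  panel <- population_panel(rownames(vt$geno),
                            rep(c("P1", "P2"), each = 10))
  res <- apply_qc(vt, panel, qc_thresholds(call_rate_min = 0.75))
  expect_true(res$report$retained[1])
  expect_false(res$report$retained[2])   # MAF 0 in P2
  expect_true(res$report$fail_maf[2])
  expect_false(res$report$retained[3])   # call rate 0.6 in P1
  expect_true(res$report$fail_call_rate[3])
})

test_that("QC is idempotent and monotone in thresholds", {
  ds <- small_dataset(seed = 9, missing_rate = 0.1)
  th <- qc_thresholds()
  once <- apply_qc(ds$vt, ds$panel, th)
  twice <- apply_qc(once$vt, ds$panel, th)
  expect_identical(unname(twice$vt$geno), unname(once$vt$geno))
  expect_true(all(twice$report$retained))

  kept <- vapply(c(0.01, 0.05, 0.1, 0.2), function(maf) {
    sum(apply_qc(ds$vt, ds$panel, qc_thresholds(maf_min = maf))$report$retained)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
  kept_cr <- vapply(c(0.5, 0.8, 0.95), function(cr) {
    sum(apply_qc(ds$vt, ds$panel,
                 qc_thresholds(call_rate_min = cr))$report$retained)
  }, numeric(1))
  expect_true(all(diff(kept_cr) <= 0))
})

test_that("all-passing table is returned unchanged by QC", {
  ds <- small_dataset(seed = 5)
  res <- apply_qc(ds$vt, ds$panel)
  if (all(res$report$retained)) {
    expect_identical(unname(res$vt$geno), unname(ds$vt$geno))
  }
  res2 <- apply_qc(res$vt, ds$panel)
  expect_identical(unname(res2$vt$geno), unname(res$vt$geno))
})

test_that("SNP-to-gene assignment uses the half-open BED convention", {
  vt <- make_vt(matrix(rbinom(40, 2, 0.5), ncol = 4),
                pos = c(100L, 101L, 200L, 250L))
  regions <- tibble::tibble(gene_id = "G1", chrom = "1",
                            start = 100L, end = 200L)
  # pos 100 -> pos0 99 < start: excluded; pos 101, 200 -> pos0 100, 199: in
  cat <- assign_snps_to_genes(vt, regions)
  expect_identical(cat$snp_idx[[1]], c(2L, 3L))
})

test_that("genes with fewer than two SNPs are dropped", {
  vt <- make_vt(matrix(rbinom(30, 2, 0.5), ncol = 5),
                pos = c(150L, 160L, 5000L, 5010L, 9000L))
  regions <- tibble::tibble(gene_id = c("G1", "G2", "G3"), chrom = "1",
                            start = c(100L, 4500L, 8500L),
                            end = c(200L, 5500L, 8999L))
  expect_message(cat <- assign_snps_to_genes(vt, regions), "dropped 1")
  expect_identical(cat$gene_id, c("G1", "G2"))
})

test_that("gene sets are pruned to the catalogue and small sets dropped", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  genes <- sprintf("G%02d", 1:15)
  writeLines(c(
    paste(c("BIG", "big set", genes[1:12]), collapse = "\t"),
    paste(c("SMALL", "nine survivors", genes[1:9], "ABSENT1"),
          collapse = "\t")), gmt)
  catalogue <- tibble::tibble(gene_id = genes, chrom = "1",
                              start = 0L, end = 1L,
                              snp_idx = replicate(15, 1:2, simplify = FALSE))
  sets <- read_gene_sets(gmt, catalogue)
  expect_identical(sets$set_id, "BIG")
  expect_equal(sets$n_genes, 12)
  # the SMALL set had 10 listed genes but only 9 in the catalogue
})
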