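#' Run the full difference pipeline
#'
#' Orchestrates QC, gene-feature computation, pairwise gene differences and
#' gene-set scoring, writing long-format TSV outputs plus a JSON manifest.
#' Given identical inputs and configuration the outputs are byte-identical:
#' every stage is deterministic.
#'
#' @param vcf Path to a VCF file (or `NULL` when `genotype_tsv` is given).
#' @param panel Path to the two-column sample-to-population TSV.
#' @param bed Path to the BED3+name gene-region file.
#' @param gmt Optional path to a GMT gene-set file.
#' @param out_dir Output directory.
#' @param genotype_tsv Optional path to the simple genotype TSV dialect,
#'   used instead of `vcf`.
#' @param thresholds QC thresholds from [qc_thresholds()].
#' @param reference_population Population orienting allele frequencies
#'   (default: first panel population).
#' @param r2_threshold Tagger/capture threshold (default 0.8).
#' @param fgt_threshold Four-gamete existence threshold (default 0.01).
#' @param max_pair_distance LD pair distance cap in bp (default Inf).
#' @param feature_subset Features to emit (default all 11).
#' @param set_category Category label for the GMT sets (default
#'   `"pathway"`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `gene_records`, `set_records`, `qc_report`,
#'   `manifest`, and the output `paths`.
#' @export
run_pipeline <- function(vcf = NULL, panel, bed, gmt = NULL, out_dir,
                         genotype_tsv = NULL,
                         thresholds = qc_thresholds(),
                         reference_population = NULL,
                         r2_threshold = 0.8, fgt_threshold = 0.01,
                         max_pair_distance = Inf,
                         feature_subset = all_features(),
                         set_category = "pathway", quiet = FALSE) {
  say <- function(...) if (!quiet) message("[popgendiff] ", ...)
  t0 <- Sys.time()
  vt <- if (!is.null(genotype_tsv)) read_genotype_tsv(genotype_tsv)
        else read_vcf(vcf)
  pp <- read_population_panel(panel, vt)
  say("loaded ", n_samples(vt), " samples x ", n_snps(vt), " SNPs, ",
      length(panel_populations(pp)), " populations")

  qc <- apply_qc(vt, pp, thresholds)
  say("QC: ", sum(qc$report$retained), "/", n_snps(vt), " SNPs retained")
  vt <- qc$vt

  regions <- read_gene_regions(bed)
  catalogue <- assign_snps_to_genes(vt, regions)
  say("catalogue: ", nrow(catalogue), "/", nrow(regions),
      " genes with >= 2 SNPs")
  if (nrow(catalogue) == 0) stop("pipeline aborted at catalogue: no gene retained")

  feats <- compute_gene_features(vt, pp, catalogue,
                                 reference_population = reference_population,
                                 r2_threshold = r2_threshold,
                                 fgt_threshold = fgt_threshold,
                                 max_pair_distance = max_pair_distance)
  gene_records <- gene_differences(feats, vt, pp,
                                   feature_subset = feature_subset,
                                   r2_threshold = r2_threshold)
  say("gene records: ", nrow(gene_records))

  set_records <- NULL
  if (!is.null(gmt)) {
    sets <- read_gene_sets(gmt, catalogue, category = set_category)
    if (nrow(sets) > 0) {
      set_records <- score_gene_sets(gene_records, sets)
      say("set records: ", nrow(set_records))
    } else {
      say("no gene set passed the >= 10 gene filter")
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gene = file.path(out_dir, "gene_differences.tsv"),
             qc = file.path(out_dir, "qc_report.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  readr::write_tsv(gene_records, paths[["gene"]], progress = FALSE)
  readr::write_tsv(qc$report, paths[["qc"]], progress = FALSE)
  if (!is.null(set_records)) {
    paths[["sets"]] <- file.path(out_dir, "set_differences.tsv")
    readr::write_tsv(set_records, paths[["sets"]], progress = FALSE)
  }
  manifest <- list(
    inputs = list(vcf = vcf, genotype_tsv = genotype_tsv, panel = panel,
                  bed = bed, gmt = gmt),
    config = list(thresholds = thresholds,
                  reference_population = reference_population %||%
                    panel_populations(pp)[1],
                  r2_threshold = r2_threshold,
                  fgt_threshold = fgt_threshold,
                  max_pair_distance = max_pair_distance,
                  feature_subset = feature_subset),
    counts = list(samples = n_samples(vt),
                  snps_post_qc = n_snps(vt),
                  genes_in = nrow(regions),
                  genes_retained = nrow(catalogue),
                  genes_dropped = nrow(regions) - nrow(catalogue),
                  gene_records = nrow(gene_records),
                  set_records = if (is.null(set_records)) 0L
                                else nrow(set_records)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(gene_records = gene_records, set_records = set_records,
                 qc_report = qc$report, manifest = manifest,
                 paths = paths))
}
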