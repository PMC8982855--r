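#' Read a pipeline configuration from YAML
#'
#' The YAML maps input paths (`counts`, `sample_meta`, `feature_meta`,
#' `atlas`, `cluster`, `peaks`, `chrom_sizes`, ...) and module settings
#' (`tau`, `de`, `ectopic`, `enrichment`, `intervals`), plus `seed` and
#' `out_dir`. Referenced files are checked for existence.
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- unlist(cfg$paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("configured input files not found: ",
         paste(missing, collapse = ", "))
  cfg
}

.write_stage <- function(out_dir, name, df) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

.manifest <- function(out_dir, manifest) {
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the ovary transcriptome analysis end to end
#'
#' Composes the full count-level workflow on a 2 genotype x 2 age count
#' matrix: low-count filter, GC and depth full-quantile normalization
#' with offsets, age-consistent differential-expression calls with
#' shrunken LFCs, RPKM (computed without the low-count filter), ectopic
#' calls of wild-type-silent genes, tissue classification of the atlas,
#' over-representation of per-tissue enriched sets among the LFC
#' extremes, and a positional cluster summary.
#'
#' @param counts a [count_matrix] with `genotype` and `age` sample
#'   factors (wild type must be the first genotype level alphabetically
#'   or supplied as `wt`).
#' @param atlas an `expression_atlas` (or RPKM matrix) for tissue
#'   classification.
#' @param cluster optional data.frame (`gene_id`, `start`, `end`) of a
#'   co-located gene cluster to summarize.
#' @param alpha DE FDR threshold (default 0.01).
#' @param pct extreme fraction for over-representation (default 0.01).
#' @param tau a [tau_config].
#' @param ectopic an [ectopic_config].
#' @param min_mean,n_strata normalization settings.
#' @param strict logical, apply the interaction exclusion in the
#'   consistency rule.
#' @param out_dir optional directory for stage TSVs and a JSON manifest.
#' @return list with `de` (consistent-call result), `rpkm`, `ectopic`,
#'   `classification`, `enrichment`, `cluster_summary`, `manifest`.
#' @export
run_ovary_analysis <- function(counts, atlas, cluster = NULL,
                               alpha = 0.01, pct = 0.01,
                               tau = tau_config(),
                               ectopic = ectopic_config(),
                               min_mean = 10, n_strata = 10,
                               strict = FALSE, out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  norm <- normalize_counts(counts, min_mean = min_mean,
                           n_strata = n_strata)
  de <- consistent_de_call(norm$counts, offsets = norm$offsets,
                           alpha = alpha, strict = strict)
  # RPKM from the unfiltered matrix: ectopic genes live below the filter
  rp <- rpkm(counts)
  sm <- counts$sample_meta
  wt_cols <- which(sm$genotype %in% c("wt", "WT", "wildtype",
                                      "wild_type"))
  if (!length(wt_cols)) wt_cols <- which(sm$genotype ==
                                           sort(unique(sm$genotype))[1])
  mut_cols <- setdiff(seq_len(ncol(rp)), wt_cols)
  ect <- call_ectopic(rp[, wt_cols, drop = FALSE],
                      rp[, mut_cols, drop = FALSE], ectopic)
  cls <- classify_genes(atlas, tau)
  # per-tissue enriched gene sets over the expressed universe
  enr_tab <- cls$table[cls$table$status == "Enriched", ]
  tissues <- unique(unlist(strsplit(enr_tab$enriched_tissues, ";")))
  sets <- lapply(stats::setNames(tissues, tissues), function(t)
    enr_tab$gene_id[vapply(strsplit(enr_tab$enriched_tissues, ";"),
                           function(x) t %in% x, TRUE)])
  enrich <- percentile_enrichment(de$main, sets, pct = pct)
  cl_sum <- if (!is.null(cluster))
    cluster_lfc_summary(de$main, cluster, ectopic = ect,
                        alpha = alpha) else NULL
  manifest <- .manifest(out_dir, list(
    analysis = "ovary", alpha = alpha, pct = pct,
    min_mean = min_mean, n_strata = n_strata, strict = strict,
    tau_threshold = tau$tau_threshold,
    n_features_in = nrow(counts$counts),
    n_features_filtered = nrow(norm$counts$counts),
    n_called = length(de$called),
    n_ectopic = sum(ect$is_ectopic)))
  .write_stage(out_dir, "de_results", de$main$results)
  .write_stage(out_dir, "ectopic_calls", ect)
  .write_stage(out_dir, "tissue_classification", cls$table)
  .write_stage(out_dir, "percentile_enrichment", enrich)
  list(de = de, rpkm = rp, ectopic = ect, classification = cls,
       enrichment = enrich, cluster_summary = cl_sum,
       manifest = manifest)
}

#' Run the two-condition (knockdown vs control) transcriptome analysis
#'
#' Same count-level stages as the ovary workflow minus the age factor:
#' filter, normalize, NB DE on `~ condition`, RPKM, ectopic calls of
#' control-silent genes, and optionally the overlap of the resulting
#' ectopic set with a comparison set from another experiment.
#'
#' @param counts a [count_matrix] with a two-level `condition` sample
#'   factor (control level first).
#' @param compare_ectopic optional character vector of ectopic gene ids
#'   from another run, for [set_overlap()].
#' @param alpha,min_mean,n_strata,ectopic,out_dir as in
#'   [run_ovary_analysis()].
#' @return list with `de`, `rpkm`, `ectopic`, `overlap`, `manifest`.
#' @export
run_s2_analysis <- function(counts, compare_ectopic = NULL,
                            alpha = 0.01, ectopic = ectopic_config(),
                            min_mean = 10, n_strata = 10,
                            out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  sm <- counts$sample_meta
  if (!"condition" %in% names(sm))
    stop("sample metadata must contain a 'condition' factor")
  cond <- factor(sm$condition)
  if (nlevels(cond) != 2) stop("condition must have exactly 2 levels")
  if (any(table(cond) < 2)) stop("need >= 2 replicates per condition")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  norm <- normalize_counts(counts, min_mean = min_mean,
                           n_strata = n_strata)
  de <- nb_de(norm$counts, ~ condition, offsets = norm$offsets,
              alpha = alpha)
  rp <- rpkm(counts)
  ctrl_cols <- which(cond == levels(cond)[1])
  trt_cols <- which(cond == levels(cond)[2])
  ect <- call_ectopic(rp[, ctrl_cols, drop = FALSE],
                      rp[, trt_cols, drop = FALSE], ectopic)
  ov <- if (!is.null(compare_ectopic))
    set_overlap(ect$gene_id[ect$is_ectopic], compare_ectopic) else NULL
  manifest <- .manifest(out_dir, list(
    analysis = "two_condition", alpha = alpha, min_mean = min_mean,
    n_strata = n_strata,
    n_features_in = nrow(counts$counts),
    n_features_filtered = nrow(norm$counts$counts),
    n_called = sum(de$results$called),
    n_ectopic = sum(ect$is_ectopic)))
  .write_stage(out_dir, "de_results", de$results)
  .write_stage(out_dir, "ectopic_calls", ect)
  list(de = de, rpkm = rp, ectopic = ect, overlap = ov,
       manifest = manifest)
}

#' Run the ChIP peak and repeat analysis end to end
#'
#' Removes IP peaks overlapping mock peaks (whole-peak subtraction),
#' merges the filtered sets across antibodies and replicates into the
#' final peak set, annotates genes with a TSS within the 1-kb window,
#' computes the promoter density profile and per-100-kb-bin coverage,
#' optionally tests randomized overlap enrichment against a reference
#' peak set, and runs the bin-anchored repeat IP-vs-mock enrichment.
#'
#' @param ip_peaks named list of IP [genomic_intervals] (e.g. 2
#'   antibodies x 2 replicates).
#' @param mock_peaks mock [genomic_intervals] used as the blacklist.
#' @param gene_models a `gene_models` data.frame.
#' @param workspace a [genome_workspace].
#' @param repeat_counts optional [count_matrix] with repeat and
#'   genomic_bin features for [repeat_enrichment()].
#' @param reference_peaks optional [genomic_intervals] for
#'   [randomized_overlap_enrichment()].
#' @param tss_window TSS annotation half-window (default 1000).
#' @param profile_flank,profile_bin density-profile settings.
#' @param coverage_bin bin width for coverage (default 1e5).
#' @param n_sims,seed randomization settings.
#' @param repeat_alpha FDR threshold for repeats (default 0.05).
#' @param out_dir optional output directory.
#' @return list with `final_peaks`, `tss_annotation`, `profile`,
#'   `bin_coverage`, `overlap_enrichment`, `repeats`, `manifest`.
#' @export
run_chip_analysis <- function(ip_peaks, mock_peaks, gene_models,
                              workspace, repeat_counts = NULL,
                              reference_peaks = NULL, tss_window = 1000,
                              profile_flank = 2000, profile_bin = 50,
                              coverage_bin = 1e5, n_sims = 1000,
                              seed = 1, repeat_alpha = 0.05,
                              out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  filtered <- lapply(ip_peaks, subtract_whole, blacklist = mock_peaks)
  pooled <- do.call(rbind, lapply(filtered, as.data.frame))
  final <- if (nrow(pooled))
    merge_intervals(genomic_intervals(pooled$chrom, pooled$start,
                                      pooled$end, score = pooled$score))
  else genomic_intervals(character(), numeric(), numeric())
  ann <- annotate_tss(final, gene_models, window = tss_window)
  # profile anchors on the replicate peak summits (merging drops them)
  pooled_iv <- genomic_intervals(pooled$chrom, pooled$start, pooled$end,
                                 score = pooled$score,
                                 summit_offset = pooled$summit_offset)
  prof <- density_profile(pooled_iv, gene_models, flank = profile_flank,
                          bin = profile_bin,
                          anchor = if (all(!is.na(
                            pooled_iv$summit_offset))) "summit"
                          else "midpoint")
  cov <- bin_coverage(final, workspace, bin = coverage_bin)
  ov <- if (!is.null(reference_peaks) && nrow(final))
    randomized_overlap_enrichment(final, reference_peaks, workspace,
                                  n_sims = n_sims, seed = seed)
  else NULL
  reps <- if (!is.null(repeat_counts))
    repeat_enrichment(repeat_counts, alpha = repeat_alpha) else NULL
  manifest <- .manifest(out_dir, list(
    analysis = "chip", tss_window = tss_window,
    coverage_bin = coverage_bin, n_sims = n_sims, seed = seed,
    n_ip_peaks_in = sum(vapply(ip_peaks, nrow, 0L)),
    n_after_mock_subtraction = sum(vapply(filtered, nrow, 0L)),
    n_final_peaks = nrow(final),
    n_bound_genes = length(ann$bound_genes),
    n_repeats_enriched = if (!is.null(reps)) sum(reps$enriched)
    else NA))
  .write_stage(out_dir, "tss_annotation", ann$table)
  .write_stage(out_dir, "bin_coverage", cov)
  if (!is.null(reps)) .write_stage(out_dir, "repeat_enrichment", reps)
  if (!is.null(out_dir)) write_peaks(final,
                                     file.path(out_dir,
                                               "final_peaks.broadPeak"))
  list(final_peaks = final, tss_annotation = ann, profile = prof,
       bin_coverage = cov, overlap_enrichment = ov, repeats = reps,
       manifest = manifest)
}
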