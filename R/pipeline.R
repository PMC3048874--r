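#' Pipeline parameter set
#'
#' All tunable thresholds of the analysis in one place; every report
#' embeds the exact set used.
#'
#' @param ext fragment extension in bp (133).
#' @param window_bp coverage window / window step in bp (10).
#' @param pvalue peak-calling Poisson threshold (1e-7).
#' @param min_height post-filter on peak height (1).
#' @param flank peak-to-gene proximity in bp (25000).
#' @param fold within-treatment expression fold cutoff (1.7).
#' @param expr_fold between-treatment expression fold cutoff (1.2).
#' @param ptm_fold pS46 binding fold cutoff (2.0).
#' @param n_bins occupancy bins (5).
#' @param k expression clusters (10).
#' @param seed integer seed for normalization and clustering.
#' @export
pipeline_params <- function(ext = 133, window_bp = 10, pvalue = 1e-7,
                            min_height = 1, flank = 25000, fold = 1.7,
                            expr_fold = 1.2, ptm_fold = 2.0, n_bins = 5,
                            k = 10, seed = 1) {
  stopifnot(ext >= 1, window_bp >= 1, pvalue > 0, flank >= 0, fold > 1,
            expr_fold > 1, ptm_fold > 0, n_bins >= 1, k >= 1)
  as.list(environment())
}

#' Run the full occupancy / phospho-occupancy / expression analysis
#'
#' Executes the study's analysis order on a bundle of inputs: depth
#' normalization (uniform read removal, per antibody across the two
#' conditions), total-p53 peak calling in both conditions,
#' common/preferential classification with RPP, R-squared and KS
#' summaries, phospho peak calling restricted to the total-p53 reference
#' sites, occupancy-quintile modification fractions, five-category region
#' annotation with enrichment, response-element motif scanning, expression
#' integration (ratios, treatment correlation, bound-and-changed counts,
#' uncentered-correlation k-means), and differential-pS46 candidate
#' selection. When the bundle carries simulation truth, recovery metrics
#' are added.
#'
#' @param bundle a [simulate_study()] bundle, or any list with the same
#'   `genome`, `genes`, `libraries` (`total_A`, `total_B`, and optionally
#'   `pS15_*`, `pS46_*`), and optionally `sequence`, `expression`,
#'   `truth_sites`, `truth_genes`.
#' @param params a [pipeline_params()] list.
#' @param blacklist optional `GRanges` of artifact regions removed from
#'   every peak list.
#' @param skip_expression run the binding-only analysis.
#' @return a nested list of results; see the methods vignette for a tour.
#' @export
run_occupancy_pipeline <- function(bundle, params = pipeline_params(),
                                   blacklist = NULL,
                                   skip_expression = FALSE) {
  genome <- bundle$genome
  libs <- bundle$libraries
  stopifnot(!is.null(libs$total_A), !is.null(libs$total_B))
  res <- list(params = params)

  antibodies <- intersect(c("total", "pS15", "pS46"),
                          unique(sub("_[AB]$", "", names(libs))))
  norm <- list()
  for (ab in antibodies) {
    pair <- libs[paste0(ab, "_", c("A", "B"))]
    norm[paste0(ab, "_", c("A", "B"))] <- normalize_libraries(
      pair, seed = params$seed)
  }
  res$normalized_depths <- vapply(norm, library_depth, numeric(1))

  call1 <- function(lib) {
    pk <- call_peaks(lib, genome, p_threshold = params$pvalue,
                     ext = params$ext, window_bp = params$window_bp,
                     min_height = params$min_height)
    if (!is.null(blacklist)) pk <- filter_artifacts(pk, blacklist)
    pk
  }
  peaks_A <- call1(norm$total_A)
  peaks_B <- call1(norm$total_B)
  cls <- classify_common_preferential(peaks_A, peaks_B)
  res$peaks <- list(total_A = peaks_A, total_B = peaks_B)
  res$classification <- cls
  res$overlap_percent_A <- if (length(peaks_A))
    overlap_fraction(length(peaks_A), sum(cls$is_common_A)) else NA
  res$overlap_percent_B <- if (length(peaks_B))
    overlap_fraction(length(peaks_B), sum(cls$is_common_B)) else NA

  # reference site list: condition-A peaks plus B-preferential peaks
  reference <- c(peaks_A, cls$preferential_B)
  if (length(reference))
    reference$name <- paste0("site_", seq_along(reference))
  res$reference_peaks <- reference

  rpp <- list(
    total_A = reads_per_peak(reference, norm$total_A, params$ext, genome),
    total_B = reads_per_peak(reference, norm$total_B, params$ext, genome))
  rppA_own <- reads_per_peak(peaks_A, norm$total_A, params$ext, genome)
  rppB_own <- reads_per_peak(peaks_B, norm$total_B, params$ext, genome)
  res$rsq_total <- if (length(reference) >= 2)
    tryCatch(rsq(rpp$total_A, rpp$total_B), error = function(e) NA_real_)
    else NA_real_
  res$median_rpp <- median_rpp_report(cls, rppA_own, rppB_own)

  # phospho peaks restricted to the total-p53 reference sites
  phospho <- list()
  for (ab in setdiff(antibodies, "total")) {
    for (cond in c("A", "B")) {
      nm <- paste0(ab, "_", cond)
      phospho[[nm]] <- restrict_to_reference(call1(norm[[nm]]), reference)
      rpp[[nm]] <- reads_per_peak(reference, norm[[nm]], params$ext, genome)
    }
  }
  res$peaks <- c(res$peaks, phospho)
  res$rpp <- rpp
  for (ab in setdiff(antibodies, "total")) {
    res[[paste0("rsq_", ab)]] <- if (length(reference) >= 2)
      tryCatch(rsq(rpp[[paste0(ab, "_A")]], rpp[[paste0(ab, "_B")]]),
               error = function(e) NA_real_) else NA_real_
  }

  if (length(reference) >= params$n_bins) {
    pooled <- rpp$total_A + rpp$total_B
    res$bin_fractions <- lapply(phospho, function(mp)
      binned_modification_fraction(reference, pooled, mp, params$n_bins))
  }

  map <- build_region_map(bundle$genes, genome)
  ann <- annotate_peaks(reference, map)
  dist <- genomic_distribution(map)
  res$region_map_fractions <- dist
  res$annotation <- ann
  res$enrichment <- enrichment_test(ann$counts, length(reference), dist)

  if (!is.null(bundle$sequence) && length(reference))
    res$motif <- fraction_with_motif(reference, bundle$sequence)

  gene_peaks <- assign_peaks_to_genes(reference, bundle$genes, params$flank)
  res$gene_peaks <- gene_peaks

  if (!skip_expression && !is.null(bundle$expression)) {
    ratios <- compute_ratios(bundle$expression)
    res$ratios <- ratios
    res$treatment_correlation <- treatment_correlation(ratios)
    res$bound_changed <- lapply(
      stats::setNames(c("A", "B"), c("A", "B")),
      function(cond) select_bound_changed(gene_peaks, ratios, cond,
                                          params$fold))
    bound <- intersect(unique(gene_peaks$gene_id), ratios$gene_id)
    X <- as.matrix(ratios[match(bound, ratios$gene_id),
                          grep("^change_", names(ratios))])
    rownames(X) <- bound
    if (nrow(X) >= params$k && all(rowSums(X^2) > 0)) {
      km <- kmeans_uncentered(X, k = params$k, seed = params$seed)
      res$clusters <- data.frame(gene_id = bound, cluster = km$cluster)
      res$kmeans <- km
    }
    if (!is.null(rpp$pS46_A)) {
      cand <- select_differential_ptm_candidates(
        rpp$pS46_A, rpp$pS46_B, gene_peaks, ratios,
        ptm_fold = params$ptm_fold, expr_fold = params$expr_fold)
      res$candidates <- cand
      res$n_candidate_sites <- nrow(cand)
      res$n_candidate_genes <- attr(cand, "n_unique_genes")
    }
  }

  if (!is.null(bundle$truth_sites)) {
    res$recovery <- recovery_report(bundle$truth_sites, peaks_A,
                                    rpp = rppA_own)
    if (!is.null(res$candidates) && !is.null(bundle$truth_genes))
      res$candidate_metrics <- candidate_metrics(bundle$truth_genes,
                                                 res$candidates$gene_id)
  }
  res
}

#' Write the pipeline's tabular reports
#'
#' Emits peak BED files, the RPP matrix, classification and bin-fraction
#' tables, region annotation and enrichment reports, expression outputs,
#' and a JSON summary embedding the parameter set.
#'
#' @param res a [run_occupancy_pipeline()] result.
#' @param outdir output directory.
#' @export
write_pipeline_reports <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  for (nm in names(res$peaks))
    write_peaks(res$peaks[[nm]], p(paste0("peaks_", nm, ".bed")))
  if (!is.null(res$rpp)) {
    rm <- data.table::data.table(site = res$reference_peaks$name,
                                 as.data.frame(res$rpp))
    data.table::fwrite(rm, p("rpp_matrix.tsv"), sep = "\t")
  }
  if (!is.null(res$bin_fractions)) {
    bf <- data.table::data.table(bin = seq_along(res$bin_fractions[[1]]),
                                 as.data.frame(res$bin_fractions))
    data.table::fwrite(bf, p("bin_fractions.tsv"), sep = "\t")
  }
  data.table::fwrite(res$enrichment, p("enrichment.tsv"), sep = "\t")
  if (!is.null(res$ratios))
    data.table::fwrite(res$ratios, p("ratios.tsv"), sep = "\t")
  if (!is.null(res$clusters))
    data.table::fwrite(res$clusters, p("clusters.tsv"), sep = "\t")
  if (!is.null(res$candidates))
    data.table::fwrite(res$candidates, p("candidates.tsv"), sep = "\t")
  summary <- list(
    params = res$params,
    normalized_depths = as.list(res$normalized_depths),
    n_peaks = lapply(res$peaks, length),
    classification = as.list(res$classification$counts),
    overlap_percent_A = res$overlap_percent_A,
    overlap_percent_B = res$overlap_percent_B,
    rsq_total = res$rsq_total, rsq_pS15 = res$rsq_pS15,
    rsq_pS46 = res$rsq_pS46,
    median_rpp = res$median_rpp[c("median_common_A", "median_preferential_A",
                                  "median_common_B", "median_preferential_B")],
    motif_percent = res$motif$percent,
    treatment_correlation = res$treatment_correlation,
    bound_changed = lapply(res$bound_changed, function(b)
      b[c("n_bound", "n_changed", "percent")]),
    n_candidate_sites = res$n_candidate_sites,
    n_candidate_genes = res$n_candidate_genes,
    recovery = if (!is.null(res$recovery))
      res$recovery[c("sensitivity", "fdr", "rpp_strength_spearman")],
    candidate_metrics = if (!is.null(res$candidate_metrics))
      res$candidate_metrics[c("precision", "recall")])
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(outdir)
}
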