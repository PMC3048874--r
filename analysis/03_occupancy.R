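#!/usr/bin/env Rscript
# Stage 3 -- quantitative occupancy comparison.
#
# Reads per peak (RPP) for every reference site in both conditions and all
# three antibodies; R-squared between treatments; common vs preferential
# classification with median RPP and KS tests; random-region background;
# and the occupancy-quintile phospho fractions.

suppressPackageStartupMessages(library(p53occupancy))

seed <- 1
outdir <- "results/occupancy"

bundle <- simulate_study(simulation_config(seed = seed))
res <- run_occupancy_pipeline(bundle, pipeline_params(seed = seed),
                              skip_expression = TRUE)
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rpp <- data.frame(site = res$reference_peaks$name, res$rpp)
write.table(rpp, file.path(outdir, "rpp_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
bf <- data.frame(bin = seq_along(res$bin_fractions[[1]]),
                 res$bin_fractions)
write.table(bf, file.path(outdir, "bin_fractions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("RPP R^2 between treatments: total %.2f, pS15 %.2f, pS46 %.2f\n",
            res$rsq_total, res$rsq_pS15, res$rsq_pS46))
cat("Total and pS15 occupancy agree well across treatments while pS46\n")
cat("diverges -- the B-specific S46 phosphorylation at strong sites.\n\n")
m <- res$median_rpp
cat(sprintf("Median RPP, condition A: common %s vs preferential %s (KS p = %.2g)\n",
            format(m$median_common_A), format(m$median_preferential_A),
            m$ks_A$p.value))
cat(sprintf("Median RPP, condition B: common %s vs preferential %s (KS p = %.2g)\n",
            format(m$median_common_B), format(m$median_preferential_B),
            m$ks_B$p.value))

# preferential peaks still carry reads in the other treatment, above the
# random-region background
cls <- res$classification
norm <- normalize_libraries(bundle$libraries[c("total_A", "total_B")],
                            seed = seed)
if (length(cls$preferential_A)) {
  other <- reads_per_peak(cls$preferential_A, norm[[2]],
                          genome = bundle$genome)
  bg <- background_rpp(norm[[2]], 2000,
                       round(mean(GenomicRanges::width(cls$preferential_A))),
                       bundle$genome, seed = seed)
  ks <- ks_two_sample(other, bg$rpp)
  cat(sprintf("\nA-preferential sites in the B library: median RPP %s vs background %s (KS p = %.2g)\n",
              format(median(other)), format(median(bg$rpp)), ks$p.value))
}

cat("\nQuintile phospho fractions (low to high occupancy):\n")
print(round(bf, 2))
nb <- nrow(bf)
cat(sprintf("\nTop-quintile pS46 fraction: %.2f (B) vs %.2f (A) -- S46\n",
            bf$pS46_B[nb], bf$pS46_A[nb]))
cat("phosphorylation marks the strongest sites preferentially under the\n")
cat("apoptosis-biased treatment; pS15 shows no such treatment contrast.\n")
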