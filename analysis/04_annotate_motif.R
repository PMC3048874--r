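#!/usr/bin/env Rscript
# Stage 4 -- genomic context and sequence content of the binding sites.
#
# Partitions the genome into the five annotation categories, annotates
# every reference site by its summit, tests per-category enrichment
# against the genomic background, and scans each site's 200-bp core for
# the bipartite p53 response element.

suppressPackageStartupMessages(library(p53occupancy))

seed <- 1
outdir <- "results/annotation"

bundle <- simulate_study(simulation_config(seed = seed))
res <- run_occupancy_pipeline(bundle, pipeline_params(seed = seed),
                              skip_expression = TRUE)
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

write.table(res$enrichment, file.path(outdir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ann <- data.frame(site = res$reference_peaks$name,
                  category = res$annotation$category)
write.table(ann, file.path(outdir, "site_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Genomic fraction per category:\n")
print(round(res$region_map_fractions, 3))
cat("\nSite enrichment vs genomic background (binomial, Bonferroni):\n")
print(res$enrichment, digits = 3)
cat("\nSites were placed uniformly and near genes by the generator, so\n")
cat("gene-proximal categories are enriched roughly in proportion to the\n")
cat("responsive-site placement.\n")
cat(sprintf("\n%.0f%% of sites contain a p53 response element (threshold %.0f)\n",
            res$motif$percent, default_p53_model()$threshold))
cat("-- the generator implants a consensus element at every true site.\n")
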