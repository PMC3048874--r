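#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic two-treatment phospho-p53 study.
#
# The bundle emulates the design every later stage assumes: two conditions
# (A, growth-arrest-biased; B, apoptosis-biased) x three antibodies (total
# p53, pS15, pS46) over one shared set of 120 binding sites on a 2 x 500 kb
# genome, plus an expression matrix in which the 20 genes tied to the
# strongest sites respond in condition B only. Everything is deterministic
# for the seed below; truth tables accompany the data files.

suppressPackageStartupMessages(library(p53occupancy))

seed <- 1
outdir <- "results/simdata"

bundle <- simulate_study(simulation_config(seed = seed))
write_study(bundle, outdir)

depths <- vapply(bundle$libraries, library_depth, numeric(1))
cat("Synthetic study written to", outdir, "\n")
cat(sprintf("  genome: %d chromosomes, %d bp\n",
            length(bundle$genome), genome_size(bundle$genome)))
cat(sprintf("  genes: %d (%d responsive)\n", nrow(bundle$genes),
            sum(bundle$truth_genes$responsive)))
cat(sprintf("  sites: %d (strengths %.0f-%.0f expected fragments)\n",
            nrow(bundle$truth_sites), min(bundle$truth_sites$strength),
            max(bundle$truth_sites$strength)))
cat("  library depths (tags):\n")
print(depths)
cat("Responsive sites carry S46-phosphorylation fraction",
    bundle$config$f46_responsive_B, "in condition B vs the basal",
    bundle$config$f46_base, "\n")
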