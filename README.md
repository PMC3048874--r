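# p53occupancy

Genome-wide comparison of total and phospho-specific p53 chromatin
binding across two stress treatments, integrated with expression
changes.

## The problem

Activated p53 drives different programs — growth arrest under one
chemotherapeutic stress, apoptosis under another — yet ChIP-seq shows
its binding-site repertoire is largely the same under both. This package
implements the analysis that locates the difference one level up, in the
post-translational state of the bound protein: it quantifies, genome
wide, how much of the chromatin-bound p53 carries the serine-15 or
serine-46 phosphomark under each treatment, and selects binding sites
where S46-phosphorylated p53 binds treatment-specifically alongside a
concordant expression change of the nearby gene. It is written for
computational biologists who want each stage of that analysis as a
tested, seedable R function rather than a one-off script stack.

## The method in brief

For a depth-normalized tag library (uniform read removal to the common
minimum), tags are directionally extended to the fragment length
(133 bp) and counted in sliding windows of width `W = 2·ext`. A window
with `k` overlapping fragments is a peak seed when the Poisson upper
tail

&nbsp;&nbsp;&nbsp;&nbsp;P(X ≥ k), X ~ Pois(λ), λ = max(λ_genome, λ_5kb, λ_10kb)·(W + ext − 1)

falls below 1e-7, where the λs are fragment rates estimated genome-wide
and in 5/10 kb local windows. Merged seeds become peaks with summit,
height, and p-value. Occupancy is RPP (reads per peak); treatments are
compared by squared Pearson correlation of RPP, common/preferential
classification (≥ 1 bp overlap), and two-sample Kolmogorov–Smirnov
tests. Phospho-specific peaks are restricted to total-p53 sites; sites
ranked by RPP and cut into quintiles give the per-bin fraction carrying
each phosphomark. Peak summits are annotated against a five-category
partition of the genome (TSS-flank, intragenic, 5 kb downstream,
5–25 kb flank, intergenic) and scanned for the bipartite p53 response
element (two RRRCWWGYYY half-sites, log-odds matrix, threshold
calibrated to < 1% hits on random 200 bp sequence). Expression changes
(log2 24 h/0 h per condition) are clustered with k-means under
uncentered correlation, and candidate sites satisfy
(RPP^pS46_B + 1)/(RPP^pS46_A + 1) ≥ 2 with
|Δlog2 change| ≥ log2 1.2 for the assigned gene.

A truth-annotated synthetic study generator (`simulate_study()`)
produces the full input bundle — genome, genes, six tag libraries,
expression matrix — under exactly the statistical structure the
analysis assumes, so every stage is validated by parameter recovery.
See `vignettes/phospho-p53-occupancy.Rmd` for the models, defaults, and
their rationale.

## Worked example

```r
library(p53occupancy)

bundle <- simulate_study(simulation_config(seed = 1))
res <- run_occupancy_pipeline(bundle, pipeline_params(seed = 1))

length(res$peaks$total_A); length(res$peaks$total_B)
#> [1] 119
#> [1] 117
res$overlap_percent_A
#> [1] 97
round(c(total = res$rsq_total, pS15 = res$rsq_pS15, pS46 = res$rsq_pS46), 2)
#> total  pS15  pS46
#>  0.64  0.52  0.30
round(res$bin_fractions$pS46_B, 2)
#> [1] 0.00 0.00 0.00 0.08 0.79
round(res$bin_fractions$pS46_A, 2)
#> [1] 0.00 0.00 0.00 0.00 0.21
res$n_candidate_genes
#> [1] 18
unlist(res$candidate_metrics[c("precision", "recall")])
#> precision    recall
#>      1.00      0.90
```

Reading: 119 and 117 binding sites are called in the two conditions and
97% of condition-A sites are re-found in condition B — total binding is
shared. RPP correlates across treatments for total p53 and pS15 but
much less for pS46, and in the top occupancy quintile 79% of sites
carry a pS46 peak under the apoptosis-biased condition versus 21% under
the other: the S46 phosphomark, not the binding site choice,
distinguishes the treatments. The candidate selector recovers 18 of the
20 genes the generator designated as pS46-responsive, with no false
positives.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (`01_simulate.R` … `05_expression.R`), writing their
tables under `results/`.

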