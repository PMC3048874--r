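---
title: "Methods: differential occupancy of total and phospho-specific p53"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential occupancy of total and phospho-specific p53}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the design

When p53 is activated by different chemotherapeutic stresses -- one
biasing cells toward growth arrest (condition A), one toward apoptosis
(condition B) -- does the choice of transcriptional program play out at
the level of where p53 binds, or at the level of how the bound protein is
modified? This package implements the analysis that addresses the
question with ChIP-seq of total p53 alongside two phospho-specific forms
(serine 15 and serine 46) under both conditions, integrated with
gene-level expression changes. The working picture it quantifies: total
binding is nearly identical across treatments, while the fraction of
bound p53 carrying the S46 phosphomark rises specifically at strong sites
under the apoptosis-biased treatment, and a subset of those sites sits
near genes whose expression responds to that treatment only.

The pipeline runs from aligned tags (BED6, one record per uniquely
mapped read) to a candidate gene list:

1. depth normalization by uniform read removal,
2. directional tag extension and window-averaged coverage,
3. local-Poisson peak calling,
4. occupancy comparison (reads per peak, R^2, common/preferential
   classes, KS tests, quintile phospho fractions),
5. five-category genomic annotation,
6. bipartite response-element scanning,
7. expression integration (log2 ratios, uncentered-correlation k-means,
   bound-and-changed counts), and
8. selection of sites differentially bound by pS46 with a concordant
   expression difference.

# Core models and conventions

## Coordinates and containers

All ranges live in Bioconductor `GRanges` (1-based, closed), the
established interval algebra in this field; BED-style 0-based half-open
coordinates appear only at file boundaries (`read_tags()`,
`write_peaks()`, refFlat gene models, bedGraph export). Overlap always
means at least one shared base; abutting half-open intervals do not
overlap. A tag is reduced to its 5'-most aligned base plus strand; on the
minus strand that base is `end - 1` of the BED record because BED ends
are exclusive.

## Tag extension and coverage

Each sequenced tag marks one end of a ~133 bp fragment, so tags are
directionally extended to the fragment length (`ext`, default 133 bp,
a library-preparation property and a config key, not a constant). The
coverage track stores mean per-base depth in fixed windows (default
10 bp); the final partial window of a chromosome averages over the bases
it actually contains rather than zero-padding, avoiding an edge bias.
Duplicate tags are retained -- nothing in the analysis model calls for
deduplication, and the generator produces none artificially.

## Normalization

Libraries are equalized by uniformly removing reads down to the smallest
depth involved (`normalize_libraries()`), the simplest scheme that makes
raw overlap counts comparable. Normalization happens before peak calling
and artifact filtering, matching the stage order of the analysis.
The pipeline normalizes *per antibody across the two conditions* (total
A with total B, pS15 A with pS15 B, pS46 A with pS46 B): every
quantitative comparison in the analysis -- R^2 between treatments,
common/preferential medians, the pS46 B/A binding ratio -- is
within-antibody, and the phospho libraries are intrinsically sparser
than the total-p53 library, so forcing a global common depth would
discard most of the total-p53 signal without making any reported number
more comparable. Cross-antibody statements are presence/absence
(peak overlap), which is robust to depth differences at these
thresholds.

## Peak calling

The caller is a deliberately transparent local-Poisson scan -- the same
logic class as model-based ChIP-seq callers, without model building,
shift estimation, or a control library (the analysis design includes
none). Windows of twice the fragment length slide at the coverage window
step. A window of width W is scored by the number k of extended
fragments overlapping it. Under a homogeneous fragment rate r, the
expected overlap count is r(W + ext - 1) (a fragment of length ext
overlaps the window when its start falls in a span of that length). The
local rate is the most conservative of three estimates -- genome-wide,
5 kb, and 10 kb windows centered on the tested window -- guarding
against locally elevated background, and the window is significant when
the Poisson upper tail P(X >= k) falls below the threshold (default
1e-7, a strict setting chosen to keep only high-confidence sites; the
false-positive budget at this threshold is about 0.01 expected windows
per 10^5 windows). Significant windows closer than one fragment length
merge into a peak; the summit is the leftmost maximum of per-base depth
(a deterministic tie-break), the height that maximum, and the peak
p-value the minimum window p-value. A `min_height` post-filter is
exposed (default 1) because reported peak sets in this kind of analysis
carry a minimum height; at 1e-7 the emergent heights are well above it.

Phospho-specific peaks are only interpreted at sites bound by total p53:
`restrict_to_reference()` keeps modification peaks overlapping the union
of the two conditions' total-p53 peaks. Artifact regions (e.g.
centromeric/telomeric spikes) are removed by a user-supplied blacklist;
no default list ships because such lists are genome-build-specific.

## Occupancy comparison

Reads per peak (RPP) -- extended tags overlapping the peak interval --
is the occupancy measure throughout. R^2 is the squared Pearson
correlation of raw RPP between treatments; raw rather than
log-transformed values are the default because that is the literal
occupancy comparison, and callers can transform upstream if desired. A
peak is *common* when it overlaps (>= 1 bp) any peak of the other
condition, else *preferential*; one-to-many overlaps count once at the
site level, and the classification is reported from both directions.
The >= 1 bp criterion (rather than summit-in-peak) is the default
because it is the weakest defensible overlap notion; at these peak
widths the two agree almost always. Common-versus-preferential RPP
distributions are compared with the two-sample Kolmogorov-Smirnov test
(asymptotic p-values throughout -- count data are tie-heavy, so exact
small-sample p-values are unavailable anyway), and preferential peaks
are additionally scored against random same-length regions
(`background_rpp()`) to show they still carry signal in the other
treatment.

For the phosphorylation-versus-strength question, reference sites are
ranked by RPP (ties broken by genomic coordinate so binning is
deterministic), cut into five near-equal bins low to high (remainder to
the lowest bins), and each bin reports the fraction of sites overlapping
a pS15 or pS46 peak. The pipeline ranks by the *pooled* (A + B) total-p53
RPP so both conditions' fractions are computed over identical bins --
the contrast of interest is between conditions within a bin, which
requires a shared ranking.

## Region annotation

Five categories partition the genome: TSS-flanking (5 kb upstream of the
TSS plus the first exon and first intron), intragenic (remaining exons
and introns), 5 kb downstream of the last exon, 5-25 kb up- or
downstream, and intergenic (everything else). Regions are built per
transcript, strand-aware (for minus-strand genes the TSS is at the high
coordinate), merged across overlapping transcripts, and resolved by the
fixed precedence TSS_flank > intragenic > downstream_5kb > flank_5_25kb >
intergenic, so promoter-like labels win and the result is an exact
partition (verified per base in the tests). A single-exon gene
contributes no intragenic territory -- its only exon belongs to the
TSS-flank by the definition above. Peaks are annotated by the category
of their *summit*: a single unambiguous label per peak, which a
whole-interval rule cannot give once intervals straddle category
boundaries. Enrichment per category is a one-sided binomial upper-tail
test of observed counts against the genomic fraction,
Bonferroni-corrected across the five categories; the test behind this
kind of enrichment flag is not standardized, and the binomial choice is
flagged in the report.

Peak-to-gene assignment is summit within the transcript extended by
25 kb both sides, inclusive at the upstream bound and exclusive at the
downstream bound in half-open terms; many-to-many assignments are kept
and unique gene lists derived from them.

## Motif scanning

The p53 response element is two RRRCWWGYYY decamer half-sites; both are
scored with one 4 x 10 log-odds matrix and summed, with an optional
spacer (default 0 bp, the modern consensus; up to ~13 bp can be
enabled). The default matrix is consensus-derived: within each column
the allowed bases split the probability evenly after each disallowed
base receives a 0.01 pseudo-weight; log-odds are base-2 against a
uniform background. `N` scores as the column's worst case; other
ambiguity codes are rejected loudly. Scanning evaluates every start,
strand, and spacer, returning the best hit at or above the threshold
(ties: smallest spacer, then leftmost, then '+'). Each peak is reduced
to its summit +/- 100 bp before scanning, the conventional "200 bp core"
for this motif analysis.

The default threshold (10) was calibrated once against the null: on
i.i.d. uniform 200-bp sequence the hit probability is ~0.5% (measured at
n = 10^4 seeded draws; `motif_null_rate()` reproduces this), under the
1% design bound. In score terms the threshold tolerates at most two
consensus-class mismatches over the 20 informative positions. Published
scanners for this motif family use trained matrices and their own
thresholds; the published motif-fraction numbers are therefore not
parity targets here -- the mechanism (bipartite scan over the 200-bp
core, threshold calibrated to a stated false-positive rate) is the
implemented contribution, and a user-supplied matrix file is accepted.

## Expression integration

Input is an already-normalized gene-level log2 intensity matrix
(array preprocessing is upstream and out of scope) with
(condition, timepoint, replicate) metadata. Per condition, replicates are
averaged per timepoint and the change is mean(24h) - mean(0h) on the
log2 scale. "Changed at least f-fold" means |log2 change| >= log2(f),
inclusive; the within-treatment default is f = 1.7 and the
between-treatment difference default f = 1.2, both config keys.
"Differs at least 1.2-fold between treatments" is implemented as
|change_B - change_A| >= log2(1.2) -- a difference of log-ratios,
the only scale on which the two treatments' changes are comparable.

Bound genes' change profiles are clustered with k-means (default k = 10)
under distance 1 - uncentered correlation (cosine similarity without
mean-centering, so profiles are grouped by direction of regulation, not
shape around their own mean). Lloyd iterations use the mean of the
members' unit vectors as the centroid -- the minimizer of total cosine
distance, which keeps the objective non-increasing; empty clusters are
re-seeded from the worst-fit point; 10 seeded restarts keep the best
objective, making results deterministic given the seed. The originating
clustering tool's initialization is undocumented, so seeded restarts are
this package's choice.

## Candidate selection

A reference site passes the binding criterion when its pS46 occupancy is
at least 2-fold stronger in condition B, computed as
(RPP_B + 1)/(RPP_A + 1) -- the +1 pseudo-count keeps ratios defined and
damps noise at near-zero counts, and the 2-fold default reflects the
observed magnitude of condition-specific pS46 binding at validated
sites. Its assigned gene passes when the between-treatment expression
difference is at least 1.2-fold as above. The output is every passing
(site, gene) pair plus the unique-gene count. Both thresholds are
parameters because the exact published criterion for this list is not
fully specified; the defaults are the stated fold magnitudes.

# The synthetic study

`simulate_study()` produces a truth-annotated miniature of the design:
2 x 500 kb genome, 60 genes, 120 shared binding sites, six tag libraries
(3 antibodies x 2 conditions), an 8-array expression matrix, and
genome sequence with a consensus response element implanted at every
site center. The scale was chosen so a full pipeline run takes seconds
on one CPU while every statistic still has enough sites/genes behind it
to be stable (see the problem sizes in the acceptance script).

Generative model, and why each piece:

* **Background**: uniform Poisson tags at 0.01 per bp per total library
  (~10^4 background tags per library; per-base background depth after
  extension ~1.3, so sites at the default strengths sit at roughly
  15-75x local enrichment -- strong-but-realistic ChIP enrichment).
* **Sites**: fragment centers fall uniformly within half a fragment
  length of the site center, so extension by 133 bp covers the site --
  the geometric fingerprint of real ChIP fragments. Site strengths
  (expected fragments per site) are log-normal (meanlog = log 45,
  sdlog = 0.4), giving the heavy-tailed occupancy spread that makes RPP
  ranking meaningful. A fixed-strength variant
  (`strength = list(type = "fixed", value = 30)`) provides the
  peak-recovery benchmark at a stated enrichment.
* **Phospho libraries as thinning**: a site-bound protein is
  phosphorylated with the site's modification fraction, so the pS15/pS46
  libraries are thinned copies of the total fragment process (background
  thinned at the basal fraction). This is the simplest model consistent
  with modification fractions of chromatin-bound protein. Defaults:
  f15 = 0.5 in both conditions (S15 is treatment-independent);
  f46 = 0.1 basal, rising to 0.5 in condition B at the 20 "responsive"
  sites only.
* **Responsive sites are the strongest sites** (they take the top
  strengths): the treatment-specific S46 signal concentrates in the top
  occupancy quintile, which is exactly the contrast the quintile
  analysis is designed to expose.
* **Expression**: responsive genes (one per responsive site, the site
  placed within the gene's proximity window) move by log2 ~1.5 +/- 0.2 in
  condition B only; every other true change is N(0, 0.05), and
  replicates add N(0, 0.05) measurement noise -- typical
  post-normalization array variability. With these spreads a
  non-responsive gene crosses the 1.2-fold between-treatment filter with
  probability under 1%, so candidate precision measures the selector,
  not the noise model.

What the generator does *not* emulate: mappability structure, PCR
duplicates, sequencing error, GC bias, fragment-length dispersion,
antibody cross-reactivity, and probe-level array effects. Passing the
recovery suite therefore shows the pipeline's statistics are correct
under the stated model, not that the pipeline is robust to every
real-data artifact; the artifact-blacklist and threshold knobs exist for
the real-data cases.

# Numerical choices and degenerate inputs

* Poisson and binomial tails come from `stats::ppois`/`pbinom`
  (upper-tail with `k - 1`), never normal approximations.
* KS p-values are asymptotic (`exact = FALSE`) because RPP ties make
  exact p-values unavailable; D itself is exact.
* R^2 and correlations error on constant input rather than return NA.
* Empty peak classes report NA medians; empty libraries yield empty peak
  lists; a zero genome-wide fragment rate is an error.
* Downsampling, placement, clustering, and scanning all take explicit
  seeds; `with_seed` isolation means package calls never disturb the
  caller's RNG stream.
* Summit ties break leftmost; RPP-ranking ties break by coordinate;
  k-means assignment ties break to the first cluster.

# Known limitations

* The peak caller is not a reimplementation of any published caller;
  peak counts on real data are not expected to match those of a
  particular caller version and configuration.
* One summit per peak: closely spaced double sites merged by the window
  logic are annotated and scanned once.
* The enrichment test conditions on total peak count per category
  independently; categories are not jointly modeled.
* Candidate selection uses fold thresholds, not a count model; with
  deeper libraries a negative-binomial test would discriminate better,
  but the analysis this package implements defines itself by the fold
  criteria.
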