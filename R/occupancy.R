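#' Reads per peak (RPP)
#'
#' The occupancy measure: for each peak, the number of extended tags of a
#' depth-normalized library overlapping the peak interval by at least one
#' base.
#'
#' @param peaks peak `GRanges`.
#' @param library a depth-normalized [tag_library()].
#' @param ext fragment extension in bp (default 133).
#' @param genome optional [genome_def()] for clipping.
#' @return integer vector parallel to `peaks`.
#' @export
reads_per_peak <- function(peaks, library, ext = 133, genome = NULL) {
  frags <- extend_tags(library, ext, genome)
  GenomicRanges::countOverlaps(peaks, frags)
}

#' Squared Pearson correlation (R^2)
#'
#' The square of the sample correlation coefficient, used to compare
#' occupancy (RPP) between two treatments.
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return R-squared in `[0, 1]`.
#' @export
rsq <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)^2
}

#' Classify peaks as common or treatment-preferential
#'
#' A peak is common when it overlaps (>= 1 bp) at least one peak called in
#' the other condition, otherwise preferential for its own condition. The
#' classification is reported from both directions; one-to-many overlaps
#' collapse to the site level (a peak counts once however many partners it
#' has).
#'
#' @param peaks_A,peaks_B peak `GRanges` for the two conditions.
#' @return an object of class `"PeakClassification"`: list with the
#'   common/preferential index vectors and subsets for each condition, and
#'   a `counts` summary.
#' @export
classify_common_preferential <- function(peaks_A, peaks_B) {
  # peak lists from two calls may carry different seqlevels
  common_A <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks_A, peaks_B)) > 0L
  common_B <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks_B, peaks_A)) > 0L
  structure(list(
    common_A = peaks_A[common_A], preferential_A = peaks_A[!common_A],
    common_B = peaks_B[common_B], preferential_B = peaks_B[!common_B],
    is_common_A = common_A, is_common_B = common_B,
    counts = c(n_A = length(peaks_A), n_B = length(peaks_B),
               common_A = sum(common_A), common_B = sum(common_B),
               preferential_A = sum(!common_A),
               preferential_B = sum(!common_B))),
    class = "PeakClassification")
}

#' @export
print.PeakClassification <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over observed points of the absolute difference of
#' the two empirical CDFs; the p-value comes from the asymptotic KS
#' distribution (counts are tied-heavy, so the asymptotic form is used
#' throughout).
#'
#' @param x,y nonempty numeric samples.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("KS test needs nonempty samples")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Median RPP of common versus preferential peaks
#'
#' Summarizes occupancy of the peak classes per condition and tests, per
#' condition, whether common and preferential peaks have the same RPP
#' distribution (two-sample KS). Medians of empty classes are reported as
#' `NA`.
#'
#' @param classification a [classify_common_preferential()] result.
#' @param rpp_A RPP vector parallel to the condition-A peaks.
#' @param rpp_B RPP vector parallel to the condition-B peaks.
#' @return list of per-condition medians and KS results.
#' @export
median_rpp_report <- function(classification, rpp_A, rpp_B) {
  stopifnot(inherits(classification, "PeakClassification"))
  cA <- rpp_A[classification$is_common_A]
  pA <- rpp_A[!classification$is_common_A]
  cB <- rpp_B[classification$is_common_B]
  pB <- rpp_B[!classification$is_common_B]
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  ks <- function(a, b) if (length(a) && length(b)) ks_two_sample(a, b)
        else list(statistic = NA_real_, p.value = NA_real_)
  list(median_common_A = med(cA), median_preferential_A = med(pA),
       median_common_B = med(cB), median_preferential_B = med(pB),
       ks_A = ks(cA, pA), ks_B = ks(cB, pB))
}

#' RPP of random background regions
#'
#' Places `n_regions` intervals of fixed length uniformly on the genome and
#' scores them like peaks; used as the null sample when testing whether
#' preferential peaks carry more reads than background.
#'
#' @param library a depth-normalized [tag_library()].
#' @param n_regions number of random regions.
#' @param region_length region length in bp (must fit the smallest
#'   chromosome).
#' @param genome a [genome_def()].
#' @param seed integer seed.
#' @param ext fragment extension in bp.
#' @return list with `regions` (`GRanges`) and `rpp` (integer vector).
#' @export
background_rpp <- function(library, n_regions, region_length, genome, seed,
                           ext = 133) {
  if (region_length > min(unclass(genome)))
    stop("region_length exceeds the smallest chromosome")
  sizes <- unclass(genome)
  regions <- with_seed(seed, {
    chr <- sample(names(sizes), n_regions, replace = TRUE,
                  prob = sizes / sum(sizes))
    start <- vapply(chr, function(cc)
      sample.int(sizes[[cc]] - region_length + 1L, 1L), integer(1))
    GenomicRanges::GRanges(chr, IRanges::IRanges(start, width = region_length))
  })
  list(regions = regions,
       rpp = reads_per_peak(regions, library, ext = ext, genome = genome))
}

#' Modification fraction by occupancy quintile
#'
#' Reference peaks are ranked by RPP (ascending; ties broken by genomic
#' coordinate for determinism), split into `n_bins` near-equal groups from
#' low to high (any remainder goes to the lowest bins), and for each bin
#' the fraction of reference peaks overlapping at least one
#' modification-specific peak is reported.
#'
#' @param reference_peaks reference peak `GRanges` (e.g. total p53).
#' @param rpp RPP vector parallel to `reference_peaks` used for ranking.
#' @param mod_peaks modification-specific peak `GRanges`.
#' @param n_bins number of bins (default 5, i.e. quintiles).
#' @return numeric vector of length `n_bins`, low-occupancy bin first.
#' @export
binned_modification_fraction <- function(reference_peaks, rpp, mod_peaks,
                                         n_bins = 5) {
  n <- length(reference_peaks)
  if (length(rpp) != n) stop("rpp must parallel reference_peaks")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n < n_bins) stop("fewer peaks (", n, ") than bins (", n_bins, ")")
  ord <- order(rpp,
               as.character(GenomicRanges::seqnames(reference_peaks)),
               GenomicRanges::start(reference_peaks))
  base_size <- n %/% n_bins
  sizes <- rep(base_size, n_bins)
  rem <- n %% n_bins
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  has_mod <- suppressWarnings(
    GenomicRanges::countOverlaps(reference_peaks, mod_peaks)) > 0L
  as.numeric(tapply(has_mod[ord], bin, mean))
}
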