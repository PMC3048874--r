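#' Call binding-site peaks with a local-Poisson model
#'
#' A deliberately transparent sliding-window caller in the spirit of
#' model-based ChIP-seq peak finders: fragment counts in windows of twice
#' the fragment length are tested against a Poisson background whose rate
#' is the most conservative of a genome-wide estimate and local estimates
#' from 5 kb and 10 kb windows centred on the tested window (guarding
#' against locally elevated background). No control library is used.
#'
#' A window of width `W` is scored by `k`, the number of extended fragments
#' overlapping it; under a homogeneous fragment-start rate `r` the expected
#' overlap count is `r * (W + ext - 1)`. The window is significant when the
#' Poisson upper tail `P(X >= k)` falls below `p_threshold`. Significant
#' windows closer than `ext` are merged into one peak; the summit is the
#' leftmost position of maximal per-base depth, the height that maximal
#' depth, and the peak p-value the smallest window p-value.
#'
#' @param library a depth-normalized [tag_library()].
#' @param genome a [genome_def()].
#' @param p_threshold Poisson upper-tail threshold (default `1e-7`; a strict
#'   cutoff that keeps only high-confidence peaks).
#' @param ext fragment extension in bp (default 133).
#' @param window_bp window step in bp (default 10); window width is `2 * ext`.
#' @param min_height post-filter on peak height (default 1; emergent heights
#'   are usually well above this at strict thresholds).
#' @return `GRanges` of peaks with metadata columns `name`, `summit`
#'   (1-based position), `height`, and `pvalue`.
#' @export
call_peaks <- function(library, genome, p_threshold = 1e-7, ext = 133,
                       window_bp = 10, min_height = 1) {
  stopifnot(inherits(library, "TagLibrary"))
  empty <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    name = character(0), summit = integer(0), height = integer(0),
    pvalue = numeric(0))
  if (library$depth == 0L) return(empty)
  frags <- extend_tags(library, ext, genome)
  gsize <- genome_size(genome)
  rate_genome <- length(frags) / gsize
  if (rate_genome == 0) stop("genome-wide fragment rate is zero")
  W <- 2L * as.integer(ext)
  eff_w <- function(width) width + ext - 1   # effective width for overlap counts

  chrom_gr <- GenomicRanges::GRanges(
    names(genome), IRanges::IRanges(1L, as.integer(genome)),
    seqinfo = genome_seqinfo(genome))
  windows <- unlist(GenomicRanges::slidingWindows(
    chrom_gr, width = min(W, min(unclass(genome))), step = as.integer(window_bp)))
  k <- GenomicRanges::countOverlaps(windows, frags)

  cand <- which(k > 0L)
  if (!length(cand)) return(empty)
  wins <- windows[cand]
  kc <- k[cand]
  loc5 <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(wins, min(5000L, min(unclass(genome))),
                          fix = "center")))
  loc10 <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(wins, min(10000L, min(unclass(genome))),
                          fix = "center")))
  r5 <- GenomicRanges::countOverlaps(loc5, frags) / eff_w(GenomicRanges::width(loc5))
  r10 <- GenomicRanges::countOverlaps(loc10, frags) / eff_w(GenomicRanges::width(loc10))
  rate <- pmax(rate_genome, r5, r10)
  lambda <- rate * eff_w(GenomicRanges::width(wins))
  pv <- stats::ppois(kc - 1, lambda, lower.tail = FALSE)
  sig <- pv < p_threshold
  if (!any(sig)) return(empty)
  sig_win <- wins[sig]
  sig_p <- pv[sig]

  peaks <- GenomicRanges::reduce(sig_win, min.gapwidth = as.integer(ext) + 1L)
  hit <- GenomicRanges::findOverlaps(sig_win, peaks)
  minp <- tapply(sig_p[S4Vectors::queryHits(hit)],
                 S4Vectors::subjectHits(hit), min)
  pvalue <- as.numeric(minp[as.character(seq_along(peaks))])

  cov <- GenomicRanges::coverage(frags, width = stats::setNames(
    as.integer(genome), names(genome)))
  summit <- integer(length(peaks))
  height <- integer(length(peaks))
  for (chr in unique(as.character(GenomicRanges::seqnames(peaks)))) {
    idx <- which(as.character(GenomicRanges::seqnames(peaks)) == chr)
    v <- IRanges::Views(cov[[chr]],
                        IRanges::IRanges(GenomicRanges::start(peaks)[idx],
                                         GenomicRanges::end(peaks)[idx]))
    summit[idx] <- IRanges::viewWhichMaxs(v)  # leftmost max by convention
    height[idx] <- as.integer(IRanges::viewMaxs(v))
  }
  S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
    name = paste0("peak_", seq_along(peaks)),
    summit = summit, height = height, pvalue = pvalue)
  peaks[peaks$height >= min_height]
}

#' Remove peaks overlapping a blacklist
#'
#' Drops peaks sharing at least one base with any blacklist interval
#' (spurious signal such as centromeric/telomeric artifact regions). Order
#' is preserved.
#'
#' @param peaks peak `GRanges`.
#' @param blacklist `GRanges` of regions to exclude (may be empty).
#' @export
filter_artifacts <- function(peaks, blacklist) {
  if (length(blacklist) == 0L || length(peaks) == 0L) return(peaks)
  # the two sets may carry different seqlevels; that is not an error here
  peaks[suppressWarnings(
    GenomicRanges::countOverlaps(peaks, blacklist)) == 0L]
}

#' Restrict modification-specific peaks to a reference peak set
#'
#' Phospho-specific binding is only interpreted at sites bound by total
#' p53: keep peaks overlapping (>= 1 bp) the union of the reference peaks.
#'
#' @param mod_peaks peak `GRanges` from a modification-specific library.
#' @param reference_peaks `GRanges` of the reference (total-p53) peaks.
#' @export
restrict_to_reference <- function(mod_peaks, reference_peaks) {
  if (length(mod_peaks) == 0L) return(mod_peaks)
  mod_peaks[suppressWarnings(
    GenomicRanges::countOverlaps(mod_peaks, reference_peaks)) > 0L]
}

#' Write peaks as BED6+ (score = height, extra columns summit offset and
#' p-value)
#' @param peaks peak `GRanges` from [call_peaks()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = if (length(peaks)) peaks$name else character(0),
    score = if (length(peaks)) peaks$height else integer(0),
    strand = rep(".", length(peaks)),
    summit_offset = if (length(peaks)) peaks$summit - GenomicRanges::start(peaks)
                    else integer(0),
    pvalue = if (length(peaks)) peaks$pvalue else numeric(0))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
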