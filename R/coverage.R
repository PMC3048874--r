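#' Directionally extend tags to fragment length
#'
#' Each tag marks the 5' end of a sequenced fragment; extending it in the
#' read direction reconstructs the fragment interval. A `+` tag at 5' base
#' p covers `[p, p + length)`; a `-` tag covers `(p - length, p]` (0-based
#' half-open: `[p - length + 1, p + 1)`). Intervals are clipped to
#' chromosome bounds.
#'
#' @param tags width-1 `GRanges` with strand, or a [tag_library()].
#' @param length fragment length in bp (default 133, the sequencing library
#'   insert size this pipeline was designed around).
#' @param genome a [genome_def()] used for clipping.
#' @return unstranded-use `GRanges` of fragment intervals, parallel to the
#'   input tags.
#' @export
extend_tags <- function(tags, length = 133, genome = NULL) {
  if (inherits(tags, "TagLibrary")) tags <- tags$tags
  if (length < 1) stop("extension length must be >= 1")
  if (length(tags) == 0L) return(tags)
  if (!is.null(genome)) {
    check_within_genome(tags, genome, "tag")
    GenomeInfoDb::seqlevels(tags) <- names(genome)
    GenomeInfoDb::seqlengths(tags) <- as.integer(genome)
  }
  # resize with fix = "start" anchors at the 5' end on either strand;
  # out-of-bound intermediates are expected and trimmed
  suppressWarnings({
    ext <- GenomicRanges::resize(tags, width = as.integer(length),
                                 fix = "start")
    GenomicRanges::trim(ext)
  })
}

#' Window-averaged genome coverage
#'
#' Per-base depth is the number of extended fragments covering each base;
#' the track stores the mean depth over consecutive fixed-width windows.
#' A final partial window at a chromosome end averages over the bases it
#' actually contains.
#'
#' @param library a [tag_library()] (typically depth-normalized).
#' @param genome a [genome_def()].
#' @param ext fragment extension in bp (default 133).
#' @param window averaging window in bp (default 10).
#' @return an object of class `"CoverageTrack"`: list with `genome`,
#'   `window`, and `values`, a per-chromosome list of window means.
#' @export
compute_coverage <- function(library, genome, ext = 133, window = 10) {
  stopifnot(inherits(library, "TagLibrary"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1 bp")
  frags <- extend_tags(library, ext, genome)
  GenomeInfoDb::seqlevels(frags) <- names(genome)
  cov <- GenomicRanges::coverage(frags, width = stats::setNames(
    as.integer(genome), names(genome)))
  values <- lapply(names(genome), function(chr) {
    sz <- unclass(genome)[[chr]]
    n_win <- ceiling(sz / window)
    widths <- rep(window, n_win)
    widths[n_win] <- sz - (n_win - 1L) * window
    v <- IRanges::Views(cov[[chr]],
                        IRanges::successiveIRanges(widths))
    as.numeric(IRanges::viewMeans(v))
  })
  names(values) <- names(genome)
  structure(list(genome = genome, window = window, values = values),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: %d-bp windows over %d chromosome(s)\n",
              x$window, length(x$values)))
  invisible(x)
}

#' Total coverage mass of a track
#'
#' Sum over all bases of per-base depth, recovered from window means. By
#' conservation this equals the summed (clipped) extended fragment lengths.
#'
#' @param track a [compute_coverage()] result.
#' @export
coverage_mass <- function(track) {
  total <- 0
  for (chr in names(track$values)) {
    sz <- unclass(track$genome)[[chr]]
    v <- track$values[[chr]]
    n_win <- length(v)
    widths <- rep(track$window, n_win)
    if (n_win) widths[n_win] <- sz - (n_win - 1L) * track$window
    total <- total + sum(v * widths)
  }
  total
}

#' Export a coverage track as bedGraph
#'
#' Fixed-step windows; runs of consecutive windows with identical value
#' (including zeros) are collapsed into one record. Coordinates are BED-style
#' 0-based half-open.
#'
#' @param track a [compute_coverage()] result.
#' @param path output path.
#' @param drop_zero omit zero-valued runs (default TRUE).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  recs <- list()
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    if (!length(v)) next
    r <- rle(v)
    ends_win <- cumsum(r$lengths)
    starts_win <- c(0L, ends_win[-length(ends_win)])
    sz <- unclass(track$genome)[[chr]]
    dt <- data.table::data.table(
      chrom = chr,
      start = starts_win * track$window,
      end = pmin(ends_win * track$window, sz),
      value = r$values)
    if (drop_zero) dt <- dt[dt$value != 0, ]
    recs[[chr]] <- dt
  }
  out <- data.table::rbindlist(recs)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
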