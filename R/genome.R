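#' Genome coordinate system
#'
#' A genome is an ordered set of named chromosomes with integer lengths.
#' Every interval handled by the pipeline must lie within its chromosome.
#' Internally all ranges are `GRanges` (1-based, closed, the Bioconductor
#' convention); 0-based half-open coordinates appear only in BED/bedGraph
#' and refFlat files at the I/O boundary.
#'
#' @param sizes named integer vector of chromosome lengths (bp), all > 0,
#'   names unique.
#' @return an object of class `"Genome"`: the validated named integer
#'   vector, carrying its `Seqinfo` for use with `GRanges`.
#' @examples
#' gn <- genome_def(c(chr1 = 1e5, chr2 = 5e4))
#' genome_size(gn)
#' @export
genome_def <- function(sizes) {
  if (length(sizes) == 0L) stop("genome needs at least one chromosome")
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(sizes))) stop("chromosome names must be unique")
  nm <- names(sizes)
  sizes <- round(as.numeric(sizes))
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome sizes must be positive integers")
  structure(stats::setNames(as.integer(sizes), nm), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", length(x), "chromosome(s),", sum(as.numeric(x)), "bp total\n")
  print(unclass(x))
  invisible(x)
}

#' Total genome length in bp
#' @param genome a [genome_def()] object.
#' @export
genome_size <- function(genome) sum(as.numeric(genome))

#' `Seqinfo` for a Genome (used when building `GRanges`)
#' @param genome a [genome_def()] object.
#' @export
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return a [genome_def()] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          colClasses = list(character = 1))
  if (ncol(dt) != 2L) stop("chrom.sizes must have exactly two columns")
  genome_def(stats::setNames(dt$size, dt$chrom))
}

#' Write a chrom.sizes file
#' @param genome a [genome_def()] object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  data.table::fwrite(data.table::data.table(names(genome), unclass(genome)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# internal: assert a GRanges lies within the genome
check_within_genome <- function(gr, genome, what = "interval") {
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(genome))
  if (any(bad))
    stop(what, " on undefined chromosome: ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]), collapse = ", "))
  sz <- unclass(genome)[as.character(GenomicRanges::seqnames(gr))]
  if (any(GenomicRanges::start(gr) < 1L) || any(GenomicRanges::end(gr) > sz))
    stop(what, " outside chromosome bounds")
  invisible(TRUE)
}

#' Do two genomic intervals overlap?
#'
#' Overlap means at least one shared base: on the same chromosome, with
#' half-open coordinates, `a.start < b.end && b.start < a.end`. Intervals
#' that merely abut do not overlap.
#'
#' @param a,b `GRanges` of length 1.
#' @return logical.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
#' intervals_overlap(a, b) # FALSE: adjacent, no shared base
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))) return(FALSE)
  GenomicRanges::start(a) <= GenomicRanges::end(b) &&
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}

#' Percent of reference peaks overlapped
#'
#' The overlap statistic quoted for two peak sets: `100 * n_overlap / n_ref`,
#' rounded to the nearest integer percent (the precision at which such
#' overlaps are reported).
#'
#' @param n_ref number of reference peaks (> 0).
#' @param n_overlap number of those with an overlap (`0 <= n_overlap <= n_ref`).
#' @return integer percent.
#' @examples
#' overlap_fraction(2132, 1612) # 76
#' @export
overlap_fraction <- function(n_ref, n_overlap) {
  if (length(n_ref) != 1L || n_ref <= 0) stop("n_ref must be a positive count")
  if (n_overlap < 0 || n_overlap > n_ref)
    stop("n_overlap must lie in [0, n_ref]")
  as.integer(round(100 * n_overlap / n_ref))
}

# internal: evaluate RNG-dependent code under a seed without disturbing the
# caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
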