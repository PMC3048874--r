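#' Tag libraries
#'
#' A tag is one uniquely mapped sequencing read, reduced to the genomic
#' position of its 5'-most aligned base plus the strand. A tag library is
#' the set of tags from one immunoprecipitation (one antibody in one
#' condition). Tags are stored as width-1 `GRanges` at the 5' base.
#'
#' @param tags width-1 `GRanges` with strand `+`/`-`.
#' @param sample_id sample identifier.
#' @param antibody one of `"total"`, `"pS15"`, `"pS46"` (or any label).
#' @param condition condition label (e.g. `"A"`, `"B"`).
#' @param genome optional [genome_def()]; when given, tags are checked to
#'   lie within it.
#' @return an object of class `"TagLibrary"`.
#' @export
tag_library <- function(tags, sample_id = "sample", antibody = "total",
                        condition = "A", genome = NULL) {
  stopifnot(methods::is(tags, "GRanges"))
  if (length(tags) && any(GenomicRanges::width(tags) != 1L))
    stop("tags must be width-1 ranges at the 5' base")
  st <- as.character(GenomicRanges::strand(tags))
  if (length(tags) && !all(st %in% c("+", "-")))
    stop("tag strand must be '+' or '-'")
  if (!is.null(genome) && length(tags)) check_within_genome(tags, genome, "tag")
  structure(list(sample_id = sample_id, antibody = antibody,
                 condition = condition, tags = tags,
                 depth = length(tags)),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary %s [%s / %s]: %d tags\n",
              x$sample_id, x$antibody, x$condition, x$depth))
  invisible(x)
}

#' Library depth (number of tags)
#' @param library a [tag_library()].
#' @export
library_depth <- function(library) library$depth

#' Read aligned tags from a BED6 file
#'
#' Each BED record is one uniquely mapped read. The tag position is the
#' 5'-most aligned base: BED `start` for `+` records, `end - 1` for `-`
#' records (BED end is exclusive). Record order is preserved.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand;
#'   uncompressed, tab- or space-separated).
#' @param genome optional [genome_def()] for bounds checking.
#' @inheritParams tag_library
#' @return a [tag_library()].
#' @export
read_tags <- function(path, genome = NULL, sample_id = basename(path),
                      antibody = "total", condition = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(tag_library(GenomicRanges::GRanges(), sample_id, antibody,
                       condition, genome))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, fill = FALSE,
                      colClasses = list(character = c(1, 4, 6))),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) {
    gr <- GenomicRanges::GRanges()
    return(tag_library(gr, sample_id, antibody, condition, genome))
  }
  if (ncol(dt) < 6L) stop("BED6 requires 6 columns, got ", ncol(dt))
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end0 <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(!is.finite(start0) | !is.finite(end0) | start0 < 0 |
                 end0 <= start0)
  if (length(bad))
    stop("malformed BED record at line ", bad[1], " of ", path)
  strand <- dt[[6]]
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr))
    stop("invalid strand '", strand[badstr[1]], "' at line ", badstr[1],
         " of ", path)
  pos5p0 <- ifelse(strand == "+", start0, end0 - 1)  # 0-based 5' base
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1]],
    ranges = IRanges::IRanges(start = pos5p0 + 1, width = 1L),
    strand = strand)
  if (!is.null(genome))
    GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
      names(genome), as.integer(genome))[GenomeInfoDb::seqlevels(gr)]
  tag_library(gr, sample_id, antibody, condition, genome)
}

#' Write a tag library as BED6
#'
#' Each tag is written as a 1-bp record whose 5' base round-trips through
#' [read_tags()] exactly.
#'
#' @param library a [tag_library()].
#' @param path output path.
#' @export
write_tags <- function(library, path) {
  gr <- library$tags
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::start(gr),
    name = if (length(gr)) paste0("tag", seq_along(gr)) else character(0),
    score = if (length(gr)) 0L else integer(0),
    strand = as.character(GenomicRanges::strand(gr)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Downsample a tag library to an exact depth
#'
#' Uniform sampling without replacement, reproducible for a fixed seed; the
#' result is a subset of the input tags with input order preserved.
#'
#' @param library a [tag_library()].
#' @param target number of tags to keep (`0 <= target <= depth`).
#' @param seed integer RNG seed.
#' @return a [tag_library()] of depth `target`.
#' @export
downsample_library <- function(library, target, seed) {
  stopifnot(inherits(library, "TagLibrary"))
  if (target < 0 || target > library$depth)
    stop("target depth ", target, " outside [0, ", library$depth, "]")
  if (target == library$depth) return(library)
  keep <- with_seed(seed, sort(sample.int(library$depth, target)))
  out <- library
  out$tags <- library$tags[keep]
  out$depth <- target
  out
}

#' Depth every library is normalized to
#'
#' Libraries are equalized by uniformly removing reads until every library
#' has the depth of the smallest one.
#'
#' @param depths numeric vector of library depths.
#' @return the common target depth: `min(depths)`.
#' @examples
#' normalized_depth(c(5.4, 6.1, 8.2, 5.3, 8.7, 6.8)) # 5.3 (millions)
#' @export
normalized_depth <- function(depths) {
  if (length(depths) == 0L) stop("no depths supplied")
  min(depths)
}

#' Normalize libraries to a common depth
#'
#' Between-sample normalization by uniform read removal: every library is
#' downsampled to the minimum depth across libraries.
#'
#' @param libraries list of [tag_library()] objects (at least 2).
#' @param seed integer seed; each library uses a sub-seed derived from it.
#' @return list of libraries, all with equal depth.
#' @export
normalize_libraries <- function(libraries, seed) {
  if (length(libraries) < 2L) stop("need at least two libraries to normalize")
  target <- normalized_depth(vapply(libraries, library_depth, numeric(1)))
  lapply(seq_along(libraries), function(i)
    downsample_library(libraries[[i]], target, seed + i))
}
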