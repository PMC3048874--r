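#' Gene models
#'
#' A gene model is one transcript: id, chromosome, strand, transcript
#' bounds, and exon structure. Coordinates in the data frame are BED-style
#' 0-based half-open (as read from refFlat/BED12); conversion to 1-based
#' `GRanges` happens inside the operations that need it.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `tx_start`, `tx_end` (0-based half-open) and `exon_starts`,
#'   `exon_ends` (comma-separated 0-based coordinates, refFlat style).
#' @return validated data.frame of class `"GeneModels"`.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    stop("gene model table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- as.data.frame(df)[need]
  if (any(!df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    es <- parse_coord_list(df$exon_starts[i])
    ee <- parse_coord_list(df$exon_ends[i])
    if (length(es) == 0L || length(es) != length(ee))
      stop("gene ", df$gene_id[i], ": exon lists empty or unequal")
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop("gene ", df$gene_id[i], ": exons must be sorted and non-overlapping")
    if (es[1] < df$tx_start[i] || ee[length(ee)] > df$tx_end[i])
      stop("gene ", df$gene_id[i], ": exons outside transcript bounds")
  }
  class(df) <- c("GeneModels", "data.frame")
  df
}

parse_coord_list <- function(s) {
  as.numeric(strsplit(sub(",$", "", as.character(s)), ",")[[1]])
}

#' Read gene models from refFlat or BED12
#'
#' Both common RefSeq export formats are accepted and normalized to the
#' same [gene_models()] table. refFlat columns: geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds (the transcript `name` is used as `gene_id` when distinct
#' gene/transcript names are present; `geneName` otherwise).
#'
#' @param path input file.
#' @param format `"refflat"` or `"bed12"`; `"auto"` decides by column count.
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path, format = c("auto", "refflat", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  # comma-separated block lists must never be sniffed as decimal commas
  dt <- data.table::fread(path, header = FALSE, colClasses = "character",
                          dec = ".")
  if (format == "auto")
    format <- if (ncol(dt) == 12L) "bed12" else "refflat"
  if (format == "refflat") {
    if (ncol(dt) != 11L) stop("refFlat requires 11 columns, got ", ncol(dt))
    df <- data.frame(gene_id = as.character(dt[[1]]),
                     chrom = as.character(dt[[3]]),
                     strand = as.character(dt[[4]]),
                     tx_start = as.numeric(dt[[5]]),
                     tx_end = as.numeric(dt[[6]]),
                     exon_starts = as.character(dt[[10]]),
                     exon_ends = as.character(dt[[11]]))
  } else {
    if (ncol(dt) != 12L) stop("BED12 requires 12 columns, got ", ncol(dt))
    start <- as.numeric(dt[[2]])
    sizes <- lapply(dt[[11]], parse_coord_list)
    offs <- lapply(dt[[12]], parse_coord_list)
    es <- mapply(function(s, o) paste(s + o, collapse = ","),
                 start, offs)
    ee <- mapply(function(s, o, z) paste(s + o + z, collapse = ","),
                 start, offs, sizes)
    df <- data.frame(gene_id = as.character(dt[[4]]),
                     chrom = as.character(dt[[1]]),
                     strand = as.character(dt[[6]]),
                     tx_start = start, tx_end = as.numeric(dt[[3]]),
                     exon_starts = es, exon_ends = ee)
  }
  gene_models(df)
}

#' Write gene models as refFlat
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  dt <- data.table::data.table(
    geneName = genes$gene_id, name = genes$gene_id, chrom = genes$chrom,
    strand = genes$strand, txStart = genes$tx_start, txEnd = genes$tx_end,
    cdsStart = genes$tx_start, cdsEnd = genes$tx_end,
    exonCount = vapply(genes$exon_starts,
                       function(s) length(parse_coord_list(s)), numeric(1)),
    exonStarts = genes$exon_starts, exonEnds = genes$exon_ends)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

REGION_CATEGORIES <- c("TSS_flank", "intragenic", "downstream_5kb",
                       "flank_5_25kb", "intergenic")

# internal: per-gene candidate regions per category, 0-based half-open,
# strand-aware; returns list of matrices (start0, end0)
gene_category_regions <- function(gene) {
  es <- parse_coord_list(gene$exon_starts)
  ee <- parse_coord_list(gene$exon_ends)
  n_ex <- length(es)
  s0 <- gene$tx_start; e0 <- gene$tx_end
  if (gene$strand == "+") {
    # TSS flank: 5 kb upstream + first exon + first intron
    tss_end <- if (n_ex >= 2L) es[2] else e0
    tss <- c(s0 - 5000, tss_end)
    intra <- if (n_ex >= 2L) c(es[2], e0) else NULL
    down <- c(e0, e0 + 5000)
  } else {
    tss_start <- if (n_ex >= 2L) ee[n_ex - 1L] else s0
    tss <- c(tss_start, e0 + 5000)
    intra <- if (n_ex >= 2L) c(s0, ee[n_ex - 1L]) else NULL
    down <- c(s0 - 5000, s0)
  }
  flank <- rbind(c(s0 - 25000, s0 - 5000), c(e0 + 5000, e0 + 25000))
  list(TSS_flank = rbind(tss), intragenic = if (is.null(intra)) NULL
       else rbind(intra), downstream_5kb = rbind(down), flank_5_25kb = flank)
}

#' Partition the genome into five annotation categories
#'
#' The categories, in precedence order, are: TSS-flanking region (5 kb
#' upstream of the transcription start site plus the first exon and first
#' intron), intragenic (all exons and introns except the first), 5 kb
#' downstream of the last exon, 5-25 kb up- or downstream of a gene, and
#' intergenic (everything else). Regions are built per transcript,
#' strand-aware, clipped to chromosome bounds, merged across transcripts,
#' and overlaps between categories are resolved by the precedence order so
#' the result is an exact partition of the genome.
#'
#' @param genes a [gene_models()] table (may have zero rows).
#' @param genome a [genome_def()].
#' @return an object of class `"RegionMap"`: list with `regions` (named
#'   list of `GRanges`) and `nucleotides` (named totals summing to the
#'   genome size).
#' @export
build_region_map <- function(genes, genome) {
  si <- genome_seqinfo(genome)
  empty <- GenomicRanges::GRanges(seqinfo = si)
  cats <- stats::setNames(
    rep(list(list()), 4), REGION_CATEGORIES[1:4])
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(genome))
      stop("gene ", g$gene_id, " on undefined chromosome ", g$chrom)
    sz <- unclass(genome)[[g$chrom]]
    regs <- gene_category_regions(g)
    for (cat in names(regs)) {
      m <- regs[[cat]]
      if (is.null(m)) next
      st0 <- pmax(m[, 1], 0); en0 <- pmin(m[, 2], sz)
      keep <- en0 > st0
      if (!any(keep)) next
      cats[[cat]] <- c(cats[[cat]], list(GenomicRanges::GRanges(
        g$chrom, IRanges::IRanges(st0[keep] + 1, en0[keep]), seqinfo = si)))
    }
  }
  merged <- lapply(cats, function(lst)
    if (length(lst)) GenomicRanges::reduce(do.call(c, lst)) else empty)
  regions <- list()
  claimed <- empty
  for (cat in REGION_CATEGORIES[1:4]) {
    r <- GenomicRanges::setdiff(merged[[cat]], claimed)
    regions[[cat]] <- r
    claimed <- GenomicRanges::reduce(c(claimed, r))
  }
  whole <- GenomicRanges::GRanges(names(genome),
                                  IRanges::IRanges(1, as.integer(genome)),
                                  seqinfo = si)
  regions[["intergenic"]] <- GenomicRanges::setdiff(whole, claimed)
  nt <- vapply(regions, function(r) sum(as.numeric(GenomicRanges::width(r))),
               numeric(1))
  structure(list(regions = regions, nucleotides = nt, genome = genome),
            class = "RegionMap")
}

#' @export
print.RegionMap <- function(x, ...) {
  cat("RegionMap (", sum(x$nucleotides), "bp )\n")
  print(x$nucleotides)
  invisible(x)
}

#' Genomic fraction of each annotation category
#'
#' The number of nucleotides in each category divided by the total number
#' of nucleotides in the genome; fractions sum to one because the map is a
#' partition.
#'
#' @param map a [build_region_map()] result.
#' @param genome a [genome_def()] (defaults to the map's genome).
#' @export
genomic_distribution <- function(map, genome = map$genome) {
  map$nucleotides / genome_size(genome)
}

#' Annotate peaks by the category of their summit
#'
#' Each peak gets the single category containing its summit base.
#'
#' @param peaks peak `GRanges` with a `summit` metadata column.
#' @param map a [build_region_map()] result.
#' @return list with `category` (factor per peak) and `counts` (per
#'   category, summing to the number of peaks).
#' @export
annotate_peaks <- function(peaks, map) {
  if (is.null(peaks$summit)) stop("peaks need a 'summit' metadata column")
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(peaks$summit, width = 1L))
  check_within_genome(pts, map$genome, "summit")
  category <- rep(NA_character_, length(peaks))
  for (cat in REGION_CATEGORIES) {
    hit <- GenomicRanges::countOverlaps(pts, map$regions[[cat]]) > 0L
    category[is.na(category) & hit] <- cat
  }
  category <- factor(category, levels = REGION_CATEGORIES)
  list(category = category,
       counts = stats::setNames(as.integer(table(category)),
                                REGION_CATEGORIES))
}

#' Category enrichment versus genomic background
#'
#' One-sided binomial upper-tail test per category: is the observed number
#' of peaks in the category larger than expected from the fraction of the
#' genome it occupies? P-values are Bonferroni-adjusted across the
#' categories.
#'
#' @param observed named integer vector of peak counts per category.
#' @param n_peaks total number of peaks.
#' @param expected_fraction named fractions per category (sum to 1).
#' @return data.frame with observed, expected, p, adjusted p, and an
#'   enrichment flag at adjusted p < 0.05.
#' @export
enrichment_test <- function(observed, n_peaks, expected_fraction) {
  if (abs(sum(expected_fraction) - 1) > 1e-6)
    stop("expected fractions must sum to 1")
  cats <- names(expected_fraction)
  obs <- observed[cats]
  p <- stats::pbinom(obs - 1, n_peaks, expected_fraction[cats],
                     lower.tail = FALSE)
  p_adj <- pmin(1, p * length(cats))
  data.frame(category = cats, observed = as.integer(obs),
             expected = n_peaks * as.numeric(expected_fraction[cats]),
             p = as.numeric(p), p_adj = as.numeric(p_adj),
             enriched = as.numeric(p_adj) < 0.05, row.names = NULL)
}

#' Assign peaks to nearby genes
#'
#' A peak is assigned to every gene whose transcript, extended by `flank`
#' bp on both sides, contains the peak summit (inclusive at the upstream
#' bound, exclusive at the downstream bound, in 0-based half-open terms).
#' Many-to-many assignments are allowed.
#'
#' @param peaks peak `GRanges` with `summit` and `name` columns.
#' @param genes a [gene_models()] table.
#' @param flank proximity window in bp (default 25000).
#' @return data.frame with columns `peak`, `gene_id`, `peak_index`,
#'   `gene_index`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, flank = 25000) {
  if (length(peaks) == 0L || nrow(genes) == 0L)
    return(data.frame(peak = character(0), gene_id = character(0),
                      peak_index = integer(0), gene_index = integer(0)))
  if (is.null(peaks$summit)) stop("peaks need a 'summit' metadata column")
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(peaks$summit, width = 1L))
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tx_start + 1 - flank),
                     genes$tx_end + flank))
  hit <- GenomicRanges::findOverlaps(pts, win)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  data.frame(peak = if (is.null(peaks$name)) as.character(qi)
             else peaks$name[qi],
             gene_id = genes$gene_id[si],
             peak_index = qi, gene_index = si)
}
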