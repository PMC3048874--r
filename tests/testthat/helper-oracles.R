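# Brute-force oracles and tiny fixture builders. Everything here is
# deliberately naive (per-base loops, exhaustive enumeration) and
# independent of the package's vectorized implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

with_seed_for_tests <- function(seed, expr) {
  set.seed(seed)
  expr
}

make_tags <- function(chrom, pos5_0based, strand, genome = NULL, ...) {
  gr <- GRanges(chrom, IRanges(pos5_0based + 1, width = 1L), strand = strand)
  tag_library(gr, genome = genome, ...)
}

gr1 <- function(chrom, start1, end1) GRanges(chrom, IRanges(start1, end1))

# per-base depth by counting, 0/1-based handled via 1-based closed ints
bf_perbase_depth <- function(frag_start1, frag_end1, chrom_of, chrom, size) {
  depth <- numeric(size)
  keep <- which(chrom_of == chrom)
  for (i in keep) {
    s <- max(1L, frag_start1[i]); e <- min(size, frag_end1[i])
    if (s <= e) depth[s:e] <- depth[s:e] + 1
  }
  depth
}

bf_window_means <- function(depth, window) {
  n_win <- ceiling(length(depth) / window)
  vapply(seq_len(n_win), function(w) {
    lo <- (w - 1L) * window + 1L
    hi <- min(w * window, length(depth))
    mean(depth[lo:hi])
  }, numeric(1))
}

# extended fragment interval (1-based closed) for a tag
bf_extend <- function(pos5_0, strand, len, size) {
  if (strand == "+") c(pos5_0 + 1, min(size, pos5_0 + len))
  else c(max(1, pos5_0 + 1 - len + 1), pos5_0 + 1)
}

# pairwise overlap counting for RPP
bf_rpp <- function(peak_start1, peak_end1, peak_chrom, frag_start1,
                   frag_end1, frag_chrom) {
  vapply(seq_along(peak_start1), function(i) {
    sum(frag_chrom == peak_chrom[i] &
          frag_start1 <= peak_end1[i] & peak_start1[i] <= frag_end1)
  }, numeric(1))
}

# KS D as the sup of |ECDF_x - ECDF_y| over all observed points
bf_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# exhaustive motif scan using only score_site on substrings
bf_scan_best <- function(model, seq) {
  seq <- toupper(seq)
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
  n <- nchar(seq)
  best <- -Inf
  for (spacer in model$spacer_range) {
    L <- 20 + spacer
    if (n < L) next
    for (s in seq_len(n - L + 1)) {
      best <- max(best,
                  score_site(model, substr(seq, s, s + L - 1), spacer),
                  score_site(model, substr(rc, s, s + L - 1), spacer))
    }
  }
  best
}

# the worked one-gene annotation example: '+' gene on a 100 kb chromosome,
# tx [30000,40000), exons [30000,31000) and [35000,40000) (0-based)
toy_gene_plus <- function() {
  gene_models(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    tx_start = 30000, tx_end = 40000,
    exon_starts = "30000,35000", exon_ends = "31000,40000"))
}

toy_gene_minus <- function() {
  gene_models(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "-",
    tx_start = 30000, tx_end = 40000,
    exon_starts = "30000,35000", exon_ends = "31000,40000"))
}

# peaks GRanges with summits, minimal metadata
toy_peaks <- function(chrom, start1, end1, summit = NULL) {
  gr <- GRanges(chrom, IRanges(start1, end1))
  if (is.null(summit)) summit <- floor((start1 + end1) / 2)
  mcols(gr) <- S4Vectors::DataFrame(name = paste0("p", seq_along(gr)),
                                    summit = summit,
                                    height = rep(10L, length(gr)),
                                    pvalue = rep(1e-9, length(gr)))
  gr
}

# category of a single base (1-based) by direct reading of the region
# definitions, used for the per-base partition oracle
region_of_base <- function(map, chrom, pos1) {
  for (cat in names(map$regions)) {
    r <- map$regions[[cat]]
    idx <- which(as.character(seqnames(r)) == chrom &
                   start(r) <= pos1 & end(r) >= pos1)
    if (length(idx)) return(cat)
  }
  NA_character_
}
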