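test_that("refFlat and BED12 gene models normalize to the same table", {
  # the toy gene in both interchange formats
  rf <- tempfile(); b12 <- tempfile()
  writeLines("g1\tg1\tchr1\t+\t30000\t40000\t30000\t40000\t2\t30000,35000,\t31000,40000,",
             rf)
  writeLines("chr1\t30000\t40000\tg1\t0\t+\t30000\t40000\t0\t2\t1000,5000\t0,5000",
             b12)
  g_rf <- read_gene_models(rf)
  g_b12 <- read_gene_models(b12)
  expect_equal(g_rf$tx_start, 30000)
  expect_equal(g_b12$exon_starts, "30000,35000")
  expect_equal(g_b12$exon_ends, "31000,40000")
  expect_equal(p53occupancy:::parse_coord_list(g_rf$exon_starts),
               p53occupancy:::parse_coord_list(g_b12$exon_starts))
  # both feed the same region map
  gn <- genome_def(c(chr1 = 100000L))
  expect_equal(build_region_map(g_b12, gn)$nucleotides,
               build_region_map(toy_gene_plus(), gn)$nucleotides)
  # malformed exon structure is rejected
  expect_error(gene_models(data.frame(
    gene_id = "bad", chrom = "chr1", strand = "+", tx_start = 0,
    tx_end = 100, exon_starts = "0,50", exon_ends = "60,100")),
    "non-overlapping")
})

test_that("the worked one-gene region map matches the category definitions", {
  gn <- genome_def(c(chr1 = 100000L))
  map <- build_region_map(toy_gene_plus(), gn)
  # expectations in 0-based half-open coordinates
  as0 <- function(gr) cbind(GenomicRanges::start(gr) - 1L,
                            GenomicRanges::end(gr))
  expect_equal(as0(map$regions$TSS_flank), cbind(25000L, 35000L))
  expect_equal(as0(map$regions$intragenic), cbind(35000L, 40000L))
  expect_equal(as0(map$regions$downstream_5kb), cbind(40000L, 45000L))
  expect_equal(as0(map$regions$flank_5_25kb),
               cbind(c(5000L, 45000L), c(25000L, 65000L)))
  expect_equal(sum(map$nucleotides), 100000)
  expect_equal(unname(map$nucleotides["intergenic"]), 100000 - 60000)

  dist <- genomic_distribution(map, gn)
  expect_equal(unname(dist["TSS_flank"]), 0.10)
  expect_equal(sum(dist), 1, tolerance = 1e-12)
})

test_that("a minus-strand gene produces the mirror-image layout", {
  gn <- genome_def(c(chr1 = 100000L))
  map <- build_region_map(toy_gene_minus(), gn)
  as0 <- function(gr) cbind(GenomicRanges::start(gr) - 1L,
                            GenomicRanges::end(gr))
  # TSS at tx_end side: 5 kb up (right) + first exon [35000,40000) + first
  # intron [31000,35000)
  expect_equal(as0(map$regions$TSS_flank), cbind(31000L, 45000L))
  expect_equal(as0(map$regions$intragenic), cbind(30000L, 31000L))
  expect_equal(as0(map$regions$downstream_5kb), cbind(25000L, 30000L))
  expect_equal(as0(map$regions$flank_5_25kb),
               cbind(c(5000L, 45000L), c(25000L, 65000L)))
  expect_equal(sum(map$nucleotides), 100000)
})

test_that("region maps are exact partitions, checked per base", {
  gn <- genome_def(c(chr1 = 150000L, chr2 = 50000L))
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(30000, 33000, 2000), # g1/g2 overlap; g3 near chrom edge
    tx_end = c(40000, 42000, 9000),
    exon_starts = c("30000,35000", "33000,38000", "2000"),
    exon_ends = c("31000,40000", "34000,42000", "9000")))
  map <- build_region_map(genes, gn)
  expect_equal(sum(map$nucleotides), 200000)
  # no base in two categories: total width of the union equals genome size
  all_gr <- do.call(c, unname(map$regions))
  expect_equal(sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(all_gr)))), 200000)
  # spot-check random bases against a direct region lookup
  set.seed(99)
  for (i in 1:50) {
    chrom <- sample(c("chr1", "chr2"), 1)
    pos <- sample.int(unclass(gn)[[chrom]], 1)
    hits <- vapply(map$regions, function(r)
      any(as.character(GenomicRanges::seqnames(r)) == chrom &
            GenomicRanges::start(r) <= pos & GenomicRanges::end(r) >= pos),
      logical(1))
    expect_equal(sum(hits), 1L)
  }
  # single-exon gene: its first exon lives in TSS_flank
  tss3 <- map$regions$TSS_flank
  g3_exon <- gr1("chr2", 2001, 9000)
  ov <- GenomicRanges::intersect(tss3, g3_exon)
  expect_equal(sum(GenomicRanges::width(ov)), 7000)
})

test_that("an empty gene list leaves everything intergenic", {
  gn <- genome_def(c(chr1 = 80000L))
  map <- build_region_map(gene_models(data.frame(
    gene_id = character(0), chrom = character(0), strand = character(0),
    tx_start = numeric(0), tx_end = numeric(0),
    exon_starts = character(0), exon_ends = character(0))), gn)
  expect_equal(unname(map$nucleotides["intergenic"]), 80000)
  expect_equal(unname(genomic_distribution(map)["intergenic"]), 1.0)
})

test_that("peaks are annotated by summit and counts are order-invariant", {
  gn <- genome_def(c(chr1 = 100000L))
  map <- build_region_map(toy_gene_plus(), gn)
  peaks <- toy_peaks("chr1", c(26000, 36000, 41000, 10000, 70000),
                     c(26200, 36200, 41200, 10200, 70200),
                     summit = c(26100, 36100, 41100, 10100, 70100))
  ann <- annotate_peaks(peaks, map)
  expect_equal(as.character(ann$category),
               c("TSS_flank", "intragenic", "downstream_5kb", "flank_5_25kb",
                 "intergenic"))
  expect_equal(sum(ann$counts), length(peaks))
  shuffled <- annotate_peaks(peaks[c(3, 1, 5, 2, 4)], map)
  expect_equal(shuffled$counts, ann$counts)
  bad <- toy_peaks("chr1", 99990, 99999, summit = 100005)
  expect_error(annotate_peaks(bad, map), "bounds")
})

test_that("binomial enrichment matches exact tail summation", {
  frac <- c(a = 0.1, b = 0.2, c = 0.7)
  obs <- c(a = 20, b = 10, c = 20)
  res <- enrichment_test(obs, 50, frac)
  exact_tail <- function(k, n, p) sum(dbinom(k:n, n, p))
  for (i in 1:3)
    expect_equal(res$p[i], exact_tail(obs[i], 50, frac[i]))
  expect_equal(res$p_adj, pmin(1, res$p * 3))
  expect_true(res$enriched[1])  # 20/50 observed vs 10% expected
  expect_false(res$enriched[3]) # below expectation cannot be enriched
  expect_error(enrichment_test(obs, 50, c(a = 0.5, b = 0.2, c = 0.2)),
               "sum to 1")
})

test_that("peak-to-gene assignment uses an inclusive-exclusive 25 kb window", {
  gn <- genome_def(c(chr1 = 200000L))
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    tx_start = c(50000, 150000, 160000), tx_end = c(60000, 155000, 165000),
    exon_starts = c("50000", "150000", "160000"),
    exon_ends = c("60000", "155000", "165000")))
  # summits in 1-based coordinates; tx_start - 25000 is 0-based inclusive
  at <- function(summit1) toy_peaks("chr1", summit1 - 50, summit1 + 50,
                                    summit = summit1)
  expect_equal(assign_peaks_to_genes(at(25001), genes)$gene_id, "g1")
  expect_equal(nrow(assign_peaks_to_genes(at(25000), genes)), 0L)
  expect_equal(assign_peaks_to_genes(at(85000), genes)$gene_id, "g1")
  expect_equal(nrow(assign_peaks_to_genes(at(85001), genes)), 0L)
  # a summit between g2 and g3 maps to both (many-to-many allowed)
  both <- assign_peaks_to_genes(at(157000), genes)
  expect_setequal(both$gene_id, c("g2", "g3"))

  # toy fixture vs brute-force distance check
  set.seed(17)
  summits <- sample(20000:140000, 30)
  got <- assign_peaks_to_genes(toy_peaks("chr1", summits - 10, summits + 10,
                                         summit = summits), genes)
  for (i in seq_along(summits)) {
    for (j in 1:3) {
      inside <- summits[i] - 1 >= genes$tx_start[j] - 25000 &&
        summits[i] - 1 < genes$tx_end[j] + 25000
      expect_equal(any(got$peak_index == i & got$gene_index == j), inside)
    }
  }
})
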