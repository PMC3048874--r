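# a smaller-than-default study for fast structural checks
small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed,
                    chrom_sizes = c(chr1 = 200000L, chr2 = 200000L),
                    n_genes = 30, n_sites = 50, n_responsive = 10, ...)
}

test_that("the generator is deterministic given config and seed", {
  b1 <- simulate_study(small_config(seed = 7))
  b2 <- simulate_study(small_config(seed = 7))
  expect_identical(b1$truth_sites, b2$truth_sites)
  expect_identical(b1$truth_genes, b2$truth_genes)
  expect_identical(b1$expression$values, b2$expression$values)
  expect_identical(as.character(b1$sequence), as.character(b2$sequence))
  for (nm in names(b1$libraries))
    expect_identical(GenomicRanges::start(b1$libraries[[nm]]$tags),
                     GenomicRanges::start(b2$libraries[[nm]]$tags))
  b3 <- simulate_study(small_config(seed = 8))
  expect_false(identical(b1$truth_sites$center, b3$truth_sites$center))
})

test_that("the bundle is internally consistent with its truth tables", {
  b <- simulate_study(small_config(seed = 3))
  cfg <- b$config
  expect_equal(nrow(b$truth_sites), cfg$n_sites)
  expect_equal(sum(b$truth_sites$responsive), cfg$n_responsive)
  expect_equal(sum(b$truth_genes$responsive), cfg$n_responsive)
  # responsive sites sit within the proximity window of their gene
  resp <- b$truth_sites[b$truth_sites$responsive, ]
  for (i in seq_len(nrow(resp))) {
    g <- b$genes[b$genes$gene_id == resp$gene_id[i], ]
    expect_equal(g$chrom, resp$chrom[i])
    expect_gte(resp$center[i], g$tx_start - 25000)
    expect_lte(resp$center[i], g$tx_end + 25000)
  }
  # responsive sites carry the strongest enrichment and the B-specific
  # phosphorylation fraction
  expect_gt(min(resp$strength),
            max(b$truth_sites$strength[!b$truth_sites$responsive]) - 1e-9)
  expect_true(all(resp$f46_B == cfg$f46_responsive_B))
  expect_true(all(b$truth_sites$f46_A == cfg$f46_base))
  # six libraries, three antibodies x two conditions
  expect_setequal(names(b$libraries),
                  c("total_A", "total_B", "pS15_A", "pS15_B",
                    "pS46_A", "pS46_B"))
  # thinning: phospho libraries are sparser than total
  expect_lt(library_depth(b$libraries$pS46_A),
            library_depth(b$libraries$total_A))
})

test_that("implanted motifs are present at every site center", {
  b <- simulate_study(small_config(seed = 5))
  m <- default_p53_model()
  idx <- seq(1, nrow(b$truth_sites), by = 5)
  for (i in idx) {
    chr <- b$truth_sites$chrom[i]
    ctr <- b$truth_sites$center[i]
    core <- Biostrings::subseq(b$sequence[[chr]], ctr - 100, ctr + 99)
    hit <- scan_region(m, core)
    expect_false(is.null(hit))
    # the implant sits 91 bases into the 200-bp core (0-based)
    expect_equal(hit$position, 91)
  }
  b0 <- simulate_study(small_config(seed = 5, motif_implant = FALSE))
  expect_true(all(is.na(b0$truth_sites$motif_pos)))
})

test_that("with equal phospho fractions the two pS46 libraries are exchangeable", {
  for (seed in 1:3) {
    b <- simulate_study(small_config(seed = seed,
                                     f46_responsive_B = 0.1))
    sites <- GenomicRanges::GRanges(
      b$truth_sites$chrom,
      IRanges::IRanges(b$truth_sites$center - 100,
                       b$truth_sites$center + 100))
    norm <- normalize_libraries(b$libraries[c("pS46_A", "pS46_B")],
                                seed = seed)
    rA <- reads_per_peak(sites, norm[[1]], genome = b$genome)
    rB <- reads_per_peak(sites, norm[[2]], genome = b$genome)
    expect_gt(ks_two_sample(rA, rB)$p.value, 0.01)
  }
})

test_that("recovery metrics implement their definitions", {
  b <- simulate_study(small_config(seed = 9))
  truth <- b$truth_sites
  perfect <- toy_peaks(truth$chrom, pmax(1, truth$center - 133),
                       truth$center + 133, summit = truth$center)
  rep <- recovery_report(truth, perfect, rpp = truth$strength)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$fdr, 0.0)
  expect_equal(rep$rpp_strength_spearman, 1.0)

  none <- recovery_report(truth, GenomicRanges::GRanges())
  expect_equal(none$sensitivity, 0.0)

  # peaks placed away from every site are all false discoveries
  shifted <- toy_peaks(truth$chrom, truth$center + 600, truth$center + 800,
                       summit = truth$center + 700)
  far <- recovery_report(truth, shifted)
  expect_equal(far$sensitivity, 0.0)
  expect_equal(far$fdr, 1.0)

  cm <- candidate_metrics(b$truth_genes,
                          b$truth_genes$gene_id[b$truth_genes$responsive])
  expect_equal(cm$precision, 1.0)
  expect_equal(cm$recall, 1.0)
  half <- candidate_metrics(
    b$truth_genes, b$truth_genes$gene_id[b$truth_genes$responsive][1:5])
  expect_equal(half$recall, 0.5)
})

test_that("a written bundle lists and round-trips its files", {
  b <- simulate_study(small_config(seed = 2))
  out <- tempfile("bundle")
  write_study(b, out)
  manifest <- readLines(file.path(out, "MANIFEST"))
  expect_true(all(file.exists(file.path(out, manifest))))
  lib <- read_tags(file.path(out, "tags_total_A.bed"), genome = b$genome)
  expect_equal(library_depth(lib), library_depth(b$libraries$total_A))
  expect_identical(GenomicRanges::start(lib$tags),
                   GenomicRanges::start(b$libraries$total_A$tags))
  genes <- read_gene_models(file.path(out, "genes.refflat.tsv"))
  expect_equal(genes$gene_id, b$genes$gene_id)
  expect_equal(genes$tx_start, b$genes$tx_start)
  sq <- Biostrings::readDNAStringSet(file.path(out, "genome.fa"))
  expect_equal(as.character(sq), as.character(b$sequence))
  md <- read.delim(file.path(out, "expression_metadata.tsv"))
  et <- read_expression(file.path(out, "expression.tsv"), md)
  expect_equal(et$values, b$expression$values, tolerance = 1e-9)
  unlink(out, recursive = TRUE)
})
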