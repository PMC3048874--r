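#' Configuration of a synthetic two-treatment phospho-p53 study
#'
#' Defines a miniature study with the statistical structure the pipeline
#' assumes: two conditions (A: growth-arrest-biased, B: apoptosis-biased)
#' x three antibodies (total p53, pS15, pS46) sharing one set of binding
#' sites; site-specific enrichment strengths; condition- and site-specific
#' phosphorylation fractions; Poisson background; and an expression matrix
#' in which a subset of site-proximal genes responds only in condition B.
#'
#' Defaults define the study conditions used throughout the package's
#' validation (see the methods vignette for the rationale): a 2 x 500 kb
#' genome, 60 genes, 120 sites of which the 20 strongest are
#' "B-responsive" (their bound p53 is S46-phosphorylated at fraction 0.5
#' in condition B versus the basal 0.1, and their nearest designated gene
#' changes expression in condition B only).
#'
#' @param seed integer seed; with the config it determines the bundle
#'   byte-for-byte.
#' @param chrom_sizes named chromosome lengths.
#' @param n_genes number of genes.
#' @param n_sites number of binding sites.
#' @param n_responsive number of B-responsive sites (each tied to one
#'   designated responsive gene).
#' @param strength site strength distribution: expected fragments per site
#'   in a total-p53 library. `list(type = "lognormal", meanlog, sdlog)` or
#'   `list(type = "fixed", value)`.
#' @param background_rate background tags per bp per total-p53 library.
#' @param f15 fraction of bound p53 phosphorylated at S15 (both
#'   conditions).
#' @param f46_base basal fraction phosphorylated at S46.
#' @param f46_responsive_B S46 fraction at responsive sites in condition B.
#' @param fragment_length sequenced fragment length in bp.
#' @param expr_effect mean true log2 change (24h/0h) of responsive genes
#'   in condition B.
#' @param expr_effect_sd spread of that effect.
#' @param expr_null_sd spread of true changes of non-responsive genes.
#' @param expr_noise_sd replicate-level measurement noise (log2 scale).
#' @param motif_implant implant a perfect consensus response element at
#'   each site center in the genome sequence.
#' @return a `"SimulationConfig"` list.
#' @export
simulation_config <- function(seed = 1,
                              chrom_sizes = c(chr1 = 500000L, chr2 = 500000L),
                              n_genes = 60,
                              n_sites = 120,
                              n_responsive = 20,
                              strength = list(type = "lognormal",
                                              meanlog = log(45), sdlog = 0.4),
                              background_rate = 0.01,
                              f15 = 0.5,
                              f46_base = 0.1,
                              f46_responsive_B = 0.5,
                              fragment_length = 133,
                              expr_effect = 1.5,
                              expr_effect_sd = 0.2,
                              expr_null_sd = 0.05,
                              expr_noise_sd = 0.05,
                              motif_implant = TRUE) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("f15", "f46_base", "f46_responsive_B")]) >= 0),
            all(unlist(cfg[c("f15", "f46_base", "f46_responsive_B")]) <= 1),
            background_rate > 0, n_sites >= n_responsive,
            n_genes >= n_responsive, fragment_length >= 1)
  structure(cfg, class = "SimulationConfig")
}

# internal: draw site strengths per config
draw_strengths <- function(cfg, n) {
  switch(cfg$strength$type,
         lognormal = stats::rlnorm(n, cfg$strength$meanlog,
                                   cfg$strength$sdlog),
         fixed = rep(cfg$strength$value, n),
         stop("unknown strength distribution type ", cfg$strength$type))
}

# internal: lay out non-overlapping gene models on the genome
place_genes <- function(cfg, genome) {
  sizes <- unclass(genome)
  per_chr <- table(factor(sample(names(sizes), cfg$n_genes, replace = TRUE,
                                 prob = sizes / sum(sizes)),
                          levels = names(sizes)))
  rows <- list()
  gid <- 0L
  for (chr in names(sizes)) {
    n <- per_chr[[chr]]
    if (!n) next
    # even slots with jitter keep genes separated
    slot <- sizes[[chr]] / n
    for (j in seq_len(n)) {
      gid <- gid + 1L
      tx_len <- round(stats::runif(1, 2000, 8000))
      lo <- round((j - 1) * slot + 0.1 * slot)
      hi <- round(j * slot - 0.1 * slot) - tx_len
      tx_start <- if (hi > lo) round(stats::runif(1, lo, hi)) else lo
      tx_end <- tx_start + tx_len
      n_ex <- sample(2:6, 1)
      cuts <- sort(sample(seq(tx_start + 100, tx_end - 100, by = 50),
                          2 * (n_ex - 1)))
      es <- c(tx_start, cuts[seq(2, length(cuts), by = 2)])
      ee <- c(cuts[seq(1, length(cuts), by = 2)], tx_end)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("gene_%03d", gid), chrom = chr,
        strand = sample(c("+", "-"), 1),
        tx_start = tx_start, tx_end = tx_end,
        exon_starts = paste(es, collapse = ","),
        exon_ends = paste(ee, collapse = ","))
    }
  }
  gene_models(do.call(rbind, rows))
}

# internal: site positions; responsive sites inside their gene's proximity
# window, all sites >= min_gap apart and away from chromosome edges
place_sites <- function(cfg, genome, genes, responsive_genes,
                        min_gap = 1500) {
  sizes <- unclass(genome)
  centers <- data.frame(chrom = character(0), center = numeric(0),
                        gene_id = character(0))
  add_site <- function(chr, pos, gene_id = NA_character_) {
    clash <- centers$chrom == chr & abs(centers$center - pos) <= 2 * min_gap
    if (any(clash)) return(FALSE)
    centers[nrow(centers) + 1L, ] <<- list(chr, pos, gene_id)
    TRUE
  }
  for (g in responsive_genes) {
    row <- genes[genes$gene_id == g, ]
    for (try in 1:50) {
      pos <- round(stats::runif(1, max(200, row$tx_start - 10000),
                                min(sizes[[row$chrom]] - 200,
                                    row$tx_end + 10000)))
      if (add_site(row$chrom, pos, g)) break
    }
  }
  while (nrow(centers) < cfg$n_sites) {
    chr <- sample(names(sizes), 1, prob = sizes / sum(sizes))
    pos <- round(stats::runif(1, 200, sizes[[chr]] - 200))
    add_site(chr, pos)
  }
  centers
}

# internal: tags for one library given per-site expected fragment counts
draw_library_tags <- function(sites, site_mean, bg_rate, genome, frag_len) {
  sizes <- unclass(genome)
  half <- floor(frag_len / 2)
  chrom <- character(0); center <- numeric(0)
  # background fragment centers, uniform
  for (chr in names(sizes)) {
    n_bg <- stats::rpois(1, bg_rate * sizes[[chr]])
    chrom <- c(chrom, rep(chr, n_bg))
    center <- c(center, round(stats::runif(n_bg, 1, sizes[[chr]])))
  }
  # site fragments: centers uniform within +/- half around the site
  for (i in seq_len(nrow(sites))) {
    n_i <- stats::rpois(1, site_mean[i])
    if (!n_i) next
    chrom <- c(chrom, rep(sites$chrom[i], n_i))
    center <- c(center, round(stats::runif(n_i, sites$center[i] - half,
                                           sites$center[i] + half)))
  }
  strand <- sample(c("+", "-"), length(center), replace = TRUE)
  pos5 <- ifelse(strand == "+", center - half, center + half)
  pos5 <- pmin(pmax(pos5, 1), sizes[chrom])
  ord <- order(chrom, pos5)
  GenomicRanges::GRanges(chrom[ord], IRanges::IRanges(pos5[ord], width = 1L),
                         strand = strand[ord])
}

#' Generate a synthetic study bundle
#'
#' Produces, deterministically for a given config (whose seed covers all
#' randomness), the complete in-memory inputs of the pipeline plus the
#' truth tables used for parameter-recovery scoring: genome definition and
#' sequence, gene models, six tag libraries (3 antibodies x 2 conditions),
#' the expression table, and per-site/per-gene truth.
#'
#' Generative model: background tags are uniform Poisson per bp; each site
#' adds Poisson(strength x thinning) fragments whose centers fall within
#' half a fragment length of the site center, so extension recovers the
#' site; the modification-specific libraries are thinned copies of the
#' total-p53 fragment process (a bound protein is phosphorylated with the
#' site's modification fraction), including thinned background. Responsive
#' genes change expression (log2) in condition B only; replicates add
#' Gaussian noise.
#'
#' @param config a [simulation_config()].
#' @return a `"StudyBundle"` list: `genome`, `sequence` (`DNAStringSet`),
#'   `genes`, `libraries` (named list of [tag_library()]:
#'   `total_A` ... `pS46_B`), `expression` ([expression_table()]),
#'   `truth_sites`, `truth_genes`, and the `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  genome <- genome_def(cfg$chrom_sizes)
  with_seed(cfg$seed, {
    genes <- place_genes(cfg, genome)
    responsive_genes <- sort(sample(genes$gene_id, cfg$n_responsive))
    sites <- place_sites(cfg, genome, genes, responsive_genes)
    strengths <- draw_strengths(cfg, cfg$n_sites)
    # responsive sites take the largest strengths: the B-specific S46
    # signal sits at strong sites, mirroring the top-quintile contrast
    strengths <- sort(strengths)
    responsive <- !is.na(sites$gene_id)
    strength <- numeric(cfg$n_sites)
    strength[responsive] <- utils::tail(strengths, sum(responsive))
    strength[!responsive] <- utils::head(strengths, sum(!responsive))
    f46_A <- rep(cfg$f46_base, cfg$n_sites)
    f46_B <- ifelse(responsive, cfg$f46_responsive_B, cfg$f46_base)

    libs <- list()
    for (cond in c("A", "B")) {
      f46 <- if (cond == "A") f46_A else f46_B
      spec <- list(total = list(thin = rep(1, cfg$n_sites), bg = 1),
                   pS15 = list(thin = rep(cfg$f15, cfg$n_sites),
                               bg = cfg$f15),
                   pS46 = list(thin = f46, bg = cfg$f46_base))
      for (ab in names(spec)) {
        tags <- draw_library_tags(
          sites, strength * spec[[ab]]$thin,
          cfg$background_rate * spec[[ab]]$bg, genome, cfg$fragment_length)
        libs[[paste0(ab, "_", cond)]] <- tag_library(
          tags, sample_id = paste0(ab, "_", cond), antibody = ab,
          condition = cond, genome = genome)
      }
    }

    # genome sequence: i.i.d. uniform bases, consensus implanted at sites
    base_chars <- lapply(names(genome), function(chr)
      sample(c("A", "C", "G", "T"), unclass(genome)[[chr]], replace = TRUE))
    names(base_chars) <- names(genome)
    motif_pos <- rep(NA_integer_, cfg$n_sites)
    if (cfg$motif_implant) {
      consensus <- strsplit("GGGCATGTCCGGGCATGTCC", "")[[1]]
      for (i in seq_len(cfg$n_sites)) {
        st <- sites$center[i] - 9L # site centered on the peak center
        base_chars[[sites$chrom[i]]][st:(st + 19L)] <- consensus
        motif_pos[i] <- st
      }
    }
    sequence <- Biostrings::DNAStringSet(vapply(base_chars, paste,
                                                character(1), collapse = ""))
    names(sequence) <- names(genome)

    # expression: true change per gene per condition, duplicate arrays
    true_A <- stats::rnorm(cfg$n_genes, 0, cfg$expr_null_sd)
    true_B <- stats::rnorm(cfg$n_genes, 0, cfg$expr_null_sd)
    is_resp <- genes$gene_id %in% responsive_genes
    true_B[is_resp] <- stats::rnorm(sum(is_resp), cfg$expr_effect,
                                    cfg$expr_effect_sd)
    baseline <- stats::rnorm(cfg$n_genes, 7, 1)
    md <- expand.grid(replicate = 1:2, timepoint = c("0h", "24h"),
                      condition = c("A", "B"), stringsAsFactors = FALSE)
    md$sample <- sprintf("%s_%s_r%d", md$condition, md$timepoint,
                         md$replicate)
    vals <- sapply(seq_len(nrow(md)), function(j) {
      mu <- baseline
      if (md$timepoint[j] == "24h")
        mu <- mu + if (md$condition[j] == "A") true_A else true_B
      mu + stats::rnorm(cfg$n_genes, 0, cfg$expr_noise_sd)
    })
    colnames(vals) <- md$sample
    rownames(vals) <- genes$gene_id
    expr <- expression_table(vals, md[c("sample", "condition", "timepoint",
                                        "replicate")])

    truth_sites <- data.frame(
      site = sprintf("site_%03d", seq_len(cfg$n_sites)),
      chrom = sites$chrom, center = sites$center,
      strength = strength, f46_A = f46_A, f46_B = f46_B,
      f15 = cfg$f15, responsive = responsive,
      gene_id = sites$gene_id, motif_pos = motif_pos)
    truth_genes <- data.frame(
      gene_id = genes$gene_id, responsive = is_resp,
      true_change_A = true_A, true_change_B = true_B)

    structure(list(genome = genome, sequence = sequence, genes = genes,
                   libraries = libs, expression = expr,
                   truth_sites = truth_sites, truth_genes = truth_genes,
                   config = cfg),
              class = "StudyBundle")
  })
}

#' Write a study bundle to disk
#'
#' Emits plain-text files: genome FASTA and chrom.sizes, refFlat gene
#' models, six BED6 tag files, the expression TSV with its metadata TSV,
#' the two truth TSVs, and a MANIFEST listing every file.
#'
#' @param bundle a [simulate_study()] result.
#' @param outdir output directory (created if needed).
#' @export
write_study <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  files <- c("genome.fa", "chrom.sizes", "genes.refflat.tsv",
             paste0("tags_", names(bundle$libraries), ".bed"),
             "expression.tsv", "expression_metadata.tsv",
             "truth_sites.tsv", "truth_genes.tsv")
  Biostrings::writeXStringSet(bundle$sequence, p("genome.fa"))
  write_chrom_sizes(bundle$genome, p("chrom.sizes"))
  write_gene_models(bundle$genes, p("genes.refflat.tsv"))
  for (nm in names(bundle$libraries))
    write_tags(bundle$libraries[[nm]], p(paste0("tags_", nm, ".bed")))
  ev <- data.table::data.table(gene_id = rownames(bundle$expression$values),
                               bundle$expression$values)
  data.table::fwrite(ev, p("expression.tsv"), sep = "\t")
  data.table::fwrite(bundle$expression$metadata, p("expression_metadata.tsv"),
                     sep = "\t")
  data.table::fwrite(bundle$truth_sites, p("truth_sites.tsv"), sep = "\t")
  data.table::fwrite(bundle$truth_genes, p("truth_genes.tsv"), sep = "\t")
  writeLines(files, p("MANIFEST"))
  invisible(p("MANIFEST"))
}

#' Score pipeline output against the simulation truth
#'
#' A true site is recovered when some called peak has its summit within
#' `match_bp` of the site center; a called peak is a false discovery when
#' its summit is not within `match_bp` of any site center.
#'
#' @param truth_sites `truth_sites` table from a [simulate_study()] bundle.
#' @param peaks called peak `GRanges` with `summit`.
#' @param rpp optional RPP vector parallel to `peaks`; when given, the
#'   Spearman correlation between matched peaks' RPP and the true site
#'   strengths is reported.
#' @param match_bp match radius in bp (default 200).
#' @return list with `sensitivity`, `fdr`, `n_sites`, `n_peaks`,
#'   `rpp_strength_spearman` (NA without `rpp`), and the per-site
#'   `recovered` flags.
#' @export
recovery_report <- function(truth_sites, peaks, rpp = NULL, match_bp = 200) {
  site_gr <- GenomicRanges::GRanges(
    truth_sites$chrom, IRanges::IRanges(truth_sites$center, width = 1L))
  if (length(peaks)) {
    summit_gr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(peaks),
      IRanges::IRanges(peaks$summit, width = 1L))
    hit <- GenomicRanges::findOverlaps(
      site_gr, summit_gr, maxgap = match_bp)
    recovered <- seq_along(site_gr) %in% S4Vectors::queryHits(hit)
    peak_true <- seq_along(summit_gr) %in% S4Vectors::subjectHits(hit)
  } else {
    recovered <- rep(FALSE, length(site_gr))
    peak_true <- logical(0)
  }
  rho <- NA_real_
  if (!is.null(rpp) && length(peaks)) {
    # best-matching peak per recovered site
    hit <- GenomicRanges::findOverlaps(site_gr, summit_gr, maxgap = match_bp,
                                       select = "first")
    ok <- !is.na(hit)
    if (sum(ok) >= 3L)
      rho <- suppressWarnings(stats::cor(truth_sites$strength[ok],
                                         rpp[hit[ok]], method = "spearman"))
  }
  list(sensitivity = mean(recovered),
       fdr = if (length(peak_true)) mean(!peak_true) else NA_real_,
       n_sites = length(site_gr), n_peaks = length(peaks),
       rpp_strength_spearman = rho, recovered = recovered)
}

#' Precision/recall of the candidate gene selector
#'
#' @param truth_genes `truth_genes` table from a bundle.
#' @param candidate_genes character vector of selected gene ids.
#' @return list with `precision`, `recall`, `n_selected`, `n_true`.
#' @export
candidate_metrics <- function(truth_genes, candidate_genes) {
  truth <- truth_genes$gene_id[truth_genes$responsive]
  sel <- unique(candidate_genes)
  tp <- length(intersect(sel, truth))
  list(precision = if (length(sel)) tp / length(sel) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       n_selected = length(sel), n_true = length(truth))
}
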