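#' Bipartite p53 response-element model
#'
#' The p53 response element is two decamer half-sites of consensus
#' RRRCWWGYYY, optionally separated by a short spacer. Both half-sites are
#' scored with the same 4 x 10 log-odds matrix; a full-site score is the
#' sum of the two half-site scores.
#'
#' @param half_site_matrix 4 x 10 numeric log-odds matrix, rows named
#'   A, C, G, T.
#' @param spacer_range integer vector of allowed spacer lengths in bp.
#' @param background length-4 base frequencies summing to 1.
#' @param threshold minimum full-site score for a hit.
#' @return object of class `"MotifModel"`.
#' @export
motif_model <- function(half_site_matrix, spacer_range = 0L,
                        background = rep(0.25, 4), threshold = 0) {
  m <- as.matrix(half_site_matrix)
  if (!all(dim(m) == c(4L, 10L))) stop("half-site matrix must be 4 x 10")
  if (any(!is.finite(m))) stop("matrix weights must be finite")
  rownames(m) <- c("A", "C", "G", "T")
  if (!length(spacer_range) || any(spacer_range < 0))
    stop("spacer_range must be non-negative and non-empty")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  structure(list(mat = m, spacer_range = as.integer(sort(spacer_range)),
                 background = background, threshold = threshold,
                 worst = apply(m, 2, min)),
            class = "MotifModel")
}

#' Default consensus-derived p53 motif model
#'
#' Built from the degenerate half-site consensus RRRCWWGYYY: within each
#' column the allowed bases share probability uniformly after giving each
#' disallowed base a pseudo-weight of 0.01; log-odds are taken against a
#' uniform 0.25 background (base-2). The default hit threshold of 10
#' tolerates at most two consensus-class mismatches across the 20
#' full-site positions, which keeps the false-positive rate on random
#' 200-bp sequence under 1% (see the methods vignette for the
#' calibration).
#'
#' @param spacer_range allowed spacer lengths (default 0, the modern p53
#'   response-element consensus; up to ~13 bp can be allowed).
#' @param threshold minimum full-site score (default 10).
#' @return a [motif_model()].
#' @export
default_p53_model <- function(spacer_range = 0L, threshold = 10) {
  classes <- c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y")
  allowed <- list(R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                  C = "C", G = "G")
  bases <- c("A", "C", "G", "T")
  prob <- sapply(classes, function(cl) {
    ok <- allowed[[cl]]
    p <- rep(0.01, 4); names(p) <- bases
    p[ok] <- (1 - 0.01 * (4 - length(ok))) / length(ok)
    p
  })
  motif_model(log2(prob / 0.25), spacer_range = spacer_range,
              threshold = threshold)
}

#' Read a half-site matrix file
#'
#' Whitespace-separated, 4 rows (A, C, G, T) by 10 columns. Rows that sum
#' to ~1 are treated as probabilities and converted to log-odds against
#' the model background; otherwise values are taken as log-odds directly.
#'
#' @param path matrix file.
#' @param background base frequencies for the probability-to-log-odds
#'   conversion.
#' @inheritParams motif_model
#' @return a [motif_model()].
#' @export
read_motif_matrix <- function(path, spacer_range = 0L,
                              background = rep(0.25, 4), threshold = 10) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!all(dim(m) == c(4L, 10L))) stop("matrix file must be 4 rows x 10 cols")
  if (all(abs(colSums(m) - 1) < 1e-3)) # columns are per-position probabilities
    m <- log2(sweep(m, 1, background, "/"))
  motif_model(m, spacer_range, background, threshold)
}

# internal: encode A/C/G/T/N as 1..4 / NA; reject other ambiguity codes
encode_seq <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  code <- match(s, c("A", "C", "G", "T"))
  bad <- is.na(code) & s != "N"
  if (any(bad))
    stop("unsupported base(s) in sequence: ",
         paste(unique(s[bad]), collapse = ", "),
         " (only A/C/G/T/N are accepted)")
  code
}

# internal: half-site scores at every valid start of an encoded sequence;
# N positions take the column's worst-case weight
half_site_scores <- function(model, code) {
  n <- length(code)
  if (n < 10L) return(numeric(0))
  idx <- seq_len(n - 9L)
  sc <- numeric(length(idx))
  for (j in 0:9) {
    b <- code[idx + j]
    w <- model$mat[cbind(b, j + 1L)]
    w[is.na(b)] <- model$worst[j + 1L]
    sc <- sc + w
  }
  sc
}

#' Score one full site
#'
#' Scores a window of length `20 + spacer`: the first half-site at offset
#' 0 plus the second at offset `10 + spacer`. `N` bases take the
#' worst-case column weight.
#'
#' @param model a [motif_model()].
#' @param sequence character or `DNAString` of length exactly
#'   `20 + spacer`.
#' @param spacer spacer length in bp (must be in the model's range).
#' @return numeric score (sum of half-site log-odds).
#' @export
score_site <- function(model, sequence, spacer = model$spacer_range[1]) {
  if (!spacer %in% model$spacer_range)
    stop("spacer ", spacer, " outside the model's range")
  code <- encode_seq(sequence)
  if (length(code) != 20L + spacer)
    stop("window must be exactly ", 20L + spacer, " bp for spacer ", spacer)
  h <- half_site_scores(model, code)
  h[1L] + h[11L + spacer]
}

#' Scan a region for the best response-element hit
#'
#' Evaluates every start position, both strands, and every allowed spacer;
#' returns the highest-scoring hit at or above the model threshold, or
#' `NULL` if none. Ties resolve to the leftmost position, `+` strand
#' before `-`, then the smallest spacer.
#'
#' @param model a [motif_model()].
#' @param sequence character or `DNAString` (typically a 200-bp peak core).
#' @return `NULL` or a list (`position` 0-based start of the full site on
#'   the forward sequence, `strand`, `spacer`, `score`).
#' @export
scan_region <- function(model, sequence) {
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  if (n < 20L + min(model$spacer_range)) return(NULL)
  fwd <- encode_seq(seq_chr)
  rev <- rev(5L - fwd) # complement of 1..4 is 5-code; N (NA) stays NA
  h_fwd <- half_site_scores(model, fwd)
  h_rev <- half_site_scores(model, rev)
  pos0 <- integer(0); strand <- character(0); spacer_v <- integer(0)
  score <- numeric(0)
  for (spacer in model$spacer_range) {
    site_len <- 20L + spacer
    if (n < site_len) next
    starts <- seq_len(n - site_len + 1L)
    s_fwd <- h_fwd[starts] + h_fwd[starts + 10L + spacer]
    s_rev <- h_rev[starts] + h_rev[starts + 10L + spacer]
    pos_rev <- n - (starts - 1L) - site_len # reverse start in forward coords
    pos0 <- c(pos0, starts - 1L, pos_rev)
    strand <- c(strand, rep(c("+", "-"), each = length(starts)))
    spacer_v <- c(spacer_v, rep(spacer, 2L * length(starts)))
    score <- c(score, s_fwd, s_rev)
  }
  ok <- score >= model$threshold
  if (!any(ok)) return(NULL)
  top <- max(score[ok])
  cand <- which(score == top)
  cand <- cand[order(pos0[cand], strand[cand], spacer_v[cand])][1]
  list(position = pos0[cand], strand = strand[cand],
       spacer = spacer_v[cand], score = score[cand])
}

#' Fraction of peaks whose 200-bp core contains a motif
#'
#' Each peak is reduced to its summit +/- 100 bp (clipped to the sequence
#' with a warning when necessary) and scanned; reported is the percentage
#' of peaks with a hit at or above the model threshold.
#'
#' @param peaks peak `GRanges` with a `summit` column.
#' @param sequences named `DNAStringSet` (one entry per chromosome).
#' @param model a [motif_model()].
#' @param core_half half-width of the scanned core (default 100 bp).
#' @return list with `percent`, `n_hit`, `n`, and the per-peak logical
#'   `has_hit`.
#' @export
fraction_with_motif <- function(peaks, sequences, model = default_p53_model(),
                                core_half = 100) {
  n <- length(peaks)
  if (n == 0L) stop("no peaks to scan")
  has_hit <- logical(n)
  clipped <- FALSE
  for (i in seq_len(n)) {
    chr <- as.character(GenomicRanges::seqnames(peaks)[i])
    if (!chr %in% names(sequences)) stop("no sequence for chromosome ", chr)
    L <- Biostrings::width(sequences[chr])
    s <- peaks$summit[i] - core_half
    e <- peaks$summit[i] + core_half - 1L
    if (s < 1L || e > L) { clipped <- TRUE; s <- max(1L, s); e <- min(L, e) }
    core <- Biostrings::subseq(sequences[[chr]], s, e)
    has_hit[i] <- !is.null(scan_region(model, core))
  }
  if (clipped) warning("some peak cores were clipped to the sequence bounds")
  list(percent = 100 * mean(has_hit), n_hit = sum(has_hit), n = n,
       has_hit = has_hit)
}

#' Empirical motif false-positive rate on random sequence
#'
#' Estimates the probability that a region of i.i.d. uniform random bases
#' contains a hit at the model threshold; used to calibrate the default
#' threshold.
#'
#' @param model a [motif_model()].
#' @param n number of random regions.
#' @param region_length region length in bp (default 200).
#' @param seed integer seed.
#' @return hit probability estimate.
#' @export
motif_null_rate <- function(model, n = 1000, region_length = 200, seed = 1) {
  hits <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), region_length,
                        replace = TRUE), collapse = "")
      !is.null(scan_region(model, s))
    }, logical(1))
  })
  mean(hits)
}
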