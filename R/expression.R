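#' Expression table with sample metadata
#'
#' Gene-level, already-normalized intensities on the log2 scale (e.g. RMA
#' summaries), one column per array, with a metadata table mapping columns
#' to (condition, timepoint, replicate).
#'
#' @param values data.frame or matrix: first column `gene_id` (or rownames)
#'   plus one numeric column per sample.
#' @param metadata data.frame with columns `sample` (matching value column
#'   names), `condition`, `timepoint` (`"0h"`/`"24h"`), `replicate`.
#' @return object of class `"ExpressionTable"`.
#' @export
expression_table <- function(values, metadata) {
  values <- as.data.frame(values)
  if ("gene_id" %in% names(values)) {
    gene_id <- as.character(values$gene_id)
    mat <- as.matrix(values[setdiff(names(values), "gene_id")])
  } else {
    gene_id <- rownames(values)
    mat <- as.matrix(values)
  }
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  rownames(mat) <- gene_id
  need <- c("sample", "condition", "timepoint", "replicate")
  if (!all(need %in% names(metadata)))
    stop("metadata missing columns: ",
         paste(setdiff(need, names(metadata)), collapse = ", "))
  missing <- setdiff(metadata$sample, colnames(mat))
  if (length(missing))
    stop("metadata samples absent from table: ",
         paste(missing, collapse = ", "))
  mat <- mat[, metadata$sample, drop = FALSE]
  structure(list(values = mat, metadata = as.data.frame(metadata)),
            class = "ExpressionTable")
}

#' Read an expression TSV plus metadata
#'
#' @param path TSV with a `gene_id` column and one column per sample.
#' @param metadata data.frame as in [expression_table()].
#' @export
read_expression <- function(path, metadata) {
  dt <- data.table::fread(path, header = TRUE)
  expression_table(as.data.frame(dt), metadata)
}

#' Per-condition expression change (log2 24h / 0h)
#'
#' For each condition, replicate intensities are averaged per timepoint
#' and the change is `mean(24h) - mean(0h)` on the log2 scale (i.e. the
#' log2 of the 24h/0h intensity ratio).
#'
#' @param table an [expression_table()].
#' @return data.frame `gene_id` plus one `change_<condition>` column per
#'   condition.
#' @export
compute_ratios <- function(table) {
  stopifnot(inherits(table, "ExpressionTable"))
  md <- table$metadata
  conditions <- unique(md$condition)
  out <- data.frame(gene_id = rownames(table$values))
  for (cond in conditions) {
    for (tp in c("0h", "24h")) {
      if (!any(md$condition == cond & md$timepoint == tp))
        stop("condition ", cond, " is missing timepoint ", tp)
    }
    m0 <- rowMeans(table$values[, md$sample[md$condition == cond &
                                              md$timepoint == "0h"],
                                drop = FALSE])
    m24 <- rowMeans(table$values[, md$sample[md$condition == cond &
                                               md$timepoint == "24h"],
                                 drop = FALSE])
    out[[paste0("change_", cond)]] <- m24 - m0
  }
  out
}

#' Correlation of expression changes between treatments
#'
#' Pearson correlation of the per-gene log2 changes of the two conditions.
#'
#' @param ratios a [compute_ratios()] result with exactly two change
#'   columns.
#' @export
treatment_correlation <- function(ratios) {
  chg <- ratios[grep("^change_", names(ratios))]
  if (ncol(chg) != 2L) stop("need exactly two conditions")
  if (nrow(chg) < 2L) stop("need at least two genes")
  if (stats::sd(chg[[1]]) == 0 || stats::sd(chg[[2]]) == 0)
    stop("correlation undefined for constant changes")
  stats::cor(chg[[1]], chg[[2]])
}

#' Percent of bound genes rounded to integer
#' @param n_bound genes with a proximal binding site (> 0).
#' @param n_changed the subset that changed expression.
#' @examples bound_changed_percent(1320, 185) # 14
#' @export
bound_changed_percent <- function(n_bound, n_changed) {
  if (n_bound <= 0) stop("n_bound must be positive")
  as.integer(round(100 * n_changed / n_bound))
}

#' Bound genes that changed expression
#'
#' Among genes with at least one assigned binding site, counts those whose
#' absolute log2 change in the given condition is at least `log2(fold)`
#' ("at least" is inclusive).
#'
#' @param gene_peak_table an [assign_peaks_to_genes()] result.
#' @param ratios a [compute_ratios()] result.
#' @param condition condition whose change column is tested.
#' @param fold fold-change threshold (> 1; default 1.7).
#' @return list with `n_bound`, `n_changed`, `percent`, and the changed
#'   gene ids.
#' @export
select_bound_changed <- function(gene_peak_table, ratios, condition,
                                 fold = 1.7) {
  if (fold <= 1) stop("fold must be > 1")
  col <- paste0("change_", condition)
  if (!col %in% names(ratios)) stop("no change column for condition ", condition)
  bound <- intersect(unique(gene_peak_table$gene_id), ratios$gene_id)
  chg <- ratios[[col]][match(bound, ratios$gene_id)]
  changed <- bound[abs(chg) >= log2(fold)]
  list(n_bound = length(bound), n_changed = length(changed),
       percent = if (length(bound)) bound_changed_percent(length(bound),
                                                          length(changed))
                 else NA_integer_,
       changed_genes = changed)
}

#' Uncentered correlation similarity
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` -- cosine similarity without mean
#' centering. Scale-invariant but not shift-invariant; the clustering
#' distance is one minus this value.
#'
#' @param x,y numeric vectors of equal length, neither with zero norm.
#' @return similarity in `[-1, 1]`.
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("uncentered correlation undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

# internal: matrix of 1 - uncentered correlation between rows of X and
# rows of C
ucor_dist <- function(X, C) {
  nx <- sqrt(rowSums(X^2)); nc <- sqrt(rowSums(C^2))
  1 - (X %*% t(C)) / outer(nx, nc)
}

#' K-means clustering under uncentered correlation
#'
#' Lloyd-style iteration with distance `1 - uncentered_correlation`;
#' centroids are the (direction of the) mean of cluster members. The
#' objective (total distance of points to their centroid) is
#' non-increasing across iterations; an empty cluster is re-seeded from
#' the point farthest from its centroid. `nstart` seeded restarts are run
#' and the best objective kept, so the result is deterministic given the
#' seed.
#'
#' @param X numeric matrix (n x p), no zero-norm rows; n >= k.
#' @param k number of clusters (default 10).
#' @param seed integer seed.
#' @param max_iter iteration cap per restart (default 100).
#' @param nstart number of random restarts (default 10).
#' @return list with `cluster` (assignment per row), `centers`,
#'   `objective`, and `iterations`.
#' @export
kmeans_uncentered <- function(X, k = 10, seed = 1, max_iter = 100,
                              nstart = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("fewer rows (", n, ") than clusters (", k, ")")
  if (any(rowSums(X^2) == 0)) stop("zero-norm rows cannot be clustered")
  Xn <- X / sqrt(rowSums(X^2)) # unit rows: the centroid minimizing total
                               # cosine distance is their mean direction
  run_once <- function() {
    centers <- X[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      D <- ucor_dist(X, centers)
      assign_new <- max.col(-D, ties.method = "first")
      for (j in which(tabulate(assign_new, k) == 0L)) {
        # re-seed an empty cluster from the worst-fit point
        far <- which.max(D[cbind(seq_len(n), assign_new)])
        centers[j, ] <- X[far, ]
        assign_new[far] <- j
      }
      trace <- c(trace, sum(D[cbind(seq_len(n), assign_new)]))
      if (all(assign_new == assign_old)) break
      assign_old <- assign_new
      for (j in seq_len(k)) {
        cm <- colMeans(Xn[assign_new == j, , drop = FALSE])
        if (sum(cm^2) > 0) centers[j, ] <- cm # degenerate mean: keep center
      }
    }
    list(cluster = assign_new, centers = centers,
         objective = trace[length(trace)], objective_trace = trace,
         iterations = it)
  }
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      res <- run_once()
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    best
  })
}

#' Candidate sites differentially bound by phospho-S46 p53
#'
#' A peak passes the binding criterion when its pS46 occupancy is at least
#' `ptm_fold` stronger in condition B than in condition A, with a +1
#' pseudo-count on both sides: `(rpp_B + 1) / (rpp_A + 1) >= ptm_fold`.
#' Its assigned gene passes the expression criterion when the two
#' conditions' log2 changes differ by at least `log2(expr_fold)`
#' (inclusive). Reported are all passing (peak, gene) pairs and the unique
#' passing genes.
#'
#' @param ps46_rpp_A,ps46_rpp_B pS46 RPP per reference peak, parallel
#'   vectors.
#' @param gene_peak_table an [assign_peaks_to_genes()] result whose
#'   `peak_index` indexes the same reference peaks.
#' @param ratios a [compute_ratios()] result with `change_A`/`change_B`
#'   columns (names taken from `conditions`).
#' @param conditions length-2 character: the condition labels (B first
#'   position is the "stronger binding" condition, i.e.
#'   `c(A = ..., B = ...)`).
#' @param ptm_fold binding fold threshold (default 2).
#' @param expr_fold between-treatment expression fold threshold
#'   (default 1.2).
#' @return data.frame of candidate records with an attribute
#'   `n_unique_genes`; also columns `rpp_A`, `rpp_B`, `change_A`,
#'   `change_B`, `ptm_fold_pass`, `expr_fold_pass`.
#' @export
select_differential_ptm_candidates <- function(ps46_rpp_A, ps46_rpp_B,
                                               gene_peak_table, ratios,
                                               conditions = c(A = "A", B = "B"),
                                               ptm_fold = 2.0,
                                               expr_fold = 1.2) {
  stopifnot(length(ps46_rpp_A) == length(ps46_rpp_B))
  colA <- paste0("change_", conditions[["A"]])
  colB <- paste0("change_", conditions[["B"]])
  gp <- gene_peak_table[order(gene_peak_table$peak_index,
                              gene_peak_table$gene_id), , drop = FALSE]
  pi <- gp$peak_index
  rA <- ps46_rpp_A[pi]; rB <- ps46_rpp_B[pi]
  ptm_pass <- (rB + 1) / (rA + 1) >= ptm_fold
  m <- match(gp$gene_id, ratios$gene_id)
  dA <- ratios[[colA]][m]; dB <- ratios[[colB]][m]
  expr_pass <- !is.na(m) & abs(dB - dA) >= log2(expr_fold)
  rec <- data.frame(peak = gp$peak, gene_id = gp$gene_id,
                    peak_index = pi,
                    rpp_A = rA, rpp_B = rB,
                    change_A = dA, change_B = dB,
                    ptm_fold_pass = ptm_pass, expr_fold_pass = expr_pass)
  out <- rec[ptm_pass & expr_pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unique_genes") <- length(unique(out$gene_id))
  out
}
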