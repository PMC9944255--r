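# Single-cell stage: QC filtering with fixed thresholds, 0-100 per-cell
# signature scores, cell-type fold enrichment, and fibroblast-vs-parenchyma
# Wilcoxon comparisons. Normalization, integration and cell typing happen
# upstream; labels arrive as input.

#' Per-cell QC metrics table
#'
#' @param cell_id Cell barcodes (unique).
#' @param n_features Detected genes per cell.
#' @param n_counts Total transcripts per cell.
#' @param mito_fraction Fraction of mitochondrial reads, in [0, 1].
#' @return data.frame of class \code{CellQCMetrics}.
#' @export
cell_qc_metrics <- function(cell_id, n_features, n_counts, mito_fraction) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("duplicate cell ids")
  stopifnot(length(n_features) == length(cell_id),
            length(n_counts) == length(cell_id),
            length(mito_fraction) == length(cell_id))
  if (any(!is.finite(n_features)) || any(!is.finite(n_counts)) ||
      any(!is.finite(mito_fraction))) {
    stop("QC metrics must be finite")
  }
  if (any(mito_fraction < 0 | mito_fraction > 1)) {
    stop("mito_fraction must lie in [0, 1]")
  }
  structure(data.frame(cell_id = cell_id, n_features = n_features,
                       n_counts = n_counts, mito_fraction = mito_fraction,
                       stringsAsFactors = FALSE),
            class = c("CellQCMetrics", "data.frame"))
}

#' QC thresholds used by [qc_filter()]
#'
#' A cell passes iff n_features > 200 and n_features < 6000 and
#' mito_fraction < 0.15 and n_counts < 15000 — all bounds strict.
#'
#' @return Named list of the four thresholds.
#' @export
qc_thresholds <- function() {
  list(min_features = 200, max_features = 6000,
       max_mito = 0.15, max_counts = 15000)
}

#' Filter cells on fixed QC thresholds
#'
#' @param metrics A [cell_qc_metrics()] table.
#' @param thresholds Threshold list as returned by [qc_thresholds()].
#' @return List with \code{kept} (cell ids passing all criteria) and
#'   \code{summary} (cells removed per criterion; a cell can count toward
#'   several criteria).
#' @export
qc_filter <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(inherits(metrics, "CellQCMetrics"))
  th <- thresholds
  low_feat <- !(metrics$n_features > th$min_features)
  high_feat <- !(metrics$n_features < th$max_features)
  high_mito <- !(metrics$mito_fraction < th$max_mito)
  high_counts <- !(metrics$n_counts < th$max_counts)
  fail <- low_feat | high_feat | high_mito | high_counts
  list(kept = metrics$cell_id[!fail],
       summary = c(n_input = nrow(metrics), n_kept = sum(!fail),
                   n_removed = sum(fail),
                   low_features = sum(low_feat),
                   high_features = sum(high_feat),
                   high_mito = sum(high_mito),
                   high_counts = sum(high_counts)))
}

#' Cell annotation table
#'
#' @param cell_id Cell barcodes (unique).
#' @param cell_type Cell-type label per cell (e.g. fibroblast, epithelial,
#'   endothelial, myeloid_progenitor).
#' @param sample Sample of origin (optional).
#' @param vocabulary Declared label vocabulary; labels outside it error.
#' @return data.frame of class \code{CellAnnotation}.
#' @export
cell_annotation <- function(cell_id, cell_type, sample = NA_character_,
                            vocabulary = unique(as.character(cell_type))) {
  cell_id <- as.character(cell_id)
  cell_type <- as.character(cell_type)
  if (anyDuplicated(cell_id)) stop("duplicate cell ids")
  stopifnot(length(cell_type) == length(cell_id))
  bad <- setdiff(unique(cell_type), vocabulary)
  if (length(bad)) {
    stop("cell type(s) outside vocabulary: ", paste(bad, collapse = ", "))
  }
  structure(data.frame(cell_id = cell_id, cell_type = cell_type,
                       sample = sample, stringsAsFactors = FALSE),
            class = c("CellAnnotation", "data.frame"))
}

#' Per-cell signature scores on a 0-100 scale
#'
#' Raw score = mean normalized expression over the set genes present in
#' the matrix (mean rather than median: single-cell sparsity makes
#' per-cell medians mostly zero). Raw scores are min-max rescaled to
#' [0, 100] over all cells in the dataset; if every cell has the same raw
#' score the result is all zeros with a \code{degenerate} flag.
#'
#' @param expr An [expression_matrix()] of normalized expression, genes x
#'   cells (dense or \pkg{Matrix} sparse).
#' @param set A [gene_set()] with at least one gene in the matrix.
#' @return A [score_table()] (cells x 1) with attributes
#'   \code{raw_scores}, \code{n_genes_used} and \code{degenerate}.
#' @export
per_cell_score <- function(expr, set) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(set, "GeneSet"))
  genes <- intersect(set$genes, expr$gene_ids)
  if (length(genes) == 0L) {
    stop("gene set '", set$name, "' shares no genes with the matrix")
  }
  raw <- Matrix::colMeans(expr$values[genes, , drop = FALSE])
  rng <- range(raw)
  degenerate <- rng[1] == rng[2]
  scaled <- if (degenerate) {
    rep(0, length(raw))
  } else {
    (raw - rng[1]) / (rng[2] - rng[1]) * 100
  }
  m <- matrix(scaled, ncol = 1,
              dimnames = list(expr$sample_ids, set$name))
  st <- score_table(m, group = expr$group,
                    n_genes_used = stats::setNames(length(genes), set$name))
  attr(st, "raw_scores") <- stats::setNames(as.numeric(raw), expr$sample_ids)
  attr(st, "degenerate") <- degenerate
  st
}

#' Signature enrichment by cell type
#'
#' Per cell type: the median 0-100 score and the fold enrichment, defined
#' as the type's mean score divided by the grand mean score over all
#' cells. A grand mean of 0 leaves folds undefined (NA, flagged).
#'
#' @param scores A one-signature [score_table()] from [per_cell_score()].
#' @param ann A [cell_annotation()] covering every scored cell.
#' @return data.frame (cell_type, n_cells, median_score, mean_score,
#'   fold_enrichment), attribute \code{grand_mean_zero}.
#' @export
celltype_enrichment <- function(scores, ann) {
  stopifnot(inherits(scores, "ScoreTable"), inherits(ann, "CellAnnotation"))
  missing <- setdiff(scores$sample_ids, ann$cell_id)
  if (length(missing)) {
    stop("unannotated cell(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  }
  v <- scores$scores[, 1L]
  type <- ann$cell_type[match(scores$sample_ids, ann$cell_id)]
  grand <- mean(v)
  out <- do.call(rbind, lapply(split(seq_along(v), type), function(idx) {
    data.frame(n_cells = length(idx),
               median_score = stats::median(v[idx]),
               mean_score = mean(v[idx]),
               fold_enrichment = if (grand == 0) NA_real_ else
                 mean(v[idx]) / grand)
  }))
  out <- data.frame(cell_type = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "grand_mean_zero") <- grand == 0
  out
}

#' Wilcoxon comparison of signature scores between two cell types
#'
#' \code{rank_sum} (Mann-Whitney, the default: the fibroblast and
#' parenchymal cell groups are unpaired) or \code{signed_rank} (paired,
#' requires equal-length vectors matched by position). p-values are by
#' exact enumeration when both groups have at most 10 observations
#' (all \code{choose(n, m)} assignments / all sign flips, midranks for
#' ties), otherwise by normal approximation with tie correction.
#'
#' @param scores A one-signature [score_table()].
#' @param ann A [cell_annotation()].
#' @param type_a,type_b Cell-type labels to compare.
#' @param mode \code{"rank_sum"} or \code{"signed_rank"}.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (a: first group shifted below / above b).
#' @return List: statistic (U for rank_sum, V for signed_rank), p, method,
#'   exact flag, n_a, n_b.
#' @export
compare_groups <- function(scores, ann, type_a, type_b,
                           mode = c("rank_sum", "signed_rank"),
                           alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(inherits(scores, "ScoreTable"), inherits(ann, "CellAnnotation"))
  type <- ann$cell_type[match(scores$sample_ids, ann$cell_id)]
  a <- scores$scores[which(type == type_a), 1L]
  b <- scores$scores[which(type == type_b), 1L]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (mode == "rank_sum") {
    wilcoxon_rank_sum(a, b, alternative)
  } else {
    if (length(a) != length(b)) {
      stop("signed_rank requires equal-length paired groups")
    }
    wilcoxon_signed_rank(a, b, alternative)
  }
}

#' Mann-Whitney rank-sum test
#'
#' @param a,b Numeric vectors.
#' @param alternative See [compare_groups()].
#' @return List(statistic = U for group a, p, method, exact, n_a, n_b).
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks for ties
  w_obs <- sum(rk[seq_len(m)])
  u_obs <- w_obs - m * (m + 1) / 2
  exact <- m <= 10 && n <= 10
  if (exact) {
    combs <- utils::combn(m + n, m)
    w_null <- colSums(matrix(rk[combs], nrow = m))
    eps <- 1e-9
    p_le <- mean(w_null <= w_obs + eps)
    p_ge <- mean(w_null >= w_obs - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
  } else {
    mu <- m * (m + n + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * (m + n + 1 - tie_term)
    z <- (w_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = u_obs, p = min(1, p), method = "rank_sum",
       exact = exact, n_a = m, n_b = n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard practice); V is the sum of
#' positive-difference ranks.
#'
#' @inheritParams wilcoxon_rank_sum
#' @return List(statistic = V, p, method, exact, n_a, n_b).
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, method = "signed_rank", exact = TRUE,
                n_a = length(a), n_b = length(b)))
  }
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  exact <- n <= 10
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_null <- as.numeric(signs %*% rk)
    eps <- 1e-9
    p_le <- mean(v_null <= v_obs + eps)
    p_ge <- mean(v_null >= v_obs - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = v_obs, p = min(1, p), method = "signed_rank",
       exact = exact, n_a = length(a), n_b = length(b))
}

#' Read sparse single-cell expression (matrix-market triplet)
#'
#' @param mtx Path to the MatrixMarket file (genes x cells).
#' @param genes,cells Paths to one-column text files of gene ids and cell
#'   barcodes (no header).
#' @return An [expression_matrix()] holding a sparse matrix.
#' @export
read_sparse_expression <- function(mtx, genes, cells) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  g <- readLines(genes)
  cb <- readLines(cells)
  expression_matrix(m, gene_ids = g, sample_ids = cb)
}
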