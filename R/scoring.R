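#' Construct an expression matrix
#'
#' Genes x samples numeric matrix with unique gene and sample identifiers
#' and an optional per-sample group label (e.g. tumor type). The values may
#' be a base matrix or a \pkg{Matrix} sparse matrix (single-cell use).
#'
#' @param values Numeric genes x samples matrix.
#' @param gene_ids,sample_ids Identifiers; default taken from dimnames.
#' @param group Optional per-sample group labels (length = n samples).
#' @return An \code{ExpressionMatrix} object.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), group = NULL) {
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    stop("values must be a matrix")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (or set dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("gene_ids length mismatch")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length mismatch")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(group)) {
    if (length(group) != length(sample_ids)) stop("group length mismatch")
    group <- stats::setNames(as.character(group), sample_ids)
  }
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, group = group),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$group)) {
    cat(sprintf(", %d group(s)", length(unique(x$group))))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a delimited expression matrix
#'
#' Genes as rows, first column the gene id, header row of sample ids.
#'
#' @param path Path to a tab-delimited text file.
#' @param annotation Optional path to a sample annotation table with columns
#'   \code{sample_id} and \code{group} (extra columns such as \code{purity}
#'   are kept in the \code{annotation} attribute).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1]])
  group <- NULL
  ann <- NULL
  if (!is.null(annotation)) {
    ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(ann))) {
      stop("annotation table needs columns sample_id and group")
    }
    idx <- match(colnames(vals), ann$sample_id)
    if (anyNA(idx)) {
      stop("annotation missing sample(s): ",
           paste(colnames(vals)[is.na(idx)], collapse = ", "))
    }
    group <- ann$group[idx]
  }
  em <- expression_matrix(vals, group = group)
  attr(em, "annotation") <- ann
  em
}

#' Z-score expression within each sample group
#'
#' For each gene separately, expression values are z-scored within each
#' group (tumor type): centred on the group mean and divided by the group
#' sample standard deviation (n - 1 denominator). Genes with zero variance
#' in a group are set to 0 there and flagged, rather than dropped, so that
#' gene-set intersections stay stable downstream.
#'
#' @param expr An [expression_matrix()]; a missing \code{group} means one
#'   global group.
#' @return An \code{ExpressionMatrix} of z-scores with a
#'   \code{zero_variance} attribute (data.frame of group/gene flags).
#' @export
zscore_within_group <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  vals <- as.matrix(expr$values)
  group <- expr$group
  if (is.null(group)) {
    group <- stats::setNames(rep("all", ncol(vals)), colnames(vals))
  }
  out <- vals
  flags <- list()
  for (g in unique(group)) {
    cols <- which(group == g)
    if (length(cols) < 2L) {
      stop("group '", g, "' has fewer than 2 samples; cannot z-score")
    }
    sub <- vals[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    zero <- !is.na(sdv) & sdv == 0
    sdv[zero] <- 1  # centred values are 0 already
    out[, cols] <- (sub - mu) / sdv
    if (any(zero)) {
      flags[[g]] <- data.frame(group = g, gene = rownames(vals)[zero],
                               stringsAsFactors = FALSE)
    }
  }
  z <- expression_matrix(out, group = expr$group)
  attr(z, "zero_variance") <- if (length(flags)) {
    do.call(rbind, c(flags, list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(), gene = character())
  }
  z
}

#' Per-sample signature scores
#'
#' The score of a sample for a gene set is the median, over the set genes
#' present in the matrix, of the (typically z-scored) expression values.
#' Missing values are excluded per sample; the intersection size is
#' recorded as \code{n_genes_used}.
#'
#' @param z An [expression_matrix()], usually the output of
#'   [zscore_within_group()].
#' @param sets A [gene_set()] or [gene_set_collection()].
#' @return A \code{ScoreTable}: samples x signatures score matrix plus
#'   sample ids, signature names, carried-through group labels, and a
#'   per-signature \code{n_genes_used} vector.
#' @export
signature_score <- function(z, sets) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  if (inherits(sets, "GeneSet")) sets <- gene_set_collection(list(sets))
  stopifnot(inherits(sets, "GeneSetCollection"))
  vals <- as.matrix(z$values)
  scores <- matrix(NA_real_, nrow = ncol(vals), ncol = length(sets),
                   dimnames = list(colnames(vals), names(sets)))
  n_used <- stats::setNames(integer(length(sets)), names(sets))
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]]$genes, rownames(vals))
    if (length(genes) == 0L) {
      stop("gene set '", nm, "' shares no genes with the expression matrix")
    }
    n_used[nm] <- length(genes)
    sub <- vals[genes, , drop = FALSE]
    scores[, nm] <- apply(sub, 2L, stats::median, na.rm = TRUE)
  }
  score_table(scores, group = z$group, n_genes_used = n_used)
}

#' Construct a score table
#'
#' @param scores Samples x signatures numeric matrix with dimnames.
#' @param group Optional named per-sample group labels.
#' @param n_genes_used Optional per-signature gene counts.
#' @return A \code{ScoreTable} object.
#' @export
score_table <- function(scores, group = NULL, n_genes_used = NULL) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (anyDuplicated(rownames(scores))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(scores))) stop("duplicate signature names")
  structure(list(scores = scores, sample_ids = rownames(scores),
                 signature_names = colnames(scores), group = group,
                 n_genes_used = n_genes_used),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("ScoreTable: %d samples x %d signature(s)\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Write a score table to delimited text
#'
#' @param st A [score_table()].
#' @param path Output path (tab-delimited; first column \code{sample_id},
#'   then one column per signature, plus \code{group} when present).
#' @export
write_scores <- function(st, path) {
  stopifnot(inherits(st, "ScoreTable"))
  df <- data.frame(sample_id = st$sample_ids, st$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(st$group)) df$group <- st$group[st$sample_ids]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to the delimited file.
#' @return A [score_table()].
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  group <- NULL
  if ("group" %in% names(df)) {
    group <- stats::setNames(df$group, df$sample_id)
    df$group <- NULL
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  score_table(m, group = group)
}

#' Pearson correlation between two score vectors
#'
#' Missing values are removed pairwise; the two-sided p-value comes from
#' the t transform of r on n - 2 degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length.
#' @return List with \code{r}, \code{n} (pairs used) and \code{p}.
#' @export
score_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("need >= 3 complete pairs, got ", n)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(a, b)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, n = n, p = p)
}

#' Correlation panel of signatures against target scores
#'
#' For each group and each (signature, target) pair, the Pearson
#' correlation over shared samples. Groups with fewer than 3 shared
#' samples (or a constant vector) are omitted with a warning.
#'
#' @param scores,targets [score_table()] objects sharing samples. Targets
#'   are typically purity, immune and stroma scores.
#' @return data.frame with columns group, signature, target, r, n, p.
#' @export
correlation_panel <- function(scores, targets) {
  stopifnot(inherits(scores, "ScoreTable"), inherits(targets, "ScoreTable"))
  shared <- intersect(scores$sample_ids, targets$sample_ids)
  if (length(shared) == 0L) stop("no shared samples between tables")
  group <- scores$group
  if (is.null(group)) {
    group <- stats::setNames(rep("all", length(scores$sample_ids)),
                             scores$sample_ids)
  }
  group <- group[shared]
  rows <- list()
  skipped <- character()
  for (g in unique(group)) {
    ids <- shared[group == g]
    for (sig in scores$signature_names) {
      for (tg in targets$signature_names) {
        res <- tryCatch(
          score_correlation(scores$scores[ids, sig],
                            targets$scores[ids, tg]),
          error = function(e) NULL)
        if (is.null(res)) {
          skipped <- c(skipped, sprintf("%s/%s~%s", g, sig, tg))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, signature = sig, target = tg,
          r = res$r, n = res$n, p = res$p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(skipped)) {
    warning("omitted (too few samples or constant scores): ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) " ..." else "")
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
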