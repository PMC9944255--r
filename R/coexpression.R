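# Sentinel-marker mutual-rank co-expression expansion: the construction
# behind the compact collagen CAF signature (sentinel FAP).

# Deterministic neighbor ranks of all genes around `gene`: order by
# descending signed Pearson correlation, ties by gene id; self excluded.
.neighbor_ranks <- function(cors, gene) {
  v <- cors[, gene]
  v <- v[names(v) != gene]
  ord <- order(-v, names(v))
  stats::setNames(seq_along(ord), names(v)[ord])
}

.cor_matrix <- function(expr, genes = NULL) {
  vals <- as.matrix(expr$values)
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  if (ncol(vals) < 3L) stop("need >= 3 samples for mutual ranks")
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ",
         paste(utils::head(rownames(vals)[sds == 0], 5L), collapse = ", "))
  }
  stats::cor(t(vals))
}

#' Mutual rank distance between two genes
#'
#' MR(a, b) = sqrt(rank of b among a's correlation-ordered neighbors x
#' rank of a among b's), with each gene excluded from its own neighbor
#' list. Neighbors are ordered by descending signed Pearson correlation
#' (ties broken by gene id), so MR(a, b) = MR(b, a) >= 1 and reciprocal
#' top neighbors have MR = 1.
#'
#' @param expr An [expression_matrix()].
#' @param a,b Gene identifiers present and non-constant in \code{expr}.
#' @return The mutual rank (numeric scalar).
#' @export
mutual_rank <- function(expr, a, b) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  missing <- setdiff(c(a, b), expr$gene_ids)
  if (length(missing)) stop("gene(s) absent: ", paste(missing, collapse = ", "))
  if (a == b) stop("mutual rank of a gene with itself is undefined")
  cors <- .cor_matrix(expr)
  sqrt(.neighbor_ranks(cors, a)[[b]] * .neighbor_ranks(cors, b)[[a]])
}

# Mutual ranks of every gene against one sentinel, from a full correlation
# matrix. Returns a named vector (sentinel excluded).
.sentinel_mr <- function(cors, sentinel) {
  genes <- setdiff(colnames(cors), sentinel)
  r_sent <- .neighbor_ranks(cors, sentinel)  # rank of g among sentinel's
  r_back <- vapply(genes, function(g) {
    .neighbor_ranks(cors, g)[[sentinel]]     # rank of sentinel among g's
  }, numeric(1))
  sqrt(r_sent[genes] * r_back)
}

#' Expand a sentinel marker into a compact co-expression signature
#'
#' Genes whose mutual rank to the sentinel is at most \code{mr_cutoff},
#' ordered by ascending mutual rank (ties broken by higher absolute
#' correlation with the sentinel, then by gene id) and truncated to
#' \code{max_genes}. The sentinel itself is excluded. This is the
#' construction that reduces a CAF sentinel (FAP) to the 3 collagen genes
#' COL1A1/COL1A2/COL3A1 on bulk tumor cohorts.
#'
#' @param expr An [expression_matrix()].
#' @param sentinel Sentinel gene id (e.g. \code{"FAP"}).
#' @param mr_cutoff Maximum mutual rank retained (default 5; the source
#'   analysis is "stringent" but unspecified, so the cutoff is explicit).
#' @param max_genes Maximum signature size (default 25).
#' @param name,category Name/category of the returned set.
#' @return A [gene_set()]; empty (with a warning) if nothing passes.
#' @export
sentinel_expansion <- function(expr, sentinel, mr_cutoff = 5,
                               max_genes = 25,
                               name = paste0(sentinel, "_neighbors"),
                               category = "CAF") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!sentinel %in% expr$gene_ids) stop("sentinel absent: ", sentinel)
  cors <- .cor_matrix(expr)
  mr <- .sentinel_mr(cors, sentinel)
  .select_by_mr(mr, abs(cors[names(mr), sentinel]), mr_cutoff, max_genes,
                name, category)
}

.select_by_mr <- function(mr, abscor, mr_cutoff, max_genes, name, category) {
  keep <- names(mr)[!is.na(mr) & mr <= mr_cutoff]
  if (length(keep) == 0L) {
    warning("no gene passes mr_cutoff = ", mr_cutoff)
    return(gene_set(name, character(), category = category,
                    allow_empty = TRUE))
  }
  ord <- order(mr[keep], -abscor[keep], keep)
  keep <- keep[ord][seq_len(min(max_genes, length(keep)))]
  gs <- gene_set(name, keep, category = category)
  attr(gs, "mutual_rank") <- mr[keep]
  gs
}

#' Sentinel expansion aggregated over multiple cohorts
#'
#' Mutual ranks are computed independently within each cohort (emulating
#' per-tumor-type TCGA cohorts); each gene is scored by its median mutual
#' rank across the cohorts in which both it and the sentinel are present
#' and non-constant. Selection then proceeds as in [sentinel_expansion()].
#'
#' @inheritParams sentinel_expansion
#' @param cohorts List of [expression_matrix()] objects.
#' @return A [gene_set()].
#' @export
multi_cohort_expansion <- function(cohorts, sentinel, mr_cutoff = 5,
                                   max_genes = 25,
                                   name = paste0(sentinel, "_neighbors"),
                                   category = "CAF") {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  mr_list <- list()
  cor_list <- list()
  for (co in cohorts) {
    stopifnot(inherits(co, "ExpressionMatrix"))
    if (!sentinel %in% co$gene_ids) next
    cors <- tryCatch(.cor_matrix(co), error = function(e) NULL)
    if (is.null(cors)) next
    mr_list[[length(mr_list) + 1L]] <- .sentinel_mr(cors, sentinel)
    cor_list[[length(cor_list) + 1L]] <-
      abs(cors[setdiff(colnames(cors), sentinel), sentinel])
  }
  if (length(mr_list) == 0L) {
    stop("sentinel '", sentinel, "' usable in no cohort")
  }
  genes <- unique(unlist(lapply(mr_list, names)))
  med_mr <- vapply(genes, function(g) {
    stats::median(unlist(lapply(mr_list, function(v) v[g])), na.rm = TRUE)
  }, numeric(1))
  med_cor <- vapply(genes, function(g) {
    stats::median(unlist(lapply(cor_list, function(v) v[g])), na.rm = TRUE)
  }, numeric(1))
  .select_by_mr(med_mr, med_cor, mr_cutoff, max_genes, name, category)
}
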