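# Dual-species PDX machinery: per-gene mouse (stromal) read fractions,
# within-sample adjustment, median ranking, preranked permutation
# enrichment, and BH FDR per tumor type.

#' Construct dual-species xenograft counts
#'
#' Transcript counts from a patient-derived xenograft split by genome of
#' origin: mouse reads measure the stromal compartment, human reads the
#' tumor parenchyma. Both matrices share the same gene/sample index.
#'
#' @param mouse,human Non-negative genes x samples count matrices with
#'   identical dimnames.
#' @param tumor_type Optional per-sample tumor-type labels.
#' @return A \code{DualSpeciesCounts} object.
#' @export
dual_species_counts <- function(mouse, human, tumor_type = NULL) {
  stopifnot(is.matrix(mouse), is.matrix(human))
  if (!identical(dim(mouse), dim(human))) stop("dimension mismatch")
  if (is.null(rownames(mouse)) || is.null(colnames(mouse))) {
    stop("mouse matrix needs gene and sample dimnames")
  }
  if (!identical(dimnames(mouse), dimnames(human))) {
    stop("mouse and human matrices must share gene/sample dimnames")
  }
  if (anyDuplicated(rownames(mouse))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mouse))) stop("duplicate sample ids")
  if (min(mouse, na.rm = TRUE) < 0 || min(human, na.rm = TRUE) < 0) {
    stop("counts must be non-negative")
  }
  if (!is.null(tumor_type)) {
    if (length(tumor_type) != ncol(mouse)) stop("tumor_type length mismatch")
    tumor_type <- stats::setNames(as.character(tumor_type), colnames(mouse))
  }
  structure(list(mouse = mouse, human = human,
                 gene_ids = rownames(mouse), sample_ids = colnames(mouse),
                 tumor_type = tumor_type),
            class = "DualSpeciesCounts")
}

#' @export
print.DualSpeciesCounts <- function(x, ...) {
  cat(sprintf("DualSpeciesCounts: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Read dual-species counts from delimited files
#'
#' Either two aligned genes x samples tables (\code{mouse}, \code{human};
#' first column gene id) or one long table (\code{long}) with columns
#' gene, sample, species (mouse/human), count.
#'
#' @param mouse,human Paths to per-species wide tables.
#' @param long Path to a long-format table (overrides \code{mouse}/
#'   \code{human}).
#' @param tumor_type Optional per-sample labels (recycled rules as in
#'   [dual_species_counts()]).
#' @return A [dual_species_counts()].
#' @export
read_dual_counts <- function(mouse = NULL, human = NULL, long = NULL,
                             tumor_type = NULL) {
  if (!is.null(long)) {
    df <- utils::read.delim(long, stringsAsFactors = FALSE)
    need <- c("gene", "sample", "species", "count")
    if (!all(need %in% names(df))) {
      stop("long table needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(df$species %in% c("mouse", "human"))) {
      stop("species must be 'mouse' or 'human'")
    }
    genes <- sort(unique(df$gene)); samples <- sort(unique(df$sample))
    mk <- function(sp) {
      sub <- df[df$species == sp, ]
      m <- matrix(0, length(genes), length(samples),
                  dimnames = list(genes, samples))
      m[cbind(match(sub$gene, genes), match(sub$sample, samples))] <- sub$count
      m
    }
    return(dual_species_counts(mk("mouse"), mk("human"),
                               tumor_type = tumor_type))
  }
  rd <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE]); storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]]); m
  }
  dual_species_counts(rd(mouse), rd(human), tumor_type = tumor_type)
}

#' Per-gene per-sample mouse (stromal) read fraction
#'
#' f = mouse / (mouse + human), elementwise. 0.5 marks equal stromal and
#' parenchymal contribution; entries with zero total are undefined and
#' returned as \code{NA}.
#'
#' @param counts A [dual_species_counts()].
#' @return Genes x samples matrix of fractions in [0, 1] (NA where the
#'   total count is zero).
#' @export
mouse_fraction <- function(counts) {
  stopifnot(inherits(counts, "DualSpeciesCounts"))
  tot <- counts$mouse + counts$human
  f <- counts$mouse / tot
  f[tot == 0] <- NA_real_
  f
}

#' Centre mouse fractions within each sample
#'
#' Subtracts from each sample (column) the mean of its non-missing
#' fractions, removing sample-to-sample differences in overall mouse
#' content before genes are compared.
#'
#' @param f Genes x samples fraction matrix (NA allowed).
#' @return Adjusted matrix; every column of non-missing values has mean 0.
#' @export
center_within_sample <- function(f) {
  stopifnot(is.matrix(f))
  n_ok <- colSums(!is.na(f))
  if (any(n_ok == 0)) {
    stop("sample(s) with no observed fractions: ",
         paste(colnames(f)[n_ok == 0], collapse = ", "))
  }
  sweep(f, 2L, colMeans(f, na.rm = TRUE), "-")
}

#' Rank genes by stromal (mouse) enrichment
#'
#' For each gene, the median over samples of the adjusted mouse fractions;
#' genes are ranked by descending median (rank 1 = most stromal). Ties are
#' broken lexicographically by gene id for a deterministic ranking. Genes
#' unobserved in every sample are excluded and reported.
#'
#' @param adjusted Output of [center_within_sample()].
#' @return A \code{StromaRanking}: data.frame (gene, statistic, rank)
#'   sorted by rank, with a \code{genes_excluded} attribute.
#' @export
stroma_ranking <- function(adjusted) {
  stopifnot(is.matrix(adjusted))
  n_ok <- rowSums(!is.na(adjusted))
  excluded <- rownames(adjusted)[n_ok == 0]
  keep <- adjusted[n_ok > 0, , drop = FALSE]
  med <- apply(keep, 1L, stats::median, na.rm = TRUE)
  ord <- order(-med, rownames(keep))
  out <- data.frame(gene = rownames(keep)[ord], statistic = med[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("StromaRanking", "data.frame"),
            genes_excluded = excluded)
}

# ES of the running-sum walk from sorted hit positions. `inc` are the
# normalized hit increments (in ranking order of the hits), `pos` the hit
# ranks, n the list length. Extremes occur at hits (peaks) and just before
# hits (troughs); the walk starts and ends at 0.
.walk_es <- function(pos, inc, n) {
  k <- length(pos)
  dec <- 1 / (n - k)
  up <- cumsum(inc)
  peak <- up - (pos - seq_len(k)) * dec
  trough <- c(0, up[-k]) - (pos - 1 - (seq_len(k) - 1)) * dec
  cand <- c(peak, trough)
  mx <- max(cand); mn <- min(cand)
  if (mx >= -mn) mx else mn  # prefer the positive extreme on exact ties
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Running-sum (GSEA-style) walk over a ranked gene list: moving down the
#' ranking, the sum increments at set genes (weighted by
#' |statistic|^weight, normalized) and decrements uniformly at non-set
#' genes; the enrichment score ES is the signed maximum deviation. Weight
#' 0 gives the classic Kolmogorov-Smirnov-like walk, appropriate here
#' because the input is a median-based rank list, not a signed expression
#' statistic. The null distribution comes from random placements of the
#' set's genes in the ranking (gene-label permutation); following the
#' GSEA convention, the observed ES is compared against the same-signed
#' side of the null only: Monte Carlo \code{p = (1 + b) / (1 + m)} with
#' \code{m} the number of same-signed null ES and \code{b} those at
#' least as extreme, or exhaustive enumeration of all
#' \code{choose(n, k)} placements when \code{exact = TRUE} (then
#' \code{p = b / m}). NES is ES divided by the mean |null ES| of
#' matching sign.
#'
#' @param ranking A [stroma_ranking()] (or data.frame with columns gene,
#'   statistic, rank).
#' @param set A [gene_set()]; at least 2 member genes must be in the
#'   ranking, and fewer than the whole ranking.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param weight Hit-increment exponent on |statistic| (default 0).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility in Monte Carlo mode).
#' @param exact Use exhaustive placement enumeration (only feasible for
#'   small \code{choose(n, k)}; capped at 1e6 placements).
#' @return An \code{EnrichmentResult} list: set_name, es, nes, p_perm, q
#'   (NA until BH across sets), n_genes_used, n_perm, seed, degenerate.
#' @export
preranked_enrichment <- function(ranking, set, n_perm = 1000, weight = 0,
                                 seed = NULL, exact = FALSE) {
  stopifnot(inherits(set, "GeneSet"))
  genes <- ranking$gene
  stat <- ranking$statistic
  n <- length(genes)
  hit <- genes %in% set$genes
  k <- sum(hit)
  if (k < 2L) stop("fewer than 2 genes of set '", set$name, "' in ranking")
  if (k >= n) {
    # every position a hit: no misses to decrement, walk undefined
    return(structure(list(set_name = set$name, es = NA_real_,
                          nes = NA_real_, p_perm = NA_real_, q = NA_real_,
                          n_genes_used = k, n_perm = 0L, seed = seed,
                          degenerate = TRUE),
                     class = "EnrichmentResult"))
  }
  w <- abs(stat)^weight
  es_at <- function(pos) {
    inc <- w[pos]
    .walk_es(pos, inc / sum(inc), n)
  }
  obs_pos <- which(hit)
  es <- es_at(obs_pos)
  if (exact) {
    combs <- utils::combn(n, k)
    if (ncol(combs) > 1e6) stop("too many placements for exact mode")
    null_es <- apply(combs, 2L, es_at)
    n_perm <- ncol(combs)
  } else {
    if (n_perm < 100) warning("n_perm < 100: permutation p is coarse")
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    null_es <- vapply(seq_len(n_perm),
                      function(i) es_at(sort.int(sample.int(n, k))),
                      numeric(1))
  }
  # GSEA convention: compare against the same-signed side of the null
  # only; a sign-directed count over all permutations would double the
  # nominal false-positive rate (see the methods vignette)
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  b <- if (es >= 0) sum(same_sign >= es) else sum(same_sign <= es)
  p <- if (exact) {
    if (length(same_sign)) b / length(same_sign) else 1
  } else {
    (1 + b) / (1 + length(same_sign))
  }
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  structure(list(set_name = set$name, es = es, nes = nes, p_perm = p,
                 q = NA_real_, n_genes_used = k, n_perm = n_perm,
                 seed = seed, degenerate = FALSE),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult '%s': ES = %.4f, NES = %.3f, p = %.4g%s\n",
              x$set_name, x$es, x$nes, x$p_perm,
              if (!is.na(x$q)) sprintf(", q = %.4g", x$q) else ""))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: q_i = min over j with p_j >= p_i of m * p_j /
#' rank_j, with monotonicity enforced and capped at 1.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  p <- as.numeric(pvals)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Stromal enrichment of gene sets across a xenograft cohort
#'
#' Composes the full pipeline per tumor type: mouse fractions,
#' within-sample centering, median-based stromal ranking, preranked
#' permutation enrichment for each gene set, and BH FDR computed within
#' each tumor type across its tested sets.
#'
#' @param counts A [dual_species_counts()]; a missing tumor_type label
#'   means one cohort-wide type \code{"all"}.
#' @param sets A [gene_set_collection()] (or single [gene_set()]).
#' @param n_perm,weight,seed Passed to [preranked_enrichment()]; the seed
#'   for each (type, set) is derived deterministically from \code{seed}.
#' @return data.frame (set, tumor_type, es, nes, p, q, n_genes_used),
#'   with sets unusable in a type skipped with a warning.
#' @export
enrich_all <- function(counts, sets, n_perm = 1000, weight = 0, seed = 1) {
  stopifnot(inherits(counts, "DualSpeciesCounts"))
  if (inherits(sets, "GeneSet")) sets <- gene_set_collection(list(sets))
  types <- counts$tumor_type
  if (is.null(types)) {
    types <- stats::setNames(rep("all", length(counts$sample_ids)),
                             counts$sample_ids)
  }
  frac <- mouse_fraction(counts)
  rows <- list()
  off <- 0L
  for (ty in unique(types)) {
    cols <- names(types)[types == ty]
    adj <- center_within_sample(frac[, cols, drop = FALSE])
    rk <- stroma_ranking(adj)
    res <- list()
    for (nm in names(sets)) {
      off <- off + 1L
      er <- tryCatch(
        preranked_enrichment(rk, sets[[nm]], n_perm = n_perm,
                             weight = weight, seed = seed + off),
        error = function(e) {
          warning("set '", nm, "' skipped for type '", ty, "': ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(er) && !er$degenerate) res[[nm]] <- er
    }
    if (length(res) == 0L) next
    q <- bh_fdr(vapply(res, `[[`, numeric(1), "p_perm"))
    for (i in seq_along(res)) {
      er <- res[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        set = er$set_name, tumor_type = ty, es = er$es, nes = er$nes,
        p = er$p_perm, q = q[i], n_genes_used = er$n_genes_used,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no usable gene set in any tumor type")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# RNG bookkeeping so that seeded internals do not clobber the caller's
# random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
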