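test_that("qc_filter applies the four strict thresholds", {
  qc <- cell_qc_metrics(
    cell_id = c("at_lower", "just_in", "at_counts", "at_mito", "at_upper"),
    n_features = c(200, 201, 5999, 1000, 6000),
    n_counts = c(1000, 14999, 15000, 5000, 4000),
    mito_fraction = c(0.01, 0.149, 0.0, 0.15, 0.01))
  res <- qc_filter(qc)
  expect_identical(res$kept, "just_in")  # all bounds are strict
  expect_equal(unname(res$summary["low_features"]), 1)
  expect_equal(unname(res$summary["high_counts"]), 1)
  expect_equal(unname(res$summary["high_mito"]), 1)
  expect_equal(unname(res$summary["high_features"]), 1)

  # idempotent: filtering the kept cells removes nothing
  keep_idx <- match(res$kept, qc$cell_id)
  qc2 <- cell_qc_metrics(qc$cell_id[keep_idx], qc$n_features[keep_idx],
                         qc$n_counts[keep_idx],
                         qc$mito_fraction[keep_idx])
  expect_identical(qc_filter(qc2)$kept, res$kept)
})

test_that("per_cell_score min-max rescales mean set expression to 0-100", {
  vals <- matrix(c(1, 2, 3, 4, 10,
                   3, 2, 5, 4, 10,
                   0, 0, 0, 0, 0), 3, 5, byrow = TRUE,
                 dimnames = list(c("a", "b", "out"),
                                 paste0("c", 1:5)))
  em <- expression_matrix(vals)
  st <- per_cell_score(em, gene_set("S", c("a", "b")))
  raw <- colMeans(vals[c("a", "b"), ])
  hand <- (raw - min(raw)) / (max(raw) - min(raw)) * 100
  expect_equal(unname(st$scores[, 1]), unname(hand))
  expect_equal(min(st$scores), 0)
  expect_equal(max(st$scores), 100)

  # invariant under cell reordering
  perm <- c("c3", "c5", "c1", "c4", "c2")
  st2 <- per_cell_score(expression_matrix(vals[, perm]),
                        gene_set("S", c("a", "b")))
  expect_equal(st2$scores[rownames(st$scores), 1], st$scores[, 1])

  # all-identical cells: degenerate all-zero with a flag
  const <- expression_matrix(matrix(2, 2, 4,
                                    dimnames = list(c("a", "b"),
                                                    paste0("c", 1:4))))
  stc <- per_cell_score(const, gene_set("S", c("a", "b")))
  expect_true(attr(stc, "degenerate"))
  expect_equal(unname(stc$scores[, 1]), rep(0, 4))

  expect_error(per_cell_score(em, gene_set("NONE", "zz")), "NONE")

  # sparse input takes the same path
  sp <- expression_matrix(Matrix::Matrix(vals, sparse = TRUE))
  expect_equal(per_cell_score(sp, gene_set("S", c("a", "b")))$scores,
               st$scores)
})

test_that("celltype_enrichment computes medians and fold enrichment", {
  scores <- score_table(matrix(c(10, 20, 30, 40), ncol = 1,
                               dimnames = list(paste0("c", 1:4), "S")))
  ann1 <- cell_annotation(paste0("c", 1:4), rep("fibroblast", 4))
  res1 <- celltype_enrichment(scores, ann1)
  expect_equal(res1$fold_enrichment, 1)  # single type: fold exactly 1

  ann2 <- cell_annotation(paste0("c", 1:4),
                          c("fibroblast", "fibroblast", "epithelial",
                            "epithelial"))
  res2 <- celltype_enrichment(scores, ann2)
  expect_equal(res2$mean_score[res2$cell_type == "fibroblast"], 15)
  expect_equal(res2$fold_enrichment[res2$cell_type == "fibroblast"],
               15 / 25)
  expect_equal(res2$median_score[res2$cell_type == "epithelial"], 35)

  ann_bad <- cell_annotation(paste0("c", 1:3), rep("fibroblast", 3))
  expect_error(celltype_enrichment(scores, ann_bad), "c4")
})

test_that("fibroblast-planted signatures enrich in fibroblasts", {
  sim <- simulate_single_cells(n_cells_per_type = 60, n_genes = 300,
                               set_size = 20, n_lowq = 0, seed = 31)
  st <- per_cell_score(sim$expr, sim$truth$signature)
  res <- celltype_enrichment(st, sim$annotation)
  expect_identical(res$cell_type[which.max(res$fold_enrichment)],
                   "fibroblast")
  cmp <- compare_groups(st, sim$annotation, "fibroblast", "epithelial")
  expect_lt(cmp$p, 0.01)

  # no planted shift: all folds near 1
  null_sim <- simulate_single_cells(n_cells_per_type = 60, n_genes = 300,
                                    set_size = 20, n_lowq = 0,
                                    set_shift_map = list(), seed = 32)
  stn <- per_cell_score(null_sim$expr, null_sim$truth$signature)
  resn <- celltype_enrichment(stn, null_sim$annotation)
  expect_true(all(abs(resn$fold_enrichment - 1) < 0.25))
})

test_that("rank-sum p-values match enumeration and wilcox.test", {
  mk <- function(a, b) {
    ids <- sprintf("c%02d", seq_len(length(a) + length(b)))
    list(st = score_table(matrix(c(a, b), ncol = 1,
                                 dimnames = list(ids, "S"))),
         ann = cell_annotation(ids, rep(c("A", "B"),
                                        c(length(a), length(b)))))
  }
  f <- mk(c(1, 2), c(3, 4))
  res <- compare_groups(f$st, f$ann, "A", "B", alternative = "less")
  expect_equal(res$statistic, 0)       # U = 0
  expect_equal(res$p, 1 / 6)           # exact enumeration over C(4,2)
  two <- compare_groups(f$st, f$ann, "A", "B")
  expect_equal(two$p, 1 / 3)

  # identical multisets: two-sided exact p = 1; swapping groups symmetric
  g <- mk(c(5, 7, 7), c(5, 7, 7))
  expect_equal(compare_groups(g$st, g$ann, "A", "B")$p, 1)
  h <- mk(c(1, 5, 9, 2), c(3, 8, 4))
  expect_equal(compare_groups(h$st, h$ann, "A", "B")$p,
               compare_groups(h$st, h$ann, "B", "A")$p)

  # tie-free exact case against wilcox.test
  set.seed(6)
  a <- rnorm(8); b <- rnorm(9) + 0.5
  expect_equal(wilcoxon_rank_sum(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value)
  # large samples: normal approximation with tie correction
  set.seed(8)
  a2 <- sample(1:10, 40, replace = TRUE)
  b2 <- sample(3:12, 35, replace = TRUE)
  expect_equal(wilcoxon_rank_sum(a2, b2)$p,
               wilcox.test(a2, b2, exact = FALSE,
                           correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("signed-rank mode handles pairing and errors on unpaired", {
  set.seed(13)
  a <- rnorm(9); b <- a + rnorm(9, 0.4)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$p, wilcox.test(a, b, paired = TRUE,
                                  exact = TRUE)$p.value)
  a2 <- rnorm(30); b2 <- a2 + rnorm(30, 0.3)
  expect_equal(wilcoxon_signed_rank(a2, b2)$p,
               wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value,
               tolerance = 1e-10)

  ids <- sprintf("c%02d", 1:5)
  st <- score_table(matrix(1:5, ncol = 1, dimnames = list(ids, "S")))
  ann <- cell_annotation(ids, c("A", "A", "A", "B", "B"))
  expect_error(compare_groups(st, ann, "A", "B", mode = "signed_rank"),
               "paired")
})
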