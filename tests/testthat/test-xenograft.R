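mk_counts <- function(mouse, human, genes, samples, type = NULL) {
  dn <- list(genes, samples)
  dual_species_counts(matrix(mouse, length(genes), length(samples),
                             byrow = TRUE, dimnames = dn),
                      matrix(human, length(genes), length(samples),
                             byrow = TRUE, dimnames = dn),
                      tumor_type = type)
}

test_that("mouse_fraction handles equal, zero and undefined totals", {
  dc <- mk_counts(mouse = c(100, 0, 0), human = c(100, 50, 0),
                  genes = c("eq", "none", "void"), samples = "s1")
  f <- mouse_fraction(dc)
  expect_equal(f["eq", "s1"], 0.5)   # equal contribution reference line
  expect_equal(f["none", "s1"], 0)
  expect_true(is.na(f["void", "s1"]))

  sim <- simulate_xenograft_counts(n_samples = 10, n_genes = 100, seed = 2)
  fr <- mouse_fraction(sim$counts)
  expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
})

test_that("center_within_sample zeroes per-sample means over observed", {
  m <- matrix(c(0.2, 0.4, NA, 0.1,
                0.6, 0.2, 0.3, 0.5,
                0.1, 0.9, 0.5, 0.3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  adj <- center_within_sample(m)
  # hand-computed column means over non-missing entries
  expect_equal(adj[, 1], m[, 1] - mean(c(0.2, 0.4, 0.1), na.rm = TRUE))
  expect_equal(unname(colMeans(adj, na.rm = TRUE)), rep(0, 3),
               tolerance = 1e-12)

  one <- matrix(0.7, 1, 1, dimnames = list("g", "s"))
  expect_equal(center_within_sample(one)[1, 1], 0)  # mean of one

  m[, 2] <- NA
  expect_error(center_within_sample(m), "s2")
})

test_that("stroma_ranking sorts medians descending with lexicographic ties", {
  m <- matrix(c(0.25, 0.25,
                0.25, 0.25,
                0.5, 0.0,
                -0.25, 0.75), 4, 2, byrow = TRUE,
              dimnames = list(c("b_gene", "a_gene", "mid", "hi"),
                              c("s1", "s2")))
  rk <- stroma_ranking(m)
  # every median is exactly 0.25 -- ties resolved lexicographically
  expect_identical(rk$gene, sort(rownames(m)))
  expect_identical(rk$rank, 1:4)

  # 20-gene toy against a sort oracle
  set.seed(12)
  m2 <- matrix(runif(20 * 5) - 0.5, 20, 5,
               dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:5)))
  rk2 <- stroma_ranking(m2)
  med <- apply(m2, 1, median)
  expect_identical(rk2$gene, names(med)[order(-med, names(med))])
  expect_identical(rk2$rank, 1:20)

  # all-missing genes excluded and reported; single observation = median
  m3 <- matrix(c(NA, NA, 0.4, NA), 2, 2, byrow = TRUE,
               dimnames = list(c("gone", "one"), c("s1", "s2")))
  rk3 <- stroma_ranking(m3)
  expect_identical(attr(rk3, "genes_excluded"), "gone")
  expect_equal(rk3$statistic[rk3$gene == "one"], 0.4)
})

test_that("enrichment walk matches the full-cumsum oracle", {
  rk <- data.frame(gene = paste0("g", 1:6),
                   statistic = c(0.5, 0.4, 0.3, -0.1, -0.2, -0.6),
                   rank = 1:6)
  # top-k contiguous set, weight 0: walk climbs to its analytic maximum 1
  top2 <- gene_set("TOP2", c("g1", "g2"))
  er <- preranked_enrichment(rk, top2, exact = TRUE)
  expect_equal(er$es, 1)
  expect_equal(er$es, oracle_walk_es(rk$gene, rk$statistic, top2$genes))

  # every configuration of a 2-of-6 set agrees with the oracle, for both
  # the classic and a weighted walk
  for (w in c(0, 1)) {
    for (pair in combn(6, 2, simplify = FALSE)) {
      gs <- gene_set("P", paste0("g", pair))
      er <- preranked_enrichment(rk, gs, weight = w, exact = TRUE)
      expect_equal(er$es,
                   oracle_walk_es(rk$gene, rk$statistic, gs$genes, w))
      expect_true(er$es >= -1 && er$es <= 1)
    }
  }
})

test_that("exact permutation p equals enumeration over all placements", {
  rk <- data.frame(gene = paste0("g", 1:5),
                   statistic = c(0.9, 0.5, 0.1, -0.3, -0.7), rank = 1:5)
  gs <- gene_set("S", c("g1", "g2"))
  er <- preranked_enrichment(rk, gs, weight = 0, exact = TRUE)
  # independent enumeration over all C(5,2) = 10 placements
  all_es <- apply(combn(5, 2), 2, function(pos)
    oracle_walk_es(rk$gene, rk$statistic, rk$gene[pos]))
  expect_equal(er$n_perm, 10L)
  # sign-conditional exact p: same-signed placements at least as extreme
  same <- all_es[all_es >= -1e-12]
  expect_equal(er$p_perm, sum(same >= er$es - 1e-12) / length(same))
  expect_equal(er$nes, er$es / mean(abs(same)))
})

test_that("permutation mode is seeded, reproducible and sign-consistent", {
  set.seed(40)
  stat <- sort(rnorm(80), decreasing = TRUE)
  rk <- data.frame(gene = sprintf("g%02d", 1:80), statistic = stat,
                   rank = 1:80)
  gs <- gene_set("S", sprintf("g%02d", 1:8))  # stromal-end set
  e1 <- preranked_enrichment(rk, gs, n_perm = 300, seed = 7)
  e2 <- preranked_enrichment(rk, gs, n_perm = 300, seed = 7)
  expect_identical(e1$p_perm, e2$p_perm)  # bit-exact under a fixed seed
  expect_gt(e1$es, 0)
  expect_lte(e1$p_perm, 1)
  expect_gt(e1$p_perm, 0)

  # reversing the ranking flips the ES sign (weight 0 antisymmetry)
  rk_rev <- data.frame(gene = rev(rk$gene), statistic = rev(rk$statistic),
                       rank = 1:80)
  e_rev <- preranked_enrichment(rk_rev, gs, n_perm = 100, seed = 7)
  expect_equal(e_rev$es, -e1$es)

  # a set spanning the whole ranking is degenerate
  whole <- gene_set("ALL", rk$gene)
  expect_true(preranked_enrichment(rk, whole, seed = 1)$degenerate)
  expect_error(preranked_enrichment(rk, gene_set("TINY", "g01"), seed = 1),
               "fewer than 2")
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)  # BH of one
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)))

  set.seed(10)
  for (i in 1:5) {
    p <- runif(25)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"))  # independent oracle
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  }
})

test_that("enrich_all recovers a planted stromal set with BH per type", {
  sim <- simulate_xenograft_counts(n_samples = 30, n_genes = 500,
                                   planted_set_size = 40,
                                   fraction_shift = 0.15, seed = 77)
  sets <- list(sim$truth$planted_set)
  set.seed(123)
  for (i in 1:5) {
    sets[[i + 1]] <- gene_set(paste0("NULL", i),
                              sample(setdiff(sim$counts$gene_ids,
                                             sim$truth$planted_genes), 40))
  }
  # n_perm = 500: with sign-conditional nulls only ~n_perm/2 permutations
  # land on the observed side, so the attainable q floor with 6 sets at
  # 200 permutations would sit just above 0.05
  res <- enrich_all(sim$counts, gene_set_collection(sets),
                    n_perm = 500, seed = 5)
  planted <- res[res$set == "PLANTED_STROMAL", ]
  expect_gt(planted$es, 0)
  expect_lt(planted$q, 0.05)
  expect_true(all(res$q >= res$p - 1e-12))

  # parenchyma-planted set (negative shift) yields negative ES
  sim_neg <- simulate_xenograft_counts(n_samples = 30, n_genes = 500,
                                       planted_set_size = 40,
                                       fraction_shift = -0.15, seed = 78)
  res_neg <- enrich_all(sim_neg$counts,
                        sim_neg$truth$planted_set, n_perm = 200, seed = 5)
  expect_lt(res_neg$es, 0)
  # single tumor type, single set: q = p
  expect_equal(res_neg$q, res_neg$p)
})
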