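# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# small deterministic expression matrix with optional groups
toy_expr <- function(values, genes, samples, group = NULL) {
  m <- matrix(values, nrow = length(genes), ncol = length(samples),
              byrow = TRUE, dimnames = list(genes, samples))
  expression_matrix(m, group = group)
}

rand_expr <- function(n_genes, n_samples, seed, group = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, group = group)
}

# independent full-cumsum enrichment walk: the oracle against which the
# position-based implementation is checked
oracle_walk_es <- function(ranked_genes, stat, set_genes, weight = 0) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% set_genes
  k <- sum(hit)
  w <- abs(stat)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - k))
  walk <- cumsum(inc)
  mx <- max(walk); mn <- min(walk)
  if (mx >= -mn) mx else mn  # same tie rule as the implementation
}

# brute-force mutual rank: build both genes' full correlation-ordered
# neighbor lists explicitly
oracle_mutual_rank <- function(vals, a, b) {
  rank_of <- function(center, target) {
    others <- setdiff(rownames(vals), center)
    cors <- sapply(others, function(g) cor(vals[center, ], vals[g, ]))
    ord <- others[order(-cors, others)]
    which(ord == target)
  }
  sqrt(rank_of(a, b) * rank_of(b, a))
}

# hand-coded Breslow partial log-likelihood for a single covariate
# (no-ties fixtures only), used as a grid-search oracle for fit_cox
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
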