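# Seeded generators that emulate the statistical structure each analysis
# stage assumes: bulk mixtures whose stromal genes track (1 - purity),
# dual-species xenograft counts with a planted stromal gene set, labeled
# single cells with a fibroblast-shifted signature, and survival times
# under a proportional-hazards model on scores. Each returns its ground
# truth; none claims biological realism beyond the planted structure.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Simulate a bulk expression mixture with planted stromal structure
#'
#' Per-sample tumor purity is drawn from Beta(5, 2) (tumors are mostly
#' malignant cells with a variable stromal admixture). A block of stromal
#' genes has expression baseline + effect x (1 - purity), an epithelial
#' block has baseline + effect x purity, and the remaining genes are pure
#' noise; all genes get Normal(0, noise_sd) noise.
#'
#' @param n_samples,n_genes Matrix dimensions (defaults 100 x 1000).
#' @param n_stromal_genes,n_epithelial_genes Planted block sizes
#'   (default 50 each); must leave room for noise genes.
#' @param effect Mixing effect size (expression units per unit fraction;
#'   default 2, giving strong but not deterministic purity correlations).
#' @param noise_sd Per-gene residual SD (default 1).
#' @param baseline Baseline expression level (default 5).
#' @param seed Integer seed (the dataset is bit-reproducible given it).
#' @return List: \code{expr} (an [expression_matrix()], one group
#'   "cohort1"), \code{truth} (purity, stromal/epithelial gene ids,
#'   parameters, seed).
#' @export
simulate_bulk_mixture <- function(n_samples = 100, n_genes = 1000,
                                  n_stromal_genes = 50,
                                  n_epithelial_genes = n_stromal_genes,
                                  effect = 2, noise_sd = 1, baseline = 5,
                                  seed = NULL) {
  if (n_stromal_genes + n_epithelial_genes >= n_genes) {
    stop("planted blocks must be smaller than n_genes")
  }
  if (effect < 0) stop("effect must be >= 0")
  .with_seed(seed, {
    purity <- stats::rbeta(n_samples, 5, 2)
    samples <- sprintf("S%03d", seq_len(n_samples))
    stromal <- sprintf("STROMAL_%03d", seq_len(n_stromal_genes))
    epi <- sprintf("EPI_%03d", seq_len(n_epithelial_genes))
    noise <- sprintf("NOISE_%04d",
                     seq_len(n_genes - n_stromal_genes - n_epithelial_genes))
    genes <- c(stromal, epi, noise)
    vals <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   n_genes, n_samples, dimnames = list(genes, samples))
    vals <- vals + baseline
    vals[stromal, ] <- vals[stromal, ] +
      matrix(effect * (1 - purity), n_stromal_genes, n_samples, byrow = TRUE)
    vals[epi, ] <- vals[epi, ] +
      matrix(effect * purity, n_epithelial_genes, n_samples, byrow = TRUE)
    expr <- expression_matrix(vals, group = rep("cohort1", n_samples))
    list(expr = expr,
         truth = list(purity = stats::setNames(purity, samples),
                      stromal_genes = stromal, epithelial_genes = epi,
                      effect = effect, noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate dual-species xenograft counts with a planted stromal set
#'
#' Per gene and sample, the total transcript count is Poisson with mean
#' depth x gene rate (rates Gamma(2, 2), mean 1); the mouse share is
#' Binomial with a per-sample base probability drawn from Beta(6, 14)
#' (mean 0.3, emulating variable mouse stromal content) shifted by
#' \code{fraction_shift} for the planted genes and clamped to
#' [0.01, 0.99]. A negative shift plants a parenchymal (human-enriched)
#' set, the analogue of an epithelial signature.
#'
#' @param n_samples,n_genes Dimensions (defaults 60 x 2000).
#' @param planted_set_size Planted stromal set size (default 50).
#' @param fraction_shift Mouse-fraction shift of planted genes, in
#'   [-0.5, 0.5] (default +0.15).
#' @param depth Mean sequencing depth per gene (default 50).
#' @param tumor_type Label applied to all samples (default "all").
#' @param seed Integer seed.
#' @return List: \code{counts} (a [dual_species_counts()]), \code{truth}
#'   (planted gene ids, planted [gene_set()], base mouse probabilities,
#'   parameters, seed).
#' @export
simulate_xenograft_counts <- function(n_samples = 60, n_genes = 2000,
                                      planted_set_size = 50,
                                      fraction_shift = 0.15, depth = 50,
                                      tumor_type = "all", seed = NULL) {
  if (fraction_shift < -0.5 || fraction_shift > 0.5) {
    stop("fraction_shift must lie in [-0.5, 0.5]")
  }
  if (planted_set_size >= n_genes) stop("planted set must be < n_genes")
  .with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    samples <- sprintf("PDX%03d", seq_len(n_samples))
    planted <- genes[seq_len(planted_set_size)]
    rate <- stats::rgamma(n_genes, shape = 2, rate = 2)
    total <- matrix(stats::rpois(n_genes * n_samples, depth * rate),
                    n_genes, n_samples, dimnames = list(genes, samples))
    base_p <- stats::rbeta(n_samples, 6, 14)
    p <- matrix(base_p, n_genes, n_samples, byrow = TRUE,
                dimnames = list(genes, samples))
    p[planted, ] <- p[planted, ] + fraction_shift
    p <- pmin(pmax(p, 0.01), 0.99)
    mouse <- matrix(stats::rbinom(n_genes * n_samples, total, p),
                    n_genes, n_samples, dimnames = list(genes, samples))
    human <- total - mouse
    counts <- dual_species_counts(mouse, human,
                                  tumor_type = rep(tumor_type, n_samples))
    list(counts = counts,
         truth = list(planted_genes = planted,
                      planted_set = gene_set("PLANTED_STROMAL", planted,
                                             category = "STROMA"),
                      base_p = stats::setNames(base_p, samples),
                      fraction_shift = fraction_shift, depth = depth,
                      seed = seed))
  })
}

#' Simulate labeled single cells with a signature shifted in chosen types
#'
#' Counts are negative binomial (per-gene lognormal mean, size 2) with
#' Bernoulli dropout; the first \code{set_size} genes form the planted
#' signature, whose mean is multiplied by \code{set_shift_map[[type]]} in
#' the designated cell types. Normalized expression is
#' log1p(count / total x 1e4). QC metrics are computed from the counts;
#' mitochondrial fractions are drawn from Beta(2, 28) for good cells. A
#' contaminating block of low-quality cells straddles the QC thresholds,
#' cycling through the attainable violations (too few detected genes,
#' high mitochondrial fraction, excessive total counts).
#'
#' @param n_cells_per_type Cells per type (default 200).
#' @param types Cell-type vocabulary (default fibroblast, epithelial,
#'   endothelial, myeloid_progenitor).
#' @param set_shift_map Named list/vector of multiplicative shifts on the
#'   signature genes, keys a subset of \code{types}
#'   (default fibroblast = 3).
#' @param dropout Bernoulli zeroing probability (default 0.3).
#' @param n_genes,set_size Gene space and planted signature size
#'   (defaults 1000, 30).
#' @param n_lowq Number of low-quality contaminant cells (default 20).
#' @param seed Integer seed.
#' @return List: \code{expr} (normalized sparse [expression_matrix()],
#'   QC-failing cells included), \code{counts} (sparse raw counts),
#'   \code{annotation} ([cell_annotation()]), \code{qc}
#'   ([cell_qc_metrics()]), \code{truth} (signature [gene_set()], shift
#'   map, per-cell expected QC pass, seed).
#' @export
simulate_single_cells <- function(n_cells_per_type = 200,
                                  types = c("fibroblast", "epithelial",
                                            "endothelial",
                                            "myeloid_progenitor"),
                                  set_shift_map = list(fibroblast = 3),
                                  dropout = 0.3, n_genes = 1000,
                                  set_size = 30, n_lowq = 20, seed = NULL) {
  bad_keys <- setdiff(names(set_shift_map), types)
  if (length(bad_keys)) {
    stop("set_shift_map keys not in types: ",
         paste(bad_keys, collapse = ", "))
  }
  .with_seed(seed, {
    genes <- c(sprintf("SIG_%03d", seq_len(set_size)),
               sprintf("BG_%04d", seq_len(n_genes - set_size)))
    sig_genes <- genes[seq_len(set_size)]
    mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    n_good <- n_cells_per_type * length(types)
    cell_type <- rep(types, each = n_cells_per_type)
    counts <- matrix(0L, n_genes, n_good)
    for (i in seq_len(n_good)) {
      mu_i <- mu
      sh <- set_shift_map[[cell_type[i]]]
      if (!is.null(sh)) mu_i[seq_len(set_size)] <- mu_i[seq_len(set_size)] * sh
      ci <- stats::rnbinom(n_genes, mu = mu_i, size = 2)
      ci[stats::runif(n_genes) < dropout] <- 0L
      counts[, i] <- ci
    }
    mito <- stats::rbeta(n_good, 2, 28)
    qc_pass <- rep(TRUE, n_good)
    # low-quality contaminants cycling through attainable violations; the
    # nFeature upper bound (6000) cannot be hit with this gene space
    if (n_lowq > 0) {
      modes <- rep(c("low_features", "high_mito", "high_counts"),
                   length.out = n_lowq)
      lowq <- matrix(0L, n_genes, n_lowq)
      mito_lowq <- stats::rbeta(n_lowq, 2, 28)
      src_type <- sample(types, n_lowq, replace = TRUE)
      for (j in seq_len(n_lowq)) {
        ci <- counts[, sample.int(n_good, 1L)]
        if (modes[j] == "low_features") {
          nz <- which(ci > 0)
          keep <- nz[sample.int(length(nz), min(150L, length(nz)))]
          ci[-keep] <- 0L
        } else if (modes[j] == "high_mito") {
          mito_lowq[j] <- stats::runif(1, 0.15, 0.3)
        } else {
          ci <- ci * ceiling(16000 / max(sum(ci), 1L))
        }
        lowq[, j] <- ci
      }
      counts <- cbind(counts, lowq)
      mito <- c(mito, mito_lowq)
      cell_type <- c(cell_type, src_type)
      qc_pass <- c(qc_pass, rep(FALSE, n_lowq))
    }
    cells <- sprintf("CELL_%05d", seq_len(ncol(counts)))
    dimnames(counts) <- list(genes, cells)
    tot <- colSums(counts)
    tot[tot == 0] <- 1
    norm <- log1p(sweep(counts, 2L, tot, "/") * 1e4)
    th <- qc_thresholds()
    qc <- cell_qc_metrics(cells, n_features = colSums(counts > 0),
                          n_counts = colSums(counts),
                          mito_fraction = mito)
    # expected pass combines the engineered violation with the generated
    # metrics (a good cell could in principle stray over a bound)
    qc_pass <- qc_pass &
      qc$n_features > th$min_features & qc$n_features < th$max_features &
      qc$mito_fraction < th$max_mito & qc$n_counts < th$max_counts
    ann <- cell_annotation(cells, cell_type, sample = "SIM",
                           vocabulary = types)
    list(expr = expression_matrix(Matrix::Matrix(norm, sparse = TRUE),
                                  group = cell_type),
         counts = Matrix::Matrix(counts, sparse = TRUE),
         annotation = ann, qc = qc,
         truth = list(signature = gene_set("PLANTED_SIGNATURE", sig_genes),
                      set_shift_map = set_shift_map,
                      qc_pass = stats::setNames(qc_pass, cells),
                      seed = seed))
  })
}

#' Simulate survival records under a proportional-hazards model
#'
#' Event times are Exponential with rate baseline_rate x
#' exp(true_beta x score); censoring times are independent Exponential
#' with rate censor_rate; the observed time is the minimum.
#'
#' @param scores Named or unnamed numeric score vector (one per subject).
#' @param true_beta Log-hazard per score unit (default 0.5).
#' @param baseline_rate Baseline event rate (default 0.1; time units are
#'   opaque and carried through).
#' @param censor_rate Censoring rate (default 0.05).
#' @param seed Integer seed.
#' @return List: \code{surv} (a [survival_records()] table), \code{truth}
#'   (true_beta, rates, per-subject event indicator, seed).
#' @export
simulate_survival <- function(scores, true_beta = 0.5, baseline_rate = 0.1,
                              censor_rate = 0.05, seed = NULL) {
  if (baseline_rate <= 0 || censor_rate <= 0) {
    stop("baseline_rate and censor_rate must be > 0")
  }
  n <- length(scores)
  ids <- if (!is.null(names(scores))) names(scores) else
    sprintf("P%04d", seq_len(n))
  .with_seed(seed, {
    t_event <- stats::rexp(n, rate = baseline_rate *
                             exp(true_beta * as.numeric(scores)))
    t_cens <- stats::rexp(n, rate = censor_rate)
    surv <- survival_records(ids, pmin(t_event, t_cens),
                             as.integer(t_event <= t_cens))
    list(surv = surv,
         truth = list(true_beta = true_beta, baseline_rate = baseline_rate,
                      censor_rate = censor_rate, seed = seed))
  })
}
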