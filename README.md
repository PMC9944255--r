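# cafsig

Where does an "EMT" gene-expression signal in bulk tumor RNA-seq actually
come from? Epithelial-to-mesenchymal transition (EMT) signatures are widely
scored on bulk tumors, but mesenchymal genes are also the bread and butter
of cancer-associated fibroblasts (CAFs) in the tumor stroma. `cafsig`
implements, as a tested and reusable R pipeline, the computational chain
used to show that EMT-related expression in bulk tumors is largely of
stromal/CAF origin:

1. **Bulk signature scoring** — per-gene z-scores within each tumor type,
   summarized per sample as the median over a gene set's members; Pearson
   correlation panels of EMT scores against tumor purity, immune and
   stroma scores (`zscore_within_group`, `signature_score`,
   `correlation_panel`).
2. **Dual-species xenograft analysis** — in patient-derived xenografts
   (PDX) human reads measure tumor parenchyma and mouse reads measure
   stroma. Per gene and sample the *mouse fraction*
   f = mouse/(mouse + human) (0.5 = equal contribution) is adjusted by
   subtracting each sample's mean, genes are ranked by the median adjusted
   fraction, and gene sets are tested for stromal enrichment by preranked
   permutation GSEA with Benjamini–Hochberg FDR per tumor type
   (`mouse_fraction`, `center_within_sample`, `stroma_ranking`,
   `preranked_enrichment`, `enrich_all`, `bh_fdr`).
3. **Sentinel mutual-rank expansion** — compact cell-type signatures are
   derived from bulk co-expression around a sentinel marker (FAP for
   CAFs) using the mutual rank MR(a,b) = sqrt(rank_a(b) × rank_b(a)) of
   correlation-ordered neighbor lists; this construction yields the
   packaged 3-gene CAF signature {COL1A1, COL1A2, COL3A1}
   (`mutual_rank`, `sentinel_expansion`, `multi_cohort_expansion`,
   `caf_signature`).
4. **Single-cell validation** — QC filtering with fixed thresholds
   (nFeature > 200 & < 6000, mito fraction < 0.15, nCount < 15,000),
   per-cell signature scores min–max scaled to 0–100, fold enrichment by
   cell type, and Wilcoxon comparisons of fibroblasts vs parenchymal
   cells (`qc_filter`, `per_cell_score`, `celltype_enrichment`,
   `compare_groups`).
5. **Survival association** — univariate Cox proportional hazards of
   overall survival on signature scores, reported as hazard ratios scaled
   to the score interquartile range, HR_IQR = exp(β·IQR)
   (`fit_cox`, `iqr_scaled_hr`, `survival_panel`).
6. **Synthetic data** — seeded generators with ground truth for every
   input modality (`simulate_bulk_mixture`, `simulate_xenograft_counts`,
   `simulate_single_cells`, `simulate_survival`), so the whole chain is
   testable without any external download.

The intended audience is computational biologists who want to audit or
reuse this stroma-attribution machinery on their own cohorts (expression
tables, GMT gene sets, PDX dual-species counts, single-cell matrices,
clinical tables).

## Worked example

```r
library(cafsig)

## bulk mixtures: stromal genes track (1 - purity)
sim <- simulate_bulk_mixture(n_samples = 100, seed = 7)
st  <- signature_score(zscore_within_group(sim$expr),
                       gene_set_collection(list(
  gene_set("STROMA_SET", sim$truth$stromal_genes,   category = "STROMA"),
  gene_set("EPI_SET",    sim$truth$epithelial_genes, category = "EMT_EPI"))))
purity <- score_table(matrix(sim$truth$purity, ncol = 1,
            dimnames = list(names(sim$truth$purity), "purity")))
correlation_panel(st, purity)
#>     group  signature target      r   n        p
#> 1 cohort1 STROMA_SET purity -0.885 100 3.14e-34
#> 2 cohort1    EPI_SET purity  0.883 100 6.80e-34

## xenograft: a stroma-planted set is enriched in mouse reads
xs  <- simulate_xenograft_counts(seed = 7)   # 2000 genes x 60 samples
enrich_all(xs$counts, xs$truth$planted_set, n_perm = 1000, seed = 7)
#>               set tumor_type es  nes       p       q n_genes_used
#> 1 PLANTED_STROMAL        all  1 8.45 0.00199 0.00199           50

## survival: IQR-scaled hazard ratio of a planted beta = 0.5 effect
set.seed(7); sc <- setNames(rnorm(500), sprintf("P%04d", 1:500))
sv  <- simulate_survival(sc, true_beta = 0.5, seed = 8)
fit <- fit_cox(sc, sv$surv)          # beta = 0.468, se = 0.06, 342 events
iqr_scaled_hr(fit$beta, fit$se, sc)
#> HR per IQR (1.36): 1.888 [1.611, 2.213]
```

The stroma-planted signature correlates strongly negatively with purity
while the epithelial block mirrors it with the opposite sign; the planted
stromal set attains the maximal enrichment score (ES = 1: every member
precedes every non-member in the stromal ranking) with permutation
q < 0.01; the recovered hazard ratio per IQR, 1.89 [1.61, 2.21], matches
the planted log-hazard of 0.5 per score unit (exp(0.468 × 1.36) = 1.89).

A command-line interface mirrors these stages
(`score`, `correlate`, `mutual-rank`, `xeno-enrich`, `sc-score`,
`survival`, `simulate`); see `?cafsig_cli` or `inst/scripts/cafsig`.

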