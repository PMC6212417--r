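# miract

Inference of per-sample **microRNA activity** from target-gene expression,
with molecular subtyping, miRNA screening, survival analysis and downstream
association tests — built for muscle-invasive bladder cancer cohorts and
fully testable on a bundled synthetic-cohort generator.

## The problem and who this is for

A miRNA's measured abundance is a poor proxy for how strongly it is actually
silencing its targets: RISC availability and competing endogenous RNAs
decouple expression from function. For anyone analyzing paired mRNA/miRNA
tumor expression (bulk RNA-seq, log2(RPKM+1) / log2(RPM+1)), `miract` infers
what the miRNA is *doing*, per sample, from the footprint it leaves on its
predicted target genes, and carries that activity through a complete
tumor-cohort analysis.

## The model

For a miRNA with predicted target set *T* (TargetScan-style, GMT input):

1. **Baseline** — the `max(⌈0.05 n⌉, 3)` samples with lowest miRNA
   expression approximate the no-impact state; `b_g` = mean target
   expression over them.
2. **Degradation** — `d_gs = x_gs − b_g`.
3. **Activity** — per sample, weighted least squares through the origin
   `d_gs = β_s b_g`; the activity is `a_s = −β̂_s = −Σ_g w_g b_g d_gs / Σ_g
   w_g b_g²` (larger = more degradation).
4. **IRLS** — weights `w_g ∝ max(ε, −cor(a, x_g))` are re-estimated until
   `max|Δa| < 1e−6`, concentrating the fit on targets that behave
   functionally.

A mRNA-only variant picks baselines from the summed z-scored expression of
known functional targets, for validation cohorts without miRNA profiling.
Downstream: two-step nearest-centroid subtyping (Luminal / p53-like / Basal /
Class IV), a functionally-active / key / differentially-expressed miRNA
screen, median-split Kaplan–Meier + log-rank survival screening with
1000-permutation empirical FDRs, pathway/gene-set enrichment (hypergeometric,
KS), activity-group differential expression with Connectivity-Map `.grp`
export, mutation–activity association and immune-infiltration scoring. See
`vignettes/miract-methods.Rmd` for assumptions, parameter meanings and
limitations.

## Worked example

```r
library(miract)

co  <- generate_cohort(simulation_config(seed = 1))   # 120 tumors + 25 normals
tum <- co$tumor_ids

inf <- infer_activity_matrix(co$mrna[, tum], co$mirna[, tum], co$targets)
median(sapply(rownames(inf$activity),
              function(k) cor(inf$activity[k, ], co$true_activity[k, tum])))
#> [1] 0.9989254

cen <- build_centroids(co$mrna[, tum], co$step1_truth[tum], co$signature_genes)
lab <- classify_subtypes(co$mrna[, tum], cen, co$p53_signature)
mean(lab$label == co$subtype_truth[tum])
#> [1] 1

ss <- survival_screen(inf$activity, co$survival, n_perm = 1000, seed = 7)
ss[ss$mirna == "miR-001", c("chi2", "p", "fdr", "direction")]
#>       chi2          p   fdr direction
#> 1 4.127525 0.04219103 0.234         1
```

The first number is the median Pearson correlation between inferred and true
activities across the 20 simulated miRNAs (near-perfect recovery at default
noise). The classification accuracy is 1 on this seed. The last row shows
the planted prognostic miRNA (`miR-001`, simulated with a protective
log-hazard −0.5 per activity unit): it reaches nominal log-rank p = 0.042
with `direction = 1` (overactive group survives longer) but not permutation
FDR ≤ 0.05 — at this spec-pinned effect size the screen ranks it correctly
without clearing the FDR bar, a limitation analyzed in the methods vignette.

## Command line

```sh
miract simulate --seed 1 --out fixtures/
miract infer    --expr mrna.tsv --mirna mirna.tsv --targets targets.gmt --out act.tsv
miract classify --expr mrna.tsv --centroids centroids.tsv --p53-signature p53.tsv --out labels.tsv
miract survive  --activities act.tsv --survival survival.tsv --out surv.tsv
miract run-all  --config run.conf          # flat key = value config
```

(`inst/exec/miract` after install, or call `miract_cli(c("simulate", ...))`.)

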