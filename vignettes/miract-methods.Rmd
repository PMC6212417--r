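---
title: "Inferring miRNA activity from target-gene degradation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA activity from target-gene degradation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miract)
```

## The problem

A miRNA silences genes by binding their transcripts and promoting degradation,
but its measured expression is an unreliable proxy for how strongly it is
actually doing so: RISC loading, competing endogenous RNAs and other factors
decouple abundance from function. `miract` instead infers a per-sample
*activity* from the footprint the miRNA leaves on its predicted target genes,
and builds a complete downstream analysis around that quantity: molecular
subtyping of bladder tumors, screening for functionally active / key /
differentially expressed miRNAs, median-split survival analysis with
permutation FDRs, and association analyses (pathways, gene-set correlation
shifts, mutations, immune infiltration, drug-repurposing signature export).

## The activity model

All expression is on the log2(x + 1) scale. For one miRNA with predicted
target set $T$:

1. **Baseline.** Samples where the miRNA is lowly expressed are taken as the
   state where it had no impact. The baseline of target gene $g$ is
   $b_g = \operatorname{mean}_{s \in B}\, x_{gs}$ over the baseline set $B$:
   the $\max(\lceil 0.05\,n\rceil, 3)$ samples with lowest miRNA expression
   (ties at the cut broken by sample ID). At least 20 samples are required.
2. **Degradation.** $d_{gs} = x_{gs} - b_g$; negative when the miRNA
   suppresses $g$ in sample $s$.
3. **Per-sample fit.** A weighted regression through the origin,
   $d_{gs} = \beta_s\, b_g$, gives
   $\hat\beta_s = \sum_g w_g b_g d_{gs} / \sum_g w_g b_g^2$. The activity is
   $a_s = -\hat\beta_s$, so larger values mean more degradation.
4. **IRLS.** Not every predicted target is functional. Starting from uniform
   weights, each iteration recomputes $r_g = \operatorname{cor}(a, x_g)$
   across samples and sets $w_g \propto \max(\varepsilon, -r_g)$,
   $\varepsilon = 10^{-6}$, renormalized to sum 1: genes anti-correlated with
   the activity (behaving like functional targets) dominate the next fit.
   Iteration stops when $\max_s |\Delta a_s| < 10^{-6}$ or after 100
   iterations (non-convergence is a warning carried in the profile, not an
   error). The loop is fully deterministic.

**mRNA-only variant.** Without a miRNA expression matrix, baselines come from
the sum of z-scored expression over the miRNA's negatively associated
functional targets (taken from a reference cohort). Low activity implies
*high* functional-target expression, so by default the 5% of samples with the
highest target sum are the baseline (`baseline_extreme = "high_target_sum"`).
The opposite extreme — taking the samples with the lowest target sum, which
implies the *highest* activity — is preserved as `"low_target_sum"` for
completeness, but it is not the default because it contradicts the standard
variant's low-activity baseline. From the baseline on, the procedure is
identical.

### Sign and scale conventions

The activity's absolute scale is not identifiable (only the product of
degradation effect and activity enters the model), and the procedure fixes no
canonical sign. `miract` stores $-\hat\beta_s$ so that
larger = more active; every downstream decision (median splits, correlations)
depends only on ordering, and the test suite checks that an affine shift of
all target-gene expression changes activities only by a common positive
scale.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `zero_fraction_max` | 0.85 | miRNAs with raw RPM = 0 in more than 85% of samples are dropped |
| `min_targets` | 10 | minimum in-universe predicted targets for reliable inference |
| `fraction` / `min_baseline_samples` | 0.05 / 3 | baseline sample rule (both variants) |
| `eps`, `tol`, `max_iter` | 1e-6, 1e-6, 100 | IRLS floor, convergence, cap |
| `functional_fdr` | 0.01 | BH FDR defining functional targets per miRNA |
| `key_min_targets` | 10 | "large number" of negative functional targets for key miRNAs |
| `correlated_gene_fdr` | 0.05 | permutation FDR on abs(r) defining the correlated set for enrichment |
| `p_de` | 1e-5 | tumor-vs-normal WMW threshold (chosen to track an FDR below 1% at reference-cohort scale) |
| `n_perm` | 1000 (screens), 500 (DE) | permutation counts |
| `p_mutation` | 0.003 | mutation-association flag (either WMW or FET below it) |

The standard variant's baseline fraction has no canonical published value;
5% with floor 3 mirrors the mRNA-only variant's bottom-5% rule. "A large
number of targets" (the key-miRNA notion) likewise has no canonical cutoff;
10 matches the minimum-target filter and is exposed as a parameter.

## Subtype classifier

Step 1 correlates each tumor's signature-gene vector with four class
centroids (mean expression of reference-labelled samples per class) and takes
the argmax; ties break by the fixed order I < II < III < IV, and constant
vectors are flagged unclassifiable rather than guessed. Step 2 splits class
I/II tumors by the sign of their Pearson correlation with a p53 signature:
strictly positive is p53-like, the boundary $r = 0$ goes to Luminal
("positive correlation" read strictly). Class III is Basal and class IV is
ClassIV. Centroids and the p53 signature are *inputs* here — the published
signature tables are not redistributable with this package — so the shipped
defaults are synthetic, produced by the cohort generator.

## Screens and FDRs

Two FDR machineries are deliberately kept distinct. The miRNA-level screens
use an *empirical permutation FDR* (1000 permutations by default): each
miRNA's activity vector is permuted,
the statistic recomputed, the null pooled across miRNAs and permutations, and
$\widehat{FDR}(t) = \frac{\text{fraction of null} \ge t}{\text{fraction of
observed} \ge t}$, monotonized (suffix minimum over decreasing $t$) and
capped at 1; tied statistics share one value. Functional targets instead use
per-miRNA Benjamini–Hochberg at 1%, the conventional procedure where no
permutation scheme is implied.

A miRNA is **functionally active** when its activity correlates positively
with its own expression at permutation FDR ≤ 5% *and* its activity-correlated
genes (|r| above the permutation-FDR-5% cutoff) are enriched for its
predicted targets at permutation FDR ≤ 5% (one-sided hypergeometric).
**Key** = at least `key_min_targets` negatively associated functional
targets. **Differentially expressed** = two-sided WMW tumor vs normal at
p < 1e-5. The functional-key set is the three-way conjunction.

The survival screen median-splits each activity vector (ties at the median go
to the under-active group, making the split deterministic), compares
Kaplan–Meier curves with the standard two-group log-rank test (chi-square
approximation, hypergeometric variance), and permutes the activity vector —
not the survival labels, following the stated procedure — for the FDR.

## Statistical kernels

FET/hypergeometric, WMW, KS, Kaplan–Meier and log-rank are implemented in the
package rather than delegated, so they can be validated against independent
oracles (exhaustive enumeration for FET and WMW at small n; the `survival`
package for KM/log-rank; an independently coded asymptotic series for KS):

* WMW is exact — tie-aware, via dynamic programming over doubled midranks —
  when the smaller group has ≤ 8 observations, otherwise the normal
  approximation with tie and continuity corrections. Two-sided p doubles the
  smaller tail.
* Enrichment tests are one-sided (over-representation); the
  mutation–activity FET is two-sided, since association has no preferred
  direction.
* The KS p-value uses the asymptotic Kolmogorov distribution evaluated to
  machine precision with a two-branch theta-function series. (`ks.test`
  truncates its internal series at tolerance 1e-6, which is why comparisons
  against it are made at 1e-4 while the independent series oracle is matched
  at 1e-8.)

## The synthetic cohort generator

The generator emits the world the model assumes, with known ground truth, so
every stage is testable without downloads. Per miRNA $k$ and tumor $s$:
latent activity $\alpha_{ks} = \sigma_\alpha |N(0,1)|$ (half-normal, so
low-activity samples exist to serve as baselines); functional targets follow
$x_{gs} = b_g(1 - \beta\alpha_{ks}) + N(0, \sigma_x)$ with
$b_g \sim U(4, 12)$, making the fitted through-origin slope analytically
$-\beta\alpha_{ks}$; the miRNA readout is
$\lambda\,\alpha_{ks}\,c + \text{offset} + N(0,\sigma_m)$ clipped at 0.
Subtype structure is additive centroid shifts on a signature block *disjoint*
from all target blocks, keeping subtype recovery and activity recovery
separable tests. Survival is exponential with log-hazard $\gamma\alpha_{k^*}$
under independent uniform censoring whose upper bound is solved numerically
to hit the requested censoring fraction in expectation; the designated
mutation gene is Bernoulli with logit linked to $-\alpha_{k^*}$. Normals have
activity exactly 0.

Defaults (120 tumors, 25 normals, 20 miRNAs × 60 disjoint targets, functional
fraction 0.7, β = 0.4, σ = 0.5, four balanced subtypes, centroid shift 2,
γ = −0.5, 30% censoring) are the stated test-bed conditions. Where the
source states no value, the choices are: activity scale 0.8 — the generator
rejects worlds where $\beta\alpha \ge 1$ in more than 1% of draws (expression
would go negative), which caps the scale near 0.97 at β = 0.4, and 0.8 keeps
a margin; miRNA offset 3 and coupling scale 2, giving log2(RPM+1)-like
readouts with activity–expression correlations around 0.85; baseline hazard
0.05 per time unit (median survival ≈ 14 units at zero activity); mutation
logit intercept −1.5 and slope 1.5 (≈ 12% mutation prevalence, concentrated
in low-activity tumors); background mutation rate 0.15.

What the generator does **not** emulate: read counts and their
mean–variance structure, normalization artefacts, batch effects, overlapping
target sets (blocks are disjoint so that per-miRNA truth is unambiguous),
competing-endogenous-RNA sponging, and correlated miRNA families. A green
recovery test therefore establishes correctness of the inference machinery
under the model's own assumptions, not robustness to real-data violations of
them.

## Numerical and degenerate-input choices

* Missing expression values are a load-time error, never imputed.
* Constant gene rows yield correlation 0 (weight ε) inside IRLS, p = 1 in the
  DE screen, and are dropped from z-scoring with a warning in the mRNA-only
  variant.
* Degenerate median splits (all values equal, or no sample above the median)
  are skipped with a recorded reason, not silently dropped.
* All permutation stages derive their seeds deterministically from one master
  seed (`stage_seed`), so stages can be rerun in isolation and the pipeline
  is byte-reproducible; every derived seed stays below 2^31.

## Known limitations

The planted-prognostic-survival acceptance check is expected to fail under
the stated world, and the package does not paper over it: with γ = −0.5 and
the activity scale capped by the β·α < 1 guard, the median-split
log-hazard-ratio is about 0.4–0.5, giving log-rank z ≈ 2 with ~84 events,
while detection at pooled permutation FDR ≤ 5% among 20 miRNAs needs z ≈ 3.
The screen does rank the planted miRNA at or near the top with the correct
protective direction, and the null calibration holds; only the FDR-level
detection claim is out of reach at this effect size. Increasing γ, the
cohort size, or the activity scale (with a smaller β) would make it
detectable, but those would be different stated worlds.

Other limitations: no confidence intervals on activities; no Cox or
multivariable adjustment; no isomiR/pre-miRNA handling; target maps are
consumed, never inferred; querying the Connectivity Map service is out of
scope (only .grp signature export).
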