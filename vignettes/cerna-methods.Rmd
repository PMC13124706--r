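---
title: "Methods: genome-wide ceRNA network inference and its validation model"
author: "cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide ceRNA network inference and its validation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The inference problem

Competing endogenous RNA (ceRNA) regulation posits that transcripts
carrying binding sites for the same miRNAs compete for a limited miRNA
pool: when one transcript rises, it sequesters shared miRNAs and
de-represses the others. Two observable consequences drive everything
this package computes: (i) transcript pairs coupled through shared
miRNAs should show *positive* expression correlation across samples,
and (ii) perturbing one member of a pair should shift the other in the
same direction.

`cernet` infers a genome-wide lncRNA--mRNA ceRNA network from a bulk
case/control expression cohort (the motivating application is minor
salivary gland biopsies from a primary Sjögren's syndrome cohort, 92
cases vs 34 sicca controls) and then ranks candidate regulator lncRNAs
by the coordinated case/control response of their network interactors.

A ceRNA edge joins lncRNA $L$ and coding gene $G$ when all three of the
following hold:

1. **Shared binding**: at least one *expressed* miRNA (TPM strictly
   above 1) binds $L$ (lncRNA-side binding table, used as supplied) and
   targets $G$ with high confidence (present in both an experimentally
   supported and a computationally predicted miRNA--mRNA table);
2. **Positive co-expression**: Pearson $r(L, G) > 0.5$ (strict) on the
   covariate-adjusted log-expression matrix;
3. **Significance**: Bonferroni-corrected correlation $p < 0.05$, where
   the family size is the full count of lncRNA $\times$ coding pairs
   attempted (pairs dropped for zero variance still count — a
   conservative, reproducible choice, since the natural family is every
   pair the screen considers).

Strict inequalities at both thresholds follow the "greater than"
wording of the thresholds' definitions. The single-shared-miRNA
criterion is deliberately minimal; an optional hypergeometric
overlap test of the shared-miRNA count is easy to add on top of the
recorded `shared_mirnas` edge annotation, but is not part of the
default rule.

## Expression preprocessing

The expression pipeline mirrors standard bulk-tissue practice:

* `log2_quantile_normalize()`: $\log_2(\mathrm{TPM} + 1)$ followed by
  quantile normalization. Each column's ranks are mapped onto the
  vector of cross-column rank means; tied values receive the mean of
  their tied ranks' reference values, so the operation is exactly
  idempotent and all columns share one value multiset afterwards.
  The pseudo-count of 1 is configurable; note that it compresses fold
  changes of transcripts expressed near or below 1 TPM — a real
  phenomenon that the synthetic model (below) also exhibits.
* `adjust_covariates()`: per-gene least squares on the protected design
  (group) plus nuisance covariates (immune-cell fraction, sequencing
  batch), subtracting only the fitted nuisance contribution
  (delegated to `limma::removeBatchEffect`). Immune infiltration
  differs systematically between inflamed and control tissue and
  inflates spurious case/control differences in bulk data; the
  adjustment stage exists to remove exactly that confounding while
  leaving the group contrast untouched.
* `differential_expression()`: ordinary least squares of adjusted
  log2 expression on group (plus any remaining covariates, batch by
  default), classical two-sided t-test on the group coefficient, BH
  correction across genes. A gene is DE when its linear fold change is
  at least 1.5 and FDR < 0.05. This linear model on normalized
  abundances is a deliberate, documented design decision: the
  downstream analyses consume only (log2FC, FDR, DE flag), the
  package's inputs are TPM matrices rather than read counts, and a
  negative-binomial count model would add machinery without changing
  any downstream contract. The method string is recorded in the result
  attributes. Whether the immune fraction enters the DE design as a
  covariate or is removed beforehand is configurable; the default
  pipeline removes it during adjustment.

## Genome-distribution analyses

DE genes are tested for genomic non-uniformity:

* **Clusters**: a cluster is a maximal run of TSS-sorted DE genes on
  one chromosome with consecutive gaps of at most 100 kb and at least
  3 members. No standard definition exists; both parameters are
  exposed, and the defaults give clusters of roughly 4 genes — the
  scale reported for co-regulated disease loci. Significance comes
  from a permutation null: 1000 equal-sized random subsets of the
  *non-DE* genes, with the add-one empirical p-value
  $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$.
  Because the cluster count is integer-valued, the empirical p is
  discrete; calibration checks therefore use a dense gene map where
  the null count distribution is well spread (mean $\approx 40$, so
  attainable tail probabilities bracket 0.05 closely). On sparse maps
  the test is conservative, never anti-conservative.
* **Region and locus enrichment**: one-sided Fisher tests of DE
  membership against TSS location within a fixed region (the HLA locus
  chr6:28,510,120--33,480,577 on hg38 is the default) or within 100 kb
  of any supplied association locus.
* **Distance-binned DE fractions**: coding genes are partitioned by
  distance to the nearest DE lncRNA (gene-body overlap; TSS < 100 kb;
  100--500 kb; > 500 kb) with Wilson 95% intervals per bin and a
  chi-square test across bins. Distances are TSS-to-TSS except the
  overlap bin, which uses gene bodies.

Internally all coordinates are 0-based half-open with TSS = `start` on
the plus strand and `end − 1` on the minus strand; GTF input/output is
1-based inclusive and round-trips exactly. The TSS convention is not
universal across annotation sources, so it is centralized in one
constructor.

## Statistical primitives

All hypothesis tests flow through a small set of wrappers returning a
uniform result type: Fisher's exact test (minimum-likelihood two-sided
rule; the sample cross-product odds ratio $(ad)/(bc)$ with $\infty$
allowed, not the conditional MLE), upper-tail hypergeometric
enrichment, Pearson chi-square (Yates correction on 2×2 by default,
since "chi-square test" is ambiguous), Wilcoxon rank-sum (exact by
enumeration for small untied samples, tie- and continuity-corrected
normal approximation otherwise; two constant identical samples yield
p = 1 by contract), exact binomial (minimum-likelihood two-sided),
Pearson correlation with the $t$-distribution p-value on $n-2$ df
($p = 0$ at $|r| = 1$, flagged), Bonferroni/BH adjustment, and the
add-one empirical p-value. The test suite validates each against full
enumeration over every 2×2 table with $N \le 12$ and against textbook
formulas; the two-sided minimum-likelihood convention is the one under
which the clinical table's two $p = 1$ rows are exact.

The genome-wide correlation engine standardizes each gene vector once
and computes blocks of pairs by matrix multiplication; the result is
independent of the block size up to floating-point associativity
(assertions use a 1e-12 tolerance for cross-block-size comparisons and
1e-10 against the naive per-pair oracle).

## Regulator ranking

Candidate regulators are the DE lncRNAs present in the network. Three
complementary screens are run:

* **Preranked GSEA** (`interactor_gsea_screen`): coding genes are
  ranked by $\mathrm{sign}(\log_2 FC)\cdot(-\log_{10} p)$ (the ranking
  statistic is a design choice; log2FC ranking is available), and each
  lncRNA's interactor set is tested with the classic weighted
  running-sum enrichment score (hit increments $\propto |s|^1$
  normalized over the set, miss decrement $1/(N - m)$, ES = signed
  extremum). The null is built from random same-size gene sets rather
  than phenotype permutation — the preranked situation has no
  phenotype to permute — with the two-tailed add-one empirical p,
  NES = ES / mean |same-sign null ES|, and BH across lncRNAs
  (significant at FDR < 0.01). Sets with fewer than 3 ranked
  interactors are skipped and logged.
* **Hypergeometric DE enrichment** of each lncRNA's interactors, BH
  across lncRNAs with star levels at 0.05/0.01/0.001.
* **Direction concordance**: the fraction of interactors whose log2FC
  sign matches the lncRNA's own.

## Pathway activity

Per-sample pathway scores are a rank-based running-sum statistic: the
integrated difference between the weighted (exponent 0.25) ECDF of
in-set genes and the ECDF of out-set genes along the sample's
expression ranking. Because the rank weighting gives the in-set ECDF a
nonzero expectation even for an evenly spread set, the raw statistic is
centred at its value for an evenly interleaved reference set and scaled
piecewise so that a set occupying the top ranks scores +1, the bottom
ranks −1, and an evenly spread set 0. This is a documented single-sample
surrogate for kernel-based gene-set variation scoring: the downstream
contrasts need only a per-sample score that responds monotonically to
coordinated member-gene shifts, and the rank construction makes the
score exactly invariant to monotone per-sample transforms (asserted in
the tests with $x \mapsto 2x + 7$). Differential pathway activity uses
the Wilcoxon rank-sum test by default (Student's t is available);
"fold change" thresholds on signed set scores are not implemented —
a ratio of scores is undefined where the score crosses zero.

## The synthetic cohort and what it does (and does not) validate

Every stage is validated against a seeded generative model
(`simulation_spec()`); the defaults are the package's study conditions
and are not tuned per run:

* 92 cases vs 34 controls; 3000 coding, 800 lncRNA (20% labelled
  novel), 150 miRNA genes on 5 chromosomes; inter-TSS gaps
  exponential with mean 300 kb.
* Log2 expression
  $x_{gs} = b_g + \beta_g\,\mathrm{case}_s + \gamma_g f_s -
  \sum_k s_{gk} a_{ks} + c_{d(g),s} + \varepsilon_{gs}$,
  $\mathrm{TPM} = 2^x$, residual sd $\sigma = 0.3$.
* **Group effects**: 3% of genes carry $|\beta_g| \sim U(0.6, 1.5)$
  with random sign — matching the DE prevalence (~2.8%) and bulk-tissue
  effect sizes of the motivating cohort. Larger planted effects at
  this small residual sd would make unrelated co-DE genes correlate
  near $r = 0.85$, which real tissue does not show.
* **Immune confounding**: immune fraction $f_s \sim$ Beta(12,8) in
  cases, Beta(8,12) in controls (means 0.6 vs 0.4); 10% of genes carry
  loadings $\gamma_g \sim N(0, 0.5)$; ten marker genes have
  $\gamma = 5$, $\beta = 0$ and a low baseline (~3 TPM, rising with
  infiltration, as infiltrating-cell markers do — a high baseline
  would saturate the top ranks under quantile normalization and mask
  the confounding the markers exist to demonstrate). Markers are DE
  before covariate adjustment and not after; this is the motivating
  property of the adjustment stage.
* **ceRNA coupling**: 200 planted lncRNA--mRNA pairs with coupling
  $s = 1$ to a shared latent miRNA activity $a_{ks} \sim N(\mu_k +
  \delta_k\,\mathrm{case}_s, 1)$. Three lncRNAs are key regulators
  with 40 targets each and mediator shift $\delta = -1.5$ (so the
  regulator and its targets rise ~2.8-fold in cases — the magnitude of
  well-validated abundant regulators; regulator lncRNAs get a
  well-expressed baseline of ~16 TPM because the log2(x+1)
  pseudo-count would otherwise swallow much of a low-TPM lncRNA's fold
  change). Latent *activity*, not miRNA TPM, drives the coupling; the
  miRNA TPM table is generated separately, keeps every mediator above
  the 1-TPM filter, and exists only to exercise that filter.
* **Bindings**: background Bernoulli edges at density 0.02 per
  (miRNA, gene); mRNA-side evidence experimental-only / predicted-only
  / both with probabilities 0.35/0.35/0.30; every planted pair is
  guaranteed a shared mediator with dual evidence.
* **Cis structure**: a shared latent factor (sd 0.3) per 300-kb
  genomic domain — a TAD-like model under which neighbouring genes
  co-vary — plus 30 planted pairs whose lncRNA sits 5--50 kb from its
  partner; two DE gene clusters (5 genes in 150 kb on chr1, 5 in
  200 kb on chr2) with $|\beta| = 1.5$.

Under these conditions the pipeline recovers planted edges with
precision above 0.9 and recall 1.0, places all three regulators in the
screen's top ranks at FDR < 0.01, detects the planted clusters at
empirical $p \le 0.01$, and flags the immune markers only before
adjustment — measured, not assumed, by `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`.

What the model deliberately does not emulate: sequencing-depth noise
and count overdispersion (expression is generated at the TPM level),
miRNA-level kinetics (the coupling is a linear latent-activity model,
matching the correlation-based inference rather than a titration ODE),
hub promiscuity of real miRNAs (background bindings are independent
Bernoulli), and annotation errors. Passing tests therefore show the
*inference machinery* is correct and calibrated under the stated
generative assumptions — not that those assumptions hold in any given
tissue.

## Numerical and reproducibility choices

* One master seed fans out to per-stage seeds through a stable hash of
  the stage name, so each stage is independently reproducible and the
  full demo is byte-identical across runs (the run manifest records
  the seed and configuration and deliberately omits wall-clock
  timestamps for that reason).
* Every randomized function saves and restores the caller's RNG state.
* The degree power-law fit is OLS of log10 frequency on log10 degree
  over *distinct observed degrees* by default; geometric log-binning
  (density-normalized, geometric-mean bin centers) is available for
  noisy empirical distributions but biases the slope on exact
  reference laws, so it is opt-in.
* Problem sizes in the test suite: the full synthetic cohort (126
  samples, 3800 genes, 2.4 million correlation pairs) for the
  recovery checks; a 50-sample / 380-gene cohort for the per-module
  tests; 1000-replicate null simulations for each calibration check.
* Zero p-values are capped at $10^{-320}$ before $-\log_{10}$
  transforms; GSEA scores of exactly zero fall back to unweighted
  increments.

## Known limitations

Correlation-based ceRNA inference cannot distinguish shared-miRNA
competition from any other source of positive co-expression
(co-regulation, shared tissue composition); the binding-site filter
reduces but does not remove this ambiguity, and the overexpression
comparison operations exist precisely to add perturbational evidence.
The Bonferroni family over all pairs is conservative; with small
cohorts it favours precision over recall. The cluster rule and the
100/500-kb distance bins are conventions, not estimates. Pathway
scores are comparable across samples within one matrix, not across
independently normalized datasets.
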