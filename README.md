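# cernet

Genome-wide competing-endogenous-RNA (ceRNA) network inference from
bulk transcriptomes, with regulator-lncRNA prioritization.

## What it is for

Long noncoding RNAs can regulate coding genes by sponging shared
miRNAs: transcripts carrying binding sites for the same miRNAs compete
for them, so a rise in one de-represses the others. In bulk
case/control cohorts this predicts (i) positive expression correlation
between transcript pairs with shared miRNA binding sites and (ii)
concordant case/control changes of a regulator lncRNA and its targets.

`cernet` turns those predictions into a reproducible pipeline for
cohorts such as minor-salivary-gland transcriptomes from primary
Sjögren's syndrome (pSS) cases versus sicca controls:

1. **Preprocessing** — log2 + quantile normalization of TPM,
   covariate adjustment (immune-cell fraction, batch) with the group
   contrast protected, and linear-model differential expression
   (DE: |FC| ≥ 1.5, BH FDR < 0.05).
2. **Genome distribution of DE genes** — inter-gene distances, DE
   clusters (runs of ≥ 3 genes with TSS gaps ≤ 100 kb) against a
   1000-draw permutation null of non-DE genes, and Fisher enrichment
   in fixed regions (HLA) or near association loci.
3. **Genome-wide correlation** — blocked Pearson correlation of every
   lncRNA × coding pair on the adjusted matrix, Bonferroni control
   over the full family, and a binomial test of the excess of positive
   significant correlations.
4. **ceRNA network** — an edge (L, G) requires a shared *expressed*
   miRNA (TPM > 1) binding L and targeting G with dual
   (experimental ∩ predicted) evidence, Pearson r > 0.5 and
   Bonferroni p < 0.05. Degree distributions are tested against a
   power law.
5. **Regulator screens** — per-lncRNA preranked GSEA of interactor
   sets on the signed −log10 p ranking (random-set null, BH FDR),
   hypergeometric DE enrichment of interactors, and direction
   concordance.
6. **Pathway activity** — rank-based single-sample set scores,
   Wilcoxon differential pathways, and lncRNA × pathway interactor
   enrichment grids.
7. **Validation-style comparisons** — overexpression-vs-control DE
   with relaxed-FDR mode, DEG-overlap odds ratios (ALL/UP/DOWN
   strata), and clinical-feature association tables.

A fully seeded synthetic-cohort generator (`simulation_spec()`,
`simulate_cohort()`) plants known ceRNA pairs, key regulators, genomic
clusters and immune confounding, so every stage is tested against
ground truth without any external data. See the methods vignette
(`vignettes/cerna-methods.Rmd`) for the model and all design choices.

## Worked example

```r
library(cernet)

spec   <- simulation_spec(seed = 1)   # 92 vs 34 samples, 3800 genes
cohort <- simulate_cohort(spec)
res    <- run_pipeline(cohort, seed = 1)

res$network
#> cerna_network: 210 edges, 91 lncRNAs, 208 mRNAs (r > 0.5)

res$positivity
#> binomial (two_sided)
#>   statistic = 321   p = 1.338902e-23
#>   positive_fraction = 0.7362385

head(res$gsea_screen, 3)
#>   lnc_id n_interactors    es  nes        p      fdr significant
#> 1  L0003            40 0.960 2.07 0.000999 0.000999        TRUE
#> 2  L0001            40 0.959 2.05 0.000999 0.000999        TRUE
#> 3  L0002            40 0.961 2.04 0.000999 0.000999        TRUE

res$clusters$n_clusters      # 2   (the two planted clusters)
res$clusters$empirical_p     # 0.00599
```

The 210 network edges recover the 200 planted ceRNA pairs with
precision 0.95 and recall 1.0; the three planted regulator lncRNAs
(L0001–L0003) top the GSEA screen at FDR < 0.01; significant
correlations are predominantly positive (74%, binomial p ≈ 1e-23), as
the ceRNA mechanism predicts; and the two planted genomic DE clusters
are significant against the permutation null.

A one-command demo that writes every stage's tables (plus a manifest)
to disk:

```sh
Rscript inst/scripts/run_demo.R --seed 1 --out demo_out
```

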