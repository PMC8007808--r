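# comodule

Whole-blood gene co-expression modules jointly associated with early traits
of two diseases.

`comodule` is an R package for the system-level question: *do groups of
co-expressed genes in blood relate simultaneously to subclinical traits of
osteoporosis (pQCT bone mineral density/content) and atherosclerosis
(carotid/bulbus intima-media thickness)?* It implements the full analysis
chain as a tested, reusable pipeline:

1. **Signed weighted co-expression network** — Pearson correlations `r`
   between all gene pairs, soft-thresholded as `a_ij = ((1 + r_ij)/2)^β`
   (default `β = 10`; scale-free-fit power selection is computed and
   reported for every run).
2. **Topological overlap** — `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 −
   a_ij)` with `L_ij = Σ_u a_iu a_uj`, turned into the dissimilarity
   `1 − TOM`.
3. **Module detection** — average-linkage (UPGMA) clustering and a static
   tree cut with a minimum module size, plus a cluster cohesion filter
   based on the Marchenko–Pastur bulk edge that rejects chance clusters;
   modules are named by colour, unassigned genes are "grey".
4. **Eigengenes** — each module summarised by the first principal component
   of its members' z-scored expression; quality-checked by the correlation
   of gene significance (GS, gene–trait correlation) with module membership
   (MM, gene–eigengene correlation).
5. **Dual-disease screening** — eigengene–trait Pearson correlations with
   Bonferroni adjustment over the modules × traits family; a module is a
   candidate when it is significant for at least one trait of *each*
   disease group.
6. **Joint association (MANOVA)** — for each candidate, Pillai's trace
   `V = tr(H(H+E)⁻¹)` of its eigengene (and of every member gene) against
   the bivariate outcome formed by its most significant osteoporosis and
   atherosclerosis traits, under three models: (1) unadjusted, (2) age +
   sex + BMI, (3) model 2 + smoking + alcohol + physical activity. The F
   transform is exact for these single-predictor tests.
7. **Pathway over-representation** — hypergeometric tests of module genes
   against GMT gene-set collections, Bonferroni-adjusted, with significant
   terms clustered by 1 − Jaccard similarity of their enriched core genes.

Because the motivating cohort data are access-restricted, the package ships
a first-class **synthetic-data generator**: expression with planted modules
(latent factor per module × gene loadings + noise), traits driven by chosen
module factors and covariates with realistic marginals, and matched gene-set
collections — so every stage is testable against known ground truth.

## Worked example

```r
library(comodule)
cfg <- simulation_config(n_samples = 300, module_sizes = c(40, 25, 15),
                         n_background = 320, seed = 7)
d    <- generate_dataset(cfg)                      # planted truth included
sets <- generate_gene_sets(d$truth, n_decoy_sets = 40, seed = 7)
res  <- run_pipeline(pipeline_config(
  expression = d$expression, traits = d$traits, gene_sets = sets,
  out_dir = tempfile("run_"), seed = 7))
```

The run logs each stage:

```
expression_input: 300 samples x 400 genes; 300 samples shared with traits
correlation_network: mode=signed, chosen power=13, using beta=10
module_detection: 3 modules (sizes 79/46/20), 255 genes unassigned; cut_height=0.9985
module_trait_screening: Bonferroni family=30, alpha=0.05, 1 candidate module(s): turquoise
joint_manova: 3 module rows, 237 gene rows
pathway_enrichment: 43 records, 1 significant term(s)
```

The first planted module (40 genes, wired to two bone and two vascular
traits) is recovered as `turquoise` and is the only screening candidate —
its eigengene correlates ~0.44–0.48 with the wired traits while the
trait-null modules sit near zero:

```r
round(res$module_trait$r[, c("CIMTavg", "BIMTmax", "DRToBMC", "TSCoBMC")], 2)
#>           CIMTavg BIMTmax DRToBMC TSCoBMC
#> turquoise    0.44    0.48    0.45    0.48
#> blue         0.02   -0.02    0.00   -0.03
#> brown       -0.02    0.05   -0.05   -0.10
```

Its joint association with the (osteo, athero) trait pair survives all
three covariate models, and its planted gene set is the top enrichment hit:

```r
res$manova_modules[, c("module", "model", "pillai", "F", "p_adj", "significance")]
#>      module model pillai    F    p_adj significance
#> 1 turquoise     1  0.358 82.8 2.57e-29  significant
#> 2 turquoise     2  0.354 80.4 1.39e-28  significant
#> 3 turquoise     3  0.354 79.6 2.72e-28  significant

head(res$enrichment[, c("module", "term", "k", "K", "p_adj")], 3)
#>      module        term  k  K    p_adj
#> 1 turquoise TRUE_SET_M1 34 40 1.65e-19
#> 2 turquoise   DECOY_010  7 17 1.00e+00
#> 3 turquoise   DECOY_028 13 40 1.00e+00
```

Pillai's trace lies in [0, 1] for these one-predictor tests; here ~0.36 of
the bivariate trait variation is attributable to the module eigengene, and
the Bonferroni-adjusted p-values (family = number of candidate modules per
model) remain significant after full covariate adjustment — the signature of
a genuine dual-disease module. Every intermediate table, a JSON manifest of
all parameters/family sizes, and a plain-text log are written to `out_dir`.

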