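# hybridscan

Quantifying hybridization between the flat periwinkles *Littorina fabalis*
and *L. obtusata* — two intertidal sister species at a late stage of
speciation that still exchange genes at some contact sites — from three
complementary lines of evidence:

* **Microsatellites.** A Bayesian two-population admixture model (k = 2,
  independent allele frequencies, Gibbs sampling) yields per-individual
  membership coefficients *Q*; a six-class genotype-frequency model
  (parentals F and O, F1, F2, backcrosses BCF and BCO, with a
  Jeffreys-like Dirichlet(1/A) allele prior) yields class posteriors *Pp*.
  Decision thresholds *TQ* and *TPp* are calibrated by simulating hybrid
  genotypes from the parental allele frequencies and minimising
  pure-vs-hybrid misclassification over a threshold grid.
* **Mitochondrial DNA.** *Cyt-b* haplotypes are collapsed, connected into a
  statistical-parsimony network under the 95% connection-limit criterion,
  and partitioned into two clades; introgression is the proportion of each
  genetic species carrying the clade typical of the other species.
* **Morphology.** Shell outlines (4 fixed landmarks + 24 sliding
  semilandmarks) are superimposed by generalized Procrustes analysis with
  bending-energy semilandmark sliding, analysed by PCA and permutational
  linear models (residual randomization, Z-score effect sizes), and
  classified by a linear discriminant with leave-one-out cross-validation
  (*Pp* ≥ 0.90). Male genitalia are classified by the filament/total-length
  ratio rule and by a seven-feature discriminant (*Pp* ≥ 0.99).

A synthetic-data generator reproduces the statistical structure of the
study system (parental gene pools at Fst = 0.45 over 11 loci, mtDNA clades
with controllable haplotype sharing, two shape/size distributions with
allometry and location effects), so the entire pipeline is testable end to
end without field data. The package is aimed at population geneticists and
morphometricians working on hybrid zones in these or similar taxa.

The MCMC samplers are compiled (Rcpp). Two presets are available
everywhere: `paper` (10^6 sweeps — study scale, hours) and `desk`
(5 × 10^4 sweeps — minutes, used by the tests and examples).

## Worked example

Simulate a study at the system's divergence, run the admixture model,
calibrate *TQ* on the allopatric reference sites, and count hybrids:

```r
library(hybridscan)

sim <- simulate_dataset(sim_config(seed = 1))
sim
#> hybridscan_sim: 300 individuals over 4 locations (seed 1)
#> class
#> BCF BCO   F  F1  F2   O
#>   4  10 140   4   3 139

q <- run_admixture(sim$genotypes, mcmc_settings("desk", seed = 101))
refs <- sim$genotypes[sim$genotypes$meta$context == "allopatric" &
                      sim$genotypes$meta$species != "unknown"]
tq <- calibrate_TQ(refs, n_sim = 100,
                   settings = mcmc_settings("desk", seed = 201))
tq
#> TQ calibration (global scale, all): threshold = 0.90
#> correct classification at optimum: 98.00% (n = 100 per class)

table(truth = sim$truth$true_class,
      called = classify_with_TQ(q, tq$threshold))
#>      called
#> truth hybrid pure_fab pure_obt
#>   BCF      2        2        0
#>   BCO      7        0        3
#>   F        1      139        0
#>   F1       4        0        0
#>   F2       3        0        0
#>   O        0        0      139
```

The calibrated threshold (here 0.90, with 98% of simulated genotypes
correctly separated into pure vs admixed) is then applied to the empirical
*Q* values: backcrosses are mostly caught, at the price of a few pure
individuals flagged as putative hybrids — the trade-off the calibration
measures. The same objects feed the mtDNA accounting
(`build_network()`, `introgression_summary()`) and the shell classifier
(`gpa_align()`, `train_shape_dfa()`); `run_pipeline()` chains every stage
and writes all tables to a run directory.

The per-location count tables printed in the source study are shipped as
plain-text fixtures (`littorina_sites()`, `littorina_mtdna_counts()`,
`littorina_hybrid_counts()`, `littorina_hybrid_clades()`) so the published
accounting can be recomputed directly:

```r
x <- expand_clade_counts(littorina_mtdna_counts())
introgression_summary(x$clade, x$genetic, x$metadata)
#> introgression into L. fabalis: 85/459 (18.52%)
#> introgression into L. obtusata: 49/303 (16.17%)
#> sites with atypical haplotypes: 84.6% (sympatric) vs 30.8% (allopatric)
```

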