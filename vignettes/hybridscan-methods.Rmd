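---
title: "Models and methods behind hybridscan"
author: "hybridscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

# The problem

The flat periwinkles *Littorina fabalis* and *L. obtusata* are intertidal
sister species that still hybridize at some of the shores where they
co-occur. Assessing how much they hybridize — and whether past gene flow has
left mitochondrial haplotypes stranded in the "wrong" species — requires
combining three kinds of evidence per snail: multilocus microsatellite
genotypes, a mitochondrial *Cyt-b* haplotype, and morphology (shell outline
and male genital measurements). hybridscan implements that full analysis as
a reproducible pipeline, together with a synthetic-data generator that
emulates the statistical structure of the system so every stage can be
validated without access to field samples.

# Genotype models

## Two-population admixture (membership coefficients Q)

`run_admixture()` implements the Bayesian admixture mixture model with
k = 2 clusters and independent allele frequencies. For individual $i$ with
allele copies $x_{ilc}$ at locus $l$:

$$Z_{ilc} \mid Q_i \sim \mathrm{Cat}(q_i, 1 - q_i), \qquad
  x_{ilc} \mid Z_{ilc} = k \sim P_{kl}, \qquad
  P_{kl} \sim \mathrm{Dir}(\lambda), \qquad
  Q_i \sim \mathrm{Dir}(\alpha, \alpha).$$

A Gibbs sampler (compiled, `src/admixture.cpp`) alternates between the
allele-origin indicators $Z$, the cluster frequencies $P$, the membership
coefficients $Q$, and a random-walk Metropolis update of the single shared
$\alpha$ under a Uniform(0, 10) prior (proposal s.d. 0.025). Missing allele
copies contribute no likelihood term; individuals with no genotypes at all
are flagged and reported at $Q = (0.5, 0.5)$. The reported $Q$ is the
posterior mean over thinned post-burn-in sweeps (thinning 10). The sampler
is verified against numerical integration of the exact single-locus
posterior in the test suite.

With k = 2 the only label permutation is a column swap, so replicate chains
are aligned by choosing, per replicate, the orientation closest to the
first, and the species identity of the columns is anchored by the putative
species of reference samples (allopatric sites by preference). Replicates
are then averaged and the range of between-replicate correlations reported.

Two presets are provided. The `paper` preset uses the study-scale settings
(10^6 sweeps after 10^5 burn-in; five replicates) and takes hours on a full
dataset. The `desk` preset (5 x 10^4 sweeps after 5 x 10^3 burn-in, two
replicates) keeps the same model at roughly a thousandth of the cost; the
posterior means it produces are Monte-Carlo-converged to about 0.003 on
datasets of a few hundred individuals, which is why the package's tests and
acceptance runs use it throughout.

## Six genotype-frequency classes

`run_class_inference()` classifies individuals into the six classes
relevant to recent hybridization — the parentals F and O, F1, F2, and the
two backcrosses BCF and BCO. Each class is characterised by the expected
fraction of loci whose two alleles descend from (both F, one each, both O):

```{r}
class_proportion_table()
```

These values follow from enumerating gametes over two generations of
crosses; the test suite re-derives them with a brute-force Punnett
enumeration. Per locus, the genotype likelihood under an ancestry state is
the Hardy–Weinberg product under the corresponding pool frequencies (for
the one-from-each state, $p_F(a)p_O(b) + p_F(b)p_O(a)$ for heterozygotes
and $p_F(a)p_O(a)$ for homozygotes). The sampler draws per-individual
classes, per-locus ancestry states, allele-origin assignments, mixing
proportions (flat Dirichlet prior), and pool frequencies under the
"Jeffreys-like" Dirichlet$(1/A_l)$ prior, which accommodates alleles that
are rare or absent in one pool. No prior population information enters the
likelihood; the putative species labels are used only to initialise and to
anchor the class labels after sampling (the pool-swap permutation exchanges
F with O and BCF with BCO). Class membership is reported as the
Rao-Blackwellised average of conditional class probabilities. Replicates
are aligned and compared by their maximum row-wise total-variation
distance; disagreement beyond 0.1 raises a warning.

## Threshold calibration (TQ and TPp)

Both classifiers are turned into decision rules by simulation-based
calibration. `simulate_class()` draws multilocus genotypes of each class
from parental allele frequencies (parentals: two draws from their own pool;
F1: one from each; F2: one gamete from each of two independently simulated
F1 parents; backcrosses: an F1 gamete plus a parental draw; loci
independent). Frequencies are estimated from the reference pools by plain
counting with no pseudo-counts (an optional $1/(2n)$ smoothing flag
exists but is off by default, mirroring the behaviour of the simulation
tool the procedure emulates).

`calibrate_TQ()` simulates 200 genotypes per class by default, runs the
admixture model on simulated plus reference individuals jointly, and sweeps
thresholds $t \in \{0.50, 0.51, \dots, 0.99\}$, calling an individual pure
when $\max(Q) \ge t$. The selected threshold minimises total
misclassification (pure simulated called hybrid plus hybrid simulated
called pure, all classes weighted equally); ties are resolved to the
midpoint of the minimising plateau, which is stable under resampling.

`calibrate_TPp()` does the same with the class model: an individual is
*assigned* when its maximum class posterior reaches the threshold, and
pure/hybrid status follows the arg-max class. The pure/hybrid error curve
alone is non-increasing in the threshold (raising it only shrinks the
assigned set), so minimising errors degenerates to the top of the grid
while discarding nearly every individual. The objective therefore
maximises correct classification — unassigned individuals count against a
threshold alongside pure/hybrid errors — which is the only reading under
which a calibrated threshold can simultaneously deliver a high fraction of
correctly classified individuals and a low error rate, the behaviour the
procedure is meant to certify. Per-class correct-assignment rates, the
error rate alone and the unassigned fraction are all reported. Classification at a chosen threshold is inclusive
(`classify_with_TQ()`, `classify_with_TPp()`; a posterior exactly at the
cutoff is assigned) — as are all posterior-probability cutoffs in the
package.

Calibration can be global or local. `local_scale_plan()` builds the local
groupings: every sympatric site stands alone (both parental pools are
locally available), and each allopatric site is paired with the nearest
site — great-circle distance on the site coordinates — where the missing
species occurs, with distance ties broken toward the lexicographically
smaller site code. Each grouping re-estimates its own allele frequencies.

# Mitochondrial haplotypes

`collapse_haplotypes()` groups sequences by exact string identity (sites
with N stay literal at collapse time; they become wildcards only in
pairwise distance computation, where positions with N or a gap in either
sequence are excluded — gaps are treated as missing data, not as a fifth
state). `build_network()` joins haplotypes at up to the connection limit
into a minimum-spanning forest (Kruskal order, ties broken by smaller
distance then lexicographic haplotype ids); connected components are
clades, the two largest labelled I and II and any remainder flagged
unconnected. Each edge of $d$ steps implies $d - 1$ unobserved intermediate
haplotypes.

The statistical-parsimony connection limit is the largest step count $j$ at
which a connection is still credible at the 95% level. The package
evaluates the probability that an observed difference count is parsimonious
from the underlying model: the true number of mutations $b$ separating two
sequences receives the pairwise-coalescent geometric prior with mean
$\theta$ (estimated by the observed differences, $\theta = j$), mutations
fall uniformly over the $L$ sites, and a site is visibly different exactly
when it was hit an odd number of times. The number of odd-hit sites after
$b$ uniform hits follows a simple birth–death chain
($o \to o + 1$ with probability $(L - o)/L$, else $o \to o - 1$), giving an
exact likelihood $P(J = j \mid b)$, and

$$P(\text{parsimony} \mid J = j) \;=\;
  \frac{P(b = j)\,P(J = j \mid b = j)}
       {\sum_{b \ge j} P(b)\,P(J = j \mid b)}.$$

`connection_limit(569, 0.95)` evaluates to `r connection_limit(569, 0.95)`
steps for the 569 bp *Cyt-b* fragment; the acceptance suite checks the
probability against an independent Monte-Carlo simulation of the same
generative model, and the limit grows with sequence length as it must.

`introgression_summary()` produces the per-location accounting: within each
genetic species (labels from the admixture classification), the number of
individuals carrying each clade, with introgression defined as carrying the
clade typical of the other species. Polarity — which clade is "typical" of
which species — is set by the majority clade among pure individuals of each
species, so relabelling the clades changes nothing. The summary also flags,
per site, whether any species shows at least one atypical haplotype, and
contrasts that fraction between sympatric and allopatric sites; hybrids are
tabulated separately by location and by genotype class.

# Morphometrics

## Superimposition

`gpa_align()` performs generalized Procrustes analysis on the 28-landmark
shell configurations (4 fixed landmarks, 24 semilandmarks along the outline
curve): each configuration is centred, scaled to unit centroid size
(centroid sizes are recorded first — they are the size variable), rotated
onto the consensus by SVD (reflections excluded), semilandmarks slid, and
the consensus recomputed, until the consensus moves by less than $10^{-8}$
or 10 iterations. Each semilandmark slides along the chord between its
outline neighbours. The default sliding criterion minimises thin-plate-
spline bending energy with respect to the consensus — solving
$t = -(U^\top B U)^{-1} U^\top B (x - \bar{x})$ with $B$ the consensus
bending-energy matrix and $U$ the tangent basis — because that is the
operative criterion of the method the digitisation protocol follows;
minimising Procrustes distance instead (plain tangent projection of the
residual) is available via `criterion = "procrustes"`, as the two
descriptions coexist in the literature on sliding semilandmarks. A
degenerate (zero-size) configuration is an error naming the specimen.

Translation and rotation are removed exactly; unit size is a quadratic
constraint, so the scale direction retains second-order variance. The
usable shape space therefore has $2 \times 28 - 4 = 52$ dimensions, which
the test suite verifies by projecting onto the similarity-tangent
directions rather than by a hard rank cutoff.

## Permutational linear models

`procrustes_glm()` fits sequential (Type-I) linear models to shape (the
flattened aligned coordinates) or to log centroid size, with terms entered
in the order written — species first, location nested within species, a
size covariate first when allometry is controlled, and context interactions
for the sympatry-vs-allopatry comparisons. Sums of squares are squared
Procrustes distances. Significance uses residual randomization: for each
term, the reduced-model residuals are permuted (1,000 permutations by
default), the term's SS recomputed, and $p$ taken as the proportion of the
permutation distribution (observed value included) at or above the observed
SS. Effect sizes are Z-scores of the observed SS within the log-transformed
permutation distribution; note that under a 1-df null the log-SS
distribution is heavy-tailed, so even saturating effects yield moderate Z.
Identical seeds give identical tables.

## Discriminant analyses

`train_shape_dfa()` builds the two-species shell classifier from allopatric
reference individuals. The 56 raw shape variables are collinear (rank at
most 52), so the discriminant operates on principal-component scores
retaining 99% of the variance, reduced further if a class would have fewer
individuals than dimensions. Priors equal the training frequencies;
training performance is measured by leave-one-out cross-validation
(`MASS::lda`, which also supplies the LOOCV posteriors). New shells are
projected into the model frame — centred, scaled, rotated onto the training
consensus, then through the stored reduction — and assigned to a species
when its posterior reaches 0.90 (inclusive); otherwise they are
"intermediate shape".

Male genitalia are classified two ways, as in the field protocol: the
visual rule on the filament-to-total-length ratio (10–25% typical of
*L. obtusata*, 30–60% typical of *L. fabalis*, 25–30% intermediate,
anything else unknown), and a seven-feature linear discriminant
(`genitalia_dfa()`) with training-frequency priors and a 0.99 posterior
cutoff. Two of the seven features of the original measurement protocol are
not identified in the available account; the package uses penis base width
and tip width as stand-ins and accepts any complete seven-feature table.
`concordance_report()` cross-tabulates genetic, shell and genital labels
per location.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with every latent label recorded in a truth table:

* **Genotypes.** Two parental pools under a Balding–Nichols
  parameterization: per locus, an ancestral frequency vector from a flat
  Dirichlet over 8 alleles, and pool frequencies from
  Dirichlet(ancestral $\times (1-F)/F$). Because 11 loci leave substantial
  run-to-run spread, the draw is calibrated: the parametric multilocus
  Weir–Cockerham Fst of the drawn pools is computed and the concentration
  re-adjusted until it is within 0.01 of the 0.45 target, so a simulated
  study really sits at the stated differentiation. Genotypes are drawn
  under Hardy–Weinberg within pools; hybrid classes via the class
  simulator.
* **Layout.** Four locations by default — two sympatric (both species, and
  all hybrids), one allopatric site per species — with 50 individuals per
  species per location. The default hybrid composition at sympatric sites
  (1% F1, 2% F2, 2% BCF, 5% BCO) mirrors a BCO-dominated contact, the
  pattern seen where hybridization is common in this system.
* **mtDNA.** Two clade centres 20 transitions apart on a 569 bp fragment,
  four satellite haplotypes per clade at 1–3 steps (star topology).
  Individuals carry their species-typical clade, flipped with probability
  0.185 (*fabalis*) / 0.162 (*obtusata*) — the overall introgression
  proportions observed in the study region; hybrids carry the
  *obtusata*-typical clade with probability 0.8, a maternal bias.
* **Shapes and size.** Two hand-crafted 28-point outlines (a rounder,
  wider-aperture form versus a more elongate one; shipped as a plain-text
  fixture flagged synthetic) set the species means, scaled so their
  Procrustes distance equals `shape_separation` (default 0.15). Each
  individual adds an allometric displacement along the interspecific axis
  (slope 0.1 per unit log size), a per-location offset (s.d. 0.01), and
  isotropic landmark noise (s.d. 0.01), and is then rotated, translated and
  scaled by its centroid size (log-normal; *obtusata* larger). Hybrids are
  placed by expected ancestry.
* **Genitalia.** Seven features per male from species-specific means with
  independent noise; hybrids intermediate by ancestry weight.

The generator does **not** emulate linkage or coalescent ancestry, null
alleles or genotyping error, mutation models beyond what clade assignment
needs, phenotypic plasticity, or age structure in size. Green tests
therefore demonstrate that the inference machinery recovers truth under the
model's own assumptions — not that those assumptions hold for any
particular shore.

# Numerical choices and conventions

* One seed controls each simulation (`sim_config(seed=)`); pipeline stages
  derive their seeds from a master seed by fixed offsets, so stages are
  reproducible in isolation and reruns are byte-identical.
* Allele labels are opaque strings stored as lexicographically ordered
  unordered pairs; missing genotypes are `000` per allele in GenePop and
  empty in CSV, one missing token internally.
* Grid tie-breaks use the plateau midpoint; network tie-breaks are
  lexicographic; all posterior cutoffs are inclusive.
* Test and acceptance runs use the desk preset on a few hundred simulated
  individuals (200 per class for calibration), sizes at which the
  Monte-Carlo error of posterior means (~0.003) is negligible against the
  decision thresholds.

# Known limitations

* The admixture model is k = 2 with independent frequencies only; no
  correlated-frequencies model, no location priors.
* The class model stops at the six two-generation classes; later-generation
  hybrids will scatter among them.
* The parsimony probability is this package's own evaluation of the
  statistical-parsimony model (geometric prior, odd-hit visibility); other
  implementations of the 95% criterion may differ by a step or two in the
  resulting limit.
* At the study divergence (Fst 0.45 over 11 loci with 8 alleles), roughly
  2–4% of truly pure genotypes have posterior membership below 0.95 — an
  information limit of the marker panel, matching the calibration's
  misclassification rates, not a sampler artefact (the sampler is checked
  against exact posteriors).
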