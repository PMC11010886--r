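---
title: "Models and methods: multi-population genomic prediction for pig growth traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pigGP implements the full desk-scale workflow of a multi-population
genomic selection study in Yorkshire-type pig lines: two growth traits
corrected to a 100 kg live-weight endpoint, chip genotype quality
control, population diagnostics, five genomic breeding value models, and
a repeated cross-validation harness that measures how combining
reference populations of different sizes changes predictive accuracy.
This vignette documents the models, the assumptions behind every
tunable parameter, and the design decisions that were genuinely open.

## Trait correction to the 100 kg endpoint

Growth measurements are taken at whatever weight an animal happens to
have near the end of fattening; national evaluation systems standardise
them to a common 100 kg endpoint so animals are comparable. The age
correction uses a sex-specific correction factor in kg/day,

$$\mathrm{CF} = \frac{\text{weight}}{\text{age}} \times c_{\text{sex}},
\qquad c_{\text{male}} = 1.826,\; c_{\text{female}} = 1.715,$$

and corrects age as
$\mathrm{AGE100} = \text{age} + (100 - \text{weight})/\mathrm{CF}$.
Ultrasonic backfat is corrected multiplicatively,
$\mathrm{BF100} = \text{bf} \times n_{\text{sex}} / (n_{\text{sex}} +
s_{\text{sex}} (\text{weight} - 100))$ with
$(n, s) = (12.402, 0.106)$ for males and $(13.705, 0.119)$ for females.
Both corrections are exact identities at 100 kg; AGE100 is strictly
decreasing in weight at fixed age, and BF100 is decreasing in weight
above 100 kg. The additive form of the age correction is the standard
national-program form and is the only reading of the correction that is
dimensionally consistent with CF in kg/day; this choice is asserted by
the endpoint-identity and monotonicity tests. No weight-window exclusion
is applied by the correction itself — any such filter belongs to study
configuration, not to the transform.

## Genotype quality control

QC mirrors standard chip practice for multi-line studies and is applied
*per line*: individuals with overall call rate below 0.9 are removed
first; then, within each line, SNPs with call rate below 0.9 or minor
allele frequency below 0.05 are removed. Exclusion is strict
(`< threshold`), so a MAF of exactly 0.05 survives. Because the three
lines are analysed both separately and jointly, combined analyses use
the **intersection** of the per-line surviving SNP sets — the
conservative rule that guarantees every retained SNP passed QC in every
member line. (A joint re-QC of the pooled data is the main alternative;
intersection was chosen because it preserves the per-line MAF guarantee
that the per-line filters establish.) Residual missing calls after QC
(at most 10% per SNP by construction) are mean-imputed per SNP, which
preserves allele frequencies and is the standard preparation for
VanRaden's G.

A deliberate invariant of the whole package is that the **coded allele
of every SNP is fixed when the data are created** (via an allele sidecar
next to the MAP file, or a fixed alphabetical ordering when none
exists) and never re-inferred from frequencies. Re-coding by minor
allele per subset would silently flip dosage meaning between lines and
corrupt every cross-line analysis.

## Population diagnostics

PCA standardises each SNP column by its analysis-set frequency
(centre $2p$, scale $\sqrt{2p(1-p)}$) and decomposes the
individual-by-individual covariance $WW'/m$; scores are projections on
the leading right singular vectors. The line separation visible on a
PCA plot is quantified as the mean silhouette width of the line labels
in (PC1, PC2) space; the synthetic three-line data must exceed 0.3.

Linkage disequilibrium is the composite (genotypic) $r^2$ — the squared
Pearson correlation of dosage vectors — because chip data are unphased;
this matches the default behaviour of the standard QC tooling. Pairs
are restricted to within-chromosome distances below a cutoff, and
monomorphic pairs are skipped with an accounting.

Effective population size is recovered from LD decay through Sved's
relation $E[r^2] = 1/(\alpha + 4 N_e c)$: per distance bin, base-pair
distance maps to recombination fraction $c$ by Haldane's function at
1 cM/Mb, the bin mean $r^2$ is adjusted for finite sample size
($r^2 - 1/n$), and the relation is inverted to give $N_e(t)$ at
$t = 1/(2c)$ generations ago. The constants ($\alpha = 2$, the $1/n$
adjustment, 1 cM/Mb) are the common defaults of LD-based $N_e$
software; none are fixed by theory alone, so all are configurable. One
subtlety the tests exploit: when the *entire* census is genotyped, the
observed $r^2$ *is* the population $r^2$ and the sampling adjustment
must be dropped — with it, $N_e$ is biased upward by roughly a third in
a census of 50. The estimator is validated two ways: exact inversion of
noiseless Sved input, and a 20-generation constant-size gene-dropping
simulation whose LD-based trajectory must be flat and within ±30% of
the census size (the pedigree-realised size, measured from the
inbreeding rate, is within a few percent of census in this design).

## Relationship matrices

* **G** (genomic): VanRaden method 1,
  $G = (M - P)(M - P)'/(2\sum_k p_k(1-p_k))$, with $p_k$ the
  coded-allele frequency of SNP $k$ in the analysis set. When $p$ is
  estimated from the same individuals, $G$ is singular (the vector of
  ones is in its null space); all solvers therefore work on the
  positive eigenspace of $G$ and never require $G^{-1}$.
  Frequencies for each cross-validation analysis are computed from the
  full analysis set (reference plus validation), since validation
  *genotypes* are legitimately available at prediction time.
* **A** (pedigree): the tabular method on an ancestors-first pedigree;
  verified against an independent recursive-coancestry oracle.
* **H⁻¹** (single-step): the standard construction
  $H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G_b^{-1} - A_{22}^{-1}
  \end{bmatrix}$ with unit weights on both blocks. $G$ is first rescaled
  so its mean diagonal and mean off-diagonal match $A_{22}$, then
  blended, $G_b = 0.95\,G_{\text{tuned}} + 0.05\,A_{22}$, which
  guarantees invertibility. The blending fraction and the two block
  weights are exposed as arguments because different single-step
  implementations make different choices; the defaults are the most
  widely used ones. The construction is validated against the direct
  joint-distribution form of $H$ on a small fixture.

## The five GEBV models

All five models share the linear model
$y = Xb + (\text{genetic term}) + e$ with fixed effects limited to an
overall mean and sex. Line-of-origin is deliberately **not** a default
fixed effect in combined analyses (a flag exists): the questions the
harness asks are precisely about between-line information transfer, and
absorbing line means would change what "combined reference" measures.

**BayesA / BayesB / BayesC** are single-site Gibbs samplers written in
compiled code (this is the package's core, authored from first
principles rather than delegated):

* BayesA — every marker has an effect; each effect has its own variance
  with a scaled-inverse-$\chi^2$ prior (df $v = 4.2$); the full
  conditional of the variance is $(Sv + g_i^2)/\chi^2_{v+1}$.
* BayesB — a point-mass mixture: a marker is null with prior
  probability $\pi$ and otherwise behaves as in BayesA. The indicator
  is sampled from the marginal likelihood ratio with the effect
  integrated out (collapsed Gibbs), which mixes far better than
  conditioning on the current effect. At $\pi = 0$ the BayesB update
  sequence is *identical* to BayesA — the tests assert equality of the
  chains, not mere correlation.
* BayesC — the same mixture but with a single variance shared by all
  included markers, drawn from $(Sv + \sum_{\text{incl}} g_i^2)/
  \chi^2_{v + k}$.

The package uses one consistent mixture convention — $\pi$ is the
**null fraction** — and documents that in the BayesC literature
convention the same parameter appears as the inclusion probability
$1 - \pi$. Genotypes are centred by twice the training-set allele
frequency in all three samplers (for the mixture models that is also
the literature's $-2p/1-2p/2-2p$ coding); with an intercept in the
model, centring changes nothing statistically but improves mixing.
The prior scale derives from a prior heritability of 0.5 by
$S = \sigma^2_y h^2_{\text{prior}} (v-2) / (v (1-\pi) \cdot 2\sum_k
p_k(1-p_k))$, the standard rule that makes the implied prior genetic
variance match $h^2_{\text{prior}} \sigma^2_y$; the residual scale is
set analogously. Default chain settings (20 000 iterations, 4 000
burn-in, thinning 10) are conservative for datasets of a few hundred to
a few thousand animals; the reduced pipeline runs in the tests and the
acceptance script use 600-iteration chains, which is sufficient for the
structural assertions they make (closed-form equivalences are tested
with 4 000-iteration chains). Samplers draw exclusively from R's RNG,
so every chain is reproducible from `set.seed()`.

**GBLUP / ssGBLUP** estimate variance components by EM-REML on
Henderson's mixed-model equations, using the absorbed form
$\hat u = (Z' P_X Z + \alpha K^{-1})^{-1} Z' P_X y$: one generalised
eigendecomposition makes each EM iteration O(q²), so several hundred
iterations cost less than the setup. EM was chosen over AI-REML for its
guaranteed monotone REML log-likelihood (asserted at every iteration in
the tests) and unconditional stability at desk scale; its slower
convergence is priced in via the iteration cap. GBLUP handles the
singular VanRaden G by rank truncation of its spectrum (tolerance
`1e-8` relative to the largest eigenvalue); validation animals are
predicted through $G_{\text{new,train}} G_{\text{train}}^{-}
\hat g_{\text{train}}$ on the same eigenspace. ssGBLUP solves the same
equations with $K^{-1} = H^{-1}$ over every pedigree individual, so
phenotyped but non-genotyped ancestors contribute information — the
tests verify that their breeding values correlate positively with
simulated truth, and that the model degenerates exactly to pedigree
BLUP (no genotypes) and to GBLUP (all genotyped, blending off).

## Cross-validation harness

Three reference-composition scenarios are evaluated for each target
line: all three lines combined, the two other lines predicting the
target, and the target line alone. The target line is split into five
nearly equal folds (sizes differ by at most one); each fold in turn is
the validation set with phenotypes masked; the plan is repeated (20
repeats at study scale, 2 in the reduced runs) and the reported
accuracy is the mean over repeats of per-repeat fold means. Accuracy
is the Pearson correlation between GEBV and the corrected phenotype of
the validation animals; dividing by $\sqrt{h^2}$ (to approximate the
correlation with true breeding values) is available behind a flag but
off by default, because raw correlations are the magnitudes such
studies tabulate. In the two-predict-third scenario the target's
non-validation folds are excluded from training by default — the
literal reading of "two populations predict the third" — with a flag
for the alternative where they join the reference; both readings are
defensible and the harness implements both. Training never sees
validation phenotypes; the tests prove it by perturbing validation
phenotypes and asserting bit-identical fits.

## The synthetic data generator

No genotype archive accompanies the study design this package
operationalises, so the generator is a first-class module that defines
the study conditions: three lines of 295 / 500 / 1500 genotyped animals
(60 / 100 / 200 in the reduced test configuration), tens of thousands
of SNPs (2 000 in tests), two traits with heritabilities 0.40 (AGE100)
and 0.50 (BF100) — moderate-to-high, as reported for these traits —
with phenotypic SDs of 8 days and 2 mm, sex effects of −5 days and
−1.2 mm for males, and a three-generation pedigree in which 75% of
individuals are genotyped (the youngest generation) and the ancestors
carry phenotypes only, which is what gives ssGBLUP something to work
with.

Line divergence follows the Balding–Nichols model: line frequencies are
Beta-distributed around a common base frequency with variance
$F_{st}\,p(1-p)$. The default $F_{st} = 0.1$ is a calibration choice —
the source design reports PCA separation but no divergence statistic —
picked once as a value typical of distinct breeding lines within a
breed and verified to separate the lines on PC1/PC2 (silhouette ≈ 0.9);
it was not revisited afterwards. Genotypes descend through the pedigree
by gene dropping. By default loci segregate independently, which keeps
every Mendelian oracle exact (full-sib genomic relationship 0.5,
parent-offspring transmission certainty); an LD mode instead copies
parental haplotypes in blocks with Haldane-probability switches at
1 cM/Mb, and is used wherever LD structure itself is under test ($N_e$
estimation). QTL effects are drawn standard normal at 200–300 loci
shared across the lines and rescaled to hit the target heritability;
raw measurements are *back-computed* from the simulated corrected
traits by inverting the endpoint corrections at a measurement weight
drawn near 100 kg, so the correction module is exercised end-to-end and
must reproduce the simulated traits exactly.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic recombination maps and ancestral
LD shared between lines (line founders are drawn in linkage
equilibrium), selection and assortative mating, genotyping error, and
non-additive genetic variance. Two consequences matter for
interpretation. First, because causal loci are genotyped and their
effects are identical across lines, cross-line prediction is *easier*
here than in real multi-population data; the harness's directional
findings (accuracy rises with reference size; combining references
helps the smallest line at moderate divergence; cross-line accuracy
falls as divergence grows) are qualitative reproductions, not
quantitative ones. Second, the published accuracy tables of any real
study of this design are computed on real animals and are not
reproducible from synthetic data; the package therefore validates by
oracle equivalence and property, not by matching those numbers.

## Numerical choices

* Variance floors of 1e−12 in the samplers; EM-REML tolerance 1e−6 on
  relative parameter change, 500-iteration default cap (reduced caps in
  the pipeline runs, where variance components are nuisance
  parameters).
* Rank tolerance for G's eigenspace: 1e−8 × largest eigenvalue.
* PCA sign convention: the largest-magnitude loading of each component
  is positive, making scores deterministic.
* Ties in fold allocation resolved by the seeded random permutation;
  fold sizes differ by at most one by construction.
* Degenerate inputs fail loudly: all-monomorphic G, empty SNP
  intersections, cyclic pedigrees, unknown sex/line labels, and
  half-known parent pairs are errors, not warnings.

## Problem sizes used in the shipped runs

The test suite and the acceptance script run the reduced study
(60 / 100 / 200 animals, 2 000 SNPs, 200 QTL per trait): the full
nine-scenario × five-model × two-trait grid with 2 repeats of 5-fold
cross-validation, 600-iteration samplers, and EM-REML capped at 40
iterations. These sizes were chosen so the whole suite reruns in
minutes on one core while every structural assertion of the full-scale
design still binds; all of them scale up by changing `sim_config()`,
`mcmc_settings()` and the CV plan arguments.
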