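---
title: "Estimating and mapping the inbreeding load: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and mapping the inbreeding load: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbredload)
```

## The problem

Inbreeding depression -- the decline in performance of inbred animals --
arises when recessive or partially recessive alleles carried by an
ancestor are made homozygous in its inbred descendants.  Each ancestor
therefore carries a latent, heritable quantity: its *inbreeding load*,
the expected phenotypic change in a fully inbred descendant tracing both
alleles to that ancestor.  Loads vary between ancestors, and because
they are additive quantities they can be treated like breeding values:
given enough inbred descendants with records, an ancestor's load can be
predicted, its variance estimated, and its correlation with the ordinary
additive genetic effect quantified.

`inbredload` implements this programme end to end for pedigreed
livestock populations with optional SNP data: decomposition of
inbreeding into per-ancestor parts, a bivariate Bayesian animal model
for additive effects and loads under pedigree or single-step genomic
relationships, and back-solving of the fitted animal-level solutions
into SNP effects to scan the genome for regions carrying load variance.

## Partial inbreeding coefficients

The inbreeding coefficient of animal $x$ equals the kinship of its
parents.  Every identity-by-descent event behind that kinship is created
by the Mendelian sampling of exactly one ancestor $j$: the two allele
lineages of $x$ first meet in a single allele copy of $j$.  Partitioning
by that event,

$$F_x = \sum_j F_x^{(j)},$$

where $F_x^{(j)}$ is the probability that the coalescence happens at
$j$.  `partialInbreeding()` computes these terms exactly with a
partial-kinship tabular recursion: for each candidate ancestor $j$
(a common ancestor of the parents of at least one inbred animal), a
partial kinship $\theta_j$ is propagated through the pedigree with the
usual tabular rules but with the self term placed only at $j$
($\theta_j(c,c) = \tfrac12[c=j] + \tfrac12\,\theta_j(s_c,d_c)$);
then $F_x^{(j)} = \theta_j(s_x, d_x)$.  Summed over $j$ this reproduces
the parents' kinship identically, so conservation holds to numerical
precision -- the package refuses to return a decomposition whose row
sums disagree with the Meuwissen--Luo coefficients by more than 1e-8.

Two properties follow and are enforced in the tests: coefficients are
nonnegative, and $F_x^{(j)} = 0$ unless $j$ is an ancestor (or equal to)
both parents of $x$.  An independent Monte Carlo oracle
(`geneDropInbreeding()`) drops uniquely labelled allele copies through
the pedigree and attributes each autozygosity event to the individual
containing the first shared allele-copy node; the exact decomposition
and the oracle agree within Monte Carlo error, which pins down the
attribution convention.  (An alternative exact partition seeds each
ancestor with its Mendelian sampling *variance* $d_j$ and spreads
contributions onto the ancestors of inbred common ancestors; it
conserves $F$ equally well but does not match the first-coalescence
attribution, so it is not used.)

All positive coefficients are stored without truncation: most are tiny
in deep pedigrees, but truncating them would break the conservation
identity that the model relies on.

## The model

For records $\mathbf y$ the base model is

$$\mathbf y = \mathbf f d + \mathbf X\mathbf b + \mathbf W\mathbf h +
\mathbf Z\mathbf u + \mathbf K\,\mathbf i + \mathbf e,$$

with $\mathbf f$ the pedigree inbreeding of each record's animal (so $d$
is the mean depression at $F = 1$), $\mathbf b$ fixed effects,
$\mathbf h \sim N(0, \mathbf I\sigma^2_h)$ herd-year-season effects,
$\mathbf u$ additive genetic effects and $\mathbf i$ inbreeding loads.
Traits recorded at variable ages add a centered age covariate
$\mathbf t c$; repeated-records traits add a permanent environmental
effect $\mathbf L\mathbf p \sim N(0, \mathbf I\sigma^2_p)$
(`modelSpec()` selects the variant).  The load incidence is
$\mathbf K = \mathbf R\,\mathbf T(\mathbf I - \mathbf P)$ where
$\mathbf T$ holds the partial inbreeding coefficients, $\mathbf P$ is
the parent matrix (0.5 at each known-parent link) and $\mathbf R$ maps
records to animals.  The joint prior is

$$\begin{pmatrix}\mathbf u\\ \mathbf i\end{pmatrix} \sim
N\!\left(\mathbf 0,\; \mathbf V \otimes \mathbf H\right),\qquad
\mathbf V = \begin{pmatrix}\sigma^2_u & \sigma_{ui}\\
\sigma_{ui} & \sigma^2_i\end{pmatrix},$$

where $\mathbf H$ is the pedigree numerator relationship matrix
$\mathbf A$, or the single-step matrix combining $\mathbf A$ with the
VanRaden genomic matrix $\mathbf G$ on the genotyped subset
(`hInverse()`, which implements the standard inverse augmentation
$\mathbf H^{-1} = \mathbf A^{-1} + [\,\mathbf 0;\ \mathbf 0,\
\mathbf G_s^{-1}-\mathbf A_{22}^{-1}]$).

### Genotype handling

QC applies, in order: autosome restriction, SNP call rate $\ge 0.95$,
and MAF with strict exclusion below 0.05 (a SNP at exactly 0.05 is
kept).  Missing genotypes are then imputed to $2\hat p_j$, which
preserves column means, and frequencies are recomputed.  The blending
weight of $\mathbf G_s = (1-\beta)\mathbf G + \beta\mathbf A_{22}$
defaults to $\beta = 0.05$ with optional rescaling of the mean diagonal
and off-diagonal to match $\mathbf A_{22}$ -- standard single-step
practice, exposed as arguments because no single convention is
universal.

## Gibbs sampler

`fitLoadModel()` samples all unknowns from their full conditionals.
Fixed effects and covariates are updated single-site with flat priors;
HYS and permanent-environment levels single-site under their Gaussian
priors; and each animal's pair $(u_j, i_j)$ as a joint 2-block using the
sparse $\mathbf H^{-1}$ structure.  The block update matters: with a
strongly negative $\sigma_{ui}$, single-site updates of $u_j$ and $i_j$
mix poorly.

Flat variance priors ("uniform within the parametric space") are
implemented as the limiting conjugate forms:

* $\sigma^2_e \mid \cdot = \mathrm{SSE}/\chi^2_{n-2}$,
* $\sigma^2_h \mid \cdot = \mathbf h'\mathbf h/\chi^2_{q_h-2}$ (same
  form for $\sigma^2_p$),
* $\mathbf V \mid \cdot \sim \mathrm{IW}(q - 3 + a,\ \mathbf S)$ with
  $\mathbf S = [\mathbf u'\mathbf H^{-1}\mathbf u,\
  \mathbf u'\mathbf H^{-1}\mathbf i;\ \cdot,\
  \mathbf i'\mathbf H^{-1}\mathbf i]$.

The inverse-Wishart degrees-of-freedom convention is the one genuinely
open choice: $\nu = q - 3$ makes the density proportional to
$|\mathbf V|^{-q/2}\exp(-\tfrac12\mathrm{tr}(\mathbf S\mathbf V^{-1}))$,
i.e. the likelihood of the $q$ animal pairs times a flat prior on
$\mathbf V$.  The offset $a$ (`dfAdjust`, default 0) is exposed so the
sensitivity of results to this convention can be checked directly;
at the design sizes used here, moving $a$ by a few units does not move
the posteriors appreciably.

Default chain settings are 50,000 iterations with 10,000 burn-in and
thinning 10.  These are desk-scale settings chosen so that a full
recovery study (twenty replicate fits) completes in minutes; production
analyses of large national datasets conventionally run chains an order
of magnitude longer, and the settings are plain arguments.  Chains are
reproducible bit for bit given a seed (all randomness flows through R's
RNG, single-threaded).

Correctness is established two ways: with variances fixed, posterior
means of all location effects must solve Henderson's mixed-model
equations (checked against a direct sparse solve within Monte Carlo
error); and the degenerate known-mean model must reproduce the analytic
scaled inverse-chi-square posterior of $\sigma^2_e$ (checked by a
Kolmogorov--Smirnov test).

### Derived quantities

* Accuracy: $\mathrm{acc}_j = \sqrt{1 - \mathrm{PSD}_j^2/(H_{jj}\,\sigma^2)}$,
  clamped at 0, using the posterior SD of the effect, the H diagonal and
  the posterior-mean variance.  The squared PSD is used (the
  corresponding published formula omits the square, which is
  dimensionally inconsistent).
* Depression percentages: $D\%\text{-}M = 100\,|d|/\bar y$ and
  $D\%\text{-}SD = 100\,|d|/s_y$, with the PSD of $d$ transformed by the
  same scale factors.
* Load-variance ratio at a reference inbreeding level $F$:
  $F^2\sigma^2_i/(\sigma^2_u+\sigma^2_h+\sigma^2_p+\sigma^2_e)$,
  computable per MCMC sample or from posterior means.  Whether the
  environmental variances belong in the denominator is a reporting
  convention; `includeEnv = TRUE` (the default) includes them.

## SNP effects and window scans

With posterior means $\hat{\mathbf u}$, $\hat{\mathbf i}$ restricted to
the genotyped animals, SNP effects follow from the GBLUP/SNP-BLUP
equivalence,
$\mathbf s = \mathbf W_g'\mathbf G^{-1}\hat{\mathbf v} / \sum_j 2\hat
p_j(1-\hat p_j)$, per-SNP variances are $2\hat p_j(1-\hat p_j)s_j^2$,
and windows of 25 or 50 consecutive SNPs within a chromosome accumulate
them, expressed as percentages of the genome-wide sum (LD covariances
between SNPs are ignored, as in the standard implementations, so the
percentages are an approximation to the true genetic variance shares).
Windows slide by one SNP by default; disjoint windows are available and
make the percentages sum exactly to 100.  Regions above 1% are merged
across overlapping windows per component.  When frequencies are
estimated from the sample, $\mathbf G$ is singular (centering) and must
be blended before back-solving; the equivalence test instead supplies
known founder frequencies, under which $\mathbf W_g\mathbf s$
reproduces the input values to machine-level accuracy.

## The synthetic-data generator

Because the motivating datasets in this field are not public, the
package generates data with exactly the estimator's structure:

* **Pedigree** (`simulatePedigree()`): discrete generations with a
  configurable fraction of close matings -- full-sib pairs and/or
  females mated back to their own sire.  The parent-offspring type
  mimics the heavy use of popular AI sires and concentrates partial
  inbreeding on single ancestors.
* **Genotypes** (`simulateGenotypes()`): founder haplotypes from
  per-SNP frequencies, unlinked gene dropping to descendants, optional
  missingness for QC testing.  Unlinked SNPs are sufficient for the QC,
  G-matrix and back-solving checks; the generator does *not* emulate LD,
  so passing window-scan tests says nothing about LD-induced smearing of
  real scans.
* **Phenotypes** (`simulatePhenotypes()`): $(\mathbf u,\mathbf i) \sim
  N(\mathbf 0, \mathbf V\otimes\mathbf A)$ drawn by the pedigree
  Cholesky recursion (truth generation deliberately uses the pedigree
  relationship, never the estimator's genomic machinery), plus HYS,
  permanent-environment and residual draws, assembled exactly per the
  configured model equation.

The default variance preset mirrors the published birth-weight
magnitudes for the Rubia Gallega population
($\sigma^2_u = 9.27$, $\sigma_{ui} = -11.03$, $\sigma^2_i = 57.97$,
$\sigma^2_h = 7.89$, $\sigma^2_e = 29.49$, $d = -1.20$ at $F = 1$,
mean 42.65 kg), so tests run at realistic signal-to-noise; these are
presets, not estimation targets.  The default pedigree design (40
founders, 6 generations, 25 matings of 2, close fraction 0.30) yields a
mean inbreeding coefficient near 0.05, comparable to the levels reported
for intensively pedigreed beef populations.

### The recovery design

Estimating $\sigma^2_i$ and especially the sign of $\sigma_{ui}$
requires many ancestors whose loads are well determined, which in turn
requires many inbred descendant records per ancestor -- the published
analyses leaned on hundreds of thousands of inbred records.
`recoveryDesign()` freezes the desk-scale study conditions used by the
package's parameter-recovery checks: the birth-weight preset on a
deliberately informative design of 40 founders, 7 generations, 60
matings of 3 offspring, close-mating fraction 0.85 of the
parent-offspring type, and 4 records per animal (about 1,300 animals,
5,000 records, mean $F \approx 0.28$).  At these conditions, twenty
replicate fits with 50,000-iteration chains cover the generating
$\sigma^2_u$, $\sigma^2_i$, $\sigma_{ui}$ and $d$ with their HPD95
intervals at the nominal rate, and the posterior probability of a
negative additive-load correlation typically exceeds 0.9 (its
replicate-to-replicate spread reflects the realized Mendelian sampling
of each simulated pedigree, so the checks summarize it by the median).
Sparser or less inbred designs leave $\sigma^2_i$ dominated by its
heavy-tailed flat-prior posterior; that is a property of the data, not
of the sampler, which is verified separately against the mixed-model
equations.

## Numerical choices and degenerate inputs

* Topological sorting breaks ties by birth year and then by animal
  label, making the ordering invariant to row permutations of the input
  file.
* Unknown parents are index 0; no genetic-group modelling.  Animals with
  an unknown parent have $F = 0$ and Mendelian sampling scalings follow
  the standard unknown-parent adjustments.
* A-inverse uses Henderson's rules with inbreeding; the A22 block is
  computed exactly by the tabular method on the ancestor-pruned
  pedigree (Colleau's indirect method would only pay off far beyond
  desk scale).
* "Pedigree depth" is reported as the per-animal generation count
  (founders 0, else 1 + max parent generation), flagged approximate:
  depth statistics are not standardized across packages.
* The one-pass outlier filter computes mean and SD on the input set and
  removes records beyond 3 SD; it is deliberately not iterated.
* Back-solving refuses near-singular G (reciprocal condition below
  1e-12) and advises blending; V draws that fail positive-definiteness
  abort with a diagnostic rather than being silently jittered.
* Windows wider than a chromosome collapse to one chromosome-wide
  window with a warning.

## Limitations

* Loads are modelled for inbreeding only; decomposition of coancestry,
  ROH-based inbreeding measures, genetic groups and metafounders are out
  of scope.
* The simulator omits selection response, LD and major genes; a
  large-effect locus can be mimicked by post-hoc editing of simulated
  effects but is not built in.
* Single-trait models only; no REML comparison path.
* Accuracy uses an approximate H diagonal for genotyped animals (the
  blended genomic diagonal), adequate at desk scale.
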