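# inbredload

Quantifying and mapping the **inbreeding load** in pedigreed livestock
populations.

Inbreeding depression is caused by hidden ancestral loads: each ancestor
carries recessive (or partially recessive) alleles that are harmless in
heterozygotes but depress performance when inbreeding makes them
homozygous in its descendants. Because these loads are additive,
heritable quantities, they can be predicted like breeding values,
their variance estimated, and their genetic correlation with ordinary
additive effects measured — information that matters for managing
unavoidable inbreeding in closed populations and for locating genomic
regions harbouring deleterious alleles.

`inbredload` is aimed at quantitative geneticists working with
pedigree + phenotype (+ optional SNP) data. It implements:

* **Pedigree machinery** — topological sorting, Meuwissen–Luo
  inbreeding coefficients, Henderson's sparse A⁻¹ with inbreeding,
  tabular A submatrices (`pedigree()`, `aInverse()`,
  `relationshipMatrix()`).
* **Mendelian decomposition of inbreeding** — exact per-ancestor
  partial coefficients F_x^(j) with `sum_j F_x^(j) = F_x` to numerical
  precision, validated against a gene-dropping Monte Carlo oracle
  (`partialInbreeding()`, `geneDropInbreeding()`), and the load
  incidence **K = T(I − P)** (`buildK()`).
* **A bivariate Bayesian animal model** — `y = fd + Xb + Wh + Zu + Ki
  (+ tc)(+ Lp) + e` with prior `(u, i) ~ N(0, V ⊗ H)`, fitted by a
  compiled Gibbs sampler with joint (u_j, i_j) block updates and flat
  variance priors; H is the pedigree A or the single-step matrix
  combining A with VanRaden's G (`fitLoadModel()`, `hInverse()`).
* **GBLUP → SNP-BLUP back-solving and window scans** — SNP effects
  `s = W_g'G⁻¹û / Σ 2p(1−p)`, per-SNP variances `2p(1−p)s²`, 25/50-SNP
  window percentages and the >1% region rule (`backsolveSnpEffects()`,
  `windowVariances()`, `topRegions()`).
* **A synthetic-data generator** — pedigrees with configurable close
  matings, gene-dropped genotypes and phenotypes drawn exactly under
  the model equation (`simConfig()`, `simulatePedigree()`,
  `simulateGenotypes()`, `simulatePhenotypes()`), so the entire
  pipeline is testable without external data.
* **Orchestration** — `runFullAnalysis()` runs decompose → relationship
  matrices → fit → back-solve from one seeded config and writes CSV
  reports plus a manifest; `inst/exec/inbredload` is a thin CLI
  (`ped-stats`, `decompose`, `simulate`, `report`).

## Worked example

A full-sib mating (S × D, both offspring of G1 × G2, where G1 has
founder parents U and V):

```r
library(inbredload)
ped <- pedigree(
  animal = c("U","V","G1","G2","S","D","X"),
  sire   = c("0","0","U","0","G1","G1","S"),
  dam    = c("0","0","V","0","G2","G2","D"))
inbreeding(ped)
#>   G2    U    V   G1    D    S    X
#> 0.00 0.00 0.00 0.00 0.00 0.00 0.25

pt <- partialInbreeding(ped)
partialTriplets(pt)
#>   individual ancestor partial_F
#> 1          X       G2     0.125
#> 2          X       G1     0.125
```

X's inbreeding of 0.25 splits equally between the two grandparents in
which its allele lineages can first coalesce; U and V carry none of it.
The model's load incidence row for a record on X is `K = T(I − P)`:

```r
buildK(pt, parentMatrix(ped), which(animalIds(ped) == "X"))
#>      G2       U       V    G1 D S X
#> X 0.125 -0.0625 -0.0625 0.125 . . .
```

Fitting the load model on simulated data (birth-weight-magnitude
preset, popular-sire design):

```r
cfg <- simConfig(nFounders = 24, nGenerations = 5, nMatings = 20,
  closeMatingFraction = 0.5, closeMatingType = "parent-offspring",
  recordsPerAnimal = 2)
ped  <- simulatePedigree(cfg, seed = 1)
pt   <- partialInbreeding(ped)
sim  <- simulatePhenotypes(ped, pt, cfg, seed = 2)
des  <- assembleDesign(sim$records, modelSpec(trait = "value", fixed = "sex"), ped, pt)
fit  <- fitLoadModel(des, aInverse(ped), nIter = 20000, burnIn = 5000, thin = 10, seed = 3)
varianceSummary(fit)
#>   parameter    mean     psd hpd95Lower hpd95Upper
#> 1  sigma_u2  13.397   3.716      6.819      20.56
#> 2  sigma_ui  -8.632  27.660    -55.190      38.87
#> 3  sigma_i2 151.516 161.908     12.957     457.02
#> 4  sigma_h2   7.638   3.631      2.380      15.30
#> 5  sigma_e2  27.967   2.578     23.264      33.27
#> 6         d  -6.180   4.338    -14.297       1.83
#> 7   corr_ui  -0.117   0.633     -0.946       1.00
```

`sigma_u2`/`sigma_i2`/`sigma_ui` are the additive, load and covariance
components of V (squared trait units; the load variance refers to a
fully inbred descendant of a single ancestor, so it is rescaled to a
reference inbreeding level for interpretation — `loadVarianceRatio()`),
`d` is the mean depression at F = 1 in trait units, and `corr_ui` the
derived additive–load correlation. At this deliberately small size the
posteriors are wide; `recoveryDesign()` holds the larger frozen design
on which the package's recovery checks run. Per-animal predictions and
accuracies come from `effectSummary(fit)` and `fitAccuracy(fit,
hDiagonal(ped))`, and `depressionSummary()` converts `d` into
percentages of the trait mean and SD.

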