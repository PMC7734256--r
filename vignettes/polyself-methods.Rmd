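---
title: "Selfing genetics and depression regressions at two ploidies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selfing genetics and depression regressions at two ploidies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyself)
```

## The scientific setting

Under the recessive-complementation account of inbreeding depression,
selfing erodes vigor because slightly deleterious recessive alleles become
homozygous. The rate of that homozygosis differs sharply by ploidy: a
diploid heterozygote Aa fixes half its selfed progeny per generation, while
a duplex autotetraploid AABB under tetrasomic segregation produces each
homozygote at only 1/36. If the account were sufficient, matched tetraploid
hybrids should decline much more slowly under selfing than their diploid
counterparts. This package provides the exact genetics, the segregation
goodness-of-fit analysis, a forward simulator, a synthetic field-trial
generator, and the slope regressions needed to study that contrast
quantitatively.

## The selfing chain

A biallelic locus is tracked by the dosage $d$ of allele A at ploidy $p \in
\{2, 4\}$. One generation of selfing is the Markov chain whose row $d$ is
the distribution of the sum of two independent gametes; states $0$ and $p$
are absorbing. Three gamete models are implemented.

* **Random chromosome segregation** (tetrasomic, the default): a gamete is
  2 of the 4 homologues drawn without replacement, so
  $P(g) = \binom{d}{g}\binom{4-d}{2-g} / 6$. For the duplex this gives
  gametes $1:4:1$ and the classical progeny series $1:8:18:8:1$.
* **Double reduction**: with probability $\alpha$ the gamete receives two
  copies of a single uniformly chosen homologue (the signature of
  recombination between locus and centromere followed by co-migration of
  sister-derived copies), otherwise the tetrasomic draw. The coefficient is
  applied uniformly per meiosis as a two-branch mixture; $\alpha \in
  [0, 1/6]$, with $1/6$ the classical maximum and $\alpha = 0$ recovering
  random chromosome segregation. The literature invokes the concept without
  committing to a formula; the mixture is the standard population-genetics
  parameterization and reproduces every closed-form value at $\alpha = 0$.
* **Forced unlike-bivalent pairing**: the diploid-mimicking scenario in
  which only unlike homologues pair. We model each A–B bivalent as
  disjoining independently with equal pole probabilities, giving duplex
  gametes $1:2:1$ and total homozygous progeny $1/8$ per generation —
  consistent with the quoted $1/8$ vs $1/2$ contrast. The stricter literal
  reading, in which like homologues deterministically co-segregate, would
  instead fix $1/2$ of progeny and contradict that value, so it was not
  adopted. The scenario only defines pairing for a duplex; since selfed
  duplex progeny include simplex and triplex genotypes, the chain closes by
  applying the same rule — pair unlike homologues wherever possible, random
  disjunction — to every dosage, which for dosages 1 and 3 coincides
  exactly with random chromosome segregation.

Ploidies other than 2 and 4, more than two alleles, linkage, mutation and
mixed pairing models are out of scope; centromere distance enters only
through $\alpha$.

### Numerical choices

All single-generation distributions are exact: integer numerators over a
common denominator, gcd-reduced, held in doubles (exact below $2^{53}$).
Trajectories iterate the state vector against the integer transition
matrix and remain exact while the denominator stays below $2^{51}$; for
rational $\alpha$ with large denominators the reduced denominator grows
geometrically with generation, and past the bound the iteration continues
in double precision (relative error $\sim 10^{-16}$, orders of magnitude
below every gap asserted anywhere in the package). At $\alpha = 0$ the
chain is exact through every generation used here.

```{r}
homozygosis_trajectory(locus_genotype(4, 2), generations = 7)
```

Two homozygosity conventions appear in the source literature — per-allele
(1/36 for AAAA alone) and total (1/8, 1/2 counting both alleles). The
trajectory reports `P_fixed_A`, `P_fixed_B` and their complement, so both
conventions are available without taking a position.

## Karyotype segregation test

Progeny chromosome sets are classified 4:0 … 0:4 by parental origin
(parent A first). Incomplete or unassignable sets are excluded before
tallying — mirroring the source analysis — and the exclusion count is
retained. The tally is tested against an integer ratio (default the
tetrasomic 1:8:18:8:1) by Pearson's $\chi^2$ with $k - 1 = 4$ df, unrounded
expected counts, and no continuity correction. For the packaged worked
dataset (6, 20, 41, 23, 2; $n = 92$) this gives 5.636; the printed source
value 5.60 is attributable to intermediate rounding of expected counts, and
we report the unrounded statistic, a discrepancy of about 0.04.

The extreme classes have expected counts near 2.6, below the usual rule of
five. Rather than pooling classes (the source pooled nothing), the package
provides `exact_multinomial_pvalue()`: full enumeration of compositions for
small $n$, and a seeded Monte-Carlo estimate with the add-one estimator
otherwise. For the worked dataset the Monte-Carlo p (≈ 0.22) sits close to
the asymptotic 0.228.

## Simulator

`simulate_lineages()` runs replicate selfing lineages by single-seed
descent: per generation and locus, two gametes are drawn from the exact
distributions and one selfed offspring continues the lineage. Loci are
independent — no linkage map is available to justify anything richer — and
per-locus $\alpha$ is the only representation of recombination.
Gametophytic selection multiplies the probability of heterozygous (AB)
tetraploid gametes by `w_het` and renormalizes, on both gamete sides by
default with a pollen-only switch (the biological discussion concerns
pollen-tube growth; the symmetric default is simpler and the switch
preserves the pollen-only scenario). A seed is mandatory and runs are
bit-reproducible. The suite checks the simulator against the exact chain
within three binomial standard errors at $n = 10^4$ lineages.

## Synthetic field trial

The generator emulates the trial's structure: a randomized complete block
design with 3 fields, diploid and tetraploid versions of each hybrid, three
selfing lineages per entry (replicate single-seed-descent chains), plants
recorded at generations 0, 1, 3, 5, 7 (generation 0 is the unselfed, fully
heterozygous F1), at most 12 plants per row, and nine phenotype labels,
each with its own trait model. One year label is emitted per call (years
were analyzed separately). Field (block) effects default to zero with an
additive option, as no block-effect magnitudes are reported anywhere.

Trait architectures map per-locus dosages to values:

* `recessive_complementation`: a locus contributes $a_l$ iff dosage ≥ 1 —
  the classical model, under which the noiseless expected trajectory is
  $b + \sum_l a_l\,P(\text{dosage}_l \ge 1 \text{ at } t)$ from the exact
  chain, and diploid depression is strictly steeper than tetraploid.
* `additive_dosage`: contribution $a_l \cdot \text{dosage}/p$. Allele
  frequency is a martingale under selfing, so expected values are flat in
  generation and identical across ploidies — the architecture whose
  signature matches similar inbreeding curves.
* `partial_dominance`: the blend $(1-h)\,\text{dosage}/p + h\,[\text{dosage}
  \ge 1]$, interpolating the two.

What the generator does **not** emulate: real trait means and scales,
soil/planting covariates, plant mortality, genotype-by-environment
interaction, or linkage. Passing tests therefore demonstrate the
correctness and calibration of the machinery on data satisfying the stated
models, not conclusions about the 2008/2009 field measurements, whose raw
tables are not distributed.

## Depression regressions

Plants are averaged within (year × field × genotype × ploidy × lineage ×
generation × trait) cells — the plants of a row are the biological
replicates, while the three lineages stay as rows, since they were kept
precisely to carry genetic diversity among S1 descendants and they provide
the residual degrees of freedom. Fields and years are analyzed separately
by default (passing `field = NULL` pools). The two fixed-effects OLS models
are

$$y = \beta_0 + \beta_1\,\text{gen} + \beta_2\,\text{ploidy} +
      \beta_3\,(\text{gen}\times\text{ploidy}) + \varepsilon$$

$$y = \beta_0 + \beta_1\,\text{gen} + \beta_2\,\text{geno} +
      \beta_3\,(\text{gen}\times\text{geno}) + \varepsilon$$

with generation numeric (both models are linear in it), ploidy the 0/1
indicator, and genotype dummy-coded against the alphabetically first label.
Because genotype is multi-level, the genotype model's $\beta_2, \beta_3$
are dummy vectors and the interaction null is tested by a joint F test
(per-dummy t tests are also reported); the ploidy model's scalar $\beta_3$
gets a two-sided t test. Depression in a trait means $\beta_1 < 0$; a
one-sided test accompanies the sign, and the presence flag requires a
strictly negative estimate. Raw p-values are reported — no correction was
specified across the nine traits — with `stats::p.adjust()` available for
Benjamini–Hochberg if wanted. Mixed-effects variants (lineage as a random
effect) are deliberately out of scope: the stated model is fixed-effects
OLS.

Degenerate inputs are handled explicitly: rank-deficient designs (a single
generation or ploidy) are errors, and zero-residual interpolations — which
arise from noiseless constructed datasets — are detected by the residual
scale falling below $10^{-10}$ of the fitted scale and resolved to their
boundary p-values (1 for an exactly-zero coefficient, 0 otherwise) rather
than propagating 0/0.

### Calibration conditions

Type-I error of the $\beta_3$ test is checked with a known-truth Gaussian
generator on the trial's design ($\beta_3 = 0$, $\sigma_e = 0.5$, 12
plants per cell, 1000 replicate datasets, test at level 0.05 on one
field's cell means, 30 per replicate), and slope recovery with two
genotypes of true slopes −0.3 and −0.5 over 200 replicates. The
genetics-driven generator is not used for the null calibration because
genotype sampling adds generation-dependent variance that is not part of
the stated Gaussian error model. Simulator validation uses $10^4$ lineages
per segregation model; the karyotype calibration check uses 2000 null
multinomial tallies at $n = 92$, where the asymptotic test's rejection rate
stays within ±0.02 of 0.05 despite the small extreme-class expectations.

## Known limitations

* Homozygosis trajectories for non-zero $\alpha$ at deep generations use
  the guarded floating-point path rather than exact rationals.
* The simulator's lineage continuation (one random offspring) mirrors
  replicate lineages, not ear demography; within-lineage plant sampling at
  a recorded generation draws siblings of the lineage parent.
* The exact multinomial test enumerates only small tallies; beyond that it
  is Monte-Carlo with a fixed seed, and its p carries sampling error.
* The regression stage models cell means as homoscedastic Gaussian;
  heteroscedasticity induced by genetic segregation (variance growing with
  generation) is visible in the genetics-driven generator and is not
  corrected for — matching the stated analysis, not improving on it.
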