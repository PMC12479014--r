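---
title: "Testing for local adaptation with the log-ratio of ancestral variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for local adaptation with the log-ratio of ancestral variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(logav)
```

## The problem

Subpopulations of a species diverge phenotypically both through local
adaptation and through neutral drift, so a test for local adaptation needs a
neutral baseline for how much divergence drift alone would produce. The
classical approach compares $Q_{ST} = V_B / (V_B + 2 V_W)$, the proportion
of additive genetic variance between subpopulations, with the neutral-marker
$F_{ST}$: under neutrality $E[Q_{ST}] \approx F_{ST}$, because a trait
drifting in a subdivided population partitions its ancestral additive
variance $V_\mathcal{A}$ as

$$V_B = 2 V_\mathcal{A} F_{ST}, \qquad V_W = V_\mathcal{A} (1 - F_{ST}).$$

The widely used parametric-bootstrap version of this comparison draws
neutral $Q_{ST}^* - F_{ST}$ values from chi-square resampled mean squares.
Its null distribution, however, assumes an *island model*: all demes equally
related, deme effects independent. Under stepping-stone or hierarchical
structures neighbouring demes are correlated, the effective number of
independent demes is smaller than $r$, and the test's false positive rate
inflates far beyond its nominal level.

`logav` implements a calibrated alternative. The two identities above say
that the *same* ancestral variance $V_\mathcal{A}$ can be estimated twice —
once from between-population divergence, once from within-population
resemblance. The package fits both in one coancestry-aware mixed model and
tests the null that they are equal via the posterior of
$\log(\hat V_{\mathcal{A},B} / \hat V_{\mathcal{A},W})$: positive values
indicate excess divergence (local adaptation), negative values indicate
spatially homogeneous selection.

## Coancestry estimation

All relatedness quantities come from a method-of-moments allele-sharing
estimator. For a biallelic diploid locus, the sharing score of two
individuals is 1 (same homozygote), 0 (opposite homozygotes) or 1/2 (at
least one heterozygote); $A_{ij}$ averages the score over loci observed in
both individuals (pairwise-complete, unbiased under missingness at random).

Two referenced rescalings turn raw sharing into coancestries:

* **Between populations** — the $r \times r$ matrix of mean sharing between
  (and within, excluding self-pairs) subpopulations of the parental
  generation is anchored at its minimum off-diagonal entry, the best
  available proxy for the ancestral, panmictic gene pool:
  $\hat\Theta^p = (\bar A^P_s - \min) / (1 - \min)$. The least related pair
  of demes has coancestry exactly 0 by construction.
* **Within populations** — kinship among common-garden offspring (F1) of
  deme $x$ is $\hat k_{ij} = (A_{ij} - \bar A)/(1 - \bar A)$. Relatedness is
  $2 \hat k$, and the deme block of the **M** matrix is
  $M_x = 2\hat k (1 - \hat\Theta^p_x)$, discounting ancestry already carried
  by $\hat\Theta^p$. Individuals from different demes get exactly 0 (no
  cross-population breeding).

**The kinship reference pool.** The reference $\bar A$ in the kinship
estimator is, by default, the mean sharing among the deme's *parental*
pairs, not among the F1 themselves (`kinship_reference = "parents"`). The
distinction matters: centring on F1 pairs forces the mean F1 relatedness in
each deme to zero, which deletes from **M** precisely the variance
contributed by sampling a finite number of parents per deme. That variance
then has nowhere to go but the between-population effect, biasing
$\hat V_{\mathcal{A},B}$ upward. The parental pool is also the conceptually
correct reference: it is the gene pool that $\hat\Theta^p$ itself describes.
With it, the marker-based **M** matches the pedigree-based additive
relationship matrix (available via `use_pedigree = TRUE` or
`build_m_from_pedigree()`) in its deme-mean mass, and the test is calibrated
in our neutral simulations. `"offspring"` and `"combined"` references remain
available for sensitivity analyses.

Moment estimates need not be positive semi-definite; both $2\hat\Theta^p$
and every $M_x$ block are repaired by eigenvalue clipping at zero plus a
$10^{-8}$ diagonal jitter before entering the sampler, which the
multivariate-normal effect priors require.

## The two-variance animal model

With phenotypes $z$ of the F1 (one record each, grouped by deme):

$$z = \mu + a^p_{pop} + a^i + \varepsilon, \qquad
a^p \sim \mathcal N(0,\, 2\Theta^p V_{\mathcal{A},B}), \qquad
a^i \sim \mathcal N(0,\, \mathbf M V_{\mathcal{A},W}), \qquad
\varepsilon \sim \mathcal N(0, \sigma_e^2 I).$$

The factor 2 on $\Theta^p$ (coancestry to relatedness) is applied inside the
model, keeping the stored matrix interpretable as coancestry.

**Priors.** $\mu$ gets an improper flat prior; each standard deviation
($\sqrt{V_{\mathcal{A},B}}$, $\sqrt{V_{\mathcal{A},W}}$, $\sigma_e$) gets a
weakly informative half-$t$ with 3 degrees of freedom and scale
$2.5\,\mathrm{sd}(z)$. We fix these explicitly rather than inheriting a
third-party default, so the model is reproducible from this document alone.

**Sampler.** A blocked Gibbs scheme with fully conjugate updates:

* $(\mu, a^p)$ are drawn *jointly* from their Gaussian full conditional in
  the eigenbasis of $2\Theta^p$ (the intercept and the population effects
  are strongly coupled a posteriori; updating them separately mixes
  catastrophically slowly at $r = 20$). The population block — including
  its variance and rescaling moves — is swept twice per iteration: it
  costs $O(r^2)$, and the $(a^p, V_{\mathcal{A},B})$ pair is the slow
  direction in strongly clustered coancestry structures such as the
  hierarchical 1–3–9 design.
* $a^i$ is drawn in the stacked eigenbases of the $M_x$ blocks — rank
  deficiency after PSD repair is handled naturally because near-null
  directions get conditional variance $\approx d_j V_W \to 0$, and the
  block-diagonal rotation is applied as one sparse matrix product.
* Each variance uses the Huang–Wand inverse-gamma parameter expansion of the
  half-$t$ prior, making its update conjugate.
* After the centred updates, an ancillarity–sufficiency interweaving (ASIS)
  move re-expresses each effect vector in non-centred form and updates its
  standard deviation against the data through an independence
  Metropolis–Hastings step whose Gaussian proposal is the exact likelihood
  conditional. This removes the classic centred-sampler random walk between
  a variance and its effects (bulk ESS for $V_{\mathcal{A},W}$ rose from
  roughly 70 to 650 per 2,800 draws in our stepping-stone runs).

Defaults are 4 chains of 1,000 warmup + 1,000 kept iterations, with one
master seed deriving per-chain streams. Convergence is summarized by split
$\hat R$ and bulk ESS; $\hat R > 1.05$ flags the fit (a warning and a
`converged = FALSE` flag, never a silent pass). Replicated studies use 2
chains of 200 + 400 as a deliberate throughput choice (800 kept draws
resolve the two-tailed p-value to 0.0025, well below the 0.05 threshold).

The sampler is verified two independent ways in the test suite: against a
three-dimensional quadrature of the marginal variance posterior (intercept
integrated analytically) on a tiny two-deme instance, at total variation
below 0.05; and by 95%-interval coverage of both variances across 50
exact-model simulations. `reml_point_fit()` provides a fast restricted
maximum-likelihood cross-check of posterior locations.

## The test

`compute_logav()` takes elementwise $\log(V_{\mathcal{A},B}/
V_{\mathcal{A},W})$ across posterior draws, and `bayes_p()` applies the
two-tailed Monte-Carlo tail rule
$p = 2\min(\#\{lr \le 0\} + 1, \#\{lr \ge 0\} + 1)/(S + 1)$, capped at 1.
The add-one continuity correction is the standard Monte-Carlo convention
and guarantees $p > 0$ from finite draws; draws exactly at zero count
toward both tails (a measure-zero event in practice). At least 100 draws
are required.

## The Qst–Fst baseline

`estimate_qst_components()` recovers the balanced North Carolina II ANOVA
components (population; sire and dam within population; sire-by-dam;
residual) and maps the additive within-population variance as
$4\sigma^2_{sire}$ by default (paternal half-sib mapping;
`mapping = "sire_dam"` gives $2(\sigma^2_s + \sigma^2_d)$ — both standard,
and the choice is exposed because published applications differ).
`wg_bootstrap_test()` then resamples all five *mean squares* from scaled
chi-squares — the between-population mean square centred on its neutral
expectation $2 F_{ST}/(1-F_{ST}) \cdot \hat V_W$ (plus the within
components), the rest on their observed values — and pushes every draw
through the same moment pipeline. Resampling mean squares rather than
components matters: $\hat V_B$ is a mean-square difference, and its
sampling spread is visibly wider than a single chi-square; drawing
components directly produced a 28% false positive rate on island-model data
where the mean-square scheme is calibrated. The multilocus Weir–Cockerham
estimator on the parental markers supplies $F_{ST}$.

## The metapopulation simulator

`run_scenario()` advances non-overlapping Wright–Fisher generations:
migration (island: uniform to all other demes at total rate $m$; 1-D
stepping stones: $m/2$ to each neighbour, moves off the chain cancelled;
hierarchical: none), then fitness-weighted random mating without selfing
(Gaussian stabilizing fitness $w(z) = \exp(-(z-\theta)^2/(2\omega^2))$ on
phenotype = breeding value + environmental noise; flat under neutrality),
then multinomial resampling to constant deme size. Traits are controlled by
`n_qtl` biallelic loci of identical additive effect, scaled so the
ancestral additive variance equals `v_a_ancestral` at starting frequency
1/2; neutral markers start at uniform(0.1, 0.9) frequencies (the floor
avoids monomorphic markers). No mutation by default; a rate flag exists.
All demes initialize as Hardy–Weinberg samples from one ancestral pool —
an instantaneous split.

What the generator emulates — and does not. It reproduces the study
conditions of the published verification: 2000 neutral markers, 100 trait
loci, $V_\mathcal{A} = 1$, optima at $\pm 5$ across two environment groups,
$\omega \in \{10, 22, 50\}$ (foreign fitness 0.61, 0.90, 0.98), NC II
common gardens of 5 sires $\times$ 5 dams $\times$ 2 offspring per deme,
and the Table-2 structures (island $r=8$, $N=500$; stepping stones $r=20$,
$N=1000$; hierarchical 1–3–9, $r=9$, $N=900$), shipped as YAML scenarios.
It does not emulate linkage (all loci segregate independently), unequal
deme sizes, two-dimensional landscapes, mutation–selection balance, or
non-additive gene action — so passing tests speak to calibration under
drift–migration–selection with additive traits, not to robustness against
dominance or linked selection. Environmental variance is 1 throughout
(heritability about 0.5 in the garden), a typical value for morphological
traits; phenotypes in the wild use the same variance.

**Run length.** The published generation counts are not reproducible, so
scenario runs are anchored on the observable instead: burn-in continues
until the realized neutral-marker $F_{ST}$ (Weir–Cockerham on the census)
reaches the scenario's target, checked every other generation. The
hierarchical structure splits 1→3 at initialization (the root epoch *is*
the ancestral pool) and 3→9 when $F_{ST}$ first passes half its target,
which produces the expected three blocks of elevated within-cluster
coancestry.

## Problem sizes in the test suite

The replicated calibration and power studies in `tests/testthat` run the
published scenarios through the standard diffusion rescaling
(`rescale_config()`): deme size divided by $k$, migration multiplied by $k$
(preserving $Nm$, hence the equilibrium differentiation and its spatial
pattern), $\omega^2$ divided by $k$ (preserving $N s$), and time contracted
by $k$. We use $k = 20$ for the island and hierarchical scenarios ($N = 25$
and 45) and $k = 50$ for the stepping stones ($N = 20$), with 50 trait
loci. Marker counts are a precision choice, not a dynamics choice, but
they are not free: subsampling the 2000 neutral markers measurably biased
the two variance routes apart under neutrality (noise in the
minimum-sharing reference, in the $(1 - \hat\Theta^p_x)$ scaling and in
$\hat{\mathbf M}$ attenuates $\hat V_{\mathcal{A},W}$ relative to
$\hat V_{\mathcal{A},B}$), inflating the false positive rate to roughly
13% at 200–1000 markers in the island and high-$F_{ST}$ chain scenarios.
Marker precision is therefore part of the study conditions being
preserved: the neutral calibration scenarios keep the full 2000 markers
(1000 in the $F_{ST}=0.2$ chain, whose longer simulations would otherwise
not fit the suite's runtime and whose lower coancestry scale is less
sensitive), and the selection scenarios use 1000 (power is carried by the
trait, not by marker precision). One exception: the stepping-stones $F_{ST}=0.2$ scenario keeps
its rescaled equilibrium only after thousands of generations of diffusive
relaxation (its $Nm = 10$ makes chain-wide differentiation build very
slowly), so its test-scale configuration uses the largest migration whose
burn-in completes in a few seconds per replicate ($N = 20$, $m = 0.25$,
$Nm = 5$) at the same $F_{ST}$ anchor and chain length. This halves the
between-deme correlation scale relative to the published setting, which
attenuates — without removing — the baseline test's inflation; the
calibration of LogAV itself is unaffected. Calibration runs use 100
replicates per structure (the $F_{ST}=0.2$ replicates are shared by both
methods) and power runs 20 replicates per selection scenario, against
exact binomial acceptance intervals. Full-scale scenario defaults remain available for
overnight reproduction of the published study.

## Numerical choices and degenerate inputs

* Ties in the minimum off-diagonal sharing are irrelevant (the value, not
  the index, anchors the rescaling); an undifferentiated panel
  ($\min = 1$) errors out, as does a subpopulation with fewer than two
  individuals, a pair with no jointly observed locus, a zero-variance
  phenotype, and a pedigree with cross-population matings.
* PSD repair: eigenvalue clipping at 0 plus $10^{-8}$ jitter; the sampler
  additionally drops eigenvalues below $10^{-10}$ of the largest.
* Dosages are counts of the VCF ALT allele; allele sharing is invariant to
  polarity, and the test suite asserts it.
* Per-replicate seeds derive from one master seed by a separate, restored
  RNG stream, so replicates are independent and reports byte-reproducible.

## Known limitations

Diploid biallelic markers only (the estimator generalizes to any ploidy;
this implementation does not). No fixed-effect covariates beyond the
intercept, single traits only, no dominance or epistasis in model or
simulator. The Bayesian p-value relies on the posterior's asymptotic
convergence to a sampling distribution; with very few demes ($r < 5$, say)
its uniformity under the null degrades, as it does for any $Q_{ST}$-style
comparison. Wild phenotypes (no common garden) would confound plasticity
with genetics and are out of scope.
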