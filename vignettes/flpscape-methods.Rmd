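---
title: "Methods: models, calibration and design choices in flpscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in flpscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flpscape)
```

## The scientific problem

Female-limited polymorphism (FLP) is the co-occurrence, within a species, of
a male-like (*androchrome*) female morph and a distinct (*heterochrome*)
morph. In hummingbirds this discrete female variation is widespread, and
asking why it persists requires three linked analyses:

1. **Classification.** From museum specimens scored on an ordinal androchromy
   scale (Class 1 = no male-like patches, Class 4 = at least half of the
   sexually dimorphic patches male-like), decide per species whether FLP is
   present, absent, or undeterminable.
2. **Macroevolution.** Map the three-state character (sexually monochromic,
   sexually dichromic, FLP) onto a phylogeny, estimate transition rates under
   Mk models, reconstruct ancestral states, and count independent origins.
3. **Correlates.** Within species, relate a continuous androchromy score
   (a discriminant axis through patch colours) to bill morphology; across
   species, regress the FLP indicator on socioecological covariates with
   phylogenetic error structure.

`flpscape` implements all three stages plus a seeded synthetic-data
generator, so every stage is testable and calibratable without access to
specimen collections.

## The synthetic-data generator

The generator (`simulation_spec()` and the `simulate_*()` functions) emulates
the statistical structure the analyses assume, not hummingbird biology:

* **Phylogeny.** A pure-birth (Yule) process: lineages split at rate
  $\lambda$ per lineage; the simulation stops one exponential waiting time
  after the $n$-th lineage appears so all pendant branches are positive.
  Expected root-to-tip depth is $\sum_{k=2}^{n} 1/(k\lambda)$, which the
  tests verify by simulation.
* **Character evolution.** The three-state character evolves under a
  user-supplied rate matrix; the default is an equal-rates matrix with rate
  0.9 per unit depth, a regime in which all three states coexist at the tips
  without saturating.
* **Specimen scores.** Female ordinal classes come from a two-component
  mixture: a heterochrome component on Classes 1–2 (probabilities 0.9/0.1)
  and an androchrome component on Classes 3–4 (0.1/0.9) with weight equal
  to the species' androchrome frequency. The poles dominate because the
  intermediate classes describe partial androchromy, which is rare relative
  to fully typical females and fully male-like morphs; the ordinal buffer
  classes mainly absorb scoring error. The default androchrome frequency
  in FLP species is 0.30 — comfortably above the 10% presence threshold, as
  expected for a detectable polymorphism — and exactly 0 elsewhere.
  Observer/specimen-quality error is modelled as a symmetric one-class
  misreading with probability 0.05, truncated at Classes 1 and 4. The
  default museum series is 30 females (and 10 males) per species — typical
  collections hold tens of skins per species, and the default must exceed
  the 19-female absence threshold for the classification stage to be
  exercised at all; the photographic colour series below is deliberately
  smaller. The
  mixture is an assumption: the analyses only require bimodality, and no
  published within-species score densities exist to fit instead.
* **Colours and morphometrics.** Androchrome males and Class-1 females form
  two Gaussian clusters in the 51-dimensional patch-channel space
  (17 patches × R,G,B), separated by 80 channel units along a random axis
  with isotropic channel noise (s.d. 8); variable females sit uniformly on
  the inter-cluster segment, mirroring the heterochrome-to-androchrome
  continuum. Bill length is `species mean + planted_slope × position`
  where position is expressed on the standardised LD1 scale (female
  centroid −1, male centroid +1), so a regression of relative bill length
  on LD1 recovers `planted_slope` directly. Per-species sample sizes
  default to 10 males, 6 Class-1 females and 11 variable females, the
  averages reported for comparable photographic series.
* **Covariates.** Continuous covariates are Brownian on the tree; binary
  ones threshold a latent Brownian value at a fixed prevalence (25%
  migratory, 30% dominant). Planted FLP associations shift the standardised
  latent trait of FLP species by the requested effect size (in s.d. units)
  before thresholding — a probit-style link that gives a controllable,
  sign-interpretable association while keeping the response binary. Body
  length is mapped to the observed 6–22 cm range.

What the generator does **not** emulate: real reflectance spectra or UV
channels, geographic range structure, non-Brownian trait evolution,
correlated covariates, and sexing error beyond the method tag. Passing
calibration tests on these synthetic data therefore demonstrates the
correctness and power of the *procedures*, not the robustness of the
biological conclusions to violations of those assumptions.

## Classification rule and its thresholds

`classify_species()` implements the decision rule: a species *exhibits* FLP
when at least `presence_min_prop` (default 10%) of its females are
androchromic **and** the female score distribution rejects unimodality; it
*lacks* FLP when at least `absence_min_females` (default 19) females were
sampled without meeting the presence rule; otherwise it is unclassified.
The absence default comes from the detection design: with a morph at 10%
population frequency, $1-(1-0.1)^{18} = 0.85$, so 19 or more females give
better than an 85% chance of having seen an androchrome if one exists
(`detection_probability()`, `required_sample_size()`). Species lacking FLP
carry an externally supplied dichromatism flag, yielding the three states
used downstream. A `prior_flp` column can veto the absence rule for species
already reported polymorphic in the literature.

The historical-literature clause of the original absence rule is reduced to
this optional override because no curated prior-classification table ships
with the package.

`build_sensitivity_matrices()` re-runs the classification over a factorial
grid — presence proportion ∈ {5%, 10%}, androchrome class cut ∈ {3, 4},
absence threshold ∈ {10, 19} — giving the default eight matrices. The grid
composition is a documented default and fully configurable; monotonicity
(stricter presence thresholds never add FLP species, stricter absence
thresholds never add no-FLP species) is enforced by tests.

## The dip statistic and its calibration

Unimodality is tested with Hartigan's dip: the minimax sup-distance between
the empirical CDF and the nearest unimodal CDF (convex below the mode,
concave above it, an atom permitted at the mode). The implementation
bisects on the half-width $d$ of a band around the ECDF and asks whether a
unimodal CDF can thread the band: convex-prefix/concave-suffix feasibility
via greatest-convex-minorant checks, with the mode placed at data points
(where an atom may absorb ties) or inside support gaps (where the mode
position is optimised; the entering and leaving slopes at the mode couple
the two sides and are essential — without them, two well-separated clusters
would be declared unimodal). The tests pin the implementation to an
independent linear-programming minimisation over piecewise-linear unimodal
CDFs, frozen for a battery of small datasets, at 1e-8; analytic anchors
(equally spaced values give $1/(2n)$, a balanced two-point mass gives 1/4,
a point mass gives 0) are asserted at 1e-9. The bisection itself terminates
at 1e-11, well inside those tolerances.

`dip_test()` calibrates against uniform samples of the same size, the
conventional choice (the uniform is the asymptotically least favourable
unimodal distribution), with the p-value the fraction of bootstrap dips at
least as large as the observed one. Ordinal scores are heavily tied, which
inflates the dip relative to a continuous null; tied inputs are therefore
jittered uniformly on `[class − 0.5, class + 0.5]` with a seeded draw (on
the sorted sample, so the result is invariant to record order). Type-I
error is exact at the nominal level *for the uniform null by construction*;
for unimodal-but-non-uniform data (e.g. Gaussian) the test is conservative,
which the acceptance tests check as an upper bound rather than an equality.

## Mk models, AICc and ancestral states

The three-state continuous-time Markov machinery is implemented from first
principles: `build_rate_matrix()` constructs ER/SYM/ARD matrices (1/3/6
free rates), `transition_probabilities()` exponentiates by
eigendecomposition with a scaling-and-squaring fallback for numerically
defective matrices, and `mk_log_likelihood()` runs Felsenstein pruning with
per-node rescaling (stable beyond 500 tips; the inner recursion is in C++).
Zero-length branches are nudged to 1e-8 before exponentiation to avoid
degenerate edge cases without materially changing likelihoods.

`fit_mk_model()` maximises over log-rates in $[10^{-9}, 100]$ with `nlminb`
at relative tolerance 1e-8, using five seeded log-uniform restarts (first
start at rate 1). Rates pinned at a box bound are flagged — the typical
symptom of constant tip states. Model fit is compared with the
small-sample-corrected AICc, with $n$ = number of tips (the conventional
choice for a single character), and `select_models()` reports the
best-supported set as all fits within ΔAICc < 2, ties broken towards fewer
parameters.

`marginal_asr()` computes per-node marginal posteriors by the standard
down-pass/up-pass algorithm, equivalent to rerooting at every node; the
tests verify both likelihood and marginals against exhaustive enumeration
of all internal-state assignments on trees of up to six tips (the
enumeration uses an independent matrix exponential). Two root priors are
exposed because the source procedure is ambiguous about root handling:
`"uniform"` (the neutral default) and `"conditional"`, the observed-data
(FitzJohn-style) weighting. Origins of a focal state are counted as edges
whose child is focal (marginal probability strictly above 0.5, tips by
their observed state) while the parent is not, plus one if the root itself
is focal — the edge-transition reading of "number of independent origins",
which we fix as the default since a node-counting reading is not uniquely
defined.

`root_state_resampling()` quantifies the sensitivity of root-state
likelihoods to tree composition: drop 10% of tips at random, refit
(default; a fast mode re-evaluates at the full-data rates), reconstruct,
and summarise the per-state mean and standard deviation of the root
marginals over (by default) 1000 replicates.

## Discriminant androchromy scores and morphometric slopes

`train_discriminant()` learns a per-species axis separating androchrome
males from Class-1 females: channels are standardised, reduced by PCA, and
a two-group linear discriminant is fitted on the scores. Because a typical
training set (~16 specimens) is far smaller than the 51 channels, the
number of retained components is capped at one per three training specimens
(and never above $n_\mathrm{train} - 2$), retaining at least 95% of the
variance when possible. The axis has unit-norm weights, is oriented so
androchrome males project positively, and scores are affinely standardised
so the training centroids sit at ±1 — this pins the LD1 scale, making
slopes comparable across species and letting the generator plant slopes in
interpretable units.

An axis is *validated* only if leave-one-out classification of the training
specimens is error-free **and** the training-group score ranges do not
overlap (configurable to a two-pooled-s.d. separation criterion). The
cross-validation guard is essential: with more retained dimensions than
specimens per group, any two groups separate in-sample, so an in-sample
criterion alone would validate axes trained on pure noise. Unvalidated
species are carried through `androchromy_slopes()` with a reason rather
than silently dropped.

Relative measurements centre bill (or wing, or bill/wing) within species
over both sexes; `fit_morph_slope()` regresses the relative value on LD1
over females only (males enter through axis training and the species mean),
with a two-sided t-test at the Bonferroni level
`bonferroni_alpha(n_tests, 0.05)` — for a 16-species family, 0.05/16 =
0.003125, reported as 0.0031. Phylogenetic signal in the per-species slopes
uses Blomberg's K with the phylogenetically corrected mean and the Brownian
expectation from trace identities, and a one-tailed permutation p-value
(fraction of tip-label shuffles with K at least as large). K averages 1
under Brownian simulation, which the acceptance tests verify.

## Phylogenetic regressions

`pgls_fit()` is generalised least squares with the Brownian covariance
(shared root-to-ancestor path lengths, `brownian_vcv()`): coefficients
$(X'V^{-1}X)^{-1}X'V^{-1}y$, residual variance from the whitened residual
sum of squares, t-tests on $n-p$ degrees of freedom. Computation goes
through the Cholesky factor of $V$; an exactly singular $V$ receives a
1e-10 ridge with a message. With the identity covariance the fit reproduces
OLS to 1e-10, and estimates are invariant to rescaling $V$.

The binary FLP indicator is fitted as a 0/1 Gaussian response — the
contrasts-style analysis this mirrors — rather than by a phylogenetic
logistic model, which is deliberately out of scope; coefficient signs and
approximate tests, not calibrated probabilities, are the target. The
covariance is pure Brownian with no branch-length transform: no transform
is reported for the source analysis, and estimating λ on a binary response
with ~167 species is fragile. `run_flp_models()` wires the social
(migratory + dominance + body length) and climate (four climate variables)
predictor sets, with optional exclusion of monochromic species so the
contrast is FLP versus dichromic-without-FLP.

## Numerical choices and problem sizes

Tolerances and sizes used by the test-suite calibrations, chosen as
realistic desk-scale study conditions: Mk recovery uses 20 replicates of
300-tip trees at the default rate 0.9 (median ER rate within [0.6, 1.2],
ER selected by AICc in at least 80%); the asymmetric-generation check uses
a 500-tip tree with a ten-fold asymmetric rate pair (0.5 vs 0.05) whose
stationary distribution is skewed — asymmetry with a uniform stationary
distribution is statistically indistinguishable from ER at these sizes.
Dip calibration uses 500 uniform replicates of n = 100 with 150 bootstrap
draws; power uses a 50/50 mixture of well-separated Gaussians. The
morphology battery plants slopes of −2.5 and +1.7 mm per LD1 unit among 14
null species and requires exactly those two to be flagged at α = 0.0031 in
at least 90% of seeded runs. PGLS sign recovery plants a −1.5 s.d.
migratory effect at the 167-species scale of the social model.

## Known limitations

* The dip's band-threading feasibility uses pairwise slope bounds for the
  extremal junction values; it is validated against the exact LP oracle
  over thousands of datasets (to ~1e-12) but is not accompanied by a
  formal tightness proof.
* The Gaussian-response PGLS on a binary trait gives sign/association
  evidence, not calibrated effect sizes; fitted values are not constrained
  to [0, 1].
* The generator's class mixture and uniform continuum are conventions;
  analyses sensitive to the within-morph score distribution should not
  lean on them.
* Marginal ancestral states are reported per node; no stochastic character
  mapping or hidden-rate models are provided.
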