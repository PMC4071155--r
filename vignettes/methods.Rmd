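---
title: "Models and methods behind snpvus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snpvus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`snpvus` estimates how classifier performance on coded SNP data depends
on the number of training samples per class, and inverts that
relationship to plan sample sizes. This vignette explains the model,
each approximation with its assumptions, the numerical machinery, the
design decisions taken where the construction was genuinely open, and
what the package's validation does and does not establish.

## The genotype model

Each of D classes is characterised by a vector of minor allele
frequencies θ_k = (θ_{k,1}, …, θ_{k,m}) over m statistically
independent biallelic loci. Under Hardy–Weinberg equilibrium the coded
genotype at locus j for a class-k individual is X_j ~ Binomial(2,
θ_{k,j}), independently across loci. Frequencies are constrained to
(0.01, 0.5): below 0.5 because they are minor-allele frequencies, above
0.01 to exclude rare mutations. The model deliberately ignores linkage
disequilibrium — dependent SNPs are expected to be thinned beforehand
with `select_independent()`, a greedy screen that keeps a maximal
pairwise-independent subset under a Kendall τ cutoff (tie-corrected
τ-b, because 0/1/2 data is massively tied; the cutoff is interpreted as
a statistic bound, |τ| < 0.05 by default, since reading it as a p-value
bound would conclude *dependence* at small p).

## Classifiers

With known frequencies, the maximum-a-posteriori rule reduces to
pairwise linear score comparisons in x (`snp_bayes()`): class k beats
k′ when Σ_j b_{k,k′}^j x_j > K_{k,k′} with the log-odds coefficients
and thresholds given on the help page. The test suite verifies, by
exhaustive enumeration over all 3^l genotype vectors for small l, that
this pairwise rule reproduces the posterior argmax exactly — this fixes
the threshold convention: the per-SNP term 2·log[(1−θ_{k′,j})/(1−θ_{k,j})]
must be summed over all loci in the rule.

Strictly, a sample is assigned to k only if it wins all D−1 pairwise
comparisons; genotype vectors where no class wins all its duels are
possible. `predict()` assigns such boundary cases to the class with the
largest worst-case margin, breaking residual ties toward the smallest
class index, and flags them. All probability calculations (the ξ_k
below) use the strict all-duels event, which is why "chance level" for
identical classes sits slightly below 1/D: some probability mass is
cyclic, with no overall winner.

`snp_linear()` is the data-fitted analogue: allele frequencies are
replaced by maximum-likelihood estimates clipped to
[1/(4n_k), 1−1/(4n_k)] (a continuity-correction-scale floor that keeps
the log-odds finite when a class shows no minor alleles), and each SNP
enters the score for a class pair only when a level-α Wald test (
unpooled variances) rejects equality of its two frequencies.

### The threshold convention for the linear rule

An open design question is which loci contribute to the fitted
thresholds K̃_{k,k′}. The package implements both conventions:

- `threshold_snps = "selected"` (default): the threshold sum is
  restricted to the Wald-selected SNPs of the pair, so each selected
  locus contributes the centred term W_j(b̂_j x_j − ĉ_j) and an
  unselected locus contributes nothing. Score and threshold refer to
  the same loci.
- `threshold_snps = "all"`: the threshold keeps every locus's term, so
  an unselected locus leaves a deficit −ĉ_j in the margin. At small n
  this systematically handicaps the rule; the handicap disappears as
  the tests' power approaches 1, which makes the implied sample-size
  requirements dramatically more conservative.

The default was chosen by simulation: across designs, the empirical
performance of classifiers actually fitted to data and evaluated on
fresh samples agrees with the "selected" construction's predictions
(within a few hundredths of VUS), whereas the "all" construction
predicts substantially worse performance than fitted classifiers
achieve. Published sample-size tables derived from constructions of the
"all" type are correspondingly much more conservative than the default
here; users who want comparability with such tables can switch the
convention.

## Gaussian approximations and orthant probabilities

For a class-k sample, the D−1 pairwise scores are sums of m independent
bounded contributions, so for moderate m they are treated as jointly
Gaussian (a CLT argument). With known frequencies the first two moments
are exact binomial moments. The per-class correct-classification rate
ξ_k is then a (D−1)-dimensional upper-orthant probability, and
PCC = Σ_k π_k ξ_k.

For the finite-n linear classifier (`gaussian_approx_n()`), the moments
additionally account for:

- *selection*: each SNP enters with probability equal to the Wald
  test's analytic power at its true effect, independently across SNPs
  (first order; the dependence between the selection event and the
  estimated coefficient is ignored);
- *estimation noise*: delta-method variances and covariances of the
  estimated coefficient and threshold terms, e.g.
  Var(b̂_j) ≈ 1/(2n_kθ_{k,j}(1−θ_{k,j})) + 1/(2n_{k′}θ_{k′,j}(1−θ_{k′,j}));
- *cross-pair correlation*: scores for pairs (k, k′) and (k, k″) share
  the genotype and the class-k estimate.

The construction is validated against simulation (fitting real
classifiers and measuring empirical rates); it converges to the
known-frequency moments as all n grow. Its known weaknesses: it treats
training randomness unconditionally (mixing it into the score
distribution) where the truth averages conditional performance over
fits, making it mildly conservative; and for small m with several
classes the score covariance is near-singular (adjacent-pair scores are
almost perfectly correlated), where orthant probabilities become
extremely sensitive to the 1/n noise terms and the Gaussian treatment
is least trustworthy. Sample-size answers for D = 4 with m ≲ 30 should
therefore be read as qualitative.

Orthant probabilities are computed by dedicated vectorised routines: a
single-integral bivariate normal CDF with the high-correlation branch
of Genz's algorithm beyond |ρ| = 0.925 (validated to ~1e-15 against
`mvtnorm`), and a conditioned trivariate integral whose outer
quadrature is split at the kink locations that appear in the
near-singular limit. Dimensions above three fall back to
`mvtnorm::pmvnorm`. The degenerate case (zero score variance, e.g.
literally identical classes) is handled deterministically. The default
absolute tolerance is 1e-4; rank-deficient covariances receive a
diagonal jitter of 1e-10·tr(Σ)/(D−1) before the fallback solver.

## The ROC hypersurface and its volume

Sweeping a per-class offset vector (K_1, …, K_{D−1}, with the last
class pinned at 0) shifts each pairwise threshold by K_{k′} − K_k —
exactly the family obtained by varying the class priors — and traces
the ROC hypersurface of operating points ξ = (ξ_1, …, ξ_D). For D = 2
this is the ordinary ROC curve and `auc()` integrates it on a
deterministic grid of at least 512 thresholds spanning ±8 standard
deviations of both score distributions.

For D ≥ 3, `vus()` explores threshold space stochastically: an initial
deterministic sweep (axis and pairwise/triple grids at several scales
plus uniform draws over a box covering ±6 standard deviations of every
pairwise score) seeds the surface; then an ant-colony step (Gaussian
perturbation of retained threshold vectors, scale 0.25 of their
interquartile range) alternates with a genetic step (uniform crossover
of retained parents, crossover rate 0.9, per-gene mutation 0.1) to
reach unexplored regions. Every operating point with all-positive
components joins a cumulative cloud together with its base projection
(first component zeroed); the unit-simplex anchors (origin and unit
vectors) close the body from below, so the hull volume starts at the
random-classifier floor 1/D! and grows monotonically. The search stops
when the volume gains less than `tol` (default 0.001, the printed
convergence criterion) over three consecutive iterations, after at
least five; `max_iter` (default 60) caps pathological cases, which are
then reported as non-converged.

### The exact hull engine

Volumes come from an incremental beneath-beyond convex hull written for
this package (dimensions 2–4). Operating-point clouds are adversarial
inputs for floating-point geometry: thousands of points on coordinate
hyperplanes, near-duplicates, and long sliver simplices. The engine
therefore works on an integer lattice — points are snapped to a grid
(5e-4 by default, an error well below the search tolerance) — and
evaluates every predicate (facet normals by cofactor expansion,
visibility signs, simplex volumes) in exact 64/128-bit integer
arithmetic. The facet complex consequently can never be corrupted by
rounding: the visibility flood-fill consumes exactly-coplanar
neighbours, horizon ridges are always well defined, and the running
volume equals the exact hull volume of the snapped point set. The test
suite checks analytic bodies (simplices, cubes), insertion-order
invariance, monotonicity, and frozen reference volumes for seeded
random point sets computed with an independent computational-geometry
library.

For D = 3 the suite also cross-checks the search against a
deterministic 201×201 threshold-grid integration of the surface
(exact shoelace areas of the projected grid cells times the mean
height), which agrees with the stochastic search to better than 0.01.

## Sample-size determination

`find_sample_size()` performs integer bisection for the smallest
per-class n with VUS(∞) − VUS(n) < γ: starting from a bracket with
f(n_S) ≥ 0 > f(n_L), the midpoint replaces whichever end keeps the sign
change until n_L − n_S ≤ 1 (the criterion is the strict inequality, so
f = 0 moves the lower end); unbracketable criteria expand the bracket
geometrically (factor 4) up to a cap and fail with a diagnostic.

Because both volumes come from stochastic searches, the difference of
two independent runs would be noisier than γ = 0.01. The gap is
therefore evaluated with common random numbers: one adaptive search
runs on the known-frequency surface (recorded once), one on the
finite-n surface, and both volumes are recomputed by replaying the
union of the two threshold sequences against each surface. Every
threshold probes both surfaces, so the difference reflects the
estimation effect, vanishes identically as the surfaces converge, and
is monotone in n up to the tiny asymmetry of the adaptive halves. The
returned root is re-verified at n and n−1 with a tolerance tightened to
0.0005, re-bracketing locally if a sign flips. `learning_curve()`
reuses one cache of gap evaluations across the whole γ grid, since f is
only shifted by γ.

## The simulation designs

`table1_design()` reproduces the layered study conditions used
throughout the package's simulations: θ_{1,j} ~ U(0.4, 0.49) and each
subsequent class shifted down per SNP by h_{i,j} ~ U(h−0.002, h+0.002),
with uniform priors. Designs with four or more classes extend the same
recursion one layer per class — the only construction consistent with a
single scalar separation h. Designs whose frequencies would leave
(0.01, 0.5) fail fast, naming the offending class and locus, rather
than clipping. The fraction ρ of SNPs with marginal effect is exposed
in `study_design()` (l = ⌊ρm⌋ loci enter the known-frequency
classifier) but defaults to 1, matching all simulation settings used
here. `correlated_fixture()` generates blocks of duplicated SNPs with
optional resampling noise and carries its ground-truth structure, as
the test bed for the independence screen.

What the generator emulates: independent HWE loci with class-specific
frequencies and a controlled, nearly-constant per-locus separation.
What it does not: linkage disequilibrium, missing genotypes,
genotyping error, population substructure within a class, or
non-uniform priors. Passing tests therefore demonstrate correctness of
the method under its own model, not robustness to the ways real cohort
data violate it.

## Problem sizes used in the test suite

The packaged tests run the full pipeline at reduced replication chosen
to keep the suite fast while leaving Monte Carlo error well inside each
tolerance: 5 design draws per VUS cell, 2·10⁴ simulated vectors for
PCC checks, 4·10³ replicates for Wald size/power, 10⁶ draws for orthant
Monte Carlo, and test sets of 300–400 per class for the empirical-VUS
oracle. The acceptance script uses the same sizes.

## Known limitations

- VUS is supported for 3 or 4 classes (the hull engine's exact integer
  bounds); two classes use the AUC path, five or more are out of scope.
- The finite-sample approximation is unconditional (see above) and
  least reliable for near-singular score covariances (small m, D = 4).
- Required sample sizes at very small γ inherit the slow 1/n tail of
  the estimation-noise terms; in near-singular regimes the implied n
  can become enormous and should be treated as "beyond the model's
  resolution" rather than as a literal requirement.
- The Wald screen is applied per SNP at level α with no multiplicity
  correction, by design.
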