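---
title: "Estimating and comparing longitudinal symptom networks with longnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing longitudinal symptom networks with longnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`longnet` estimates **regularized partial correlation networks** (Gaussian
graphical models, GGMs) from repeated assessments of ordinal symptom scales —
the canonical setting being a depression inventory such as the CES-D (20
items scored 0–3) measured at several waves, together with covariates such as
a self-efficacy component score and a binary treatment indicator. Nodes are
items; an edge between two nodes is their partial correlation after
conditioning on every other node. A zero edge means conditional independence
under the latent multivariate normal model.

Estimation proceeds in two stages:

1. **Latent correlations.** Because the items are ordered categories, the
   input to the GGM is not the product-moment correlation matrix but the
   latent-normal correlation matrix: polychoric correlations for
   ordinal–ordinal pairs (tetrachoric for binary), polyserial for
   continuous–ordinal pairs, and product-moment for continuous pairs. We use
   the standard **two-step** estimator: thresholds are fixed at the
   standard-normal quantiles of the observed cumulative margins, and the
   correlation then maximizes the bivariate-normal likelihood of the
   contingency table. The two-step variant (rather than full joint ML) is
   the default of the R ecosystem used in applied network psychometrics, and
   is adopted here for comparability.
2. **Graphical lasso + EBIC.** The sparse precision matrix maximizes
   `log det(Theta) - trace(R Theta) - lambda * sum(|Theta_ij|)` (off-diagonal
   penalty only), solved by block coordinate descent over a log-spaced path
   of 100 penalties from `lambda_max = max |r_ij|` down to `0.01 *
   lambda_max`. The retained model minimizes the extended BIC,
   `EBIC = -2 L + E log(n) + 4 E gamma log(p)` with `gamma = 0.5`, where `E`
   counts nonzero edges and `L = (n/2)(log det Theta - trace(R Theta))`.
   Edge weights are the partial correlations
   `w_ij = -theta_ij / sqrt(theta_ii theta_jj)`.

Downstream, the package computes node centralities (strength, betweenness,
closeness), bootstrap accuracy and stability diagnostics, a paired
permutation test of network differences between waves, and descriptive
cross-wave similarity measures.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.5 | EBIC sparsity hyperparameter; 0 recovers ordinary BIC. The source analyses do not report it; 0.5 is the community convention and errs toward sparsity. |
| `n_lambdas`, `lambda_min_ratio` | 100, 0.01 | Penalty path resolution and depth, matching the defaults of the tooling used in applied work. |
| `convergence_tol` | 1e-7 | Maximum absolute parameter change at convergence of the coordinate descent. |
| `min_pairwise_n` | 10 | Minimum pairwise-complete cases per correlation; below this the polychoric likelihood is unstable and estimation errors out naming the pair. |
| `n_boot` | 1000 | Bootstrap replicates for edge CIs and case-dropping stability. |
| `drop_proportions` | 0.10–0.75 by 0.05 | Case-dropping grid. |
| `stability_cor_threshold`, `stability_prob` | 0.7, 0.95 | CS-coefficient rule: the largest drop proportion at which ≥95% of subset replicates correlate ≥0.7 with the full-sample centrality. |
| `n_perm` | 1000 | Permutations for the paired network comparison test. |
| `subject_corr` | — | Within-subject latent correlation across waves in the generator, entering each wave with weight `sqrt(subject_corr)`. |

## Conventions and numerical choices

Several conventions are unstated in the applied literature and had to be
fixed; each is exposed and documented:

* **Global strength** is the sum of absolute edge weights over *unordered*
  node pairs ("summing the absolute values of all edges" is ambiguous
  between the pair sum and the doubled directed sum; the pair sum is used,
  and `sum(node_strength(net)) == 2 * global_strength(net)` makes the
  relation explicit).
* **Distances** for betweenness and closeness are inverse absolute weights,
  `1/|w|`; negative edges contribute through their magnitude. Betweenness
  counts ordered source–target pairs with fractional credit for tied
  shortest paths. Closeness is `1 / sum(d)`; in a disconnected network it is
  computed over the reachable nodes and scaled by `reachable/(p-1)`, and an
  isolated node gets 0 (regularized networks are routinely disconnected, so
  this case is real, not hypothetical).
* **Standardization** of centralities uses the sample SD (denominator
  `n-1`) across all nodes of the network, covariate nodes included, since
  published centrality plots place covariates on the same standardized axes;
  `centrality_table(net, nodes = ...)` restricts the node set first when the
  other convention is wanted.
* **Paired permutation scheme.** The dependent network comparison test swaps
  each subject's pair of observation vectors between the two waves with
  probability 1/2 — the standard paired exchangeability argument — and
  re-estimates both networks with the identical pipeline configuration in
  every permutation. P-values use the add-one convention
  `(1 + #{perm >= obs})/(1 + n_perm)`, so they are never exactly zero.
* **Bivariate normal CDF.** Rectangle probabilities use the arcsine-
  substitution integral with Gauss–Legendre quadrature (6/12/20 nodes by
  correlation magnitude); for `|rho| > 0.925` a composite rule geometrically
  graded toward `asin(rho)` resolves the boundary layer. Verified against
  adaptive quadrature to better than 1e-8 across the full range used by the
  optimizer (`|rho| <= 0.999`).
* **Optimizer.** The polychoric/polyserial correlation is found by Brent
  search on `[-0.999, 0.999]` with tolerance 1e-6; a monotone likelihood
  (e.g. an empty off-diagonal 2x2 cell) lands on the bound and is flagged.
* **Positive-definite repair.** Pairwise-complete polychoric matrices can be
  indefinite; eigenvalues are clipped at 1e-6, the matrix rescaled to unit
  diagonal, and the clip repeated until the floor holds (rescaling can nudge
  the smallest eigenvalue back below it). The repair is idempotent and the
  result is flagged in `pd_repaired`.
* **Effective sample size** under pairwise-complete estimation is the number
  of subjects with any observation at the wave — the EBIC needs a single
  scalar `n`, and the alternative (mean pairwise count) changes selection
  only marginally.
* **Ties in EBIC** resolve toward the larger penalty (sparser model),
  consistent with using regularization to guard against spurious edges.
* **Missing data.** Networks are estimated on all subjects with
  pairwise-complete observations; the paired comparison test uses the
  complete-case subset (subjects observed on the required items at every
  wave), as a permutation test of paired data must.

## The synthetic-data generator

`make_true_network()` draws an Erdős–Rényi edge set, assigns each edge a
partial correlation drawn uniformly from `weight_range` (default 0.15–0.4,
all positive — symptom networks are predominantly positive), and builds the
precision matrix as the identity minus the weighted adjacency, with diagonal
loading (increments of 0.05 until the smallest eigenvalue reaches 0.05)
followed by rescaling to unit partial variances. Loading preserves the edge
support exactly but shrinks edge magnitudes, so `Pcor_true` is always read
back from the final precision matrix. Thresholds default to equal-probability
categories (`qnorm(k/n_levels)`), one shared vector per item across waves;
emulating the empirical item skew of any particular instrument is
deliberately out of scope — recovery and calibration claims do not depend on
it, and skewed thresholds can be passed explicitly when wanted.

`sample_longitudinal()` gives each subject a latent component shared across
waves with weight `sqrt(subject_corr)`, so that with a common wave model the
across-wave latent correlation of an item equals `subject_corr` (study-like
emulations use 0.5). Missingness is whole-wave and completely at random —
the source study does not state its missingness mechanism, so MCAR is
assumed; a rate of 0.135 over four waves reproduces a ~56% complete-case
fraction. What the generator does **not** emulate: item-specific marginal
skew, intervention effects on the latent process, informative dropout, and
measurement non-invariance across waves. Passing tests therefore demonstrate
correctness of the estimation machinery under the latent-normal model, not
robustness to violations of it.

## What the validation suite establishes

Every stage is checked against an independent oracle or a calibration
experiment: the bivariate normal CDF against adaptive quadrature; the
polychoric optimizer against a dense grid search of the same likelihood; the
graphical lasso against direct numerical maximization of the penalized
objective (and the two-node closed form `sign(r)(|r| - lambda)`); partial
correlations against Schur-complement residualization; shortest-path
centralities against exhaustive path enumeration on 6-node graphs; the
paired comparison test against its nominal 5% type-I error over 200
replications of a dependent two-wave null (200 permutations each, n = 300,
p = 8); and the CS coefficient against its definitional monotonicity and a
pure-noise null where it must be 0.

One property deserves honesty: EBIC selection over the glasso path admits a
few **shrinkage-compensation edges** — spurious edges of negligible
magnitude that appear because zeroing them at a larger penalty would cost
more likelihood through shrinkage of the true edges than the EBIC penalty
charges. Their count grows with `n` and with the density/strength of the
true graph (at n = 5000, p = 10 their number fluctuates around 10% of the
true-zero pairs across seeds, while their magnitudes stay below ~0.03; the
behaviour was cross-checked against an independent graphical-lasso
implementation, which selects if anything denser models). The recovery tests
therefore assert what the estimator genuinely delivers: edge-weight
correlation with truth ≥ 0.9, every true edge recovered, and every spurious
edge negligible in magnitude — rather than a hard false-positive count that
a single run satisfies only by luck.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run entirely on synthetic data.
`scripts/acceptance.R` emulates the study shape — 306 subjects, 4 waves, 20
ordinal symptom items plus a 10-item self-efficacy block (reduced per wave
to its first principal component, sign-fixed and standardized) and a binary
treatment covariate, 13.5% wave-level missingness — and runs the full
pipeline with 100 bootstrap replicates on the first wave and 200
permutations per wave pair; the type-I calibration uses 200 replications of
200 permutations. These sizes are chosen so the whole validation cycle runs
comfortably on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances; the package defaults (1000 bootstraps, 1000
permutations) match reported practice and are what an applied analysis
should use.

## Known limitations

* Two-step (not full-information) polychoric estimation; both stages treat
  thresholds as fixed when the correlation is estimated.
* The latent-normal model is assumed throughout; no mixed graphical models
  or nonparanormal transforms.
* The EBIC likelihood is evaluated at the penalized estimate (no refit), so
  selected models can carry small compensation edges (see above).
* The dependent comparison test requires complete cases and compares two
  waves at a time; no omnibus multi-wave test is provided.
* Betweenness and closeness on regularized networks are intrinsically
  unstable at moderate sample sizes; strength is the only centrality whose
  stability the case-dropping bootstrap typically certifies.
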