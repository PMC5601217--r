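---
title: "Methods: linked multimodal decomposition and canonical correlation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked multimodal decomposition and canonical correlation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neocca` implements a multivariate association analysis between several
aligned voxelwise imaging modalities and a clinical covariate table, with
permutation and bootstrap inference throughout. This vignette is the
package's own account of the statistical model, the choices behind each
stage, and what the validation on synthetic cohorts does and does not
establish.

## The analysis chain

1. **Clinical encoding.** Continuous variables are z-scored; binary
   variables stay on the 0/1 scale and are centered. Missing entries are
   imputed (column mean for continuous, mode for binary) and counted;
   constant columns are rejected, since a zero-variance variable carries no
   correlation information and breaks the whitening step.
2. **Linked decomposition.** Each modality block (subjects × voxels) is
   variance-normalized — voxel columns centered, the block scaled to unit
   total variance — so that modalities with different units, sizes and
   smoothness contribute comparably. Blocks are concatenated feature-wise,
   whitened by SVD to at most `max_components` dimensions, and rotated by a
   deflation fixed-point independence contrast (tanh nonlinearity) applied
   on the *spatial* side. Every component therefore has one spatial map per
   modality and a single shared subject course; courses are rescaled to
   unit variance, components ordered by explained-variance share, and
   per-modality maps obtained by least squares of each normalized block on
   the courses.
3. **CCA.** The retained subject courses form the imaging feature matrix
   *Y*; the encoded clinical matrix is *X*. The canonical system is solved
   in closed form by SVD of the whitened cross-covariance, which is exact,
   deterministic and numerically stable; rank decisions use a tolerance of
   1e-10 times the leading singular value, and a ridge option exists for
   rank-deficient blocks (off by default — the intended regime is
   n ≫ p, K).
4. **Inference.** Pair significance uses a sequential permutation test:
   rows of the clinical block are re-ordered against the imaging block,
   the CCA refitted, and the maximum canonical correlation recorded; pair
   k receives p = (1 + #{max r_perm ≥ r_k})/(P + 1). Loading significance
   permutes the variable block against the variates with a max-|r|
   family-wise null per block (a per-variable switch exists). Confidence
   intervals are percentile bootstrap over subjects.
5. **Voxel maps.** Each canonical imaging variate is correlated back to
   every voxel; t = r√((n−2)/(1−r²)); family-wise error is controlled by
   the permutation distribution of the maximum |t| within each modality.
6. **Outcome regression.** Simple linear regression of each outcome score
   on each reported imaging variate over complete cases, with
   F = (n−2)R²/(1−R²) and multiplicity correction over the grid.

## Assumptions

The chain is linear and correlational throughout: it assumes
between-subject variation in each modality is driven by a low-rank set of
spatial patterns with additive noise, that clinical–imaging coupling is
linear in those patterns, and that subjects are exchangeable under the
null (the basis of permutation validity). No distributional assumption
beyond exchangeability is needed for the permutation p-values; bootstrap
intervals assume the empirical distribution is a usable stand-in for the
population, which degrades for very rare binary factors (see Limitations).

## Design decisions

**Decomposition estimator.** A full variational-Bayes linked ICA (with
modality noise precisions and automatic relevance determination) is a
large, stochastic estimation problem in its own right. The package instead
uses the deterministic substitute described above, which honors the same
interface — shared subject courses, per-modality maps, rejection of
unsupported components — and makes the decomposition's contribution to
downstream inference exactly reproducible. This substitution is
intentional and documented; the inferential layer (CCA + resampling) is
the package's focus, and its tests demonstrate that planted subject
courses are recovered with |correlation| > 0.9 under noise. Component
rejection uses an explained-variance-share threshold (default 1e-4), since
relevance determination has no meaning outside the Bayesian fit.

**Sign conventions.** ICA and CCA signs are arbitrary. Components are
signed so the largest-magnitude spatial-map entry is positive; canonical
pairs are signed so the clinical variable with the largest |loading| loads
positively. Both conventions are deterministic, which stabilizes bootstrap
alignment.

**Sequential permutation reading.** "Sequential" testing against the
recorded *maximum* permuted correlation is implemented as one shared
max-statistic null against which every observed r_k is compared; this
forces the reported p-values to be non-decreasing across pairs, matching
step-down reporting. An alternative reading — re-running the permutation
on residualized blocks at each step — is available via
`method = "residual"` but is not the default.

**Permuted block.** The clinical block's rows are permuted; permuting
either block yields the same null distribution, so the choice is purely a
logged convention.

**Percentile bootstrap.** Replicate CCA fits are aligned to the original
model by greedy matching on |correlation| between replicate and original
variates over the resampled subjects, with signs fixed by positive
correlation; alignment diagnostics (fraction reordered / sign-flipped) are
reported rather than hidden. Percentile intervals can fall below (or
above) the point estimate for highly biased statistics such as the leading
canonical correlation — the worked example in the README shows exactly
this for a pair-3 interval — and the package reports them as computed
instead of forcing containment.

**Loading multiplicity.** Whether the original analyses corrected loading
p-values across the ~30 clinical variables is not determinable; the
default uses the max-statistic family-wise null within each block (more
conservative), with a per-variable switch.

**Outcome degrees of freedom.** Published tables of this analysis family
sometimes print the slope F with denominator df n−1 where the conventional
simple-regression value is n−2. `regress_outcome()` computes the
conventional F and stores p under both df conventions, clearly labelled,
rather than guessing which convention a given table used.

**Outcome multiplicity.** The default is Bonferroni over the full
variate × outcome grid, with Holm and BH switches. Note that a borderline
cell (e.g. p = 0.005 among 15 tests) passes BH but not grid-wise
Bonferroni; the tests pin this sensitivity explicitly.

**Correction scope for voxel maps.** Modalities are corrected separately
(matching per-map usage of permutation tools in this field); a
cross-modality joint max switch exists (`joint = TRUE`).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the physics of MR acquisition:

- latent subject components Z (n × k), exactly standardized;
- per modality, blob-shaped contiguous spatial supports, disjoint across
  components within a modality (so spatial independence holds by
  construction), Gaussian-smoothed at the modality's FWHM
  (σ = FWHM/√(8 ln 2), single pass) and scaled to unit norm;
- blocks B_m = s_m · Z A_mᵀ + ε with i.i.d. Gaussian voxel noise;
- a clinical table mixing continuous and binary variables (prevalences
  spanning <1% to ~65% in the study-scale default), linked variables
  following s·Z_j + √(1−s²)·noise with link strengths calibrated so the
  population canonical correlation of pair j equals `planted_rho[j]`
  (with k variables linked to one component, each gets s solving
  k·s²/(1−s²) = ρ²/(1−ρ²)); for binary variables the calibration holds on
  the latent liability scale and thresholding attenuates the observable
  correlation, so exact-recovery checks use continuous links;
- outcome scores 100 + 15(effect_r · variate + √(1−effect_r²)·noise),
  the standard developmental-scale calibration (mean 100, sd 15), with a
  follow-up loss fraction defaulting to 24/449;
- one declared missing clinical entry (the study-scale default blanks a
  single parenteral-nutrition value), exercising the imputation path.

Continuous clinical variables are affine-mapped to plausible clinical
ranges for display; day-count variables can take small negative values
under this linear map, which is irrelevant to a correlation analysis and
preferable to truncation, which would distort the planted links.

What passing tests on this generator shows: the solver matches an
independent eigendecomposition oracle; the permutation and FWE machinery
are calibrated under a true null; bootstrap intervals attain nominal
coverage; planted low-rank structure at realistic n is recovered through
the full chain. What it does not show: robustness to spatially correlated
or non-Gaussian noise, registration error, lesions, or nonlinear
clinical–imaging coupling — none of which the generator produces, by
design.

## Numerical choices and problem sizes

- FWHM→σ conversion is fixed; smoothing is one separable Gaussian pass
  (kernel truncated at 3σ), replacing iterative smoothing-to-target: only
  the resulting smoothness matters downstream.
- The fixed-point rotation iterates to a 1e-6 angular tolerance with a cap
  of 500 iterations per component; hitting the cap flags the fit
  (`converged = FALSE`, with a warning) instead of failing.
- Permutation p-values use (c+1)/(P+1), strictly positive and valid; the
  floor at P = 10,000 is 1e-4.
- Degenerate bootstrap resamples (rank loss, e.g. a rare binary collapsing
  to a constant) are dropped and counted; more than 10% dropped aborts the
  run.
- Validation problem sizes were chosen as the smallest that make the
  statistical properties sharp: oracle equivalence at n = 30;
  type-I-error calibration from 300 null simulations at P = 500, n = 100;
  bootstrap coverage from 200 simulations at n = 400, B = 500; FWE
  calibration from 200 null map simulations on a 16×16×8 grid;
  end-to-end recovery at n = 500 with k = 8 components, four modality
  blocks and 12 clinical variables across 5 seeds. The study-scale
  default spec (449 subjects, 30 clinical variables) is used for the
  worked example and the cohort-summary checks.

## Known limitations

- The decomposition is a deterministic point estimator; it reports no
  posterior uncertainty and no per-subject modality weighting.
- Very rare binary factors (prevalence ≪ 1/n) can be constant in a given
  draw or in bootstrap resamples; `filter_rare()` exists precisely for
  this, and the pipeline exposes it as `rare_factor_threshold`.
- Mean/mode imputation is adequate for the intended near-complete tables
  (≤1 missing case per variable); it is not a missing-data model.
- No sparse or penalized CCA: variates remain dense combinations of all
  variables, and interpretation should lean on loadings plus their CIs.
- No cluster-level or threshold-free spatial enhancement; voxelwise
  max-|t| FWE only.
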