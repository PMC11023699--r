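---
title: "Methods: pharmacological GBC, dimensionality, surrogate maps and neuro-behavioral mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacological GBC, dimensionality, surrogate maps and neuro-behavioral mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`deltagbc` implements a complete analysis chain for pharmacological
resting-state fMRI at the parcel level: from parcellated BOLD time series
to denoised functional connectivity, global brain connectivity (GBC) maps,
drug-minus-placebo (Δ) maps, and the multivariate statistics that
characterize how a drug's effect varies across individuals. This vignette
is the package's account of the underlying models, the tunable parameters,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## The connectivity model

Each scan is a frames × parcels matrix with a repetition time `tr`
(seconds), a framewise-displacement trace (mm) and a normalized intensity
RMS trace. Denoising follows the standard resting-state recipe, in this
order:

1. **Motion scrubbing.** A frame is flagged when FD > 0.5 mm or RMS >
   1.6 × the scan's median RMS; the frames immediately before and after a
   flagged frame are discarded too (`compute_frame_flags`). A subject with
   more than 50% flagged frames is excluded outright (`scrub` returns a
   `subject_exclusion` marker rather than data). Fewer than 30 surviving
   frames is an error: correlation estimates below that are unusable. The
   30-frame floor is a package choice (`min_frames`), configurable.
2. **High-pass filtering at 0.008 Hz** is implemented as regression on the
   discrete-cosine basis functions with frequency below the cutoff
   (`highpass`). Compared to an IIR/FIR filter this gives exact DC
   removal, no ringing at the scan edges, and composes with nuisance
   regression into a single joint design.
3. **Nuisance regression** (`nuisance_regress`) removes an intercept, the
   supplied nuisance signals, their backward-difference first derivatives
   (first row zero, preserving frame count), and optionally the global
   mean signal. Collinear columns are dropped by QR pivoting with a
   warning. `preprocess_session` performs scrubbing and a *joint*
   regression of the DCT drift basis plus nuisance set — sequential
   regressions can partially reintroduce removed variance, a joint fit
   cannot.

Functional connectivity is the Pearson correlation between every pair of
parcel time series, Fisher r-to-z transformed; `|r|` is clipped at
`1 - 1e-7` before `atanh` so that numerically identical parcels produce a
large finite value instead of infinity. GBC at parcel *x* is the mean
Fisher-z connectivity of *x* with all *other* parcels. The self-connection
is excluded by construction: including `atanh(1)` would be infinite, so
exclusion is the only finite reading of the row-mean definition
(`include_self` is intentionally not offered).

## PCA of Δ-GBC maps and permutation retention

The subjects × parcels matrix of Δ-GBC maps is decomposed by SVD after
centering each parcel across subjects (`fit_delta_pca`). Parcels are *not*
variance-scaled: all features of a Δ-GBC map live on the same Fisher-z
scale, and scaling would up-weight noisy parcels. (The behavioral PCA
below *does* scale, because symptom items live on heterogeneous scales;
the asymmetry is deliberate.) Component signs are fixed by aligning each
loading with the group-mean map (ties broken by the largest-magnitude
parcel), so results are deterministic.

Significance uses a parcel-shuffle permutation null: each subject's parcel
vector is independently permuted, the PCA refit, and the variance fraction
at every rank recorded; `p_k = (1 + #exceedances) / (n_perm + 1)`. The
retained set is the *leading run* of ranks with `p < 0.05`. Stopping at
the first non-significant rank matters: ranks are correlated under the
null, and marking every rank with `p < 0.05` empirically retains at least
one component in roughly a fifth of pure-noise datasets, whereas the
sequential rule keeps the null retention rate at the nominal level (the
type-I property tests in the suite check exactly this).

One caveat the synthetic studies surface: Δ-GBC estimation noise is itself
spatially structured (all parcels of one scan share frames and the global
factor), and the parcel-shuffle null destroys that structure. On
session-level simulations the test can therefore retain one axis beyond
the planted count. This is a property of the null, not a bug; it is worth
remembering when interpreting the retained count on real data.

## Participation-ratio effective dimensionality

For maps with covariance eigenvalues `λ_i`, the participation ratio is
`PR = 1 / Σ (λ_i / Σλ)²` — 1 for rank-one data, N for N equal eigenvalues.
The spectrum is taken from the same feature-centered covariance the PCA
decomposes, so PR and PCA describe one object. Eigenvalues below
`1e-12 × λ_max` are treated as zero.

PR depends strongly on sample size, so conditions are compared at a common
subset size (default 22) via `pr_distribution`: full enumeration of
subsets, leave-one-out jackknife, or seeded random draws of distinct
subsets. `compare_conditions` runs a one-way ANOVA over the pooled PR
values with all pairwise Welch t-tests, Bonferroni-multiplied. Welch is
used because the subsample distributions routinely have unequal variances
and the safer default costs essentially nothing.

**Known limitation.** Subsample PR values from one cohort are strongly
dependent (any two size-22 subsets of 23 subjects share almost all their
members), so the spread of a subsample distribution understates the
sampling variability of the cohort-level PR by roughly a factor
`sqrt(n-1)`. t-tests between subsample distributions of *independent*
cohorts are therefore pseudo-replicated and reject far too often, even
when the two cohorts share identical generative structure: in the
package's own simulations, two independently drawn cohorts with the same
planted 8-dimensional structure are declared "significantly different" in
roughly nine out of ten runs. The mean-PR *ordering* across conditions is
reliable; the pairwise p-values between closely matched conditions should
be read with this caveat. The package implements the subsample-comparison
procedure as the field uses it, and documents rather than silently
"fixes" this property.

## Variogram-matched surrogate maps

Correlating two smooth brain maps across parcels wildly inflates
parametric significance: neighbouring parcels are not independent, so the
effective sample size is far below the parcel count. The package's
surrogate test replaces the parametric null with map surrogates that
preserve the target's spatial autocorrelation:

1. The autocorrelation fingerprint is the binned empirical variogram
   `γ(h) = ½·mean[(v_i − v_j)²]` over equal-count distance bins
   (default 25), evaluated on a seeded subsample of parcel pairs (default
   10,000) for large ensembles.
2. Each surrogate starts as a random permutation of the target's values.
3. The permutation is smoothed with a k-nearest-neighbour exponential
   distance-decay kernel for each k in `{5, 10, 20, 50, 100}` (truncated
   at P−1); each smoothed candidate is affine-rescaled (`a·x + b`) to
   minimize the squared error between its variogram and the target's —
   scaling a map by `a` scales its variogram by `a²`, so the optimal
   rescale has a closed form.
4. The candidate with the smallest realized variogram SSE wins; the
   unsmoothed permutation is always in the candidate set, so a surrogate
   is never a worse match than a plain permutation.

Two choices deserve comment. First, **no white-noise "nugget" term is
added** to the candidates. A nugget makes the short-range variogram easier
to match, but it dilutes the surrogates' large-scale spatial power — and
the null distribution of map-to-map correlations is most sensitive to
exactly that large-scale power, because the comparison maps are themselves
smooth. In calibration runs on independent smooth fields, nugget-bearing
surrogates produced measurably too many small p-values, while the pure
affine rescale calibrates (the suite's calibration test checks uniformity
of the empirical p over 200 replicate pairs at M = 1000, alongside the
demonstration that the naive parametric test rejects several times its
nominal level on the same data). Second, surrogates are pinned to the
target's mean per generation block; variograms are translation-invariant,
and this keeps hemisphere-merged surrogates free of piecewise offsets, so
the test is exactly equivariant under positive affine transforms of the
target.

Surrogates can be generated per hemisphere and merged (`hemi` argument),
mirroring how cortical gene-expression analyses are run. The p-value is
two-tailed on `|r|` with the usual `(1 + #) / (M + 1)` form, so the floor
is `1/(M+1)`; M = 1000 is the package default for tests and per-subject
profiles, and larger ensembles are only worth their cost for headline
maps. Gene maps are screened by cortical differential stability before
testing (`screen_genes` drops `|DS| ≤ 0.1`), and gene-wise p-values are
Benjamini–Hochberg corrected (`fdr_correct`).

## Behavioral PCA, subscales, and paired variance comparison

`assemble_delta_behavior` forms drug-minus-placebo item differences and
imputes missing cells with the column mean of the observed differences
(imputation never changes a column mean). The behavioral matrix in the
default configuration has 31 columns: 30 PANSS items plus one cognition
score — the conventional three subscales sum to 30 items, so a 31-variable
model is only consistent if cognition enters as its own standardized
column, which is how the package reads it. The cognition sign convention
is higher = better performance. Dissociative-state (CADSS) items are not
part of the default model; item blocks are configurable.

`fit_behavior_pca` standardizes items to unit variance before the SVD.
Significance comes from a column-shuffle null (participant order permuted
independently within every item, 5000 permutations by default) with the
same leading-run retention rule as the neural PCA. Subscale scores are
sums of member items; the three-factor configuration is the conventional
Positive(7)/Negative(7)/General(16) split, and a five-factor alternative
(Positive, Negative, Disorganization, Excitement, Emotional Distress) is
shipped as a full partition of the 30 items so subscale sums stay
comparable. Both live in `inst/extdata/subscales/` as YAML.

The spread of subject scores on two components is compared with the
Pitman–Morgan paired-variance test: `t = (F − 1)√(S − 2) /
(2√(F(1 − r²)))` on `S − 2` df, where `F` is the variance ratio and `r`
the score correlation. Equal variances give `t = 0` through the numerator;
at `|r| → 1` with unequal variances the statistic diverges and `p = 0` is
reported. The unit tests pin this implementation against the classic
sum/difference-correlation identity (`cor.test(x + y, x − y)` yields the
same t).

## Mass-univariate neuro-behavioral mapping

`mass_univariate_map` regresses each parcel's Δ-GBC on a standardized
behavioral score (simple OLS slope per parcel) and Z-scores the slope map
across parcels. Standardizing the score makes coefficient maps comparable
across behavioral variables. Family-wise error over parcels is controlled
by score-permutation (`permutation_correct`): the per-parcel statistic is
the absolute parcel–score correlation (a pivotal monotone transform of
the regression t), compared against the permutation distribution of its
maximum over parcels. Max-statistic correction is the default because it
is exactly valid with no spatial model; threshold-free cluster enhancement
(E = 0.5, H = 2, over a k-nearest-neighbour parcel graph, k = 6 by
centroid distance) is available where spatially extended effects are
expected, with positive and negative tails enhanced separately and
disconnected graphs handled per component after a warning.

Power at the single-parcel scale is intrinsically modest: with 40 subjects
a planted effect of population r = 0.6 sits almost exactly at the null
max-|r| threshold over 200 parcels (≈ 0.60), so detection hovers around
70% — the FWER-calibration test in the suite passes while the
corresponding power property is documented as not attainable at that
effect size and sample size. Detecting such effects reliably requires
either larger samples, spatial pooling (TFCE), or map-level statistics
like the subject projections below.

Single subjects are placed on a reference map by correlating their Δ-GBC
map with it and Z-scoring the r-values across the cohort
(`subject_projection`); constant maps are flagged rather than scored. The
SST−PVALB coupling analysis correlates each subject's difference in
gene-map correlations with their projection score
(`gene_coupling_correlation`), with a parametric p and an optional
subject-permutation p; a constant difference vector is flagged as
degenerate with no numeric output.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted ground
truth, so each stage has a recovery test:

- **Atlas** (`make_atlas`): centroids on the unit sphere via a Fibonacci
  lattice — deterministic and with non-degenerate pairwise distances,
  which the surrogate machinery needs; hemispheres by the sign of the
  first axis; 12 network labels following the CAB-NP naming, with the
  association/sensory class split balanced six/six so that class-contrast
  tests have equal groups (a design convenience, not an anatomical claim —
  the real parcellation's split is 8/4).
- **Δ-GBC maps** (`simulate_delta_gbc`): `mean + scores·√λ·uᵀ + noise`
  with orthonormal planted components, the first seeded with the
  association-vs-sensory contrast. `whiten = TRUE` orthonormalizes the
  scores so the planted sample spectrum is exact — used where a test
  needs the spectrum itself (e.g. PR closed forms); with iid scores the
  sample spectrum is Wishart-spread around the planted one, which is the
  realistic default.
- **Sessions** (`simulate_session`): the one-factor model
  `x_p(t) = w_p·g(t) + ε_p(t)` gives a closed-form pairwise correlation
  `w_p w_q / √((w_p²+1)(w_q²+1))`, monotone in `w`, so GBC recovery can
  be checked against theory. Motion spikes are injected into the FD/RMS
  traces only; the BOLD matrix stays clean because scrubbing logic is
  tested on flags, not on artifact modelling. Note that exact ties in a
  two-block `w` cap the rank correlation between `w` and GBC at √3/2;
  graded weight maps are used where a ≥ 0.9 rank recovery is asserted.
- **Gene maps** (`simulate_gene_map`): Gaussian fields with exponential
  spatial covariance `exp(−d/smooth_scale)` (single-parameter control of
  autocorrelation), mixed with a standardized target so the expected
  target correlation is exact.
- **Behavior** (`simulate_behavior`): `scores·coupling + noise`, with
  optional missing-cell injection for imputation tests.
- **Whole studies** (`simulate_study`): 40 subjects × 2 conditions × 718
  parcels × 400 frames at `tr = 0.7` s by default, with five planted
  neural components (spectrum 60, 45, 30, 25, 20), behavior coupled to
  the first two, and gene maps planted at correlations +0.47 / −0.22 with
  the first component — the effect scale reported for interneuron marker
  genes in pharmacological GBC work. The drug scan perturbs the session
  weight map along the subject's planted component mixture
  (`delta_scale = 0.2`, the smallest value in a pre-registered scan that
  gives robust end-to-end recovery of the planted component through the
  session → GBC → Δ chain).

**Global signal regression and the one-factor model.** In real data GSR
removes a spatially persistent artifact. In the one-factor generator the
"global signal" *is* the planted connectivity carrier, so regressing it
out removes the signal the recovery tests plant. `preprocess_session`
keeps `gsr = TRUE` as the real-data default; the synthetic-study
convenience wrapper `study_delta_gbc` defaults to `gsr = FALSE` for this
reason, and the distinction is documented on both functions.

**What the synthetic tests do not show.** The generator has no
hemodynamics, no physiological noise, no spatial noise correlations
beyond the planted components, no site or session effects, and motion
affects only the traces. Passing recovery tests therefore demonstrates
the *statistical machinery* — estimator correctness, null calibration,
retention behaviour, end-to-end plumbing — not robustness to the
artifact structure of real fMRI.

## Numerical choices and problem sizes

Degenerate inputs error loudly rather than propagate: zero-variance
parcels before correlation, constant map sets before PCA, all-zero data
before PR, zero-variance scores before regression, constant difference
vectors before coupling. Correlations are clipped before `atanh`;
eigenvalues are floored at `1e-12 × λ_max`; permutation p-values always
use the `(1 + #)/(n + 1)` form so they are never zero.

The test suite runs its heavier properties at 40 subjects × 200 parcels
with 100 replicate seeds and 500–1000 permutations, and the calibration
study at 200 replicate field pairs with M = 1000 surrogates; these sizes
were chosen so the full suite completes on a single CPU in well under half
an hour while keeping every Monte-Carlo margin (e.g. "≥ 90/100 seeds")
wide enough to be stable under seed changes. `scripts/acceptance.R` runs
the full synthetic study at 40 × 2 × 718 with 400-frame sessions — the
study-scale configuration — in about a minute.
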