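---
title: "Recurrent brain-state dynamics from amplitude-envelope connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent brain-state dynamics from amplitude-envelope connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## The problem

Resting-state electrophysiology shows that whole-brain functional
connectivity (FC) is not static: parcel-level amplitude envelopes move
through recurrent, short-lived coupling configurations ("brain states").
`dynfc` implements a complete analysis chain for this phenomenon:

1. parcel time series → orthogonalized amplitude envelopes;
2. a full-covariance Gaussian hidden Markov model (HMM) over PCA-reduced
   envelopes, with the state count selected by information criteria
   averaged across subjects;
3. temporal state features (fractional occupancy, mean lifetime, mean
   interval, transition probabilities) and spatial features (state-wise
   FC matrices reduced to within/between-network means and transition
   magnitudes);
4. an adaptive disparity-filter backbone over windowed connectivity
   graphs, with the retention threshold optimized by golden-section
   search;
5. exact Mann–Whitney group comparisons with rank-biserial effect sizes
   and Benjamini–Hochberg FDR control.

Because matched empirical recordings are not redistributable, the package
ships a first-class synthetic-data generator with known Markovian ground
truth; every stage is validated against that truth or against
independent oracles.

## The generative model

`ground_truth_model()` defines `K` hidden states over a `parcel_atlas()`
(default: 100 parcels in the seven canonical networks VIN, SMN, DAN,
VAN, LIN, FPN, DMN). A state is the *activation of one network*: its
parcels couple at `within_on` (default 0.60), it couples to a partner
network (the next in atlas order) at `between_on` (0.30), all other
within-network blocks sit at `within_off` (0.10) and the cross-network
background at `between` (0.05). States follow a Markov chain with
self-transition probability `stay_prob = 0.98`, i.e. a mean dwell of 50
samples (200 ms at 250 Hz), in the range reported for
electrophysiological brain states. A `group_effect` scales every
off-diagonal level multiplicatively; the cohort default is
OAC 1.00 < YAC 1.15 < TCOA 1.30, emulating a cross-sectional design in
which one group sits lowest and an intervention group highest.

Envelope samples are produced by drawing correlated standard Gaussians
per state and passing them through a monotone positive map. The default
map is lognormal, `exp(sigma_log * Z)` with `sigma_log = 0.3` (CV ≈ 0.31,
mild right skew, like real band-limited amplitude envelopes); its
correlation attenuation has the closed form
`g(rho) = (exp(s^2 rho) - 1)/(exp(s^2) - 1)`, which the generator
inverts analytically so the *envelope-scale* targets are met exactly
(`lognormal_corr()` / `lognormal_rho()`). A folded-normal map
(`abs(Z)`, inverted through a precomputed monotone lookup) is available
as `marginal = "folded"`. We made the lognormal map the default after
observing that the folded map's heavier skew systematically inflates the
state count selected by information criteria: a full-covariance Gaussian
HMM earns real likelihood by splitting a strongly non-Gaussian state
into two Gaussian ones, so model-order recovery — a property the
generator exists to support — degrades. The same consideration fixed
`between_mode = "partner"`: coupling each active network to *all* others
creates a heavy-tailed global factor with the same inflationary effect,
while one partner per state keeps all seven cyclic network pairs
state-modulated (so between-network connectivity carries a state-specific
signal) without that artifact.

What the generator deliberately does **not** emulate: scalp-level mixing
and source reconstruction (its parcels are leakage-free by
construction), temporal autocorrelation of envelopes within a state
(samples are conditionally independent), artifacts, or subject-level
random effects (subjects within a group differ only by sampling noise).
Passing tests therefore demonstrate the *correctness of the machinery*
and the recoverability of known effects at realistic sizes — not
robustness to the full messiness of empirical recordings.

```{r generator}
atlas <- parcel_atlas()
model <- ground_truth_model(atlas)
rec <- generate_recording(atlas, model, duration_s = 4, fs = 250,
                          seed = 1, subject_id = "demo", group = "OAC")
rec
```

## Envelope processing

`downsample()` applies a zero-phase Hamming-window FIR (cutoff 0.8 of
the target Nyquist, constant-padded edges, exact unit DC gain) before
resampling to 250 Hz. `hilbert_envelope()` takes the modulus of the
FFT-based analytic signal and flags the first and last 5% of samples as
boundary-affected. `orthogonalize()` makes the demeaned parcel rows
exactly pairwise orthogonal; the default is sequential Householder QR
(with column pivoting, outputs mapped back to input order), and
`method = "symmetric"` provides the closest-orthogonal-matrix (Löwdin)
variant that treats parcels symmetrically. Exactly collinear parcels do
not fail: the factorization still yields orthogonal components, the
collapsed directions' scales are floored, and the event is recorded in
the `regularized` attribute (triggered at condition number 1e8).

Where leakage correction acts is a real design choice. Orthogonalizing
the *envelopes* zeroes their whole-recording correlations, so any
occupancy-weighted average of state-windowed FC collapses to ≈ 0 — which
would make all network-level connectivity summaries pure noise.
Empirical studies that report positive post-correction envelope FC are
therefore operating in the standard source-space order: orthogonalize
the (analytic) signals, *then* extract envelopes. `run_pipeline()`
follows that order for oscillatory input; for envelope-mode synthetic
input — leakage-free by construction, with no signal phase to
orthogonalize — the correction is skipped unless explicitly requested
(`pipeline_config(orthogonalize = TRUE)`). The `orthogonalize()`
operation itself is fully tested either way.

## State modelling

The HMM has full-covariance Gaussian emissions: amplitude-coupling
states are *defined* by covariance structure, which diagonal models
cannot express. Fitting is Baum–Welch EM (RcppArmadillo), initialized
from k-means on short-window moment features (per-window means,
log-variances, and correlations of the leading eight dimensions,
window ≈ 50 samples): per-sample k-means cannot see covariance-defined
states, windowed moments and correlations can, and the quality of this
partition is what decides whether EM finds the state structure rather
than a local optimum. Covariance diagonals
are floored at `variance_floor_frac = 1e-3` of the largest feature
variance; EM stops when the relative log-likelihood change drops below
`em_tol`; restarts that collapse a state (posterior mass below d + 2
samples) are discarded and the best of `n_restarts` log-likelihoods
wins. Decoding is exact Viterbi.

Model-order selection fits each candidate `K` in `K_range` (default
3..12) per subject on per-subject PCA scores (95% retained variance)
and minimizes the across-subject mean of `(AIC + BIC)/2` with
`p = (K-1) + K(K-1) + Kd + Kd(d+1)/2` parameters; ties break toward the
smaller `K`. For group analyses one final HMM is fitted on the
concatenated, per-subject-standardized data (one shared PCA), and every
subject is decoded with it so state labels are comparable across
subjects.

## Features

Temporal features come from the decoded sequence: occupancy is a count
ratio (the counts sum to T exactly); lifetimes average the maximal run
lengths (boundary-truncated first/last runs included — excluding them
biases short recordings); intervals average the *gaps* between
consecutive visits (exclusive of the visits themselves; onset-to-onset
is the documented alternative); never-visited states propagate as
missing values, never as zeros. State-wise FC averages per-visit Pearson
matrices weighted by visit duration — correlating each visit separately
and averaging avoids splicing non-contiguous samples — and visits
shorter than `min_window_len = 25` samples (100 ms at 250 Hz) are
excluded as numerically meaningless. Network summaries are plain means
over off-diagonal within-network entries (7 values) and over
cross-network pairs (21 values). The transition magnitude of a summary
`m` is the occupancy- and transition-weighted mean absolute difference
`TM = Σ fo_i tp_ij |m_j − m_i| / Σ fo_i tp_ij` over `i ≠ j`, a magnitude
in correlation units that is zero when all states agree. Subject-level
connectivity is the occupancy-weighted mean over available states.

## Backbone extraction

All windowed graphs' edge weights are pooled; `bootstrap_median()`
resamples the pooled absolute weights (10000 iterations by default) and
returns the median of resample medians, `M`. For one window, edge
(u, v) survives `disparity_retention()` iff
`(|w_uv|/M)^2 / Σ_k (|w_uk|/M)^2 ≥ α` at either endpoint — the inclusive
rule keeps degree-1 nodes attached, and an equal-weight node of degree g
gives score exactly 1/g. Signs survive filtering (squaring discards
them, but retained negative couplings are scientifically meaningful).
`optimize_alpha()` minimizes the mean absolute difference in average
retained connectivity between consecutive windows over
α ∈ [0.001, 0.10] by golden-section search; because unimodality of that
objective is not guaranteed — it is in fact piecewise constant in α,
with breakpoints at the edges' retention scores — the search is
safeguarded twice: by a coarse grid scan (step 0.001, with a
golden-section refinement inside the best cell) and by an exact
incremental sweep over all breakpoints in the range, which visits every
attainable objective value; the best candidate is returned.
Windows that lose every edge contribute zero average connectivity. The
single optimized α is then applied to every window.

## Statistics

`mannwhitney_u()` counts pairs via midranks; `exact_p()` enumerates the
exact null distribution by the counting recurrence
`f(n1, n2, u) = f(n1−1, n2, u−n2) + f(n1, n2−1, u)` and doubles the
smaller tail. Tied data fall back, flagged, to the midrank normal
approximation with tie correction and continuity correction; that
approximation is also available directly (`method = "normal"`) because
it is what mainstream software reports by default at n = 15 per group —
reproducing published tables requires it. The rank-biserial effect size
is `r = 2U/(n1 n2) − 1`. FDR control is Benjamini–Hochberg within
explicit feature families (defaults: the 7 within-network variables, the
21 between-network variables, and each temporal feature type as its own
family) — family composition is configurable rather than silently
pooled. Shapiro–Wilk, Brown–Forsythe Levene, and z/IQR outlier flags are
reported for context only; nothing is removed automatically.

```{r stats}
exact_p(13, 15, 15)                      # exact two-sided p
exact_p(13, 15, 15, method = "normal")   # large-sample approximation
rank_biserial(13, 15, 15)
```

## Validation studies and problem sizes

Two replicated studies tie the pipeline to the generator's ground truth;
their problem sizes are package choices that keep each study's Monte
Carlo error small while the full suite remains convenient to run:

- `state_count_study()`: 10 replicates × 10 subjects × 60 s at 250 Hz,
  PCA capped at 20 dimensions, one EM start per fit, EM capped at 25
  iterations (relative tolerance 1e-4). The selected count is 7 — the
  generative value — in ≥ 8 of 10 replicates, with a convex mean
  criterion curve around the minimum.
- `ordering_study()`: 20 replicated cohorts of 3 × 15 subjects × 15 s at
  125 Hz with fixed K = 7, reduced bootstrap (100 iterations) and a
  0.005 safeguard grid. Group medians of subject-level mean
  within-network and between-network connectivity reproduce
  TCOA > YAC > OAC, with negative rank-biserial correlations for OAC
  versus both other groups, in ≥ 90% of replicates.

Numerical choices worth knowing: correlation targets are repaired to
positive semidefiniteness by eigenvalue flooring at 1e-10 followed by
rescaling to unit diagonal; per-subject seeds derive from the master
seed plus a stable hash of the subject id; all randomness is funneled
through seeds carried in config objects, so reruns are bitwise
reproducible.

## Known limitations

- The Gaussian emission model is deliberately misspecified for positive
  envelope data; with strongly skewed marginals, information criteria
  inflate the state count (this drove the lognormal default).
- Subject aggregation (occupancy-weighted state means) and the
  transition-magnitude normalization are this package's formalizations
  of verbally specified quantities; both are documented and
  configurable rather than canonical.
- The generator's conditional independence across samples means temporal
  features on synthetic data are cleaner than on real envelopes, where
  autocorrelation widens dwell-time distributions.
- `ordering_study()` runs without leakage correction because its input
  is leakage-free by construction; on real source-localized data the
  correction is indispensable and its residual bias is untested here.
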