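---
title: "Recurrent FC states from leading-eigenvector dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent FC states from leading-eigenvector dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Static functional connectivity summarises a whole resting-state scan as one
correlation matrix, hiding the fact that coupling between brain regions
dissolves and re-forms on the scale of seconds. `leidar` implements
leading-eigenvector dynamics analysis (LEiDA), which works at the single-frame
level: each fMRI volume is described by the dominant pattern of BOLD phase
alignment across parcels, those patterns are clustered into a small repertoire
of recurrent *FC states*, and each scan is then summarised by how the states
are visited — how often, for how long, and with what transition structure.
Because those summaries live on the subject-by-scan level, they can be
compared between groups with ordinary resampling statistics.

## The pipeline, stage by stage

**Band-pass filtering.** Parcel-averaged BOLD signals are filtered to
0.02–0.1 Hz with a second-order Butterworth filter, discarding scanner drift
below the band and cardiac/respiratory leakage above it. The filter is applied
forward and backward, because everything downstream is phase-based and a
single IIR pass would distort phases; the price is that the effective
magnitude response is the square of a single pass. Edge transients matter
here: at a 0.02 Hz lower edge the impulse response is long relative to a
210-frame scan, and padding-based zero-phase filtering (odd reflection, any
padding length) leaves ~10% amplitude artifacts tens of frames into the
series. We therefore compute Gustafsson initial conditions — the
forward-and-backward pass initial states are chosen by least squares so that
filtering forward-then-backward equals backward-then-forward — which keeps
in-band amplitude errors below ~0.5% everywhere except the outermost frames.
Column means are removed; all frames are retained, so the pooled eigenvector
count stays exactly (frames × scans).

**Instantaneous phase.** Each filtered parcel signal \(x(t)\) is written as
\(A(t)\cos\theta(t)\) via the analytic signal (FFT method: negative
frequencies zeroed, positive doubled); \(\theta\) is its argument and \(A\)
its modulus. The transform is taken over the full series with no tapering.
An all-zero parcel has no phase and is reported as an error naming the
parcel, never silently imputed.

**Phase coherence and its leading eigenvector.** At frame \(t\) the
parcels × parcels coherence matrix is
\(\mathrm{dFC}(n,p,t)=\cos(\theta_n(t)-\theta_p(t))\): +1 synchronized, 0
orthogonal, −1 antiphase. Only the leading eigenvector \(V_1(t)\) — the unit
eigenvector of the largest-magnitude eigenvalue — is retained; its element
signs split the parcels into two phase communities, and its outer product
\(V_1V_1^T\) is the rank-1 dominant pattern of the frame. Three numerical
decisions:

* the eigenvector comes from a dense symmetric eigendecomposition (N = 90 is
  small); an iterative solver would only be an internal optimization and
  would have to match the dense result to 1e−10;
* "largest magnitude" is read literally: selection is by \(|\lambda|\), and
  any frame where the selected eigenvalue is negative is flagged in QC
  (it never happens on sensible coherence matrices, whose top eigenvalue is
  positive, but the code must not assume it);
* since \(V\) and \(-V\) are the same direction, orientation is fixed by the
  majority-negative convention; when exactly half the elements are positive,
  the vector is flipped so its largest-magnitude element is negative — an
  arbitrary but deterministic tie-break.

A degenerate leading eigenvalue (multiplicity > 1 within 1e−10) makes
\(V_1\) ill-defined; such frames are counted per scan in the QC table. On any
synthetic data with nonzero noise the count must be zero.

**Clustering into FC states.** The eigenvectors of all frames of all scans
are pooled (36,120 for the 86-subject × 2-condition × 210-frame study shape)
and k-means is run independently for each k in 2..20. No optimal k is
chosen — the scientific question is whether a state difference is *consistent
across partition models*, not which model is best; silhouette-style model
selection is deliberately out of scope. Per k we run 20 restarts (10 in the
demo scripts) from random distinct rows and keep the lowest-inertia solution;
empty clusters are reseeded to the worst-fit point. The distance is cosine by
default: the samples are unit-norm directions, so cosine and Euclidean
orderings agree monotonically for unit-norm centroids, but cosine keeps the
centroid update honest about scale. Euclidean is available and is
cross-checked against `stats::kmeans` in the tests. States are relabelled by
decreasing occupancy so state 1 is always the dominant (usually global) mode,
and final centroids are re-oriented to the sign convention so that rendering
and cross-partition correlations are orientation-stable. Cross-k matching of
states uses maximum \(|r|\) (Pearson over centroid elements) with ties broken
by occupancy.

**State dynamics.** From each scan's label sequence: occupancy probability
(fraction of frames per state, sums to 1); mean lifetime (mean maximal-run
length × TR, seconds; NA for unvisited states); switching frequency
(label changes per second, Hz); and the switching profile. The switching
profile defaults to *conditional on a switch*: self-transitions are removed
from numerator and denominator and each defined row sums to 1 across the
other k−1 states — this matches reading transition arrows as "given a switch
out of state s, where does it go", which is how >20% switch probabilities
arise; the persistence-included variant is always computed alongside. Runs
truncated by the scan boundary count toward lifetimes by default: with ~2-
frame mean dwell and 210 frames the truncation bias is small, while dropping
boundary runs would silently erase rare states; a flag exposes the stricter
alternative. Shannon entropy of the occupancy distribution is reported in two
labelled variants — the full-distribution entropy \(-\sum_s p_s\log_2 p_s\)
(bits, bounded by \(\log_2 k\)) and the per-state binary entropy of
\(\{p_s, 1-p_s\}\) — because "entropy of a state's occurrence" admits both
readings and we do not privilege either.

**Group inference.** The workhorse is a permutation t test: pooled-variance
two-sample t on the observed grouping, null built by reassigning group labels
(sizes preserved), two-sided
\(p = (1 + \#\{|t_\pi| \ge |t_{obs}|\})/(n_{perm}+1)\). The +1 correction
keeps p in \([1/(n_{perm}+1), 1]\). Defaults: 10,000 permutations, nominal
\(\alpha = 0.05\), Bonferroni-corrected per partition to \(0.05/k\) (each
partition tests k hypotheses per metric; no correction is applied *across*
partition models, which are treated as complementary views of the same
sample, not independent hypotheses). Tests are two-sided throughout —
direction is read from the effect sign — and Hedges' g (pooled-SD
standardized difference with the small-sample factor \(1-3/(4(n_a+n_b)-9)\))
accompanies every comparison. Missing lifetimes are excluded pairwise with
the post-exclusion group sizes recorded; zero-filling would conflate "absent"
with "brief". Also provided: a paired sign-flip test for within-group
condition contrasts (order-invariant: the statistic depends only on the
multiset of paired differences); a covariate-adjusted group test (OLS on
group + covariate) whose primary p-value is Freedman–Lane — residuals of the
covariate-only model are permuted and added back to its fitted values — with
the classical t-test p alongside; and a group × condition interaction test
whose statistic is the between-group difference of per-subject condition
changes, inferred by permuting group labels, with the classical
repeated-measures ANOVA F reported for reference.

## The synthetic cohort generator

No public accession exists for resting-state recordings of the kind this
pipeline targets, so verification rests on a generator whose ground truth is
exact. Each scan is built from a hidden first-order Markov sequence over
planted states. State 1 is a global mode (all areas in one phase community);
every other state assigns a minority community a π phase offset against the
majority — π because it maximally separates the communities in cosine
coherence, making recovery tolerances interpretable. Area signals are
\(\cos(2\pi f t + \phi_{comm}(state(t)) + \text{jitter}) + \varepsilon\):
carrier \(f = 0.05\) Hz (inside the analysis band), von Mises phase jitter
(concentration κ = 8 by default) drawn per area per state run — offsets
change only at state switches, so each frame's true label is exact — and
Gaussian amplitude noise (σ = 0.2 relative to unit amplitude). The initial
Markov state is drawn from the chain's stationary distribution, so planted
occupancies carry no burn-in bias.

Transition matrices are built as \(P = (1-s)I + s\,\mathbf{1}\pi^T\): the
stationary distribution is exactly the requested occupancy vector \(\pi\) and
the single stickiness parameter \(s\) sets dwell times
(\(1/(s(1-\pi_i))\) frames; \(s = 0.5\) gives ~2-frame ≈ 4 s mean dwell at
TR = 2 s, the scale reported for empirical FC states). The default cohort
mirrors a two-group study: 51 + 35 subjects × 2 conditions × 210 frames × 90
areas at TR = 2 s, four planted states with group-A occupancies
(0.47, 0.25, 0.20, 0.08) and group-B (0.50, 0.25, 0.20, 0.05) — a 0.03
deficit planted in the rarest state, the regime in which a real deficit of a
clinically relevant state would have to be detected. Ground truth (planted
centroids, per-scan state sequences, empirical planted occupancies) is
written as a sidecar JSON so tests never re-derive truth from generator
internals.

What the generator does *not* emulate: hemodynamic response convolution,
scanner drift, motion artifacts, spatially correlated noise, inter-subject
anatomical variability, or realistic covariance structure between areas
beyond the planted community patterns. Passing recovery tests therefore shows
that the pipeline's inference chain is correct and calibrated under its own
model assumptions — not that real fMRI will yield states this clean. In real
data, state boundaries are soft, dwell statistics are TR-limited, and the
global mode may absorb residual global signal.

## Problem sizes used in the tests

The test suite runs the full study-shaped accounting check (172 scans,
36,120 pooled eigenvectors) once; the statistical-calibration check uses 250
null cohorts of 86 subjects at 1,000 permutations per test (the full-study
setting of 10,000 permutations is a default, not a test requirement — the p
floor 1/(n+1) only needs to sit well below 0.05/k); and the recovery check
uses one 50 + 35-subject single-condition cohort swept over k = 3..6 with 10
k-means restarts. Unit tests use 6-20-area cohorts built in code. All seeds
are fixed; identical inputs reproduce bit-identical outputs at every stage.

## Degenerate inputs and numerical choices, collected

* square time-series tables are rejected unless the orientation is given
  explicitly — never guessed;
* NaNs and non-numeric cells are format errors naming row and column;
* all-zero parcels are degenerate-signal errors naming the parcel;
* eigen-solver failures surface; they are not caught and masked;
* zero-variance centroids make Pearson similarity an error, not NA;
* permutation p-values can never be 0 (+1 correction), and
  `significant_corrected` is defined as `p < alpha/k` exactly;
* k-means determinism: restart sub-seeds derive from the partition seed, the
  sweep derives per-k seeds from the master seed, and `compare_all` fans one
  seed out to every test in a fixed order.

## Known limitations

* The entropy variants are this package's operationalizations; supplementary
  definitions in the empirical literature differ and are not always
  recoverable.
* Lifetime estimates at TR = 2 s are coarse: long apparent dwell likely
  reflects high recurrence probability at faster timescales, not a sustained
  fixed configuration; between-group *comparisons* of lifetimes are the
  meaningful quantity.
* The pipeline is parcellation-agnostic (area labels are pass-through
  strings); nothing anatomical is assumed, so anatomical interpretation of a
  state lives entirely outside the package.
* k-means with cosine distance is implemented in-package (no spherical
  k-means dependency); the Euclidean path is cross-checked against
  `stats::kmeans` in the tests.
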