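# leidar — recurrent FC states from leading-eigenvector dynamics

`leidar` implements leading-eigenvector dynamics analysis (LEiDA) of dynamic
functional connectivity for researchers who have parcellated BOLD time series
(one frames × parcels table per scan) and want to know whether recurrent
phase-coherence states differ between groups — in how often they occur, how
long they last, and how they transition into one another.

## The method

For each scan, parcel signals are band-pass filtered to 0.02–0.1 Hz
(second-order Butterworth, applied forward–backward so phases are undistorted)
and expressed via the Hilbert transform as *X*(*t*) = *A*(*t*)cos(θ(*t*)).
At every frame *t* the phase-coherence matrix

    dFC(n, p, t) = cos(θ_n(t) − θ_p(t))

is summarised by its leading eigenvector *V*₁(*t*) (largest-magnitude
eigenvalue; sign convention: majority of elements negative). The element signs
of *V*₁ split parcels into two phase communities, and *V*₁*V*₁ᵀ is the rank-1
dominant pattern of the frame. Eigenvectors from all frames of all scans are
pooled and partitioned by k-means independently for each k in a sweep
(default 2..20); the centroids are the FC states and each frame is assigned to
exactly one of them. Per scan and state the package computes occupancy
probability, mean lifetime (s), switching frequency (Hz), switching profiles
(conditional on a switch by default) and Shannon entropy, then compares
groups with permutation-based t tests (default 10,000 permutations), Hedges'
g, per-partition Bonferroni thresholds (0.05/k), paired within-group tests,
Freedman–Lane covariate adjustment and a group × condition interaction test.
Because no optimal k is assumed, the package reports whether the most
significant state is *consistent* across partition models (centroid Pearson
correlations across k).

A synthetic-cohort generator produces narrowband phase-coupled signals whose
pairwise phase relations follow a hidden Markov sequence over planted
community patterns, with configurable group differences in state occupancy
and exact per-frame ground truth — so the entire chain is testable by
parameter recovery. See `vignettes/leida-methods.Rmd` for the full model and
design rationale.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated two-group
cohort (16 vs 12 subjects × 2 conditions × 210 frames × 90 areas, TR 2 s)
with a planted occupancy deficit of ~0.03 in state 4 of group B:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort TSVs + ground truth
Rscript analysis/02_extract_states.R    # filter -> phases -> eigenvectors -> k sweep
Rscript analysis/03_state_dynamics.R    # occupancy / lifetime / switching / entropy
Rscript analysis/04_group_inference.R   # permutation tests across the sweep
```

Script 02 pools one eigenvector per acquired frame (`11760` from 56 scans)
and recovers the planted centroids at k = 4:

```
       planted_state matched_cluster pearson_r
state2             2               2     0.999
state3             3               3     0.999
state4             4               4     0.999
```

Script 04 flags exactly the planted deficit, consistently across partitions
(p-values are permutation p's; the corrected threshold is 0.05/k):

```
corrected-significant group differences (condition 1):
   k state_id metric_name mean_a mean_b p_value effect_size_g
31 4        4 probability 0.0762 0.0313  0.0035          1.02
75 5        5 probability 0.0753 0.0310  0.0030          1.03
99 6        6 probability 0.0750 0.0306  0.0060          1.03
```

Reading: group B occupies the deficit state ~3.1% of frames versus ~7.6% in
group A; the difference survives the per-partition Bonferroni correction at
k = 4, 5 and 6, and the cross-k centroid correlations of the flagged state
(`r_next = 1.000` in the consistency table) show it is the same underlying
state at every granularity. No other state or metric reaches corrected
significance, matching the null that was planted everywhere else.

Programmatic use mirrors the scripts:

```r
library(leidar)
scans    <- read_cohort("manifest.csv")          # or generate_cohort(spec)
filtered <- lapply(scans, bandpass_filter)       # 0.02-0.1 Hz, order 2
sample   <- pool_eigenvectors(filtered)          # one eigenvector per frame
models   <- sweep_k(sample, 2, 20, seed = 1)     # independent partitions
cmp      <- compare_all(sample, models, selected_k = 10, seed = 1)
```

`run_pipeline()` orchestrates all stages from a manifest and writes the
result tables plus a provenance record.

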