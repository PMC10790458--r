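---
title: "Methods: surprisal analysis and patient-specific signaling signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surprisal analysis and patient-specific signaling signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passs)
```

## The model

Tumors that would otherwise relax to a common signaling steady state are held
away from it by environmental and genomic constraints. Surprisal analysis
expresses the measured natural-log intensity of phosphosite $i$ in sample $k$
as a steady-state term plus deviations imposed by those constraints:

$$\ln X_i(k) \;=\; \sum_{\alpha=0}^{r} G_{i\alpha}\,\lambda_\alpha(k),$$

where the $\alpha = 0$ term is the steady state and each $\alpha \ge 1$ term
is an *unbalanced process*: a fixed pattern of site weights $G_{i\alpha}$
whose influence on sample $k$ is scaled by the amplitude
$\lambda_\alpha(k)$. Sites with large $|G_{i\alpha}|$ — the tails of the
weight vector — define the process; opposite-sign tail members always move in
opposite directions when the process acts. The set of processes with a
significant amplitude in a sample, together with their signs, is that
sample's signaling signature; encoded as $\{+1,-1,0\}$ across samples it
forms the cohort barcode.

`passs()` computes the factorization as a singular value decomposition of the
*uncentered* ln matrix (equivalent to diagonalizing the uncentered sample
covariance, but better conditioned than forming $Y Y^\top$). Not centering is
deliberate: the steady state must emerge as the dominant component, which is
what separates this decomposition from PCA. The singular value is absorbed
into the amplitude, $\lambda_\alpha(k) = \sigma_\alpha v_{k\alpha}$, so
weight columns stay orthonormal; any comparison with amplitudes produced
under a different normalization convention must allow a global rescaling per
component.

### Numerical conventions

* **Orientation.** Singular vectors are defined only up to sign. Each weight
  column is oriented so its largest-magnitude entry is positive; amplitudes
  flip with it. All downstream signs (barcodes, induced/repressed calls)
  inherit this deterministic rule, so they are reproducible across runs but
  only comparable within one decomposition.
* **Numerical rank.** Components with $\sigma_\alpha < 10^{-12}\sigma_0$ are
  truncated. Exactly tied singular values are returned in factorization
  order with a warning; they are practically absent from noisy data.
* **Degenerate inputs.** A constant matrix is pure steady state (zero
  processes); fewer than two samples or sites, or non-finite entries, are
  errors.

## From raw intensities to a complete ln matrix

The factorization needs a complete positive matrix. Missing cells are filled
by half-minimum imputation: a missing cell receives `floor_fraction` (default
0.5) times the smallest observed intensity of its site, the mildest standard
proxy for left-censored values; every imputed cell is recorded in the
object's provenance table. How missing phosphotyrosine quantifications were
handled in the cohorts this method is usually applied to is not published,
so the default is a documented stand-in — with typically sparse missingness
it perturbs only the lowest-intensity cells, and imputation never changes
the rank order of observed values within a sample. The natural logarithm is
used throughout and is not configurable.

## Deciding what is real: noise, thresholds, $n^\ast$

Three linked decisions turn the factorization into a signature, all driven
by a single measurement-noise scale $s$ (standard deviation in ln space,
i.e. approximately the coefficient of variation of intensities):

1. **Noise scale.** With technical replicates, $s$ is the root-mean-square
   deviation of ln intensities from their within-group means. Without
   replicates, the singular-value scree is cut at its elbow (largest ratio
   of consecutive singular values) and $s$ is $1.4826\times$ the median
   absolute deviation (about zero) of the remaining residual. The MAD is
   used because a misplaced elbow leaves sparse tail signal in the
   residual, which a robust scale estimator ignores. A relative floor of
   $10^{-12}\sigma_0$ keeps $s$ positive on noiseless input so thresholds
   sit above floating-point jitter.
2. **Amplitude threshold.** How large an amplitude can noise alone produce?
   `amplitude_threshold()` decomposes `n_null` (default 200) pure-noise
   matrices of the data's shape with i.i.d. Gaussian ln-space noise of scale
   $s$ and records each one's maximum $|\lambda|$. The threshold $T$ is the
   `level` quantile (default 0.95) of those maxima, applied identically to
   every process. Gating against the common noise envelope is
   distribution-free in the signal and sidesteps the ambiguity of matching
   null components to data components; it is simulated rather than
   closed-form, reproducible given the seed. The degenerate case $s = 0$
   yields $T = 0$ (every nonzero amplitude significant).
3. **Retained processes.** $n^\ast$ is the smallest $n$ whose reconstruction
   residual (root-mean-square over all cells, a whole-matrix criterion) is
   at or below $s$ — beyond that point the discarded components are
   indistinguishable from noise — intersected with the requirement that
   every retained process be significant in at least one sample. The
   intersection matters: on pure-noise cohorts the residual criterion alone
   can be unstable near $n = 0$, but a spurious first process still has to
   beat $T$, which by construction happens in roughly $1 - \mathrm{level}$
   of cohorts.

Significance is gated per sample and per process by default
(`per_sample = TRUE`); whether gating should instead be global per process
is a modeling choice we expose as a flag, since a process can be genuinely
inactive in some tumors while strong in others.

## Tails, subnetworks, direction

Tail membership uses mean $\pm\, c\cdot$SD on the weight column with default
$c = 2$; a quantile rule (top/bottom $q$, default 0.05) is available as an
alternative. The interaction network (a user-supplied STRING-style edge
list; there are no live database queries) is interpretive only: edges at or
above `min_confidence` (default 0.7, the usual high-confidence cut) are
induced over tail proteins to report connected components, degree and
isolated members, but the network never changes tail membership, and
proteins absent from it remain in the tails — missing annotation must not
silently drop signal. Multi-phosphosite rows (e.g. `MUC1|pY1209-pY1212`)
collapse onto one network node while remaining distinct tail members.

Per sample, a tail member is *induced* when $G_{i\alpha}\lambda_\alpha(k) >
0$ and *repressed* when negative; flipping the amplitude's sign swaps the
two lists exactly.

## Therapy prediction

For each active process of a sample, candidates are its induced, druggable
tail members; repressed members are excluded because inhibiting a protein
the process already suppresses cannot reduce the process's flux. The
central target is the candidate with the largest $|G_{i\alpha}|$ — weights
drive the reconstruction, so weight is the primary centrality notion — with
subnetwork degree as tie-break (descending) and protein symbol as the final
deterministic key; `centrality = "degree"` swaps the first two keys for
users who prefer topological centrality. One target per active process,
deduplicated across processes, gives the plan; classes are `none`,
`monotherapy` (exactly one drug) and `combination`. A process with no
druggable induced candidate is flagged *uncovered* rather than skipped, so
a plan either captures the sample's entire imbalance or says explicitly
where it cannot. The EGFR-monotherapy count in `cohort_summary()` requires
the plan's single deduplicated drug to target EGFR; tumors whose multiple
processes share EGFR therefore count as monotherapy, which we consider the
faithful reading of "one drug suffices".

The bundled `default_druggable_map()` (EGFR/erlotinib, IGF1R/AG-1024,
KIT/imatinib, SRC/dasatinib, MUC1/GO-203, MAP2K1-MAPK1-MAPK3/trametinib)
exists for examples and tests; real analyses should supply their own map.

## The synthetic cohort generator

`simulate_cohort()` is the ground truth every stage is tested against. It
emulates a phosphotyrosine tumor cohort as

$$\ln X = b\,\mathbf{1}^\top + W A + E,$$

with a per-site baseline $b$ drawn uniformly from `baseline_range` (default
ln units 6–10, intensities of roughly $4\times10^2$–$2\times10^4$), planted
weight columns $W$ with disjoint signed tails ($\pm$ entries, plus-side
central weighted 2.0, minus-side central 1.6, other members 1.0 before unit
normalization), a planted amplitude matrix $A$, and i.i.d. Gaussian ln-space
noise $E$ (multiplicative in intensity, the natural error convention for
this decomposition). Three constructions make recovery well-defined rather
than approximate:

* disjoint tails give exactly orthonormal planted weights, so there is no
  rotation ambiguity (an overlapping-tail configuration is possible, but
  recovery is then a subspace statement only);
* the baseline is projected orthogonal to $W$, so at zero noise the
  factorization's components are exactly $\{b, W\}$;
* preset amplitude designs have mutually orthogonal, mean-zero rows with
  distinct norms, so at zero noise recovered amplitudes equal planted ones
  (including exact zeros) up to orientation, and component order is
  deterministic. With rows that are not mean-zero, the uncentered
  factorization recovers the *centered* amplitudes next to the steady
  state — `truth$amplitudes_centered` records them.

The boosted plus-side central also pins the orientation rule to the planted
sign, so recovered barcodes are directly comparable to planted ones.

Two presets encode the study conditions:

* `paperlike_subset`: 3 tumors, 2 processes, amplitudes
  $2.2\cdot(1,-1,-1)$ and $1.6\cdot(0,1,-1)$ — one tumor active only in
  process 1 with sign opposite to the other two, process 2 separating the
  remaining pair; EGFR/KIT centrals for process 1, IGF1R/SRC for process 2;
  noise sd 0.02.
* `paperlike_cohort`: 28 tumors, 4 processes on 300 sites, activity built
  from Hadamard-type mean-zero block sign patterns (one 8-sample block
  carrying all four processes, five 4-sample blocks carrying one or two),
  scaled by amplitudes 3.0/2.6/2.2/1.8 ln units. Per-sample process counts
  span 1–4 and average exactly 2, EGFR is the plus-side central of two of
  the four processes, and noise sd 0.05 puts the smallest planted
  amplitude about an order of magnitude above the noise-induced amplitude
  spread $s\sqrt{p/K} \approx 0.16$.

The amplitudes correspond to $e^{1.8}$–$e^{3}$ ≈ 6–20-fold intensity shifts
on tail sites — strong but realistic signaling rewiring — and 2–5% CV noise
is typical of label-free phosphoproteome quantification. What the generator
does *not* emulate: structured (intensity-dependent) missingness beyond
uniform random masking, correlated noise across sites, batch effects, or
tails whose membership drifts across samples. Passing recovery tests on
these cohorts therefore demonstrates the statistical machinery is correct
and calibrated, not that real cohorts satisfy the model's sparsity and
orthogonality assumptions.

## Validation scales and what is checked

The test suite and `scripts/acceptance.R` validate, at desk scale:
exact-decomposition identities (relative Frobenius error $<10^{-8}$);
noiseless preset recovery of $n^\ast$ and the planted barcode exactly (up to
per-column orientation); 50-replicate noisy-cohort recovery of $n^\ast$, of
barcode cells and of planted central targets (each at $\ge 95\%$); type-I
control on process-free cohorts ($\le 10\%$ of runs with any significant
process at level 0.95); and the planted therapy fixtures (a single
EGFR-centered process yielding erlotinib monotherapy; EGFR- plus
IGF1R-centered processes yielding the erlotinib + AG-1024 combination).
Replicate counts (50) and cohort sizes (300 sites × 20–28 samples) were
chosen as the smallest scales at which 95% recovery claims are
distinguishable from chance with binomial slack.

## Known limitations

* The noise null assumes i.i.d. Gaussian ln-space noise; heteroscedastic or
  correlated noise will miscalibrate the threshold.
* Component orientation (hence barcode sign) is a within-decomposition
  convention; signs are not comparable across cohorts or after adding
  samples.
* Near-equal singular values make component identity unstable; the package
  warns but cannot disambiguate genuinely degenerate processes.
* The therapy logic is purely structural (induced + druggable + central);
  it knows nothing about dosing, synergy, resistance or pharmacokinetics,
  and re-running the pipeline on treated samples is the supported way to
  detect emergent processes, not a model of them.
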