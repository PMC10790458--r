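# passs

Patient-specific signaling signatures from phosphotyrosine proteomics.

Targeted monotherapies often fail in heterogeneous tumors because each tumor
is driven by its own *combination* of signaling processes. `passs` addresses
this for cohorts profiled by phosphosite quantification (sites × samples,
positive intensities): it identifies the distinct unbalanced signaling
processes active across the cohort, determines which of them act in each
individual sample and in which direction, and translates each sample's
active processes into a ranked set of druggable targets — one central target
per process, yielding a mono- or combination-therapy plan per sample.

## The model

Surprisal analysis decomposes the natural-log intensities into a steady
state plus constraint-driven deviations:

$$\ln X_i(k) = \sum_{\alpha=0}^{r} G_{i\alpha}\,\lambda_\alpha(k)$$

- $\alpha = 0$ — the steady state, the dominant component of the
  *uncentered* factorization (computed by SVD);
- $G_{i\alpha}$ — weight of phosphosite $i$ in unbalanced process
  $\alpha \ge 1$; the high-$|G|$ tails define the process;
- $\lambda_\alpha(k)$ — amplitude (importance and direction) of process
  $\alpha$ in sample $k$.

Amplitudes are gated against a simulated measurement-noise null: the
threshold is a quantile of the maximal amplitude that pure noise of the
estimated scale can produce in a matrix of the same shape. Processes that
survive in a sample, with their signs, form that sample's signature; across
the cohort they form a $\{+1,-1,0\}$ barcode. Per process and sample, tail
members split into induced ($G_{i\alpha}\lambda_\alpha(k) > 0$) and
repressed sites; the highest-weight induced member with a known inhibitor is
the process's central target.

## Worked example

A built-in synthetic preset emulates a three-tumor subset with two planted
processes (process 1 couples induced EGFR to repressed KIT; process 2
couples IGF1R to SRC):

```r
library(passs)

sim <- simulate_cohort(preset_cohort("paperlike_subset"))
fit <- passs(sim$quant, seed = 1)
fit
#> PaSSS fit: 60 sites x 3 samples
#>   noise sd (ln): 0.02382 (residual);  amplitude threshold: 0.2095 (level 0.95)
#>   retained unbalanced processes (n*): 2
#>   active processes per sample: mean 1.67, range 1-2

passs_barcode(fit)
#>         process1 process2
#> tumor_A        1        0
#> tumor_B       -1        1
#> tumor_C       -1       -1
```

Two processes are retained ($n^\ast = 2$). `tumor_A` has a one-process
signature with sign opposite to the other two tumors — the proteins process
1 induces in `tumor_A` are repressed in `tumor_B`/`tumor_C` and vice versa —
while process 2 separates `tumor_B` from `tumor_C`. The barcode rows are the
per-sample signatures (red/blue/white as +1/−1/0). Therapy prediction picks
the central induced, druggable target of each active process:

```r
predict_therapy(fit)
#> PaSSS therapy plans for 3 samples (mean 1.67 active processes)
#>   classes: 0 none, 1 monotherapy, 2 combination
#>   EGFR monotherapy: 1; EGFR within combination: 0
#>   tumor_A: monotherapy, erlotinib (EGFR)
#>   tumor_B: combination, imatinib (KIT) + AG-1024 (IGF1R)
#>   tumor_C: combination, imatinib (KIT) + dasatinib (SRC)
```

`tumor_A`'s single EGFR-centered process calls for erlotinib monotherapy;
the two-process tumors each need a two-drug combination covering both
processes (the sign flip of process 1 makes KIT, not EGFR, the induced
central target there).

Real data enter through `read_quant_table()` (TSV/CSV of protein, site,
samples), with an optional STRING-style edge list (`read_edge_list()`) for
subnetwork context and a druggable map (`read_druggable_map()`) replacing
the bundled default. `run_passs_pipeline()` runs everything end to end and
writes stable TSV/JSON artifacts; `exec/passs` wraps it for the shell.

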