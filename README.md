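# nacd — noise-assisted causal decomposition of bivariate time series

`nacd` infers the direction of cause and effect between two time series
from their *phase dependency*. It is built for short, oscillatory,
possibly nonstationary records — annual predator–prey counts, paired
physiological rhythms — where regression-based causality (Granger) or
attractor-based methods (convergent cross mapping) sit awkwardly.

## Method in brief

The pair `(x, y)` is augmented with auxiliary white-noise channels and
decomposed jointly by noise-assisted multivariate empirical mode
decomposition (NA-MEMD) into mode-aligned intrinsic mode functions
(IMFs). Each IMF pair *j* is summarized by its Hilbert average
frequencies and mean phase difference; pairs that share a frequency
scale with a small phase offset are the *intrinsic causal components*
(ICCs), and the main ICC is the pair with the smallest offset. The main
ICC is then removed from each raw channel in turn, each modified pair is
re-decomposed, and the disruption of the per-ICC phase coherences
(phase-locking values) is measured by a variance-weighted Euclidean
distance:

    ACS_xy = d( coherences(original pair), coherences(x − ICC, y) )
    ACS_yx = d( coherences(original pair), coherences(x, y − ICC) )
    RCS_xy = ACS_xy / (ACS_xy + ACS_yx),   RCS_yx = ACS_yx / (ACS_xy + ACS_yx)

`RCS_xy > 0.5` reads "x causes y"; when `ACS_xy + ACS_yx` falls below a
negligibility threshold (0.05) the pair is reported as 0.5/0.5 —
reciprocal or unrelated. The rationale: an autonomous cause carries the
shared rhythm as one coherent component, so deleting it destroys the
pair's phase relation, while the entrained effect keeps cause-derived
phase in neighbouring scales and its deletion is the milder perturbation.

## Worked example

Drive one stochastic phase oscillator with another (X → Y, coupling
0.8), then ask the pipeline which channel is the cause:

```r
library(nacd)

sig <- gen_coupled_oscillators(500, coupling = 0.8,
                               direction = "x_to_y", seed = 4)
cfg <- noise_config(level_noise = 0.001, noise_channel_num = 3,
                    en_num = 5, seed = 4)
res <- run_causal_decomposition(sig, cfg)
res
#> causal strengths (channel 1 = X, channel 2 = Y)
#>   RCS  X->Y: 0.6088   Y->X: 0.3912
#>   ACS  X->Y: 0.2413   Y->X: 0.1551
res$diagnostics$selection
#> ICC selection (automatic): indices {1, 2, 3, 4}, main ICC = 4
res$diagnostics$phase_summary
#> per-IMF phase summary (frequencies in cycles/time unit, phase difference in radians)
#>  imf_index av_fre1 av_fre2 difference
#>          1 0.28862 0.29313    -5.0063
#>          2 0.19868 0.19905    -6.9432
#>          3 0.04498 0.05382   -17.7177
#>          4 0.04947 0.04943     0.0133
#>          5 0.02319 0.02094     3.5745
#>          6 0.01537 0.01255     3.4609
#>          7 0.00789 0.00642     3.7385
```

Row 4 of the phase summary is the shared 0.05 cycles/sample rhythm: both
channels put an IMF there, the frequencies agree to well under a percent
and the phase offset is 0.013 rad — it is selected as the main ICC.
Removing it from X disrupts the pair's phase coherence more
(ACS 0.24) than removing it from Y (ACS 0.16), so the known driver X is
read as the cause with relative strength 0.61. A white-noise pair under
the same configuration lands near 0.5/0.5.

The same run from the shell:

```sh
Rscript inst/cli/nacd simulate coupled-oscillators --n 500 --coupling 0.8 --seed 4 --out pair.csv
Rscript inst/cli/nacd infer --input pair.csv --level-noise 0.001 --noise-channels 3 \
        --en-num 5 --seed 4 --out results_dir
```

which writes `causal_matrix.tsv`, `peakmatrix.tsv`, `selection.json` and
`run_log.txt`. `simulate lotka-volterra --years 61` produces a noisy
predator–prey series emulating the 61-year Isle Royale wolf–moose
record, so the full workflow runs without any download.

See `vignettes/nacd-methods.Rmd` for the model, its assumptions, every
tunable parameter, and the package's design decisions.

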