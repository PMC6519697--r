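# mrbranch

Branching networks and subsampling-invariant estimation of neural spike
propagation.

## The problem

Extracellular recordings sample a few dozen neurons out of the tens of
thousands in a cortical circuit.  This *spatial subsampling* wrecks the
classical way of measuring how strongly activity propagates: the lag-1
regression slope of binned population counts, which equals the branching
ratio `m` under full sampling, collapses toward 0 when only `n << N`
units are observed — so a strongly recurrent network looks
asynchronous-irregular (Poisson-like).  `mrbranch` is for
electrophysiologists and computational neuroscientists who want to place
a spiking recording on the continuum between the asynchronous-irregular
state (`m = 0`) and criticality (`m = 1`), from nothing more than spike
times of a handful of units.

## The model and the estimator

Activity is modeled as a branching process with immigration,

    A[t+1] = sum_{i=1..A[t]} Y[t,i] + h[t],

with mean offspring `m` per spike and Poisson external input of mean `h`
per bin, optionally mapped onto a random network of `N` neurons with
annealed disorder (out-degree `kappa`, per-connection probability
`m/kappa`, `n` fixed sampled units).  For `m < 1` the stationary mean is
`<A> = h/(1-m)` and the population autocorrelation decays exponentially
with the intrinsic network timescale `tau = -dt/ln(m)`.

The multistep-regression (MR) estimator computes, for each lag `k`, the
OLS slope `r_k` of `a[t+k]` on `a[t]` from the subsampled counts, and
fits

    r_k = b * m^k.

Subsampling scales the amplitude `b` but not the geometric decay, so `m`
(and `tau`) are recovered *invariantly* under subsampling — down to a
handful of units — while the conventional lag-1 estimator is biased by
exactly the factor `b`.

From `m` alone follow testable predictions: susceptibility
`chi = 1/(1-m)`, external-input fraction `1-m`, mean size `1/(1-m)` of
the spike cascade triggered by one extra spike, and `tau`.

## Worked example

Generate a synthetic "recording" (295 s, 50 sampled units at ~7.25 Hz
from a reverberating network of 10,000 neurons at `m = 0.98`), then run
the full pipeline: bin, estimate, build matched asynchronous-irregular /
reverberating / near-critical surrogates, validate, predict.

```r
library(mrbranch)
fx <- make_fixture("reverberating", seed = 4)
report <- full_report(fx$raster, k_max = 150, B = 0, run_length = 1e5,
                      seed = 1)
report
#> Full report (status: ok)
#> Multistep-regression estimate
#>   m_hat = 0.9804, tau_hat = 202.1 ms, b_hat = 0.088 (k_max = 150, dt = 4 ms)
#> Dynamical state at m = 0.980407 (dt = 4 ms)
#>   intrinsic timescale tau  : 202.1 ms
#>   susceptibility chi       : 51.039
#>   external-input fraction  : 1.96%
#>   mean perturbation size   : 51.039 spikes
#>   closest model per panel: reverberating, reverberating, reverberating,
#>   reverberating, reverberating
```

Reading the numbers: the true branching ratio 0.98 is recovered as
0.9804 from just 50 of 10,000 neurons (the conventional lag-1 estimator
returns ~0.085 on the same counts); the implied timescale is ~200 ms
(`-4/ln(0.98) = 198` ms); the network amplifies a continuous input
~51-fold; only ~2% of its spikes are externally generated; and every
validation panel (ISI CV, activity distributions, avalanche likelihood,
spike-count correlations) picks the reverberating surrogate over the AI
and near-critical alternatives:

```r
report$validation$likelihood
#>           model     loglik loglik_per_avalanche
#> 2 reverberating  -39920.44            -2.972040
#> 1            AI  -39981.14            -2.976559
#> 3 near_critical -125445.18            -9.339278
```

## Command line

```sh
Rscript inst/cli/mrbranch.R simulate --m 0.98 --rate 7.25 --N 10000 \
    --n 50 --steps 100000 --seed 1 --out-counts counts.txt
Rscript inst/cli/mrbranch.R estimate --counts counts.txt --dt 4 \
    --kmax 150 --json-out report.json
Rscript inst/cli/mrbranch.R summary --m 0.98 --dt 4
Rscript inst/cli/mrbranch.R perturb --m 0.98 --trials 500 --seed 1 \
    --out perturbations.tsv
Rscript inst/cli/mrbranch.R fixtures --kind reverberating --seed 1 --out fx/
Rscript inst/cli/mrbranch.R validate --raster fx/reverberating_seed1.tsv \
    --out report.json
```

Rasters are two-column tab-delimited text (`unit_id`, `spike_time` in
seconds, `#` comments); counts are one- or two-column integer text.

## More

See the methods vignette (`vignettes/reverberating-dynamics.Rmd`) for
the model assumptions, the numerical choices inside the fit, the
finite-size effective branching ratio of the network mapping, what the
synthetic-data generator does and does not emulate, and known
limitations.
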