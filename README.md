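# oscspike

Spike-train statistics of neurons driven by stochastic oscillations.

Many sensory neurons fire tonically while being forced by an input that
oscillates with limited coherence — for example the paddlefish
electroreceptor, where a ~25 Hz epithelial oscillator drives an afferent
firing at roughly twice that rate. `oscspike` implements the canonical
model of this situation — a perfect integrate-and-fire (PIF) neuron driven
by a constant base current, Gaussian **harmonic (narrow-band) noise** and a
broadband **Ornstein–Uhlenbeck (OU)** process — together with its
closed-form weak-noise interspike-interval (ISI) statistics and the inverse
procedure that extracts the hidden oscillator parameters from a measured
spike train.

In canonical units (time in mean ISIs, voltage in threshold units):

```
v' = 1 + y(t) + eta(t),   spike & reset when v crosses 1 (noise not reset)
y:   harmonic noise — peak frequency w (relative to the firing rate),
     quality factor Q = omega1/gamma, stationary SD sigma_h
eta: OU noise — SD sigma_ou, correlation time tau_ou
```

The package provides, for this model:

* an exact-propagation stochastic simulator (`simulate_pif()`; the linear
  noise subsystem is advanced with its exact Gaussian one-step law, so its
  statistics carry no step-size bias);
* the leading-order closed forms: ISI density (`isi_density()`),
  squared CV `CV^2 = 2 D_ou + 2 sigma_h^2 (gamma + 1 -
  exp(-gamma/2) cos omega1) / omega1^2` (`cv_theory()`), skewness
  (`skewness_theory()`), n-th-order interval variance
  (`nth_order_variance()`), serial correlation coefficients — a damped
  cosine in the lag with decay `exp(-pi*w/Q)` per lag (`scc_theory()`) —
  and the correlation lag `tau_c = sum_k |rho_k|`
  (`correlation_lag_theory()`);
* non-parametric spike-train estimators: ISI summaries, serial
  correlations with segment error bars, Welch power spectra of the spike
  train, a ±2% stationarity filter (`summary_stats()`, `scc_errorbars()`,
  `psd_estimate()`, `stationarity_filter()`);
* the inverse pipeline `extract_parameters()`: PSD peak ratio for the
  initial frequency ratio, bounded multi-start least squares of the SCC
  closed form (free parameters `Q`, `w`, `sigma_h`; CV prefactor fixed at
  the measured CV), a spike-time-jitter dephasing correction for `Q`, and
  algebraic inversion of the CV formula for the OU intensity `D_ou`;
* seeded surrogate data emulating an electroreceptor sample
  (`table1_params()`, `sample_population()`, `surrogate_dataset()`).

## Worked example: recover oscillator parameters from a spike train

Simulate 40 000 intervals at the fitted parameters of a reference afferent
(`w = 0.408`, `Q = 16.40`, `sigma_h = 0.197`, `D_ou = 5.1e-3`, 53 Hz) and
run the extraction pipeline:

```r
library(oscspike)

p   <- table1_params(1)$params
st  <- simulate_pif(p, n_spikes = 40000, seed = 1)
fit <- extract_parameters(st)
tidy(fit)
#> # A tibble: 5 × 3
#>   term     estimate std.error
#>   <chr>       <dbl>     <dbl>
#> 1 Q        16.4      0.261
#> 2 w         0.408    0.000259
#> 3 sigma_h   0.193    0.00173
#> 4 d_ou      0.00517 NA
#> 5 sigma_ou  0.227   NA
glance(fit)
#> # A tibble: 1 × 8
#>      cv rate_hz w_init residual_norm converged unidentifiable feasible n_isis
#> 1 0.175    53.0  0.409        0.0982 TRUE      FALSE          TRUE      39965
```

All four generating parameters are recovered: the quality factor of the
hidden oscillator (16.4), its frequency relative to the firing rate
(0.408), the oscillation amplitude (0.193 vs 0.197) and the broadband
noise intensity (5.17e-3 vs 5.10e-3). `autoplot(fit)` overlays the fitted
damped-cosine serial-correlation structure on the measured coefficients
and their segment error bars.

The closed forms alone are one-liners:

```r
cv_theory(p, mode = "simplified")   # 0.1817  (measured CV of that afferent: 0.181)
correlation_lag_theory(p)           # temporal extent of ISI correlations
scc_theory(1:20, p)                 # damped-cosine serial correlations
```

A thin command-line front end over the same functions is installed with
the package (`inst/scripts/oscspike`): subcommands `simulate`, `theory`,
`stats`, `fit`, `fixtures`.

## Documentation

The methods vignette (`vignettes/oscspike-methods.Rmd`) describes the
model and its assumptions, every closed form and its validity window, the
dephasing correction used by the inverse pipeline, the surrogate-data
design, and the package's numerical choices.
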