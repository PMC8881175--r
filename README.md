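# erptrial

Single-trial detection and estimation of event-related potential (ERP)
amplitude and latency by inverting an EEG classifier.

## The problem

ERP components such as the N170 or the P50 are µV-scale, stimulus-locked
deflections hidden in ongoing EEG at strongly negative SNR. Averaging
across trials recovers the component but erases its trial-to-trial
variation — which is often the scientific signal of interest (e.g.
sensory-gating suppression of the second click in a paired-click
paradigm). `erptrial` estimates the amplitude σ (µV) and latency τ (ms)
of a component in *each individual trial*.

## The method

An epoch is modelled as a monophasic Gaussian template on spontaneous
EEG, identical across the electrodes of a small region Ω:

    E(t) = σ · f(t − τ) · 1 + X(t),    f(u) = exp(−u² / 2θ²)

A binary classifier Z (logistic regression, skip-layer MLP, or
Gaussian-kernel SVM) is trained to separate spontaneous channel-vectors
(positive class) from ERP-bearing ones, and exposes a scalar distance
Δ(x, Z) — positive for spontaneous-looking vectors, zero on the decision
boundary. The two descriptors are then recovered in two steps:

1. **Latency** — exhaustive search over the discrete candidate grid:
   `τ̂ = argmin_τ Σ_{t ∈ T⁻(τ)} Δ(E(t), Z)`, where T⁻ is the
   near-latency window (±θ samples); the epoch looks least spontaneous
   around the component.
2. **Amplitude** — bounded scalar minimization of
   `Σ_{t ∈ T⁻} [Δ(E(t) − σ f(t − τ̂) 1, Z) − D]²`, where D is the mean
   distance of the trial's own far-from-latency samples: σ̂ is the
   smallest amount of template whose removal makes the near window look
   exactly as spontaneous as the rest of the trial.

Reference implementations of the **Woody adaptive filter** (iterative
cross-correlation alignment) and the **SingleTrialEM** objective (joint
data-fidelity + distance criterion, known to underrate amplitudes) run
on the same study objects for comparison. A synthetic spontaneous-EEG
generator (1/f colored noise, cross-channel correlation, bursty
trial-to-trial amplitude heterogeneity) defines reproducible simulated
studies; a paired-click P50 study with a paired t-test completes the
sensory-gating analysis. See the vignette
(`vignettes/single-trial-erp.Rmd`) for models, parameters and design
rationale.

## Worked example

Simulate a two-condition N170 study (40 trials at 6 and 15 µV, 4
channels, 256 Hz), train an MLP per condition, and estimate every trial:

```r
library(erptrial)
cfg <- default_run_config(seed = 1, n_trials = 40, amplitudes = c(6, 15))
res <- run_pipeline(cfg)
res$accuracy
#>   condition classifier accuracy
#> 1         6      mlpnn 77.77778
#> 2        15      mlpnn 88.88889
res$summary[, c("condition","n","sigma_mean","sigma_sd","tau_mean","tau_sd","snr_db")]
#>   condition  n sigma_mean sigma_sd tau_mean tau_sd snr_db
#> 1         6 40       6.49     4.56      168  11.36 -12.03
#> 2        15 40      15.23     3.99      169   8.54  -4.07
```

Test accuracy climbs with amplitude (78% at 6 µV, 89% at 15 µV — the
noise level is calibrated so the 15 µV condition sits near 90%), and
the per-trial estimates average close to the injected truth: mean
amplitudes 6.5 and 15.2 µV against true 6 and 15, mean latencies 168
and 169 ms against a true 170 ms, with spread shrinking as SNR rises
(the `snr_db` column is 20·log₁₀ of template RMS over noise RMS). A
single trial:

```r
ep <- res$study$conditions[["15"]]$epochs[[1]]
econf <- estimation_config(res$study$region, theta = res$study$theta)
estimate_trial(ep, res$models[["15"]], econf)
#> <erp_estimate> method = proposed: sigma_hat = 9.66 uV, tau_hat = 175.8 ms (D = 1.659)
```

— this particular trial drew a quiet-looking background, so its
component is estimated smaller and 6 ms later than the injected values;
that per-trial spread is exactly what the study-level summaries
quantify.

A command-line front end over the same functions is installed at
`inst/scripts/erptrial.R` (subcommands `simulate`, `preprocess`,
`train`, `estimate`, `evaluate`, `gating`).

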