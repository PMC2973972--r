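---
title: "Simulating and analysing the stop-signal anticipation task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the stop-signal anticipation task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsig)
```

## The task and what the package computes

The stop-signal anticipation task probes two forms of response inhibition.
A bar rises at constant speed and must be stopped by a button press as it
crosses a target line 800 ms after trial onset; on a minority of trials the
bar halts on its own before the line (a stop signal) and the prepared
response must be withheld. The colour of the target line cues the
probability that a stop signal will occur (0, 17, 20, 25 or 33 percent),
so the paradigm measures *reactive* inhibition (cancelling on Stop trials)
and *proactive* inhibition (anticipatory slowing as the cued probability
grows) in one design.

`stopsig` implements the full computational chain around this paradigm:

1. **Task design** — pseudorandomised trial sequences under the published
   trial economy (234 baseline Go, 180 experimental Go, 60 Stop trials in
   blocks of 12–15, 1 s intertrial interval, two 24 s rests).
2. **Adaptive staircase** — per-level 1-up-1-down tracking of the
   stop-signal onset time (SSD) in 25 ms steps from 550 ms.
3. **Race-model simulation** — per-trial outcomes from an independent
   horse race between a Go and a Stop process, with proactive slowing.
4. **Behavioural analysis** — outlier filtering, per-level RT/accuracy,
   SSRT by the integration method, ZRFT-normalised inhibition functions
   with a cumulative Weibull fit, linear contrasts and paired tests.
5. **BOLD forward model** — region-by-scan series with planted condition
   amplitudes, parametric modulation, AR(1) noise and condition-dependent
   seed-to-sink coupling.
6. **Event-related GLM** — response-locked regressors, mean-centred
   parametric modulators, 128 s discrete-cosine high-pass, AR(1)
   prewhitening, contrasts, second-level tests and a repeated-measures
   ANOVA with Greenhouse–Geisser correction.
7. **PPI** — seed eigenvariate, hemodynamic deconvolution, a ±1
   psychological vector, the neural-level product regressor, and
   sink-region regression.

Because no empirical recordings ship with the package, every analysis is
validated against the simulator by *parameter recovery*: the forward model
plants known effects and the analysis must find them.

## Trial timing and the design identities

The published description fixes the bar's time to the target line
(800 ms), the position of that line at 4/5 of the bar's travel, and the
1 s intertrial interval, but not the full bar-travel time. We let the bar
complete its travel at constant speed, giving 1000 ms of bar motion and a
2 s trial pitch; with 474 trials and two 24 s rests this reproduces the
printed total duration of 996 s exactly, which is why we treat it as the
intended geometry. Rest blocks are inserted after the block boundaries
closest to one and two thirds of the trial count.

Block sizes are drawn uniformly from 12–15 under the count constraints,
alternating baseline and experimental blocks. Within an experimental
block the trial order is re-drawn until the block opens with a Go trial
and contains no run of more than two Stop trials; the published ordering
procedure (simulation-based) is not public, so these constraints are our
own and are stated here rather than hidden. After generation, a candidate
sequence is kept only if the centred stop-signal-probability modulator
correlates below 0.4 with each convolved condition regressor; redraws are
deterministic functions of the seed, so a given `(config, seed)` always
yields the same sequence.

## The behavioural generative model

Go finishing times are ex-Gaussian,
\[
T_{go} = \mu_{go} + \beta \, p_{stop} + \mathcal N(0, \sigma_{go}^2) +
\mathrm{Exp}(\tau_{go}),
\]
the standard choice for response-time distributions; the linear term in
the cued probability implements proactive slowing. The Stop process
launches at the current SSD with latency
$T_{ssrt} \sim \mathcal N(\mu_{ssrt}, \sigma_{ssrt}^2)$ and wins ties:
stopping succeeds iff $SSD + T_{ssrt} \le T_{go}$. A trigger-failure
probability exists (default 0) so estimator bias under failed triggering
can be studied. Go omissions are not simulated. We use the independent
(non-interacting) race: the analyses implemented here use only
race-consistent outcome logic, and interaction between the processes is
not identifiable from these behavioural measures.

Cohort defaults ($\mu_{go} = 780$ ms, $\sigma_{go} = 40$ ms,
$\tau_{go} = 30$ ms, $\beta = 90$ ms per unit probability,
$\mu_{ssrt} = 260$ ms, $\sigma_{ssrt} = 30$ ms, between-subject SDs of
20/5/5/20/20/5 ms) were chosen once so that simulated sessions resemble
the task's human benchmarks qualitatively — baseline responses near the
800 ms target, tens of milliseconds of proactive slowing, SSRT in the
250–300 ms range, and staircase-balanced stopping near 50 percent — and
are not tuned to any test outcome. The staircase bounds [50, 775] ms are
ours (the source states none); an SSD at or beyond the target response
time would be meaningless.

```{r behaviour}
cfg <- task_config()
scheduled_duration(cfg)
sq <- build_trial_sequence(cfg, seed = 7)
ses <- simulate_session(sq, subject_params(), seed = 8)
rt_summary(ses)
```

## SSRT and the inhibition function

The integration method pools all levels with $p_{stop} > 0$: with
response rate $p$ on Stop trials and $n$ retained Go response times, the
SSRT is the $\lceil p\,n\rceil$-th fastest Go RT minus the mean SSD.
Outlying Go RTs (beyond 1.5 IQR from the quartiles, per level, with
linear-interpolation quantiles) are excluded before taking the quantile —
the same trials the GLM relegates to a no-interest regressor. At small
$n$ the discrete rank convention matters; we use the ceiling rank, and
the packaged worked example (ten Go RTs 700–880 ms, four Stop trials at
SSDs 500–575 with two responses) evaluates to exactly 242.5 ms.

Inhibition functions bin Stop trials by SSD and plot the stop-success
proportion against the Z-transformed relative finishing time
$\mathrm{ZRFT} = (\overline{RT}_{go} - SSD - SSRT)/SD(RT_{go})$, so
that sessions with different speeds pool onto one axis. The cumulative
Weibull $W(z) = \gamma - (\gamma - \delta)e^{-((z - z_0)/\alpha)^\beta}$
is fitted by bounded least squares ($\gamma \in [0.5, 1]$,
$\delta \in [0, 0.5]$, $\alpha, \beta > 0$, started at
$\gamma = 1, \delta = 0, \alpha = 1, \beta = 2$). The fit targets the
*group-mean* inhibition function — pooled session points aggregated into
ZRFT bins weighted by trial count — because per-session bins carry
binomial noise (roughly $\pm 0.16$ at ten Stop trials per bin) that no
smooth curve should be asked to explain. Because the Weibull is
defined on a positive support while ZRFT is signed, the fit shifts the
axis by the smallest observed ZRFT ($z_0$); the curve is monotone
increasing in ZRFT by construction, matching the convention that larger
ZRFT (earlier stop signals) means easier stopping.

## The BOLD forward model and GLM

Neural events are response-locked impulses: at trial onset plus the
recorded response time, or plus the 800 ms target for StopSuccess trials.
Each synthetic region scales these impulses by its planted amplitudes
(StopSuccess, StopFailure, experimental Go) and by centred per-trial
modulators (response time in seconds, stop-signal probability as a
fraction), adds coupling terms described below, convolves with the
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, unit
peak) at microtime resolution TR/16, samples at scan onsets, and overlays
AR(1) Gaussian noise. The default geometry is 616 usable scans at
TR = 1.6 s. The scheduled task (996 s) slightly outruns that scan window,
as in the source acquisition; forward model and design matrix truncate
identically, so recovery is unaffected.

The GLM mirrors the forward model's event placement: condition regressors
for StopSuccess, StopFailure and experimental Go; the two mean-centred
modulators on the Go events (not orthogonalised — their realised
correlation is reported and stays below 0.4 on screened sequences); rest
boxcars and outlier impulses as no-interest regressors; a discrete-cosine
basis with periods above 128 s; and an intercept. Baseline Go trials are
the implicit baseline. Serial correlation is handled by a two-pass
Cochrane–Orcutt scheme: OLS residuals give a pooled lag-1 coefficient,
data and design are quasi-differenced, and the model is refit. This
replaces restricted-maximum-likelihood variance components; for a single
AR(1) component the two agree in expectation and the two-pass scheme is
far simpler. On noiseless forward data the fit returns the planted betas
to machine precision because the design and the generator share one event
representation by construction — that is the package's core validation
identity, not a coincidence.

The probability × RT-bin analysis classifies experimental Go trials by
level and a within-level median split (our reading; the source does not
state the split's scope), and the repeated-measures ANOVA applies the
Greenhouse–Geisser epsilon to the probability factor and the interaction.
The implementation was verified to five decimals against an established
independent implementation on a frozen dataset.

## PPI: deconvolution and the interaction regressor

The seed's neural series is recovered by generalized-ridge deconvolution:
minimise $\lVert Hx - y\rVert^2 + \lambda \lVert Dx \rVert^2$ with $H$
the HRF convolution operator at microtime TR/16 and $D$ a first
difference. This is a deliberately transparent stand-in for parametric
empirical Bayes deconvolution, whose shrinkage it approximates with an
explicit smoothness penalty; $\lambda$ may be fixed (pipeline default
100) or chosen by generalized cross-validation with a Hutchinson trace
estimator. The seed series is mean-centred before deconvolution.

The psychological vector codes StopSuccess as +1 and StopFailure as −1
impulses. We place these at the *response-locked* event times — the same
times the event model uses — rather than at bar-motion onset: the
interaction term samples the neural estimate exactly at the microtime
bins where stop-related neural activity lives, and with onset-locked
codes the product would read the neural series 0.8 s before the seed's
event, where it carries almost no event information. With ±1 coding and
staircase-balanced outcomes the vector is nearly mean-zero; a centering
switch exists for unbalanced designs. All three vectors (neural,
psychological, product) are convolved with the HRF and resampled to scan
resolution, and the sink regression is AR(1)-prewhitened like every other
first-level model. Group inference reuses the second-level one-sample t.

Three further choices matter for a *calibrated* PPI and came out of
explicit estimator diagnostics rather than convention:

* **Seed eigenvariate.** The seed series entering deconvolution is the
  first eigenvariate of the seed's voxel set (the forward model tiles
  seed regions into 32 voxels sharing the clean signal with independent
  noise). A single voxel-noisy series makes the product regressor
  noise-dominated and attenuates the interaction coefficient towards
  zero; the eigenvariate's SVD denoising is precisely why sphere
  eigenvariates, not single series, are the field's standard seed
  summary.
* **Trial-to-trial neural variability.** Seed regions carry a per-trial
  amplitude fluctuation (`amp_sd`, default 0.3 in the cohort regions).
  With perfectly constant per-condition amplitudes, a coupling change is
  design-spanned — indistinguishable from a change in the sink's own
  condition amplitudes — so a PPI "over and above the main effects" is
  only identifiable through transmitted trial-to-trial variability. This
  is a substantive assumption about what PPIs measure, stated here
  explicitly.
* **Task model as nuisance.** The sink regression includes the session's
  task regressors (experimental Go, outliers, rest, modulators, drift
  basis, and the *sum* of the two Stop regressors — the psychological
  vector already spans their difference). Leaving the sink's own event
  responses unmodelled leaks them into the interaction term and breaks
  null calibration; including them restores a zero-centred null.

In the forward model, coupling enters at the neural level as
$(g + c(t)\,\Delta g)\cdot$ seed-neural, with context $c(t) = \pm 1$
during Stop trials by outcome. A positive $\Delta g$ (SMC-like sink)
yields a positive PPI, a negative $\Delta g$ (M1-like sink) a negative
PPI — the directional surface the analysis must recover. PPI recovery is
intrinsically asymmetric between seed and sink: the regressor is built
from the seed's (noisy, deconvolved) series, so reversing the roles at
matched noise recovers the planted effect with lower power, which the
test suite demonstrates as a property rather than assuming.

## Problem sizes, determinism and limitations

Simulation-based checks in the test suite and the acceptance script use
cohorts of 24 subjects (the study's sample size) and replicate counts
chosen as the smallest that make the Monte-Carlo error comfortably
smaller than the tolerance being checked (tens of cohorts for sign
recovery, hundreds of replicates for calibration rates); each draws its
seeds from a counter-based split of one master seed, so every number in
the outputs is reproducible from `(config, seed)`.

The generator emulates the study conditions, not the full richness of
real data: no learning or post-stop slowing beyond the staircase, no Go
omissions, Gaussian AR(1) noise without physiological or motion
structure, region-level rather than voxel-level signals (a tiling helper
adds voxel noise only for eigenvariate tests), and an HRF that is exactly
the analysis HRF. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated model, not robustness to
HRF mismatch, motion artefacts or spatial heterogeneity — those belong to
the out-of-scope preprocessing world.
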