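---
title: "Stochastic virtual patient populations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic virtual patient populations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucopop)
```

## The problem

People with type 1 diabetes on multiple daily injection (MDI) therapy
produce rich free-living data: a continuous glucose monitor (CGM) sampling
subcutaneous glucose every ~5 minutes, self-reported meals (with
macronutrient estimates), fast- and long-acting insulin injections,
self-reported physical activity, and wrist-worn heart-rate readings. Each
of these inputs is uncertain — carbohydrate counts are guesses, event
times are approximate, physiology varies within a day and between days.
`glucopop` turns such data into a *stochastic virtual population*: a
fitted hierarchical Bayesian model whose posterior can be replayed to
simulate realistic alternative days for each patient, with honest
intraday and interday variability.

## The deterministic core

For one 24-hour window the model simulates blood glucose $G$ (mg/dL) and
its subcutaneous, CGM-visible counterpart $SG$:

$$\dot G = -(\mathrm{GEZI} + (1 + h)\,X)\,G + \mathrm{EGP} - S_E E + R_A - F_R,
\qquad \dot{SG} = (G - SG)/\tau_G,$$

with renal excretion $F_R = 0.003\,(G - 162)$ mg/dL/min above 162 mg/dL
and zero below, and $h = H$ when $G < G_{th}$ (amplified insulin action in
hypoglycemia) and $h = 0$ otherwise.

All inputs act through cascades of first-order stages that are
individually normalized to unit DC gain, so gains appear only at the
injection points and the time constants stay interpretable:

* **Insulin.** Each bolus enters as an impulse of mass $I_A \cdot
  \mathrm{dose}$ at its (offset-corrected) time and passes through its own
  first stage $\tau_{I1}$ and shared stages $\tau_{I2}, \tau_{I3}$ to the
  plasma signal $I_p$; long-acting basal enters the same chain as a
  constant rate $\mathrm{dose}/1440$ U/min for the whole window. The final
  stage $\tau_{I4}$ is driven by $SI(t)\,I_p(t)$, producing the insulin
  effect $X$ (1/min).
* **Meals.** An impulse of mass $0.8 \cdot M_A \cdot \mathrm{carbs} \cdot
  1000 / V_G$ (mg/dL) through $\tau_{D1}, \tau_{D2}, \tau_{D2}$ gives the
  rate of appearance $R_A$; carbohydrate bioavailability is fixed at 0.8
  and the meal coefficient $M_A$ absorbs reporting error.
* **Physical activity.** Each activity perturbs insulin sensitivity by a
  superposition of a non-negative long-lived exponential ($P_{long}$,
  $\tau_{P,long}$) and a signed short-lived one.
* **Heart rate.** The clipped excess over the resting rate drives two
  stages with constant $\tau_E$; the resulting metabolic signal $E$ drains
  glucose at rate $S_E E$.
* **Intraday variation.** $SI(t) = SI_E (1 + P_A(t)) (1 + SI_A
  \sin 2\pi(t + SI_\phi))$, with $t$ in days from local midnight of the
  window's calendar day, so the phase is comparable across windows.

### A note on the hypoglycemia term

Written as $-(\mathrm{GEZI} + h X) G$ the equation would switch insulin
action *off* whenever $G \ge G_{th}$. We implement $-(\mathrm{GEZI} +
(1+h)X)G$: insulin always acts with factor $X$, and $H$ *amplifies* it
below the threshold. This reading keeps $X$ the effect of insulin
everywhere, makes $H$ the "increased sensitivity in hypoglycemia"
coefficient, and reduces exactly to the plain model as $H \to 0$.

### Numerics

The chains are linear, so the package evaluates them through closed-form
impulse responses in a polynomial-times-exponential basis that is closed
under first-order filtering; repeated time constants ($\tau_{I2} =
\tau_{I3}$, the doubled $\tau_{D2}$) are handled in confluent form
(degree-raising) rather than by nearly-cancelling partial fractions, and
rates closer than $10^{-8}$ min$^{-1}$ are snapped together. Only the
nonlinear $(G, SG, X)$ triple is integrated numerically: fixed-step RK4 at
the output resolution (1 min by default), with sub-steps at event onsets
in the exact path. A `full_ode` backend integrates every compartment by
brute force and must agree with the analytic path (the test suite demands
max $|\Delta SG| < 0.5$ mg/dL over a loaded day); conservation tests pin
the chain DC gains to 0.1%.

Failure semantics: if $G$ leaves the integrable range the simulator
reports the offending time. The likelihood treats such parameter draws as
having density zero.

## The hierarchy and priors

Latents live on four levels — cohort, patient, 24h window ("sample"), and
event — following the level map of `vp_priors()`: glucose distribution
volume, kinetics time constants, `GEZI`, `H`, `Gth`, `SE` at
cohort/patient level; `SIE`, `SIA`, `SIphi`, initial insulin state and
CGM noise down to window level; meal/bolus/activity modifiers at event
level. Endogenous glucose production is window-level with the linear
linkage $\mathrm{EGP}_s \sim \mathrm{TN}(\mathrm{EGPi}_p +
\mathrm{EGPm}_p\,SI_{E,s},\ \sigma_{EGP,p})$, so a patient's per-day EGP
and insulin sensitivity are correlated with the sign of the slope — a
pattern needed so that replayed days do not inflate glucose variance
spuriously.

Spread parameters listed with exponential or half-normal priors are
applied to *standard deviations* (not variances); for three-level latents
they sit at the patient level (that patient's day-to-day spread), for
patient-level latents at the cohort level. We parameterize the hierarchy
*centered* — each node's prior location references its parent node —
because every window carries ~288 CGM points, a data-rich regime where
centered geometry is benign, and because it keeps a one-to-one map
between latent coordinates and simulator parameters (which the gradient
engine exploits). The sinusoid phases are plain normals around their
parent (cohort phase uniform on one day) and are reported modulo one day;
wrapping is unnecessary in the likelihood because the sinusoid itself is
periodic.

Where published estimates exist they anchor the table (`source =
"literature"`): the subcutaneous lag within 5–30 min, `GEZI` bounded
below at $10^{-3}$/min, the first meal-absorption constant capped at
10 min, the short activity constant within 5–120 min, a 20% standard
deviation on the meal coefficient, the intraday modulation capped at 50%,
insulin-chain constants centered near 16/60/60/30 min, the long activity
effect centered at a 40% gain with ~12 h half-time. The remaining
locations, scales and bounds are package defaults calibrated by prior
predictive checking: with the packaged exemplary day, at least 95% of
prior-predictive trajectory-minutes must lie in the physiological
0–400 mg/dL band, and with insulin and meals removed the median terminal
glucose must exceed 300 mg/dL (glucose rising toward the renally-limited
equilibrium near 400). During calibration the binding change was
tightening the EGP linkage (`EGPi` scale 0.5, slope scale 2, window EGP
capped at 5 mg/dL/min): the high-EGP prior tail was the one feature
pushing trajectories above 400.

Units: minutes, mg/dL, grams, insulin units. No insulin distribution
volume is modelled, so the conventional μU/mL scale of insulin
sensitivity is folded into $SI$: our $SI$ is per U/min of chain output.
Only the product $SI \cdot I_p$ is identified, so this is a pure
relabeling; the same applies to the unspecified units of $E$, which
rescale $S_E$ only.

## Inference

The posterior is approximated by stochastic variational inference with a
low-rank multivariate normal guide on the unconstrained space (two-sided
supports via scaled logit, one-sided via shifted log): covariance
$\mathrm{diag}(d^2) + WW^\top$ with rank-$r$ factor $W$; $r = 0$ is
exactly mean-field. Gradients are reparameterized; the guide entropy and
its gradients are analytic (Woodbury/determinant-lemma algebra); the
model term's gradient combines analytic prior/Jacobian derivatives with
central finite differences of the per-window log-likelihood computed
inside the compiled engine — each latent coordinate only re-simulates the
windows it touches, which makes the gradient cost proportional to windows
× slots rather than to the full latent dimension. The optimizer is Adam
with a cosine learning-rate schedule; non-finite particles are skipped
and counted, and a fully failed iteration aborts with the worst-scoring
window named. Library defaults mirror the reference setup (15 ELBO
particles, 80,000 iterations); the examples and tests use scaled-down
fits (2 patients × 4 windows on a 5-min grid, 2,000 iterations) chosen to
exercise the full pipeline at desk scale. Because Adam's per-coordinate
step is bounded by the learning rate, short fits need a larger rate than
long production runs: the scaled-down configurations use `lr = 0.02`
decaying to `0.002` (the conjugate-toy check converges to the
closed-form posterior within 2% under the same setting).

Three optimizer details matter on short runs. First, initialization: the
guide location starts from cascaded prior medians, refined by coordinate
profiling per window — the sinusoid phase over an eight-point grid (the
phase is the model's one genuinely multimodal direction; started in the
wrong basin, gradient ascent collapses the amplitude and cannot recover),
then the amplitude, then the window's insulin sensitivity profiled
*jointly* with its endogenous glucose production along the glucose
mass-balance ridge `EGP = (GEZI + SIE·mean insulin)·mean G + renal − meal
appearance`. All profiling uses only the window's observed data and
prior-median kinetics. Second, the low-rank factor activates only after a
mean-field warm-up (`rank_warmup`), with its own Adam clock: learning
means and covariance simultaneously wastes the short iteration budget.
Third, iterations whose particles all fail (glucose leaving the
integrable range) are skipped and counted; twenty consecutive failures
abort as divergence, naming the worst-scoring window.

`elbo_estimate()` follows the plain Monte-Carlo definition (model density
plus log-Jacobian minus guide density averaged over particles); the
training loop uses the analytic-entropy form of the same objective, which
has lower gradient variance.

## The synthetic cohort

`generate_cohort()` is the package's test bed and defines its study
conditions: ~2.7 meals per window in breakfast / lunch / dinner (plus
occasional snack) slots, boluses paired to meals (the first meal always
bolused, others with probability 0.505, giving ~1.9 injections per
window) sized at 1 U per 10 g ± 20%, activities on 33% of days with
40–80 bpm heart-rate elevations for 20–60 min, resting heart rate
60–75 bpm, one long-acting injection each evening, and ground-truth
latents drawn from the model's own priors. CGM noise is independent
Normal with the window's own $\sigma$, clamped to a 4–9 mg/dL band so
that clean windows clear the 45 mg/dL discontinuity filter with margin
(independent noise at the upper end of the prior's $\sigma$ scale would
trip it constantly, which is one reason real sensor error is strongly
autocorrelated). A `noise_phi` option adds AR(1) correlation to emulate
that autocorrelation; fitting the independent-noise likelihood to such
data measurably biases the smooth latents (the sinusoid amplitude
collapses and EGP inflates) — we verified this, and it is why the
matched, independent-noise generator is the default for recovery
checks while the AR(1) mode exists for robustness studies.

Windows whose glucose leaves (20, 600) mg/dL or whose CGM would fail the
quality filters are re-jittered with fresh window-level latents (bounded
retries), so clean windows pass the filters *by construction* — the
defect-injection manifest's designed surviving count is a guarantee, not
a measurement. This rejection step mildly truncates the generative
distribution relative to the prior, just as the study-design filters
truncate real cohorts. What the generator does *not* emulate: unreported
meals, sensor dropouts and compression artifacts, correlated reporting
errors, glycogen dynamics of repeated exercise. Passing recovery tests on
this cohort therefore show the inference machinery is sound, not that the
model captures every feature of free-living data.

## Evaluation conventions

* Time-in-range metrics use the 70–180 mg/dL consensus thresholds; the
  three percentages are computed as complementary fractions so they sum
  to 100 exactly.
* Per-patient RMSE confidence intervals are a nonparametric bootstrap
  over that patient's windows (10,000 resamples).
* Peak-sensitivity periods: the sinusoid's argmax is at clock time
  $24\,((1/4 - \phi) \bmod 1)$ hours; draws are binned into breakfast
  (2–10 h), lunch (10–18 h), dinner (18–2 h, wrapping midnight);
  zero-amplitude draws have no argmax and are excluded but counted.
* Next-hour prediction: origins every 30 min; events inside the
  scenario's blanking windows are unknown to the predictor (dropped), or
  required absent in the no-disturbance scenario; window EGP and insulin
  sensitivity are redrawn from the patient-level posterior law; the
  predicted increment of $SG$ is anchored at the measured CGM value at
  the origin.
* The post-hoc meal regressions are ordinary least squares of the
  posterior means of each meal's $\tau_{D2}$, $T_D$, $M_A$ on carbs, fat,
  protein and $\Delta$CGM (measured glucose at the reported time minus
  40 mg/dL), refusing to run on fewer than 10 meals.

## Known limitations

* SVI gives an approximation; variance along weakly identified ridges
  depends on the guide rank covering those directions. The sharpest case
  is window-level EGP: conditionally on the other latents it is pinned to
  ±0.02 mg/dL/min, but it trades off almost flatly against `GEZI`, `VG`
  and the event-level meal/bolus coefficients. On synthetic recovery
  benchmarks the window's insulin sensitivity is recovered with
  calibrated intervals, while the EGP intervals of a low-rank Gaussian
  guide stay conditional-width — far narrower than the exact posterior's
  ridge-wide marginal — so EGP credible intervals from short fits should
  be read as precision of the *conditional*, not the marginal, posterior.
  Longer optimization does not fix this (the guide slides along the
  ridge); it is a family limitation of unimodal Gaussian guides on
  sloppy hierarchical ODE posteriors.
* Short scaled-down fits are optimization-limited: posterior means
  carry prior shrinkage that longer runs reduce.
* The model holds plasma and tissue glucose in one compartment and
  simplifies exercise physiology to two exponentials on purpose.
* Timestamps are treated as timezone-naive local clock times; the
  sinusoid anchor uses the calendar date of the window start.

## A worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_config(n_patients = 2, samples_per_patient = 4,
                                     seed = 11))
fit <- vp_fit(coh$samples,
              control = svi_config(n_particles = 4, n_iterations = 2000,
                                   rank = 20, rank_warmup = 600, seed = 3,
                                   lr = 0.02, lr_end = 0.002))
summary(fit)
plot(fit, window = 1)
rmse_posterior_mean(fit$svi, coh$samples)$by_patient
replay_variability(fit$svi, coh$samples)$metrics
```
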