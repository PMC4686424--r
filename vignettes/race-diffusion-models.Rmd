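---
title: "Race-diffusion models of reactive and proactive stopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Race-diffusion models of reactive and proactive stopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raceddm)
```

## The model

raceddm simulates and fits a family of race-diffusion models of action
stopping built around a single *execution process*. A linear accumulator
$\varphi_e$ integrates evidence with drift $v_e$ and diffusion constant
$\sigma$ from an onset delay $t_r$,

$$d\varphi_e = v_e\,dt + \sigma\,dW,$$

and the effective execution state is the accumulator scaled by a dynamic
bias (urgency) signal, a hyperbolic function of time since onset with
gain $x_b$:

$$\theta_e(t) = \varphi_e(t)\,\gamma(t - t_r), \qquad
  \gamma(s) = \cosh(x_b\,s).$$

A response is produced, with its RT, when $\theta_e$ reaches the
boundary $a$ before the end of the trial window $b$. The hyperbolic form
of $\gamma$ is a modelling choice: it equals 1 at onset, is even and
non-decreasing, and accelerates the process toward the deadline, giving
the narrow, late, slightly left-skewed RT distributions seen in
deadline-driven tasks. It is centralised in `dynamic_gain()` so an
alternative hyperbolic form can be swapped in one place.

Stopping is modelled three ways:

* **Dependent process model (DPM).** At the stop-signal delay (SSD) a
  braking process is initiated *at the current state of the execution
  process*, $\theta_b(\mathrm{SSD}) = \theta_e(\mathrm{SSD})$, and
  drifts toward 0 with rate $-v_b$ (same $\sigma$, no gain). The trial
  is stopped if $\theta_b$ reaches 0 before $\theta_e$ reaches $a$. The
  nesting means stopping difficulty depends on how far the action
  decision has already progressed.
* **Independent race.** A braking accumulator starts from 0 at the SSD
  with drift $+v_b$ and races to the same boundary $a$; go and stop
  processes share no state. Racing to the common boundary $a$ is the
  minimal assumption for the unstated braking finish line.
* **Interactive race.** After a stop-cue registration delay $sso$, a
  positively accumulating braking signal is subtracted from the
  execution signal; the response criterion becomes
  $\theta_e - \theta_b \ge a$. The braking accumulator carries its own
  diffusion noise (the description leaves this open; a noisy
  accumulator keeps the three models on the same stochastic footing).

In the proactive (cued go-probability) task only the execution process
runs: a "no-go" outcome is any trial on which $\theta_e$ fails to reach
$a$ by the deadline. The late single SSD of that task is not modelled
as a braking event.

## Parameters, units and defaults

| parameter | meaning | units | default box |
|---|---|---|---|
| `a` | boundary height | evidence | (0.05, 1.5) |
| `tr` | onset delay (pre+post decision lumped) | s | (0.001, 0.5) |
| `v_e` | execution drift | evidence/s | (0.01, 5) |
| `v_b` | braking drift magnitude | evidence/s | (0.01, 5) |
| `xb` | dynamic gain | 1/s | (0, 5) |
| `sigma` | diffusion constant | evidence/√s | fixed 0.1 |
| `sso` | stop-cue registration delay (interactive) | s | (0, 0.3) |

$\sigma$ is never estimated: it is the conventional scaling constant of
diffusion models (0.1), fixed identically in generation and fitting.
`v_b` is stored as a magnitude; the DPM applies it negatively, the
other two models positively. The boxes envelope published best-fit
values for both tasks with headroom.

`preset_params()` ships representative best-fit parameter sets for each
model and task; they drive examples and serve as ground truth in the
recovery studies.

## Task designs

`task_design("reactive")`: five SSDs from 200 to 400 ms, 650 ms trial
window, 50% stop trials, responses aimed at a 500 ms target;
per-subject defaults of 100 go trials and 20 stop trials per SSD.
`task_design("proactive")`: six go-probability cues (0–100% in 20%
steps), a single 450 ms SSD, 555 ms window; 40 trials per cue (10
blocks of 24 with each cue four times per block).

## Numerical scheme

Trials are integrated by Euler–Maruyama with a default step of 1 ms on
a grid anchored at the onset delay, with a truncated final step at the
deadline, and boundary crossings are located by linear interpolation
within the crossing step. Anchoring at onset and interpolating
crossings matters twice over: it removes most of the $O(dt)$
first-passage bias, and it makes every summary statistic a smooth
function of the parameters — with grid-snapped onsets the fitting cost
is a staircase in `tr` and the simplex stage stalls on the flat steps.
When execution and braking cross within the same step, the earlier
interpolated crossing wins. Trial noise comes from counter-based
per-trial substreams (xoshiro256++ seeded per trial), so trial $i$ is
reproducible regardless of trial order, and execution noise is shared
between a go trial and the stop trial with the same index.

## Summary statistics and the fitting cost

`summarize_trials()` produces the observables the cost consumes.
Reactive, per condition: go response probability $P_g$, stop accuracy
per SSD, RT quantiles (0.1, 0.3, 0.5, 0.7, 0.9) of correct (go)
responses, and RT quantiles of stop-trial responses collapsed across
SSDs (error responses are too rare at early SSDs to summarise per
delay). Proactive: response probability per cue and RT quantiles pooled
over high (>50%) and low (<50%) cues. Quantiles use the type-7
(linear-interpolation) definition for both data and simulation, so the
cost is internally coherent.

The cost is a weighted sum of squared differences between observed and
simulated observables ("$\chi^2$"), with quantile terms multiplied by
the observed response probability of their trial class. Quantile
weights derive from Maritz–Jarrett standard errors — the median of the
five SEs divided by each SE, so unstable quantiles are down-weighted.
"Interpolated median standard error" is read here as the median of the
five quantile SEs (a robust centre); the alternative reading (the SE of
the 0.5 quantile) can be substituted by passing explicit `se` values to
`quantile_weights()`. Accuracy weights use across-subject standard
deviations per condition (`accuracy_weights()`, `weights_from_cohort()`)
when a cohort is available, and default to 1 otherwise.

AIC and BIC are computed from the weighted SSE under the Gaussian
convention $AIC = n\log(\chi^2/n) + 2k$,
$BIC = n\log(\chi^2/n) + k\log n$, with $n$ the number of fitted data
points (16 per reactive context; 16 for a proactive fit) and $k$ the
number of free parameters. Comparisons are only made within this
convention. For modulation fits, $k$ counts the condition-varying
parameters optimised at the conditional stage.

## The fitting protocol

`fit_race_model()` runs a two-stage hierarchical protocol:

1. **Flat stage** (`fit_flat()`). All parameters free, fitted to the
   condition-averaged observables (the cost without the sum over
   conditions). The global search is basin hopping — at most 100
   iterations, stopping after 40 consecutive failures to improve, with
   hop size 10% of each parameter box and Metropolis temperature 1 —
   each hop polished by a short Nelder–Mead run.
2. **Conditional stage** (`fit_conditional()`). All parameters held at
   the flat estimates except the modulated ones (drift, onset, both, or
   boundary), which are first re-seeded per condition by a short basin
   hop on that condition's own cost terms (so the joint simplex does
   not start from identical values across conditions) and then jointly
   polished by a final Nelder–Mead simplex plus a least-squares
   refinement on the full multi-condition cost.

   The condition-averaged observables of the flat stage often cannot
   tell compensating constant-parameter sets apart (several quite
   different `(a, tr, xb)` triples reproduce one averaged response
   probability and five pooled quantiles equally well). The flat stage
   therefore hands over a diversified shortlist of solutions, and the
   conditional stage probes each one — re-seeding the modulated
   parameter per condition and evaluating the full multi-condition
   cost — before committing to the constants that explain the full
   condition structure best. This is the same selection principle as
   the protocol's run-everything-and-keep-the-lowest-AIC rule, applied
   within one run.

The whole protocol is restarted three times (`n_restarts`) and the run
with the lowest AIC is kept, with ties broken by lower cost and then
earlier run.

Several implementation choices make this tractable and reliable:

* **Common random numbers with antithetic variates.** Every cost
  evaluation inside one fit simulates with the same per-trial noise,
  cached as matrices, and consecutive trials use sign-flipped copies of
  the same noise column. The cost surface is thereby deterministic,
  locally smooth, and has far less Monte-Carlo variance than
  independent simulation at the same $n$.
* **Two resolutions.** The search stages run at a cheaper resolution
  (`n_sim_search` trials, `dt_search`); candidate solutions are
  re-ranked and the winner polished at the full `n_sim_per_eval` and
  `dt`. Matching the polish `dt` to the data's integration step avoids
  a small but systematic discretization bias.
* **Informed starts.** Besides a Latin-hypercube screen, the flat stage
  derives starting points from the observed quantiles: over a small
  grid of $(t_r, x_b)$, the median decision time fixes $a/v_e$ and the
  quantile spread fixes $v_e$ through the inverse-Gaussian standard
  deviation. This matters because the flat cost surface has several
  locally excellent "imposter" basins in which $(a, t_r, x_b, v_b)$
  jointly compensate; they are only distinguished from the
  data-consistent basin at large simulation sizes, so the search
  carries multiple candidates forward rather than committing early.
* **Derivative-free throughout.** The simplex runs with per-parameter
  scaling (`parscale` = box width); a Levenberg–Marquardt least-squares
  refinement of the winner (on the weighted residual vector) is used as
  the final deepening step of the flat polish.

## Recovery studies, problem sizes, and identifiability

The package's recovery studies (`recovery_harness()`,
`scripts/acceptance.R`, the end-to-end tests) simulate the reactive
design at the DPM preset with 200,000 go and 40,000 stop trials per SSD
(integration step 1 ms) and refit with `n_sim_per_eval` = 100,000; the
proactive designs use 20,000 trials per cue at a 2 ms step with 12,000
simulated trials per cue per evaluation. These sizes put the
Monte-Carlo noise floor of the cost well below the separation between
the data-consistent basin and its grossest imposters; at the task's
native per-subject trial counts (a few hundred trials) none of the
parameters is identifiable to within a few percent, which is why
group-scale data are the appropriate recovery setting.

Even at these sizes, recovery has a floor worth being explicit about.
The cost compresses each condition into 16 observables, and the model
family contains near-flat valleys along which `(a, tr, xb, v_b)`
(reactive) or the constants behind a modulated parameter (proactive)
co-vary while every observable moves less than its sampling noise. A
least-squares refinement started *at* the generating parameters stays
put (all parameters within 0.2%), but the realized data's noise tilts
the valley, so the global minimum typically sits 5–25% away in the
boundary and braking-drift directions — however good the optimizer,
and at any feasible simulation size. The execution drift is pinned to
a few percent; the boundary, onset, gain, and braking drift are
recovered as a mutually compensating set rather than individually.
This is a property of the summary-statistic cost, not of the
integrator or the search, and it is why the model-comparison AIC —
which only needs relative fit — is a more robust quantity than any
single constant's point estimate. Unit tests use far smaller sizes and
test structure, invariants and determinism rather than recovery
precision.

## The BOLD proxy

`predict_bold()` computes, per cue and outcome, the mean cumulative sum
of the execution process over the trial (trapezoid integral of
$\theta_e$, ending at the boundary crossing for responses and at the
deadline otherwise) — a single area-under-the-curve number standing in
for the duration and distance-to-bound of the decision, with no
hemodynamic convolution. The AUC is computed on the gain-scaled
$\theta_e$, not $\varphi_e$. Go trials from cues ≤ 60% and no-go trials
from cues ≥ 40% are additionally pooled, mirroring the imaging
contrasts. Under drift modulation the model predicts larger responses
for go than no-go outcomes and no-go responses growing with cue
probability; under onset modulation both outcomes grow with cue
probability; under boundary modulation responses shrink with cue
probability.

## Synthetic cohorts

`generate_cohort()` draws per-subject parameters around a known truth
with Gaussian between-subject dispersion truncated to the parameter
boxes (redrawn up to 1000 times, then clamped), simulates each
subject's task, and carries the truth record alongside the data. One
deviation is drawn per parameter per subject and added to all
conditions, preserving condition contrasts. This is fixture machinery:
the generator emulates trial counts, designs and plausible
heterogeneity, but not learning or sequence effects, reward dynamics,
lapses, or any empirical subject's idiosyncrasies — so passing recovery
tests demonstrates internal consistency of model and fitter, not
validity for any particular empirical dataset.

## Known limitations

* The braking finish line of the independent race and the noise of the
  interactive braking signal are modelling choices where the underlying
  description is silent; both are documented above.
* The DPM braking process is not reflected at the boundary $a$; it may
  exceed $a$ before descending.
* Absolute AIC/BIC values depend on the documented SSE convention and
  are not comparable to values computed under other conventions.
* `tr` lumps sensory and motor delays; the model cannot separate them.
* Fitting assumes $\sigma$ is the scaling constant; data generated
  under another scaling convention must be rescaled first.
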