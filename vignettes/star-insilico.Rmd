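---
title: "Model-based glycaemic control and nutrition delivery in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based glycaemic control and nutrition delivery in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starGC)
```

`starGC` is an in-silico implementation of STAR-style glycaemic control
(GC): a dosing protocol that keeps intensive-care blood glucose (BG) in the
4.4–8.0 mmol/L band by modulating insulin *and* enteral nutrition (EN),
selecting each intervention so that the forecast risk of light
hypoglycaemia (BG < 4.4 mmol/L) stays at or below 5%. This vignette
documents the science inside the package: the physiological model and its
assumptions, the identification and forecasting machinery, the dosing
rules, the nutrition analytics, the synthetic cohort generator, and the
numerical and design choices made along the way.

## 1. The glucose–insulin model

The virtual patient is a compartmental model of the ICING family:

$$\frac{dG}{dt} = -p_G G - S_I\, G\, \frac{Q}{1+\alpha_G Q}
  + \frac{P(t) + EGP - CNS}{V_G}$$
$$\frac{dI}{dt} = -n_K I - \frac{n_L I}{1+\alpha_I I} - n_I (I-Q)
  + \frac{u_{ex}(t)}{V_I}, \qquad
  \frac{dQ}{dt} = n_I (I-Q) - \frac{n_C Q}{1+\alpha_G Q}$$
$$\frac{dP_1}{dt} = -d_1 P_1 + u_{en}(t), \quad
  \frac{dP_2}{dt} = -d_2 P_2 + d_1 P_1, \quad
  P(t) = d_2 P_2 + u_{pn}(t)$$

`G` is BG (mmol/L, the controlled variable), `I` and `Q` plasma and
interstitial insulin (mU/L), `P1`/`P2` gut glucose (mmol). The two
saturation terms matter clinically: $\alpha_G$ caps the glucose-lowering
effect of additional insulin, and $\alpha_I$ saturates hepatic insulin
clearance. Insulin saturation is why a purely insulin-driven protocol
cannot always control a resistant patient, and hence why nutrition
modulation is part of the dosing problem at all.

Assumptions worth stating:

* **No endogenous insulin secretion.** Secretion is strongly suppressed in
  the critically ill patients this protocol targets; the first-pass
  hepatic extraction fraction `xL` is carried in the parameter set for
  completeness but multiplies nothing in the present equations.
* **Continuous IV insulin only** (U/h, converted at 1000/60 to mU/min);
  boluses and subcutaneous kinetics are out of scope.
* **Inputs are piecewise constant** over intervention intervals, matching
  how infusion pumps and feed pumps are actually set.

Default parameter values (`icing_params()`, also shipped as
`inst/extdata/icing_params.csv`) are representative adult-ICU magnitudes —
e.g. $p_G = 0.006$/min, $V_G = 13.3$ L, $EGP = 1.16$ mmol/min,
$\alpha_G = 1/65$ L/mU — and every constant is configurable. They are
deliberately documented as *representative*: the package's claims are about
the protocol's behaviour given a plausible physiology, not about any one
parameter fit. $S_I$ (L/(mU·min)) is patient-specific and time-varying; all
identification and forecasting concerns $S_I$ alone.

**Integration.** A fixed-step classical 4th-order Runge–Kutta scheme at
`dt = 1` min (compiled, `src/icing.cpp`) — deterministic, reproducible,
and comfortably converged for these minute-scale dynamics (the test suite
checks that halving the step moves a 3-h BG trajectory by
< 0.01 mmol/L). States are clamped at zero at step boundaries as a
positivity guard; with physiological parameters the clamp is inactive.
Non-finite states abort with the offending time.

## 2. Identifying insulin sensitivity

`fit_si()` identifies the single parameter $S_I$ over each interval between
two BG measurements by the integral method: integrate the glucose equation
over $[t_0, t_1]$, approximate $G(t)$ inside the integrals by linear
interpolation between the two measurements, simulate the insulin and gut
compartments from the known inputs (they are independent of $G$ and
$S_I$), and solve — $S_I$ enters linearly, so the estimate is one division.

Two design choices:

* **One fixed-point refinement** (default `refine = 1`). The pure
  linear-interpolation form biases the estimate when BG moves quickly
  within an interval (the true path is convex). After the linear solve, the
  model is simulated with the estimate, the simulated path is
  endpoint-corrected to pass through both measurements, and the (still
  closed-form) solve is repeated with that path. On randomized hourly
  intervals this reduces the median disagreement with a brute-force 1-D
  search from a few percent to well under 1%. `refine = 0` restores the
  classical form.
* **Unidentifiability is an explicit condition.** When the interval carries
  essentially no insulin exposure (mean saturated interstitial insulin
  below 0.05 mU/L), the denominator integral is degenerate and the fit
  raises a `starGC_unidentifiable` error; the closed loop falls back to the
  previous estimate, or to a population-median prior of
  4e-4 L/(mU·min) before the first identifiable interval. Fitted values
  are clamped to the plausibility range [1e-5, 1e-2] L/(mU·min) with a
  warning.

## 3. Forecasting SI variability

`fit_stochastic_si()` models hour-scale metabolic variability as the
conditional distribution of the next-hour $S_I$ given the current value,
estimated by a 2-D Gaussian product-kernel density with Silverman/Scott
bandwidths ($1.06\,\hat\sigma\,n^{-1/6}$).

The kernel is fitted on pairs $(x, r) = (\log S_{I,now},\ \log
S_{I,next}/S_{I,now})$ — the *log-change* — rather than on raw
$(\log S_{I,now}, \log S_{I,next})$ pairs. The distinction matters for
calibration: conditioning a raw-pair KDE at $x$ smears neighbouring
conditional means (which move one-for-one with $x$) into the forecast
interval, inflating the nominal 90% interval far beyond 90% empirical
coverage. On the change scale the conditioning bandwidth only recruits
neighbouring *change* distributions, and the interval stays calibrated
(the suite checks 87–93% coverage at 5000 held-out transitions). Working in
logs also keeps $S_I$ positive by construction.

Percentile queries solve the kernel-mixture CDF by bisection on a 121-point
conditioning grid, cached per probability and interpolated — forecast
percentile curves are smooth in $\log S_I$, so the grid error is negligible
against the kernel bandwidth, and repeated queries (thousands per
closed-loop run) are cheap. Queries outside the training support warn and
answer at the nearest supported value. Horizons beyond the 1 h reference
gap are handled by chaining the 1 h percentile map, which slightly
over-spreads relative to the exact multi-step quantile — conservative in
the safety direction.

`si_lognormal_walk(sigma, mu)` provides the parametric counterpart
($S_{I,next} = S_{I,now} e^{\mu + \sigma\varepsilon}$) with closed-form
quantiles: the small-sample fallback, the generator's truth process, and —
with `sigma = 0` — the deterministic limiting case used to validate the
controller.

## 4. The dosing logic

A patient enters GC after two successive BG measurements above 8.0 mmol/L
within 4 h (`should_start`). Each decision then:

1. identifies $S_I$ over the elapsed interval;
2. queries the stochastic model at the 5th and 95th percentiles (the
   configured `risk` and `1 - risk`);
3. enumerates reachable interventions (`candidate_interventions`): EN in
   30–100% of the caloric goal, at most ±30% of goal per hour from the
   current rate (on a 10% grid, plus the exact boundary values); insulin on
   a 0–6 U/h grid in 0.5 U/h steps, at most 2 U/h change per intervention.
   The insulin limits are typical of published implementations and
   configurable — the protocol literature fixes only the nutrition bounds;
4. forward-simulates each candidate at both $S_I$ percentile bounds
   (`bg_prediction_bounds`): the 95th percentile gives the lower BG bound,
   the 5th the upper;
5. discards candidates whose lower BG bound falls below the hypoglycaemia
   threshold (default 4.4 mmol/L; 4.6 is the config alternative) *at any
   point* of the interval — the any-time minimum is the conservative
   reading of a 5% risk of crossing the threshold;
6. chooses by preference: **highest EN first**; within an EN level, the
   candidate whose predicted BG interval best overlaps 4.4–8.0 mmol/L;
   ties to **less insulin**.

One refinement to the lexicographic order was a genuinely open design
point. Taken literally, "maximise EN, then overlap" would let an
insulin-resistant patient sit hyperglycaemic at 100% feed forever — no
hypo risk, so the top EN level always wins, and nutrition would never be
restricted, which is exactly the behaviour the saturation physiology says
must sometimes happen. The implemented rule therefore accepts an EN level
only if some hypo-safe insulin choice at that level yields either positive
band overlap or, when every prediction sits above the band, a predicted
fall of at least `min_descent` (default 0.3 mmol/L per h); otherwise the
search moves to the next lower EN level. This realises
insulin-before-nutrition — insulin raises are explored at the current feed
rate before feed is cut — while still allowing nutrition restriction when
the insulin route is exhausted. If BG is stuck above band even at minimum
EN, the safest descent is taken; if *nothing* is hypo-safe, the candidate
with the maximum predicted lower bound is returned with a
`risk_warning` flag (feeding maximally is then the protective choice, since
glucose input props BG up).

Decisions default to hourly; 2–3 h intervals are config-gated
(`interval_options`) for when predictions lie wholly in band. PN is never
modulated: it is clinician-set, the controller knows it, and EN still
targets 100% of goal — which is how delivery can exceed 100%.

`run_closed_loop()` wires this into an in-silico trial: the truth model
advances with its own hourly-varying $S_I$, the controller sees only BG
measurements and its own input history, and everything is logged. Virtual
patients start with small basal insulin levels (`I0 = 15`, `Q0 = 10` mU/L)
so the first interval already carries identifiable insulin exposure —
without an endogenous-secretion term, a truly insulin-naive interval is
exactly unidentifiable.

## 5. Caloric goal and nutrition analytics

The daily caloric goal is the ACCP-style 25 kcal/kg/day target applied to a
weight surrogate: an 80 kg reference scaled by frame (0.9/1.0/1.1), age
band (1.1/1.0/0.9/0.8 for ≤39/40–59/60–79/≥80, closed edges as printed)
and sex (1.0/0.8), spanning 1152–2420 kcal/day over the 24 combinations. A
measured-weight override is provided, since weight estimation is the
acknowledged weak point of the surrogate.

The analytics reproduce the evaluation conventions of STAR's clinical
nutrition audits:

* **Rate basis.** Percent of goal per ICU day is the delivered EN+PN
  calories over *observed GC hours*, scaled to a 24 h-equivalent rate —
  days only partially on GC are judged by their rate, not penalised for
  unobserved hours. (Whether to normalise by observed hours or the full
  24 h is genuinely under-determined; the rate basis is the documented
  choice, and the alternative would only lower partially observed days.)
* **Day alignment.** ICU day 1 is the first 24 h from admission; records
  spanning a boundary are split proportionally, so calories are conserved
  across days (a tested invariant).
* **Exclusion rule.** Hours with combined feed strictly below 30% of goal
  are flagged and dropped from rate statistics — they reflect surgery,
  imaging or intolerance, not the dosing algorithm. Exactly-at-floor hours
  are retained.
* **Per-patient variability** uses the sample (n−1) standard deviation of
  hourly rates; protein and carbohydrate calories both count. Reference
  curves (survey means, the 85% mortality-optimum benchmark) are
  user-supplied constants or per-day tables, never recomputed.

EN composition defaults describe a low-carbohydrate 1 kcal/mL formula
(74.6 g/L carbohydrate, 50 g/L protein), so ~30% of EN calories are
glucose; PN is assumed 60% dextrose calories. Both fractions sit in
`feed_composition()` and only affect the physiology, not the caloric
accounting.

## 6. The synthetic cohort generator

`generate_cohort()` produces what the analytics and the controller assume
real data looks like: demographics centred on a mixed medical-surgical ICU
(age ~63 ± 13, two-thirds male, mostly medium frame — putting the median
caloric goal near 1800 kcal/day), initial $S_I$ lognormal (median 4e-4,
sdlog 0.45), an hourly lognormal random walk whose volatility decays from
0.10/h towards 0.05/h with a 36 h time constant (metabolic stabilisation
over the stay), Poisson feeding interruptions (0.03/h, lognormal durations
around 4 h — about 14% of hours interrupted), PN in 46.8% of patients at
lognormal rates (median 6.4% of goal), and lognormal stay lengths (median
8.4 days). Admission BG is uniform on 8.5–12 mmol/L: the generator
deliberately emulates the *hyperglycaemic* subpopulation that needs GC.

What it does **not** emulate — and therefore what passing tests cannot
show about real data: sensor error and measurement timing jitter; nurse
compliance; insulin boluses; endogenous secretion recovery; admission
case-mix beyond coarse marginals (no severity-score structure); any
correlation between interruptions and clinical state; and real
identified-$S_I$ series, whose conditional distributions are richer than a
lognormal walk. Calibration results (e.g. forecast-interval coverage) are
statements about self-consistency under the generator's assumptions, not
clinical validation.

`make_fixture_logs()` builds treatment logs directly from feeding
schedules with the per-day percent-of-goal computed analytically during
generation — an exact, independently-computed oracle for the analytics
pipeline.

## 7. Problem sizes and reproducibility

The shipped tests and acceptance script use: 200 randomized intervals for
$S_I$ recovery (median relative error < 5%); 2000 training / 5000 held-out
transitions for coverage (87–93% at nominal 90%); and a closed-loop trial
of 50 virtual patients × 72 h at 1-min integration steps (≈3500
measurements) for the hypoglycaemia-risk calibration — sizes chosen so the
binomial/Monte-Carlo error is small against the tolerances being checked
while the whole suite runs in a few minutes. All randomness flows through
explicit seeds; the integrator and percentile queries are deterministic,
so identical seeds reproduce cohorts and trials exactly.

## 8. Known limitations

* Model parameters other than $S_I$ are fixed at representative values,
  not identified; structural mismatch between a real patient and the ICING
  family is invisible to the in-silico loop, which uses the same family
  for truth and prediction.
* The stochastic model conditions on $S_I$ alone (not, e.g., time since
  admission), and multi-hour forecasts are conservatively over-spread by
  percentile chaining.
* The caloric goal's weight surrogate inherits the subjectivity of frame
  assessment; only the arithmetic is testable here.
* The controller's candidate EN grid is discrete (10% steps); a finer grid
  changes decisions marginally at the cost of proportionally more forward
  simulations.
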