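---
title: "Modelling frailty progression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frailty progression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailsim)
```

# The modelling problem

Frailty in older people is progressive: without intervention, individuals
tend to move from lesser to greater severity, and frailty raises the risk of
costly, quality-of-life-reducing events — hip fracture, falls, hospital and
residential care admission, physical disability, delirium and death.
Economic evaluations run alongside 12-month trials systematically miss the
downstream consequences of changing someone's frailty level, so funding
decisions need a lifetime extrapolation model.

A cohort Markov model is the conventional tool, but its defining assumption
— transition probabilities that ignore attributes and history — is exactly
wrong for frailty, where a prior fracture raises future fracture risk and
where age, comorbidity and event history all modify progression. `frailsim`
therefore implements an *individual-level discrete-time microsimulation*:
each simulated person carries attributes and an event history, and per-cycle
event probabilities are evaluated from risk equations on that state. The
cohort Markov model is retained, deliberately, as a *validation oracle*: in
configurations where history coefficients are zero the two models coincide,
and the engine is required to reproduce the exact Markov trace up to
Monte-Carlo error.

# Structure selection: the Delphi classifier

The model's structural choices (which events, which attributes) are decided
by a three-round expert consensus procedure over 1–5 Likert scores. The
implemented bands are:

* **acceptable** — panel mean in \[4, 5\] *and* at least 80 % of panellists
  scoring 4 or 5;
* **moderate** — panel mean ≥ 3 *and* at least 60 % scoring ≥ 4, evaluated
  only after the acceptable test fails;
* **unacceptable** — everything else.

Two boundary conventions deserve note. First, the published band
descriptions ("4 to 5" and "3 to 4") overlap at a mean of exactly 4; we
evaluate the acceptable test first and define moderate as "≥ 3 and not
acceptable", which makes the bands exhaustive and mutually exclusive, and
sends a high-mean/low-consensus item (mean 4.2, 70 % high scores) to
*moderate* — fed back to the panel — rather than discarding it. Second,
"at least 80 %" is read literally as a fraction ≥ 0.8 with no head-count
rounding: for a 9-member panel that means ≥ 8 of 9. The test suite verifies
both properties by exhaustively classifying all 5⁹ ≈ 1.95 million possible
score vectors: every acceptable vector has ≥ 8/9 high scorers, every
moderate vector ≥ 6/9.

Health events are scored on two aspects (strength of association with
frailty; impact on mortality, quality of life and resource use). Whether the
impact aspect was elicited as one combined score or three separate ones is
ambiguous in the source procedure; we model a **single combined impact
score** — a design decision, configurable by supplying separate aspects as
separate choices. A moderate-strength event whose impact is unacceptable is
**rejected**, not fed back. Round 3 includes a fed-back choice only if it
then reaches acceptable agreement; anything still moderate is rejected.

The default structure encodes the consensus outcome: seven events (the six
accepted directly plus delirium, accepted in round 3) and eleven attributes
(ten accepted directly plus depression, accepted in round 3). Depression was
rejected *as an event* and is therefore represented only as a time-varying
attribute — the hook through which its bidirectional relationship with
frailty can be expressed. Residential care admission and physical disability
are modelled as persistent binary states once they occur; falls, fractures,
hospital admissions and delirium are recurrent. Vertebral fracture does not
appear in the final consensus lists and is omitted.

# Frailty measurement

Both standard measurement approaches are supported. The Frailty Index is the
proportion of deficits present out of a fixed measured list (20 of 50
→ 0.4); it is scale-invariant and monotone. The Frailty Phenotype counts
five physical criteria and maps 0 / 1–2 / ≥ 3 criteria to non-frail /
pre-frail / frail; the zero-criteria class is *named* non-frail here since
the source bands name only the upper two. No canonical FI cut-points exist
for categorical use, so `fi_to_category()` requires explicit cut-points
(half-open intervals, lower cut inclusive) rather than shipping a default.
In risk equations, frailty enters as phenotype-category indicator columns by
default; an FI score can be used as a continuous covariate instead.

# Risk equations and the transition model

Each event has a per-cycle probability `logit⁻¹(β₀ + Σ βⱼ xⱼ)`. The logit
link is our choice — the source framework specifies "risk equations" without
a functional form — because it is the standard, closed-form-invertible model
for per-cycle binary outcomes and makes maximum-likelihood fitting a GLM.
Death equations include an age term by default (log-linear in the logit, a
discrete Gompertz-like approximation) so that mortality rises over a
lifetime horizon. Frailty category evolves by a 3 × 3 per-cycle transition
matrix. Intervention effects enter in two places: a multiplier on worsening
(and optionally improving) transition mass, with the freed probability
reassigned to staying — so a worsening multiplier of 0.5 turns a non-frail
row (0.6, 0.3, 0.1) into (0.8, 0.15, 0.05) — and optional hazard
multipliers on event odds.

Fitting uses IRLS (`stats::glm`, binomial family) with a relative
convergence tolerance of 1e-8 and a 100-iteration cap, returning estimates,
standard errors, log-likelihood and a convergence flag. Degenerate outcomes
(no variation) and complete separation (deviance numerically zero, or a
fitted-probability-0/1 warning with near-zero deviance) raise diagnostic
errors instead of returning garbage coefficients.

# The simulation engine

Cycles are **1 year** by default (configurable); the horizon defaults to
running until everyone could reach `max_age = 110`. Within a cycle the order
is fixed: death first (if death is sampled, the cycle is recorded and the
individual stops — no other events, no accrual that cycle), then each
non-fatal event as an independent Bernoulli given the linear predictors
(events may co-occur in a cycle), then the frailty transition, then history
counter and persistent-state updates, then ageing. Death-first ordering
gives clean life-year accounting: expected cycles entered under a constant
death probability *q* is exactly 1/*q*.

Random numbers follow a **fixed draw layout**: every individual consumes one
uniform for death, one per non-fatal event and one for the frailty
transition in every cycle, alive or dead. Consumption therefore never
depends on outcomes, so two runs with the same seed are draw-for-draw
paired — the common-random-numbers mechanism behind `run_comparison()`. A
scenario compared against itself yields *exactly* zero incremental cost and
QALYs, and incremental estimates use paired Monte-Carlo errors. (The same
guarantee is often implemented as one RNG substream per individual; the
fixed layout achieves it with a single stream.)

# Health-economic accrual

QALYs accrue as cycle-length × combined utility × discount factor, summed
over cycles lived. Combined utility is the baseline utility of the current
frailty category multiplied by the decrement of each event experienced that
cycle and the multiplier of each persistent state occupied at cycle start;
with all inputs in \[0, 1\] the combination stays in \[0, 1\]. Costs
combine event one-offs, annual frailty-category and persistent-state costs,
and intervention costs (one-off at model start, per cycle lived). The
default discount rate is **5 % per year for both costs and effects** — a
common convention in jurisdictions such as Australia — applied at cycle
starts; half-cycle correction (mid-cycle discounting) is off by default and
switchable, as it is a reporting convention rather than part of the model.
Cost entries are currency-agnostic, and perspective (government vs societal)
is handled simply by which cost categories the user includes.

The source framework publishes no utility or cost values for any state;
`illustrative_utilities()` and `illustrative_costs()` are clearly-labelled
placeholders so examples and tests run, nothing more.

Probabilistic sensitivity analysis draws coefficients from normals,
utilities from betas and costs from gammas (per declared `psa_param()`s),
reruns the paired comparison per draw, and reports the CEAC — the fraction
of draws with positive incremental net monetary benefit at each
willingness-to-pay threshold. One simulation seed is shared across draws, so
parameter uncertainty is isolated from simulation noise and zero-variance
distributions reproduce the deterministic result exactly.

# Synthetic data: what it emulates, what it does not

`generate_cohort()` builds baseline tables from per-attribute marginals
coupled by a Gaussian copula on Spearman correlations (converted to the
latent Pearson scale by `2 sin(πρ/6)`; non-positive-semi-definite
specifications are rejected). `generate_panel()` then advances the cohort
through repeated waves with the *same* engine and ground-truth parameters,
emitting one row per individual-wave with covariates at wave start and event
indicators — a stand-in for longitudinal ageing panels (repeated waves,
attrition by death, event histories) such as SHARE or DYNOPTA.

Defaults state a plausible world once: baseline age uniform 65–90 (the
target population is older people; no baseline age distribution is
specified by the source, and a flat spread exercises the age terms across
the relevant range), frailty 50 % / 35 % / 15 % non-frail / pre-frail /
frail (within the published 4–17 % frailty prevalence span for 65+, with a
substantial pre-frail fraction), sparse Poisson event histories and binary
comorbidities at textbook prevalences, and mild positive age–history
correlations. The generator does **not** emulate survey features like
non-death attrition, measurement error, interval censoring between waves, or
informative missingness — so a green validation loop establishes internal
consistency of generator, estimator and engine, not fidelity to any real
database. `default_risk_params()` is likewise an illustrative ground truth
(plausible signs and magnitudes), not an estimate.

# Validation design

Three levels, mirroring standard model-validation practice:

* **Cross-model validity.** `markov_oracle()` computes the exact cohort
  trace of any stochastic matrix. `compare_microsim_to_oracle()` builds the
  exact 4-state chain (three frailty categories + dead) implied by a
  memoryless configuration — death first, transition second, matching the
  engine's cycle order — and requires simulated occupancy to stay within 3
  binomial standard errors of the oracle at every cycle and state. Nonzero
  history coefficients violate the precondition and raise an error.
* **Internal validity.** `panel_targets()` extracts per-wave death rates,
  event rates among survivors and frailty prevalences from a panel;
  `internal_validation()` compares a simulation against them, passing a
  target when |predicted − observed| < 3 × the observed rate's binomial SE.
  The full loop — generate a panel at truth, fit the equations, simulate at
  the fitted parameters, validate against the same panel — is exercised in a
  seed sweep. The simulated arm replicates the panel's baseline several-fold
  so simulation Monte-Carlo error is small relative to the observed-rate SEs
  the pass rule is built on; this is a design choice made up front, since
  with equal arm sizes the rule would conflate estimation and simulation
  noise.
* **External validity** is emulated by validating against a second panel
  generated from the same truth under a different seed; real externally
  collected data are out of scope. Face validity (expert judgement) is not
  computable and is not attempted.

The 3-SE pass rule itself is a design decision — no quantitative criterion
is fixed by the source framework.

# Numerical conventions and degenerate inputs

* Probability boundaries: agreement-band and FI-category thresholds are
  inclusive at their lower edges; `fi_to_category` uses half-open intervals.
* Scenario transition modifiers that push any probability outside \[0, 1\]
  after renormalisation raise configuration errors rather than clipping.
* The engine treats a death cycle as recorded-but-unaccrued: life-years,
  QALYs and per-cycle costs count only cycles lived; one-off intervention
  costs are charged at time 0 regardless.
* Empty cohorts, missing attributes, missing equations, non-stochastic
  matrices, all-zero outcomes and out-of-range Likert scores all raise
  early, specific errors.
* Determinism: every stochastic function takes a seed; identical seeds give
  byte-identical outputs. Seeds derived internally stay below 2³¹.

# Known limitations

* Within-cycle event co-occurrence is independent given covariates; no
  same-cycle event interactions (e.g. a fracture causing an admission in the
  same year) beyond what next-cycle history terms capture.
* Continuous-time formulations, competing-risks likelihoods and interacting
  individuals are out of scope by design.
* Depression, although time-varying in the structure, has no built-in update
  equation; users wiring the frailty–depression feedback must supply one.
* The cohort generator's copula induces monotone dependence only, and
  categorical marginals are coupled through their latent codes.
* All shipped utilities, costs and risk coefficients are illustrative; any
  decision-grade use requires fitting to real data, which this package
  supports but does not ship.
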