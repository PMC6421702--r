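---
title: "Safety protocols for autonomous e-mental-health systems: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safety protocols for autonomous e-mental-health systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhtriage)
```

## The problem

Autonomous e-mental-health (AEMH) systems — chatbots, virtual coaches,
self-help apps — deliver first-line mental-health support without a human
caregiver in the loop. That autonomy creates a safety obligation: the system
itself must notice when a user's situation exceeds its scope (suicidality
being the canonical example) and must then get the user back to human care.
`mhtriage` implements three protocols covering this path as executable,
testable components:

1. **Risk detection** — decide that a possible risk exists, then decide
   whether it is severe enough to refer.
2. **Auto-referral** — when the system may contact a caregiver on the user's
   behalf, do so through a consent-gated workflow.
3. **Motivated self-referral** — when auto-referral is impossible (e.g.
   anonymous web services), adapt the persuasive strategy of a
   conversational agent to the user's situation so that they contact a
   caregiver themselves.

The third protocol is the one that lends itself to experimental evaluation;
the package therefore also ships a synthetic generator for the
within-subject 3 (stance) x 3 (severity) x 3 (agent strategy) experiment
around it, and the multilevel analysis pipeline used to test its hypotheses.

## Model 1: two-step risk detection

A `risk_profile()` operationalises the protocol for one risk type. Step 1
(does a risk possibly exist?) screens free text against a keyword lexicon
(`screen_text()`) and closed screening questions against risk-indicating
answer sets (`screen_answers()`). Step 2 (is it severe enough to refer?)
uses a questionnaire threshold where one exists (`questionnaire_refer()`),
and otherwise the duration/severity/progression (DSP) rule
(`dsp_refer()`): refer when at least *k* of *n* factors are negative,
defaulting to 2 of 3.

Deliberate choices where the protocol leaves latitude:

* **Inclusive threshold** (`total >= threshold`): with a referral cutoff
  stated only as "a threshold", the inclusive reading refers the boundary
  case — the conservative direction for a safety system.
* **Middle factor levels are not negative** by default (`medium`, `stable`).
  How middle levels count is genuinely open; the default takes the
  non-referring reading and makes the whole map configuration
  (`default_factor_map()`), so a deployment can flip any level.
* **Questionnaire gating** (`questionnaire_gated = TRUE`): severity
  questionnaires are solicited and used only *after* a step-1 signal.
  For suicide in particular, probing without indication is itself a risk
  (contagion), so `run_detection()` ignores and flags totals that arrive
  before any signal.
* **Plain-phrase lexicons**, matched case-insensitively at word boundaries,
  with overlapping matches allowed. Lexicons are data, not regular
  expressions, so a clinical reviewer can audit them; no statistical text
  classification is attempted — detecting an "expression of despair" beyond
  keyword matching is out of scope.
* **Risk-specific escalation** (a suicide profile referring faster than a
  sleep-problem profile) is expressed entirely through per-profile `k`,
  thresholds and maps, never hard-coded risk names.

`run_detection()` folds a session stream (utterances, answers, totals,
ratings) into a decision with a complete ordered trace, so every referral
and non-referral is replayable and auditable. Outcomes map to conventional
exit codes (0/10/20) for shell use.

## Model 2: consent-gated auto-referral

`run_referral()` drives a deterministic state machine over explicit events.
Consent is an absolute gate: without prior consent the machine emits
`refuse_no_consent` — surfacing that a risk was detected but auto-referral
was not authorised — and nothing else. (Referral *despite* missing consent
when safety overrides autonomy is a real design question, but it is
explicitly not modelled here; the gate is absolute.)

With consent, three branches follow: direct caregiver takeover (announce,
then hand over); crisis (alert the caregiver, tell the patient when to
expect contact, provide contact details, provide short-term coping options —
each exactly once); and non-crisis (ask the patient to self-contact, inform
the caregiver as a safety net, and escalate to caregiver outreach only when
the self-contact deadline passes without contact).

Numerical/temporal choices: time advances only through explicit `tick`
events, never a wall clock, so `run_referral(case, events)` is a pure
function and every property can be checked by enumeration; the deadline
comparison is strict (`clock > deadline`), so contact *at* the deadline
still counts; contact details are emitted in the non-crisis branch too,
because a network failure must never leave the patient without a way to
reach help. The test suite verifies safety (no referral action without
consent), crisis-branch completeness and at-most-once outreach by dynamic
programming over all reachable machine configurations, which covers every
event sequence up to length 8.

## Model 3: situation-adapted self-referral

The user's situation is a cell in a 3x3 grid of initial stance on seeking
human care (negative / doubting / positive) and situation severity (low /
medium / high). Following the social-judgement-theory latitudes, the nine
cells partition into three types with one referral strategy each:

| type | cells (row-major, severity high to low) | strategy |
|---|---|---|
| care potential | 1, 2, 5 | persuade, then facilitate by default |
| accept care | 3, 6, 9 | facilitate (contact details immediately) |
| reject care | 4, 7, 8 | accept the rejection, keep a standing offer |

The cell numbering is inferred from the three printed membership lists; the
memberships — not the numbering — are the tested contract. The prose
definition of "care potential" in the source material is internally
inconsistent with its own membership list, so the lists are authoritative
here. Severe situations with a negative stance (cell 1) are *potential*,
not rejection: with high severity there is little to lose by persuading.

Dialogue scripts are JSON data files, fully overridable; the engine
guarantees structure, not wording: ordering (greeting, the two three-option
manipulation-check questions, optional tips), branch resolution, placeholder
totality per concern (money amount, travel hours, stigma group), and the
**default bias** — in the persuade script the contact details are reached
when the user does nothing, and only an explicit `object` choice avoids
them. Objection is a multiple-choice branch, not sentiment analysis.
Every strategy's script keeps a path to contact details; in the
accept-rejection script it is reachable only on request, preserving both
the acceptance message and the user's ability to change their mind.

## Instruments

Outcomes are 7-point scales centred at the neutral midpoint
(`center_likert()`: raw 1..7 to −3..3), so deviation from neutral is
directly testable. The stated span "between −3.5 and 3.5" is read as the
containing interval of a centred 7-point response; with seven options the
realised range is −3..3. The feeling-of-being-heard (FBH) score is the mean
of seven centred items (`score_fbh()`), item-content-agnostic, no
imputation. ISI totals (`score_isi()`) use the standard published bands
(0–7 / 8–14 / 15–21 / 22–28, left-inclusive) — the bands are a clinical
convention and are exposed as arguments, not assertions.
`cronbach_alpha()` implements the variance-ratio formula with n−1
denominators and refuses degenerate input (fewer than two items or zero
total variance) rather than returning an undefined value.

## The synthetic trial generator

`generate_trial()` emulates the crowd-sourced experiment: 160 participants,
three scenario-chats each, sampled without replacement from the
situation-by-strategy crossing; participant-level concern (money 128/160,
travel time 15/160, stigma 17/160 — the observed counts; the printed
percentages do not quite sum to 100), gender (91/67/2 of 160), age
(mean 36, SD 10.41) and a simulated 7-item ISI centred on the observed
totals (mean 17, SD 6.53).

Outcomes follow a latent Gaussian random-intercept model: grand mean +
situation effect + strategy effect (+ optional interaction) + participant
intercept + residual, rounded and clamped to the centred 7-point scale.
Defaults are the study conditions, chosen once:

* grand means at the observed centred means (ISR 0.76, ICAA −0.03,
  FBH 0.79);
* `sigma_participant = 0.9`, `sigma_residual = 1.55`, giving total outcome
  SDs near the observed 1.7–2.0;
* sum-to-zero effect matrices that qualitatively mirror the reported
  contrasts (persuasion helping ISR most, strategy mattering for FBH,
  situation mattering most for ISR);
* FBH item noise `fbh_item_sd = 0.8`, which puts the simulated scale's
  internal consistency in the reported 0.93–0.97 neighbourhood;
* per-gender FBH offsets from the reported per-gender means (male +0.36,
  female −0.25, other −0.50 around the grand mean) — the one covariate
  effect the study found;
* manipulation checks answered correctly with probability 0.8
  (`manipulation_fidelity`), or via an alternative latent ordinal-threshold
  model (`manipulation_model = "ordinal"`) with its own participant
  intercept, used to exercise the cumulative-link fits.

The crossing defaults to the full 27 cells; a `restricted` 21-cell mode
(accept-care situations paired only with facilitation) is provided because
the design descriptions are ambiguous between 21 and 27 — the discrepancy
is surfaced as configuration, not resolved. The recruitment/exclusion
funnel (229 recruited, 160 included) is not simulated; `n_participants` is
specified directly. No free-text chat content, dropout or attention checks
are simulated.

What passing tests on this generator do and do not show: they validate the
*pipeline* — that the estimators recover planted effects, that the tests
are calibrated under a true null, that subsets and degrees of freedom match
the analysis plan — under a data-generating process that is, by
construction, close to the fitted model. They do not validate the protocol
on humans: real responses are ordinal, skewed and ceiling-bound in ways a
rounded Gaussian only approximates, and real participants are not exchangeable
draws from one intercept distribution.

## Inference

All models are fit by **full maximum likelihood, never REML**, because
every reported comparison is a likelihood-ratio test (LRT) on fixed
effects, and REML likelihoods are not comparable across fixed-effect
specifications. This can make variance estimates (and hence fitted
log-likelihoods) deviate slightly from REML-based outputs elsewhere.

`fit_lmm()` fits the Gaussian random-intercept model with the likelihood
profiled analytically to the single variance ratio: per-group
compound-symmetric blocks are inverted by the Woodbury identity, fixed
effects and residual variance have closed forms given the ratio, and the
ratio is optimised by golden-section search on `[0, 1e4]` at tolerance
1e-10, with the boundary (no participant variance) checked explicitly.
Factors are sum-to-zero coded so the intercept is the grand mean and its
deviation from the neutral score is directly testable
(`wald_intercept()`). Rank-deficient designs fail with the aliased term
named. The test suite cross-checks the fits against lme4's ML estimates and
against direct evaluation of the marginal Gaussian likelihood.

`fit_clmm()` fits the proportional-odds cumulative-logit model with a
participant intercept for the three-level manipulation-check outcomes. The
random intercept is integrated out by Gauss–Hermite quadrature (15 nodes by
default, configurable); thresholds stay ordered via a log-difference
parameterisation; optimisation is BFGS on the joint parameter vector, and
non-convergence is warned about and flagged, never silently returned —
`lrt()` refuses non-converged fits.

`run_hypothesis_ladders()` mirrors the published analysis plan (the four
hypothesis ladders with their situation subsets {1,2,5}, {3,6,9} under
facilitation, and {4,7,8}; gender as a fixed covariate in every FBH model),
`manipulation_check()` runs the ordinal comparisons with Cohen's
`w = sqrt(chisq/n)`, and `covariate_checks()` screens age, gender, ISI and
concern. No multiple-testing correction is applied, matching the raw
reporting of the original analysis. Two deliberate deviations:

* **Pseudo-R²**: the originally cited computation method is not
  identifiable, so `pseudo_r2()` reports both McFadden and Nagelkerke and
  privileges neither.
* **Intercept-test degrees of freedom**: the published F-statistics carry
  denominator df that cannot be reconstructed from the stated models (160
  participants x 3 observations); `wald_intercept()` reports its own naive
  df (`n_groups − 1`) and both `t` and `F = t²`.

### Calibration

Under a zero-effect generator at the design size (160 x 3), the headline
hypothesis tests — the 2-df strategy LRTs of H1/H2/H4 and the H3 intercept
Wald test — reject at close to the nominal 5% rate (the acceptance suite
verifies this over 200 replicates against the binomial 99% interval), and
power for a planted strategy effect rises monotonically with effect size.
The *multi-degree-of-freedom* LRTs (8-df situation, 16-df interaction) are
mildly anticonservative for the FBH outcome under these conditions
(empirically up to ~0.11 at the 5% level); this is a property of the
chi-square reference for ML LRTs on a ceiling-clamped outcome — lme4's ML
fits give p-values identical to ours to 1e-13 — and is worth keeping in
mind when reading multi-df comparisons on real data of this shape.

### Problem sizes used by the checks

The shipped checks simulate at the study design (160 x 3 = 480
scenario-chats) for calibration and power (200 null and 100-per-level power
replicates), 150 participants for the ordinal-model reduction check, 40
participants for the permutation-null ordinal check (60 replicates), and
10,000 participants for the crossing-uniformity goodness-of-fit check.

## Known limitations

* Keyword screening is exact-phrase matching; negation, paraphrase and
  misspelling are out of scope by design (lexicons are configuration).
* The state machine models one case at a time; scheduling, messaging and
  identity are integration concerns outside the package.
* The generator's discretisation (round-and-clamp) attenuates large latent
  effects near the scale ends; planted-effect recovery is therefore checked
  at variance settings where clamping is negligible.
* Thresholds, lexicons and bands shipped as examples are illustrative
  configuration, not clinically validated values; nothing here carries
  clinical validity in itself.
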