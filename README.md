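# mhtriage

Safety protocols and referral triage for autonomous e-mental-health (AEMH)
systems.

AEMH systems — chatbots, virtual coaches, web-based self-help — deliver
mental-health support without a human caregiver in the loop, which means the
software itself must notice when a user's situation exceeds its scope and
must get that user back to human care. `mhtriage` implements that path as
three executable, auditable protocols, plus the experiment-and-analysis
machinery to evaluate the third one:

* **Risk detection** (`run_detection()`): two steps. Step 1 screens free
  text against a configurable keyword lexicon and closed screening
  questions for risk-indicating answers. Step 2 decides severity: a
  questionnaire threshold when one is configured (`total ≥ threshold`,
  solicited only after a step-1 signal when gated), otherwise the
  duration/severity/progression rule — *refer when at least k of n factors
  are negative* (default 2 of 3). Every check lands in an ordered trace.
* **Auto-referral** (`run_referral()`): a consent-gated state machine.
  Without prior consent the referral is refused and surfaced. With consent:
  caregiver takeover when possible; in a crisis, alert the caregiver, state
  when contact can be expected, provide contact details and short-term
  coping options; otherwise ask the user to self-contact, notify the
  caregiver as a safety net, and trigger caregiver outreach only when the
  deadline passes without contact. Time is explicit tick events, so runs
  are pure and replayable.
* **Motivated self-referral** (`run_policy()`): classify the user's
  situation on the 3×3 stance-by-severity grid, whose cells partition into
  *care potential* {1, 2, 5}, *accept care* {3, 6, 9} and *reject care*
  {4, 7, 8}; select the matching strategy (persuade / facilitate / accept
  rejection); render it as a scripted dialogue personalised to the user's
  concern (money, travel time, stigma). Persuasion continues into
  facilitation *by default* — only an explicit objection stops it — and the
  accept-rejection script keeps a standing offer of contact details.

For evaluation, `generate_trial()` simulates the within-subject
3 × 3 × 3 experiment around the third protocol (160 participants × 3
scenario-chats; 7-point outcomes ISR = intention to self-refer, ICAA =
intention to contact the agent again, FBH = feeling of being heard, centred
so 0 is neutral), and the inference module reproduces its analysis plan:
random-intercept linear mixed models fit by full maximum likelihood
(`fit_lmm()`), cumulative-link mixed models via Gauss–Hermite quadrature
for the ordinal manipulation checks (`fit_clmm()`), likelihood-ratio model
ladders per hypothesis (`run_hypothesis_ladders()`), covariate checks, and
effect sizes (Cohen's *w* = √(χ²/N), McFadden/Nagelkerke pseudo-R²).
Instrument scoring (`score_isi()`, `score_fbh()`, `center_likert()`,
`cronbach_alpha()`) is included.

Everything takes and returns tibbles; fitted models have broom-style
`tidy()`/`glance()` methods and `autoplot()`/`plot_strategy_effects()`
ggplot2 graphics.

## Worked example

```r
library(mhtriage)

# --- detection: one signal, then the 2-of-3 severity rule ---
prof <- read_risk_profile(
  system.file("extdata/profiles/low_mood.yaml", package = "mhtriage"))
sess <- session(
  session_utterance("Lately I feel there is no way out"),
  session_rating("long", "high", "stable"))
run_detection(sess, prof)
#> <mh_detection> profile 'low_mood_self_harm': REFER
#>   fired rule: k_of_n_factors; signals: 1; negative factors: 2
```

The utterance matched the lexicon phrase "no way out" (step 1); the rating
has two negative factors (`long`, `high`; `stable` is not negative), which
meets the 2-of-3 rule (step 2), so the decision is to refer.

```r
# --- dialogue policy: doubting stance + severe situation ---
run_policy("doubting", "high", concern("money", money_problem_amount = 50))
#> <mh_policy_run> situation 2 (care_potential) -> strategy 'persuade'
#>
#> AGENT | Hello, I am here to talk with you about your sleeping problems.
#> AGENT | First, how severe would you say your situation is at the moment?
#> AGENT | And how do you currently feel about seeing a human therapist for this?
#> AGENT | Would you like a few tips that may help in the meantime?
#> AGENT | Try to keep a regular sleep schedule, avoid screens late at night, ...
#> AGENT | I understand that a cost of around 50 feels like a lot. ...
#> AGENT | Talking to a human therapist could really help you. I will give you
#>         the contact details of a clinic now, unless you would rather I did not.
#> AGENT | You can reach a therapist at the Sleep Clinic, 555-0100. ...
```

Doubt plus high severity is grid cell 2, a care-potential situation, so the
agent persuades (tailored to the stated money concern) and then — because
the user did not object — continues into facilitation and hands over the
contact details.

```r
# --- simulate the experiment and test persuasion where there is potential ---
trial <- generate_trial(seed = 1)          # 160 x 3 = 480 scenario-chats
lad <- run_hypothesis_ladders(trial)
lad$h2
#>   comparison                       n  chisq    df p.value
#> 1 strategy (all three)           144  9.57      2 0.00834
#> 2 persuade vs accept_rejection   106 10.5       1 0.00122
#> 3 persuade vs facilitate          92  0.100     1 0.751
```

On this simulated dataset, agent strategy affects the intention to
self-refer within the care-potential situations (χ²₂ = 9.57, p = .008),
driven by persuasion beating accept-rejection (χ²₁ = 10.5); each row is a
likelihood-ratio comparison of nested random-intercept models on the
indicated subset of `n` scenario-chats.

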