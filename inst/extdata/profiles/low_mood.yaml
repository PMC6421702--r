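# Example risk profile: persistent low mood with self-harm risk.
# Lexicon and threshold values are illustrative configuration, not validated
# clinical instruments; operationalise per system with clinical specialists.
risk_name: low_mood_self_harm
lexicon:
  - end my life
  - kill myself
  - hurt myself
  - no way out
  - better off without me
screening_questions:
  q_down:
    - nearly every day
    - more than half the days
  q_harm_thoughts:
    - "yes"
    - sometimes
questionnaire_id: phq9_item9
questionnaire_threshold: 2
questionnaire_gated: true
referral_rule: [2, 3]
factor_map:
  duration:
    levels: [short, medium, long]
    negative: [long]
  severity:
    levels: [low, medium, high]
    negative: [high]
  progression:
    levels: [improving, stable, worsening]
    negative: [worsening]
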