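# Shared fixtures, built in code.

basic_profile <- function(...) {
  risk_profile(
    "test_risk",
    lexicon = c("end my life", "no way out", "give up"),
    screening_questions = list(
      q1 = c("yes"),
      q2 = c("often", "always"),
      q3 = c("yes")
    ),
    ...
  )
}

thresholded_profile <- function(threshold = 2, ...) {
  basic_profile(questionnaire_id = "phq9_item9",
                questionnaire_threshold = threshold, ...)
}

# a generator with every systematic effect switched off
null_respondent_model <- function(...) {
  args <- utils::modifyList(
    list(grand_means = c(isr = 0, icaa = 0, fbh = 0),
         situation_effects = 0, strategy_effects = 0,
         gender_fbh_shift = c(female = 0, male = 0, other = 0)),
    list(...))
  do.call(respondent_model, args)
}

# strategy effect on ISR only, of a given half-range
isr_strategy_model <- function(scale, ...) {
  se <- rbind(facilitate = c(0, 0, 0),
              persuade = c(scale, 0, 0),
              accept_rejection = c(-scale, 0, 0))
  colnames(se) <- c("isr", "icaa", "fbh")
  null_respondent_model(strategy_effects = se, ...)
}

all_factor_levels <- function() {
  tidyr::expand_grid(duration = c("short", "medium", "long"),
                     severity = c("low", "medium", "high"),
                     progression = c("improving", "stable", "worsening"))
}
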