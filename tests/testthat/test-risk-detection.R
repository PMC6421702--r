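test_that("text screening finds lexicon phrases at word boundaries", {
  prof <- basic_profile()
  expect_equal(nrow(screen_text("", prof)), 0)
  expect_equal(nrow(screen_text("I slept badly", prof)), 0)

  one <- screen_text("Some days I want to end my life", prof)
  expect_equal(nrow(one), 1)
  expect_equal(one$evidence, "end my life")
  expect_equal(one$source, "text_match")

  # two distinct phrases, ordered by match position (positions checked
  # against an independent regexpr scan)
  txt <- "I see no way out and I want to give up"
  two <- screen_text(txt, prof)
  expect_equal(nrow(two), 2)
  expect_equal(tolower(two$evidence), c("no way out", "give up"))
  expect_equal(two$position,
               c(regexpr("no way out", txt), regexpr("give up", txt)))

  # case-insensitive; word-boundary (no match inside a longer word)
  expect_equal(nrow(screen_text("NO WAY OUT", prof)), 1)
  prof2 <- risk_profile("r", lexicon = "harm")
  expect_equal(nrow(screen_text("this is harmless", prof2)), 0)
})

test_that("answer screening flags risk-indicating answers and rejects unknown ids", {
  prof <- basic_profile()
  expect_equal(nrow(screen_answers(c(q1 = "no", q2 = "never"), prof)), 0)
  one <- screen_answers(c(q1 = "yes"), prof)
  expect_equal(one$source, "screening_answer")
  expect_equal(one$evidence, "q1")
  two <- screen_answers(c(q1 = "yes", q2 = "often", q3 = "no"), prof)
  expect_equal(nrow(two), 2)
  expect_error(screen_answers(c(q9 = "yes"), prof), "Unknown screening")
})

test_that("questionnaire threshold is inclusive", {
  expect_true(questionnaire_refer(2, 2))
  expect_false(questionnaire_refer(1, 2))
  expect_false(questionnaire_refer(0, 5))
  expect_error(questionnaire_refer(3, NULL), "threshold")
})

test_that("negative-factor counting follows the factor map", {
  expect_equal(count_negatives(list(duration = "long", severity = "high",
                                    progression = "worsening")), 3)
  expect_equal(count_negatives(list(duration = "short", severity = "low",
                                    progression = "improving")), 0)
  expect_equal(count_negatives(list(duration = "long", severity = "high",
                                    progression = "improving")), 2)
  expect_error(
    count_negatives(list(duration = "ages", severity = "low",
                         progression = "stable")),
    "not mapped")
})

test_that("DSP k-of-n rule matches brute-force counting over all ratings and rules", {
  ratings <- all_factor_levels()
  fm <- default_factor_map()
  for (k in 1:3) {
    for (i in seq_len(nrow(ratings))) {
      r <- as.list(ratings[i, ])
      brute <- sum(fm$duration[[r$duration]], fm$severity[[r$severity]],
                   fm$progression[[r$progression]])
      d <- dsp_refer(r, rule = c(k, 3))
      expect_equal(d$negatives, brute)
      expect_equal(d$refer, brute >= k)
      expect_equal(d$fired_rule,
                   if (brute >= k) "k_of_n_factors" else "none")
    }
  }
  # all-extreme corners: exactly half refer under the default 2-of-3 rule
  corners <- tidyr::expand_grid(duration = c("short", "long"),
                                severity = c("low", "high"),
                                progression = c("improving", "worsening"))
  refers <- vapply(seq_len(nrow(corners)),
                   function(i) dsp_refer(as.list(corners[i, ]))$refer,
                   logical(1))
  expect_equal(sum(refers), 4)
})

test_that("two-step detection composes screening with the severity rules", {
  prof <- thresholded_profile(threshold = 2)

  quiet <- session(session_utterance("lovely weather"),
                   session_answer("q1", "no"))
  expect_equal(run_detection(quiet, prof)$outcome, "no_risk")

  referred <- run_detection(
    session(session_utterance("I want to end my life"),
            session_questionnaire(3)), prof)
  expect_equal(referred$outcome, "refer")
  expect_equal(referred$fired_rule, "questionnaire_threshold")

  below <- run_detection(
    session(session_utterance("I want to end my life"),
            session_questionnaire(1)), prof)
  expect_equal(below$outcome, "possible_risk")

  # no questionnaire: DSP rating decides
  dsp <- run_detection(
    session(session_answer("q1", "yes"),
            session_rating("long", "high", "improving")),
    basic_profile())
  expect_equal(dsp$outcome, "refer")
  expect_equal(dsp$fired_rule, "k_of_n_factors")
  expect_equal(dsp$negatives, 2L)

  # a signal with no severity information stays a possible risk
  open <- run_detection(session(session_utterance("no way out")), prof)
  expect_equal(open$outcome, "possible_risk")
})

test_that("questionnaire gating ignores totals given before any signal", {
  prof <- thresholded_profile(threshold = 2)
  gated <- run_detection(
    session(session_questionnaire(5),
            session_utterance("nothing risky here")), prof)
  expect_equal(gated$outcome, "no_risk")
  expect_true("gating_violation" %in% gated$trace$check)

  # ungated profile accepts the early total (still needs a signal to act)
  prof_open <- thresholded_profile(threshold = 2,
                                   questionnaire_gated = FALSE)
  early <- run_detection(
    session(session_questionnaire(5),
            session_utterance("I want to end my life")), prof_open)
  expect_equal(early$outcome, "refer")
  expect_false("gating_violation" %in% early$trace$check)

  # gating invariant: any questionnaire check in the trace follows a signal
  ok <- run_detection(
    session(session_utterance("I want to end my life"),
            session_questionnaire(5)), prof)
  q_pos <- ok$trace$position[ok$trace$check == "questionnaire"]
  sig_pos <- min(ok$signals$position)
  expect_true(all(q_pos > sig_pos))
})

test_that("detection is deterministic and monotone in negatives and totals", {
  prof <- thresholded_profile(threshold = 2)
  sess <- session(session_utterance("no way out"), session_questionnaire(2),
                  session_rating("long", "medium", "worsening"))
  d1 <- run_detection(sess, prof)
  d2 <- run_detection(sess, prof)
  expect_identical(d1$trace, d2$trace)
  expect_identical(d1$outcome, d2$outcome)

  # raising a questionnaire total never flips refer -> not refer
  for (total in 2:9) {
    expect_equal(run_detection(
      session(session_utterance("no way out"),
              session_questionnaire(total)), prof)$outcome, "refer")
  }

  # adding a negative factor never flips refer -> not refer
  fm <- default_factor_map()
  worsen <- list(duration = c(short = "long", medium = "long", long = "long"),
                 severity = c(low = "high", medium = "high", high = "high"),
                 progression = c(improving = "worsening", stable = "worsening",
                                 worsening = "worsening"))
  ratings <- all_factor_levels()
  for (k in 1:3) {
    for (i in seq_len(nrow(ratings))) {
      r <- as.list(ratings[i, ])
      before <- dsp_refer(r, rule = c(k, 3))$refer
      for (f in names(worsen)) {
        r2 <- r
        r2[[f]] <- unname(worsen[[f]][r[[f]]])
        after <- dsp_refer(r2, rule = c(k, 3))$refer
        expect_false(before && !after)
      }
    }
  }
})

test_that("risk profiles round-trip through YAML and validate their invariants", {
  path <- system.file("extdata/profiles/low_mood.yaml", package = "mhtriage")
  prof <- read_risk_profile(path)
  expect_s3_class(prof, "risk_profile")
  expect_equal(prof$referral_rule, c(k = 2L, n = 3L))
  expect_equal(prof$questionnaire_threshold, 2)
  expect_true(prof$factor_map$duration[["long"]])
  expect_false(prof$factor_map$progression[["stable"]])

  expect_error(risk_profile("r", lexicon = character()), "lexicon")
  expect_error(risk_profile("r", lexicon = "x", questionnaire_id = "q"),
               "if and only if")
  expect_error(risk_profile("r", lexicon = "x", referral_rule = c(4, 3)),
               "referral_rule")
})

test_that("sessions round-trip through JSON Lines and exit codes follow outcomes", {
  sess <- session(session_utterance("no way out"),
                  session_answer("q1", "yes"),
                  session_questionnaire(3),
                  session_rating("long", "high", "stable"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  lines <- c(
    '{"type":"utterance","text":"no way out"}',
    '{"type":"screening_answer","question":"q1","answer":"yes"}',
    '{"type":"questionnaire","total":3}',
    '{"type":"factor_rating","duration":"long","severity":"high","progression":"stable"}'
  )
  writeLines(lines, path)
  expect_equal(read_session_jsonl(path), sess)

  expect_equal(detection_exit_code("no_risk"), 0L)
  expect_equal(detection_exit_code("possible_risk"), 10L)
  expect_equal(detection_exit_code("refer"), 20L)
})
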