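test_that("the stance-by-severity grid partitions into the three situation types", {
  grid <- situation_grid()
  expect_equal(nrow(grid), 9)
  expect_equal(sort(grid$id[grid$sit_type == "care_potential"]), c(1, 2, 5))
  expect_equal(sort(grid$id[grid$sit_type == "accept_care"]), c(3, 6, 9))
  expect_equal(sort(grid$id[grid$sit_type == "reject_care"]), c(4, 7, 8))

  # spot checks from the protocol's own reading of the grid
  s1 <- classify_situation("negative", "high")
  expect_equal(s1$id, 1)                       # severe overrides the low stance
  expect_equal(as.character(s1$sit_type), "care_potential")
  s9 <- classify_situation("positive", "low")
  expect_equal(s9$id, 9)
  expect_equal(as.character(s9$sit_type), "accept_care")
  s8 <- classify_situation("doubting", "low")
  expect_equal(s8$id, 8)
  expect_equal(as.character(s8$sit_type), "reject_care")

  expect_error(classify_situation("ambivalent", "high"), "Invalid stance")
  expect_error(classify_situation("negative", "extreme"), "Invalid severity")
})

test_that("each situation type maps to its referral strategy", {
  expect_equal(select_strategy("accept_care"), "facilitate")
  expect_equal(select_strategy("care_potential"), "persuade")
  expect_equal(select_strategy("reject_care"), "accept_rejection")
  grid <- situation_grid()
  expect_equal(select_strategy(grid),
               unname(c(accept_care = "facilitate",
                        care_potential = "persuade",
                        reject_care = "accept_rejection")[
                          as.character(grid$sit_type)]))
  expect_error(select_strategy("undecided"), "Invalid situation type")
})

test_that("concerns carry exactly the fields of their kind", {
  expect_equal(concern("money", money_problem_amount = 50)$money_problem_amount,
               50)
  expect_error(concern("money"), "money_problem_amount")
  expect_error(concern("time", travel_problem_hours = 2, stigma_group = "boss"),
               "only")
  expect_error(concern("stigma", stigma_group = "colleagues"))
  expect_equal(concern("stigma", stigma_group = "boss")$stigma_group, "boss")
})

test_that("every strategy renders for every concern with no unresolved placeholders", {
  concerns <- list(concern("money", money_problem_amount = 80),
                   concern("time", travel_problem_hours = 2),
                   concern("stigma", stigma_group = "friends"))
  for (strat in c("facilitate", "persuade", "accept_rejection")) {
    for (cn in concerns) {
      script <- render_dialogue(strat, cn)
      expect_false(any(grepl("\\{[a-z_]+\\}", script$text)),
                   info = paste(strat, cn$kind))
      # manipulation checks precede the strategy block, severity first
      sev <- which(script$turn_id == "severity_check")
      stn <- which(script$turn_id == "stance_check")
      expect_lt(sev, stn)
      expect_equal(script$options[[sev]], c("low", "medium", "high"))
      expect_equal(script$options[[stn]],
                   c("negative", "doubting", "positive"))
      # contact details are reachable in every script
      expect_true("contact_details" %in% script$turn_id)
    }
  }
})

test_that("persuasive messages are tailored to the concern", {
  money <- render_dialogue("persuade", concern("money",
                                               money_problem_amount = 80))
  expect_match(money$text[money$turn_id == "persuade_message"], "80")
  time <- render_dialogue("persuade", concern("time",
                                              travel_problem_hours = 2.5))
  expect_match(time$text[time$turn_id == "persuade_message"], "2.5")
  stigma <- render_dialogue("persuade", concern("stigma",
                                                stigma_group = "boss"))
  expect_match(stigma$text[stigma$turn_id == "persuade_message"], "boss")

  expect_error(
    render_dialogue("persuade", concern("money", money_problem_amount = 1),
                    params = list()),
    "Unresolved placeholder")
})

test_that("the policy composes grid, strategy and script with default bias", {
  cn <- concern("time", travel_problem_hours = 1)

  # accept care: facilitation ends in contact details with no input needed
  fac <- run_policy("positive", "medium", cn)
  expect_equal(fac$strategy, "facilitate")
  expect_equal(fac$transcript$turn_id[nrow(fac$transcript)],
               "contact_details")

  # reject care: acceptance plus standing offer, no unsolicited details
  rej <- run_policy("negative", "medium", concern("stigma",
                                                  stigma_group = "family"))
  expect_equal(rej$strategy, "accept_rejection")
  expect_true("standing_offer" %in% rej$transcript$turn_id)
  expect_false("contact_details" %in% rej$transcript$turn_id)
  # ...but the user can still ask for them (contact-offer liveness)
  rej2 <- run_policy("negative", "medium",
                     concern("stigma", stigma_group = "family"),
                     user_events = "request_details")
  expect_true("contact_details" %in% rej2$transcript$turn_id)

  # care potential: default path reaches facilitation, objection avoids it
  per <- run_policy("doubting", "high", concern("money",
                                                money_problem_amount = 50))
  expect_equal(per$strategy, "persuade")
  expect_true("contact_details" %in% per$transcript$turn_id)
  obj <- run_policy("doubting", "high",
                    concern("money", money_problem_amount = 50),
                    user_events = "object")
  expect_false("contact_details" %in% obj$transcript$turn_id)
  expect_true("accept_objection" %in% obj$transcript$turn_id)

  # declining the tips skips the tips block
  notips <- run_policy("positive", "low", cn, user_events = "no")
  expect_false("tips" %in% notips$transcript$turn_id)

  # strategy override supports the experimental crossing
  forced <- run_policy("positive", "low", cn,
                       strategy_override = "accept_rejection")
  expect_equal(forced$strategy, "accept_rejection")
  expect_true("accept_message" %in% forced$transcript$turn_id)
})

test_that("user answers to the manipulation checks are recorded in the transcript", {
  cn <- concern("money", money_problem_amount = 10)
  run <- run_policy("doubting", "high", cn,
                    user_events = c("high", "doubting", "no"))
  users <- run$transcript[run$transcript$speaker == "user", ]
  expect_equal(users$text[users$turn_id == "severity_check"], "high")
  expect_equal(users$text[users$turn_id == "stance_check"], "doubting")
  expect_false("tips" %in% run$transcript$turn_id)
})
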