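test_that("the profiled ML fit agrees with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  trial <- generate_trial(trial_design(n_participants = 60), seed = 21)
  trial <- trial[-c(3, 50, 101), ]  # unbalance the groups
  f <- fit_lmm(trial, isr ~ situation + strategy)
  lf <- lme4::lmer(
    isr ~ situation + strategy + (1 | participant_id),
    data = transform(trial, situation = factor(situation),
                     strategy = factor(strategy,
                                       levels = c("facilitate", "persuade",
                                                  "accept_rejection"))),
    REML = FALSE,
    contrasts = list(situation = "contr.sum", strategy = "contr.sum"))
  expect_equal(f$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$sigma_p, vc$sdcor[1], tolerance = 1e-4)
  expect_equal(f$sigma_e, vc$sdcor[2], tolerance = 1e-4)
})

test_that("a generator without participant variance yields sigma_p near zero", {
  m <- null_respondent_model(sigma_participant = 0)
  trial <- generate_trial(model = m, seed = 22)
  f <- fit_lmm(trial, isr ~ 1)
  expect_lt(f$sigma_p, 0.15)
})

test_that("rank-deficient designs fail loudly, naming the aliased term", {
  trial <- generate_trial(trial_design(n_participants = 30), seed = 23)
  trial$strategy_copy <- trial$strategy
  expect_error(fit_lmm(trial, isr ~ strategy + strategy_copy),
               "rank deficient.*strategy_copy")
})

test_that("adding fixed terms never decreases the ML log-likelihood", {
  trial <- generate_trial(seed = 24)
  ladder <- list(
    fit_lmm(trial, isr ~ 1),
    fit_lmm(trial, isr ~ situation),
    fit_lmm(trial, isr ~ situation + strategy),
    fit_lmm(trial, isr ~ situation + strategy + situation:strategy)
  )
  lls <- vapply(ladder, function(f) f$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("likelihood-ratio tests follow the chi-square reference and guard nesting", {
  trial <- generate_trial(seed = 25)
  f0 <- fit_lmm(trial, isr ~ 1)
  f1 <- fit_lmm(trial, isr ~ strategy)

  # a fit against itself: nothing gained
  self <- lrt(f0, f0)
  expect_equal(self$chisq, 0)
  expect_equal(self$df, 0L)
  expect_equal(self$p.value, 1)

  # strong true effect: decisively significant
  strong <- generate_trial(model = isr_strategy_model(0.8), seed = 26)
  s0 <- fit_lmm(strong, isr ~ 1)
  s1 <- fit_lmm(strong, isr ~ strategy)
  expect_lt(lrt(s0, s1)$p.value, 0.001)

  # the chi-square reference itself
  expect_lt(pchisq(69.84, 8, lower.tail = FALSE), 0.001)

  # misuse guards
  expect_error(lrt(f1, f0), "nested")
  other_rows <- fit_lmm(trial[1:300, ], isr ~ strategy)
  expect_error(lrt(f0, other_rows), "different numbers of observations")
  expect_error(lrt(f0, fit_lmm(trial, icaa ~ strategy)),
               "different outcomes")
})

test_that("Cohen's w obeys its scale property and input guards", {
  expect_equal(cohen_w(0, 100), 0)
  w <- cohen_w(37.5, 400)
  expect_equal(cohen_w(3 * 37.5, 3 * 400), w)
  expect_equal(w, sqrt(37.5 / 400))
  expect_error(cohen_w(10, 0), "positive")
  expect_error(cohen_w(-1, 10), "non-negative")
})

test_that("the intercept Wald test recovers a known grand mean", {
  m <- null_respondent_model(grand_means = c(isr = 0.8, icaa = 0, fbh = 0))
  trial <- generate_trial(model = m, seed = 27)
  acc <- trial[trial$sit_type == "accept_care" &
                 trial$strategy == "facilitate", ]
  res <- wald_intercept(fit_lmm(acc, isr ~ 1))
  expect_lt(res$p.value, 0.05)
  expect_equal(res$estimate, 0.8, tolerance = 0.35)
  expect_equal(res$f, res$t^2)
  expect_error(wald_intercept(fit_lmm(trial, isr ~ 0 + strategy)),
               "no intercept")
})

test_that("the ordinal mixed fit reduces to an ordinary cumulative-logit fit", {
  skip_if_not_installed("MASS")
  m <- respondent_model(manipulation_model = "ordinal", manip_loading = 1,
                        manip_sigma_p = 0)
  trial <- generate_trial(trial_design(n_participants = 150), m, seed = 28)
  trial$sev_code <- match(trial$severity, c("low", "medium", "high")) - 2
  fc <- fit_clmm(trial, perceived_severity ~ sev_code)
  pol <- MASS::polr(
    factor(perceived_severity, levels = c("low", "medium", "high")) ~ sev_code,
    data = trial)
  # with no true participant variance the mixed fit may spend a little
  # likelihood on sigma, but the slope must agree with the fixed-effect CLM
  expect_gte(fc$loglik, as.numeric(stats::logLik(pol)) - 1e-6)
  expect_equal(unname(fc$beta), unname(stats::coef(pol)), tolerance = 0.15)
  expect_lt(fc$sigma_p, 0.8)
})

test_that("scripted levels predict perceived levels when fidelity is perfect", {
  m <- respondent_model(manipulation_fidelity = 1)
  trial <- generate_trial(trial_design(n_participants = 60), m, seed = 29)
  mc <- manipulation_check(trial)
  expect_equal(mc$df, c(1L, 1L))
  expect_true(all(mc$p.value < 0.001))
  expect_true(all(mc$cohens_w > 0.5))
})

test_that("permuting the scripted levels removes the manipulation effect", {
  m <- respondent_model(manipulation_fidelity = 0.8)
  set.seed(30)
  nonsig <- replicate(60, {
    trial <- generate_trial(trial_design(n_participants = 40), m)
    trial$severity <- sample(trial$severity)  # break the link
    trial$sev_code <- match(trial$severity, c("low", "medium", "high")) - 2
    f0 <- fit_clmm(trial, perceived_severity ~ 1)
    f1 <- fit_clmm(trial, perceived_severity ~ sev_code)
    lrt(f0, f1)$p.value > 0.01
  })
  expect_gte(mean(nonsig), 0.9)
})

test_that("the fitted strategy effects recover the generator truth on average", {
  truth <- 0.4  # persuade-vs-facilitate half-range on the latent ISR scale
  m <- isr_strategy_model(truth, sigma_participant = 0.5, sigma_residual = 1)
  set.seed(31)
  est <- replicate(200, {
    trial <- generate_trial(trial_design(n_participants = 160), m)
    f <- fit_lmm(trial, isr ~ strategy)
    f$beta[["strategy[persuade]"]]
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 2 * mc_se + 0.02)
})

test_that("hypothesis ladders use the prescribed subsets and degrees of freedom", {
  trial <- generate_trial(seed = 32)
  lad <- run_hypothesis_ladders(trial)

  expect_equal(lad$h1$df, rep(c(8L, 2L, 16L), 3))
  expect_true(all(lad$h1$n == 480))

  n_pot <- sum(trial$situation %in% c(1, 2, 5))
  expect_equal(lad$h2$n[1], n_pot)
  n_pa <- sum(trial$situation %in% c(1, 2, 5) &
                trial$strategy %in% c("persuade", "accept_rejection"))
  expect_equal(lad$h2$n[2], n_pa)
  expect_equal(lad$h2$df, c(2L, 1L, 1L))

  expect_equal(lad$h3$n,
               sum(trial$situation %in% c(3, 6, 9) &
                     trial$strategy == "facilitate"))

  n_rej <- sum(trial$situation %in% c(4, 7, 8))
  expect_true(all(lad$h4$n[lad$h4$comparison == "strategy (all three)"] ==
                    n_rej))
  expect_equal(unique(lad$h4$outcome), c("icaa", "fbh"))

  # FBH ladders carry gender as fixed covariate: its null model has more
  # parameters than the ISR null
  f_fbh <- fit_lmm(trial, fbh ~ gender)
  expect_equal(f_fbh$n_params, 5L)  # intercept + 2 gender contrasts + 2 variances
  expect_error(run_hypothesis_ladders(trial[, setdiff(names(trial), "gender")]),
               "missing column")
})

test_that("covariate checks detect a planted gender effect and exclude constants", {
  m <- respondent_model(gender_fbh_shift = c(female = -0.8, male = 0.9,
                                             other = 0))
  trial <- generate_trial(model = m, seed = 33)
  cv <- covariate_checks(trial)
  g_fbh <- cv[cv$covariate == "gender" & cv$outcome == "fbh", ]
  expect_lt(g_fbh$p.value, 0.01)

  trial0 <- generate_trial(model = null_respondent_model(), seed = 34)
  cv0 <- covariate_checks(trial0)
  g0 <- cv0[cv0$covariate == "gender" & cv0$outcome == "fbh", ]
  expect_gt(g0$p.value, 0.001)

  trial$age <- 40
  cva <- covariate_checks(trial)
  expect_true(all(cva$note[cva$covariate == "age"] ==
                    "constant covariate; excluded"))
})

test_that("pseudo-R2 variants are finite and ordered sensibly for a real effect", {
  strong <- generate_trial(model = isr_strategy_model(0.8), seed = 35)
  f0 <- fit_lmm(strong, isr ~ 1)
  f1 <- fit_lmm(strong, isr ~ strategy)
  r2 <- pseudo_r2(f0, f1)
  expect_true(is.finite(r2$mcfadden) && is.finite(r2$nagelkerke))
  expect_gt(r2$mcfadden, 0)
  expect_gt(r2$nagelkerke, 0)
  expect_lte(r2$nagelkerke, 1)
})

test_that("broom-style accessors return tidy tibbles", {
  trial <- generate_trial(trial_design(n_participants = 40), seed = 36)
  f <- fit_lmm(trial, isr ~ strategy)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  expect_equal(nrow(td), 3)
  gl <- glance(f)
  expect_equal(gl$n_obs, 120)
  expect_equal(gl$n_params, 5)

  trial$sev_code <- match(trial$severity, c("low", "medium", "high")) - 2
  fc <- fit_clmm(trial, perceived_severity ~ sev_code)
  expect_true(all(c("threshold", "fixed") %in% tidy(fc)$type))
  expect_true(glance(fc)$converged)
})
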