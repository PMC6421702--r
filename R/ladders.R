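#' Run the four hypothesis ladders of the referral-strategy experiment
#'
#' Reproduces the experiment's analysis plan as nested random-intercept
#' model ladders compared by likelihood ratio, one ladder per hypothesis:
#'
#' * **H1** (personalisation matters): on all data and each outcome (ISR,
#'   ICAA, FBH), null model (intercept + random intercept; for FBH also
#'   gender as fixed covariate), then situation (8 df), strategy (2 df), and
#'   the situation-by-strategy interaction on top of both mains (16 df).
#' * **H2** (persuasion works where there is care potential): ISR on the
#'   care-potential situations (grid ids 1, 2, 5); strategy overall (2 df),
#'   then the pairwise subsets persuade vs accept-rejection and persuade vs
#'   facilitate (1 df each).
#' * **H3** (facilitation suffices when care is accepted): on the
#'   accept-care situations (ids 3, 6, 9) under the facilitate strategy,
#'   the null-model intercept is tested against the neutral score 0 by a
#'   Wald test ([wald_intercept()]).
#' * **H4** (accepting rejection preserves the relationship): ICAA and FBH
#'   on the reject-care situations (ids 4, 7, 8); strategy overall, then
#'   accept-rejection vs persuade and accept-rejection vs facilitate.
#'
#' @param data Long-format trial data with columns `situation`, `sit_type`,
#'   `strategy`, `isr`, `icaa`, `fbh`, `gender`, and the grouping column.
#' @param group Grouping column name.
#' @return An object of class `mh_ladders`: a list of tibbles `h1`, `h2`,
#'   `h3`, `h4` (LRT rows carry `hypothesis`, `outcome`, `comparison`, `n`,
#'   `chisq`, `df`, `p.value`, `cohens_w`).
#' @examples
#' trial <- generate_trial(seed = 1)
#' run_hypothesis_ladders(trial)
#' @export
run_hypothesis_ladders <- function(data, group = "participant_id") {
  required <- c("situation", "sit_type", "strategy", "isr", "icaa", "fbh",
                "gender", group)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Trial data is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }

  base_terms <- function(outcome) if (outcome == "fbh") "gender" else "1"
  ladder_fit <- function(d, outcome, terms) {
    fit_lmm(d, stats::reformulate(terms, response = outcome), group = group)
  }
  strategy_lrt <- function(d, outcome, label, hypothesis) {
    m0 <- ladder_fit(d, outcome, base_terms(outcome))
    m1 <- ladder_fit(d, outcome, c(base_terms(outcome), "strategy"))
    dplyr::bind_cols(tibble(hypothesis = hypothesis, outcome = outcome,
                            comparison = label), lrt(m0, m1))
  }
  pair_subset <- function(d, strategies) {
    d[d$strategy %in% strategies, , drop = FALSE]
  }

  # H1 -----------------------------------------------------------------
  h1 <- purrr::map_dfr(c("isr", "icaa", "fbh"), function(o) {
    m0 <- ladder_fit(data, o, base_terms(o))
    m1 <- ladder_fit(data, o, c(base_terms(o), "situation"))
    m2 <- ladder_fit(data, o, c(base_terms(o), "strategy"))
    m3 <- ladder_fit(data, o, c(base_terms(o), "situation", "strategy"))
    m4 <- ladder_fit(data, o, c(base_terms(o), "situation", "strategy",
                                "situation:strategy"))
    dplyr::bind_rows(
      dplyr::bind_cols(tibble(hypothesis = "H1", outcome = o,
                              comparison = "situation (M0 vs M1)"),
                       lrt(m0, m1)),
      dplyr::bind_cols(tibble(hypothesis = "H1", outcome = o,
                              comparison = "strategy (M0 vs M2)"),
                       lrt(m0, m2)),
      dplyr::bind_cols(tibble(hypothesis = "H1", outcome = o,
                              comparison = "situation x strategy (M3 vs M4)"),
                       lrt(m3, m4))
    )
  })

  # H2 -----------------------------------------------------------------
  pot <- data[data$sit_type == "care_potential", , drop = FALSE]
  h2 <- dplyr::bind_rows(
    strategy_lrt(pot, "isr", "strategy (all three)", "H2"),
    strategy_lrt(pair_subset(pot, c("persuade", "accept_rejection")),
                 "isr", "persuade vs accept_rejection", "H2"),
    strategy_lrt(pair_subset(pot, c("persuade", "facilitate")),
                 "isr", "persuade vs facilitate", "H2")
  )

  # H3 -----------------------------------------------------------------
  acc <- data[data$sit_type == "accept_care" &
                data$strategy == "facilitate", , drop = FALSE]
  h3 <- dplyr::bind_cols(
    tibble(hypothesis = "H3", outcome = "isr",
           comparison = "null intercept vs neutral 0"),
    wald_intercept(ladder_fit(acc, "isr", "1"))
  )

  # H4 -----------------------------------------------------------------
  rej <- data[data$sit_type == "reject_care", , drop = FALSE]
  h4 <- purrr::map_dfr(c("icaa", "fbh"), function(o) {
    dplyr::bind_rows(
      strategy_lrt(rej, o, "strategy (all three)", "H4"),
      strategy_lrt(pair_subset(rej, c("accept_rejection", "persuade")),
                   o, "accept_rejection vs persuade", "H4"),
      strategy_lrt(pair_subset(rej, c("accept_rejection", "facilitate")),
                   o, "accept_rejection vs facilitate", "H4")
    )
  })

  structure(list(h1 = h1, h2 = h2, h3 = h3, h4 = h4),
            class = "mh_ladders")
}

#' @export
print.mh_ladders <- function(x, ...) {
  cat("<mh_ladders> likelihood-ratio model comparisons\n")
  for (h in c("h1", "h2", "h4")) {
    cat("\n", toupper(h), ":\n", sep = "")
    print(as.data.frame(x[[h]][c("outcome", "comparison", "n", "chisq",
                                 "df", "p.value")]), digits = 4)
  }
  cat("\nH3 (intercept vs neutral 0):\n")
  print(as.data.frame(x$h3[c("estimate", "std.error", "f", "df1", "df2",
                             "p.value", "n")]), digits = 4)
  invisible(x)
}

#' @rdname tidy.mh_lmm
#' @export
tidy.mh_ladders <- function(x, ...) {
  dplyr::bind_rows(x$h1, x$h2, x$h4)
}

#' Covariate checks for the trial outcomes
#'
#' Tests, within the random-intercept framework, whether each participant
#' covariate (age, gender, ISI score, main concern) adds to a null model of
#' each outcome, by likelihood ratio. Covariates that are constant in the
#' data are excluded with a diagnostic note instead of being fit.
#'
#' @inheritParams run_hypothesis_ladders
#' @param covariates Covariate column names to test.
#' @param outcomes Outcome column names.
#' @return Tibble: `covariate`, `outcome`, `n`, `chisq`, `df`, `p.value`,
#'   `note`.
#' @export
covariate_checks <- function(data,
                             covariates = c("age", "gender", "isi_total",
                                            "concern"),
                             outcomes = c("isr", "icaa", "fbh"),
                             group = "participant_id") {
  missing_cols <- setdiff(c(covariates, outcomes, group), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Data is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(covariate = covariates, outcome = outcomes)
  purrr::pmap_dfr(grid, function(covariate, outcome) {
    if (dplyr::n_distinct(data[[covariate]]) < 2L) {
      return(tibble(covariate = covariate, outcome = outcome,
                    n = NA_integer_, chisq = NA_real_, df = NA_integer_,
                    p.value = NA_real_,
                    note = "constant covariate; excluded"))
    }
    m0 <- fit_lmm(data, stats::reformulate("1", response = outcome),
                  group = group)
    m1 <- fit_lmm(data, stats::reformulate(covariate, response = outcome),
                  group = group)
    res <- lrt(m0, m1)
    tibble(covariate = covariate, outcome = outcome, n = res$n,
           chisq = res$chisq, df = res$df, p.value = res$p.value,
           note = NA_character_)
  })
}
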