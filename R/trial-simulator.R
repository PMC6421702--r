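#' Configure the synthetic referral-strategy trial design
#'
#' Describes the within-subject 3 (stance) x 3 (severity) x 3 (agent
#' strategy) experiment: each participant reads several imagined sleeping-
#' problem scenarios and chats with a virtual agent that plays one referral
#' strategy per scenario. Defaults reproduce the reported study conditions:
#' 160 participants, 3 scenario-chats each, and the observed distribution of
#' the main concern about seeking care (money 128/160, travel time 15/160,
#' social stigma 17/160).
#'
#' Two crossings are available. `full_27` crosses all 9 situations with all
#' 3 strategies. `restricted` drops the six cells pairing accept-care
#' situations (ids 3, 6, 9) with a non-facilitate strategy, leaving 21
#' combinations — the crossing implied where only 21 combinations are in
#' play; both are provided because the design descriptions are ambiguous on
#' this point.
#'
#' @param n_participants Number of participants (default 160).
#' @param scenarios_per_participant Scenario-chats per participant (default
#'   3); must not exceed the number of available combinations.
#' @param crossing `"full_27"` or `"restricted"`.
#' @param concern_probs Named probabilities over `money`, `time`, `stigma`;
#'   must sum to 1.
#' @param gender_probs Named probabilities over `female`, `male`, `other`
#'   (defaults 91/160, 67/160, 2/160).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_participants = 160L,
                         scenarios_per_participant = 3L,
                         crossing = c("full_27", "restricted"),
                         concern_probs = c(money = 128, time = 15,
                                           stigma = 17) / 160,
                         gender_probs = c(female = 91, male = 67,
                                          other = 2) / 160) {
  crossing <- match.arg(crossing)
  stopifnot(n_participants >= 1, scenarios_per_participant >= 1)
  if (abs(sum(concern_probs) - 1) > 1e-9) {
    abort("`concern_probs` must sum to 1.")
  }
  if (!setequal(names(concern_probs), .mh_levels$concern)) {
    abort("`concern_probs` must be named money/time/stigma.")
  }
  if (abs(sum(gender_probs) - 1) > 1e-9) {
    abort("`gender_probs` must sum to 1.")
  }
  cells <- crossing_cells(crossing)
  if (scenarios_per_participant > nrow(cells)) {
    abort(sprintf(
      "scenarios_per_participant (%d) exceeds the %d available combinations.",
      scenarios_per_participant, nrow(cells)))
  }
  structure(
    list(n_participants = as.integer(n_participants),
         scenarios_per_participant = as.integer(scenarios_per_participant),
         crossing = crossing,
         concern_probs = concern_probs[.mh_levels$concern],
         gender_probs = gender_probs[c("female", "male", "other")]),
    class = "trial_design"
  )
}

crossing_cells <- function(crossing) {
  cells <- tidyr::expand_grid(situation = 1:9,
                              strategy = .mh_levels$strategy)
  if (crossing == "restricted") {
    grid <- situation_grid()
    accept <- grid$id[grid$sit_type == "accept_care"]
    cells <- cells[!(cells$situation %in% accept &
                       cells$strategy != "facilitate"), ]
  }
  cells
}

default_strategy_effects <- function() {
  m <- rbind(facilitate       = c(isr =  0.10, icaa = -0.25, fbh = -0.30),
             persuade         = c(isr =  0.30, icaa =  0.15, fbh =  0.25),
             accept_rejection = c(isr = -0.40, icaa =  0.10, fbh =  0.05))
  m
}

default_situation_effects <- function() {
  grid <- situation_grid()
  stance_eff <- list(
    isr = c(negative = -0.4, doubting = 0, positive = 0.4),
    icaa = c(negative = -0.1, doubting = 0, positive = 0.1),
    fbh = c(negative = -0.1, doubting = 0, positive = 0.1))
  sev_eff <- list(
    isr = c(low = -0.3, medium = 0, high = 0.3),
    icaa = c(low = -0.1, medium = 0, high = 0.1),
    fbh = c(low = 0, medium = 0, high = 0))
  m <- sapply(c("isr", "icaa", "fbh"), function(o) {
    stance_eff[[o]][as.character(grid$stance)] +
      sev_eff[[o]][as.character(grid$severity)]
  })
  rownames(m) <- grid$id
  m
}

#' Configure the respondent model of the trial generator
#'
#' The generator draws, for each participant and outcome, a random intercept
#' around a grand mean, adds situation and strategy effects (optionally an
#' interaction) on a continuous latent centred 7-point scale, and
#' discretises by rounding and clamping to -3..3. Defaults are calibrated to
#' the reported study conditions: grand means at the observed centred means
#' (ISR 0.76, ICAA -0.03, FBH 0.79), effect patterns that qualitatively
#' mirror the reported strategy and situation contrasts, and variance
#' components giving overall outcome SDs near the reported 1.7-2.0.
#'
#' @param grand_means Named numeric `c(isr=, icaa=, fbh=)` baselines on the
#'   centred scale.
#' @param situation_effects 9 x 3 matrix (situations x outcomes), columns
#'   sum-to-zero, or the scalar `0` for no situation effects.
#' @param strategy_effects 3 x 3 matrix (strategies x outcomes), columns
#'   sum-to-zero, or the scalar `0`.
#' @param interaction Optional list of 9 x 3 (situation x strategy)
#'   matrices, one per outcome, or `NULL` for none.
#' @param sigma_participant Random-intercept SD (per outcome).
#' @param sigma_residual Residual SD of the latent outcome.
#' @param fbh_item_sd Item-level noise SD around the latent FBH score; 0.8
#'   gives the scale an internal consistency near the reported alpha of
#'   0.93-0.97.
#' @param manipulation_fidelity Probability that a respondent reports the
#'   scripted severity/stance level on the manipulation check; otherwise a
#'   uniformly chosen other level.
#' @param manipulation_model `"fidelity"` (categorical misreport model) or
#'   `"ordinal"` (latent ordinal-threshold model with participant intercept,
#'   for cumulative-link model testing).
#' @param manip_loading,manip_sigma_p Ordinal manipulation model: loading of
#'   the scripted level (coded -1, 0, 1) on the latent report, and the
#'   participant-intercept SD.
#' @param gender_fbh_shift Named per-gender offsets added to the FBH latent
#'   score (the one covariate effect the study reported); offsets are
#'   approximately centred under the default gender distribution.
#' @param age_mean,age_sd Participant age distribution.
#' @param isi_mean,isi_sd Participant-level ISI total distribution used to
#'   seed the seven simulated 0-4 ISI items.
#' @return An object of class `respondent_model`.
#' @export
respondent_model <- function(grand_means = c(isr = 0.76, icaa = -0.03,
                                             fbh = 0.79),
                             situation_effects = default_situation_effects(),
                             strategy_effects = default_strategy_effects(),
                             interaction = NULL,
                             sigma_participant = 0.9,
                             sigma_residual = 1.55,
                             fbh_item_sd = 0.8,
                             manipulation_fidelity = 0.8,
                             manipulation_model = c("fidelity", "ordinal"),
                             manip_loading = 2,
                             manip_sigma_p = 1,
                             gender_fbh_shift = c(female = -0.25,
                                                  male = 0.36,
                                                  other = -0.50),
                             age_mean = 36, age_sd = 10.41,
                             isi_mean = 17, isi_sd = 6.53) {
  manipulation_model <- match.arg(manipulation_model)
  outcomes <- c("isr", "icaa", "fbh")
  expand_zero <- function(x, nrow, rows) {
    if (identical(x, 0) || identical(x, 0L)) {
      x <- matrix(0, nrow, 3, dimnames = list(rows, outcomes))
    }
    x
  }
  situation_effects <- expand_zero(situation_effects, 9, as.character(1:9))
  strategy_effects <- expand_zero(strategy_effects, 3, .mh_levels$strategy)
  check_effects <- function(m, nrow, what) {
    if (!is.matrix(m) || nrow(m) != nrow || ncol(m) != 3) {
      abort(sprintf("`%s` must be a %d x 3 matrix.", what, nrow))
    }
    if (any(abs(colSums(m)) > 1e-8)) {
      abort(sprintf("`%s` columns must sum to zero.", what))
    }
  }
  check_effects(situation_effects, 9, "situation_effects")
  check_effects(strategy_effects, 3, "strategy_effects")
  stopifnot(sigma_participant >= 0, sigma_residual >= 0, fbh_item_sd >= 0,
            manipulation_fidelity >= 0, manipulation_fidelity <= 1)
  stopifnot(setequal(names(grand_means), outcomes))
  structure(
    list(grand_means = grand_means[outcomes],
         situation_effects = situation_effects,
         strategy_effects = strategy_effects,
         interaction = interaction,
         sigma_participant = sigma_participant,
         sigma_residual = sigma_residual,
         fbh_item_sd = fbh_item_sd,
         manipulation_fidelity = manipulation_fidelity,
         manipulation_model = manipulation_model,
         manip_loading = manip_loading,
         manip_sigma_p = manip_sigma_p,
         gender_fbh_shift = gender_fbh_shift,
         age_mean = age_mean, age_sd = age_sd,
         isi_mean = isi_mean, isi_sd = isi_sd),
    class = "respondent_model"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

discretize_centered <- function(latent) clamp(round(latent), -3, 3)

#' Generate a synthetic referral-strategy trial dataset
#'
#' Produces a long-format dataset with one row per scenario-chat: the
#' situation (stance, severity, grid id, type), the agent strategy played,
#' the raw and centred outcome responses (ISR, ICAA, the seven FBH items and
#' their scale score), the three-option manipulation-check answers, and the
#' participant covariates (gender, age, ISI, main concern). Each participant
#' contributes `scenarios_per_participant` distinct (situation, strategy)
#' combinations sampled uniformly without replacement from the design's
#' crossing. The dataset is byte-reproducible from `seed`.
#'
#' @param design A [trial_design()].
#' @param model A [respondent_model()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A tibble of class `mh_trial` with one row per scenario-chat.
#' @examples
#' trial <- generate_trial(seed = 1)
#' dplyr::count(trial, strategy)
#' @export
generate_trial <- function(design = trial_design(),
                           model = respondent_model(),
                           seed = NULL) {
  stopifnot(inherits(design, "trial_design"),
            inherits(model, "respondent_model"))
  if (!is.null(seed)) set.seed(seed)
  np <- design$n_participants
  spp <- design$scenarios_per_participant
  cells <- crossing_cells(design$crossing)
  grid <- situation_grid()
  outcomes <- c("isr", "icaa", "fbh")

  # participant-level draws
  gender <- sample(names(design$gender_probs), np, replace = TRUE,
                   prob = design$gender_probs)
  age <- round(clamp(rnorm(np, model$age_mean, model$age_sd), 18, 90))
  concern <- sample(names(design$concern_probs), np, replace = TRUE,
                    prob = design$concern_probs)
  isi_latent <- clamp(rnorm(np, model$isi_mean, model$isi_sd), 0, 28)
  isi_items <- vapply(1:7, function(i)
    clamp(round(isi_latent / 7 + rnorm(np, 0, 0.6)), 0, 4), numeric(np))
  isi_total <- rowSums(matrix(isi_items, nrow = np))
  intercepts <- matrix(rnorm(np * 3, 0, model$sigma_participant), np, 3,
                       dimnames = list(NULL, outcomes))
  manip_u <- rnorm(np, 0, model$manip_sigma_p)

  # distinct (situation, strategy) cells per participant, then one flat table
  picks <- vapply(seq_len(np),
                  function(p) sample.int(nrow(cells), spp), integer(spp))
  idx <- as.vector(matrix(picks, nrow = spp))
  pid <- rep(seq_len(np), each = spp)
  N <- length(idx)
  situation <- cells$situation[idx]
  strategy <- cells$strategy[idx]
  sit <- grid[situation, ]
  strat_idx <- match(strategy, .mh_levels$strategy)

  lat <- vapply(outcomes, function(o) {
    mu <- model$grand_means[[o]] +
      model$situation_effects[situation, o] +
      model$strategy_effects[strat_idx, o] +
      intercepts[cbind(pid, match(o, outcomes))]
    if (!is.null(model$interaction)) {
      mu <- mu + model$interaction[[o]][cbind(situation, strat_idx)]
    }
    if (o == "fbh") {
      mu <- mu + model$gender_fbh_shift[gender[pid]]
    }
    unname(mu + rnorm(N, 0, model$sigma_residual))
  }, numeric(N))

  fbh_items <- vapply(1:7, function(i)
    clamp(round(lat[, "fbh"] + rnorm(N, 0, model$fbh_item_sd) + 4), 1, 7),
    numeric(N))
  fbh_items <- matrix(fbh_items, nrow = N,
                      dimnames = list(NULL, paste0("fbh_", 1:7)))

  trial <- dplyr::bind_cols(
    tibble(
      participant_id = pid,
      scenario_index = rep(seq_len(spp), np),
      situation = situation,
      stance = as.character(sit$stance),
      severity = as.character(sit$severity),
      sit_type = as.character(sit$sit_type),
      strategy = strategy,
      concern = concern[pid], gender = gender[pid], age = age[pid],
      isi_total = isi_total[pid],
      isr_raw = discretize_centered(lat[, "isr"]) + 4,
      icaa_raw = discretize_centered(lat[, "icaa"]) + 4
    ),
    as_tibble(fbh_items),
    tibble(
      perceived_severity = manip_answer(as.character(sit$severity),
                                        .mh_levels$severity, model,
                                        manip_u[pid]),
      perceived_stance = manip_answer(as.character(sit$stance),
                                      .mh_levels$stance, model,
                                      manip_u[pid])
    )
  )
  trial$isr <- center_likert(trial$isr_raw)
  trial$icaa <- center_likert(trial$icaa_raw)
  trial$fbh <- score_fbh(trial[paste0("fbh_", 1:7)])
  class(trial) <- c("mh_trial", class(trial))
  trial
}

# one manipulation-check answer per scenario row: either the scripted level
# with probability `manipulation_fidelity` (else a uniform other level), or
# under the ordinal model a thresholded latent report with participant
# intercept u.
manip_answer <- function(scripted, levels, model, u) {
  n <- length(scripted)
  coded <- match(scripted, levels)
  if (model$manipulation_model == "fidelity") {
    faithful <- runif(n) < model$manipulation_fidelity
    offset <- sample(1:2, n, replace = TRUE)
    reported <- ifelse(faithful, coded, (coded - 1 + offset) %% 3 + 1)
  } else {
    z <- model$manip_loading * (coded - 2) + u + rnorm(n, 0, 1)
    reported <- findInterval(z, c(-model$manip_loading,
                                  model$manip_loading)) + 1
  }
  levels[reported]
}

#' Summarise a trial dataset
#'
#' Descriptive statistics in the layout of a participant-characteristics
#' table: centred outcome means and SDs, the concern distribution, ISI
#' severity bands and the gender split (participant-level where
#' appropriate).
#'
#' @param data A trial tibble from [generate_trial()] or
#'   [read_trial_csv()].
#' @return An object of class `mh_trial_summary`: a list of tibbles
#'   `outcomes`, `concern`, `isi`, `gender`.
#' @export
summarize_trial <- function(data) {
  outcomes <- intersect(c("isr", "icaa", "fbh"), names(data))
  out <- purrr::map_dfr(outcomes, function(o) {
    tibble(outcome = o, mean = mean(data[[o]]), sd = sd(data[[o]]))
  })
  participants <- dplyr::distinct(
    data, .data$participant_id, .keep_all = TRUE)
  concern_tab <- dplyr::count(participants, .data$concern)
  concern_tab$pct <- 100 * concern_tab$n / sum(concern_tab$n)
  isi_tab <- NULL
  if ("isi_total" %in% names(data)) {
    bands <- score_isi(matrix(0, 1, 7))  # reuse default labels
    cat_lv <- levels(bands$category)
    cats <- cat_lv[findInterval(participants$isi_total, c(0, 8, 15, 22))]
    isi_tab <- dplyr::count(tibble(category = factor(cats, cat_lv)),
                            .data$category, .drop = FALSE)
    isi_tab$pct <- 100 * isi_tab$n / sum(isi_tab$n)
  }
  gender_tab <- NULL
  if ("gender" %in% names(data)) {
    gender_tab <- dplyr::count(participants, .data$gender)
    gender_tab$pct <- 100 * gender_tab$n / sum(gender_tab$n)
  }
  structure(list(outcomes = out, concern = concern_tab, isi = isi_tab,
                 gender = gender_tab, n_participants = nrow(participants),
                 n_obs = nrow(data)),
            class = "mh_trial_summary")
}

#' @export
print.mh_trial_summary <- function(x, ...) {
  cat("<mh_trial_summary> ", x$n_participants, " participants, ",
      x$n_obs, " scenario-chats\n\nCentred outcomes:\n", sep = "")
  print(x$outcomes)
  cat("\nMain concern (participants):\n"); print(x$concern)
  if (!is.null(x$isi)) { cat("\nISI severity:\n"); print(x$isi) }
  if (!is.null(x$gender)) { cat("\nGender:\n"); print(x$gender) }
  invisible(x)
}

#' Read or write a trial dataset as CSV
#'
#' The on-disk schema is the long format produced by [generate_trial()]:
#' one row per scenario-chat. `col_map` renames external columns into that
#' schema (e.g. for a deposited dataset whose headers differ), and centred
#' outcome scores are recomputed from the raw responses when absent.
#'
#' @param path CSV path.
#' @param col_map Named character vector `c(internal = "external", ...)`.
#' @return A trial tibble.
#' @export
read_trial_csv <- function(path, col_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw)) {
        abort(sprintf("Mapped column '%s' not found in %s.",
                      col_map[[nm]], path))
      }
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  trial <- as_tibble(raw)
  if (!"isr" %in% names(trial) && "isr_raw" %in% names(trial)) {
    trial$isr <- center_likert(trial$isr_raw)
  }
  if (!"icaa" %in% names(trial) && "icaa_raw" %in% names(trial)) {
    trial$icaa <- center_likert(trial$icaa_raw)
  }
  if (!"fbh" %in% names(trial) && all(paste0("fbh_", 1:7) %in% names(trial))) {
    trial$fbh <- score_fbh(trial[paste0("fbh_", 1:7)])
  }
  class(trial) <- c("mh_trial", class(trial))
  trial
}

#' @rdname read_trial_csv
#' @param data Trial tibble to write.
#' @export
write_trial_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
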