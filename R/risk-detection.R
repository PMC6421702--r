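#' Build a detection session from typed observations
#'
#' A session is the ordered stream of observations the detection engine
#' consumes: free-text utterances, answers to screening questions,
#' questionnaire totals, and duration/severity/progression ratings. Each
#' helper returns a one-row tibble; `session()` binds them in order.
#'
#' @param ... One-row observation tibbles, in session order.
#' @return A session tibble with columns `type`, `text`, `question`, `answer`,
#'   `total`, `duration`, `severity`, `progression`.
#' @examples
#' session(
#'   session_utterance("I have not slept properly for months"),
#'   session_rating("long", "medium", "stable")
#' )
#' @export
session <- function(...) {
  obs <- list(...)
  if (length(obs) == 0L) return(empty_session())
  dplyr::bind_rows(empty_session(), !!!obs)
}

empty_session <- function() {
  tibble(
    type = character(), text = character(), question = character(),
    answer = character(), total = double(), duration = character(),
    severity = character(), progression = character()
  )
}

#' @rdname session
#' @param text Free-text utterance.
#' @export
session_utterance <- function(text) {
  tibble(type = "utterance", text = as.character(text))
}

#' @rdname session
#' @param question Screening question id (must exist in the profile).
#' @param answer The answer given.
#' @export
session_answer <- function(question, answer) {
  tibble(type = "screening_answer", question = as.character(question),
         answer = as.character(answer))
}

#' @rdname session
#' @param total Questionnaire total score.
#' @export
session_questionnaire <- function(total) {
  tibble(type = "questionnaire", total = as.numeric(total))
}

#' @rdname session
#' @param duration,severity,progression Factor levels for the DSP rating
#'   (`short`/`medium`/`long`, `low`/`medium`/`high`,
#'   `improving`/`stable`/`worsening`).
#' @export
session_rating <- function(duration, severity, progression) {
  tibble(
    type = "factor_rating",
    duration = .match_level(duration, "duration"),
    severity = .match_level(severity, "severity"),
    progression = .match_level(progression, "progression")
  )
}

#' Screen free text against a risk lexicon
#'
#' Step 1 of the detection protocol for systems with free-text input: scan an
#' utterance for the profile's keywords and phrases. Matching is
#' case-insensitive at word boundaries; every occurrence of every pattern
#' yields one signal, ordered by match position then pattern.
#'
#' @param text A single character string (possibly empty).
#' @param profile A [risk_profile()].
#' @return Tibble of risk signals with columns `profile`, `source`
#'   (`"text_match"`), `evidence` (the matched text) and `position`
#'   (character offset of the match).
#' @examples
#' prof <- risk_profile("suicide", lexicon = c("end my life", "no way out"))
#' screen_text("Some days I feel there is no way out", prof)
#' @export
screen_text <- function(text, profile) {
  stopifnot(inherits(profile, "risk_profile"))
  text <- as.character(text)
  if (length(text) != 1L || is.na(text)) abort("`text` must be a single string.")
  hits <- purrr::map_dfr(profile$lexicon, function(pattern) {
    rx <- paste0("\\b", escape_regex(pattern), "\\b")
    m <- gregexpr(rx, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    tibble(
      evidence = substring(text, m, m + attr(m, "match.length") - 1L),
      position = as.integer(m),
      pattern = pattern
    )
  })
  if (nrow(hits) == 0L) return(empty_signals(profile))
  hits <- dplyr::arrange(hits, .data$position, .data$pattern)
  tibble(profile = profile$risk_name, source = "text_match",
         evidence = hits$evidence, position = hits$position)
}

escape_regex <- function(x) gsub("([.\\\\|()\\[\\]{}^$*+?-])", "\\\\\\1", x, perl = TRUE)

empty_signals <- function(profile) {
  tibble(profile = character(), source = character(),
         evidence = character(), position = integer())
}

#' Screen closed-question answers for risk indications
#'
#' Step 1 of the detection protocol for systems without free-text input:
#' compare answers to the profile's screening questions against each
#' question's risk-indicating answer set.
#'
#' @param answers Named character vector or list mapping question id to the
#'   answer given. Every id must be configured in the profile.
#' @inheritParams screen_text
#' @return Tibble of risk signals (`source = "screening_answer"`, `evidence`
#'   is the question id, `position` the answer's index).
#' @examples
#' prof <- risk_profile("suicide", lexicon = "end my life",
#'                      screening_questions = list(q_harm = c("yes")))
#' screen_answers(c(q_harm = "yes"), prof)
#' @export
screen_answers <- function(answers, profile) {
  stopifnot(inherits(profile, "risk_profile"))
  answers <- unlist(answers)
  if (length(answers) == 0L) return(empty_signals(profile))
  ids <- names(answers)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("`answers` must be named by question id.")
  }
  unknown <- setdiff(ids, names(profile$screening_questions))
  if (length(unknown)) {
    abort(sprintf("Unknown screening question id(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  flagged <- purrr::imap_lgl(
    as.list(answers),
    function(ans, id) ans %in% profile$screening_questions[[id]]
  )
  if (!any(flagged)) return(empty_signals(profile))
  tibble(profile = profile$risk_name, source = "screening_answer",
         evidence = ids[flagged], position = which(flagged))
}

#' Questionnaire threshold rule
#'
#' Step 2 of the detection protocol when a validated severity questionnaire
#' exists for the risk: refer when the total reaches the configured cutoff.
#' The comparison is inclusive (`total >= threshold`), the conservative
#' choice when a protocol states only "a threshold".
#'
#' @param total Numeric questionnaire total.
#' @param threshold Numeric referral cutoff (must be configured).
#' @return `TRUE` if the total warrants referral.
#' @export
questionnaire_refer <- function(total, threshold) {
  if (is.null(threshold) || length(threshold) != 1L || is.na(threshold)) {
    abort("No questionnaire threshold configured for this profile.")
  }
  stopifnot(is.numeric(total), length(total) == 1L, !is.na(total))
  total >= threshold
}

#' Count negative duration/severity/progression factors
#'
#' @param rating Named list or one-row tibble with one entry per configured
#'   factor (by default `duration`, `severity`, `progression`).
#' @param factor_map Factor-level map as in [default_factor_map()].
#' @return Integer count of factors whose level maps to negative.
#' @examples
#' count_negatives(list(duration = "long", severity = "high",
#'                      progression = "improving"))
#' @export
count_negatives <- function(rating, factor_map = default_factor_map()) {
  check_factor_map(factor_map)
  rating <- as.list(rating)
  neg <- vapply(names(factor_map), function(f) {
    level <- as.character(rating[[f]])
    if (length(level) != 1L || is.na(level) || !level %in% names(factor_map[[f]])) {
      abort(sprintf("Level '%s' of factor '%s' is not mapped in `factor_map`.",
                    if (length(level)) level else "<missing>", f))
    }
    factor_map[[f]][[level]]
  }, logical(1))
  sum(neg)
}

#' Duration/severity/progression referral rule
#'
#' Step 2 of the detection protocol when no questionnaire threshold exists:
#' refer when at least `k` of the `n` situation factors are negative. The
#' protocol's default guideline is 2 of 3 (a long-standing, severe, or
#' worsening situation on at least two counts).
#'
#' @inheritParams count_negatives
#' @param rule Integer `c(k, n)` rule; default `c(2, 3)`.
#' @return A list with `refer` (logical), `negatives` (count) and
#'   `fired_rule` (`"k_of_n_factors"` when referring, else `"none"`).
#' @examples
#' dsp_refer(list(duration = "long", severity = "high", progression = "stable"))
#' @export
dsp_refer <- function(rating, rule = c(2L, 3L),
                      factor_map = default_factor_map()) {
  rule <- as.integer(rule)
  if (length(rule) != 2L || rule[1] < 1L || rule[1] > rule[2]) {
    abort("`rule` must be c(k, n) with 1 <= k <= n.")
  }
  negatives <- count_negatives(rating, factor_map)
  refer <- negatives >= rule[1]
  list(refer = refer, negatives = negatives,
       fired_rule = if (refer) "k_of_n_factors" else "none")
}

#' Run the two-step risk-detection protocol over a session
#'
#' Processes a session stream in order. Step 1 collects risk signals from
#' text screening and screening-question answers. Step 2 decides severity:
#' when a questionnaire total is available (and, if the profile is gated, was
#' observed after at least one step-1 signal) the threshold rule decides;
#' otherwise the most recent DSP factor rating decides via the k-of-n rule.
#' With signals but no usable severity information the outcome is
#' `possible_risk`. A questionnaire total observed before any signal on a
#' gated profile is ignored and flagged as a gating violation in the trace.
#'
#' @param session A session tibble built with [session()] or read with
#'   [read_session_jsonl()].
#' @param profile A [risk_profile()].
#' @return An object of class `mh_detection` with fields `outcome`
#'   (`no_risk`/`possible_risk`/`refer`), `fired_rule`
#'   (`questionnaire_threshold`/`k_of_n_factors`/`none`), `negatives`,
#'   `signals` (tibble) and `trace` (tibble, one row per check in order).
#' @examples
#' prof <- risk_profile("suicide", lexicon = "end my life",
#'                      questionnaire_id = "phq9_item9",
#'                      questionnaire_threshold = 2)
#' sess <- session(
#'   session_utterance("sometimes I want to end my life"),
#'   session_questionnaire(3)
#' )
#' run_detection(sess, prof)
#' @export
run_detection <- function(session, profile) {
  stopifnot(inherits(profile, "risk_profile"), is.data.frame(session))
  signals <- empty_signals(profile)
  trace <- list()
  quest_total <- NULL
  rating <- NULL
  add_trace <- function(position, check, detail, result) {
    trace[[length(trace) + 1L]] <<-
      tibble(position = position, check = check, detail = detail,
             result = result)
  }
  for (i in seq_len(nrow(session))) {
    obs <- session[i, ]
    switch(obs$type,
      utterance = {
        s <- screen_text(obs$text, profile)
        if (nrow(s)) s$position <- rep(i, nrow(s))
        signals <- dplyr::bind_rows(signals, s)
        add_trace(i, "text_screen", obs$text,
                  sprintf("%d signal(s)", nrow(s)))
      },
      screening_answer = {
        ans <- stats::setNames(obs$answer, obs$question)
        s <- screen_answers(ans, profile)
        if (nrow(s)) s$position <- rep(i, nrow(s))
        signals <- dplyr::bind_rows(signals, s)
        add_trace(i, "answer_screen", obs$question,
                  sprintf("%d signal(s)", nrow(s)))
      },
      questionnaire = {
        if (profile$questionnaire_gated && nrow(signals) == 0L) {
          add_trace(i, "gating_violation",
                    "questionnaire total before any step-1 signal",
                    "total ignored")
        } else {
          quest_total <- obs$total
          add_trace(i, "questionnaire", sprintf("total=%g", obs$total),
                    "recorded")
        }
      },
      factor_rating = {
        rating <- list(duration = obs$duration, severity = obs$severity,
                       progression = obs$progression)
        add_trace(i, "factor_rating",
                  paste(obs$duration, obs$severity, obs$progression,
                        sep = "/"), "recorded")
      },
      abort(sprintf("Unknown session observation type '%s'.", obs$type))
    )
  }

  negatives <- NA_integer_
  if (nrow(signals) == 0L) {
    outcome <- "no_risk"; fired <- "none"
    add_trace(nrow(session) + 1L, "decision", "no step-1 signals", outcome)
  } else if (!is.null(quest_total) && !is.null(profile$questionnaire_threshold)) {
    refer <- questionnaire_refer(quest_total, profile$questionnaire_threshold)
    outcome <- if (refer) "refer" else "possible_risk"
    fired <- if (refer) "questionnaire_threshold" else "none"
    add_trace(nrow(session) + 1L, "decision",
              sprintf("questionnaire %g vs threshold %g", quest_total,
                      profile$questionnaire_threshold), outcome)
  } else if (!is.null(rating)) {
    d <- dsp_refer(rating, profile$referral_rule, profile$factor_map)
    negatives <- d$negatives
    outcome <- if (d$refer) "refer" else "possible_risk"
    fired <- d$fired_rule
    add_trace(nrow(session) + 1L, "decision",
              sprintf("%d of %d factors negative (rule k=%d)", d$negatives,
                      profile$referral_rule[["n"]],
                      profile$referral_rule[["k"]]), outcome)
  } else {
    outcome <- "possible_risk"; fired <- "none"
    add_trace(nrow(session) + 1L, "decision",
              "signals present, no severity information", outcome)
  }

  structure(
    list(outcome = outcome, fired_rule = fired, negatives = negatives,
         signals = signals, trace = dplyr::bind_rows(trace),
         profile = profile$risk_name),
    class = "mh_detection"
  )
}

#' @export
print.mh_detection <- function(x, ...) {
  cat("<mh_detection> profile '", x$profile, "': ", toupper(x$outcome),
      "\n", sep = "")
  cat("  fired rule: ", x$fired_rule, "; signals: ", nrow(x$signals),
      if (!is.na(x$negatives)) sprintf("; negative factors: %d", x$negatives),
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.mh_lmm
#' @export
tidy.mh_detection <- function(x, ...) x$trace

#' Exit code for a detection outcome
#'
#' Convention used by the command-line wrapper: 0 = no risk, 10 = possible
#' risk, 20 = refer.
#' @param outcome A detection outcome string or `mh_detection` object.
#' @return Integer exit code.
#' @export
detection_exit_code <- function(outcome) {
  if (inherits(outcome, "mh_detection")) outcome <- outcome$outcome
  c(no_risk = 0L, possible_risk = 10L, refer = 20L)[[outcome]]
}

#' Read a session stream from JSON Lines
#'
#' One typed observation per line, e.g.
#' `{"type":"utterance","text":"..."}`,
#' `{"type":"screening_answer","question":"q1","answer":"yes"}`,
#' `{"type":"questionnaire","total":3}`,
#' `{"type":"factor_rating","duration":"long","severity":"high","progression":"stable"}`.
#'
#' @param path Path to a JSON Lines file.
#' @return A session tibble.
#' @export
read_session_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    switch(rec$type,
      utterance = session_utterance(rec$text),
      screening_answer = session_answer(rec$question, rec$answer),
      questionnaire = session_questionnaire(rec$total),
      factor_rating = session_rating(rec$duration, rec$severity,
                                     rec$progression),
      abort(sprintf("Unknown observation type '%s' in %s.", rec$type, path))
    )
  })
  dplyr::bind_rows(empty_session(), !!!rows)
}

#' Write a tibble as JSON Lines
#'
#' @param x A data frame (e.g. a decision trace or transcript).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    row <- as.list(x[i, ])
    row <- row[!vapply(row, function(v) all(is.na(v)), logical(1))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
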