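#' Load dialogue script templates
#'
#' Scripts are shipped as JSON data files (one per strategy) and fully
#' overridable: the engine guarantees structure — turn ordering, branch
#' resolution, placeholder totality — not wording. Each turn has an `id`,
#' `speaker`, a `text` (or per-concern `text_by_concern` variants), an
#' optional `expect` block (multiple-choice options), optional `branch`
#' labels mapping answers to turn ids (or `"end"`), a `default_branch`
#' taken when the user gives no input, and a `next_id`.
#'
#' @param dir Directory holding `facilitate.json`, `persuade.json`,
#'   `accept_rejection.json`. Defaults to the templates shipped with the
#'   package.
#' @return Named list of raw template lists, one per strategy.
#' @export
load_dialogue_templates <- function(dir = system.file("extdata", "dialogue",
                                                      package = "mhtriage")) {
  strategies <- .mh_levels$strategy
  templates <- lapply(strategies, function(s) {
    path <- file.path(dir, paste0(s, ".json"))
    if (!file.exists(path)) {
      abort(sprintf("No dialogue template for strategy '%s' in %s.", s, dir))
    }
    jsonlite::read_json(path)
  })
  stats::setNames(templates, strategies)
}

#' Render a referral-strategy dialogue script
#'
#' Instantiates a strategy's template for a user's concern: selects the
#' concern-specific variant of the persuasive message and resolves every
#' placeholder (`{money_problem_amount}`, `{travel_problem_hours}`,
#' `{stigma_group}`, `{contact_details}`, ...). Rendering fails if any
#' placeholder cannot be resolved, so a script that renders is guaranteed
#' playable.
#'
#' Script structure, common to all three strategies: greeting; the two
#' manipulation-check elicitations (perceived severity and stance, each
#' three-option multiple choice); an optional tips block (skipped when the
#' user answers no). Then the strategy block: *persuade* adds the
#' concern-tailored persuasive message, the announcement that contact will
#' be facilitated, and the contact details — reached by default unless the
#' user explicitly objects; *facilitate* goes straight to contact details;
#' *accept rejection* explicitly accepts the refusal and keeps a standing
#' offer of the details on request.
#'
#' @param strategy `"facilitate"`, `"persuade"` or `"accept_rejection"`.
#' @param concern An [concern()] object.
#' @param params Named list of additional placeholder values; must include
#'   `contact_details`.
#' @param templates Templates from [load_dialogue_templates()].
#' @return A tibble of class `mh_dialogue` with columns `turn_id`,
#'   `speaker`, `text`, `options` (list), `branch` (list), `default_branch`,
#'   `next_id`; attribute `"strategy"`.
#' @examples
#' render_dialogue("persuade", concern("money", money_problem_amount = 50))
#' @export
render_dialogue <- function(strategy, concern,
                            params = list(contact_details =
                                            "the Sleep Clinic, 555-0100"),
                            templates = load_dialogue_templates()) {
  strategy <- .match_level(strategy, "strategy")
  if (!inherits(concern, "mh_concern")) {
    abort("`concern` must be built with concern().")
  }
  tmpl <- templates[[strategy]]
  values <- c(unclass(concern)[setdiff(names(unclass(concern)), "kind")],
              params)
  turns <- purrr::map_dfr(tmpl$turns, function(turn) {
    text <- turn[["text"]]
    if (is.null(text) && !is.null(turn[["text_by_concern"]])) {
      text <- turn[["text_by_concern"]][[concern$kind]]
      if (is.null(text)) {
        abort(sprintf("Turn '%s' has no text variant for concern '%s'.",
                      turn$id, concern$kind))
      }
    }
    if (is.null(text)) {
      abort(sprintf("Turn '%s' has no text.", turn$id))
    }
    tibble(
      turn_id = turn$id,
      speaker = turn$speaker,
      text = fill_placeholders(text, values, turn$id),
      options = list(as.character(unlist(turn$expect$options))),
      branch = list(turn$branch),
      default_branch = turn$default_branch %||% NA_character_,
      next_id = turn$next_id %||% "end"
    )
  })
  # every branch label must resolve to a turn or to end
  targets <- unique(c(unlist(turns$branch), turns$next_id))
  unknown <- setdiff(targets, c(turns$turn_id, "end"))
  if (length(unknown)) {
    abort(sprintf("Branch target(s) not defined in script: %s.",
                  paste(unknown, collapse = ", ")))
  }
  attr(turns, "strategy") <- strategy
  class(turns) <- c("mh_dialogue", class(turns))
  turns
}

fill_placeholders <- function(text, values, turn_id) {
  for (nm in names(values)) {
    text <- gsub(paste0("{", nm, "}"), as.character(values[[nm]]), text,
                 fixed = TRUE)
  }
  left <- regmatches(text, gregexpr("\\{[a-z_]+\\}", text))[[1]]
  if (length(left)) {
    abort(sprintf("Unresolved placeholder(s) in turn '%s': %s.",
                  turn_id, paste(left, collapse = ", ")))
  }
  text
}

#' Run the full self-referral motivation policy
#'
#' Composes the three policy stages — classify the situation on the
#' stance-by-severity grid, select the matching referral strategy, render
#' its dialogue for the user's concern — and then walks the script against
#' a log of user choices.
#'
#' At a multiple-choice turn, the next pending user event is consumed if it
#' is one of that turn's options; otherwise the turn is answered by its
#' default branch (recorded as no response). This gives the policy its
#' default bias: in the persuade script, reaching the contact details
#' requires *no* input, while avoiding them requires the explicit
#' `"object"` event.
#'
#' @inheritParams render_dialogue
#' @param stance,severity The scenario's stance and severity levels.
#' @param user_events Character vector of user choices, consumed in order at
#'   the turns where they are valid options.
#' @param strategy_override Optional strategy to play instead of the one the
#'   grid selects (used to cross strategies with situations
#'   experimentally).
#' @return An object of class `mh_policy_run`: a list with `situation` (one
#'   grid row), `strategy`, and `transcript` — a tibble with `turn_id`,
#'   `speaker` (`agent`/`user`), `text`.
#' @examples
#' run_policy("doubting", "high", concern("money", money_problem_amount = 50))
#' @export
run_policy <- function(stance, severity, concern,
                       user_events = character(),
                       strategy_override = NULL,
                       params = list(contact_details =
                                       "the Sleep Clinic, 555-0100"),
                       templates = load_dialogue_templates()) {
  situation <- classify_situation(stance, severity)
  strategy <- strategy_override %||% select_strategy(situation)
  script <- render_dialogue(strategy, concern, params = params,
                            templates = templates)
  pending <- as.character(user_events)
  rows <- list()
  current <- script$turn_id[1]
  visited <- 0L
  while (!identical(current, "end")) {
    visited <- visited + 1L
    if (visited > 10L * nrow(script)) {
      abort("Dialogue script does not terminate.")
    }
    turn <- script[script$turn_id == current, ]
    rows[[length(rows) + 1L]] <-
      tibble(turn_id = turn$turn_id, speaker = turn$speaker,
             text = turn$text)
    options <- turn$options[[1]]
    if (length(options)) {
      answer <- NA_character_
      if (length(pending) && pending[1] %in% options) {
        answer <- pending[1]
        pending <- pending[-1]
        rows[[length(rows) + 1L]] <-
          tibble(turn_id = turn$turn_id, speaker = "user", text = answer)
      }
      choice <- if (is.na(answer)) turn$default_branch else answer
      branch <- turn$branch[[1]]
      current <- if (!is.null(branch) && !is.na(choice) &&
                     choice %in% names(branch)) {
        branch[[choice]]
      } else {
        turn$next_id
      }
    } else {
      current <- turn$next_id
    }
  }
  structure(
    list(situation = situation, strategy = strategy,
         transcript = dplyr::bind_rows(rows)),
    class = "mh_policy_run"
  )
}

#' @export
print.mh_policy_run <- function(x, ...) {
  cat("<mh_policy_run> situation ", x$situation$id, " (",
      as.character(x$situation$sit_type), ") -> strategy '", x$strategy,
      "'\n\n", sep = "")
  for (i in seq_len(nrow(x$transcript))) {
    cat(format(toupper(x$transcript$speaker[i]), width = 6), "| ",
        x$transcript$text[i], "\n", sep = "")
  }
  invisible(x)
}
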