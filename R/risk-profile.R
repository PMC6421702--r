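#' Configure a risk profile for the detection engine
#'
#' A risk profile holds everything the two-step detection protocol needs for
#' one risk type: the keyword lexicon and screening questions used to detect
#' that a risk *might* exist (step 1), and either a questionnaire threshold or
#' a duration/severity/progression (DSP) k-of-n rule used to decide whether
#' the situation is severe enough to refer to human care (step 2). The
#' protocol deliberately leaves these blanks to be filled per system and risk
#' type; a profile is that filled-in configuration.
#'
#' @param risk_name Identifier for the risk (e.g. `"suicide"`, `"insomnia"`).
#' @param lexicon Character vector of non-empty keyword phrases, matched
#'   case-insensitively at word boundaries. Plain phrases, not regular
#'   expressions, so configurations stay auditable.
#' @param screening_questions Named list: one entry per screening question id,
#'   each a character vector of risk-indicating answers.
#' @param questionnaire_id Optional identifier of a severity questionnaire
#'   (e.g. an item or scale known to track the risk). Must be paired with
#'   `questionnaire_threshold`.
#' @param questionnaire_threshold Optional numeric referral cutoff; a total
#'   score greater than or equal to the threshold refers (inclusive
#'   comparison, the conservative reading).
#' @param factor_map Named list mapping each DSP factor level to `TRUE`
#'   (negative, i.e. counting toward referral) or `FALSE`. See
#'   [default_factor_map()].
#' @param referral_rule Integer vector `c(k, n)`: refer when at least `k` of
#'   the `n` DSP factors are negative. Default `c(2, 3)`.
#' @param questionnaire_gated Logical; when `TRUE` (default) questionnaire
#'   totals are only acted on after a step-1 signal. This encodes the
#'   contagion-avoidance principle of not probing a sensitive risk until the
#'   session already indicates it may be present.
#'
#' @return An object of class `risk_profile`.
#' @seealso [run_detection()], [read_risk_profile()]
#' @examples
#' prof <- risk_profile(
#'   "suicide",
#'   lexicon = c("end my life", "kill myself"),
#'   screening_questions = list(q_harm = c("yes", "sometimes")),
#'   questionnaire_id = "phq9_item9", questionnaire_threshold = 2
#' )
#' prof
#' @export
risk_profile <- function(risk_name,
                         lexicon,
                         screening_questions = list(),
                         questionnaire_id = NULL,
                         questionnaire_threshold = NULL,
                         factor_map = default_factor_map(),
                         referral_rule = c(2L, 3L),
                         questionnaire_gated = TRUE) {
  stopifnot(is.character(risk_name), length(risk_name) == 1L)
  lexicon <- as.character(lexicon)
  if (length(lexicon) == 0L || any(!nzchar(trimws(lexicon)))) {
    abort("`lexicon` must contain at least one non-empty phrase.")
  }
  if (length(screening_questions) &&
      (is.null(names(screening_questions)) ||
       any(!nzchar(names(screening_questions))))) {
    abort("`screening_questions` must be a named list (names are question ids).")
  }
  if (is.null(questionnaire_id) != is.null(questionnaire_threshold)) {
    abort("`questionnaire_threshold` must be supplied if and only if `questionnaire_id` is.")
  }
  check_factor_map(factor_map)
  referral_rule <- as.integer(referral_rule)
  k <- referral_rule[1]; n <- referral_rule[2]
  if (length(referral_rule) != 2L || is.na(k) || is.na(n) || k < 1L || k > n) {
    abort("`referral_rule` must be c(k, n) with 1 <= k <= n.")
  }
  if (n != length(factor_map)) {
    abort("`referral_rule` n must equal the number of configured DSP factors.")
  }
  structure(
    list(
      risk_name = risk_name,
      lexicon = lexicon,
      screening_questions = screening_questions,
      questionnaire_id = questionnaire_id,
      questionnaire_threshold = questionnaire_threshold,
      factor_map = factor_map,
      referral_rule = c(k = k, n = n),
      questionnaire_gated = isTRUE(questionnaire_gated)
    ),
    class = "risk_profile"
  )
}

#' Default duration/severity/progression factor map
#'
#' Maps each factor level to whether it counts as *negative* for the k-of-n
#' referral rule. The defaults mark only the worst pole of each factor as
#' negative (`long`, `high`, `worsening`); middle levels such as `stable` are
#' not negative, the non-referring reading of levels the protocol leaves open.
#' Override per profile to change how middle levels count.
#'
#' @return Named list of three named logical vectors (`duration`, `severity`,
#'   `progression`), one entry per level.
#' @examples
#' default_factor_map()
#' @export
default_factor_map <- function() {
  list(
    duration    = c(short = FALSE, medium = FALSE, long = TRUE),
    severity    = c(low = FALSE, medium = FALSE, high = TRUE),
    progression = c(improving = FALSE, stable = FALSE, worsening = TRUE)
  )
}

check_factor_map <- function(factor_map) {
  if (!is.list(factor_map) || is.null(names(factor_map)) ||
      !all(vapply(factor_map, is.logical, logical(1)))) {
    abort("`factor_map` must be a named list of named logical vectors.")
  }
  invisible(factor_map)
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile> ", x$risk_name, "\n", sep = "")
  cat("  lexicon: ", length(x$lexicon), " phrase(s)\n", sep = "")
  cat("  screening questions: ", length(x$screening_questions), "\n", sep = "")
  if (!is.null(x$questionnaire_id)) {
    cat("  questionnaire: ", x$questionnaire_id, " (refer at >= ",
        x$questionnaire_threshold, if (x$questionnaire_gated) ", gated", ")\n",
        sep = "")
  } else {
    cat("  questionnaire: none (DSP rule only)\n")
  }
  cat("  DSP rule: refer when >= ", x$referral_rule[["k"]], " of ",
      x$referral_rule[["n"]], " factors negative\n", sep = "")
  invisible(x)
}

#' Read or write a risk profile as YAML or JSON
#'
#' Profiles are plain configuration files so they can be reviewed and
#' version-controlled outside the code. The on-disk schema mirrors the
#' [risk_profile()] arguments; `factor_map` entries use `negative: [level,
#' ...]` lists for readability.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `risk_profile` object.
#' @examples
#' path <- system.file("extdata/profiles/low_mood.yaml", package = "mhtriage")
#' read_risk_profile(path)
#' @export
read_risk_profile <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fm <- if (is.null(raw$factor_map)) default_factor_map() else {
    lapply(raw$factor_map, function(entry) {
      levels <- unlist(entry$levels)
      stats::setNames(levels %in% unlist(entry$negative), levels)
    })
  }
  sq <- lapply(raw$screening_questions, function(q) as.character(unlist(q)))
  risk_profile(
    risk_name = raw$risk_name,
    lexicon = as.character(unlist(raw$lexicon)),
    screening_questions = sq,
    questionnaire_id = raw$questionnaire_id,
    questionnaire_threshold = raw$questionnaire_threshold,
    factor_map = fm,
    referral_rule = if (is.null(raw$referral_rule)) c(2L, 3L)
                    else as.integer(unlist(raw$referral_rule)),
    questionnaire_gated = raw$questionnaire_gated %||% TRUE
  )
}
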