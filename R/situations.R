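#' The stance-by-severity situation grid
#'
#' The self-referral motivation protocol distinguishes nine situations by
#' the user's initial stance on seeking human care (negative / doubting /
#' positive) and the severity of their health situation (low / medium /
#' high). Each cell belongs to one of three situation types, grounded in the
#' social-judgement-theory latitudes: *accept care* (latitude of acceptance
#' — positive stance at any severity), *care potential* (latitude of
#' noncommitment — doubt with medium or high severity, or a negative stance
#' with a high-severity situation, where there is little to lose by trying),
#' and *reject care* (latitude of rejection — doubt with a low-severity
#' situation, or a negative stance with medium or low severity).
#'
#' Cell ids are numbered row-major with severity rows high to low and stance
#' columns negative to positive, so the types partition the ids as
#' care potential = \{1, 2, 5\}, accept care = \{3, 6, 9\},
#' reject care = \{4, 7, 8\}.
#'
#' @return A 9-row tibble with columns `stance`, `severity`, `id`,
#'   `sit_type`.
#' @examples
#' situation_grid()
#' @export
situation_grid <- function() {
  grid <- tidyr::expand_grid(
    severity = factor(c("high", "medium", "low"),
                      levels = .mh_levels$severity),
    stance = factor(.mh_levels$stance, levels = .mh_levels$stance)
  )
  grid$id <- seq_len(nrow(grid))
  type_of <- c("care_potential", "care_potential", "accept_care",
               "reject_care", "care_potential", "accept_care",
               "reject_care", "reject_care", "accept_care")
  grid$sit_type <- factor(type_of, levels = .mh_levels$sit_type)
  dplyr::select(as_tibble(grid), "stance", "severity", "id", "sit_type")
}

#' Classify situations by stance and severity
#'
#' Vectorised lookup into the fixed [situation_grid()].
#'
#' @param stance Character vector of stances (`negative`/`doubting`/
#'   `positive`).
#' @param severity Character vector of severities (`low`/`medium`/`high`),
#'   recycled against `stance`.
#' @return A tibble with one row per input pair: `stance`, `severity`, `id`,
#'   `sit_type`.
#' @examples
#' classify_situation("negative", "high")   # severe but unwilling: still potential
#' classify_situation("doubting", "low")    # reject care
#' @export
classify_situation <- function(stance, severity) {
  n <- max(length(stance), length(severity))
  stance <- rep_len(as.character(stance), n)
  severity <- rep_len(as.character(severity), n)
  bad <- !stance %in% .mh_levels$stance
  if (any(bad)) abort(sprintf("Invalid stance value(s): %s.",
                              paste(unique(stance[bad]), collapse = ", ")))
  bad <- !severity %in% .mh_levels$severity
  if (any(bad)) abort(sprintf("Invalid severity value(s): %s.",
                              paste(unique(severity[bad]), collapse = ", ")))
  grid <- situation_grid()
  key <- match(paste(stance, severity),
               paste(grid$stance, grid$severity))
  grid[key, ]
}

#' Select the referral strategy for a situation
#'
#' One strategy per situation type: *facilitate* (provide contact details —
#' motivation is already high, so raise capability and trigger the
#' behaviour) for accept-care situations; *persuade* (raise motivation
#' first, then announce facilitation as the default continuation) for
#' care-potential situations; *accept rejection* (explicitly accept the
#' refusal while keeping a standing offer of contact details) for
#' reject-care situations, where pushing referral risks a backfire.
#'
#' @param situation A tibble from [classify_situation()]/[situation_grid()],
#'   or a character vector of situation types.
#' @return Character vector of strategies (`facilitate`, `persuade`,
#'   `accept_rejection`).
#' @examples
#' select_strategy(classify_situation("doubting", "high"))
#' @export
select_strategy <- function(situation) {
  sit_type <- if (is.data.frame(situation)) as.character(situation$sit_type)
              else as.character(situation)
  bad <- !sit_type %in% .mh_levels$sit_type
  if (any(bad)) abort("Invalid situation type.")
  unname(c(accept_care = "facilitate",
           care_potential = "persuade",
           reject_care = "accept_rejection")[sit_type])
}

#' Describe the user's main concern about seeking human care
#'
#' Scenarios and persuasive messages are personalised to the one factor most
#' likely to stop the user from seeing a therapist: money (with the amount
#' that would be a problem), travel time (hours), or social stigma (the
#' group the user most fears telling).
#'
#' @param kind `"money"`, `"time"` or `"stigma"`.
#' @param money_problem_amount Currency amount (money concern only).
#' @param travel_problem_hours Travel hours (time concern only).
#' @param stigma_group `"family"`, `"friends"` or `"boss"` (stigma only).
#' @return An object of class `mh_concern`.
#' @examples
#' concern("money", money_problem_amount = 50)
#' @export
concern <- function(kind, money_problem_amount = NULL,
                    travel_problem_hours = NULL, stigma_group = NULL) {
  kind <- .match_level(kind, "concern", "kind")
  fields <- switch(kind,
    money = {
      if (is.null(money_problem_amount))
        abort("A money concern needs `money_problem_amount`.")
      if (!is.null(travel_problem_hours) || !is.null(stigma_group))
        abort("A money concern sets only `money_problem_amount`.")
      list(money_problem_amount = money_problem_amount)
    },
    time = {
      if (is.null(travel_problem_hours))
        abort("A time concern needs `travel_problem_hours`.")
      if (!is.null(money_problem_amount) || !is.null(stigma_group))
        abort("A time concern sets only `travel_problem_hours`.")
      list(travel_problem_hours = travel_problem_hours)
    },
    stigma = {
      if (is.null(stigma_group))
        abort("A stigma concern needs `stigma_group`.")
      if (!is.null(money_problem_amount) || !is.null(travel_problem_hours))
        abort("A stigma concern sets only `stigma_group`.")
      list(stigma_group = match.arg(stigma_group,
                                    c("family", "friends", "boss")))
    }
  )
  structure(c(list(kind = kind), fields), class = "mh_concern")
}
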