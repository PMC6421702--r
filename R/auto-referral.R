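#' Describe an auto-referral case
#'
#' The auto-referral protocol lets a system contact a human caregiver on the
#' user's behalf, and is only permissible when the user approved the
#' procedure beforehand. A case captures the facts the workflow branches on:
#' consent, whether a caregiver can step into the conversation directly,
#' whether the situation is a direct crisis, and the contact/timing
#' parameters the emitted messages carry.
#'
#' @param case_id Identifier.
#' @param consent_given Did the user consent to auto-referral beforehand?
#' @param caregiver_can_step_in Can a caregiver take over the interaction
#'   directly?
#' @param crisis Is this a direct crisis situation?
#' @param caregiver_contact Non-empty contact record (string), required
#'   whenever a referral path can be taken.
#' @param expected_response_time How soon the caregiver is expected to make
#'   contact (same time unit as the tick events fed to [referral_step()]).
#' @param self_contact_deadline Non-crisis branch: how long the user has to
#'   contact the caregiver before the caregiver seeks contact. Strictly
#'   positive.
#' @return An object of class `referral_case`.
#' @seealso [run_referral()], [referral_step()]
#' @export
referral_case <- function(case_id,
                          consent_given,
                          caregiver_can_step_in = FALSE,
                          crisis = FALSE,
                          caregiver_contact = "caregiver on file",
                          expected_response_time = 24,
                          self_contact_deadline = 48) {
  stopifnot(length(case_id) == 1L, is.logical(consent_given))
  if (consent_given &&
      (!is.character(caregiver_contact) || !nzchar(caregiver_contact))) {
    abort("`caregiver_contact` must be non-empty when a referral path can be taken.")
  }
  if (expected_response_time <= 0 || self_contact_deadline <= 0) {
    abort("Deadlines must be strictly positive.")
  }
  structure(
    list(case_id = as.character(case_id),
         consent_given = isTRUE(consent_given),
         caregiver_can_step_in = isTRUE(caregiver_can_step_in),
         crisis = isTRUE(crisis),
         caregiver_contact = caregiver_contact,
         expected_response_time = expected_response_time,
         self_contact_deadline = self_contact_deadline),
    class = "referral_case"
  )
}

#' Plan the auto-referral branch for a case
#'
#' Pure routing, before any event is processed: no consent blocks the
#' referral outright; with consent, a caregiver who can step in takes over;
#' otherwise the crisis flag selects between the crisis branch (system alerts
#' the caregiver) and the non-crisis branch (user is asked to self-contact,
#' caregiver informed as safety net).
#'
#' @param case A [referral_case()].
#' @return One of `"refuse_no_consent"`, `"takeover"`, `"crisis"`,
#'   `"non_crisis"`.
#' @export
route <- function(case) {
  stopifnot(inherits(case, "referral_case"))
  if (!case$consent_given) return("refuse_no_consent")
  if (case$caregiver_can_step_in) return("takeover")
  if (case$crisis) "crisis" else "non_crisis"
}

#' Create a fresh auto-referral workflow state
#'
#' @return A `referral_state` object in state `"idle"` with clock 0.
#' @export
new_referral_state <- function() {
  structure(list(state = "idle", clock = 0, outreach_fired = FALSE),
            class = "referral_state")
}

workflow_states <- c("idle", "risk_detected", "takeover_announced",
                     "caregiver_in_control", "crisis_alerted",
                     "awaiting_self_contact", "caregiver_outreach", "closed")

action_row <- function(kind, payload = NA_character_) {
  tibble(action = kind, payload = as.character(payload))
}

#' Advance the auto-referral workflow by one event
#'
#' The workflow is a deterministic state machine driven by explicit events;
#' time advances only through `tick` events so every run is replayable.
#' Events are `"risk_referred"`, `"tick"` (with a positive `duration`),
#' `"patient_contacted"`, `"caregiver_responded"` and `"close"`. An event
#' that is not legal in the current state is rejected: the state is
#' unchanged and the rejection is reported in the result.
#'
#' Branch semantics on `risk_referred`:
#' * no consent: emit `refuse_no_consent` (the blocked referral is surfaced,
#'   never silently dropped) and close;
#' * takeover: emit `announce_handover`; the caregiver's response moves the
#'   case to `caregiver_in_control`;
#' * crisis: emit `alert_caregiver`, `inform_patient_eta`,
#'   `provide_contact_info` and `provide_coping_options` exactly once each;
#' * non-crisis: emit `request_self_contact`, `provide_contact_info` (so the
#'   user knows who to reach even if the network fails) and
#'   `notify_caregiver_safety_net`, then await self-contact. Once the clock
#'   strictly exceeds `self_contact_deadline` without `patient_contacted`,
#'   `trigger_caregiver_outreach` fires, at most once per case.
#'
#' @param state A `referral_state` from [new_referral_state()] or a previous
#'   step.
#' @param event Event name (see above).
#' @param case The [referral_case()] being processed.
#' @param duration Elapsed time for `tick` events.
#' @return A list with `state` (new `referral_state`), `actions` (tibble of
#'   emitted actions with payloads), `rejected` (logical) and `note`
#'   (diagnostic for rejected events).
#' @export
referral_step <- function(state, event, case, duration = NULL) {
  stopifnot(inherits(state, "referral_state"),
            inherits(case, "referral_case"))
  actions <- action_row(character(0))
  rejected <- FALSE
  note <- NA_character_
  s <- state

  reject <- function(msg) {
    rejected <<- TRUE
    note <<- msg
  }

  if (event == "tick") {
    if (is.null(duration) || duration <= 0) {
      abort("`tick` events need a strictly positive `duration`.")
    }
    if (s$state == "closed") {
      reject("tick after case closed")
    } else {
      s$clock <- s$clock + duration
      if (s$state == "awaiting_self_contact" &&
          s$clock > case$self_contact_deadline && !s$outreach_fired) {
        actions <- action_row("trigger_caregiver_outreach",
                              case$caregiver_contact)
        s$outreach_fired <- TRUE
        s$state <- "caregiver_outreach"
      }
    }
  } else if (event == "risk_referred") {
    if (s$state != "idle") {
      reject(sprintf("risk_referred not legal in state '%s'", s$state))
    } else if (!case$consent_given) {
      actions <- action_row("refuse_no_consent",
                            "risk detected but auto-referral not authorized")
      s$state <- "closed"
    } else if (case$caregiver_can_step_in) {
      actions <- action_row("announce_handover", case$caregiver_contact)
      s$state <- "takeover_announced"
    } else if (case$crisis) {
      actions <- dplyr::bind_rows(
        action_row("alert_caregiver", case$caregiver_contact),
        action_row("inform_patient_eta",
                   sprintf("expect contact within %g",
                           case$expected_response_time)),
        action_row("provide_contact_info", case$caregiver_contact),
        action_row("provide_coping_options",
                   "short-term risk-reduction options")
      )
      s$state <- "crisis_alerted"
    } else {
      actions <- dplyr::bind_rows(
        action_row("request_self_contact",
                   sprintf("please contact your caregiver within %g",
                           case$self_contact_deadline)),
        action_row("provide_contact_info", case$caregiver_contact),
        action_row("notify_caregiver_safety_net", case$caregiver_contact)
      )
      s$state <- "awaiting_self_contact"
    }
  } else if (event == "patient_contacted") {
    if (s$state %in% c("crisis_alerted", "awaiting_self_contact",
                       "caregiver_outreach")) {
      s$state <- "closed"
    } else {
      reject(sprintf("patient_contacted not legal in state '%s'", s$state))
    }
  } else if (event == "caregiver_responded") {
    if (s$state == "takeover_announced") {
      s$state <- "caregiver_in_control"
    } else if (s$state %in% c("crisis_alerted", "caregiver_outreach")) {
      s$state <- "closed"
    } else {
      reject(sprintf("caregiver_responded not legal in state '%s'", s$state))
    }
  } else if (event == "close") {
    if (s$state == "closed") {
      reject("case already closed")
    } else {
      s$state <- "closed"
    }
  } else {
    abort(sprintf("Unknown event '%s'.", event))
  }

  list(state = s, actions = actions, rejected = rejected, note = note)
}

#' Replay an auto-referral case over an event log
#'
#' Folds [referral_step()] over a time-ordered event tibble and returns the
#' full transcript: one row per event, with emitted actions nested. The run
#' is a pure function of `(case, events)`.
#'
#' @param case A [referral_case()].
#' @param events Tibble with columns `event` and (for ticks) `duration`;
#'   or a character vector of event names for tick-free logs.
#' @return A tibble of class `mh_transcript`: columns `step`, `event`,
#'   `state_after`, `rejected`, `note`, `action`, `payload` (one row per
#'   emitted action; events that emit none keep a single row with `action =
#'   NA`). The final `referral_state` is attached as attribute
#'   `"final_state"`.
#' @examples
#' case <- referral_case("c1", consent_given = TRUE, crisis = TRUE)
#' run_referral(case, c("risk_referred", "caregiver_responded"))
#' @export
run_referral <- function(case, events) {
  stopifnot(inherits(case, "referral_case"))
  if (is.character(events)) events <- tibble(event = events)
  if (!"duration" %in% names(events)) events$duration <- NA_real_
  state <- new_referral_state()
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events$event[i]
    dur <- events$duration[i]
    res <- referral_step(state, ev, case,
                         duration = if (is.na(dur)) NULL else dur)
    state <- res$state
    acts <- res$actions
    if (nrow(acts) == 0L) acts <- action_row(NA_character_)
    out[[i]] <- tibble(step = i, event = ev, state_after = state$state,
                       rejected = res$rejected, note = res$note,
                       action = acts$action, payload = acts$payload)
  }
  transcript <- if (length(out)) dplyr::bind_rows(out) else
    tibble(step = integer(), event = character(), state_after = character(),
           rejected = logical(), note = character(), action = character(),
           payload = character())
  attr(transcript, "final_state") <- state
  class(transcript) <- c("mh_transcript", class(transcript))
  transcript
}

#' Read an auto-referral case or event log from JSON
#'
#' @param path Path to a JSON file. A case file carries the
#'   [referral_case()] fields; an event file is an array of
#'   `{"event": ..., "duration": ...}` records.
#' @return A `referral_case` or an events tibble.
#' @export
read_referral_case <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(referral_case, raw)
}

#' @rdname read_referral_case
#' @export
read_referral_events <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw <- as_tibble(raw)
  if (!"duration" %in% names(raw)) raw$duration <- NA_real_
  raw
}
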