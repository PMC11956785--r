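# Four-state space of the multistate model: three transient disease states
# ordered by chronicity plus absorbing death. The order matters: apparent
# recoveries are repaired by carrying the highest state forward, and
# transition records must never move down the order.

#' Health-state levels
#'
#' The four states of the multistate model, in their total order:
#' `no_disease < one_disease < multimorbid < dead`. Chronic conditions are
#' assumed irreversible, so observed states may only move up this order;
#' death is absorbing.
#'
#' @return Character vector of the four state labels, in order.
#' @export
state_levels <- function() {
  c("no_disease", "one_disease", "multimorbid", "dead")
}

#' Transient (non-absorbing) states
#' @return Character vector of the three living states.
#' @export
transient_states <- function() state_levels()[1:3]

# coerce labels to an ordered factor over the state space
as_state <- function(x) {
  lv <- state_levels()
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), lv)
  if (length(bad) > 0) {
    abort(paste0("unknown health state(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Destinations reachable from a transient origin
#'
#' The admissible (non-reverse) destinations, stay first; all other
#' destinations are structural zeros of the transition matrix.
#'
#' @param origin Transient state label.
#' @return Character vector of destination labels.
#' @export
admissible_destinations <- function(origin) {
  switch(origin,
    no_disease  = c("no_disease", "one_disease", "multimorbid", "dead"),
    one_disease = c("one_disease", "multimorbid", "dead"),
    multimorbid = c("multimorbid", "dead"),
    abort(paste0("no destinations from origin '", origin, "' (absorbing or unknown)"))
  )
}

#' The chronic conditions counted towards multimorbidity
#'
#' Fourteen self-reported or measured chronic conditions: Alzheimer's disease,
#' arthritis, asthma, cancer, diabetes, emphysema, epilepsy, heart problems,
#' HIV, hypertension, kidney problems, psychological/psychiatric disorders,
#' stroke and tuberculosis.
#'
#' @return Character vector of the 14 condition column names used in panels.
#' @export
condition_names <- function() {
  c("alzheimers", "arthritis", "asthma", "cancer", "diabetes", "emphysema",
    "epilepsy", "heart_problems", "hiv", "hypertension", "kidney_problems",
    "psychiatric", "stroke", "tuberculosis")
}

#' Define multimorbidity
#'
#' A multimorbidity definition is the set of conditions counted, the count
#' threshold (two or more conditions by default), and how hypertension is
#' established: from the recorded indicator (`"from_flag"`) or re-derived from
#' mean systolic/diastolic blood pressure (`"from_bp"`, see
#' [classify_hypertension()]).
#'
#' @param included_conditions Character vector of condition names; defaults to
#'   all 14 of [condition_names()].
#' @param threshold Minimum number of co-occurring conditions that counts as
#'   multimorbidity (default 2).
#' @param hypertension_rule `"from_flag"` or `"from_bp"`.
#' @param variant Convenience shortcut overriding `included_conditions`:
#'   `"full"`, `"no_hypertension"`, `"no_tb"`, or `"no_hypertension_no_tb"`
#'   (the sensitivity-analysis definitions).
#' @return An object of class `mm_definition`.
#' @export
mm_definition <- function(included_conditions = condition_names(),
                          threshold = 2L,
                          hypertension_rule = c("from_flag", "from_bp"),
                          variant = NULL) {
  hypertension_rule <- match.arg(hypertension_rule)
  if (!is.null(variant)) {
    variant <- match.arg(variant,
      c("full", "no_hypertension", "no_tb", "no_hypertension_no_tb"))
    drop <- switch(variant,
      full = character(),
      no_hypertension = "hypertension",
      no_tb = "tuberculosis",
      no_hypertension_no_tb = c("hypertension", "tuberculosis"))
    included_conditions <- setdiff(condition_names(), drop)
  }
  unknown <- setdiff(included_conditions, condition_names())
  if (length(unknown) > 0) {
    abort(paste0("unknown condition name(s) in definition: ",
                 paste(unknown, collapse = ", ")))
  }
  if (length(included_conditions) == 0) abort("included_conditions must be non-empty")
  threshold <- as.integer(threshold)
  if (threshold < 2L) abort("threshold must be >= 2 (multimorbidity is co-occurrence)")
  structure(
    list(included_conditions = included_conditions,
         threshold = threshold,
         hypertension_rule = hypertension_rule),
    class = "mm_definition")
}

#' Classify hypertension from mean blood pressure
#'
#' A person-wave is hypertensive when the mean systolic pressure is at least
#' 140 mmHg, the mean diastolic pressure is at least 90 mmHg, and the
#' difference between the two is at least 15 mmHg. Inputs are the per-wave
#' means of the two repeated cuff measurements. A missing pressure yields
#' `NA` (condition unknown) so the record can flow to the missing-data
#' exclusion path rather than being silently classified negative.
#'
#' @param sbp_mean,dbp_mean Numeric vectors of mean systolic and diastolic
#'   blood pressure in mmHg.
#' @param require_difference Apply the >= 15 mmHg pulse-pressure clause
#'   (default `TRUE`); can be disabled for sensitivity checks.
#' @return Logical vector (`NA` where a pressure is missing).
#' @examples
#' classify_hypertension(150, 95)  # TRUE
#' classify_hypertension(139, 95)  # FALSE: systolic below cutoff
#' classify_hypertension(140, 130) # FALSE: difference below 15
#' @export
classify_hypertension <- function(sbp_mean, dbp_mean, require_difference = TRUE) {
  if (length(sbp_mean) != length(dbp_mean)) {
    abort("sbp_mean and dbp_mean must have equal length")
  }
  neg <- (!is.na(sbp_mean) & sbp_mean <= 0) | (!is.na(dbp_mean) & dbp_mean <= 0)
  if (any(neg)) abort("blood pressures must be positive")
  out <- sbp_mean >= 140 & dbp_mean >= 90
  if (require_difference) out <- out & (sbp_mean - dbp_mean) >= 15
  out
}

#' Count included conditions on person-wave rows
#'
#' @param panel Data frame of person-wave observations carrying the condition
#'   flag columns (and `sbp_mean`/`dbp_mean` when the definition derives
#'   hypertension from blood pressure).
#' @param defn An [mm_definition()].
#' @return Integer vector of condition counts, one per row; `NA` where any
#'   included flag is missing (incomplete disease block).
#' @export
count_conditions <- function(panel, defn = mm_definition()) {
  stopifnot(inherits(defn, "mm_definition"))
  missing_cols <- setdiff(defn$included_conditions, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel lacks condition column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  flags <- panel[defn$included_conditions]
  if ("hypertension" %in% defn$included_conditions &&
      defn$hypertension_rule == "from_bp") {
    if (!all(c("sbp_mean", "dbp_mean") %in% names(panel))) {
      abort("hypertension_rule = 'from_bp' requires sbp_mean and dbp_mean columns")
    }
    flags$hypertension <- classify_hypertension(panel$sbp_mean, panel$dbp_mean)
  }
  m <- as.matrix(as.data.frame(lapply(flags, as.logical)))
  cnt <- rowSums(m)
  as.integer(cnt)
}

#' Derive the health state of a person-wave
#'
#' Death dominates; otherwise the condition count is compared with the
#' multimorbidity threshold.
#'
#' @param n_conditions Integer vector of included-condition counts.
#' @param alive Logical vector of vital status.
#' @param defn An [mm_definition()].
#' @return Ordered factor over [state_levels()]; `NA` where an alive row has
#'   an unknown count.
#' @export
derive_state <- function(n_conditions, alive, defn = mm_definition()) {
  stopifnot(inherits(defn, "mm_definition"))
  lab <- dplyr::case_when(
    !alive ~ "dead",
    is.na(n_conditions) ~ NA_character_,
    n_conditions >= defn$threshold ~ "multimorbid",
    n_conditions == 1L ~ "one_disease",
    TRUE ~ "no_disease"
  )
  as_state(lab)
}

#' Repair apparent recoveries by carry-forward of the highest state
#'
#' Chronic conditions are modelled as irreversible, so a wave sequence may
#' never step down the state order. Observed reversals (reporting noise,
#' under-diagnosis at a later wave) are repaired by replacing each state with
#' the running maximum of the sequence so far. `NA` entries (invalid waves)
#' are left `NA` and do not interrupt the carry-forward. A death followed by
#' a living observation is a data-integrity error, not repairable noise.
#'
#' @param states Ordered factor (or character) vector of states for one
#'   individual, ordered by wave.
#' @return Ordered factor of the same length, monotone non-decreasing.
#' @export
enforce_monotone_states <- function(states) {
  st <- as_state(states)
  idx <- as.integer(st)
  obs <- which(!is.na(idx))
  if (length(obs) > 1) {
    run <- cummax(idx[obs])
    dead_i <- which(idx[obs] == 4L)
    if (length(dead_i) > 0 && any(idx[obs][seq_along(obs) > min(dead_i)] < 4L)) {
      abort("living observation after a recorded death: unrepairable data-integrity error")
    }
    idx[obs] <- run
  }
  as_state(state_levels()[idx])
}

#' Attach condition counts and derived states to a panel
#'
#' Convenience wrapper: computes `n_conditions` and `state` columns, then
#' repairs reversals per person via [enforce_monotone_states()].
#'
#' @inheritParams count_conditions
#' @param repair_reversals Carry the highest attained state forward
#'   (default `TRUE`).
#' @return The panel tibble with `n_conditions` and `state` columns added.
#' @export
derive_states <- function(panel, defn = mm_definition(), repair_reversals = TRUE) {
  panel <- as_tibble(panel)
  cnt <- count_conditions(panel, defn)
  cnt[!panel$alive] <- NA_integer_
  panel$n_conditions <- cnt
  panel$state <- derive_state(cnt, panel$alive, defn)
  panel <- panel %>% arrange(.data$person_id, .data$wave)
  if (repair_reversals) {
    panel$state <- monotone_states_by_person(panel$state, panel$person_id)
  }
  panel
}

# vectorised per-person running maximum over valid (non-NA) states; same
# semantics as enforce_monotone_states() applied within each person
monotone_states_by_person <- function(states, person_id) {
  idx <- as.integer(as_state(states))
  valid <- which(!is.na(idx))
  iv <- idx[valid]
  pv <- person_id[valid]
  same_prev <- c(FALSE, pv[-1] == pv[-length(pv)])
  if (any(same_prev & c(0L, iv[-length(iv)]) == 4L & iv < 4L)) {
    abort("living observation after a recorded death: unrepairable data-integrity error")
  }
  repeat {                               # a few passes suffice (<= waves - 1)
    prev <- c(NA_integer_, iv[-length(iv)])
    cand <- ifelse(same_prev, pmax(iv, prev), iv)
    if (all(cand == iv)) break
    iv <- cand
  }
  idx[valid] <- iv
  as_state(state_levels()[idx])
}
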