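# Sample construction: the exclusion cascade and the transition records
# (the unit of model fitting). Each individual contributes one baseline
# pseudo-transition -- the first observed state counted as a self-move,
# reflecting chronic status acquired before entering the panel -- plus one
# record per consecutive pair of observed waves.

#' Exclusion tally
#'
#' Bookkeeping for the sample-construction cascade. The invariant
#' `final_n = initial_n - excluded_single_wave - excluded_nonresponse -
#' excluded_missing` is enforced at construction.
#'
#' @param initial_n,excluded_single_wave,excluded_nonresponse,excluded_missing,final_n
#'   Non-negative counts.
#' @return One-row tibble of class `exclusion_tally`.
#' @export
exclusion_tally <- function(initial_n, excluded_single_wave,
                            excluded_nonresponse, excluded_missing,
                            final_n = NULL) {
  expected <- initial_n - excluded_single_wave - excluded_nonresponse - excluded_missing
  if (is.null(final_n)) final_n <- expected
  if (final_n != expected) {
    abort("exclusion tally inconsistent: final_n must equal initial_n minus all exclusions")
  }
  out <- tibble(initial_n = as.integer(initial_n),
                excluded_single_wave = as.integer(excluded_single_wave),
                excluded_nonresponse = as.integer(excluded_nonresponse),
                excluded_missing = as.integer(excluded_missing),
                final_n = as.integer(final_n))
  class(out) <- c("exclusion_tally", class(out))
  out
}

#' Apply the sample-construction exclusion cascade
#'
#' Removes, in order: (a) individuals observed at exactly one wave (present
#' once and lost to follow-up -- an individual with one interview plus a
#' subsequent household-reported death has two observations and is kept);
#' (b) individuals without at least two valid adult interviews -- a valid
#' interview is an alive wave with a complete disease block -- unless a death
#' record makes a single valid interview informative; (c) individuals missing
#' essential socio-demographic fields (sex, race, education, residence,
#' design weight) or vital status at any wave.
#'
#' @param panel Long person-wave tibble.
#' @param defn An [mm_definition()]; determines which flags must be complete
#'   for an interview to count as valid.
#' @return List with elements `panel` (the retained rows) and `tally`
#'   (an [exclusion_tally()]).
#' @export
apply_exclusions <- function(panel, defn = mm_definition()) {
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) {
    return(list(panel = panel, tally = exclusion_tally(0, 0, 0, 0)))
  }
  cnt <- count_conditions(panel, defn)
  info <- panel %>%
    mutate(.complete = !is.na(.env$cnt) & !is.na(.data$alive) & .data$alive,
           .dead = !is.na(.data$alive) & !.data$alive) %>%
    group_by(.data$person_id) %>%
    summarise(
      n_obs = n(),
      n_valid = sum(.data$.complete),
      any_death = any(.data$.dead),
      miss_vital = any(is.na(.data$alive)),
      miss_socio = any(is.na(.data$sex) | is.na(.data$race) |
                         is.na(.data$education) | is.na(.data$residence) |
                         is.na(.data$design_weight)),
      .groups = "drop")

  initial_n <- nrow(info)
  single <- info$n_obs == 1L & !info$any_death
  left <- !single
  nonresp <- left & ((info$n_valid < 2L & !info$any_death) |
                       (info$n_valid < 1L & info$any_death))
  left <- left & !nonresp
  missing <- left & (info$miss_socio | info$miss_vital)
  keep_ids <- info$person_id[left & !missing]

  tally <- exclusion_tally(initial_n, sum(single), sum(nonresp), sum(missing))
  list(panel = panel %>% filter(.data$person_id %in% keep_ids), tally = tally)
}

#' Build transition records from a state-classified panel
#'
#' Converts each individual's ordered, monotone state sequence into
#' origin-to-destination records: one baseline pseudo-transition (origin =
#' destination = first observed state, the survey convention counting
#' pre-survey chronic status as one transition) plus one record per
#' consecutive pair of valid observed waves. Each record carries the exact
#' age at the origin wave, the individual's fixed covariates and design
#' weight. Waves with an invalid state (incomplete disease block while
#' alive) contribute no transition; their flanking valid waves pair up, and
#' all pairs are treated as one biennial transition regardless of calendar
#' gap unless `drop_gapped = TRUE`.
#'
#' @param panel A panel that has passed [apply_exclusions()] and carries a
#'   `state` column (see [derive_states()]).
#' @param include_baseline Include the baseline pseudo-transition
#'   (default `TRUE`).
#' @param drop_gapped Drop record pairs separated by more than one wave
#'   (default `FALSE`).
#' @return Tibble with one row per transition record: `person_id`,
#'   `origin_state`, `destination_state`, `age_at_origin`, `sex`, `race`,
#'   `education`, `residence`, `urban` (numeric indicator), `design_weight`,
#'   `is_baseline_pseudo`, `gapped`.
#' @export
build_transition_records <- function(panel, include_baseline = TRUE,
                                     drop_gapped = FALSE) {
  if (!"state" %in% names(panel)) {
    abort("panel must carry a 'state' column; run derive_states() first")
  }
  valid <- panel %>%
    filter(!is.na(.data$state)) %>%
    arrange(.data$person_id, .data$wave)
  n_per <- valid %>% count(.data$person_id)
  if (any(n_per$n < 2)) {
    abort(paste0(sum(n_per$n < 2), " individual(s) with fewer than 2 valid ",
                 "observations; apply_exclusions() should have removed them"))
  }
  same_next <- c(valid$person_id[-1] == valid$person_id[-nrow(valid)], FALSE)
  dest <- lead(valid$state)
  dest[!same_next] <- NA
  moves <- valid
  moves$destination_state <- dest
  moves$gapped <- same_next & lead(valid$wave, default = 0L) - valid$wave > 1L
  moves$is_first <- c(TRUE, valid$person_id[-1] != valid$person_id[-nrow(valid)])

  base_cols <- function(d, origin, dest, pseudo, gapped) {
    tibble(person_id = d$person_id,
           origin_state = as_state(origin),
           destination_state = as_state(dest),
           age_at_origin = d$age,
           sex = d$sex, race = d$race, education = d$education,
           residence = d$residence,
           urban = as.numeric(d$residence == "urban"),
           design_weight = d$design_weight,
           is_baseline_pseudo = pseudo,
           gapped = gapped)
  }

  pairs <- moves %>% filter(!is.na(.data$destination_state))
  rec <- base_cols(pairs, pairs$state, pairs$destination_state,
                   FALSE, pairs$gapped)
  if (drop_gapped) rec <- rec %>% filter(!.data$gapped)
  if (include_baseline) {
    first <- moves %>% filter(.data$is_first)
    if (any(first$state == "dead")) {
      abort("individual first observed dead: no transient origin")
    }
    rec <- bind_rows(base_cols(first, first$state, first$state, TRUE, FALSE), rec)
  }
  rec <- rec %>% arrange(.data$person_id, .data$age_at_origin, !.data$is_baseline_pseudo)
  if (any(rec$origin_state == "dead")) abort("record originating from death")
  if (any(rec$destination_state < rec$origin_state)) {
    abort("record moving down the state order; enforce monotone states first")
  }
  rec
}
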