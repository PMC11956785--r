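# Discrete-time multistate life-table engine. Predicted biennial transition
# probabilities are assembled into age-indexed 4x4 matrices over 2-year
# intervals from the start age up to the truncation age; truncated state
# expectancies come from the fundamental matrix N = (I - U)^{-1} of the
# age-expanded transient chain (state x age interval), cross-checked against
# direct forward accumulation of occupancy vectors. Occupancy convention:
# the state at the start of an interval is credited with the full step.

#' Assemble the age-indexed transition matrix set
#'
#' Builds one row-stochastic 4x4 matrix per 2-year age interval, with
#' interval starts at `start_age, start_age + 2, ...` strictly below
#' `truncation_age` (33 matrices for ages 20 to 85). Probabilities come from
#' [predict_probability_row()] evaluated at the interval start (or midpoint);
#' the death row is absorbing and the structural zeros hold exactly.
#'
#' @param fit An `mmle_fit`.
#' @param sex Stratum.
#' @param profile An [mmle_profile()].
#' @param start_age,truncation_age Age grid bounds (years), default 20 to 85.
#' @param step Interval width in years (fixed at 2 in the main analysis).
#' @param prediction_age `"start"` (default) or `"midpoint"` of each interval.
#' @param half_final_interval Credit only half of the final interval, so the
#'   horizon lands on the truncation age exactly rather than overshooting by
#'   one half-step (default `FALSE`).
#' @return Object of class `mmle_matrix_set`.
#' @export
build_matrix_set <- function(fit, sex, profile,
                             start_age = 20, truncation_age = 85, step = 2,
                             prediction_age = c("start", "midpoint"),
                             half_final_interval = FALSE) {
  prediction_age <- match.arg(prediction_age)
  if (start_age >= truncation_age) abort("start_age must be below truncation_age")
  starts <- seq(start_age, by = step,
                length.out = ceiling((truncation_age - start_age) / step))
  ages <- if (prediction_age == "start") starts else starts + step / 2
  P <- array(0, dim = c(4, 4, length(starts)),
             dimnames = list(state_levels(), state_levels(), NULL))
  for (o in transient_states()) {
    rows <- predict_probability_row(fit, sex, o, profile, ages)
    P[o, , ] <- t(rows)
  }
  P["dead", "dead", ] <- 1
  for (k in seq_along(starts)) {
    if (max(abs(rowSums(P[, , k]) - 1)) > 1e-10) {
      abort("non-stochastic transition matrix produced")
    }
  }
  structure(list(starts = starts, step = step, P = P, sex = sex,
                 profile = profile, start_age = start_age,
                 truncation_age = truncation_age,
                 half_final_interval = half_final_interval),
            class = "mmle_matrix_set")
}

#' Construct a matrix set from explicit matrices
#'
#' Mainly for testing and for the Monte Carlo oracle: wraps a list of 4x4
#' row-stochastic matrices (ordered by age interval) as an `mmle_matrix_set`.
#'
#' @param matrices List of 4x4 matrices, rows/cols ordered as
#'   [state_levels()].
#' @param start_age First interval start.
#' @param step Interval width in years.
#' @param half_final_interval See [build_matrix_set()].
#' @return Object of class `mmle_matrix_set`.
#' @export
matrix_set_from_list <- function(matrices, start_age = 20, step = 2,
                                 half_final_interval = FALSE) {
  n <- length(matrices)
  P <- array(0, dim = c(4, 4, n),
             dimnames = list(state_levels(), state_levels(), NULL))
  for (k in seq_len(n)) {
    M <- matrices[[k]]
    stopifnot(all(dim(M) == c(4, 4)))
    if (max(abs(rowSums(M) - 1)) > 1e-10 || any(M < 0)) {
      abort("matrices must be row-stochastic with entries in [0, 1]")
    }
    if (any(M[lower.tri(M)] != 0)) {
      abort("reverse transitions must have probability exactly zero")
    }
    P[, , k] <- M
  }
  structure(list(starts = seq(start_age, by = step, length.out = n),
                 step = step, P = P, sex = NA_character_, profile = NULL,
                 start_age = start_age,
                 truncation_age = start_age + n * step,
                 half_final_interval = half_final_interval),
            class = "mmle_matrix_set")
}

# interval credit weights (full step each, optionally half for the final one)
interval_weights <- function(ms) {
  wt <- rep(ms$step, length(ms$starts))
  if (isTRUE(ms$half_final_interval)) wt[length(wt)] <- ms$step / 2
  wt
}

# forward accumulation of occupancy vectors over the transient states
expectancy_forward <- function(ms, origin) {
  wt <- interval_weights(ms)
  v <- as.numeric(state_levels()[1:3] == origin)
  years <- numeric(3)
  for (k in seq_along(ms$starts)) {
    years <- years + wt[k] * v
    v <- as.vector(v %*% ms$P[1:3, 1:3, k])
  }
  names(years) <- transient_states()
  years
}

# fundamental matrix of the age-expanded transient chain
expectancy_fundamental <- function(ms, origin) {
  n <- length(ms$starts)
  wt <- interval_weights(ms)
  U <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(n - 1)) {
    ri <- (k - 1) * 3 + 1:3
    U[ri, ri + 3] <- ms$P[1:3, 1:3, k]
  }
  N <- solve(diag(3 * n) - U)
  row <- N[match(origin, transient_states()), ]
  occ <- matrix(row, nrow = 3)                    # states x intervals
  years <- as.vector(occ %*% wt)
  names(years) <- transient_states()
  years
}

#' Truncated state expectancies conditional on an origin state
#'
#' Expected years spent in each transient state between the start and
#' truncation ages, for an individual in `origin` at the start age. Computed
#' through the fundamental matrix of the age-expanded absorbing chain and
#' verified against direct forward accumulation (the two must agree to
#' 1e-9); total truncated life expectancy is the sum across states.
#'
#' @param ms An `mmle_matrix_set`.
#' @param origin Transient origin state.
#' @return One-row tibble: `origin`, `years_no_disease`, `years_one_disease`,
#'   `years_multimorbid`, `total_le`.
#' @export
conditional_expectancies <- function(ms, origin) {
  stopifnot(inherits(ms, "mmle_matrix_set"))
  if (!origin %in% transient_states()) abort("origin must be a transient state")
  yrs_f <- expectancy_forward(ms, origin)
  yrs_n <- expectancy_fundamental(ms, origin)
  if (max(abs(yrs_f - yrs_n)) > 1e-9) {
    abort("internal cross-check failed: fundamental-matrix and forward expectancies disagree")
  }
  tibble(origin = origin,
         years_no_disease = yrs_n[["no_disease"]],
         years_one_disease = yrs_n[["one_disease"]],
         years_multimorbid = yrs_n[["multimorbid"]],
         total_le = sum(yrs_n))
}

#' Origin-state distribution at the starting ages
#'
#' Design-weighted shares of the three transient states among individuals'
#' baseline (first valid) observations within an age window — by default
#' ages 20 up to (but excluding) 30, the window used to stabilize the
#' origin weights at starting age 20.
#'
#' @param panel State-classified panel (see [derive_states()]).
#' @param sex Stratum.
#' @param age_window Two-element numeric `[lower, upper)`.
#' @return One-row tibble with columns `no_disease`, `one_disease`,
#'   `multimorbid` (summing to one), `sex`, `n` (individuals in window).
#' @export
origin_distribution <- function(panel, sex, age_window = c(20, 30)) {
  base <- panel %>%
    filter(.data$sex == .env$sex, !is.na(.data$state), .data$state != "dead") %>%
    group_by(.data$person_id) %>%
    slice(1) %>%
    ungroup() %>%
    filter(.data$age >= age_window[1], .data$age < age_window[2])
  if (nrow(base) == 0) {
    abort(paste0("no baseline observations in age window [", age_window[1],
                 ", ", age_window[2], ") for sex '", sex, "'"))
  }
  w <- vapply(transient_states(), function(s)
    sum(base$design_weight[base$state == s]), numeric(1))
  w <- w / sum(w)
  tibble(no_disease = w[["no_disease"]], one_disease = w[["one_disease"]],
         multimorbid = w[["multimorbid"]], sex = sex, n = nrow(base))
}

#' Origin-weighted life expectancy and MMLE
#'
#' Averages the conditional state expectancies over an origin-state
#' distribution: weighted LE is the weighted mean of the conditional total
#' LEs, and multimorbid life expectancy (MMLE) the weighted mean of the
#' years spent multimorbid.
#'
#' @param conditional Tibble of [conditional_expectancies()] rows covering
#'   every origin with positive weight.
#' @param dist One-row tibble (or named vector) of origin weights over the
#'   transient states, summing to one.
#' @return One-row tibble: `weighted_le`, `mmle`, `pct_mm` (percentage of LE
#'   spent multimorbid, unrounded), plus the per-state weighted years.
#' @export
weighted_expectancies <- function(conditional, dist) {
  if (is_tibble(dist) || is.data.frame(dist)) {
    dist <- unlist(dist[1, transient_states()])
  }
  dist <- dist[transient_states()]
  if (any(is.na(dist)) || abs(sum(dist) - 1) > 1e-8 || any(dist < 0)) {
    abort("origin distribution must be non-negative and sum to 1")
  }
  need <- transient_states()[dist > 0]
  missing <- setdiff(need, conditional$origin)
  if (length(missing) > 0) {
    abort(paste0("positive origin weight on state(s) without conditional ",
                 "expectancies: ", paste(missing, collapse = ", ")))
  }
  cond <- conditional[match(transient_states(), conditional$origin), ]
  dvec <- as.numeric(dist)
  dvec[is.na(cond$total_le)] <- 0          # zero-weight origins may be absent
  le <- sum(dvec * cond$total_le, na.rm = TRUE)
  tibble(
    weighted_le = le,
    mmle = sum(dvec * cond$years_multimorbid, na.rm = TRUE),
    years_no_disease = sum(dvec * cond$years_no_disease, na.rm = TRUE),
    years_one_disease = sum(dvec * cond$years_one_disease, na.rm = TRUE),
    pct_mm = 100 * sum(dvec * cond$years_multimorbid, na.rm = TRUE) / le
  )
}

#' @export
print.mmle_matrix_set <- function(x, ...) {
  cat("<mmle_matrix_set>", length(x$starts), "intervals of", x$step,
      "years from age", x$start_age, "to", x$truncation_age,
      if (!is.na(x$sex)) paste0("(", x$sex, ")") else "", "\n")
  invisible(x)
}

#' Plot transition probabilities against age
#'
#' Line plot of each admissible transition's probability over the age grid,
#' faceted by origin state.
#'
#' @param object An `mmle_matrix_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mmle_matrix_set
#' @export
autoplot.mmle_matrix_set <- function(object, ...) {
  rows <- list()
  for (o in transient_states()) {
    for (d in admissible_destinations(o)) {
      rows[[paste(o, d)]] <- tibble(
        age = object$starts, origin = o, destination = d,
        probability = object$P[o, d, ])
    }
  }
  df <- bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$probability,
                                   colour = .data$destination)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~origin) +
    ggplot2::labs(x = "age at interval start (years)",
                  y = "biennial transition probability",
                  colour = "destination") +
    ggplot2::theme_minimal()
}
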