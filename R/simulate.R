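# Synthetic NIDS-like panel generator. Individuals carry fixed covariates
# and a latent health state that evolves through biennial waves under the
# multinomial-logit transition model in the config; the observed panel is
# the long person-wave table with disease flags, blood pressure, vital
# status and design weight. Deaths between waves surface as an alive=FALSE
# row at the following wave (household-report convention); attrition removes
# all later rows.

# vectorised categorical draw: one draw per row of a probability matrix
sample_rows <- function(prob) {
  k <- ncol(prob)
  if (k == 1) return(rep(1L, nrow(prob)))
  cp <- prob
  for (j in 2:k) cp[, j] <- cp[, j - 1] + cp[, j]
  u <- runif(nrow(prob))
  as.integer(rowSums(u > cp[, -k, drop = FALSE]) + 1L)
}

# build a design matrix for named coefficient columns from covariate vectors
design_for_terms <- function(term_names, age, urban, race = NULL, education = NULL) {
  n <- length(age)
  edu2 <- NULL
  col <- function(nm) {
    switch(nm,
      "(Intercept)" = rep(1, n),
      "age" = age,
      "urban" = urban,
      "race_asian_indian" = as.numeric(race == "Asian/Indian"),
      "race_coloured" = as.numeric(race == "Coloured"),
      "race_white" = as.numeric(race == "White"),
      "edu_secondary" = as.numeric(education == "secondary"),
      "edu_post_secondary" = as.numeric(education == "post_secondary"),
      "edu2_secondary_plus" = as.numeric(education %in% c("secondary", "post_secondary")),
      "race_coloured_x_edu2" = as.numeric(race == "Coloured") *
        as.numeric(education %in% c("secondary", "post_secondary")),
      "race_white_x_edu2" = as.numeric(race == "White") *
        as.numeric(education %in% c("secondary", "post_secondary")),
      abort(paste0("unknown model term: ", nm))
    )
  }
  X <- vapply(term_names, col, numeric(n))
  if (n == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, term_names))
  X
}

# biennial transition probabilities over admissible destinations, stay first
transition_probs <- function(B, age, urban, race = NULL, education = NULL) {
  X <- design_for_terms(colnames(B), age, urban, race, education)
  eta <- X %*% t(B)
  ex <- exp(eta)
  denom <- 1 + rowSums(ex)
  cbind(stay = 1 / denom, ex / denom)
}

#' Generate a synthetic NIDS-like panel
#'
#' Simulates the long person-wave panel described by an [mmle_sim_config()]:
#' baseline states drawn from the configured baseline distribution, forward
#' evolution through the configured multinomial-logit transition dynamics at
#' each individual's exact age (no reverse transitions by construction, death
#' absorbing), independent per-wave attrition, and deaths recorded at the
#' wave after they occur. Disease flags consistent with the latent state are
#' assigned from baseline prevalence weights; hypertensive person-waves get
#' blood-pressure means satisfying the hypertension rule, others get
#' normotensive values.
#'
#' @param config An [mmle_sim_config()].
#' @return Tibble with one row per person-wave: `person_id`, `wave`, `age`,
#'   `alive`, the 14 condition flag columns, `sbp_mean`, `dbp_mean`, `sex`,
#'   `race`, `education`, `residence`, `design_weight`. The config (the
#'   generative truth) is attached as attribute `"config"`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "mmle_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  W <- config$n_waves
  mix <- config$covariate_mix

  sex <- names(mix$sex)[sample_rows(matrix(mix$sex, n, length(mix$sex), byrow = TRUE))]
  race <- names(mix$race)[sample_rows(matrix(mix$race, n, length(mix$race), byrow = TRUE))]
  education <- names(mix$education)[
    sample_rows(matrix(mix$education, n, length(mix$education), byrow = TRUE))]
  urban <- as.numeric(runif(n) < mix$urban)
  weight <- rlnorm(n, config$design_weight_model$meanlog, config$design_weight_model$sdlog)

  base_age <- runif(n, config$baseline_age_range[1], config$baseline_age_range[2])
  age <- matrix(NA_real_, n, W)
  for (w in seq_len(W)) {
    age[, w] <- base_age + (w - 1) * config$wave_spacing_years +
      runif(n, -config$age_jitter, config$age_jitter)
  }
  age[, 1] <- pmax(age[, 1], 20)

  # baseline state
  bsd <- config$baseline_state_distribution
  if (is.function(bsd)) {
    p0 <- bsd(age[, 1], sex)
  } else {
    p0 <- t(vapply(sex, function(sx) bsd[[sx]], numeric(3)))
  }
  state <- matrix(NA_integer_, n, W)       # 1..4 over state_levels()
  observed <- matrix(FALSE, n, W)
  state[, 1] <- sample_rows(p0)
  observed[, 1] <- TRUE

  in_study <- rep(TRUE, n)                 # not yet attrited
  for (w in 2:W) {
    at_risk <- in_study & observed[, w - 1] & state[, w - 1] < 4L
    # attrition decided per wave, possibly state-dependent
    p_drop <- config$attrition_prob *
      config$state_attrition_multiplier[pmin(state[, w - 1], 3L)]
    dropped <- at_risk & (runif(n) < p_drop)
    in_study[dropped] <- FALSE
    live <- which(at_risk & !dropped)
    if (length(live) > 0) {
      for (sx in c("male", "female")) {
        for (oi in 1:3) {
          idx <- live[sex[live] == sx & state[live, w - 1] == oi]
          if (length(idx) == 0) next
          B <- config$true_coefficients[[sx]][[transient_states()[oi]]]
          pr <- transition_probs(B, age[idx, w - 1], urban[idx],
                                 race[idx], education[idx])
          draw <- sample_rows(pr)
          dests <- c(transient_states()[oi], rownames(B))
          state[idx, w] <- match(dests[draw], state_levels())
        }
      }
      observed[live, w] <- TRUE
    }
  }

  # assign up to two concrete conditions per person, consistent with the
  # latent counts (states only distinguish 0 / 1 / 2+ conditions)
  cw <- default_condition_weights()
  cond <- condition_names()
  state_obs <- state; state_obs[!observed] <- NA_integer_
  max_state <- do.call(pmax, c(lapply(seq_len(W), function(w) state_obs[, w]),
                               list(na.rm = TRUE)))
  d1 <- rep(NA_integer_, n); d2 <- rep(NA_integer_, n)
  need1 <- max_state >= 2
  d1[need1] <- sample_rows(matrix(cw / sum(cw), sum(need1), length(cw), byrow = TRUE))
  need2 <- max_state >= 3
  if (any(need2)) {
    w2 <- matrix(cw, sum(need2), length(cw), byrow = TRUE)
    w2[cbind(seq_len(sum(need2)), d1[need2])] <- 0    # distinct second condition
    d2[need2] <- sample_rows(w2 / rowSums(w2))
  }

  # long format
  obs_idx <- which(observed, arr.ind = TRUE)
  obs_idx <- obs_idx[order(obs_idx[, 1], obs_idx[, 2]), , drop = FALSE]
  i <- obs_idx[, 1]; w <- obs_idx[, 2]
  st <- state[cbind(i, w)]
  alive <- st < 4L
  n_cond <- pmin(st, 3L) - 1L               # 0, 1, 2 conditions by state
  flags <- matrix(FALSE, length(i), length(cond), dimnames = list(NULL, cond))
  has1 <- alive & n_cond >= 1L
  flags[cbind(which(has1), d1[i[has1]])] <- TRUE
  has2 <- alive & n_cond >= 2L
  flags[cbind(which(has2), d2[i[has2]])] <- TRUE
  flags[!alive, ] <- NA

  hyp <- flags[, "hypertension"]
  sbp <- dbp <- rep(NA_real_, length(i))
  hy <- which(alive & !is.na(hyp) & hyp)
  no <- which(alive & !is.na(hyp) & !hyp)
  sbp[hy] <- runif(length(hy), 150, 190)
  dbp[hy] <- runif(length(hy), 90, 110)
  sbp[no] <- runif(length(no), 100, 138)
  dbp[no] <- runif(length(no), 65, 88)

  panel <- tibble(
    person_id = i,
    wave = as.integer(obs_idx[, 2]),
    age = age[cbind(i, obs_idx[, 2])],
    alive = alive
  )
  panel <- dplyr::bind_cols(panel, as_tibble(as.data.frame(flags)))
  panel$sbp_mean <- sbp
  panel$dbp_mean <- dbp
  panel$sex <- factor(sex[i], levels = c("male", "female"))
  panel$race <- factor(race[i], levels = names(default_covariate_mix()$race))
  panel$education <- factor(education[i], levels = names(default_covariate_mix()$education))
  panel$residence <- factor(ifelse(urban[i] == 1, "urban", "rural"),
                            levels = c("urban", "rural"))
  panel$design_weight <- weight[i]
  attr(panel, "config") <- config
  panel
}

#' Inject apparent recoveries into a panel
#'
#' Randomly downgrades the observed condition count of later-wave alive rows
#' (to at most one condition), creating state reversals that violate the
#' irreversibility assumption. Used to exercise the monotone-coding repair
#' in [enforce_monotone_states()]; the blood-pressure columns are left
#' untouched, so the noise targets flag-based classification.
#'
#' @param panel A panel tibble as from [simulate_panel()].
#' @param rate Per-row downgrade probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The panel with some later-wave condition flags dropped; the number
#'   of modified rows is attached as attribute `"n_reversals"`.
#' @export
inject_reversal_noise <- function(panel, rate, seed = 1L) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  cfg <- attr(panel, "config")
  if (rate == 0) return(panel)
  set.seed(as.integer(seed))
  panel <- panel %>% arrange(.data$person_id, .data$wave)
  first_wave <- panel %>%
    group_by(.data$person_id) %>%
    mutate(is_first = row_number() == 1L) %>%
    pull(.data$is_first)
  eligible <- which(panel$alive & !first_wave)
  hit <- eligible[runif(length(eligible)) < rate]
  cond <- condition_names()
  fl <- as.matrix(panel[cond])
  for (r in hit) {
    on <- which(fl[r, ])
    if (length(on) > 1) fl[r, on[-1]] <- FALSE else if (length(on) == 1) fl[r, on] <- FALSE
  }
  panel[cond] <- as.data.frame(fl)
  attr(panel, "config") <- cfg
  attr(panel, "n_reversals") <- length(hit)
  panel
}

#' Write / read a panel as long-format CSV
#'
#' @param panel Panel tibble.
#' @param path File path.
#' @return `read_panel_csv()` returns the panel tibble with factor columns
#'   restored; `write_panel_csv()` returns `path` invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  panel$sex <- factor(panel$sex, levels = c("male", "female"))
  panel$race <- factor(panel$race, levels = names(default_covariate_mix()$race))
  panel$education <- factor(panel$education,
                            levels = names(default_covariate_mix()$education))
  panel$residence <- factor(panel$residence, levels = c("urban", "rural"))
  panel
}

#' Serialize the generative truth of a config as JSON
#'
#' Writes the true coefficient matrices (and baseline distribution) so that
#' parameter-recovery checks can reload the truth alongside a panel CSV.
#'
#' @param config An [mmle_sim_config()].
#' @param path Output path.
#' @export
write_generative_truth <- function(config, path) {
  truth <- list(
    true_coefficients = lapply(config$true_coefficients, function(sx)
      lapply(sx, function(B) {
        list(destinations = rownames(B), terms = colnames(B),
             coefficients = unname(B))
      })),
    baseline_state_distribution = config$baseline_state_distribution,
    seed = config$seed
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
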