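# Shared fixture builders. Everything is generated in code; sizes are kept
# small in unit tests and scaled up only in the acceptance suite.

# small default-condition config
tiny_config <- function(n = 500, seed = 1L, ...) {
  mmle_sim_config(n_individuals = n, seed = seed, ...)
}

# coefficients with zero age/urban slopes: constant biennial probabilities
constant_prob_coefficients <- function(p_nd = c(no_disease = 0.885, one_disease = 0.082,
                                                multimorbid = 0.011, dead = 0.022),
                                       p_1d = c(one_disease = 0.831, multimorbid = 0.119,
                                                dead = 0.05),
                                       p_mm = c(multimorbid = 0.888, dead = 0.112)) {
  zero <- c(disease = 0, dead = 0)
  one_sex <- list(
    no_disease = calibrate_coefficients(p_nd, "no_disease", 0, 0, zero, zero),
    one_disease = calibrate_coefficients(p_1d, "one_disease", 0, 0, zero, zero),
    multimorbid = calibrate_coefficients(p_mm, "multimorbid", 0, 0, zero, zero))
  list(male = one_sex, female = one_sex)
}

# coefficients under which death is structurally impossible
deathless_coefficients <- function() {
  co <- constant_prob_coefficients()
  for (sx in names(co)) for (o in names(co[[sx]])) {
    co[[sx]][[o]]["dead", "(Intercept)"] <- -Inf
  }
  co
}

# seeded random valid matrix set: upper-triangular row-stochastic matrices
# with absorbing death
random_matrix_set <- function(seed, n_intervals = 10, start_age = 20) {
  set.seed(seed)
  mats <- lapply(seq_len(n_intervals), function(k) {
    M <- matrix(0, 4, 4, dimnames = list(state_levels(), state_levels()))
    for (i in 1:3) {
      raw <- runif(4 - i + 1)
      # keep a healthy stay probability so chains do not die instantly
      raw[1] <- raw[1] + 2
      M[i, i:4] <- raw / sum(raw)
    }
    M[4, 4] <- 1
    M
  })
  matrix_set_from_list(mats, start_age = start_age)
}

# single-transient-state geometric survival chain: stay with probability p,
# die with 1 - p, in every interval
geometric_matrix_set <- function(p, n_intervals = 33) {
  M <- matrix(0, 4, 4, dimnames = list(state_levels(), state_levels()))
  M["no_disease", "no_disease"] <- p
  M["no_disease", "dead"] <- 1 - p
  M["one_disease", "one_disease"] <- 1
  M["multimorbid", "multimorbid"] <- 1
  M["dead", "dead"] <- 1
  matrix_set_from_list(rep(list(M), n_intervals))
}

# hand-built fit object with given MM-origin death log-odds eta (age and
# urban slopes zero); used for closed-form logistic checks
fit_with_mm_eta <- function(eta, vcov_scale = 0) {
  cfg <- tiny_config()
  co <- constant_prob_coefficients()
  for (sx in c("male", "female")) {
    co[[sx]]$multimorbid["dead", "(Intercept)"] <- eta
  }
  cfg$true_coefficients <- co
  fit <- true_transition_model(cfg)
  if (vcov_scale > 0) {
    for (sx in c("male", "female")) for (o in transient_states()) {
      np <- length(fit$strata[[sx]][[o]]$coef)
      fit$strata[[sx]][[o]]$vcov <- diag(vcov_scale, np)
    }
  }
  fit
}

# a tiny hand-written panel for exclusion/record tests
hand_panel <- function() {
  flags0 <- as.list(setNames(rep(FALSE, 14), condition_names()))
  row <- function(id, wave, age, alive, n_dis = 0, sex = "female", miss_edu = FALSE) {
    fl <- flags0
    if (n_dis >= 1) fl$hypertension <- TRUE
    if (n_dis >= 2) fl$diabetes <- TRUE
    if (!alive) fl[] <- NA
    tibble::tibble(person_id = id, wave = as.integer(wave), age = age,
                   alive = alive, !!!fl,
                   sbp_mean = NA_real_, dbp_mean = NA_real_,
                   sex = factor(sex, levels = c("male", "female")),
                   race = factor("African",
                                 levels = c("African", "Asian/Indian", "Coloured", "White")),
                   education = factor(if (miss_edu) NA else "secondary",
                                      levels = c("less_than_secondary", "secondary",
                                                 "post_secondary")),
                   residence = factor("urban", levels = c("urban", "rural")),
                   design_weight = 1)
  }
  dplyr::bind_rows(
    row(1, 1, 25, TRUE, 0), row(1, 2, 27, TRUE, 1),          # kept, 2 waves
    row(2, 1, 40, TRUE, 2),                                  # single wave -> excluded
    row(3, 1, 50, TRUE, 1), row(3, 2, 52, FALSE),            # interview + death -> kept
    row(4, 1, 30, TRUE, 0, miss_edu = TRUE),
    row(4, 2, 32, TRUE, 0, miss_edu = TRUE),                 # missing education -> excluded
    row(5, 1, 60, TRUE, 1), row(5, 3, 64, TRUE, 2),          # gapped pair -> kept
    row(6, 1, 35, TRUE, 2), row(6, 2, 37, TRUE, 2),
    row(6, 3, 39, TRUE, 2), row(6, 4, 41, TRUE, 2),
    row(6, 5, 43, TRUE, 2)                                   # all five waves
  )
}
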