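test_that("predicted rows follow the closed-form logistic from the multimorbid origin", {
  # symmetric case: zero linear predictor -> (0.5, 0.5) over {stay, dead}
  fit0 <- fit_with_mm_eta(0)
  row0 <- predict_probability_row(fit0, "female", "multimorbid",
                                  mmle_profile(0), 50)
  expect_equal(unname(row0[1, c("multimorbid", "dead")]), c(0.5, 0.5),
               tolerance = 1e-12)
  # closed form P(dead) = exp(eta) / (1 + exp(eta))
  for (eta in c(-2, 0, 1)) {
    row <- predict_probability_row(fit_with_mm_eta(eta), "male", "multimorbid",
                                   mmle_profile(0), 40)
    expect_equal(unname(row[1, "dead"]), exp(eta) / (1 + exp(eta)),
                 tolerance = 1e-12)
    # structural zeros: reverse destinations are exactly zero
    expect_identical(unname(row[1, c("no_disease", "one_disease")]), c(0, 0))
    expect_equal(sum(row), 1, tolerance = 1e-12)
  }
})

test_that("predicted rows are probability distributions across ages and profiles", {
  panel <- simulate_panel(tiny_config(n = 2500, seed = 14))
  cl <- derive_states(apply_exclusions(panel)$panel)
  rec <- build_transition_records(cl)
  fit <- fit_transition_models(rec, model_spec("M2"))
  ages <- seq(20, 84, 2)
  for (race in c("African", "White")) {
    prof <- mmle_profile(fit$urban_proportion, race = race)
    for (o in transient_states()) {
      rows <- predict_probability_row(fit, "female", o, prof, ages)
      expect_true(all(rows >= 0 & rows <= 1))
      expect_equal(rowSums(rows), rep(1, length(ages)), tolerance = 1e-12)
      # structural zeros at inadmissible destinations
      banned <- setdiff(state_levels(), admissible_destinations(o))
      if (length(banned) > 0) expect_true(all(rows[, banned] == 0))
    }
  }
  # a profile lacking a required covariate is rejected by name
  expect_error(predict_probability_row(fit, "female", "no_disease",
                                       mmle_profile(0.5), 40),
               "race")
})

test_that("raising the death coefficient strictly raises predicted death probability", {
  fit <- true_transition_model(tiny_config())
  p0 <- predict_probability_row(fit, "male", "one_disease", mmle_profile(0.5), 60)
  fit2 <- fit
  fit2$strata$male$one_disease$coef["dead", "(Intercept)"] <-
    fit2$strata$male$one_disease$coef["dead", "(Intercept)"] + 0.5
  p1 <- predict_probability_row(fit2, "male", "one_disease", mmle_profile(0.5), 60)
  expect_gt(p1[1, "dead"], p0[1, "dead"])
})

test_that("fitted probabilities recover the generative ones on a moderate panel", {
  cfg <- tiny_config(n = 15000, seed = 23)
  panel <- simulate_panel(cfg)
  cl <- derive_states(apply_exclusions(panel)$panel)
  rec <- build_transition_records(cl, include_baseline = FALSE)
  fit <- fit_transition_models(rec, model_spec("M1"), vcov_type = "model")
  tm <- true_transition_model(cfg)
  prof_f <- mmle_profile(fit$urban_proportion)
  prof_t <- mmle_profile(cfg$covariate_mix$urban)
  for (sx in c("male", "female")) for (o in transient_states()) {
    for (age in c(40, 60, 80)) {
      est <- predict_probability_row(fit, sx, o, prof_f, age)
      tru <- predict_probability_row(tm, sx, o, prof_t, age)
      expect_lt(max(abs(est - tru)), 0.03)
    }
  }
})

test_that("degenerate destination patterns raise a convergence error naming the origin", {
  panel <- simulate_panel(tiny_config(n = 600, seed = 45))
  cl <- derive_states(apply_exclusions(panel)$panel)
  rec <- build_transition_records(cl)
  # force all multimorbid-origin records to one destination
  rec$destination_state[rec$origin_state == "multimorbid"] <- "multimorbid"
  expect_error(suppressWarnings(fit_transition_models(rec, model_spec("M1"))),
               "multimorbid")
})

test_that("an origin without observed deaths triggers a boundary warning", {
  co <- default_true_coefficients <- tiny_config()$true_coefficients
  for (sx in c("male", "female")) {
    co[[sx]]$no_disease["dead", "(Intercept)"] <- -Inf   # deathless origin only
  }
  cfg <- tiny_config(n = 400, seed = 6, true_coefficients = co,
                     attrition_prob = 0)
  cl <- derive_states(apply_exclusions(simulate_panel(cfg))$panel)
  rec <- build_transition_records(cl)
  w <- capture_warnings(fit <- fit_transition_models(rec, model_spec("M1")))
  expect_true(any(grepl("boundary.*no_disease", w)))   # one warning per sex
  # the degenerate death probability is exactly zero in predictions
  row <- predict_probability_row(fit, "male", "no_disease",
                                 mmle_profile(fit$urban_proportion), 60)
  expect_identical(unname(row[1, "dead"]), 0)
})

test_that("a generative zero age slope is not spuriously detected", {
  co <- constant_prob_coefficients()          # zero age slope everywhere
  n_sig <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    cfg <- mmle_sim_config(n_individuals = 2500, seed = 1000 + r,
                           true_coefficients = co)
    cl <- derive_states(apply_exclusions(simulate_panel(cfg))$panel)
    rec <- build_transition_records(cl, include_baseline = FALSE)
    fit <- fit_transition_models(rec, model_spec("M1"), vcov_type = "model")
    td <- tidy(fit)
    p <- td$p.value[td$sex == "female" & td$origin == "one_disease" &
                      td$destination == "multimorbid" & td$term == "age"]
    if (p < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_rep - n_sig, 93)
})

test_that("tidy and glance summarize the fit in broom shape", {
  panel <- simulate_panel(tiny_config(n = 2000, seed = 9))
  cl <- derive_states(apply_exclusions(panel)$panel)
  rec <- build_transition_records(cl)
  fit <- fit_transition_models(rec, model_spec("M1"))
  td <- tidy(fit)
  expect_named(td, c("sex", "origin", "destination", "term", "estimate",
                     "std.error", "statistic", "p.value"))
  # M1: per sex 3 + 2 + 1 destination equations x 3 terms = 18 coefficients
  expect_identical(nrow(td), 36L)
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_identical(gl$model_id, "M1")
  expect_true(gl$converged)
  expect_identical(gl$n_parameters, 36)
  # serialization round-trip keeps the coefficients
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(unlist(back$strata$male$no_disease$coef$values),
               as.vector(t(fit$strata$male$no_disease$coef)), tolerance = 1e-9)
})
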