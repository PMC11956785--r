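test_that("generation is deterministic given the seed", {
  p1 <- simulate_panel(tiny_config(n = 300, seed = 42))
  p2 <- simulate_panel(tiny_config(n = 300, seed = 42))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- simulate_panel(tiny_config(n = 300, seed = 43))
  expect_false(identical(p1$age, p3$age))
})

test_that("structurally impossible death plus zero attrition yields complete alive panels", {
  cfg <- tiny_config(n = 200, seed = 5,
                     true_coefficients = deathless_coefficients(),
                     attrition_prob = 0)
  panel <- simulate_panel(cfg)
  expect_true(all(panel$alive))
  obs <- dplyr::count(panel, person_id)
  expect_identical(nrow(obs), 200L)
  expect_true(all(obs$n == cfg$n_waves))
})

test_that("empirical one-disease to multimorbidity fraction matches the generative probability", {
  p_true <- 0.119
  cfg <- mmle_sim_config(n_individuals = 50000, n_waves = 2, seed = 99,
                         true_coefficients = constant_prob_coefficients(),
                         attrition_prob = 0,
                         baseline_state_distribution = list(
                           male = c(no_disease = 0, one_disease = 1, multimorbid = 0),
                           female = c(no_disease = 0, one_disease = 1, multimorbid = 0)))
  panel <- simulate_panel(cfg)
  cl <- derive_states(panel, mm_definition())
  rec <- build_transition_records(cl, include_baseline = FALSE)
  one <- rec[rec$origin_state == "one_disease", ]
  frac <- mean(one$destination_state == "multimorbid")
  se <- sqrt(p_true * (1 - p_true) / nrow(one))
  expect_lt(abs(frac - p_true), 3 * se)
})

test_that("trajectories are monotone with absorbing death and marginals match the mix", {
  cfg <- tiny_config(n = 3000, seed = 7)
  panel <- simulate_panel(cfg)
  cl <- derive_states(panel, mm_definition(), repair_reversals = FALSE)
  st <- dplyr::arrange(cl, person_id, wave)
  by_person <- split(as.integer(st$state), st$person_id)
  expect_true(all(vapply(by_person, function(s) all(diff(s[!is.na(s)]) >= 0), logical(1))))
  # no observation after death (death terminates the trajectory)
  expect_true(all(vapply(by_person, function(s) {
    d <- which(s == 4L); length(d) <= 1 && (length(d) == 0 || d == length(s))
  }, logical(1))))
  # covariate marginals within sampling error of the configured mix
  ind <- dplyr::distinct(panel, person_id, sex, race, residence)
  expect_lt(abs(mean(ind$sex == "female") - cfg$covariate_mix$sex[["female"]]), 0.03)
  expect_lt(abs(mean(ind$race == "African") - cfg$covariate_mix$race[["African"]]), 0.03)
  expect_lt(abs(mean(ind$residence == "urban") - cfg$covariate_mix$urban), 0.03)
  expect_true(all(panel$design_weight > 0))
  # ages non-decreasing within person, none below 20 at first interview
  first <- dplyr::slice(dplyr::group_by(panel, person_id), 1)
  expect_true(all(first$age >= 20))
})

test_that("generated blood pressure is consistent with the hypertension flag", {
  panel <- simulate_panel(tiny_config(n = 1000, seed = 21))
  alive <- panel[panel$alive, ]
  expect_identical(classify_hypertension(alive$sbp_mean, alive$dbp_mean),
                   alive$hypertension)
})

test_that("reversal noise creates repairable downgrades", {
  panel <- simulate_panel(tiny_config(n = 400, seed = 3))
  expect_identical(inject_reversal_noise(panel, 0), panel)

  # rate 1 on a two-wave panel starting multimorbid: every second wave drops below MM
  cfg <- mmle_sim_config(n_individuals = 200, n_waves = 2, seed = 8,
                         true_coefficients = deathless_coefficients(),
                         attrition_prob = 0,
                         baseline_state_distribution = list(
                           male = c(no_disease = 0, one_disease = 0, multimorbid = 1),
                           female = c(no_disease = 0, one_disease = 0, multimorbid = 1)))
  mm2 <- inject_reversal_noise(simulate_panel(cfg), 1, seed = 2)
  cl <- derive_states(mm2, mm_definition(), repair_reversals = FALSE)
  w2 <- cl[cl$wave == 2L, ]
  expect_true(all(as.character(w2$state) != "multimorbid"))
  expect_true(all(as.character(cl$state[cl$wave == 1L]) == "multimorbid"))

  # seeded determinism of the injected count
  n1 <- attr(inject_reversal_noise(panel, 0.1, seed = 4), "n_reversals")
  n2 <- attr(inject_reversal_noise(panel, 0.1, seed = 4), "n_reversals")
  expect_identical(n1, n2)
  expect_gt(n1, 0)
  expect_error(inject_reversal_noise(panel, 1.5), "rate")
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(mmle_sim_config(n_individuals = 0), "n_individuals")
  expect_error(mmle_sim_config(n_waves = 1), "n_waves")
  expect_error(mmle_sim_config(wave_spacing_years = 0), "wave_spacing_years")
  expect_error(mmle_sim_config(attrition_prob = 1.2), "attrition_prob")
  bad <- default_true_dist <- list(
    male = c(no_disease = 0.5, one_disease = 0.4, multimorbid = 0.2),
    female = c(no_disease = 0.7, one_disease = 0.2, multimorbid = 0.1))
  expect_error(mmle_sim_config(baseline_state_distribution = bad),
               "baseline_state_distribution")
})

test_that("panel CSV round trip and truth serialization preserve content", {
  panel <- simulate_panel(tiny_config(n = 50, seed = 12))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(panel, tmp)
  back <- read_panel_csv(tmp)
  expect_equal(back$age, panel$age, tolerance = 1e-12)
  expect_identical(as.character(back$race), as.character(panel$race))
  expect_identical(back$alive, panel$alive)
  truth_path <- withr::local_tempfile(fileext = ".json")
  write_generative_truth(tiny_config(n = 50, seed = 12), truth_path)
  truth <- jsonlite::read_json(truth_path)
  expect_named(truth$true_coefficients, c("male", "female"))
})
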