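test_that("the age grid yields the expected number of matrices", {
  fit <- true_transition_model(tiny_config())
  prof <- mmle_profile(0.5)
  ms <- build_matrix_set(fit, "female", prof)              # 20 to 85
  expect_identical(length(ms$starts), 33L)
  expect_identical(ms$starts[1], 20)
  expect_identical(ms$starts[33], 84)
  ms40 <- build_matrix_set(fit, "female", prof, start_age = 40)
  expect_identical(length(ms40$starts), 23L)
  # every matrix row-stochastic with structural zeros and absorbing death
  for (k in c(1, 17, 33)) {
    M <- ms$P[, , k]
    expect_equal(rowSums(M), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(M[lower.tri(M)] == 0))
    expect_identical(unname(M["dead", ]), c(0, 0, 0, 1))
  }
  expect_error(build_matrix_set(fit, "female", prof, start_age = 85,
                                truncation_age = 85), "start_age")
})

test_that("degenerate chains give the forced expectancies", {
  # identity on transient states: nobody moves, 33 x 2 = 66 years in origin
  I4 <- diag(4); dimnames(I4) <- list(state_levels(), state_levels())
  ms <- matrix_set_from_list(rep(list(I4), 33))
  ce <- conditional_expectancies(ms, "no_disease")
  expect_equal(ce$total_le, 66)
  expect_equal(ce$years_no_disease, 66)
  expect_equal(ce$years_one_disease + ce$years_multimorbid, 0)

  # certain death in the first interval: the origin interval is still credited
  D <- matrix(0, 4, 4, dimnames = list(state_levels(), state_levels()))
  D[, "dead"] <- 1
  msd <- matrix_set_from_list(rep(list(D), 33))
  for (o in transient_states()) {
    expect_equal(conditional_expectancies(msd, o)$total_le, 2)
  }
})

test_that("the geometric survival chain matches its closed form to 1e-9", {
  for (p in c(0.9, 0.5, 0.99)) {
    ms <- geometric_matrix_set(p, n_intervals = 33)
    le <- conditional_expectancies(ms, "no_disease")$total_le
    expect_equal(le, 2 * (1 - p^33) / (1 - p), tolerance = 1e-9)
  }
})

test_that("state decomposition and convexity hold on random matrix sets", {
  for (seed in 1:8) {
    ms <- random_matrix_set(seed, n_intervals = 12)
    cond <- dplyr::bind_rows(lapply(transient_states(),
                                    function(o) conditional_expectancies(ms, o)))
    # decomposition identity
    expect_equal(cond$years_no_disease + cond$years_one_disease +
                   cond$years_multimorbid, cond$total_le, tolerance = 1e-9)
    expect_true(all(cond$total_le >= 0 & cond$total_le <= 2 * 12))
    # multimorbid origin can only occupy the multimorbid state
    mm <- cond[cond$origin == "multimorbid", ]
    expect_equal(mm$years_no_disease + mm$years_one_disease, 0)
    # weighted LE is a convex combination of conditional LEs
    set.seed(seed)
    d <- runif(3); d <- d / sum(d); names(d) <- transient_states()
    w <- weighted_expectancies(cond, d)
    expect_gte(w$weighted_le, min(cond$total_le) - 1e-12)
    expect_lte(w$weighted_le, max(cond$total_le) + 1e-12)
  }
})

test_that("raising death probabilities never raises life expectancy", {
  for (seed in 1:5) {
    ms <- random_matrix_set(seed, n_intervals = 10)
    worse <- ms
    for (k in seq_along(ms$starts)) {
      M <- ms$P[, , k]
      for (i in 1:3) {
        extra <- 0.5 * M[i, i]           # shift stay mass into death
        M[i, i] <- M[i, i] - extra
        M[i, 4] <- M[i, 4] + extra
      }
      worse$P[, , k] <- M
    }
    for (o in transient_states()) {
      expect_lte(conditional_expectancies(worse, o)$total_le,
                 conditional_expectancies(ms, o)$total_le + 1e-12)
    }
  }
})

test_that("weighted expectancies reduce correctly for degenerate distributions", {
  ms <- random_matrix_set(3, n_intervals = 12)
  cond <- dplyr::bind_rows(lapply(transient_states(),
                                  function(o) conditional_expectancies(ms, o)))
  d1 <- c(no_disease = 1, one_disease = 0, multimorbid = 0)
  w1 <- weighted_expectancies(cond, d1)
  expect_equal(w1$weighted_le, cond$total_le[cond$origin == "no_disease"])
  # identical conditionals collapse to the common value under any distribution
  same <- cond
  same[2:3, 2:5] <- same[rep(1, 2), 2:5]
  for (seed in 1:3) {
    set.seed(seed)
    d <- runif(3); d <- d / sum(d); names(d) <- transient_states()
    expect_equal(weighted_expectancies(same, d)$weighted_le,
                 cond$total_le[1], tolerance = 1e-12)
  }
  # hand-computed dot product
  d <- c(no_disease = 0.5, one_disease = 0.3, multimorbid = 0.2)
  w <- weighted_expectancies(cond, d)
  expect_equal(w$weighted_le, sum(d * cond$total_le), tolerance = 1e-12)
  expect_equal(w$mmle, sum(d * cond$years_multimorbid), tolerance = 1e-12)
  # positive weight on a missing origin is rejected
  expect_error(weighted_expectancies(cond[1:2, ], d), "multimorbid")
})

test_that("origin distributions are weighted baseline shares", {
  panel <- hand_panel()
  cl <- derive_states(panel)
  # person 1 (age 25, no disease) is the only female aged 20-29 at baseline
  d <- origin_distribution(cl, "female", c(20, 30))
  expect_equal(unname(unlist(d[1, 1:3])), c(1, 0, 0))
  # weighted share 2:1 between no-disease and multimorbid baselines
  p <- dplyr::bind_rows(
    dplyr::mutate(cl[cl$person_id == 1 & cl$wave == 1, ], design_weight = 2),
    dplyr::mutate(cl[cl$person_id == 6 & cl$wave == 1, ], age = 24))
  d2 <- origin_distribution(p, "female", c(20, 30))
  expect_equal(unname(unlist(d2[1, 1:3])), c(2/3, 0, 1/3), tolerance = 1e-12)
  expect_equal(sum(unlist(d2[1, 1:3])), 1, tolerance = 1e-12)
  expect_error(origin_distribution(cl, "male", c(20, 30)), "no baseline")
})

test_that("midpoint prediction and half-final-interval options shift the horizon", {
  fit <- true_transition_model(tiny_config())
  prof <- mmle_profile(0.5)
  full <- conditional_expectancies(
    build_matrix_set(fit, "male", prof), "no_disease")$total_le
  half <- conditional_expectancies(
    build_matrix_set(fit, "male", prof, half_final_interval = TRUE),
    "no_disease")$total_le
  expect_lt(half, full)
  expect_lt(full - half, 1)          # at most one half-interval of difference
  mid <- conditional_expectancies(
    build_matrix_set(fit, "male", prof, prediction_age = "midpoint"),
    "no_disease")$total_le
  expect_lt(mid, full)               # higher within-interval age, more mortality
})
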