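# End-to-end orchestration (simulate / load -> classify states -> exclusion
# cascade -> transition records -> per-sex model fits -> matrix sets ->
# weighted expectancies -> delta CIs), plus the small derived-quantity
# arithmetic used when summarizing stratified results, and the packaged
# fixture of published South African (NIDS 2008-17) expectancy estimates
# used for exact consistency checks.

#' Percentage of life expectancy spent with multimorbidity
#'
#' `round(100 * mmle / le)` to the nearest integer, halves away from zero —
#' the display convention of stratified expectancy tables.
#'
#' @param mmle,le Years; requires `le > 0` and `0 <= mmle <= le`.
#' @return Integer percentage(s).
#' @examples
#' percent_of_le(17.3, 44.3)  # 39
#' percent_of_le(9.8, 37.6)   # 26
#' @export
percent_of_le <- function(mmle, le) {
  if (any(le <= 0)) abort("le must be positive")
  if (any(mmle < 0 | mmle > le)) abort("mmle must lie in [0, le]")
  as.integer(floor(100 * mmle / le + 0.5))
}

#' Difference between two group estimates
#'
#' One-decimal difference `value_a - value_b`, the convention used when
#' quoting sex gaps and education gains in years.
#'
#' @param value_a,value_b Finite numerics (years).
#' @return `value_a - value_b` rounded to one decimal.
#' @export
group_gap <- function(value_a, value_b) {
  if (any(!is.finite(value_a)) || any(!is.finite(value_b))) {
    abort("group_gap requires finite inputs")
  }
  round(value_a - value_b, 1)
}

#' Packaged published expectancy estimates (South Africa, NIDS 2008-17)
#'
#' Published stratified estimates of weighted life expectancy at age 20,
#' multimorbid life expectancy and percentage of LE spent multimorbid, by
#' sex, for covariate sets M1-M4, from the incidence-based multistate
#' analysis of the South African NIDS panel. Used as a numeric fixture for
#' exact derived-quantity consistency checks; these estimates come from
#' restricted microdata and are not reproducible from synthetic panels.
#'
#' @return Tibble with columns `model`, `stratum`, `sex`, `weighted_le`,
#'   `le_lower`, `le_upper`, `mmle`, `mmle_lower`, `mmle_upper`, `pct_mm`.
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "published_expectancy_estimates.csv", package = "mmle",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published exclusion cascade of the NIDS analytic sample
#'
#' @return An [exclusion_tally()] with the published counts; construction
#'   re-verifies the cascade arithmetic.
#' @export
nids_exclusion_cascade <- function() {
  path <- system.file("extdata", "nids_exclusion_cascade.csv", package = "mmle",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  exclusion_tally(x$initial_n, x$excluded_single_wave, x$excluded_nonresponse,
                  x$excluded_missing, x$final_n)
}

# cell lookup helper for the fixture
fixture_cell <- function(fx, model, stratum, sex, col) {
  row <- fx[fx$model == model & fx$stratum == stratum & fx$sex == sex, ]
  if (nrow(row) != 1) {
    abort(paste0("malformed fixture: expected one row for ", model, " / ",
                 stratum, " / ", sex))
  }
  row[[col]]
}

#' Consistency checks of the published-estimate fixture
#'
#' Verifies, for every fixture row, that the printed percentage equals
#' `round(100 * mmle / weighted_le)` within one point (integer-rounding
#' tolerance), and recomputes from fixture cells every derived quantity
#' quoted alongside the published table: per-race and per-education sex gaps
#' in MMLE, and the education gains in LE and differences in MMLE within
#' each race of the interaction model.
#'
#' @param fixture Fixture tibble, by default [published_estimates()].
#' @return Tibble with one row per check: `quantity`, `expected`,
#'   `computed`, `pass`.
#' @export
check_published_estimates <- function(fixture = published_estimates()) {
  need <- c("model", "stratum", "sex", "weighted_le", "mmle", "pct_mm")
  if (!all(need %in% names(fixture))) abort("malformed fixture: missing columns")
  rows <- list()

  for (i in seq_len(nrow(fixture))) {
    r <- fixture[i, ]
    comp <- percent_of_le(r$mmle, r$weighted_le)
    rows[[paste0("pct_identity_", r$model, "_", r$stratum, "_", r$sex)]] <-
      tibble(quantity = paste("pct identity", r$model, r$stratum, r$sex),
             expected = r$pct_mm, computed = as.numeric(comp),
             pass = abs(comp - r$pct_mm) <= 1)
  }

  gap <- function(name, expected, model, stratum_a, sex_a, col_a,
                  stratum_b, sex_b, col_b) {
    comp <- group_gap(fixture_cell(fixture, model, stratum_a, sex_a, col_a),
                      fixture_cell(fixture, model, stratum_b, sex_b, col_b))
    rows[[name]] <<- tibble(quantity = name, expected = expected,
                            computed = comp, pass = comp == expected)
  }

  # sex gaps in MMLE by race (covariate set M2)
  gap("sex_gap_mmle_african", 7.5, "M2", "African", "female", "mmle",
      "African", "male", "mmle")
  gap("sex_gap_mmle_white", 7.5, "M2", "White", "female", "mmle",
      "White", "male", "mmle")
  gap("sex_gap_mmle_asian_indian", 8.1, "M2", "Asian/Indian", "female", "mmle",
      "Asian/Indian", "male", "mmle")
  gap("sex_gap_mmle_coloured", 8.3, "M2", "Coloured", "female", "mmle",
      "Coloured", "male", "mmle")
  # sex gaps in MMLE by education (M3)
  gap("sex_gap_mmle_less_than_secondary", 7.9, "M3", "less_than_secondary",
      "female", "mmle", "less_than_secondary", "male", "mmle")
  gap("sex_gap_mmle_secondary", 7.4, "M3", "secondary", "female", "mmle",
      "secondary", "male", "mmle")
  gap("sex_gap_mmle_post_secondary", 7.2, "M3", "post_secondary", "female", "mmle",
      "post_secondary", "male", "mmle")
  # education gains in LE within race, males (M4)
  gap("edu_gain_le_coloured_male", 10.3, "M4", "Coloured:secondary_plus", "male",
      "weighted_le", "Coloured:less_than_secondary", "male", "weighted_le")
  gap("edu_gain_le_african_male", 1.7, "M4", "African:secondary_plus", "male",
      "weighted_le", "African:less_than_secondary", "male", "weighted_le")
  gap("edu_gain_le_white_male", 1.3, "M4", "White:secondary_plus", "male",
      "weighted_le", "White:less_than_secondary", "male", "weighted_le")
  # education differences in MMLE within race, males (M4)
  gap("edu_diff_mmle_african_male", -1.5, "M4", "African:secondary_plus", "male",
      "mmle", "African:less_than_secondary", "male", "mmle")
  gap("edu_diff_mmle_white_male", -6.2, "M4", "White:secondary_plus", "male",
      "mmle", "White:less_than_secondary", "male", "mmle")
  gap("edu_diff_mmle_coloured_male", 4.9, "M4", "Coloured:secondary_plus", "male",
      "mmle", "Coloured:less_than_secondary", "male", "mmle")
  # education gains in LE within race, females (M4)
  gap("edu_gain_le_coloured_female", 8.7, "M4", "Coloured:secondary_plus", "female",
      "weighted_le", "Coloured:less_than_secondary", "female", "weighted_le")
  gap("edu_gain_le_african_female", 0.9, "M4", "African:secondary_plus", "female",
      "weighted_le", "African:less_than_secondary", "female", "weighted_le")
  gap("edu_gain_le_white_female", 0.1, "M4", "White:secondary_plus", "female",
      "weighted_le", "White:less_than_secondary", "female", "weighted_le")
  # education differences in MMLE within race, females (M4)
  gap("edu_diff_mmle_coloured_female", 4.5, "M4", "Coloured:secondary_plus",
      "female", "mmle", "Coloured:less_than_secondary", "female", "mmle")
  gap("edu_diff_mmle_african_female", -2.3, "M4", "African:secondary_plus",
      "female", "mmle", "African:less_than_secondary", "female", "mmle")
  gap("edu_diff_mmle_white_female", -7.7, "M4", "White:secondary_plus",
      "female", "mmle", "White:less_than_secondary", "female", "mmle")

  # headline integer percentages (M1)
  for (sx in c("male", "female")) {
    exp_pct <- fixture_cell(fixture, "M1", "overall", sx, "pct_mm")
    comp <- percent_of_le(fixture_cell(fixture, "M1", "overall", sx, "mmle"),
                          fixture_cell(fixture, "M1", "overall", sx, "weighted_le"))
    rows[[paste0("pct_mm_overall_", sx)]] <-
      tibble(quantity = paste0("pct_mm_overall_", sx), expected = exp_pct,
             computed = as.numeric(comp), pass = comp == exp_pct)
  }

  bind_rows(rows)
}

# enumerate the prediction strata of a covariate set
model_strata <- function(model_id) {
  switch(model_id,
    M1 = tibble(stratum = "overall", race = NA_character_, education = NA_character_),
    M2 = tibble(stratum = names(default_covariate_mix()$race),
                race = names(default_covariate_mix()$race),
                education = NA_character_),
    M3 = tibble(stratum = names(default_covariate_mix()$education),
                race = NA_character_,
                education = names(default_covariate_mix()$education)),
    M4 = tidyr::expand_grid(race = c("African", "Coloured", "White"),
                            edu2 = c("less_than_secondary", "secondary_plus")) %>%
      mutate(stratum = paste0(.data$race, ":", .data$edu2),
             education = if_else(.data$edu2 == "secondary_plus",
                                 "secondary", "less_than_secondary")) %>%
      select("stratum", "race", "education"))
}

#' Run the full expectancy pipeline
#'
#' Executes every stage in order: obtain a panel (simulate from a config, or
#' use one supplied), classify person-waves into the four states under the
#' requested multimorbidity-definition variant, apply the exclusion cascade,
#' build transition records (including the baseline pseudo-transition by
#' default), fit the sex-stratified multinomial-logit transition models,
#' assemble age-indexed matrix sets per prediction stratum, and compute
#' origin-weighted truncated LE and MMLE with delta-method confidence
#' intervals. Deterministic given the seed.
#'
#' @param panel A long person-wave panel tibble, or `NULL` to simulate.
#' @param sim_config An [mmle_sim_config()] used when `panel` is `NULL`
#'   (exactly one of the two must be supplied).
#' @param models Character subset of `c("M1","M2","M3","M4")`.
#' @param variant Multimorbidity-definition variant: `"full"`,
#'   `"no_hypertension"`, `"no_tb"`, `"no_hypertension_no_tb"`.
#' @param hypertension_rule Passed to [mm_definition()].
#' @param start_age,truncation_age Age grid bounds; the origin-state
#'   distribution is computed from baseline observations aged within
#'   `[start_age, start_age + 10)`.
#' @param alpha CI level.
#' @param seed Overrides the sim config seed when simulating.
#' @param include_baseline Include baseline pseudo-transitions in fitting.
#' @param vcov_type Passed to [fit_transition_models()].
#' @param compute_ci Compute delta-method CIs (set `FALSE` to skip, e.g. in
#'   replication loops that only need point estimates).
#' @param output_dir Optional directory: writes `expectancies.csv` plus a
#'   JSON metadata sidecar.
#' @return Tibble in stratified-table layout (one row per model x stratum x
#'   sex): `model`, `stratum`, `sex`, `weighted_le`, `le_lower`, `le_upper`,
#'   `mmle`, `mmle_lower`, `mmle_upper`, `pct_mm`, plus per-state years.
#'   Attributes: `tally` (exclusion cascade), `origin_distributions`,
#'   `fits`.
#' @export
run_pipeline <- function(panel = NULL, sim_config = NULL,
                         models = "M1",
                         variant = c("full", "no_hypertension", "no_tb",
                                     "no_hypertension_no_tb"),
                         hypertension_rule = "from_flag",
                         start_age = 20, truncation_age = 85,
                         alpha = 0.05, seed = NULL,
                         include_baseline = TRUE,
                         vcov_type = "sandwich",
                         compute_ci = TRUE,
                         output_dir = NULL) {
  variant <- match.arg(variant)
  if (is.null(panel) == is.null(sim_config)) {
    abort("supply exactly one of 'panel' or 'sim_config'")
  }
  if (start_age >= truncation_age) abort("start_age must be below truncation_age")
  if (is.null(panel)) {
    if (!is.null(seed)) sim_config$seed <- as.integer(seed)
    panel <- simulate_panel(sim_config)
  }
  defn <- mm_definition(variant = variant, hypertension_rule = hypertension_rule)

  excl <- apply_exclusions(panel, defn)
  classified <- derive_states(excl$panel, defn)
  records <- build_transition_records(classified, include_baseline = include_baseline)

  dists <- lapply(setNames(nm = c("male", "female")), function(sx)
    origin_distribution(classified, sx, c(start_age, start_age + 10)))

  out <- list()
  fits <- list()
  for (m in models) {
    spec <- model_spec(m)
    fit <- fit_transition_models(records, spec, vcov_type = vcov_type)
    fits[[m]] <- fit
    strata <- model_strata(m)
    for (i in seq_len(nrow(strata))) {
      prof <- mmle_profile(
        urban_proportion = fit$urban_proportion,
        race = if (is.na(strata$race[i])) NULL else strata$race[i],
        education = if (is.na(strata$education[i])) NULL else strata$education[i])
      for (sx in c("male", "female")) {
        ms <- build_matrix_set(fit, sx, prof, start_age, truncation_age)
        cond <- bind_rows(lapply(transient_states(),
                                 function(o) conditional_expectancies(ms, o)))
        wres <- weighted_expectancies(cond, dists[[sx]])
        row <- tibble(model = m, stratum = strata$stratum[i], sex = sx,
                      weighted_le = wres$weighted_le,
                      le_lower = NA_real_, le_upper = NA_real_,
                      mmle = wres$mmle,
                      mmle_lower = NA_real_, mmle_upper = NA_real_,
                      pct_mm = percent_of_le(wres$mmle, wres$weighted_le),
                      years_no_disease = wres$years_no_disease,
                      years_one_disease = wres$years_one_disease)
        if (compute_ci) {
          ci_le <- delta_method_ci(fit, sx, prof, dists[[sx]], "weighted_le",
                                   start_age = start_age,
                                   truncation_age = truncation_age,
                                   alpha = alpha)
          ci_mm <- delta_method_ci(fit, sx, prof, dists[[sx]], "mmle",
                                   start_age = start_age,
                                   truncation_age = truncation_age,
                                   alpha = alpha)
          row$le_lower <- ci_le$lower; row$le_upper <- ci_le$upper
          row$mmle_lower <- ci_mm$lower; row$mmle_upper <- ci_mm$upper
        }
        out[[paste(m, strata$stratum[i], sx)]] <- row
      }
    }
  }
  res <- bind_rows(out)
  attr(res, "tally") <- excl$tally
  attr(res, "origin_distributions") <- bind_rows(dists)
  attr(res, "fits") <- fits

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res, file.path(output_dir, "expectancies.csv"))
    jsonlite::write_json(
      list(models = models, variant = variant, start_age = start_age,
           truncation_age = truncation_age, alpha = alpha,
           seed = if (is.null(seed)) NA else seed,
           package_version = as.character(utils::packageVersion("mmle"))),
      file.path(output_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Stacked expectancy plot
#'
#' Horizontal stacked bars of weighted LE split into years in each state,
#' one bar per stratum, faceted by sex.
#'
#' @param results Result tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_expectancy <- function(results) {
  long <- results %>%
    select("model", "stratum", "sex", "years_no_disease",
           "years_one_disease", "mmle") %>%
    rename(years_multimorbid = "mmle") %>%
    tidyr::pivot_longer(dplyr::starts_with("years_"),
                        names_to = "state", values_to = "years") %>%
    mutate(state = factor(sub("years_", "", .data$state),
                          levels = rev(transient_states())))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$years,
                                     y = paste(.data$model, .data$stratum),
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "expected years from age 20", y = NULL,
                  fill = "state") +
    ggplot2::theme_minimal()
}
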