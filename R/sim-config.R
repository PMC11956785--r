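# Generator configuration. Defaults emulate the structure of the South
# African National Income Dynamics Study (NIDS) adult panel, 2008-17: five
# biennial waves, adults aged 20+, household-reported deaths, attrition, and
# per-sex biennial transition frequencies matching the observed pooled
# transition table of that panel.

# Biennial transition fractions (per origin state, by sex) that the default
# generative coefficients reproduce at the per-sex mean interview age. These
# are the observed NIDS pooled fractions.
default_transition_targets <- function() {
  list(
    male = list(
      no_disease  = c(no_disease = 0.885, one_disease = 0.082, multimorbid = 0.011, dead = 0.022),
      one_disease = c(one_disease = 0.831, multimorbid = 0.113, dead = 0.056),
      multimorbid = c(multimorbid = 0.888, dead = 0.112)
    ),
    female = list(
      no_disease  = c(no_disease = 0.873, one_disease = 0.096, multimorbid = 0.016, dead = 0.015),
      one_disease = c(one_disease = 0.845, multimorbid = 0.122, dead = 0.033),
      multimorbid = c(multimorbid = 0.937, dead = 0.063)
    )
  )
}

# Age slopes (per year of age, log-odds vs staying) used by the default
# truth: disease incidence rises gently, death risk rises faster.
default_age_slopes <- function() c(disease = 0.035, dead = 0.07)

#' Build generative coefficients from target biennial probabilities
#'
#' Solves for per-destination intercepts so that, at a reference age and
#' urban share, the multinomial-logit transition model reproduces the given
#' biennial destination fractions exactly. Columns are
#' `(Intercept)`, `age`, `urban`; rows are the non-stay destinations
#' admissible from the origin.
#'
#' @param targets Named probability vector over the admissible destinations
#'   (including the stay probability first); must sum to 1.
#' @param origin Origin state label.
#' @param age_ref Reference age (years) at which the targets hold.
#' @param urban_ref Reference urban share.
#' @param age_slopes Named vector with elements `disease` and `dead`.
#' @param urban_effects Named vector with elements `disease` and `dead`.
#' @return Coefficient matrix (non-stay destinations x 3 terms).
#' @export
calibrate_coefficients <- function(targets, origin, age_ref,
                                   urban_ref = 0.5,
                                   age_slopes = default_age_slopes(),
                                   urban_effects = c(disease = 0.1, dead = -0.1)) {
  dests <- admissible_destinations(origin)
  stopifnot(abs(sum(targets) - 1) < 1e-8, identical(names(targets), dests))
  non_stay <- dests[-1]
  p_stay <- targets[[1]]
  B <- matrix(0, nrow = length(non_stay), ncol = 3,
              dimnames = list(non_stay, c("(Intercept)", "age", "urban")))
  for (d in non_stay) {
    kind <- if (d == "dead") "dead" else "disease"
    B[d, "age"] <- age_slopes[[kind]]
    B[d, "urban"] <- urban_effects[[kind]]
    B[d, "(Intercept)"] <- log(targets[[d]] / p_stay) -
      B[d, "age"] * age_ref - B[d, "urban"] * urban_ref
  }
  B
}

default_true_coefficients <- function() {
  targets <- default_transition_targets()
  mean_age <- c(male = 40.9, female = 42.7)
  out <- list()
  for (sx in c("male", "female")) {
    out[[sx]] <- lapply(setNames(nm = transient_states()), function(o) {
      calibrate_coefficients(targets[[sx]][[o]], o, age_ref = mean_age[[sx]])
    })
  }
  out
}

# Baseline state distributions per sex (origin-state shares of the NIDS
# analytic sample).
default_baseline_state_distribution <- function() {
  list(
    male   = c(no_disease = 0.763, one_disease = 0.183, multimorbid = 0.054),
    female = c(no_disease = 0.654, one_disease = 0.250, multimorbid = 0.096)
  )
}

default_covariate_mix <- function() {
  list(
    sex = c(male = 0.401, female = 0.599),
    race = c(African = 0.799, `Asian/Indian` = 0.012, Coloured = 0.148, White = 0.041),
    education = c(less_than_secondary = 0.462, secondary = 0.416, post_secondary = 0.122),
    urban = 0.502
  )
}

# relative baseline prevalence used when assigning which condition a newly
# diseased simulated person acquires
default_condition_weights <- function() {
  c(alzheimers = 0.01, arthritis = 0.05, asthma = 0.06, cancer = 0.02,
    diabetes = 0.11, emphysema = 0.01, epilepsy = 0.02, heart_problems = 0.06,
    hiv = 0.05, hypertension = 0.40, kidney_problems = 0.02, psychiatric = 0.03,
    stroke = 0.02, tuberculosis = 0.12)
}

#' Configure the synthetic panel generator
#'
#' Returns a validated generator configuration. The defaults are the study
#' conditions the package is exercised under: 18,030 adults aged 20+, five
#' biennial waves, per-sex baseline state distributions and transition
#' dynamics calibrated to the pooled biennial transition fractions of the
#' NIDS adult panel, independent per-wave attrition, household-style death
#' reporting (a death between waves is recorded at the next wave), and
#' lognormal design weights.
#'
#' @param n_individuals Number of adults in the panel.
#' @param n_waves Number of interview waves (>= 2).
#' @param wave_spacing_years Years between scheduled waves.
#' @param baseline_age_range Two-element numeric, minimum/maximum baseline age.
#' @param true_coefficients Per-sex, per-origin coefficient matrices (columns
#'   `(Intercept)`, `age`, `urban`, plus optional covariate-dummy columns)
#'   giving log-odds of each non-stay destination versus staying.
#' @param baseline_state_distribution Per-sex probability vectors over the
#'   three transient states, or a `function(age, sex)` returning a matrix of
#'   per-row probabilities (age-dependent baseline mix).
#' @param covariate_mix Marginal distributions for `sex`, `race`,
#'   `education`, and the scalar `urban` share.
#' @param design_weight_model List with `meanlog` and `sdlog` for lognormal
#'   positive design weights.
#' @param attrition_prob Per-wave probability that a not-yet-interviewed-
#'   this-wave individual drops out permanently.
#' @param state_attrition_multiplier Optional length-3 multiplier on
#'   `attrition_prob` by current state, to emulate health-dependent attrition.
#' @param age_jitter Half-width (years) of the uniform jitter applied to each
#'   scheduled interview age so that exact age is continuous.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `mmle_sim_config`.
#' @export
mmle_sim_config <- function(n_individuals = 18030,
                            n_waves = 5,
                            wave_spacing_years = 2,
                            baseline_age_range = c(20, 90),
                            true_coefficients = default_true_coefficients(),
                            baseline_state_distribution = default_baseline_state_distribution(),
                            covariate_mix = default_covariate_mix(),
                            design_weight_model = list(meanlog = 0, sdlog = 0.5),
                            attrition_prob = 0.15,
                            state_attrition_multiplier = c(1, 1, 1),
                            age_jitter = 0.5,
                            seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_waves = as.integer(n_waves),
    wave_spacing_years = wave_spacing_years,
    baseline_age_range = baseline_age_range,
    true_coefficients = true_coefficients,
    baseline_state_distribution = baseline_state_distribution,
    covariate_mix = covariate_mix,
    design_weight_model = design_weight_model,
    attrition_prob = attrition_prob,
    state_attrition_multiplier = state_attrition_multiplier,
    age_jitter = age_jitter,
    seed = as.integer(seed)
  )
  class(cfg) <- "mmle_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 1) abort("invalid config field 'n_individuals': must be >= 1")
  if (cfg$n_waves < 2) abort("invalid config field 'n_waves': must be >= 2 (no transitions observable)")
  if (cfg$wave_spacing_years <= 0) abort("invalid config field 'wave_spacing_years': must be > 0")
  if (length(cfg$baseline_age_range) != 2 || diff(cfg$baseline_age_range) < 0 ||
      cfg$baseline_age_range[1] < 20) {
    abort("invalid config field 'baseline_age_range': need [min, max] with min >= 20")
  }
  if (cfg$attrition_prob < 0 || cfg$attrition_prob > 1) {
    abort("invalid config field 'attrition_prob': must be in [0, 1]")
  }
  if (!is.function(cfg$baseline_state_distribution)) {
    for (sx in c("male", "female")) {
      p <- cfg$baseline_state_distribution[[sx]]
      if (is.null(p) || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-12) {
        abort(paste0("invalid config field 'baseline_state_distribution' (", sx,
                     "): probabilities must lie in [0,1] and sum to 1"))
      }
    }
  }
  for (nm in c("sex", "race", "education")) {
    p <- cfg$covariate_mix[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0("invalid config field 'covariate_mix$", nm, "': must sum to 1"))
    }
  }
  if (cfg$covariate_mix$urban < 0 || cfg$covariate_mix$urban > 1) {
    abort("invalid config field 'covariate_mix$urban': must be in [0, 1]")
  }
  for (sx in c("male", "female")) {
    for (o in transient_states()) {
      B <- cfg$true_coefficients[[sx]][[o]]
      dests <- admissible_destinations(o)
      if (is.null(B) || !all(rownames(B) %in% dests[-1]) ||
          !all(c("(Intercept)", "age", "urban") %in% colnames(B))) {
        abort(paste0("invalid config field 'true_coefficients' (", sx, ", ", o, ")"))
      }
    }
  }
  invisible(cfg)
}
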