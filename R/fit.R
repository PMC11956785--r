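# Sex-stratified, design-weighted multinomial-logit transition models.
# Point estimation is delegated to nnet::multinom on explicit numeric design
# columns; the per-origin coefficient layout, the design-adjusted
# (cluster-robust sandwich) variance-covariance and the prediction path with
# structural zeros are implemented here. The reference destination of every
# origin is "remain in the same state", which generalizes the no-disease
# reference of the published model form to the origins whose admissible
# destinations exclude no-disease.

#' Specify a transition-model covariate set
#'
#' The four covariate sets: `M1` age + residence (the base model, always
#' stratified by sex); `M2` adds race; `M3` adds education; `M4` adds the
#' simplified race-by-education interaction, for which the Asian/Indian
#' group is excluded and education is dichotomized into less-than-secondary
#' versus secondary-or-more.
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return Object of class `mmle_model_spec` with the ordered design terms.
#' @export
model_spec <- function(model_id = c("M1", "M2", "M3", "M4")) {
  model_id <- match.arg(model_id)
  terms <- switch(model_id,
    M1 = c("age", "urban"),
    M2 = c("age", "urban", "race_asian_indian", "race_coloured", "race_white"),
    M3 = c("age", "urban", "edu_secondary", "edu_post_secondary"),
    M4 = c("age", "urban", "race_coloured", "race_white",
           "edu2_secondary_plus", "race_coloured_x_edu2", "race_white_x_edu2"))
  structure(list(model_id = model_id, terms = terms,
                 drop_asian_indian = model_id == "M4"),
            class = "mmle_model_spec")
}

#' Covariate profile for prediction
#'
#' The profile at which transition probabilities are evaluated: residence is
#' set to a continuous urban share (its sample proportion, following the
#' marginal-standardization convention), and the categorical covariates to a
#' specific group where the model includes them.
#'
#' @param urban_proportion Fraction in `[0, 1]`.
#' @param race,education Category labels, or `NULL` when the model omits them.
#' @return Object of class `mmle_profile`.
#' @export
mmle_profile <- function(urban_proportion, race = NULL, education = NULL) {
  if (urban_proportion < 0 || urban_proportion > 1) {
    abort("urban_proportion must be in [0, 1]")
  }
  structure(list(urban_proportion = urban_proportion, race = race,
                 education = education),
            class = "mmle_profile")
}

# which profile fields each design term needs
term_needs <- function(term) {
  if (grepl("^race", term) && grepl("edu2", term)) return(c("race", "education"))
  if (grepl("^race", term)) return("race")
  if (grepl("^edu", term)) return("education")
  character()
}

#' Fit the sex-stratified multinomial-logit transition models
#'
#' For each sex and each transient origin state, fits a design-weighted
#' multinomial logit of destination state on the covariate set of `spec`,
#' with "stay in the same state" as the reference destination and only the
#' admissible (non-reverse) destinations in the choice set; the
#' multimorbidity origin therefore reduces to a binary logit of death.
#' Weights enter the log-likelihood as frequency-style weights (normalized
#' to mean one within sex); the default variance-covariance is a
#' cluster-robust sandwich (clustered on individual) from the weighted score
#' and information, accounting for the weighting and repeated records per
#' person. An origin with no observed deaths proceeds with a boundary
#' warning (the death probability degenerates to zero).
#'
#' @param records Transition-record tibble from [build_transition_records()].
#' @param spec A [model_spec()].
#' @param vcov_type `"sandwich"` (default) or `"model"` (inverse weighted
#'   information).
#' @return Object of class `mmle_fit`: per-sex, per-origin coefficient
#'   matrices and variance-covariance matrices, plus the weighted urban
#'   sample proportion used for prediction profiles.
#' @export
fit_transition_models <- function(records, spec = model_spec("M1"),
                                  vcov_type = c("sandwich", "model")) {
  vcov_type <- match.arg(vcov_type)
  stopifnot(inherits(spec, "mmle_model_spec"))
  records <- as_tibble(records)
  if (spec$drop_asian_indian) {
    records <- records %>% filter(.data$race != "Asian/Indian")
  }
  if (nrow(records) == 0) abort("no records to fit")
  urban_prop <- sum(records$design_weight * records$urban) / sum(records$design_weight)

  strata <- lapply(setNames(nm = c("male", "female")), function(sx) {
    recs <- records %>% filter(.data$sex == sx)
    if (nrow(recs) == 0) abort(paste0("no records in sex stratum '", sx, "'"))
    w_norm <- recs$design_weight / mean(recs$design_weight)
    fits <- lapply(setNames(nm = transient_states()), function(o) {
      sub <- recs$origin_state == o
      if (!any(sub)) {
        abort(paste0("no records from origin '", o, "' in sex stratum '", sx, "'"))
      }
      fit_origin(recs[sub, ], w_norm[sub], o, sx, spec, vcov_type)
    })
    fits
  })

  structure(list(spec = spec, strata = strata, urban_proportion = urban_prop,
                 vcov_type = vcov_type, n_records = nrow(records)),
            class = "mmle_fit")
}

# fit a single origin within one sex stratum
fit_origin <- function(recs, w, origin, sx, spec, vcov_type) {
  adm <- admissible_destinations(origin)
  obs <- intersect(adm, unique(as.character(recs$destination_state)))
  if (length(obs) < 2) {
    abort(paste0("convergence error: all records from origin '", origin,
                 "' (", sx, ") share destination '", obs,
                 "'; the multinomial logit is degenerate"))
  }
  if (!origin %in% obs) {
    abort(paste0("no stays observed from origin '", origin, "' (", sx,
                 "); reference destination unidentified"))
  }
  boundary <- "dead" %in% adm && !"dead" %in% obs
  if (boundary) {
    warn(paste0("boundary: no deaths observed from origin '", origin, "' (",
                sx, "); death probability degenerates to zero"))
  }
  lev <- c(origin, setdiff(obs, origin))
  X <- design_for_terms(spec$terms, recs$age_at_origin, recs$urban,
                        recs$race, recs$education)
  dat <- as.data.frame(X)
  dat$.dest <- factor(as.character(recs$destination_state), levels = lev)
  dat$.w <- w
  fml <- stats::as.formula(paste(".dest ~", paste(spec$terms, collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat, weights = dat$.w, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  cm <- coef(fit)
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1, dimnames = list(lev[2], names(cm)))
  cm <- cm[, c("(Intercept)", spec$terms), drop = FALSE]
  if (any(!is.finite(cm)) || max(abs(cm)) > 20) {
    worst <- rownames(cm)[which.max(apply(abs(cm), 1, max))]
    abort(paste0("convergence error (separation) fitting origin '", origin,
                 "' → destination '", worst, "' (", sx, ")"))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  V <- multinom_vcov(cm, Xd, dat$.dest, w, recs$person_id, vcov_type)
  list(origin = origin, destinations = lev, coef = cm, vcov = V,
       n = nrow(recs), boundary = boundary,
       converged = fit$convergence == 0)
}

# Weighted-information / cluster-robust sandwich vcov for a multinomial
# logit with coefficient matrix B (non-reference destinations x terms).
# Parameter order: destination-major (all terms of destination 1, then 2, ...).
multinom_vcov <- function(B, X, dest, w, cluster, vcov_type) {
  k1 <- nrow(B)
  p <- ncol(B)
  eta <- X %*% t(B)
  ex <- exp(eta)
  pr <- ex / (1 + rowSums(ex))            # n x k1, non-reference probabilities
  A <- matrix(0, k1 * p, k1 * p)
  for (d in seq_len(k1)) {
    for (e in seq_len(d)) {
      wt <- w * (pr[, d] * ((d == e) - pr[, e]))
      blk <- crossprod(X, X * wt)
      ri <- (d - 1) * p + seq_len(p); ci <- (e - 1) * p + seq_len(p)
      A[ri, ci] <- blk
      if (d != e) A[ci, ri] <- t(blk)
    }
  }
  Ainv <- solve(A)
  if (vcov_type == "model") {
    V <- Ainv
  } else {
    Y <- vapply(seq_len(k1), function(d) as.numeric(dest == levels(dest)[d + 1]),
                numeric(nrow(X)))
    S <- matrix(0, nrow(X), k1 * p)
    for (d in seq_len(k1)) {
      S[, (d - 1) * p + seq_len(p)] <- X * (w * (Y[, d] - pr[, d]))
    }
    Sg <- rowsum(S, group = cluster)
    V <- Ainv %*% crossprod(Sg) %*% Ainv
  }
  V <- (V + t(V)) / 2
  nm <- as.vector(t(outer(rownames(B), colnames(B), paste, sep = ":")))
  dimnames(V) <- list(nm, nm)
  V
}

#' Predict a destination-probability row
#'
#' Evaluates the fitted multinomial logit at a covariate profile and exact
#' age, returning the biennial destination probabilities over the full
#' four-state space: the softmax over admissible destinations, exact zeros
#' at the structurally impossible (reverse) destinations.
#'
#' @param fit An `mmle_fit` (or the truth model from
#'   [true_transition_model()]).
#' @param sex `"male"` or `"female"`.
#' @param origin Transient origin state.
#' @param profile An [mmle_profile()].
#' @param age Numeric vector of ages (years).
#' @return Matrix `length(age)` x 4 with columns [state_levels()]; each row
#'   sums to one.
#' @export
predict_probability_row <- function(fit, sex, origin, profile, age) {
  stopifnot(inherits(fit, "mmle_fit"), inherits(profile, "mmle_profile"))
  of <- fit$strata[[sex]][[origin]]
  if (is.null(of)) abort(paste0("no fitted model for origin '", origin, "' (", sex, ")"))
  B <- of$coef
  for (tm in colnames(B)) {
    need <- term_needs(tm)
    for (fld in need) {
      if (is.null(profile[[fld]])) {
        abort(paste0("profile missing covariate '", fld,
                     "' required by model term '", tm, "'"))
      }
    }
  }
  pr <- transition_probs(B, age, rep(profile$urban_proportion, length(age)),
                         if (is.null(profile$race)) NULL else rep(profile$race, length(age)),
                         if (is.null(profile$education)) NULL else rep(profile$education, length(age)))
  out <- matrix(0, length(age), 4, dimnames = list(NULL, state_levels()))
  out[, of$destinations[1]] <- pr[, 1]
  if (length(of$destinations) > 1) {
    out[, of$destinations[-1]] <- pr[, -1, drop = FALSE]
  }
  out
}

#' Truth model implied by a generator config
#'
#' Wraps the generative coefficient matrices of an [mmle_sim_config()] as an
#' `mmle_fit`-shaped object (zero variance), so the analytic expectancy
#' implied by the generative truth can be computed through the same matrix
#' engine as fitted models.
#'
#' @param config An [mmle_sim_config()].
#' @return Object of class `mmle_fit`.
#' @export
true_transition_model <- function(config) {
  strata <- lapply(config$true_coefficients, function(sx) {
    imap(sx, function(B, o) {
      cm <- B[, c("(Intercept)", setdiff(colnames(B), "(Intercept)")), drop = FALSE]
      np <- length(cm)
      list(origin = o, destinations = c(o, rownames(B)), coef = cm,
           vcov = matrix(0, np, np), n = NA_integer_,
           boundary = FALSE, converged = TRUE)
    })
  })
  terms <- setdiff(colnames(config$true_coefficients$male$no_disease), "(Intercept)")
  spec <- structure(list(model_id = "truth", terms = terms,
                         drop_asian_indian = FALSE),
                    class = "mmle_model_spec")
  structure(list(spec = spec, strata = strata,
                 urban_proportion = config$covariate_mix$urban,
                 vcov_type = "none", n_records = NA_integer_),
            class = "mmle_fit")
}

#' @export
print.mmle_fit <- function(x, ...) {
  cat("<mmle_fit> model", x$spec$model_id, "| vcov:", x$vcov_type,
      "|", x$n_records, "records\n")
  for (sx in names(x$strata)) {
    for (o in names(x$strata[[sx]])) {
      of <- x$strata[[sx]][[o]]
      cat(sprintf("  %-6s %-12s n=%6s dest={%s}%s\n", sx, o,
                  of$n, paste(of$destinations, collapse = ","),
                  if (isTRUE(of$boundary)) " [boundary]" else ""))
    }
  }
  invisible(x)
}

#' Tidy a fitted transition model
#'
#' @param x An `mmle_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `sex`, `origin`,
#'   `destination`, `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy mmle_fit
#' @export
tidy.mmle_fit <- function(x, ...) {
  out <- list()
  for (sx in names(x$strata)) {
    for (o in names(x$strata[[sx]])) {
      of <- x$strata[[sx]][[o]]
      est <- as.vector(t(of$coef))
      se <- sqrt(pmax(diag(of$vcov), 0))
      out[[paste(sx, o)]] <- tibble(
        sex = sx, origin = o,
        destination = rep(rownames(of$coef), each = ncol(of$coef)),
        term = rep(colnames(of$coef), times = nrow(of$coef)),
        estimate = est, std.error = se,
        statistic = est / se,
        p.value = 2 * stats::pnorm(-abs(est / se)))
    }
  }
  bind_rows(out)
}

#' One-row fit summary
#'
#' @param x An `mmle_fit`.
#' @param ... Unused.
#' @return Tibble: model id, vcov type, record and parameter counts,
#'   whether all origin fits converged, number of boundary origins.
#' @method glance mmle_fit
#' @export
glance.mmle_fit <- function(x, ...) {
  origins <- unlist(x$strata, recursive = FALSE)
  tibble(model_id = x$spec$model_id,
         vcov_type = x$vcov_type,
         n_records = x$n_records,
         n_parameters = sum(vapply(origins, function(o) length(o$coef), numeric(1))),
         converged = all(vapply(origins, function(o) isTRUE(o$converged), logical(1))),
         n_boundary = sum(vapply(origins, function(o) isTRUE(o$boundary), logical(1))))
}

#' Serialize a fitted transition model to JSON
#'
#' @param fit An `mmle_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    model_id = fit$spec$model_id,
    terms = fit$spec$terms,
    vcov_type = fit$vcov_type,
    urban_proportion = fit$urban_proportion,
    strata = lapply(fit$strata, function(sx) lapply(sx, function(o) {
      list(origin = o$origin, destinations = o$destinations,
           coef = list(rows = rownames(o$coef), cols = colnames(o$coef),
                       values = unname(o$coef)),
           vcov = unname(o$vcov), n = o$n, boundary = o$boundary)
    })))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
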