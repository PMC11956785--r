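# Delta-method confidence intervals. The expectancy functionals (weighted
# LE, MMLE, conditional entries) are smooth functions of the multinomial-
# logit coefficients; their variance is g' V g with g the numerical gradient
# (central differences) with respect to the full stacked coefficient vector
# of one sex stratum and V the block-diagonal variance-covariance across the
# per-origin fits. Negative lower limits are clamped to zero (negative
# expectancies are impossible); the clamping is flagged.

# stack all origin coefficient matrices of one sex into a vector
# (destination-major within origin, matching the per-origin vcov order)
stack_theta <- function(fit, sex) {
  unlist(lapply(fit$strata[[sex]], function(o) as.vector(t(o$coef))))
}

unstack_fit <- function(fit, sex, theta) {
  pos <- 0
  for (o in names(fit$strata[[sex]])) {
    B <- fit$strata[[sex]][[o]]$coef
    np <- length(B)
    fit$strata[[sex]][[o]]$coef <-
      matrix(theta[pos + seq_len(np)], nrow = nrow(B), byrow = TRUE,
             dimnames = dimnames(B))
    pos <- pos + np
  }
  fit
}

stack_vcov <- function(fit, sex) {
  Vs <- lapply(fit$strata[[sex]], function(o) o$vcov)
  np <- vapply(Vs, nrow, numeric(1))
  V <- matrix(0, sum(np), sum(np))
  pos <- 0
  for (v in Vs) {
    idx <- pos + seq_len(nrow(v))
    V[idx, idx] <- v
    pos <- pos + nrow(v)
  }
  V
}

# expectancy functional evaluated from a fit (forward accumulation only)
expectancy_functional <- function(fit, sex, profile, dist, start_age,
                                  truncation_age, step = 2,
                                  quantity = c("weighted_le", "mmle"),
                                  origin = NULL,
                                  half_final_interval = FALSE) {
  quantity <- match.arg(quantity,
    c("weighted_le", "mmle", "conditional_le", "conditional_mmle"))
  ms <- build_matrix_set(fit, sex, profile, start_age, truncation_age, step,
                         half_final_interval = half_final_interval)
  if (quantity %in% c("conditional_le", "conditional_mmle")) {
    yrs <- expectancy_forward(ms, origin)
    return(if (quantity == "conditional_le") sum(yrs) else yrs[["multimorbid"]])
  }
  if (is_tibble(dist) || is.data.frame(dist)) dist <- unlist(dist[1, transient_states()])
  dist <- dist[transient_states()]
  total <- 0
  for (o in transient_states()) {
    if (dist[[o]] == 0) next
    yrs <- expectancy_forward(ms, o)
    total <- total + dist[[o]] * (if (quantity == "weighted_le") sum(yrs) else yrs[["multimorbid"]])
  }
  total
}

#' Delta-method confidence interval for an expectancy functional
#'
#' Propagates the variance-covariance of the fitted multinomial-logit
#' coefficients to an expectancy functional: the gradient is computed by
#' central finite differences (step 1e-5 on the coefficient scale), the
#' variance is the quadratic form with the block-diagonal coefficient vcov,
#' and the interval is the asymptotic-normal
#' point +/- z quantile times standard error. A negative lower limit is set
#' to zero and flagged (`clamped`), since negative expectancies are
#' impossible.
#'
#' @param fit An `mmle_fit` carrying variance-covariance matrices.
#' @param sex Stratum.
#' @param profile An [mmle_profile()].
#' @param dist Origin-state distribution (ignored for conditional
#'   quantities).
#' @param quantity `"weighted_le"`, `"mmle"`, `"conditional_le"` or
#'   `"conditional_mmle"`.
#' @param origin Origin state, required for conditional quantities.
#' @param start_age,truncation_age,step Age grid, as in
#'   [build_matrix_set()].
#' @param alpha Two-sided level (default 0.05 for 95 per cent intervals).
#' @param fd_step Finite-difference step on the coefficient scale.
#' @param half_final_interval See [build_matrix_set()].
#' @return One-row tibble: `quantity`, `point`, `lower`, `upper`, `se`,
#'   `alpha`, `clamped`.
#' @export
delta_method_ci <- function(fit, sex, profile, dist = NULL,
                            quantity = "weighted_le", origin = NULL,
                            start_age = 20, truncation_age = 85, step = 2,
                            alpha = 0.05, fd_step = 1e-5,
                            half_final_interval = FALSE) {
  stopifnot(inherits(fit, "mmle_fit"))
  theta <- stack_theta(fit, sex)
  V <- stack_vcov(fit, sex)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort("coefficient variance-covariance matrix is not positive semi-definite")
  }
  f <- function(th) {
    expectancy_functional(unstack_fit(fit, sex, th), sex, profile, dist,
                          start_age, truncation_age, step, quantity, origin,
                          half_final_interval)
  }
  point <- f(theta)
  g <- numeric(length(theta))
  for (j in seq_along(theta)) {
    up <- theta; up[j] <- up[j] + fd_step
    dn <- theta; dn[j] <- dn[j] - fd_step
    g[j] <- (f(up) - f(dn)) / (2 * fd_step)
    if (!is.finite(g[j])) {
      abort(paste0("non-finite gradient at coefficient ", j))
    }
  }
  se <- sqrt(max(0, as.numeric(t(g) %*% V %*% g)))
  z <- qnorm(1 - alpha / 2)
  lower_raw <- point - z * se
  clamped <- lower_raw < 0
  tibble(quantity = quantity, point = point,
         lower = max(0, lower_raw), upper = point + z * se,
         se = se, alpha = alpha, clamped = clamped)
}

#' Monte Carlo trajectory oracle for state expectancies
#'
#' Simulates individual trajectories through the age-indexed chain of a
#' matrix set under the same occupancy convention as the analytic engine
#' (state at interval start credited with the full step), and returns mean
#' years per transient state with Monte Carlo standard errors. Used as an
#' independent check of the fundamental-matrix computation.
#'
#' @param ms An `mmle_matrix_set`.
#' @param origin Transient origin state.
#' @param n_paths Number of simulated trajectories.
#' @param seed Integer seed.
#' @return One-row tibble: mean years per state and `total_le`, with
#'   matching standard errors (`se_*`), `n_paths`.
#' @export
mc_oracle <- function(ms, origin, n_paths = 100000, seed = 1L) {
  stopifnot(inherits(ms, "mmle_matrix_set"), n_paths >= 1)
  if (!origin %in% transient_states()) abort("origin must be a transient state")
  set.seed(as.integer(seed))
  wt <- interval_weights(ms)
  state <- rep(match(origin, state_levels()), n_paths)
  years <- matrix(0, n_paths, 3)
  for (k in seq_along(ms$starts)) {
    for (s in 1:3) {
      idx <- state == s
      if (any(idx)) years[idx, s] <- years[idx, s] + wt[k]
    }
    new_state <- state
    for (s in 1:3) {
      idx <- which(state == s)
      if (length(idx) == 0) next
      cp <- cumsum(ms$P[s, , k])
      new_state[idx] <- findInterval(runif(length(idx)), cp,
                                     rightmost.closed = TRUE) + 1L
    }
    state <- new_state
  }
  total <- rowSums(years)
  m <- colMeans(years)
  se <- apply(years, 2, sd) / sqrt(n_paths)
  tibble(origin = origin,
         years_no_disease = m[1], years_one_disease = m[2],
         years_multimorbid = m[3], total_le = mean(total),
         se_no_disease = se[1], se_one_disease = se[2],
         se_multimorbid = se[3], se_total = sd(total) / sqrt(n_paths),
         n_paths = n_paths)
}
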