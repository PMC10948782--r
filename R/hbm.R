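#' Build a model frame with orthogonal quadratic basis
#'
#' Prepares aligned, within-person scaled observations for the hierarchical
#' quadratic model. Rows whose squared scaled glucose lies more than 3 SDs
#' from the pooled mean of squared scaled glucose are flagged excluded
#' (reason `glucose2_outlier`) before basis construction. Over the included
#' rows an orthogonal quadratic basis is built (via [stats::poly()], i.e.
#' QR): two columns with zero mean, unit norm and zero mutual dot product,
#' orthogonal to the intercept. The affine map between the orthogonal and the
#' raw basis `(1, g, g^2)` is retained so coefficients can be reported on
#' either basis.
#'
#' @param observations Data frame with `person_id`, `glucose_scaled` and the
#'   outcome column (plus optionally `person_glu_mean`, `person_glu_sd`,
#'   carried into the frame for mg/dL conversions).
#' @param outcome Name of the outcome column.
#' @param direction `"min"` if smaller is better (RT outcomes), `"max"`
#'   otherwise; defaults from the outcome name (`*rt*` implies `"min"`).
#' @param outlier_sd Exclusion threshold in SDs of squared scaled glucose.
#' @return An object of class `model_frame`: `data` (with `poly1`, `poly2`,
#'   `excluded`, `reason`), `outcome`, `direction`, `basis` (`poly` object
#'   and 3x3 map `M` with `raw = orth_basis %*% M`), `sd_y`, `person`
#'   (per-person glucose mean/SD when available).
#' @export
#' @examples
#' obs <- data.frame(person_id = rep(c("a", "b"), each = 5),
#'                   glucose_scaled = rnorm(10), y = rnorm(10))
#' fr <- build_model_frame(obs, "y", direction = "min")
#' colSums(fr$data[!fr$data$excluded, c("poly1", "poly2")])
build_model_frame <- function(observations, outcome,
                              direction = NULL, outlier_sd = 3) {
  stopifnot(outcome %in% names(observations))
  if (is.null(direction)) {
    direction <- if (grepl("rt", outcome, ignore.case = TRUE)) "min" else "max"
  }
  df <- data.frame(person_id = observations$person_id,
                   y = observations[[outcome]],
                   g = observations$glucose_scaled,
                   stringsAsFactors = FALSE)
  keep_in <- !is.na(df$y) & !is.na(df$g)
  df <- df[keep_in, , drop = FALSE]
  g2 <- df$g^2
  dev <- abs(g2 - mean(g2))
  df$excluded <- dev > outlier_sd * sd(g2)
  df$reason <- ifelse(df$excluded, "glucose2_outlier", "")
  inc <- !df$excluded
  if (length(unique(df$g[inc])) < 3) {
    stop("need at least 3 distinct glucose values to build a quadratic basis",
         call. = FALSE)
  }
  pol <- poly(df$g[inc], 2)
  df$poly1 <- NA_real_
  df$poly2 <- NA_real_
  df[inc, c("poly1", "poly2")] <- unclass(pol)[, 1:2]
  B <- cbind(1, df$poly1[inc], df$poly2[inc])
  A <- cbind(1, df$g[inc], df$g[inc]^2)
  M <- solve(crossprod(B), crossprod(B, A))
  dimnames(M) <- list(c("b0", "b1", "b2"), c("1", "g", "g2"))

  person <- NULL
  if (all(c("person_glu_mean", "person_glu_sd") %in% names(observations))) {
    p <- observations[keep_in, c("person_id", "person_glu_mean",
                                 "person_glu_sd")]
    person <- unique(p)
  }
  structure(list(data = df, outcome = outcome, direction = direction,
                 basis = list(poly = pol, M = M),
                 sd_y = sd(df$y[inc]), mean_y = mean(df$y[inc]),
                 n_included = sum(inc), n_excluded = sum(!inc),
                 person = person),
            class = "model_frame")
}

#' @exportS3Method base::print
print.model_frame <- function(x, ...) {
  cat(sprintf("Model frame for %s: %d rows (%d excluded as g^2 outliers), %d persons\n",
              x$outcome, nrow(x$data), x$n_excluded,
              length(unique(x$data$person_id))))
  invisible(x)
}

# basis matrix of the frame evaluated at new scaled-glucose values
frame_basis_at <- function(frame, g) {
  cbind(1, predict(frame$basis$poly, g))
}

# orthogonal-basis coefficient draws -> raw-basis draws (rows = draws)
orth_to_raw <- function(draws, M) {
  t(solve(M, t(draws)))
}

jags_model_string <- "
model {
  for (i in 1:N) {
    mu[i] <- beta[pid[i],1] + beta[pid[i],2]*p1[i] + beta[pid[i],3]*p2[i]
    y[i] ~ dnorm(mu[i], tau_e)
  }
  for (j in 1:J) { beta[j,1:3] ~ dmnorm(gamma[1:3], Omega[1:3,1:3]) }
  Omega[1:3,1:3] ~ dwish(S[1:3,1:3], 4)
  Sigma[1:3,1:3] <- inverse(Omega[1:3,1:3])
  gamma[1] ~ dnorm(mu_y, prec_b)
  gamma[2] ~ dnorm(0, prec_b)
  gamma[3] ~ dnorm(0, prec_b)
  sigma_e ~ dexp(rate_e)
  tau_e <- pow(sigma_e, -2)
  for (k in 1:3) { sd_u[k] <- sqrt(Sigma[k,k]) }
  rho[1] <- Sigma[1,2]/(sd_u[1]*sd_u[2])
  rho[2] <- Sigma[1,3]/(sd_u[1]*sd_u[3])
  rho[3] <- Sigma[2,3]/(sd_u[2]*sd_u[3])
}"

#' Fit the hierarchical Bayesian random quadratic-slope model
#'
#' Samples the posterior of the within-person quadratic glucose-cognition
#' model: each person's intercept, linear and quadratic coefficients on the
#' orthogonal basis deviate from the group coefficients with a full 3x3
#' covariance, and residuals are Gaussian. Priors are weakly informative at
#' the outcome scale: coefficients `normal(0, 2.5 * SD_y)` (intercept
#' centered at the outcome mean), residual SD half-exponential with rate
#' `1 / SD_y`, and an inverse-Wishart (df 4, scale `SD_y^2 * I`) on the
#' random-effect covariance. Sampling uses JAGS with hierarchical centering;
#' convergence is gated on the potential scale reduction factor: the fit is
#' flagged converged only when max Rhat over all monitored parameters is at
#' most `rhat_max`.
#'
#' @param frame A [build_model_frame()] result.
#' @param control A [sampler_control()].
#' @param seed Integer seed (chains use sequential offsets).
#' @param rhat_max Convergence gate on the maximum Rhat.
#' @return An object of class `vulnerability_fit` holding posterior draws
#'   (`gamma_draws` n x 3, `beta_draws` n x J x 3 person coefficients,
#'   `sd_u_draws`, `rho_draws`, `sigma_draws`), diagnostics (`rhat`, `neff`,
#'   `converged`), the basis metadata, outcome metadata, and the sampler
#'   settings used.
#' @export
fit_vulnerability_model <- function(frame, control = sampler_control(),
                                    seed = 1, rhat_max = 1.01) {
  stopifnot(inherits(frame, "model_frame"))
  d <- frame$data[!frame$data$excluded, , drop = FALSE]
  persons <- sort(unique(d$person_id))
  if (length(persons) < 2) stop("need at least 2 persons", call. = FALSE)
  pid <- match(d$person_id, persons)
  sdy <- frame$sd_y
  dat <- list(N = nrow(d), J = length(persons), pid = pid, y = d$y,
              p1 = d$poly1, p2 = d$poly2,
              S = diag(3) * sdy^2, mu_y = frame$mean_y,
              prec_b = 1 / (2.5 * sdy)^2, rate_e = 1 / sdy)
  # data-informed starting values: pooled OLS coefficients and residual SD
  ols <- stats::lm.fit(cbind(1, d$poly1, d$poly2), d$y)
  sigma0 <- sqrt(sum(ols$residuals^2) / max(1, nrow(d) - 3))
  sigma0 <- max(sigma0, 1e-9 * max(sdy, 1))
  inits <- lapply(seq_len(control$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed + k,
         gamma = as.numeric(ols$coefficients), sigma_e = sigma0)
  })
  jm <- rjags::jags.model(textConnection(jags_model_string), data = dat,
                          inits = inits, n.chains = control$chains,
                          n.adapt = control$adapt, quiet = TRUE)
  if (control$burnin > 0) {
    stats::update(jm, control$burnin, progress.bar = "none")
  }
  samples <- rjags::coda.samples(
    jm, c("gamma", "beta", "sd_u", "rho", "sigma_e"),
    n.iter = control$iter, thin = control$thin, progress.bar = "none")

  rhat <- tryCatch({
    gd <- coda::gelman.diag(samples, multivariate = FALSE,
                            autoburnin = FALSE)$psrf[, 1]
    gd[is.finite(gd)]
  }, error = function(e) setNames(NA_real_, "gelman_failed"))
  converged <- length(rhat) > 0 && all(!is.na(rhat)) &&
    max(rhat) <= rhat_max
  m <- as.matrix(samples)
  n_draws <- nrow(m)
  J <- length(persons)
  gamma_draws <- m[, sprintf("gamma[%d]", 1:3), drop = FALSE]
  beta_draws <- array(NA_real_, c(n_draws, J, 3))
  for (k in 1:3) {
    beta_draws[, , k] <- m[, sprintf("beta[%d,%d]", seq_len(J), k)]
  }
  neff <- coda::effectiveSize(
    samples[, c(sprintf("gamma[%d]", 1:3), sprintf("sd_u[%d]", 1:3),
                "sigma_e"), drop = FALSE])
  structure(list(
    gamma_draws = gamma_draws, beta_draws = beta_draws,
    sd_u_draws = m[, sprintf("sd_u[%d]", 1:3), drop = FALSE],
    rho_draws = m[, sprintf("rho[%d]", 1:3), drop = FALSE],
    sigma_draws = m[, "sigma_e"],
    persons = persons, rhat = rhat, neff = neff, converged = converged,
    rhat_max = rhat_max, sd_y = sdy, mean_y = frame$mean_y,
    basis = frame$basis, outcome = frame$outcome,
    direction = frame$direction, person = frame$person,
    n_obs = nrow(d), control = control, seed = seed),
    class = "vulnerability_fit")
}

#' @exportS3Method base::print
print.vulnerability_fit <- function(x, ...) {
  cat(sprintf("Hierarchical quadratic fit: %s (%d obs, %d persons)\n",
              x$outcome, x$n_obs, length(x$persons)))
  cat(sprintf("  max Rhat %.4f (%s), %d draws\n", max(x$rhat),
              ifelse(x$converged, "converged", "NOT converged"),
              nrow(x$gamma_draws)))
  g <- colMeans(x$gamma_draws)
  cat(sprintf("  gamma (orthogonal basis): %.2f, %.2f, %.2f\n",
              g[1], g[2], g[3]))
  invisible(x)
}

check_converged <- function(fit, force) {
  if (!fit$converged && !force) {
    stop("fit did not converge (max Rhat ",
         sprintf("%.3f", suppressWarnings(max(fit$rhat))),
         " > ", fit$rhat_max, "); pass force = TRUE to proceed anyway",
         call. = FALSE)
  }
  invisible(TRUE)
}

eq_tail_ci <- function(x, level) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a)))
}

#' Summarize group-level coefficients
#'
#' Posterior means, SDs and equal-tailed credible intervals for the group
#' coefficients, random-effect SDs, their correlations and the residual SD;
#' a coefficient is flagged significant when its interval excludes zero.
#'
#' @param fit A converged [fit_vulnerability_model()] result.
#' @param level Credible level for the intervals.
#' @param basis Report coefficients on the `"orthogonal"` fitting basis or
#'   back-transformed to the `"raw"` polynomial basis `(1, g, g^2)`.
#' @param force Proceed despite a non-converged fit.
#' @return Data frame with `term`, `estimate`, `se`, `cil`, `ciu`,
#'   `significant`.
#' @export
summarize_group_effects <- function(fit, level = 0.95,
                                    basis = c("orthogonal", "raw"),
                                    force = FALSE) {
  basis <- match.arg(basis)
  check_converged(fit, force)
  gd <- fit$gamma_draws
  if (basis == "raw") gd <- orth_to_raw(gd, fit$basis$M)
  terms <- c("(Intercept)", "glucose", "glucose^2")
  rows <- lapply(1:3, function(k) {
    ci <- eq_tail_ci(gd[, k], level)
    data.frame(term = terms[k], estimate = mean(gd[, k]), se = sd(gd[, k]),
               cil = ci[1], ciu = ci[2],
               significant = ci[1] > 0 | ci[2] < 0)
  })
  extras <- cbind(fit$sd_u_draws, fit$rho_draws, sigma_e = fit$sigma_draws)
  xnames <- c("sd_u0", "sd_u1", "sd_u2", "cor_u0_u1", "cor_u0_u2",
              "cor_u1_u2", "sd_residual")
  xrows <- lapply(seq_along(xnames), function(k) {
    ci <- eq_tail_ci(extras[, k], level)
    data.frame(term = xnames[k], estimate = mean(extras[, k]),
               se = sd(extras[, k]), cil = ci[1], ciu = ci[2],
               significant = NA)
  })
  out <- do.call(rbind, c(rows, xrows))
  attr(out, "basis") <- basis
  attr(out, "level") <- level
  out
}

#' Per-person posterior summaries of cognitive vulnerability
#'
#' Extracts each person's quadratic deviation u2j (and total quadratic effect
#' gamma20 + u2j) with equal-tailed 95/90/66% credible intervals and a
#' certainty class: the widest interval level at which the u2j interval
#' excludes zero (`ci95_excludes_zero`, `ci90_excludes_zero`,
#' `ci66_excludes_zero`, or `none`).
#'
#' @inheritParams summarize_group_effects
#' @return Data frame, one row per person: `person_id`, `u2_mean`,
#'   `total_quadratic_mean`, `l95`/`u95`, `l90`/`u90`, `l66`/`u66`,
#'   `ci_class`.
#' @export
extract_individual_vulnerability <- function(fit,
                                             basis = c("orthogonal", "raw"),
                                             force = FALSE) {
  basis <- match.arg(basis)
  check_converged(fit, force)
  J <- length(fit$persons)
  gd <- fit$gamma_draws
  rows <- lapply(seq_len(J), function(j) {
    bj <- fit$beta_draws[, j, ]
    if (basis == "raw") {
      bj <- orth_to_raw(bj, fit$basis$M)
      gdj <- orth_to_raw(gd, fit$basis$M)
    } else gdj <- gd
    u2 <- bj[, 3] - gdj[, 3]
    ci95 <- eq_tail_ci(u2, 0.95)
    ci90 <- eq_tail_ci(u2, 0.90)
    ci66 <- eq_tail_ci(u2, 0.66)
    excl <- function(ci) ci[1] > 0 || ci[2] < 0
    cls <- if (excl(ci95)) "ci95_excludes_zero" else
      if (excl(ci90)) "ci90_excludes_zero" else
        if (excl(ci66)) "ci66_excludes_zero" else "none"
    data.frame(person_id = fit$persons[j], u2_mean = mean(u2),
               total_quadratic_mean = mean(bj[, 3]),
               l95 = ci95[1], u95 = ci95[2], l90 = ci90[1], u90 = ci90[2],
               l66 = ci66[1], u66 = ci66[2], ci_class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "basis") <- basis
  out
}

#' Practical-equivalence (ROPE) test of random-effect SDs
#'
#' Tests whether each person-level random-effect SD is practically
#' negligible. The region of practical equivalence is
#' `[0, rope_factor * SD_y]`. Decision per SD: `negligible` when the
#' equal-tailed 95% interval of its posterior lies entirely inside the ROPE,
#' `meaningful` when entirely outside, `undecided` otherwise.
#'
#' @inheritParams summarize_group_effects
#' @param rope_factor ROPE upper bound as a multiple of the outcome SD.
#' @return Data frame with `parameter`, `rope_low`, `rope_high`,
#'   `prop_in_rope`, `cil`, `ciu`, `decision`.
#' @export
test_random_effect_equivalence <- function(fit, rope_factor = 0.2,
                                           force = FALSE) {
  check_converged(fit, force)
  hi <- rope_factor * fit$sd_y
  rows <- lapply(1:3, function(k) {
    x <- fit$sd_u_draws[, k]
    ci <- eq_tail_ci(x, 0.95)
    decision <- if (ci[2] <= hi) "negligible" else
      if (ci[1] >= hi) "meaningful" else "undecided"
    data.frame(parameter = c("sd_u0", "sd_u1", "sd_u2")[k],
               rope_low = 0, rope_high = hi,
               prop_in_rope = mean(x <= hi), cil = ci[1], ciu = ci[2],
               decision = decision, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Locate optimal cognitive performance on the glucose axis
#'
#' Evaluates the expected outcome over a grid of scaled glucose values for a
#' subsample of posterior draws, averages across draws, and locates the
#' minimum (RT outcomes) or maximum (accuracy outcomes) of the resulting
#' curve, for the group and for each person. Performance at the optimum is
#' expressed as percent deviation from typical performance (the curve value
#' at scaled glucose 0, i.e. the person's or group's glucose mean), and the
#' optimum is converted to mg/dL above the glucose mean using the person SD
#' (group scope: average of person SDs) when available.
#'
#' @inheritParams summarize_group_effects
#' @param domain Grid limits in person-SD units.
#' @param step Grid step.
#' @param n_draws Number of posterior draws averaged.
#' @param scope `"both"`, `"group"` or `"person"`.
#' @param seed Seed for the draw subsample.
#' @return Data frame with `scope`, `person_id` (NA for group),
#'   `glucose_star_scaled`, `glucose_star_mgdl`, `performance_at_star`,
#'   `typical_performance`, `pct_deviation_from_typical`, `on_boundary`.
#' @export
locate_optimal_performance <- function(fit, domain = c(-4, 4), step = 0.05,
                                       n_draws = 1000,
                                       scope = c("both", "group", "person"),
                                       seed = 1, force = FALSE) {
  scope <- match.arg(scope)
  check_converged(fit, force)
  grid <- seq(domain[1], domain[2], by = step)
  Bg <- frame_basis_at(fit, grid)
  B0 <- frame_basis_at(fit, 0)
  total <- nrow(fit$gamma_draws)
  set.seed(seed)
  idx <- if (n_draws < total) sample.int(total, n_draws) else seq_len(total)
  mean_sd <- if (!is.null(fit$person)) mean(fit$person$person_glu_sd) else NA
  sd_by_person <- if (!is.null(fit$person)) {
    setNames(fit$person$person_glu_sd, fit$person$person_id)
  } else NULL

  summarize_curve <- function(coef_draws, who, sd_mgdl) {
    curve <- colMeans(coef_draws[idx, , drop = FALSE] %*% t(Bg))
    typical <- mean(coef_draws[idx, , drop = FALSE] %*% t(B0))
    i <- if (fit$direction == "min") which.min(curve) else which.max(curve)
    data.frame(scope = who$scope, person_id = who$person_id,
               glucose_star_scaled = grid[i],
               glucose_star_mgdl = grid[i] * sd_mgdl,
               performance_at_star = curve[i],
               typical_performance = typical,
               pct_deviation_from_typical = 100 * (curve[i] - typical) /
                 typical,
               on_boundary = i == 1 || i == length(grid),
               stringsAsFactors = FALSE)
  }

  out <- list()
  if (scope %in% c("both", "group")) {
    out[[1]] <- summarize_curve(fit$gamma_draws,
                                list(scope = "group", person_id = NA),
                                mean_sd)
  }
  if (scope %in% c("both", "person")) {
    pp <- lapply(seq_along(fit$persons), function(j) {
      pid <- fit$persons[j]
      psd <- if (!is.null(sd_by_person) && pid %in% names(sd_by_person)) {
        sd_by_person[[pid]]
      } else NA
      summarize_curve(fit$beta_draws[, j, ],
                      list(scope = "person", person_id = pid), psd)
    })
    out <- c(out, pp)
  }
  do.call(rbind, out)
}

#' Sample-size-weighted combination of group optima across analysis samples
#'
#' @param optima List of one-row group-scope results from
#'   [locate_optimal_performance()], one per completion cutoff.
#' @param n Sample sizes (persons) per cutoff, used as weights.
#' @return One-row data frame of weighted averages of the numeric columns.
#' @export
combine_optima <- function(optima, n) {
  stopifnot(length(optima) == length(n))
  w <- n / sum(n)
  num <- c("glucose_star_scaled", "glucose_star_mgdl", "performance_at_star",
           "typical_performance", "pct_deviation_from_typical")
  out <- optima[[1]][, num, drop = FALSE]
  for (cl in num) {
    out[[cl]] <- sum(vapply(seq_along(optima),
                            function(i) w[i] * optima[[i]][[cl]], 0))
  }
  out
}
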