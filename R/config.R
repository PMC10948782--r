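#' Study configuration
#'
#' Bundles every tunable of the synthetic study and the downstream analysis:
#' cohort size, CGM sampling, the EMA schedule, generating parameters of the
#' quadratic glucose-cognition model for each outcome, session/participant
#' quality-control thresholds, completion cutoffs, sampler settings, and
#' stability-selection settings.
#'
#' Defaults emulate the study conditions of a 200-person type 1 diabetes
#' cohort wearing a 5-minute CGM for 20 days with a 3-per-day x 15-day EMA
#' schedule: person glucose means ~182.3 (44.3) mg/dL and SDs ~65.6 (18.8)
#' mg/dL (truncated normal draws), AR(1) smoothness phi = 0.95 per 5-minute
#' step, mean EMA compliance ~0.85, and a 58-column person feature table with
#' seven planted predictors of vulnerability.
#'
#' @param n_persons Number of participants.
#' @param n_features Number of person-level features generated.
#' @param duration_days CGM wear duration in days.
#' @param ema_days Number of EMA days.
#' @param ema_start_day Day offset (from CGM start) of the first EMA day.
#' @param cgm_interval_min Nominal CGM inter-reading interval, minutes.
#' @param glycemic List of population parameters for person glycemic
#'   parameters: `mean_mu`, `mean_sd`, `mean_range` (truncation bounds for the
#'   person glucose mean, mg/dL), `sd_mu`, `sd_sd`, `sd_range` (person glucose
#'   SD, mg/dL), and `ar1_phi` in `[0, 1)`.
#' @param compliance List with `shape1`, `shape2` of the Beta distribution of
#'   per-person EMA response probability.
#' @param outcomes Named list of per-outcome generating parameters; see
#'   [outcome_params()].
#' @param planted_features Named numeric vector mapping feature names to
#'   coefficients linking the standardized feature to the person quadratic
#'   deviation u2j of the first outcome.
#' @param qc List of session QC thresholds (`min_dsm_accuracy`,
#'   `min_dsm_correct`, `max_gcpt_omission`).
#' @param cutoffs EMA completion cutoffs defining the analysis samples.
#' @param sampler A [sampler_control()] list.
#' @param selection List with `repetitions` and `folds` for
#'   [stability_lasso()].
#' @param rope_factor ROPE upper bound as a multiple of the outcome SD.
#'
#' @return An object of class `study_config` (a validated list).
#' @export
#' @examples
#' cfg <- study_config(n_persons = 4, duration_days = 3, ema_days = 2)
#' cfg$n_persons
study_config <- function(n_persons = 200,
                         n_features = 58,
                         duration_days = 20,
                         ema_days = 15,
                         ema_start_day = 2,
                         cgm_interval_min = 5,
                         glycemic = list(mean_mu = 182.3, mean_sd = 44.3,
                                         mean_range = c(115, 380),
                                         sd_mu = 65.6, sd_sd = 18.8,
                                         sd_range = c(24, 117),
                                         ar1_phi = 0.95),
                         compliance = list(shape1 = 8, shape2 = 1.4),
                         outcomes = default_outcomes(),
                         planted_features = default_planted_features(),
                         qc = list(min_dsm_accuracy = 0.5,
                                   min_dsm_correct = 6,
                                   max_gcpt_omission = 0.5),
                         cutoffs = c(0.50, 0.66, 0.80),
                         sampler = sampler_control(),
                         selection = list(repetitions = 1000, folds = 10),
                         rope_factor = 0.2) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 1) {
    stop("`n_persons` must be a positive integer", call. = FALSE)
  }
  if (glycemic$ar1_phi < 0 || glycemic$ar1_phi >= 1) {
    stop("`glycemic$ar1_phi` must lie in [0, 1)", call. = FALSE)
  }
  if (any(cutoffs <= 0) || any(cutoffs > 1)) {
    stop("completion cutoffs must lie in (0, 1]", call. = FALSE)
  }
  for (nm in names(outcomes)) {
    validate_outcome_params(outcomes[[nm]], nm)
  }
  cfg <- list(n_persons = as.integer(n_persons),
              n_features = as.integer(n_features),
              duration_days = duration_days,
              ema_days = ema_days,
              ema_start_day = ema_start_day,
              cgm_interval_min = cgm_interval_min,
              glycemic = glycemic,
              compliance = compliance,
              outcomes = outcomes,
              planted_features = planted_features,
              qc = qc,
              cutoffs = cutoffs,
              sampler = sampler,
              selection = selection,
              rope_factor = rope_factor)
  class(cfg) <- "study_config"
  cfg
}

#' Generating parameters for one cognitive outcome
#'
#' The latent session score for outcome Y follows the random quadratic-slope
#' model on within-person scaled glucose g:
#' \deqn{Y_{ij} = (\gamma_{00} + u_{0j}) + (\gamma_{10} + u_{1j}) g_{ij} +
#'   (\gamma_{20} + u_{2j}) g_{ij}^2 + \varepsilon_{ij}}
#' with person deviations (u0j, u1j, u2j) drawn from a multivariate normal
#' with standard deviations `re_sd` and correlation matrix `re_cor`.
#' Coefficients here are on the raw polynomial basis (per scaled-glucose
#' unit), the natural parameterization for generation; the model-fitting side
#' reports both the orthogonal and the raw basis.
#'
#' @param gamma Numeric length 3: intercept, linear, quadratic coefficients.
#' @param re_sd Numeric length 3, non-negative person random-effect SDs.
#' @param re_cor 3x3 correlation matrix of the person random effects.
#' @param residual_sd Residual SD, outcome units.
#' @param direction `"min"` if lower scores are better (reaction times),
#'   `"max"` otherwise (accuracy-type scores).
#' @return A list of class `outcome_params`.
#' @export
outcome_params <- function(gamma, re_sd, re_cor = diag(3), residual_sd,
                           direction = c("min", "max")) {
  direction <- match.arg(direction)
  out <- list(gamma = as.numeric(gamma), re_sd = as.numeric(re_sd),
              re_cor = re_cor, residual_sd = residual_sd,
              direction = direction)
  class(out) <- "outcome_params"
  out
}

validate_outcome_params <- function(p, name = "outcome") {
  if (length(p$gamma) != 3) stop(name, ": `gamma` must have length 3", call. = FALSE)
  if (length(p$re_sd) != 3 || any(p$re_sd < 0)) {
    stop(name, ": `re_sd` must be 3 non-negative values", call. = FALSE)
  }
  rc <- p$re_cor
  if (!is.matrix(rc) || any(dim(rc) != 3) || max(abs(rc - t(rc))) > 1e-8 ||
      max(abs(diag(rc) - 1)) > 1e-8) {
    stop(name, ": `re_cor` must be a symmetric 3x3 correlation matrix",
         call. = FALSE)
  }
  ev <- eigen(rc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(name, ": `re_cor` is not positive semi-definite", call. = FALSE)
  }
  if (p$residual_sd < 0) stop(name, ": `residual_sd` must be >= 0", call. = FALSE)
  invisible(p)
}

re_cor_matrix <- function(r01, r02, r12) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r01
  m[1, 3] <- m[3, 1] <- r02
  m[2, 3] <- m[3, 2] <- r12
  m
}

#' @rdname study_config
#' @export
default_outcomes <- function() {
  # Raw-basis generating values sized to the published descriptive scale of
  # each task: a DSM RT vertex 0.72 person-SDs above the glucose mean with a
  # ~0.57% (5.4 ms) gain over typical performance, and analogous mild
  # curvature for the other scores.
  list(
    dsm_rt = outcome_params(
      gamma = c(952, -15.0, 10.4),
      re_sd = c(210, 7, 5),
      re_cor = re_cor_matrix(-0.19, 0.16, -0.28),
      residual_sd = 125, direction = "min"),
    dsm_num_correct = outcome_params(
      gamma = c(43, 0.55, -0.35),
      re_sd = c(7, 0.5, 0.35),
      re_cor = re_cor_matrix(0.30, 0.12, -0.06),
      residual_sd = 2.6, direction = "max"),
    gcpt_rt = outcome_params(
      gamma = c(822, -3.5, 2.2),
      re_sd = c(85, 4, 3),
      re_cor = re_cor_matrix(-0.08, -0.07, -0.36),
      residual_sd = 59, direction = "min"),
    gcpt_dprime = outcome_params(
      gamma = c(2.47, 0.02, -0.015),
      re_sd = c(0.6, 0.05, 0.04),
      re_cor = re_cor_matrix(-0.03, -0.10, -0.02),
      residual_sd = 0.55, direction = "max")
  )
}

#' @rdname study_config
#' @export
default_planted_features <- function() {
  # Seven person-level characteristics planted as linear contributors to the
  # DSM RT quadratic deviation u2j (standardized-feature coefficients in
  # outcome units per feature SD).
  c(age = 1.5, gluBelow70 = 1.2, SevereHypoEvents = 1.2,
    microvascular_binary = 1.0, gluCV = 1.0, tired_binary = 0.8,
    NeckCir_binary = 0.8)
}

#' MCMC sampler settings
#'
#' @param chains Number of chains.
#' @param adapt Adaptation iterations.
#' @param burnin Burn-in iterations discarded after adaptation.
#' @param iter Post-burn-in iterations per chain (before thinning).
#' @param thin Thinning interval.
#' @return A list of class `sampler_control`.
#' @export
sampler_control <- function(chains = 4, adapt = 1000, burnin = 5000,
                            iter = 30000, thin = 15) {
  stopifnot(chains >= 2, adapt >= 100, burnin >= 0, iter >= thin, thin >= 1)
  structure(list(chains = chains, adapt = adapt, burnin = burnin,
                 iter = iter, thin = thin),
            class = "sampler_control")
}

#' @exportS3Method base::print
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat("  persons:", x$n_persons, " features:", x$n_features, "\n")
  cat("  CGM:", x$duration_days, "days @", x$cgm_interval_min, "min;",
      "EMA:", x$ema_days, "days x 3 prompts\n")
  cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  cat("  cutoffs:", paste(format(x$cutoffs), collapse = ", "), "\n")
  invisible(x)
}
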