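#' @importFrom stats rnorm runif rbinom qnorm pnorm quantile median sd var
#'   rbeta rexp aggregate complete.cases coef predict poly setNames
#' @importFrom utils write.csv head
NULL

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

draw_sub_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the study population and its ground truth
#'
#' Draws per-person glycemic parameters (glucose mean and SD at the cohort's
#' descriptive scale, truncated normal), EMA compliance probabilities,
#' correlated person random effects (u0j, u1j, u2j) for every configured
#' outcome, and a person-level feature table. A configured subset of features
#' is "planted": their standardized values contribute linearly to the
#' quadratic deviation u2j of the first outcome, so stability selection has a
#' recoverable ground truth.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the returned truth is fully reproducible.
#' @return A list of class `truth_record` with elements `person` (data frame
#'   of per-person glycemic/compliance parameters), `person_effects` (named
#'   list of n x 3 matrices of (u0j, u1j, u2j) per outcome), `outcomes`
#'   (generating parameters), `feature_effects` (planted coefficients),
#'   `features` (the person feature table), and `config`.
#' @export
#' @examples
#' truth <- simulate_population(study_config(n_persons = 10), seed = 1)
#' head(truth$person)
simulate_population <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  if (config$n_persons < 1) stop("n_persons must be positive", call. = FALSE)
  set.seed(seed)
  n <- config$n_persons
  gl <- config$glycemic
  person <- data.frame(
    person_id = sprintf("p%03d", seq_len(n)),
    glu_mean = rtruncnorm(n, gl$mean_mu, gl$mean_sd,
                          gl$mean_range[1], gl$mean_range[2]),
    glu_sd = rtruncnorm(n, gl$sd_mu, gl$sd_sd, gl$sd_range[1], gl$sd_range[2]),
    ar1_phi = gl$ar1_phi,
    compliance = rbeta(n, config$compliance$shape1, config$compliance$shape2),
    stringsAsFactors = FALSE)

  features <- simulate_feature_table(person, config$n_features)

  person_effects <- lapply(config$outcomes, function(p) {
    validate_outcome_params(p)
    sig <- diag(p$re_sd) %*% p$re_cor %*% diag(p$re_sd)
    u <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = sig)
    if (n == 1) u <- matrix(u, nrow = 1)
    colnames(u) <- c("u0", "u1", "u2")
    u
  })
  names(person_effects) <- names(config$outcomes)

  planted <- config$planted_features
  if (length(planted)) {
    missing <- setdiff(names(planted), names(features))
    if (length(missing)) {
      stop("planted features absent from feature table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    target <- names(config$outcomes)[1]
    for (nm in names(planted)) {
      x <- features[[nm]]
      xs <- if (length(x) > 1 && isTRUE(sd(x) > 0)) {
        (x - mean(x)) / sd(x)
      } else x * 0
      person_effects[[target]][, "u2"] <-
        person_effects[[target]][, "u2"] + planted[[nm]] * xs
    }
  }

  out <- list(person = person, person_effects = person_effects,
              outcomes = config$outcomes, feature_effects = planted,
              features = features, config = config, seed = seed)
  class(out) <- "truth_record"
  out
}

# Person feature table: planted clinical/CGM/demographic constructs first
# (the glycemic ones derived from the person's true stationary distribution),
# then filler covariates to reach `n_features` columns.
simulate_feature_table <- function(person, n_features) {
  n <- nrow(person)
  f <- data.frame(person_id = person$person_id, stringsAsFactors = FALSE)
  f$age <- rtruncnorm(n, 45.7, 15.6, 18, 84)
  f$gluBelow70 <- 100 * pnorm(70, person$glu_mean, person$glu_sd)
  f$gluCV <- 100 * person$glu_sd / person$glu_mean
  f$SevereHypoEvents <- sample(0:6, n, replace = TRUE,
                               prob = c(.41, .17, .10, .075, .035, .11, .10))
  f$microvascular_binary <- rbinom(n, 1, 0.30)
  f$tired_binary <- rbinom(n, 1, 0.40)
  f$NeckCir_binary <- rbinom(n, 1, 0.25)
  n_core <- ncol(f) - 1L
  n_fill <- max(0L, n_features - n_core)
  for (k in seq_len(n_fill)) {
    nm <- sprintf("cov%02d", k)
    f[[nm]] <- if (k %% 3 == 0) rbinom(n, 1, runif(1, 0.1, 0.5)) else rnorm(n)
  }
  f
}

#' Simulate one person's CGM stream
#'
#' Stationary AR(1) glucose at a fixed reading interval: mean and stationary
#' SD equal to the person's glycemic parameters, lag-1 autocorrelation `phi`
#' per step. The device identifier switches once mid-series, emulating a
#' two-sensor wear protocol, and readings are clamped to the 40-400 mg/dL
#' sensor reporting range.
#'
#' @param glycemic List or one-row data frame with `glu_mean`, `glu_sd`,
#'   `ar1_phi`.
#' @param duration_days Wear duration, days.
#' @param interval_min Reading interval, minutes.
#' @param seed Integer seed.
#' @param person_id Identifier stored in the output.
#' @param start Absolute time of the first reading.
#' @param device_switch_day Day at which the second sensor replaces the first.
#' @return Data frame with columns `person_id`, `timestamp`, `glucose`,
#'   `device_id`, one row per reading.
#' @export
#' @examples
#' s <- simulate_glucose_series(list(glu_mean = 180, glu_sd = 60,
#'                                   ar1_phi = 0.95),
#'                              duration_days = 2, seed = 1)
#' range(s$glucose)
simulate_glucose_series <- function(glycemic, duration_days = 20,
                                    interval_min = 5, seed = 1,
                                    person_id = "p001",
                                    start = as.POSIXct("2023-03-01 00:00:00",
                                                       tz = "UTC"),
                                    device_switch_day = 10) {
  if (interval_min <= 0) stop("`interval_min` must be positive", call. = FALSE)
  phi <- glycemic$ar1_phi
  if (phi < 0 || phi >= 1) {
    stop("`ar1_phi` must lie in [0, 1): the process must be stationary",
         call. = FALSE)
  }
  set.seed(seed)
  n <- floor(duration_days * 24 * 60 / interval_min)
  mu <- glycemic$glu_mean
  sd_st <- glycemic$glu_sd
  x <- numeric(n)
  x[1] <- rnorm(1, mu, sd_st)
  innov_sd <- sd_st * sqrt(1 - phi^2)
  eps <- rnorm(n - 1, 0, innov_sd)
  for (t in seq_len(n - 1)) {
    x[t + 1] <- mu + phi * (x[t] - mu) + eps[t]
  }
  ts <- start + (seq_len(n) - 1) * interval_min * 60
  device <- ifelse(as.numeric(ts - start, units = "days") < device_switch_day,
                   "A", "B")
  data.frame(person_id = person_id, timestamp = ts,
             glucose = pmin(pmax(x, 40), 400),
             device_id = device, stringsAsFactors = FALSE)
}

ema_windows <- function() {
  # prompt windows in hours of the local day: morning 9:00-12:59,
  # afternoon 13:00-16:59, evening 17:00-21:00
  data.frame(window = c("morning", "afternoon", "evening"),
             lo = c(9, 13, 17), hi = c(13, 17, 21),
             stringsAsFactors = FALSE)
}

#' Simulate one person's EMA sessions with trial-level task records
#'
#' Schedules 3 prompts per day at uniform-random times within the morning,
#' afternoon and evening windows over the EMA period. Each prompt is answered
#' with the person's compliance probability; answered sessions start within 30
#' minutes of the prompt. For answered sessions, latent session scores follow
#' the quadratic model at the within-person scaled glucose at session start
#' (most recent reading), plus residual noise, and trial-level digit-symbol
#' and go/no-go records are generated so the scoring rules recover the latent
#' scores up to trial-sampling noise.
#'
#' @param person One row of `truth$person`.
#' @param glucose_series That person's CGM stream (see
#'   [simulate_glucose_series()]).
#' @param truth A `truth_record`.
#' @param seed Integer seed.
#' @return List with data frames `sessions`, `dsm_trials`, `gcpt_trials`.
#' @export
simulate_ema_sessions <- function(person, glucose_series, truth, seed = 1) {
  stopifnot(inherits(truth, "truth_record"))
  cfg <- truth$config
  compliance <- person$compliance
  if (compliance < 0 || compliance > 1) {
    stop("compliance must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  j <- match(person$person_id, truth$person$person_id)
  start0 <- min(glucose_series$timestamp)
  day0 <- as.POSIXct(trunc(start0, "days"), tz = "UTC")
  win <- ema_windows()
  n_days <- cfg$ema_days
  span_days <- as.numeric(max(glucose_series$timestamp) - start0,
                          units = "days")
  if (span_days < cfg$ema_start_day + n_days - 1) {
    stop("glucose series does not cover the EMA window", call. = FALSE)
  }

  rows <- vector("list", n_days * 3L)
  dsm_list <- list()
  gcpt_list <- list()
  idx <- 0L
  for (d in seq_len(n_days)) {
    for (w in seq_len(3L)) {
      idx <- idx + 1L
      prompt <- day0 + ((cfg$ema_start_day + d - 1) * 24 +
                        runif(1, win$lo[w], win$hi[w])) * 3600
      answered <- runif(1) < compliance
      start_time <- if (answered) prompt + runif(1, 0.5, 29.5) * 60 else
        as.POSIXct(NA)
      row <- data.frame(person_id = person$person_id, session_index = idx,
                        day = d, window = win$window[w],
                        prompt_time = prompt, start_time = start_time,
                        touchscreen_used = NA, task_completed = NA,
                        stringsAsFactors = FALSE)
      if (answered) {
        row$touchscreen_used <- runif(1) > 0.005
        row$task_completed <- runif(1) > 0.01
        g_raw <- glucose_at(glucose_series, start_time)
        g <- (g_raw - person$glu_mean) / person$glu_sd
        latent <- latent_scores(truth, j, g)
        tr <- simulate_session_trials(latent, person$person_id, idx)
        dsm_list[[length(dsm_list) + 1L]] <- tr$dsm
        gcpt_list[[length(gcpt_list) + 1L]] <- tr$gcpt
      }
      rows[[idx]] <- row
    }
  }
  sessions <- do.call(rbind, rows)
  list(sessions = sessions,
       dsm_trials = if (length(dsm_list)) do.call(rbind, dsm_list) else NULL,
       gcpt_trials = if (length(gcpt_list)) do.call(rbind, gcpt_list) else NULL)
}

glucose_at <- function(series, when) {
  i <- findInterval(as.numeric(when), as.numeric(series$timestamp))
  if (i < 1) return(series$glucose[1])
  series$glucose[i]
}

# latent expected session scores for person j at scaled glucose g
latent_scores <- function(truth, j, g, noiseless = FALSE) {
  out <- lapply(names(truth$outcomes), function(nm) {
    p <- truth$outcomes[[nm]]
    u <- truth$person_effects[[nm]][j, ]
    mu <- (p$gamma[1] + u[1]) + (p$gamma[2] + u[2]) * g +
      (p$gamma[3] + u[3]) * g^2
    if (!noiseless) mu <- mu + rnorm(1, 0, p$residual_sd)
    mu
  })
  setNames(as.numeric(out), names(truth$outcomes))
}

# trial-level generation: DSM RTs log-normal around the latent median; GCPT
# hit/false-alarm probabilities placed symmetrically around a response bias of
# 0.5 on the z-scale so the quantile link recovers the latent d-prime
simulate_session_trials <- function(latent, person_id, session_index,
                                    dsm_sdlog = 0.25, gcpt_sdlog = 0.2,
                                    dsm_accuracy = 0.93, gcpt_bias = 0.5,
                                    gcpt_city = 60L, gcpt_mountain = 15L) {
  m_rt <- max(latent[["dsm_rt"]], 250)
  nc <- max(latent[["dsm_num_correct"]], 1)
  n_att <- max(1L, round(nc / dsm_accuracy))
  correct <- runif(n_att) < dsm_accuracy
  dsm <- data.frame(person_id = person_id, session_index = session_index,
                    trial = seq_len(n_att),
                    rt_ms = exp(rnorm(n_att, log(m_rt), dsm_sdlog)),
                    correct = correct, stringsAsFactors = FALSE)

  dp <- max(latent[["gcpt_dprime"]], 0)
  zh <- dp / 2 + gcpt_bias
  zf <- -dp / 2 + gcpt_bias
  types <- sample(c(rep("city", gcpt_city), rep("mountain", gcpt_mountain)))
  p_resp <- ifelse(types == "city", pnorm(zh), pnorm(zf))
  responded <- runif(length(types)) < p_resp
  g_rt <- max(latent[["gcpt_rt"]], 250)
  rt <- ifelse(responded, exp(rnorm(length(types), log(g_rt), gcpt_sdlog)),
               NA_real_)
  gcpt <- data.frame(person_id = person_id, session_index = session_index,
                     trial = seq_along(types), trial_type = types,
                     responded = responded, rt_ms = rt,
                     stringsAsFactors = FALSE)
  list(dsm = dsm, gcpt = gcpt)
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_population()], then per person [simulate_glucose_series()]
#' and [simulate_ema_sessions()], and binds the results into study-level
#' tables. Optionally writes every table (and the truth record) as
#' comma-separated text with ISO-8601 timestamps.
#'
#' @param config A [study_config()].
#' @param seed Integer seed controlling every draw.
#' @param out_dir Optional directory; when given, `cgm.csv`, `sessions.csv`,
#'   `dsm_trials.csv`, `gcpt_trials.csv`, `features.csv` and `truth.yaml`-like
#'   `truth_person.csv` are written there.
#' @return A list of class `study_bundle` with elements `truth`, `cgm`,
#'   `sessions`, `dsm_trials`, `gcpt_trials`, `features`.
#' @export
#' @examples
#' study <- simulate_study(study_config(n_persons = 2, duration_days = 4,
#'                                      ema_days = 2), seed = 7)
#' nrow(study$sessions)
simulate_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  truth <- simulate_population(config, seed)
  seeds <- draw_sub_seeds(seed + 1L, 2L * config$n_persons)
  cgm_list <- vector("list", config$n_persons)
  ses_list <- vector("list", config$n_persons)
  dsm_list <- vector("list", config$n_persons)
  gcpt_list <- vector("list", config$n_persons)
  for (j in seq_len(config$n_persons)) {
    person <- truth$person[j, ]
    cgm_list[[j]] <- simulate_glucose_series(
      person, duration_days = config$duration_days,
      interval_min = config$cgm_interval_min, seed = seeds[2 * j - 1],
      person_id = person$person_id)
    ema <- simulate_ema_sessions(person, cgm_list[[j]], truth,
                                 seed = seeds[2 * j])
    ses_list[[j]] <- ema$sessions
    dsm_list[[j]] <- ema$dsm_trials
    gcpt_list[[j]] <- ema$gcpt_trials
  }
  bundle <- list(truth = truth,
                 cgm = do.call(rbind, cgm_list),
                 sessions = do.call(rbind, ses_list),
                 dsm_trials = do.call(rbind, dsm_list),
                 gcpt_trials = do.call(rbind, gcpt_list),
                 features = truth$features)
  class(bundle) <- "study_bundle"
  if (!is.null(out_dir)) write_study(bundle, out_dir)
  bundle
}

#' @rdname simulate_study
#' @param bundle A `study_bundle`.
#' @export
write_study <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    for (cl in c("timestamp", "prompt_time", "start_time")) {
      if (cl %in% names(df)) df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%S")
    }
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(bundle$cgm, "cgm.csv")
  wr(bundle$sessions, "sessions.csv")
  wr(bundle$dsm_trials, "dsm_trials.csv")
  wr(bundle$gcpt_trials, "gcpt_trials.csv")
  wr(bundle$features, "features.csv")
  wr(bundle$truth$person, "truth_person.csv")
  for (nm in names(bundle$truth$person_effects)) {
    u <- as.data.frame(bundle$truth$person_effects[[nm]])
    u$person_id <- bundle$truth$person$person_id
    wr(u, paste0("truth_effects_", nm, ".csv"))
  }
  invisible(out_dir)
}

#' Simulate aligned observations directly from the quadratic model
#'
#' Bypasses the CGM/EMA layers and draws (person, session) observations
#' straight from the random quadratic-slope model, for parameter-recovery
#' experiments: scaled glucose g ~ N(0, 1), person deviations from the
#' specified covariance, and Gaussian residual noise. Coefficients can be
#' interpreted on the raw polynomial basis `(1, g, g^2)` or on the orthogonal
#' basis that model fitting uses (intercept plus zero-mean, unit-norm,
#' mutually orthogonal linear/quadratic columns built over all rows).
#'
#' @param params An [outcome_params()] (its `direction` is carried through).
#' @param n_persons,n_sessions Cohort dimensions.
#' @param basis Basis on which `params$gamma` and the random effects act:
#'   `"raw"` (coefficients per scaled-glucose unit), `"orthogonal"`
#'   (zero-mean, unit-norm columns over all rows), or `"model"` (the basis
#'   [build_model_frame()] itself would construct: orthogonal columns over
#'   the rows surviving the squared-glucose outlier rule, so that fitting
#'   recovers exactly these coefficients).
#' @param seed Integer seed.
#' @return Data frame with columns `person_id`, `session_index`,
#'   `glucose_scaled`, `y`; the generating truth is attached as attribute
#'   `"truth"` (gamma, re_sd, re_cor, residual_sd, person effect matrix `u`).
#' @export
#' @examples
#' fr <- simulate_model_frame(outcome_params(c(950, -15, 10), c(0, 0, 0),
#'                                           residual_sd = 0), 5, 10, seed = 2)
#' head(fr)
simulate_model_frame <- function(params, n_persons, n_sessions,
                                 basis = c("raw", "orthogonal", "model"),
                                 seed = 1) {
  basis <- match.arg(basis)
  validate_outcome_params(params)
  set.seed(seed)
  n <- n_persons * n_sessions
  pid <- rep(seq_len(n_persons), each = n_sessions)
  g <- rnorm(n)
  sig <- diag(params$re_sd) %*% params$re_cor %*% diag(params$re_sd)
  u <- MASS::mvrnorm(n_persons, c(0, 0, 0), sig)
  if (n_persons == 1) u <- matrix(u, nrow = 1)
  colnames(u) <- c("u0", "u1", "u2")
  B <- if (basis == "raw") {
    cbind(1, g, g^2)
  } else if (basis == "orthogonal") {
    cbind(1, poly(g, 2))
  } else {
    # basis the analysis itself will build: outlier rule + QR on survivors
    probe <- data.frame(person_id = pid, glucose_scaled = g, y = 0)
    fr0 <- build_model_frame(probe, "y", direction = params$direction)
    cbind(1, predict(fr0$basis$poly, g))
  }
  beta <- sweep(u[pid, , drop = FALSE], 2, params$gamma, "+")
  y <- rowSums(B * beta) + rnorm(n, 0, params$residual_sd)
  out <- data.frame(person_id = sprintf("p%03d", pid), session_index =
                      sequence(rep(n_sessions, n_persons)),
                    glucose_scaled = g, y = y, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(gamma = params$gamma, re_sd = params$re_sd,
                             re_cor = params$re_cor,
                             residual_sd = params$residual_sd,
                             direction = params$direction, u = u,
                             basis = basis)
  out
}

#' @exportS3Method base::print
print.truth_record <- function(x, ...) {
  cat("Synthetic study ground truth\n")
  cat("  persons:", nrow(x$person), " outcomes:",
      paste(names(x$outcomes), collapse = ", "), "\n")
  cat("  planted features:", paste(names(x$feature_effects), collapse = ", "),
      "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle\n")
  cat("  CGM readings:", nrow(x$cgm), "\n")
  cat("  EMA sessions:", nrow(x$sessions),
      sprintf("(%d answered)", sum(!is.na(x$sessions$start_time))), "\n")
  invisible(x)
}
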