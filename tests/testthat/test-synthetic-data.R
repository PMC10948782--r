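test_that("population defaults match the study conditions", {
  truth <- simulate_population(study_config(), seed = 2)
  expect_equal(nrow(truth$person), 200)
  expect_equal(ncol(truth$features) - 1L, 58) # person_id + 58 features
  expect_true(all(truth$person$glu_mean >= 115 & truth$person$glu_mean <= 380))
  expect_true(all(truth$person$glu_sd >= 24 & truth$person$glu_sd <= 117))
  expect_true(all(truth$person$compliance >= 0 & truth$person$compliance <= 1))
  # cohort-scale means of the glycemic parameters
  expect_equal(mean(truth$person$glu_mean), 182.3, tolerance = 0.05)
  expect_equal(mean(truth$person$glu_sd), 65.6, tolerance = 0.08)

  expect_error(simulate_population(study_config(n_persons = 0)), "positive")
  bad <- study_config(n_persons = 4)
  bad$outcomes$dsm_rt$re_cor <- matrix(c(1, .9, -.9, .9, 1, .9,
                                         -.9, .9, 1), 3)
  expect_error(simulate_population(bad, 1), "positive semi-definite")
})

test_that("degenerate covariance gives exactly zero person effects", {
  cfg <- study_config(n_persons = 12, planted_features = c())
  for (nm in names(cfg$outcomes)) cfg$outcomes[[nm]]$re_sd <- c(0, 0, 0)
  truth <- simulate_population(cfg, seed = 5)
  for (nm in names(truth$person_effects)) {
    expect_equal(max(abs(truth$person_effects[[nm]])), 0)
  }
})

test_that("planted-feature correlation with u2j matches its closed form", {
  # u2j = b * x_std + e, sd(e) = s  =>  cor(x, u2j) = b / sqrt(b^2 + s^2)
  b <- 0.5; s <- 0.5
  cfg <- study_config(n_persons = 2000, planted_features = c(age = b))
  for (nm in names(cfg$outcomes)) {
    cfg$outcomes[[nm]]$re_sd <- if (nm == "dsm_rt") c(0, 0, s) else c(0, 0, 0)
  }
  truth <- simulate_population(cfg, seed = 9)
  r <- cor(truth$features$age, truth$person_effects$dsm_rt[, "u2"])
  analytic <- b / sqrt(b^2 + s^2)
  expect_equal(r, analytic, tolerance = 0.05)

  # brute-force oracle: regenerate the construction directly
  set.seed(1)
  x <- rnorm(2000); xs <- (x - mean(x)) / sd(x)
  u <- b * xs + rnorm(2000, 0, s)
  expect_equal(cor(x, u), analytic, tolerance = 0.05)
})

test_that("AR(1) glucose series has the specified stationary moments", {
  glyc <- list(glu_mean = 182.3, glu_sd = 66, ar1_phi = 0.95)
  s <- simulate_glucose_series(glyc, duration_days = 20, seed = 21)
  g <- s$glucose
  expect_true(all(diff(as.numeric(s$timestamp)) == 300))
  expect_true(all(g >= 40 & g <= 400))
  expect_equal(length(unique(s$device_id)), 2)

  # clamping to the sensor range censors the marginal normal slightly;
  # closed-form moments of the clamped N(mu, sd^2) marginal:
  mu <- 182.3; sd_ <- 66; a <- (40 - mu) / sd_; b <- (400 - mu) / sd_
  pa <- pnorm(a); pb <- 1 - pnorm(b)
  m1 <- 40 * pa + 400 * pb +
    mu * (pnorm(b) - pnorm(a)) - sd_ * (dnorm(b) - dnorm(a))
  ex2_mid <- (mu^2 + sd_^2) * (pnorm(b) - pnorm(a)) -
    sd_^2 * (b * dnorm(b) - a * dnorm(a)) -
    2 * mu * sd_ * (dnorm(b) - dnorm(a))
  m2 <- 40^2 * pa + 400^2 * pb + ex2_mid
  sd_clamped <- sqrt(m2 - m1^2)
  # autocorrelation at phi = 0.95 leaves ~150 effective observations in 20
  # days, so the SD is measured to ~6%; allow 3 such standard errors
  expect_equal(sd(g), sd_clamped, tolerance = 0.18)
  expect_equal(mean(g), m1, tolerance = 0.05)
  r1 <- cor(g[-1], g[-length(g)])
  expect_equal(r1, 0.95, tolerance = 0.03)

  # degenerate: no noise, no autocorrelation -> constant at the person mean
  flat <- simulate_glucose_series(list(glu_mean = 150, glu_sd = 0,
                                       ar1_phi = 0), 2, seed = 1)
  expect_true(all(flat$glucose == 150))

  expect_error(simulate_glucose_series(list(glu_mean = 150, glu_sd = 10,
                                            ar1_phi = 1), 2),
               "stationary")
  expect_error(simulate_glucose_series(glyc, interval_min = 0), "positive")
})

test_that("EMA schedule: 45 prompts in windows, compliance drives presence", {
  cfg <- study_config(n_persons = 1)
  truth <- simulate_population(cfg, seed = 3)
  truth$person$compliance <- 1
  series <- simulate_glucose_series(truth$person[1, ], seed = 4)
  ema <- simulate_ema_sessions(truth$person[1, ], series, truth, seed = 5)
  ses <- ema$sessions
  expect_equal(nrow(ses), 45)
  expect_true(all(!is.na(ses$start_time)))
  expect_true(all(as.numeric(ses$start_time - ses$prompt_time,
                             units = "mins") <= 30))
  hrs <- as.numeric(format(ses$prompt_time, "%H")) +
    as.numeric(format(ses$prompt_time, "%M")) / 60
  lo <- c(morning = 9, afternoon = 13, evening = 17)
  hi <- c(morning = 13, afternoon = 17, evening = 21)
  expect_true(all(hrs >= lo[ses$window] & hrs < hi[ses$window]))

  # GCPT trial structure: 75 trials, 60 city / 15 mountain per session
  per_session <- table(ema$gcpt_trials$session_index)
  expect_true(all(per_session == 75))
  tt <- table(ema$gcpt_trials$session_index, ema$gcpt_trials$trial_type)
  expect_true(all(tt[, "city"] == 60) && all(tt[, "mountain"] == 15))

  truth$person$compliance <- 0
  none <- simulate_ema_sessions(truth$person[1, ], series, truth, seed = 6)
  expect_equal(sum(!is.na(none$sessions$start_time)), 0)
  scored <- data.frame(person_id = "p001", session_index = 1:45,
                       qc_status = "excluded")
  m <- apply_participant_filters(scored, cutoffs = 0.5)
  expect_false(m$member_0.5) # later fails every completion filter

  truth$person$compliance <- 2
  expect_error(simulate_ema_sessions(truth$person[1, ], series, truth, 1),
               "compliance")
  short <- simulate_glucose_series(truth$person[1, ], duration_days = 3,
                                   seed = 1)
  truth$person$compliance <- 1
  expect_error(simulate_ema_sessions(truth$person[1, ], short, truth, 1),
               "cover")
})

test_that("generated session scores recover the generating quadratic (OLS)", {
  # no residual noise, no person effects: session scores deviate from the
  # parabola only through trial-level sampling noise
  cfg <- study_config(n_persons = 30, planted_features = c())
  for (nm in names(cfg$outcomes)) {
    cfg$outcomes[[nm]]$re_sd <- c(0, 0, 0)
    cfg$outcomes[[nm]]$residual_sd <- 0
  }
  study <- simulate_study(cfg, seed = 17)
  scores <- score_sessions(study$sessions, study$dsm_trials,
                           study$gcpt_trials)
  # scaled glucose from the generating truth
  cleaned <- lapply(split(study$cgm, study$cgm$person_id), clean_glucose)
  aligned <- do.call(rbind, lapply(names(cleaned), function(pid) {
    align_glucose_to_ema(cleaned[[pid]]$series,
                         scores[scores$person_id == pid, ])
  }))
  d <- merge(aligned, scores, by = c("person_id", "session_index"))
  tp <- study$truth$person
  i <- match(d$person_id, tp$person_id)
  g <- (d$glucose_raw - tp$glu_mean[i]) / tp$glu_sd[i]

  fit_rt <- lm(d$dsm_median_rt ~ g + I(g^2))
  expect_lt(abs(coef(fit_rt)[1] - 952), 6)
  expect_lt(abs(coef(fit_rt)[2] - (-15.0)), 5)
  expect_lt(abs(coef(fit_rt)[3] - 10.4), 4)

  fit_nc <- lm(d$dsm_num_correct ~ g + I(g^2))
  expect_lt(abs(coef(fit_nc)[1] - 43), 0.8)
})

test_that("scored d-prime inverts the generator's latent d-prime", {
  set.seed(8)
  latent <- c(dsm_rt = 950, dsm_num_correct = 43, gcpt_rt = 820,
              gcpt_dprime = 2.0)
  ds <- replicate(400, {
    tr <- glucocog:::simulate_session_trials(latent, "p", 1L)
    score_gcpt(tr$gcpt)$gcpt_dprime
  })
  # log-linear correction shrinks extreme rates slightly; stay within the
  # combined correction bias + sampling error
  expect_equal(mean(ds), 2.0, tolerance = 0.15)
})

test_that("noiseless generation lies exactly on the stated parabola", {
  p <- outcome_params(c(950, -14.6, 10.2), c(0, 0, 0), residual_sd = 0)
  fr <- simulate_model_frame(p, 4, 12, basis = "raw", seed = 3)
  pred <- 950 - 14.6 * fr$glucose_scaled + 10.2 * fr$glucose_scaled^2
  expect_equal(fr$y, pred)
  # convex parabola with a positive quadratic coefficient
  vertex <- 14.6 / (2 * 10.2)
  expect_true(all(fr$y >= 950 - 14.6 * vertex + 10.2 * vertex^2 - 1e-9))
})

test_that("study bundle round-trips to delimited text", {
  study <- simulate_study(study_config(n_persons = 2, duration_days = 18,
                                       ema_days = 15), seed = 23)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "cgm.csv", "sessions.csv", "dsm_trials.csv", "gcpt_trials.csv",
    "features.csv", "truth_person.csv")))))
  cgm <- read.csv(file.path(dir, "cgm.csv"))
  expect_equal(nrow(cgm), nrow(study$cgm))
  expect_equal(cgm$glucose, study$cgm$glucose, tolerance = 1e-9)
  # ISO-8601 timestamps
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$",
                        cgm$timestamp)))
})

test_that("moment matching: generator output recovers the truth record", {
  p <- outcome_params(c(955, -373, 261), c(224, 312, 238),
                      glucocog:::re_cor_matrix(-0.19, 0.155, -0.278),
                      residual_sd = 125)
  fr <- simulate_model_frame(p, 4000, 4, basis = "raw", seed = 13)
  u <- attr(fr, "truth")$u
  expect_equal(unname(apply(u, 2, sd)), c(224, 312, 238), tolerance = 0.05)
  expect_lt(abs(cor(u)[1, 2] - (-0.19)), 0.05)
  expect_lt(abs(cor(u)[2, 3] - (-0.278)), 0.05)
})
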