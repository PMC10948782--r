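strong_params <- function() {
  # strongly identified small-scale generating values for fast MCMC checks
  outcome_params(gamma = c(100, 30, 20), re_sd = c(10, 6, 6),
                 re_cor = diag(3), residual_sd = 5, direction = "min")
}

fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fr <- simulate_model_frame(strong_params(), 20, 20, basis = "raw",
                                 seed = 4)
      mf <- build_model_frame(fr, "y", direction = "min")
      ctrl <- sampler_control(chains = 3, adapt = 500, burnin = 1500,
                              iter = 12000, thin = 6)
      cache <<- list(frame = mf, obs = fr,
                     fit = fit_vulnerability_model(mf, ctrl, seed = 7))
    }
    cache
  }
})

test_that("squared-glucose outlier rule matches its definition", {
  set.seed(12)
  g <- rnorm(400)
  obs <- data.frame(person_id = rep(1:20, each = 20), glucose_scaled = g,
                    y = rnorm(400))
  fr <- build_model_frame(obs, "y")
  g2 <- g^2
  expect_equal(fr$data$excluded, abs(g2 - mean(g2)) > 3 * sd(g2))
  expect_true(all(fr$data$reason[fr$data$excluded] == "glucose2_outlier"))
  # hand-arithmetic instance: with pooled mean(g2) = 1 and SD(g2) = 1.2,
  # a row at g = 2.5 has (6.25 - 1) / 1.2 = 4.4 > 3
  expect_true((2.5^2 - 1) / 1.2 > 3)

  inc <- !fr$data$excluded
  p1 <- fr$data$poly1[inc]; p2 <- fr$data$poly2[inc]
  expect_equal(mean(p1), 0, tolerance = 1e-12)
  expect_equal(mean(p2), 0, tolerance = 1e-12)
  expect_equal(sum(p1^2), 1)
  expect_equal(sum(p2^2), 1)
  expect_equal(sum(p1 * p2), 0, tolerance = 1e-12)

  expect_error(build_model_frame(
    data.frame(person_id = 1:4, glucose_scaled = c(1, 1, 2, 2),
               y = rnorm(4)), "y"), "distinct")
})

test_that("predictions are invariant to the basis parameterization", {
  set.seed(2)
  g <- rnorm(60)
  y <- 5 + 2 * g - 1.5 * g^2 # noiseless quadratic
  obs <- data.frame(person_id = rep(1:6, each = 10), glucose_scaled = g,
                    y = y)
  fr <- build_model_frame(obs, "y", direction = "min")
  d <- fr$data[!fr$data$excluded, ]
  raw_fit <- lm(y ~ g + I(g^2), data = d)
  orth_fit <- lm(y ~ poly1 + poly2, data = d)
  expect_equal(unname(fitted(raw_fit)), unname(fitted(orth_fit)),
               tolerance = 1e-10)
  # the stored affine map carries orthogonal coefficients to raw ones
  b_orth <- matrix(coef(orth_fit), nrow = 1)
  b_raw <- glucocog:::orth_to_raw(b_orth, fr$basis$M)
  expect_equal(as.numeric(b_raw), unname(coef(raw_fit)), tolerance = 1e-8)
  expect_equal(as.numeric(b_raw), c(5, 2, -1.5), tolerance = 1e-8)
})

test_that("posterior recovers strongly identified generating values", {
  fs <- fit_small()
  fit <- fs$fit
  expect_true(fit$converged)
  expect_lte(max(fit$rhat), 1.01)
  g_raw <- colMeans(glucocog:::orth_to_raw(fit$gamma_draws, fit$basis$M))
  truth <- attr(fs$obs, "truth")
  g_sd <- apply(glucocog:::orth_to_raw(fit$gamma_draws, fit$basis$M), 2, sd)
  for (k in 1:3) {
    expect_lt(abs(g_raw[k] - truth$gamma[k]),
              pmax(3 * g_sd[k], 0.1 * abs(truth$gamma[k])))
  }
  expect_equal(mean(fit$sigma_draws), 5, tolerance = 0.15)
})

test_that("pure-noise data concentrate slope posteriors at zero", {
  p <- outcome_params(c(0, 0, 0), c(0, 0, 0), residual_sd = 1,
                      direction = "min")
  fr <- simulate_model_frame(p, 15, 15, seed = 6)
  mf <- build_model_frame(fr, "y", direction = "min")
  fit <- fit_vulnerability_model(mf, fast_sampler(), seed = 3)
  for (k in 2:3) {
    m <- mean(fit$gamma_draws[, k]); s <- sd(fit$gamma_draws[, k])
    expect_lt(abs(m), 3 * s)
  }
  sm <- summarize_group_effects(fit, force = TRUE)
  expect_false(any(sm$significant[sm$term %in% c("glucose", "glucose^2")]))
})

test_that("group summaries flag significance by interval exclusion of zero", {
  fs <- fit_small()
  sm <- summarize_group_effects(fs$fit)
  expect_equal(sm$significant[1:3], sm$cil[1:3] > 0 | sm$ciu[1:3] < 0)
  expect_true(all(sm$cil <= sm$estimate & sm$estimate <= sm$ciu))
  # strong generating effects are detected
  expect_true(all(sm$significant[sm$term %in% c("glucose", "glucose^2")]))
  raw <- summarize_group_effects(fs$fit, basis = "raw")
  truth <- attr(fs$obs, "truth")
  i <- raw$term == "glucose^2"
  expect_lt(abs(raw$estimate[i] - truth$gamma[3]), 4 * raw$se[i])
})

test_that("individual vulnerability: nesting, class labels, and shrinkage", {
  fs <- fit_small()
  vul <- extract_individual_vulnerability(fs$fit)
  expect_true(all(vul$l95 <= vul$l90 & vul$l90 <= vul$l66))
  expect_true(all(vul$u66 <= vul$u90 & vul$u90 <= vul$u95))
  excl <- function(l, u) l > 0 | u < 0
  expected_cls <- ifelse(excl(vul$l95, vul$u95), "ci95_excludes_zero",
                  ifelse(excl(vul$l90, vul$u90), "ci90_excludes_zero",
                  ifelse(excl(vul$l66, vul$u66), "ci66_excludes_zero",
                         "none")))
  expect_equal(vul$ci_class, expected_cls)
  expect_equal(vul$total_quadratic_mean - vul$u2_mean,
               rep(mean(fs$fit$gamma_draws[, 3]), nrow(vul)),
               tolerance = 1e-8)

  # posterior person quadratic effects track unshrunk per-person OLS fits
  d <- fs$frame$data[!fs$frame$data$excluded, ]
  ols <- vapply(split(d, d$person_id), function(dd) {
    unname(coef(lm(y ~ g + I(g^2), data = dd))[3])
  }, 0)
  vul_raw <- extract_individual_vulnerability(fs$fit, basis = "raw")
  post <- vul_raw$total_quadratic_mean[match(names(ols), vul_raw$person_id)]
  expect_gt(cor(post, ols, method = "spearman"), 0.8)
})

test_that("ROPE equivalence decisions follow the interval-vs-region rule", {
  fs <- fit_small()
  eq <- test_random_effect_equivalence(fs$fit)
  expect_equal(eq$parameter, c("sd_u0", "sd_u1", "sd_u2"))
  expect_equal(eq$rope_high, rep(0.2 * fs$fit$sd_y, 3))
  expect_true(all(eq$prop_in_rope >= 0 & eq$prop_in_rope <= 1))
  for (i in 1:3) {
    want <- if (eq$ciu[i] <= eq$rope_high[i]) "negligible" else
      if (eq$cil[i] >= eq$rope_high[i]) "meaningful" else "undecided"
    expect_equal(eq$decision[i], want)
  }
})

test_that("grid optimum matches the analytic vertex and percent deviation", {
  # essentially noiseless fit with raw-basis vertex at +0.70
  p <- outcome_params(c(950, -14, 10), c(0, 0, 0), residual_sd = 0.5,
                      direction = "min")
  fr <- simulate_model_frame(p, 15, 20, basis = "raw", seed = 9)
  mf <- build_model_frame(fr, "y", direction = "min")
  fit <- fit_vulnerability_model(mf, fast_sampler(), seed = 2)
  opt <- locate_optimal_performance(fit, scope = "group", force = TRUE)
  expect_equal(opt$glucose_star_scaled, 0.70, tolerance = 0.051)
  expect_false(opt$on_boundary)
  # analytic vertex value: 950 - 14^2 / (4 * 10) = 945.1
  expect_equal(opt$performance_at_star, 945.1, tolerance = 0.01)
  expect_equal(opt$pct_deviation_from_typical,
               100 * (945.1 - 950) / 950, tolerance = 0.02)

  # accuracy-direction outcomes maximize instead
  pmax_ <- outcome_params(c(40, 2, -3), c(0, 0, 0), residual_sd = 0.2,
                          direction = "max")
  fr2 <- simulate_model_frame(pmax_, 10, 20, basis = "raw", seed = 10)
  mf2 <- build_model_frame(fr2, "y", direction = "max")
  fit2 <- fit_vulnerability_model(mf2, fast_sampler(), seed = 5)
  opt2 <- locate_optimal_performance(fit2, scope = "group", force = TRUE)
  expect_equal(opt2$glucose_star_scaled, 2 / (2 * 3), tolerance = 0.06)
})

test_that("per-person optima and weighted cross-sample combination", {
  fs <- fit_small()
  opt <- locate_optimal_performance(fs$fit, scope = "both", force = TRUE)
  expect_equal(sum(opt$scope == "group"), 1)
  expect_equal(sum(opt$scope == "person"), length(fs$fit$persons))
  grp <- opt[opt$scope == "group", ]
  comb <- combine_optima(list(grp, grp, grp), n = c(10, 20, 30))
  expect_equal(comb$glucose_star_scaled, grp$glucose_star_scaled)
  two <- combine_optima(list(transform(grp, glucose_star_scaled = 1),
                             transform(grp, glucose_star_scaled = 0)),
                        n = c(30, 10))
  expect_equal(two$glucose_star_scaled, 0.75)
})

test_that("downstream operations refuse an unconverged fit unless forced", {
  fs <- fit_small()
  bad <- fs$fit
  bad$converged <- FALSE
  expect_error(summarize_group_effects(bad), "force")
  expect_error(extract_individual_vulnerability(bad), "force")
  expect_error(test_random_effect_equivalence(bad), "force")
  expect_error(locate_optimal_performance(bad), "force")
  expect_silent(invisible(summarize_group_effects(bad, force = TRUE)))
})

test_that("scaled and centered-only variants rank persons consistently", {
  # one synthetic dataset with clear person-level curvature differences,
  # run through both processing variants of the same pipeline
  set.seed(101)
  J <- 15; n <- 25
  sd_j <- runif(J, 45, 85); mean_j <- runif(J, 150, 220)
  pid <- rep(1:J, each = n)
  g <- rnorm(J * n)
  u <- MASS::mvrnorm(J, c(0, 0, 0), diag(c(30, 8, 8))^2)
  y <- (100 + u[pid, 1]) + (-14 + u[pid, 2]) * g +
    (10 + u[pid, 3]) * g^2 + rnorm(J * n, 0, 20)
  obs0 <- data.frame(person_id = sprintf("p%02d", pid),
                     glucose_raw = mean_j[pid] + g * sd_j[pid], y = y)
  ctrl <- sampler_control(chains = 2, adapt = 500, burnin = 1000,
                          iter = 8000, thin = 4)
  u2 <- lapply(c(TRUE, FALSE), function(sc) {
    obs <- center_scale_within_person(obs0, scale = sc)
    mf <- build_model_frame(obs, "y", direction = "min")
    fit <- fit_vulnerability_model(mf, ctrl, seed = 8)
    extract_individual_vulnerability(fit, force = TRUE)
  })
  stopifnot(identical(u2[[1]]$person_id, u2[[2]]$person_id))
  expect_gt(cor(u2[[1]]$u2_mean, u2[[2]]$u2_mean, method = "spearman"), 0.7)
})
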