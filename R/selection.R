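#' Build a standardized person-level feature table
#'
#' Merges CGM profile metrics with person-level covariates, drops
#' zero-variance columns (with a warning), imputes missing entries with the
#' column median, and standardizes every feature to mean 0 / SD 1 (binary
#' features coded 0/1 first, then standardized like any other column).
#'
#' @param covariates Data frame with `person_id` and feature columns.
#' @param profiles Optional data frame of per-person glycemic metrics with
#'   `person_id` (e.g. built from [glycemic_profile()]); merged in.
#' @return A data frame with `person_id` plus standardized features;
#'   attributes `imputed` (named count of imputed cells per column) and
#'   `dropped` (zero-variance columns removed).
#' @export
build_feature_table <- function(covariates, profiles = NULL) {
  stopifnot("person_id" %in% names(covariates))
  df <- covariates
  if (!is.null(profiles)) {
    stopifnot("person_id" %in% names(profiles))
    df <- merge(df, profiles, by = "person_id", sort = FALSE)
  }
  feats <- setdiff(names(df), "person_id")
  imputed <- integer(0)
  dropped <- character(0)
  for (nm in feats) {
    x <- as.numeric(df[[nm]])
    n_na <- sum(is.na(x))
    if (n_na > 0) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
      imputed[nm] <- n_na
    }
    if (sd(x) == 0) {
      dropped <- c(dropped, nm)
      df[[nm]] <- NULL
      next
    }
    df[[nm]] <- (x - mean(x)) / sd(x)
  }
  if (length(dropped)) {
    warning("dropped zero-variance feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  attr(df, "imputed") <- imputed
  attr(df, "dropped") <- dropped
  df
}

#' Repeated cross-validated lasso with retention counts
#'
#' Runs the data-driven predictor screen: in each repetition, folds are
#' reassigned at random, the lasso penalty is tuned by cross-validated error
#' (`glmnet::cv.glmnet`), the tuned model is refit to the full data, and the
#' nonzero coefficients are recorded. Across repetitions the result
#' aggregates per-feature retention counts and coefficient summaries, plus
#' mean cross-validated RMSE and R squared. Randomness across repetitions
#' comes from fold assignment only; the data are fixed.
#'
#' The default penalty rule is the one-SE convention (`"1se"`): the largest
#' penalty whose cross-validated error is within one standard error of the
#' minimum. Under the minimum-error rule the tuned penalty can collapse to
#' near zero on a fixed dataset, after which most features are retained in
#' nearly every repetition and retention frequencies stop discriminating
#' signal from noise; the one-SE rule keeps the retained set sparse and
#' retention frequencies interpretable. `rule = "min"` is available for
#' comparison.
#'
#' @param features Feature table from [build_feature_table()] (`person_id`
#'   plus standardized columns).
#' @param outcome Named numeric vector (names = person ids) or data frame
#'   with `person_id` and `value`: the person-level outcome (e.g. posterior
#'   mean vulnerability u2j).
#' @param repetitions Number of repetitions.
#' @param folds Cross-validation folds.
#' @param rule Penalty tuning rule: `"1se"` (default) or `"min"`.
#' @param seed Integer seed; identical seeds give identical retention counts.
#' @param label Optional label (e.g. the completion cutoff) carried through.
#' @return An object of class `stability_selection`: `summary` (per feature:
#'   `retention_count`, `retention_prop`, `coef_mean`, `coef_sd`),
#'   `mean_rmse`, `mean_r2`, `repetitions`, `label`.
#' @export
stability_lasso <- function(features, outcome, repetitions = 1000,
                            folds = 10, rule = c("1se", "min"), seed = 1,
                            label = NULL) {
  rule <- match.arg(rule)
  s_lab <- paste0("lambda.", rule)
  if (is.data.frame(outcome)) {
    outcome <- setNames(outcome$value, outcome$person_id)
  }
  ids <- intersect(features$person_id, names(outcome))
  x <- as.matrix(features[match(ids, features$person_id),
                          setdiff(names(features), "person_id")])
  y <- as.numeric(outcome[ids])
  if (length(y) < 2 * folds) {
    stop("need at least 2 x folds persons", call. = FALSE)
  }
  if (sd(y) == 0) stop("outcome is constant", call. = FALSE)
  p <- ncol(x)
  set.seed(seed)
  retained <- matrix(0, repetitions, p, dimnames = list(NULL, colnames(x)))
  coefs <- matrix(NA_real_, repetitions, p,
                  dimnames = list(NULL, colnames(x)))
  rmse <- numeric(repetitions)
  r2 <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    foldid <- sample(rep(seq_len(folds), length.out = length(y)))
    cv <- glmnet::cv.glmnet(x, y, foldid = foldid)
    b <- as.numeric(coef(cv, s = s_lab))[-1]
    nz <- b != 0
    retained[r, ] <- nz
    coefs[r, nz] <- b[nz]
    mse <- cv$cvm[cv$lambda == cv[[s_lab]]]
    rmse[r] <- sqrt(mse)
    r2[r] <- 1 - mse / var(y)
  }
  summ <- data.frame(
    feature = colnames(x),
    retention_count = colSums(retained),
    retention_prop = colMeans(retained),
    coef_mean = apply(coefs, 2, mean, na.rm = TRUE),
    coef_sd = apply(coefs, 2, sd, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(summary = summ, mean_rmse = mean(rmse), mean_r2 = mean(r2),
                 repetitions = repetitions, n = length(y), rule = rule,
                 label = label),
            class = "stability_selection")
}

#' @exportS3Method base::print
print.stability_selection <- function(x, ...) {
  cat(sprintf("Stability selection (%d reps, n = %d%s)\n", x$repetitions,
              x$n, if (is.null(x$label)) "" else paste0(", ", x$label)))
  cat(sprintf("  mean CV RMSE %.3f, mean CV R2 %.3f\n", x$mean_rmse,
              x$mean_r2))
  top <- x$summary[order(-x$summary$retention_prop), ][1:min(8, nrow(x$summary)), ]
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Robust predictors across completion cutoffs
#'
#' A feature is robust when it was retained in strictly more than
#' `threshold` of repetitions in every cutoff's stability-selection result.
#'
#' @param results Named list of [stability_lasso()] results, one per
#'   completion cutoff.
#' @param threshold Retention-proportion threshold (strict `>`).
#' @return Character vector of robust feature names; the per-cutoff
#'   retention-proportion matrix is attached as attribute `"retention"`.
#' @export
robust_predictors <- function(results, threshold = 0.5) {
  stopifnot(length(results) >= 1)
  feats <- results[[1]]$summary$feature
  for (r in results) {
    if (!identical(sort(r$summary$feature), sort(feats))) {
      stop("cutoff results have mismatched feature sets", call. = FALSE)
    }
  }
  mat <- sapply(results, function(r) {
    r$summary$retention_prop[match(feats, r$summary$feature)]
  })
  rownames(mat) <- feats
  robust <- feats[apply(mat > threshold, 1, all)]
  attr(robust, "retention") <- mat
  robust
}

#' Correlate vulnerability estimates with additional covariates
#'
#' Pearson correlation and two-sided p-value between per-person vulnerability
#' estimates and each covariate, for post-hoc construct checks.
#'
#' @param estimates Data frame with `person_id` and `u2_mean` (e.g. from
#'   [extract_individual_vulnerability()]), or a named numeric vector.
#' @param covariates Data frame with `person_id` and covariate columns.
#' @return Data frame with `covariate`, `n`, `r`, `p`.
#' @export
correlate_vulnerability <- function(estimates, covariates) {
  if (is.data.frame(estimates)) {
    estimates <- setNames(estimates$u2_mean, estimates$person_id)
  }
  ids <- intersect(names(estimates), covariates$person_id)
  if (length(ids) < 3) stop("need >=3 persons with both values", call. = FALSE)
  v <- as.numeric(estimates[ids])
  rows <- lapply(setdiff(names(covariates), "person_id"), function(nm) {
    x <- as.numeric(covariates[[nm]][match(ids, covariates$person_id)])
    ok <- !is.na(x) & !is.na(v)
    if (sd(x[ok]) == 0 || sd(v[ok]) == 0) {
      stop("zero variance in ", nm, " or in the estimates", call. = FALSE)
    }
    ct <- stats::cor.test(v[ok], x[ok])
    data.frame(covariate = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
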