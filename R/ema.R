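#' Score a digit-symbol matching (DSM) session
#'
#' Accuracy is the number of correct responses over attempted trials within
#' the 30-second session; the reaction-time score is the median RT over
#' correct responses only.
#'
#' @param trials Data frame with `rt_ms` and logical `correct`, one row per
#'   attempted trial.
#' @return One-row data frame: `dsm_num_correct`, `dsm_median_rt` (NA when no
#'   trial was correct), `dsm_accuracy`.
#' @export
#' @examples
#' score_dsm(data.frame(rt_ms = c(700, 900, 800, 650),
#'                      correct = c(TRUE, TRUE, TRUE, FALSE)))
score_dsm <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("score_dsm needs at least one trial", call. = FALSE)
  }
  nc <- sum(trials$correct)
  data.frame(
    dsm_num_correct = nc,
    dsm_median_rt = if (nc > 0) median(trials$rt_ms[trials$correct]) else
      NA_real_,
    dsm_accuracy = nc / nrow(trials))
}

#' Score a go/no-go (GCPT) session
#'
#' Hit rate is the response rate on go (city) trials; false-alarm rate is the
#' response rate on no-go (mountain) trials. Discrimination sensitivity is
#' \eqn{d' = \Phi^{-1}(hit) - \Phi^{-1}(fa)}. With
#' `correction = "loglinear"` (default) 0.5 is added to the hit and
#' false-alarm counts and 1 to the trial counts before taking quantiles,
#' keeping d-prime finite at extreme rates. The omission rate is the fraction
#' of unanswered go trials, and the RT score is the median RT over correct
#' (responded go) trials.
#'
#' @param trials Data frame with `trial_type` (`"city"`/`"mountain"`),
#'   logical `responded`, and `rt_ms` (NA when no response).
#' @param correction `"loglinear"` or `"none"`.
#' @return One-row data frame: `gcpt_dprime`, `gcpt_median_rt`,
#'   `gcpt_omission_rate`, `gcpt_hit_rate`, `gcpt_fa_rate`.
#' @export
#' @examples
#' tr <- data.frame(trial_type = rep(c("city", "mountain"), c(60, 15)),
#'                  responded = rep(c(TRUE, FALSE, TRUE, FALSE),
#'                                  c(55, 5, 3, 12)),
#'                  rt_ms = 800)
#' score_gcpt(tr, correction = "none")$gcpt_dprime
score_gcpt <- function(trials, correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  city <- trials$trial_type == "city"
  n_city <- sum(city)
  n_mtn <- sum(!city)
  if (n_city == 0 || n_mtn == 0) {
    stop("score_gcpt needs both city and mountain trials", call. = FALSE)
  }
  hits <- sum(trials$responded[city])
  fas <- sum(trials$responded[!city])
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_city + 1)
    fr <- (fas + 0.5) / (n_mtn + 1)
  } else {
    hr <- hits / n_city
    fr <- fas / n_mtn
  }
  corr_go <- city & trials$responded
  data.frame(
    gcpt_dprime = qnorm(hr) - qnorm(fr),
    gcpt_median_rt = if (any(corr_go)) median(trials$rt_ms[corr_go]) else
      NA_real_,
    gcpt_omission_rate = (n_city - hits) / n_city,
    gcpt_hit_rate = hits / n_city,
    gcpt_fa_rate = fas / n_mtn)
}

#' Score every answered session of a study
#'
#' @param sessions Session table (see [simulate_ema_sessions()]).
#' @param dsm_trials,gcpt_trials Trial tables keyed by `person_id` and
#'   `session_index`.
#' @return One row per answered session: identifiers, completion flags and
#'   the [score_dsm()] / [score_gcpt()] columns.
#' @export
score_sessions <- function(sessions, dsm_trials, gcpt_trials) {
  present <- sessions[!is.na(sessions$start_time), , drop = FALSE]
  key <- function(df) paste(df$person_id, df$session_index)
  dsm_split <- split(dsm_trials, key(dsm_trials))
  gcpt_split <- split(gcpt_trials, key(gcpt_trials))
  rows <- lapply(seq_len(nrow(present)), function(i) {
    k <- paste(present$person_id[i], present$session_index[i])
    cbind(present[i, c("person_id", "session_index", "start_time",
                       "touchscreen_used", "task_completed")],
          score_dsm(dsm_split[[k]]), score_gcpt(gcpt_split[[k]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Session-level quality control
#'
#' Flags sessions whose performance is consistent with chance or inadequate
#' effort, or whose administration was non-standard. Rules (reason codes):
#' DSM accuracy below `min_dsm_accuracy` (`dsm_accuracy<50%`), DSM number
#' correct below `min_dsm_correct` (`dsm_num_correct<6`), GCPT omission rate
#' strictly above `max_gcpt_omission` (`gcpt_omissions>50%`), responses not
#' registered by touchscreen (`non_touchscreen`), and task not marked
#' complete (`incomplete`). A session is excluded iff at least one rule
#' fires; `qc_reasons` enumerates all fired rules.
#'
#' @param scores Output of [score_sessions()] (must carry the completion
#'   flags).
#' @param min_dsm_accuracy,min_dsm_correct,max_gcpt_omission Thresholds.
#' @return `scores` with `qc_status` (`"kept"`/`"excluded"`) and
#'   `qc_reasons` (`;`-separated codes, empty when kept) added.
#' @export
apply_session_qc <- function(scores, min_dsm_accuracy = 0.5,
                             min_dsm_correct = 6, max_gcpt_omission = 0.5) {
  reasons <- lapply(seq_len(nrow(scores)), function(i) {
    r <- character()
    if (!is.na(scores$dsm_accuracy[i]) &&
        scores$dsm_accuracy[i] < min_dsm_accuracy) r <- c(r, "dsm_accuracy<50%")
    if (!is.na(scores$dsm_num_correct[i]) &&
        scores$dsm_num_correct[i] < min_dsm_correct) {
      r <- c(r, "dsm_num_correct<6")
    }
    if (!is.na(scores$gcpt_omission_rate[i]) &&
        scores$gcpt_omission_rate[i] > max_gcpt_omission) {
      r <- c(r, "gcpt_omissions>50%")
    }
    if (!isTRUE(scores$touchscreen_used[i])) r <- c(r, "non_touchscreen")
    if (!isTRUE(scores$task_completed[i])) r <- c(r, "incomplete")
    r
  })
  scores$qc_reasons <- vapply(reasons, paste, "", collapse = ";")
  scores$qc_status <- ifelse(scores$qc_reasons == "", "kept", "excluded")
  scores
}

#' Participant-level analysis-sample filters
#'
#' Determines membership in the analysis sample at each EMA completion
#' cutoff. A person is excluded outright when they recorded more than
#' `n_scheduled` sessions (protocol anomaly) or failed session QC in 50% or
#' more of possible sessions; otherwise they are a member at cutoff c when
#' kept sessions / `n_scheduled` >= c.
#'
#' @param qc_scores QC'd session scores (from [apply_session_qc()]).
#' @param cutoffs Completion cutoffs, proportions of `n_scheduled`.
#' @param n_scheduled Scheduled sessions per person.
#' @return Data frame, one row per person: `person_id`, `n_recorded`,
#'   `n_kept`, `excluded_anomaly`, `excluded_qc_rate`, and a logical
#'   `member_<cutoff>` column per cutoff.
#' @export
apply_participant_filters <- function(qc_scores,
                                      cutoffs = c(0.50, 0.66, 0.80),
                                      n_scheduled = 45) {
  by_person <- split(qc_scores, qc_scores$person_id)
  rows <- lapply(names(by_person), function(pid) {
    s <- by_person[[pid]]
    n_rec <- nrow(s)
    n_kept <- sum(s$qc_status == "kept")
    n_failed <- sum(s$qc_status == "excluded")
    anomaly <- n_rec > n_scheduled
    qc_fail <- n_failed >= 0.5 * n_scheduled
    out <- data.frame(person_id = pid, n_recorded = n_rec, n_kept = n_kept,
                      excluded_anomaly = anomaly, excluded_qc_rate = qc_fail,
                      stringsAsFactors = FALSE)
    for (ct in cutoffs) {
      out[[sprintf("member_%g", ct)]] <-
        !anomaly && !qc_fail && (n_kept / n_scheduled >= ct)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multilevel reliability of an EMA outcome
#'
#' Between-person reliability uses the variance components of a
#' random-intercept decomposition (fit with `lme4`):
#' \deqn{BPR = \sigma^2_{person} / (\sigma^2_{person} +
#'   \sigma^2_{resid} / \bar{T})}
#' with \eqn{\bar{T}} the mean number of sessions per person. Within-person
#' reliability, computed only when trial-level records are supplied, is the
#' split-half consistency of within-person deviations: each session is scored
#' separately on odd- and even-numbered trials, both half-scores are centered
#' within person, the pooled deviations are correlated across sessions, and
#' the correlation is Spearman-Brown adjusted.
#'
#' @param scores Session scores with `person_id` and the outcome column.
#' @param outcome Name of the outcome column in `scores`.
#' @param trials Optional trial table for the split-half computation.
#' @param scorer Function scoring a half-session's trials to a single number;
#'   required with `trials`.
#' @return A list of class `reliability_estimate`: `outcome`,
#'   `between_person`, `within_person` (NA without trials),
#'   `variance_components` (person, residual), `t_bar`.
#' @export
estimate_reliability <- function(scores, outcome, trials = NULL,
                                 scorer = NULL) {
  y <- scores[[outcome]]
  ok <- !is.na(y)
  y <- y[ok]
  pid <- scores$person_id[ok]
  if (length(unique(pid)) < 2 || length(y) < 4) {
    stop("need >=2 sessions for >=2 persons", call. = FALSE)
  }
  if (var(y) == 0) stop("outcome has zero variance", call. = FALSE)
  fit <- lme4::lmer(y ~ 1 + (1 | pid),
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_person <- vc$vcov[vc$grp == "pid"]
  v_resid <- vc$vcov[vc$grp == "Residual"]
  t_bar <- mean(table(pid))
  bpr <- v_person / (v_person + v_resid / t_bar)

  wpr <- NA_real_
  if (!is.null(trials)) {
    stopifnot(is.function(scorer))
    halves <- lapply(split(trials, paste(trials$person_id,
                                         trials$session_index)),
                     function(tr) {
                       odd <- tr[seq_len(nrow(tr)) %% 2 == 1, , drop = FALSE]
                       even <- tr[seq_len(nrow(tr)) %% 2 == 0, , drop = FALSE]
                       if (nrow(odd) == 0 || nrow(even) == 0) return(NULL)
                       data.frame(person_id = tr$person_id[1],
                                  h1 = scorer(odd), h2 = scorer(even))
                     })
    hh <- do.call(rbind, halves)
    hh <- hh[complete.cases(hh), , drop = FALSE]
    dev <- do.call(rbind, lapply(split(hh, hh$person_id), function(d) {
      if (nrow(d) < 2) return(NULL)
      data.frame(d1 = d$h1 - mean(d$h1), d2 = d$h2 - mean(d$h2))
    }))
    if (!is.null(dev) && nrow(dev) >= 3 && sd(dev$d1) > 0 && sd(dev$d2) > 0) {
      r <- stats::cor(dev$d1, dev$d2)
      wpr <- 2 * r / (1 + r)
    }
  }
  structure(list(outcome = outcome, between_person = bpr,
                 within_person = wpr,
                 variance_components = c(person = v_person,
                                         residual = v_resid),
                 t_bar = t_bar),
            class = "reliability_estimate")
}

#' @exportS3Method base::print
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("Reliability of %s: BPR %.3f, WPR %s (T-bar %.1f)\n",
              x$outcome, x$between_person,
              ifelse(is.na(x$within_person), "--",
                     sprintf("%.3f", x$within_person)), x$t_bar))
  invisible(x)
}
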