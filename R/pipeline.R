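#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates simulate -> clean -> score -> QC -> align -> center/scale ->
#' fit -> equivalence/optimum -> stability selection across the EMA
#' completion cutoffs, with a run manifest accounting for every exclusion.
#' Results are flagged by cross-cutoff consistency: an effect is interpreted
#' only when significant in every completion sample.
#'
#' @param config A [study_config()].
#' @param seed Integer seed governing simulation and every fit.
#' @param outcomes Outcomes to fit (default: all configured). The first one
#'   is the primary outcome whose person vulnerability feeds selection.
#' @param out_dir Optional directory; when given, stage outputs are persisted
#'   as comma-separated text.
#' @param keep_fits Keep the full posterior objects in the result (memory
#'   heavy for large runs).
#' @param run_selection Run stability selection per cutoff (requires the
#'   primary outcome to be fit).
#' @param force Proceed with downstream summaries when a fit misses the Rhat
#'   gate.
#' @return A list of class `pipeline_report`: `manifest`, `group_effects`,
#'   `consistency`, `vulnerability`, `equivalence`, `optima`,
#'   `optima_combined`, `selection`, `robust`, `membership`, `profiles`,
#'   `aligned`, `qc_sessions`, and (optionally) `fits`.
#' @export
run_pipeline <- function(config = study_config(), seed = 1,
                         outcomes = names(config$outcomes), out_dir = NULL,
                         keep_fits = FALSE, run_selection = TRUE,
                         force = FALSE) {
  study <- simulate_study(config, seed)
  n_scheduled <- config$ema_days * 3L

  # --- CGM cleaning and person-level profiles ------------------------------
  cgm_by_person <- split(study$cgm, study$cgm$person_id)
  cleaned <- lapply(cgm_by_person, clean_glucose,
                    interval_min = config$cgm_interval_min)
  eligible <- vapply(cleaned, `[[`, TRUE, "eligible")
  profiles <- do.call(rbind, lapply(names(cleaned)[eligible], function(pid) {
    cbind(person_id = pid, glycemic_profile(cleaned[[pid]]$series,
                                            config$cgm_interval_min))
  }))

  # --- EMA scoring, session QC, participant filters ------------------------
  scores <- score_sessions(study$sessions, study$dsm_trials,
                           study$gcpt_trials)
  scores <- apply_session_qc(scores,
                             min_dsm_accuracy = config$qc$min_dsm_accuracy,
                             min_dsm_correct = config$qc$min_dsm_correct,
                             max_gcpt_omission = config$qc$max_gcpt_omission)
  scores <- scores[scores$person_id %in% names(cleaned)[eligible], ,
                   drop = FALSE]
  membership <- apply_participant_filters(scores, config$cutoffs, n_scheduled)

  # --- alignment and within-person centering/scaling -----------------------
  kept <- scores[scores$qc_status == "kept", , drop = FALSE]
  aligned <- do.call(rbind, lapply(unique(kept$person_id), function(pid) {
    align_glucose_to_ema(cleaned[[pid]]$series,
                         kept[kept$person_id == pid, , drop = FALSE])
  }))
  outcome_cols <- c("dsm_median_rt", "dsm_num_correct", "gcpt_median_rt",
                    "gcpt_dprime")
  name_map <- c(dsm_rt = "dsm_median_rt", dsm_num_correct = "dsm_num_correct",
                gcpt_rt = "gcpt_median_rt", gcpt_dprime = "gcpt_dprime")
  aligned <- merge(aligned,
                   kept[, c("person_id", "session_index", outcome_cols)],
                   by = c("person_id", "session_index"), sort = TRUE)
  n_align <- table(aligned$person_id)
  too_few <- names(n_align)[n_align < 2]
  aligned <- aligned[!aligned$person_id %in% too_few, , drop = FALSE]
  aligned <- center_scale_within_person(aligned, scale = TRUE)

  # --- model fits per outcome x cutoff -------------------------------------
  fit_seeds <- draw_sub_seeds(seed + 2L,
                              length(outcomes) * length(config$cutoffs))
  fits <- list()
  group_rows <- list()
  vul_rows <- list()
  eq_rows <- list()
  opt_rows <- list()
  k <- 0L
  for (oc in outcomes) {
    for (ci in seq_along(config$cutoffs)) {
      k <- k + 1L
      ct <- config$cutoffs[ci]
      members <- membership$person_id[membership[[sprintf("member_%g", ct)]]]
      obs <- aligned[aligned$person_id %in% members, , drop = FALSE]
      obs$outcome_value <- obs[[name_map[[oc]]]]
      frame <- build_model_frame(obs, "outcome_value",
                                 direction = config$outcomes[[oc]]$direction)
      frame$outcome <- oc
      fit <- fit_vulnerability_model(frame, config$sampler,
                                     seed = fit_seeds[k])
      tag <- data.frame(outcome = oc, cutoff = ct,
                        stringsAsFactors = FALSE)
      ge <- summarize_group_effects(fit, force = force)
      group_rows[[k]] <- cbind(tag, ge)
      vul_rows[[k]] <- cbind(tag, extract_individual_vulnerability(
        fit, force = force))
      eq_rows[[k]] <- cbind(tag, test_random_effect_equivalence(
        fit, config$rope_factor, force = force))
      opt_rows[[k]] <- cbind(tag, locate_optimal_performance(
        fit, scope = "group", force = force))
      if (keep_fits) fits[[sprintf("%s_%g", oc, ct)]] <- fit
      if (oc == outcomes[1]) {
        # vulnerability estimates for selection, keyed by cutoff
        fits[[sprintf(".vul_%g", ct)]] <-
          extract_individual_vulnerability(fit, force = force)
      }
    }
  }
  group_effects <- do.call(rbind, group_rows)
  vulnerability <- do.call(rbind, vul_rows)
  equivalence <- do.call(rbind, eq_rows)
  optima <- do.call(rbind, opt_rows)

  # effects interpreted only when significant across every completion sample
  sig <- group_effects[group_effects$term %in%
                         c("glucose", "glucose^2"), , drop = FALSE]
  consistency <- aggregate(significant ~ outcome + term, data = sig,
                           FUN = all)
  names(consistency)[3] <- "significant_all_cutoffs"

  optima_combined <- do.call(rbind, lapply(outcomes, function(oc) {
    rows <- optima[optima$outcome == oc, , drop = FALSE]
    ns <- vapply(config$cutoffs, function(ct) {
      sum(membership[[sprintf("member_%g", ct)]])
    }, 0)
    cbind(data.frame(outcome = oc),
          combine_optima(split(rows, seq_len(nrow(rows))), ns))
  }))

  # --- stability selection per cutoff --------------------------------------
  selection <- NULL
  robust <- NULL
  if (run_selection) {
    feat <- build_feature_table(study$features)
    sel_seeds <- draw_sub_seeds(seed + 3L, length(config$cutoffs))
    selection <- lapply(seq_along(config$cutoffs), function(ci) {
      ct <- config$cutoffs[ci]
      vul <- fits[[sprintf(".vul_%g", ct)]]
      stability_lasso(feat, setNames(vul$u2_mean, vul$person_id),
                      repetitions = config$selection$repetitions,
                      folds = config$selection$folds, seed = sel_seeds[ci],
                      label = sprintf(">=%g%%", 100 * ct))
    })
    names(selection) <- sprintf("cutoff_%g", config$cutoffs)
    robust <- robust_predictors(selection)
  }
  fits <- fits[!startsWith(names(fits), ".vul_")]

  manifest <- list(
    seed = seed,
    n_persons = config$n_persons,
    n_scheduled_sessions = n_scheduled,
    cgm_readings_total = nrow(study$cgm),
    cgm_readings_dropped_warmup = sum(vapply(cleaned, `[[`, 0L, "n_dropped")),
    persons_ineligible_cgm = sum(!eligible),
    sessions_missed = sum(is.na(study$sessions$start_time)),
    sessions_scored = nrow(scores),
    sessions_excluded_qc = sum(scores$qc_status == "excluded"),
    qc_reason_counts = qc_reason_counts(scores),
    persons_excluded_anomaly = sum(membership$excluded_anomaly),
    persons_excluded_qc_rate = sum(membership$excluded_qc_rate),
    persons_too_few_aligned = length(too_few),
    aligned_observations = nrow(aligned),
    n_per_cutoff = setNames(
      vapply(config$cutoffs,
             function(ct) sum(membership[[sprintf("member_%g", ct)]]), 0),
      sprintf("cutoff_%g", config$cutoffs)),
    qc_thresholds = config$qc,
    cutoffs = config$cutoffs,
    sampler = unclass(config$sampler))

  report <- list(manifest = manifest, group_effects = group_effects,
                 consistency = consistency, vulnerability = vulnerability,
                 equivalence = equivalence, optima = optima,
                 optima_combined = optima_combined, selection = selection,
                 robust = robust, membership = membership,
                 profiles = profiles, aligned = aligned,
                 qc_sessions = scores,
                 fits = if (keep_fits) fits else NULL)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

qc_reason_counts <- function(scores) {
  reasons <- unlist(strsplit(scores$qc_reasons[scores$qc_reasons != ""], ";"))
  if (!length(reasons)) return(integer(0))
  table(reasons)
}

#' @rdname run_pipeline
#' @param report A `pipeline_report`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(report$group_effects, "group_effects.csv")
  wr(report$consistency, "consistency.csv")
  wr(report$vulnerability, "vulnerability.csv")
  wr(report$equivalence, "equivalence.csv")
  wr(report$optima, "optima.csv")
  wr(report$optima_combined, "optima_combined.csv")
  wr(report$membership, "membership.csv")
  wr(report$profiles, "profiles.csv")
  if (!is.null(report$selection)) {
    for (nm in names(report$selection)) {
      wr(report$selection[[nm]]$summary, sprintf("selection_%s.csv", nm))
    }
    wr(data.frame(feature = as.character(report$robust)), "robust.csv")
  }
  mf <- report$manifest
  lines <- unlist(lapply(names(mf), function(nm) {
    v <- mf[[nm]]
    if (is.list(v) || length(v) > 1) {
      c(paste0(nm, ":"),
        paste0("  ", names(unlist(v)), ": ", unlist(v)))
    } else paste0(nm, ": ", v)
  }))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  aligned observations:", x$manifest$aligned_observations, "\n")
  cat("  analysis sample sizes:",
      paste(names(x$manifest$n_per_cutoff), x$manifest$n_per_cutoff,
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$consistency)) {
    print(x$consistency, row.names = FALSE)
  }
  if (!is.null(x$robust)) {
    cat("  robust predictors:", paste(x$robust, collapse = ", "), "\n")
  }
  invisible(x)
}
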