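# Trial-log I/O and the end-to-end pipeline.

.trial_log_cols <- c("participant_id", "group", "trial", "cue", "shift_mm",
                     "sensed_mm", "hand_x_mm", "cursor_x_mm", "hit", "reward")

#' Write a trial log as CSV
#'
#' @param records a trial-record data.frame (see
#'   [simulate_exp1_participant()] for the schema).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  missing_cols <- setdiff(.trial_log_cols, names(records))
  if (length(missing_cols))
    stop("trial log missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[, .trial_log_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Columns are matched by header name (any order). Validation errors name
#' the offending row: the trial index must be strictly increasing and every
#' row must satisfy `cursor_x = hand_x + shift` within 1e-6 mm.
#'
#' @param path CSV path.
#' @return A trial-record data.frame in canonical column order.
#' @export
read_trial_log <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trial_log_cols, names(rec))
  if (length(missing_cols))
    stop("trial log ", path, " missing columns: ",
         paste(missing_cols, collapse = ", "))
  rec <- rec[, .trial_log_cols]
  if (any(diff(rec$trial) <= 0)) {
    i <- which(diff(rec$trial) <= 0)[1L] + 1L
    stop("non-monotone trial index at row ", i, " of ", path)
  }
  bad <- abs(rec$cursor_x_mm - (rec$hand_x_mm + rec$shift_mm)) > 1e-6
  if (any(bad))
    stop("cursor_x != hand_x + shift at row ", which(bad)[1L], " of ", path)
  rec$hit <- as.logical(rec$hit)
  rec$reward <- as.logical(rec$reward)
  rec
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate -> analyze -> fit (2000-trial design) or
#' simulate -> analyze -> aims + group statistics (500-trial design),
#' writing all artifacts under `out_dir`:
#'
#' * `logs/` -- per-participant trial-log CSVs plus the cohort manifest;
#' * 2000-trial design: `fits/<id>.json` per participant and
#'   `cohort_summary.csv` (alpha and sigma estimates, objective);
#' * 500-trial design: `summary.csv` (asymptote and movement variability per
#'   participant, left-skew values flipped about 0 mm), `aims.json`
#'   (per-group optimal aims from the measured group variability) and
#'   `stats.json` (pairwise bootstrap comparisons with Holm adjustment,
#'   common-language effect sizes and percentile CIs);
#' * `manifest.json` -- config hash, master seed and written files, from
#'   which the run is reproducible.
#'
#' @param config a config list; see [default_exp1_config()] and
#'   [default_exp2_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the pipeline outputs (`summary`, and
#'   `fits` or `aims`/`stats`) plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config), config$experiment %in% c(1L, 2L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  unlink(file.path(out_dir, "FAILED"))

  sim <- stage("simulate",
               simulate_cohort(config, file.path(out_dir, "logs")))
  parts <- sim$manifest$participants
  logs <- lapply(sim$files, read_trial_log)
  names(logs) <- parts$participant_id

  result <- if (config$experiment == 1L) {
    stage("fit", {
      dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
      fits <- lapply(seq_len(nrow(parts)), function(i) {
        prior <- make_exp1_prior(parts$skew[i])
        tab <- condition_averages(logs[[i]], last_n = config$last_n %||% 1000L)
        fit <- fit_bayes_model(tab, prior,
                               restarts = config$restarts %||% 8L)
        jsonlite::write_json(
          list(participant_id = parts$participant_id[i],
               group = parts$group[i],
               alpha_opt = fit$alpha_opt,
               sigma_opt = as.list(fit$sigma_opt),
               objective = fit$objective, converged = fit$converged),
          file.path(out_dir, "fits",
                    paste0(parts$participant_id[i], ".json")),
          auto_unbox = TRUE, digits = NA)
        fit
      })
      summary <- data.frame(participant_id = parts$participant_id,
                            group = parts$group,
                            alpha_opt = vapply(fits, `[[`, numeric(1L), "alpha_opt"),
                            sigma_dot = vapply(fits, function(f) f$sigma_opt[[1L]], numeric(1L)),
                            sigma_cloud15 = vapply(fits, function(f) f$sigma_opt[[2L]], numeric(1L)),
                            sigma_cloud30 = vapply(fits, function(f) f$sigma_opt[[3L]], numeric(1L)),
                            objective = vapply(fits, `[[`, numeric(1L), "objective"))
      utils::write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
                       row.names = FALSE)
      list(summary = summary, fits = fits)
    })
  } else {
    stage("analyze", {
      last_n <- config$last_n %||% 400L
      summary <- data.frame(
        participant_id = parts$participant_id,
        group = parts$group, skew = parts$skew,
        asymptote_mm = vapply(logs, asymptote_mean, numeric(1L),
                              last_n = last_n),
        variability_mm = vapply(logs, movement_variability, numeric(1L),
                                last_n = last_n))
      # pool skews: flip left-skew compensation about the 0 mm alignment point
      left <- summary$skew == "left"
      summary$asymptote_flipped_mm <- ifelse(left,
                                             flip_values(summary$asymptote_mm, 0),
                                             summary$asymptote_mm)
      utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)

      groups <- unique(summary$group)
      aims <- lapply(groups, function(g) {
        sd_g <- mean(summary$variability_mm[summary$group == g])
        d <- make_exp2_prior("right")
        list(group = g, sigma_mv_mm = sd_g,
             aim_min_sq_error_mm = aim_min_sq_error(d, sd_g)$aim_mm,
             aim_max_hits_mode_mm = aim_max_hits_mode(d, sd_g)$aim_mm,
             aim_max_hits_width_mm = aim_max_hits_width(d, sd_g)$aim_mm)
      })
      jsonlite::write_json(aims, file.path(out_dir, "aims.json"),
                           auto_unbox = TRUE, digits = NA)

      pairs <- utils::combn(groups, 2L, simplify = FALSE)
      B <- config$n_resamples %||% 1e6
      cmp <- lapply(pairs, function(pr) {
        xa <- summary$asymptote_flipped_mm[summary$group == pr[1L]]
        xb <- summary$asymptote_flipped_mm[summary$group == pr[2L]]
        bt <- bootstrap_test(xa, xb, kind = "two_sample", tails = "two",
                             n_resamples = B, seed = config$seed)
        list(comparison = paste(pr, collapse = " vs "),
             p_value = bt$p_value, statistic_mm = bt$statistic,
             ci_95_mm = unname(bt$ci_95),
             theta_pct = common_language_effect(xa, xb))
      })
      p_adj <- holm_bonferroni(vapply(cmp, `[[`, numeric(1L), "p_value"))
      for (i in seq_along(cmp)) cmp[[i]]$p_holm <- p_adj[i]
      jsonlite::write_json(cmp, file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
      list(summary = summary, aims = aims, stats = cmp)
    })
  }

  manifest <- list(package = "reachloss",
                   version = as.character(utils::packageVersion("reachloss")),
                   config_hash = .config_hash(config),
                   master_seed = config$seed,
                   experiment = config$experiment,
                   files = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest)))
}
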