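#' Derive a reproducible stage-specific seed
#'
#' Fans a single global seed out to per-stage seeds by stable hashing of the
#' stage name, so stages can be rerun independently yet reproducibly. The
#' result always fits in a 32-bit integer.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Full-run configuration
#'
#' @param cohort A [cohort_config()].
#' @param control An [ev_control()] for the fitting stage.
#' @param split First-block boundary for the behavioral metrics; default 40.
#' @param seed Global seed fanned out to the stages via [stage_seed()].
#' @return List of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_config(), control = ev_control(),
                       split = 40L, seed = 20160901L) {
  structure(list(cohort = cohort, control = control, split = as.integer(split),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Accepts a JSON object with optional members `cohort`, `control`, `split`
#' and `seed`; members present override the corresponding defaults of
#' [cohort_config()] / [ev_control()].
#'
#' @param path JSON file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- do.call(cohort_config, as.list(obj$cohort))
  control <- do.call(ev_control, as.list(obj$control))
  run_config(cohort = cohort, control = control,
             split = if (!is.null(obj$split)) obj$split else 40L,
             seed = if (!is.null(obj$seed)) obj$seed else 20160901L)
}

fmt6 <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, 6)
  df
}

write_table <- function(df, path) {
  write.csv(fmt6(df), path, row.names = FALSE, quote = FALSE)
}

suite_table <- function(suite) {
  do.call(rbind, lapply(names(suite), function(nm) {
    s <- as.data.frame(suite[[nm]])
    model <- sub("_.*$", "", nm)
    focal <- sub("^modelI?I?_", "", nm)
    cbind(data.frame(model = model, focal = focal,
                     outcome = attr(suite[[nm]], "outcome"),
                     stringsAsFactors = FALSE), s)
  }))
}

test_record <- function(x) {
  if (inherits(x, "igt_test"))
    list(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = x$method)
  else x
}

#' Run the full analysis pipeline
#'
#' One reproducible end-to-end run: generate (or accept) a synthetic cohort,
#' fit the rEV model to every subject's session, compute the behavioral
#' metrics, and run the statistical stage — the T1-by-T2 smoking contingency
#' test, the gender/school composition tests at both waves, t-tests of the
#' key measures between smoking groups, the block-by-group split-plot
#' contrasts, and the adjusted prediction-model suite. All randomness derives
#' from the global seed via [stage_seed()], so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `subjects.csv`, `sessions.csv`, `fits.csv`, `metrics.csv`,
#'   `prediction_models.csv` and `analysis.json`.
#' @param cohort Optional pre-built `"igt_cohort"` (skips the generation
#'   stage).
#' @return List of class `"run_report"`: stage record counts, fit convergence
#'   summary, mean BIC statistic, the test results, and the prediction suite.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cohort = NULL) {
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  notes <- character()

  cohort <- tick("cohort", {
    if (is.null(cohort))
      generate_cohort(config$cohort, seed = stage_seed(config$seed, "cohort"))
    else cohort
  })
  subj <- cohort$subjects
  if (is.null(cohort$sessions)) stop("pipeline requires cohort sessions")

  fits <- tick("fit", fit_sessions(cohort$sessions, config$control))
  stopifnot(nrow(fits) == nrow(subj))  # record-count conservation

  metrics <- tick("metrics", igt_metrics(cohort$sessions,
                                         split = config$split))
  stopifnot(nrow(metrics) == nrow(subj))

  analysis <- tick("analysis", {
    safe <- function(expr) tryCatch(expr, error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    })
    tab_t1t2 <- table(t1 = factor(subj$smoker_t1, 0:1),
                      t2 = factor(subj$smoker_t2, 0:1))
    comp <- function(var, wave) {
      safe(chisq_2x2(table(subj[[var]],
                           factor(subj[[wave]], 0:1))))
    }
    dat <- merge(merge(subj, fits[c("subject_id", "w", "phi", "c")],
                       by = "subject_id"),
                 metrics, by = "subject_id")
    stopifnot(nrow(dat) == nrow(subj))
    ttests <- list()
    for (wave in c("smoker_t1", "smoker_t2")) {
      g <- dat[[wave]] == 1
      for (m in c("age", "net_total", "w", "phi", "c", "wm_score", "sap")) {
        ttests[[paste(wave, m, sep = ".")]] <-
          safe(group_t_test(dat[[m]][!g], dat[[m]][g]))
      }
    }
    covs <- subj[c("age", "gender", "school_type")]
    blocks <- list(
      t1 = safe(block_group_interaction(metrics$net_first, metrics$net_last,
                                        subj$smoker_t1, covs)),
      t2 = safe(block_group_interaction(metrics$net_first, metrics$net_last,
                                        subj$smoker_t2, covs)))
    suite <- safe(run_prediction_suite(cohort, fits = fits,
                                       metrics = metrics))
    list(table_t1_t2 = tab_t1t2,
         chisq_t1_t2 = safe(chisq_2x2(tab_t1t2)),
         chisq_gender_t1 = comp("gender", "smoker_t1"),
         chisq_school_t1 = comp("school_type", "smoker_t1"),
         chisq_gender_t2 = comp("gender", "smoker_t2"),
         chisq_school_t2 = comp("school_type", "smoker_t2"),
         t_tests = ttests, block_tests = blocks, suite = suite)
  })

  report <- structure(list(
    n_subjects = nrow(subj),
    n_sessions = length(cohort$sessions),
    n_fits = nrow(fits),
    n_converged = sum(fits$converged),
    mean_bic = mean(fits$bic_stat),
    analysis = analysis,
    fits = fits, metrics = metrics, subjects = subj,
    notes = notes, seed = config$seed, timings = timings
  ), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(subj, file.path(out_dir, "subjects.csv"))
    write_sessions_csv(cohort$sessions, file.path(out_dir, "sessions.csv"))
    write_table(fits, file.path(out_dir, "fits.csv"))
    write_table(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(analysis$suite))
      write_table(suite_table(analysis$suite),
                  file.path(out_dir, "prediction_models.csv"))
    json <- list(
      seed = config$seed, n_subjects = nrow(subj),
      mean_bic = report$mean_bic, n_converged = report$n_converged,
      table_t1_t2 = as.vector(analysis$table_t1_t2),
      tests = lapply(Filter(Negate(is.null), c(
        list(chisq_t1_t2 = analysis$chisq_t1_t2,
             chisq_gender_t1 = analysis$chisq_gender_t1,
             chisq_school_t1 = analysis$chisq_school_t1,
             chisq_gender_t2 = analysis$chisq_gender_t2,
             chisq_school_t2 = analysis$chisq_school_t2),
        analysis$t_tests)), test_record),
      notes = notes)
    jsonlite::write_json(json, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("IGT pipeline run (seed", x$seed, ")\n")
  cat(" subjects:", x$n_subjects, " sessions fit:", x$n_fits,
      sprintf("(%d converged)\n", x$n_converged))
  cat(sprintf(" mean BIC statistic: %.3f %s\n", x$mean_bic,
              if (x$mean_bic > 0) "(cognitive model preferred on average)"
              else "(baseline preferred on average)"))
  cat(" T1 x T2 current-smoker table:\n")
  print(x$analysis$table_t1_t2)
  if (!is.null(x$analysis$chisq_t1_t2))
    cat(sprintf(" chi-square(T1, T2) = %.2f, p = %.3g\n",
                x$analysis$chisq_t1_t2$statistic,
                x$analysis$chisq_t1_t2$p_value))
  if (length(x$notes))
    cat(" notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
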