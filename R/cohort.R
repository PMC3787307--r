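# truncated-normal draws by inverse CDF (exact, vectorised)
rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

dtnorm <- function(x, mean, sd, lower, upper) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  ifelse(x >= lower & x <= upper, dnorm(x, mean, sd) / z, 0)
}

#' Configuration of the synthetic two-wave cohort generator
#'
#' Defines the generative model for a cohort of adolescents with baseline
#' (T1) and one-year follow-up (T2) smoking status, demographic and cognitive
#' covariates, subject-level rEV parameters, and simulated 100-trial IGT
#' sessions. Defaults emulate a 181-subject cohort: age ~ N(16.2, 0.55),
#' roughly balanced gender, a 99:82 academic:vocational school split, a 9.4%
#' T1 current-smoker prevalence with elevated odds for males and vocational
#' students, working memory ~ N(61.8, 6.8) truncated to \[0, 72\], academic
#' performance on a 1-5 scale centred near 3.5 (lower among smokers), and
#' rEV parameters from truncated normals (overall w: 0.40 +/- 0.36;
#' phi: 0.23 +/- 0.33; c: 4.0 +/- 4.0 on \[0, 5\]).
#'
#' T2 smoking is generated from a logistic model on T1 status and the *true*
#' attention weight, `logit P(smoker_t2) = b0 + 3.075 * smoker_t1 - 2.673 *
#' w`, with the intercept calibrated numerically so the marginal T2
#' prevalence is 12.2%. The T1 intercept is likewise calibrated to the 9.4%
#' margin given the gender and school odds ratios. Smoking levels (ordinal
#' 0-6) are drawn conditionally on current-smoker status from the observed
#' level frequencies at each wave.
#'
#' @param n_subjects Cohort size; default 181.
#' @param n_trials IGT trials per subject; default 100.
#' @param seed Default seed used by [generate_cohort()].
#' @param p_smoker_t1,p_smoker_t2 Target marginal current-smoker prevalences.
#' @param or_male,or_vocational Odds ratios of T1 smoking for males vs
#'   females and vocational vs academic students (defaults are the odds
#'   ratios implied by the printed group compositions).
#' @param beta_smoke_t2,beta_w Logistic coefficients of the T2 outcome model
#'   on T1 smoking status and on the true attention weight `w`.
#' @param w_mean,w_sd,phi_mean,phi_sd,c_mean,c_sd rEV parameter distributions
#'   (truncated normals) for T1 non-smokers.
#' @param w_mean_s1,w_sd_s1,phi_mean_s1,phi_sd_s1,c_mean_s1,c_sd_s1 The same
#'   for T1 smokers.
#' @param c_max Consistency box bound.
#' @param age_mean,age_sd,p_male,p_vocational,wm_mean,wm_sd Covariate
#'   distributions.
#' @param sap_probs,sap_probs_s1 Probabilities of academic-performance scores
#'   1..5 for T1 non-smokers and smokers.
#' @param level_t1_probs,level_t2_probs Conditional distributions of smoking
#'   level 1..6 given current smoking at each wave.
#' @param theta_variant Sensitivity variant used when simulating sessions.
#' @return A list of class `"cohort_config"`, including the calibrated
#'   logistic intercepts `beta0_t1` and `beta0_t2`.
#' @export
cohort_config <- function(n_subjects = 181L, n_trials = 100L, seed = 20160901L,
                          p_smoker_t1 = 0.094, p_smoker_t2 = 0.122,
                          or_male = (15 / 76) / (2 / 88),
                          or_vocational = (13 / 69) / (4 / 95),
                          beta_smoke_t2 = 3.075, beta_w = -2.673,
                          w_mean = 0.40, w_sd = 0.36,
                          phi_mean = 0.23, phi_sd = 0.33,
                          c_mean = 4.0, c_sd = 4.0,
                          w_mean_s1 = 0.37, w_sd_s1 = 0.38,
                          phi_mean_s1 = 0.13, phi_sd_s1 = 0.26,
                          c_mean_s1 = 5.0, c_sd_s1 = 4.2,
                          c_max = 5,
                          age_mean = 16.2, age_sd = 0.55,
                          p_male = 0.5, p_vocational = 82 / 181,
                          wm_mean = 61.8, wm_sd = 6.8,
                          sap_probs = c(0.04, 0.10, 0.28, 0.42, 0.16),
                          sap_probs_s1 = c(0.10, 0.22, 0.35, 0.25, 0.08),
                          level_t1_probs = c(7, 3, 5, 2, 0, 0) / 17,
                          level_t2_probs = c(6, 3, 10, 1, 1, 1) / 22,
                          theta_variant = "pow3") {
  stopifnot(n_subjects >= 1, n_trials >= 1,
            p_smoker_t1 >= 0, p_smoker_t1 <= 1,
            p_smoker_t2 >= 0, p_smoker_t2 <= 1,
            all(sap_probs >= 0), all(sap_probs_s1 >= 0),
            w_sd >= 0, phi_sd >= 0, c_sd >= 0, wm_sd >= 0, age_sd >= 0)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials), seed = as.integer(seed),
              p_smoker_t1 = p_smoker_t1, p_smoker_t2 = p_smoker_t2,
              beta_male = log(or_male), beta_voc = log(or_vocational),
              beta_smoke_t2 = beta_smoke_t2, beta_w = beta_w,
              w_mean = w_mean, w_sd = w_sd, phi_mean = phi_mean,
              phi_sd = phi_sd, c_mean = c_mean, c_sd = c_sd,
              w_mean_s1 = w_mean_s1, w_sd_s1 = w_sd_s1,
              phi_mean_s1 = phi_mean_s1, phi_sd_s1 = phi_sd_s1,
              c_mean_s1 = c_mean_s1, c_sd_s1 = c_sd_s1, c_max = c_max,
              age_mean = age_mean, age_sd = age_sd, p_male = p_male,
              p_vocational = p_vocational, wm_mean = wm_mean, wm_sd = wm_sd,
              sap_probs = sap_probs / sum(sap_probs),
              sap_probs_s1 = sap_probs_s1 / sum(sap_probs_s1),
              level_t1_probs = level_t1_probs / sum(level_t1_probs),
              level_t2_probs = level_t2_probs / sum(level_t2_probs),
              theta_variant = theta_variant)
  cfg$beta0_t1 <- calibrate_beta0_t1(cfg)
  cfg$beta0_t2 <- calibrate_beta0_t2(cfg)
  structure(cfg, class = "cohort_config")
}

# intercept giving the target T1 margin over the gender x school cells
calibrate_beta0_t1 <- function(cfg) {
  if (cfg$p_smoker_t1 <= 0) return(-Inf)
  cells <- expand.grid(m = 0:1, v = 0:1)
  pcell <- with(cells,
                ifelse(m == 1, cfg$p_male, 1 - cfg$p_male) *
                ifelse(v == 1, cfg$p_vocational, 1 - cfg$p_vocational))
  f <- function(b0) {
    sum(pcell * plogis(b0 + cfg$beta_male * cells$m +
                         cfg$beta_voc * cells$v)) - cfg$p_smoker_t1
  }
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# intercept giving the target T2 margin, integrating over the w distribution
# of each T1 group
calibrate_beta0_t2 <- function(cfg) {
  p1 <- cfg$p_smoker_t1
  expected <- function(b0, s1) {
    mu <- if (s1 == 1) cfg$w_mean_s1 else cfg$w_mean
    sdv <- if (s1 == 1) cfg$w_sd_s1 else cfg$w_sd
    if (sdv == 0) {
      plogis(b0 + cfg$beta_smoke_t2 * s1 + cfg$beta_w * mu)
    } else {
      integrate(function(w)
        plogis(b0 + cfg$beta_smoke_t2 * s1 + cfg$beta_w * w) *
          dtnorm(w, mu, sdv, 0, 1), 0, 1, rel.tol = 1e-10)$value
    }
  }
  f <- function(b0) {
    (1 - p1) * expected(b0, 0) + p1 * expected(b0, 1) - cfg$p_smoker_t2
  }
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:", x$n_subjects, "subjects,",
      x$n_trials, "IGT trials\n")
  cat(sprintf(" T1 smoking: target %.1f%% (intercept %.3f, OR male %.2f, OR vocational %.2f)\n",
              100 * x$p_smoker_t1, x$beta0_t1, exp(x$beta_male),
              exp(x$beta_voc)))
  cat(sprintf(" T2 smoking: target %.1f%% (intercept %.3f, beta T1 %.3f, beta w %.3f)\n",
              100 * x$p_smoker_t2, x$beta0_t2, x$beta_smoke_t2, x$beta_w))
  cat(sprintf(" rEV parameters: w %.2f+/-%.2f, phi %.2f+/-%.2f, c %.1f+/-%.1f on [0,%g]\n",
              x$w_mean, x$w_sd, x$phi_mean, x$phi_sd, x$c_mean, x$c_sd,
              x$c_max))
  invisible(x)
}

#' Draw subject covariates, T1 smoking and true rEV parameters
#'
#' Samples `n` subject records (without IGT sessions) from the generative
#' model in `config`, using the current RNG stream.
#'
#' @param n Number of subjects.
#' @param config A [cohort_config()].
#' @return Data frame with demographic covariates, T1 smoking status/level
#'   and the true parameters `true_w`, `true_phi`, `true_c`.
#' @export
sample_subjects <- function(n, config) {
  age <- rnorm(n, config$age_mean, config$age_sd)
  male <- rbinom(n, 1, config$p_male)
  voc <- rbinom(n, 1, config$p_vocational)
  p1 <- plogis(config$beta0_t1 + config$beta_male * male +
                 config$beta_voc * voc)
  smoker_t1 <- rbinom(n, 1, p1)
  wm <- rtnorm(n, config$wm_mean, config$wm_sd, 0, 72)
  sap <- integer(n)
  ns <- smoker_t1 == 0
  sap[ns] <- sample.int(5, sum(ns), replace = TRUE, prob = config$sap_probs)
  sap[!ns] <- sample.int(5, sum(!ns), replace = TRUE,
                         prob = config$sap_probs_s1)
  w <- numeric(n)
  w[ns] <- rtnorm(sum(ns), config$w_mean, config$w_sd, 0, 1)
  w[!ns] <- rtnorm(sum(!ns), config$w_mean_s1, config$w_sd_s1, 0, 1)
  phi <- numeric(n)
  phi[ns] <- rtnorm(sum(ns), config$phi_mean, config$phi_sd, 0, 1)
  phi[!ns] <- rtnorm(sum(!ns), config$phi_mean_s1, config$phi_sd_s1, 0, 1)
  cc <- numeric(n)
  cc[ns] <- rtnorm(sum(ns), config$c_mean, config$c_sd, 0, config$c_max)
  cc[!ns] <- rtnorm(sum(!ns), config$c_mean_s1, config$c_sd_s1, 0,
                    config$c_max)
  level_t1 <- integer(n)
  sm <- smoker_t1 == 1
  if (any(sm)) {
    level_t1[sm] <- sample.int(6, sum(sm), replace = TRUE,
                               prob = config$level_t1_probs)
  }
  data.frame(subject_id = sprintf("s%04d", seq_len(n)),
             age = age,
             gender = factor(ifelse(male == 1, "male", "female"),
                             levels = c("female", "male")),
             school_type = factor(ifelse(voc == 1, "vocational", "academic"),
                                  levels = c("academic", "vocational")),
             wm_score = wm, sap = sap,
             smoker_t1 = smoker_t1, level_t1 = level_t1,
             true_w = w, true_phi = phi, true_c = cc,
             stringsAsFactors = FALSE)
}

#' Assign follow-up smoking outcomes
#'
#' Draws T2 current-smoker status from the logistic outcome model on T1
#' status and the true attention weight, then a conditional smoking level.
#' Uses the current RNG stream.
#'
#' @param subjects Data frame from [sample_subjects()].
#' @param config A [cohort_config()].
#' @return `subjects` with columns `smoker_t2` and `level_t2` appended.
#' @export
assign_t2_smoking <- function(subjects, config) {
  p2 <- plogis(config$beta0_t2 + config$beta_smoke_t2 * subjects$smoker_t1 +
                 config$beta_w * subjects$true_w)
  smoker_t2 <- rbinom(nrow(subjects), 1, p2)
  level_t2 <- integer(nrow(subjects))
  sm <- smoker_t2 == 1
  if (any(sm)) {
    level_t2[sm] <- sample.int(6, sum(sm), replace = TRUE,
                               prob = config$level_t2_probs)
  }
  subjects$smoker_t2 <- smoker_t2
  subjects$level_t2 <- level_t2
  subjects
}

#' Generate a complete synthetic two-wave cohort
#'
#' Samples subjects, assigns follow-up outcomes, and (optionally) simulates
#' each subject's IGT session from their true rEV parameters. The whole
#' cohort is a pure function of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param sessions If `TRUE` (default) simulate an IGT session per subject.
#' @return An object of class `"igt_cohort"`: list with `subjects` (data
#'   frame), `sessions` (named list of [igt_session()] or `NULL`) and
#'   `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 20), seed = 1)
#' table(coh$subjects$smoker_t1, coh$subjects$smoker_t2)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            sessions = TRUE) {
  set.seed(seed)
  subjects <- sample_subjects(config$n_subjects, config)
  subjects <- assign_t2_smoking(subjects, config)
  sess <- NULL
  if (sessions) {
    decks <- igt_decks()
    sess <- lapply(seq_len(nrow(subjects)), function(i) {
      simulate_igt(ev_params(subjects$true_w[i], subjects$true_phi[i],
                             subjects$true_c[i], c_max = config$c_max),
                   decks = decks, n_trials = config$n_trials,
                   theta_variant = config$theta_variant,
                   subject_id = subjects$subject_id[i])
    })
    names(sess) <- subjects$subject_id
  }
  structure(list(subjects = subjects, sessions = sess, config = config),
            class = "igt_cohort")
}

#' @export
print.igt_cohort <- function(x, ...) {
  s <- x$subjects
  cat("Synthetic IGT cohort:", nrow(s), "subjects",
      if (!is.null(x$sessions)) paste0("with ", x$config$n_trials,
                                       "-trial sessions") else
        "(no sessions)", "\n")
  cat(sprintf(" current smokers: T1 %d (%.1f%%), T2 %d (%.1f%%), both %d\n",
              sum(s$smoker_t1), 100 * mean(s$smoker_t1),
              sum(s$smoker_t2), 100 * mean(s$smoker_t2),
              sum(s$smoker_t1 & s$smoker_t2)))
  invisible(x)
}

#' Code a smoking-frequency questionnaire response
#'
#' Maps the seven response options of the past-30-day smoking item to the
#' ordinal level 0-6; any smoking in the past 30 days (level > 0) defines a
#' current smoker.
#'
#' @param response Character vector of response options (en-dash or hyphen
#'   accepted in ranges).
#' @return Integer vector of levels 0-6.
#' @examples
#' code_smoking_level("2-5 cigarettes per day")   # 3
#' @export
code_smoking_level <- function(response) {
  options <- c("I did not smoke cigarettes during the past 30 days",
               "Less than 1 cigarette per day",
               "1 cigarette per day",
               "2-5 cigarettes per day",
               "6-10 cigarettes per day",
               "11-20 cigarettes per day",
               "More than 20 cigarettes per day")
  norm <- gsub("–", "-", trimws(response))
  idx <- match(tolower(norm), tolower(options))
  if (anyNA(idx))
    stop("unknown response option(s): ",
         paste(unique(response[is.na(idx)]), collapse = "; "))
  idx - 1L
}

#' Smoking-level labels
#'
#' @return Character vector of the seven response options, in level order
#'   0-6.
#' @export
smoking_level_labels <- function() {
  c("I did not smoke cigarettes during the past 30 days",
    "Less than 1 cigarette per day", "1 cigarette per day",
    "2-5 cigarettes per day", "6-10 cigarettes per day",
    "11-20 cigarettes per day", "More than 20 cigarettes per day")
}

#' Parameter-recovery experiment
#'
#' Draws agents with parameters uniform over the box, simulates a session
#' for each, refits by maximum likelihood, and summarises recovery quality
#' per parameter (Pearson and Spearman correlation, bias, RMSE).
#'
#' @param n_agents Number of simulated agents (>= 2).
#' @param n_trials Trials per session; default 100.
#' @param seed Seed.
#' @param control An [ev_control()] used for fitting (its `c_max` also bounds
#'   the generating box).
#' @param horizons Optional increasing vector of session lengths. When given,
#'   one session of `max(horizons)` trials is simulated per agent and the
#'   model is refit on each leading prefix, so horizons are compared on
#'   common realisations (the paired design removes between-session noise
#'   from the comparison). `n_trials` is ignored in that case.
#' @return Object of class `"ev_recovery"`: list with `draws` (data frame of
#'   true and estimated parameters) and `stats` (per-parameter summary).
#'   With `horizons`, `draws` and `stats` gain a `horizon` column.
#' @export
recovery_experiment <- function(n_agents, n_trials = 100, seed = 1L,
                                control = ev_control(), horizons = NULL) {
  if (n_agents < 2) stop("'n_agents' must be >= 2")
  if (is.null(horizons)) horizons <- n_trials
  horizons <- sort(unique(as.integer(horizons)))
  set.seed(seed)
  true <- data.frame(w = runif(n_agents), phi = runif(n_agents),
                     c = runif(n_agents, 0, control$c_max))
  decks <- igt_decks()
  draws <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    s <- simulate_igt(ev_params(true$w[i], true$phi[i], true$c[i],
                                c_max = control$c_max),
                      decks = decks, n_trials = max(horizons),
                      theta_variant = control$theta_variant,
                      subject_id = paste0("agent", i))
    draws[[i]] <- do.call(rbind, lapply(horizons, function(h) {
      f <- ev_fit(s[seq_len(h), , drop = FALSE], control)
      data.frame(agent = i, horizon = h, w = true$w[i], phi = true$phi[i],
                 c = true$c[i], est.w = f$params$w, est.phi = f$params$phi,
                 est.c = f$params$c, converged = f$converged)
    }))
  }
  draws <- do.call(rbind, draws)
  stats <- do.call(rbind, lapply(horizons, function(h) {
    d <- draws[draws$horizon == h, ]
    do.call(rbind, lapply(c("w", "phi", "c"), function(p) {
      tr <- d[[p]]
      es <- d[[paste0("est.", p)]]
      data.frame(horizon = h, parameter = p,
                 pearson = if (n_agents > 2) cor(tr, es) else NA_real_,
                 spearman = if (n_agents > 2)
                   cor(tr, es, method = "spearman") else NA_real_,
                 bias = mean(es - tr),
                 rmse = sqrt(mean((es - tr)^2)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(stats) <- NULL
  structure(list(draws = draws, stats = stats, n_agents = n_agents,
                 n_trials = max(horizons), horizons = horizons, seed = seed),
            class = "ev_recovery")
}

#' @export
print.ev_recovery <- function(x, ...) {
  cat("rEV parameter recovery:", x$n_agents, "agents,", x$n_trials,
      "trials\n")
  print(transform(x$stats, pearson = round(pearson, 3),
                  spearman = round(spearman, 3), bias = round(bias, 3),
                  rmse = round(rmse, 3)), row.names = FALSE)
  invisible(x)
}
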