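#' Pearson chi-square test for a 2x2 contingency table
#'
#' Plain Pearson statistic \eqn{\sum (O - E)^2 / E} with expected counts from
#' the product of margins, 1 degree of freedom, and no continuity
#' correction.
#'
#' @param table A 2x2 matrix of nonnegative counts.
#' @return List of class `"igt_test"` with `statistic`, `df`, `p_value`.
#' @examples
#' chisq_2x2(matrix(c(153, 11, 6, 11), 2))   # statistic ~ 48.53
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("'table' must be 2x2")
  if (any(table < 0) || sum(table) < 1) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 method = "Pearson chi-square (no continuity correction)"),
            class = "igt_test")
}

#' @export
print.igt_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf(" statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value))
  invisible(x)
}

#' Independent two-sample t-test
#'
#' Student's pooled-variance t-test by default (Welch available via
#' `pooled = FALSE`), two-sided.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param pooled Use the pooled-variance (Student) form; default `TRUE`.
#' @return List of class `"igt_test"`.
#' @export
group_t_test <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 values")
  if (sd(x) == 0 && sd(y) == 0)
    stop("degenerate input: both samples have zero variance")
  tt <- t.test(x, y, var.equal = pooled)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = unname(tt$p.value),
                 method = if (pooled) "Student t-test (pooled variance)"
                          else "Welch t-test"),
            class = "igt_test")
}

#' Group-by-block interaction test on two-block IGT scores
#'
#' Split-plot (between-within) contrast with exactly two within-subject
#' blocks, realised through difference scores: with two blocks, the
#' group-by-block interaction is identical to the between-group effect on
#' `block2 - block1`, tested by ANCOVA with the supplied covariates. The
#' group main effect is tested the same way on the subject means.
#'
#' @param net_first,net_last Per-subject net scores for the two blocks.
#' @param group Two-level factor or 0/1 vector (e.g. smoking status).
#' @param covariates Optional data frame of adjustment covariates.
#' @return List of class `"igt_blocktest"` with elements `interaction` and
#'   `group`, each an `"igt_test"` (F statistic, df, p).
#' @export
block_group_interaction <- function(net_first, net_last, group,
                                    covariates = NULL) {
  n <- length(net_first)
  if (length(net_last) != n || length(group) != n)
    stop("inputs must have one value per subject")
  dat <- data.frame(.diff = net_last - net_first,
                    .mean = (net_first + net_last) / 2,
                    .group = factor(group))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
    if (anyNA(covariates)) stop("missing covariate values")
    dat <- cbind(dat, covariates)
  }
  covs <- setdiff(names(dat), c(".diff", ".mean", ".group"))
  rhs_null <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  ftest <- function(response) {
    full <- lm(stats::as.formula(paste(response, "~ .group +", rhs_null)),
               data = dat)
    null <- lm(stats::as.formula(paste(response, "~", rhs_null)), data = dat)
    an <- anova(null, full)
    structure(list(statistic = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                   p_value = an$`Pr(>F)`[2],
                   method = "ANCOVA F-test (difference-score split-plot)"),
              class = "igt_test")
  }
  structure(list(interaction = ftest(".diff"), group = ftest(".mean")),
            class = "igt_blocktest")
}

#' @export
print.igt_blocktest <- function(x, ...) {
  cat("Two-block split-plot contrasts\n group x block interaction: ")
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g\n", x$interaction$df[1],
              x$interaction$df[2], x$interaction$statistic,
              x$interaction$p_value))
  cat(sprintf(" group main effect:         F(%d, %d) = %.3f, p = %.4g\n",
              x$group$df[1], x$group$df[2], x$group$statistic,
              x$group$p_value))
  invisible(x)
}

model_summary_frame <- function(B, SE, effect, ci_low, ci_high, p) {
  data.frame(term = names(B), B = unname(B), SE = unname(SE),
             effect = unname(effect), ci_low = unname(ci_low),
             ci_high = unname(ci_high), p_value = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Logistic prediction model with Wald summaries
#'
#' Maximum-likelihood logistic regression reporting, per term, the raw
#' coefficient B, its standard error, the odds ratio `exp(B)` with Wald 95%
#' interval `exp(B +/- 1.96 SE)`, and the Wald p-value. Complete or
#' quasi-complete separation is flagged (attribute `separation` and a
#' warning), not silently returned.
#'
#' @param formula Model formula with a binary outcome.
#' @param data Data frame.
#' @return A `"model_summary"` data frame (one row per coefficient) with
#'   attributes `outcome`, `n`, `model` and `separation`.
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("design is rank-deficient")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  B <- coef(fit)
  SE <- sqrt(diag(vcov(fit)))
  if (any(abs(B[-1]) > 15) || any(SE > 50)) sep <- TRUE
  if (sep) warning("possible complete separation: coefficients may be non-identifiable")
  p <- 2 * pnorm(-abs(B / SE))
  out <- model_summary_frame(B, SE, exp(B), exp(B - 1.96 * SE),
                             exp(B + 1.96 * SE), p)
  structure(out, outcome = deparse(formula[[2]]), n = nrow(mf),
            model = "logistic", separation = sep,
            class = c("model_summary", "data.frame"))
}

#' Linear prediction model with standardized coefficients
#'
#' Ordinary least squares reporting, per term, the raw coefficient B, its
#' standard error, the standardized beta (coefficient after z-scoring the
#' outcome and every predictor column, including dummies), the Wald 95%
#' interval on the raw scale `B +/- 1.96 SE`, and the p-value.
#'
#' @param formula Model formula with a numeric outcome.
#' @param data Data frame.
#' @return A `"model_summary"` data frame with attributes `outcome`, `n`,
#'   `model`.
#' @export
fit_linear_std <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("design is rank-deficient")
  if (nrow(X) <= ncol(X)) stop("more terms than observations")
  fit <- lm(formula, data = data)
  sm <- summary(fit)$coefficients
  B <- sm[, 1]
  SE <- sm[, 2]
  p <- sm[, 4]
  sds <- apply(X, 2, sd)
  beta_std <- ifelse(sds > 0, B * sds / sd(y), NA_real_)
  beta_std[1] <- NA_real_  # intercept has no standardized form
  out <- model_summary_frame(B, SE, beta_std, B - 1.96 * SE, B + 1.96 * SE, p)
  structure(out, outcome = deparse(formula[[2]]), n = nrow(mf),
            model = "linear", separation = FALSE,
            class = c("model_summary", "data.frame"))
}

#' @export
print.model_summary <- function(x, digits = 3, ...) {
  cat(attr(x, "model"), "model for", attr(x, "outcome"),
      "(n =", paste0(attr(x, "n"), ")"),
      if (isTRUE(attr(x, "separation"))) "[separation flagged]" else "",
      "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run the adjusted prediction-model suite over the four focal predictors
#'
#' For each focal predictor (overall IGT net score and the three rEV
#' parameters w, phi, c), fits two models: Model I, a logistic regression of
#' follow-up current-smoker status, and Model II, a linear regression of
#' follow-up smoking level — each adjusted for age, gender, school type,
#' working memory, academic performance and the baseline (T1) value of the
#' outcome. Focal predictors are examined one at a time, never jointly.
#'
#' @param cohort An `"igt_cohort"`.
#' @param fits Data frame from [fit_sessions()] with per-subject `w`, `phi`,
#'   `c` (ignored when `use_true_params = TRUE`).
#' @param metrics Data frame from [igt_metrics()]; computed from the cohort's
#'   sessions when `NULL` and sessions are present.
#' @param use_true_params Use the generator's true parameters instead of
#'   fitted ones (useful for large-n checks of the generative structure).
#' @return List of class `"prediction_suite"`: eight `"model_summary"`
#'   objects named `modelI_<focal>` / `modelII_<focal>`.
#' @export
run_prediction_suite <- function(cohort, fits = NULL, metrics = NULL,
                                 use_true_params = FALSE) {
  subj <- cohort$subjects
  if (use_true_params) {
    pars <- data.frame(subject_id = subj$subject_id, w = subj$true_w,
                       phi = subj$true_phi, c = subj$true_c,
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(fits)) stop("'fits' required unless use_true_params = TRUE")
    pars <- fits[c("subject_id", "w", "phi", "c")]
  }
  if (is.null(metrics)) {
    if (is.null(cohort$sessions))
      stop("'metrics' required when the cohort has no sessions")
    metrics <- igt_metrics(cohort$sessions)
  }
  dat <- merge(subj, pars, by = "subject_id")
  dat <- merge(dat, metrics[c("subject_id", "net_total")], by = "subject_id")
  if (nrow(dat) != nrow(subj))
    stop("join failure: fits/metrics do not cover every subject")
  base_terms <- "age + gender + school_type + wm_score + sap"
  out <- list()
  for (focal in c("net_total", "w", "phi", "c")) {
    f1 <- stats::as.formula(paste("smoker_t2 ~", base_terms,
                                  "+ smoker_t1 +", focal))
    f2 <- stats::as.formula(paste("level_t2 ~", base_terms,
                                  "+ level_t1 +", focal))
    out[[paste0("modelI_", focal)]] <- fit_logistic(f1, dat)
    out[[paste0("modelII_", focal)]] <- fit_linear_std(f2, dat)
  }
  structure(out, class = "prediction_suite")
}

#' @export
print.prediction_suite <- function(x, ...) {
  cat("Prediction-model suite:", length(x), "adjusted models\n")
  for (nm in names(x)) {
    focal <- sub("^modelI?I?_", "", nm)
    row <- x[[nm]][x[[nm]]$term == focal, ]
    cat(sprintf(" %-18s %s = %8.4f (SE %.4f, p = %.4g)\n", nm, focal,
                row$B, row$SE, row$p_value))
  }
  invisible(x)
}
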