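#' rEV model parameters
#'
#' The revised Expectancy-Valence model describes trial-by-trial IGT choice
#' with three subject-level parameters: the attention weight to gains `w`
#' (0 = all attention to losses, 1 = all to gains), the recency `phi`
#' (learning rate of the expectancy update; 1 = only the last outcome
#' matters), and the choice consistency `c`, which sets the sensitivity
#' `theta` of the softmax choice rule (c = 0 gives uniform random choice).
#'
#' @param w Attention weight to gains, in \[0, 1\].
#' @param phi Recency (learning rate), in \[0, 1\].
#' @param c Choice consistency, in \[0, `c_max`\].
#' @param c_max Upper bound for `c`; default 5.
#' @return A named list of class `"ev_params"`.
#' @export
ev_params <- function(w, phi, c, c_max = 5) {
  if (!is.finite(w) || w < 0 || w > 1)
    stop("'w' must lie in [0, 1]")
  if (!is.finite(phi) || phi < 0 || phi > 1)
    stop("'phi' must lie in [0, 1]")
  if (!is.finite(c) || c < 0 || c > c_max)
    stop("'c' must lie in [0, ", c_max, "]")
  structure(list(w = w, phi = phi, c = c, c_max = c_max),
            class = "ev_params")
}

#' Fitting settings for the rEV model
#'
#' @param n_grid Starting points per parameter for the multi-start lattice
#'   (total starts = `n_grid^3`); default 4.
#' @param tol Relative convergence tolerance of the local search, and the
#'   log-likelihood margin within which optima are considered tied; ties are
#'   broken toward lexicographically smaller `(w, phi, c)`.
#' @param prob_floor Smallest choice probability used inside logarithms;
#'   bounds the likelihood surface when `theta` saturates the softmax.
#' @param theta_variant `"pow3"` (default): trial-independent
#'   \eqn{\theta = 3^c - 1}; `"trial_pow"`: trial-dependent
#'   \eqn{\theta(t) = (t/10)^c}.
#' @param c_max Upper bound of the consistency parameter box.
#' @param seed Seed reserved for optional start jitter; the default lattice
#'   is deterministic, so fits do not depend on it.
#' @param max_iter Iteration cap per local search.
#' @return A list of class `"ev_control"`.
#' @export
ev_control <- function(n_grid = 4, tol = 1e-6, prob_floor = 1e-10,
                       theta_variant = c("pow3", "trial_pow"), c_max = 5,
                       seed = 1L, max_iter = 500L) {
  theta_variant <- match.arg(theta_variant)
  if (prob_floor <= 0) stop("'prob_floor' must be > 0")
  if (n_grid < 1) stop("'n_grid' must be >= 1")
  structure(list(n_grid = as.integer(n_grid), tol = tol,
                 prob_floor = prob_floor, theta_variant = theta_variant,
                 c_max = c_max, seed = as.integer(seed),
                 max_iter = as.integer(max_iter)),
            class = "ev_control")
}

#' Valence of a trial outcome
#'
#' The subjective value of a card's outcome is a weighted combination of the
#' amounts won and lost, \eqn{v = w \cdot win - (1 - w) \cdot loss}, with the
#' loss supplied as a positive magnitude.
#'
#' @param win,loss Nonnegative money amounts (vectorised).
#' @param w Attention weight to gains, in \[0, 1\].
#' @return Numeric valence(s).
#' @examples
#' ev_valence(100, 0, 0.4)    # 40
#' @export
ev_valence <- function(win, loss, w) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("'w' must lie in [0, 1]")
  w * win - (1 - w) * loss
}

#' Expectancy update (delta rule)
#'
#' Moves the chosen deck's expectancy toward the experienced valence by a
#' fraction `phi`: \eqn{E \leftarrow E + \phi (v - E)}. Only the chosen
#' alternative is updated; the result always lies between `E_prev` and `v`.
#'
#' @param E_prev Previous expectancy.
#' @param v Valence of the current outcome.
#' @param phi Recency parameter in \[0, 1\].
#' @return Updated expectancy.
#' @export
ev_update_expectancy <- function(E_prev, v, phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("'phi' must lie in [0, 1]")
  E_prev + phi * (v - E_prev)
}

#' Choice sensitivity theta
#'
#' Maps the consistency parameter `c` to the softmax sensitivity. The default
#' variant `"pow3"` is trial-independent, \eqn{\theta = 3^c - 1}; the
#' `"trial_pow"` variant is the trial-dependent \eqn{\theta(t) = (t/10)^c}.
#' Both are monotone nondecreasing in `c`, and `c = 0` yields uniform random
#' choice under `"pow3"`.
#'
#' @param c Consistency parameter (scalar).
#' @param t Trial index (used only by `"trial_pow"`).
#' @param variant `"pow3"` or `"trial_pow"`.
#' @return Sensitivity `theta >= 0` (vectorised over `t`).
#' @export
ev_theta <- function(c, t = 1L, variant = c("pow3", "trial_pow")) {
  variant <- match.arg(variant)
  if (!is.finite(c) || c < 0) stop("'c' must be >= 0")
  switch(variant,
         pow3 = rep.int(3^c - 1, length(t)),
         trial_pow = (t / 10)^c)
}

# per-trial theta vector for a T-trial session
theta_vector <- function(c, n_trials, variant) {
  ev_theta(c, seq_len(n_trials), variant)
}

#' Softmax choice probabilities from expectancies
#'
#' Luce-rule strength ratio \eqn{p_j = e^{\theta E_j} / \sum_k e^{\theta
#' E_k}}, computed with max-subtraction so that extreme sensitivities do not
#' overflow.
#'
#' @param E Numeric vector of deck expectancies (finite).
#' @param theta Sensitivity \eqn{\ge 0}.
#' @return Probability vector summing to 1.
#' @examples
#' ev_choice_prob(c(1, 0, 0, 0), log(2))   # 0.4 0.2 0.2 0.2
#' @export
ev_choice_prob <- function(E, theta) {
  if (any(!is.finite(E))) stop("expectancies must be finite")
  if (theta < 0) stop("'theta' must be >= 0")
  z <- theta * E
  e <- exp(z - max(z))
  e / sum(e)
}

deck_index <- function(deck) {
  idx <- match(deck, c("A", "B", "C", "D"))
  if (anyNA(idx)) stop("invalid deck label in session")
  as.integer(idx)
}

#' One-step-ahead log-likelihood of a session under the rEV model
#'
#' All expectancies start at zero (the first choice is therefore uniform);
#' at each trial the log-probability of the observed choice given the history
#' is accumulated, then the chosen deck's expectancy is updated with that
#' trial's valence. Probabilities are floored at `control$prob_floor` before
#' taking logs.
#'
#' @param session An [igt_session()].
#' @param params An [ev_params()] (or list with `w`, `phi`, `c`).
#' @param control An [ev_control()].
#' @return Scalar log-likelihood (\eqn{\le 0}).
#' @export
ev_loglik <- function(session, params, control = ev_control()) {
  if (nrow(session) == 0L) stop("session has no trials")
  th <- theta_vector(params$c, nrow(session), control$theta_variant)
  ev_loglik_cpp(deck_index(session$deck), session$win, session$loss,
                params$w, params$phi, th, control$prob_floor)
}

#' Baseline (static choice proportion) log-likelihood
#'
#' The baseline model predicts every choice from the subject's overall choice
#' proportions; its maximised log-likelihood has the closed form
#' \eqn{\sum_j n_j \log(n_j / T)}, with never-chosen decks contributing
#' nothing.
#'
#' @param session An [igt_session()].
#' @return Scalar log-likelihood (\eqn{\le 0}).
#' @export
baseline_loglik <- function(session) {
  if (nrow(session) == 0L) stop("session has no trials")
  n <- tabulate(deck_index(session$deck), nbins = 4L)
  T <- nrow(session)
  nz <- n > 0
  sum(n[nz] * log(n[nz] / T))
}

#' BIC statistic comparing the cognitive and baseline models
#'
#' \eqn{2(\ell_{model} - \ell_{baseline}) - (k_{model} - k_{baseline})
#' \log n}. With the default equal parameter counts (3 rEV parameters; 3 free
#' baseline proportions) the penalty cancels and the statistic is twice the
#' log-likelihood difference. Positive values favour the cognitive model.
#'
#' @param loglik_model,loglik_baseline Log-likelihoods.
#' @param k_model,k_baseline Parameter counts; defaults 3 and 3.
#' @param n Number of trials.
#' @return Scalar BIC statistic.
#' @export
bic_statistic <- function(loglik_model, loglik_baseline, k_model = 3,
                          k_baseline = 3, n = 100) {
  if (n < 1) stop("'n' must be >= 1")
  2 * (loglik_model - loglik_baseline) - (k_model - k_baseline) * log(n)
}

# box <-> unconstrained transforms for the optimiser
ev_to_unconstrained <- function(p, c_max) {
  c(qlogis(p[1]), qlogis(p[2]), qlogis(p[3] / c_max))
}
ev_from_unconstrained <- function(z, c_max) {
  c(w = plogis(z[1]), phi = plogis(z[2]), c = c_max * plogis(z[3]))
}

#' Fit the rEV model to one IGT session by maximum likelihood
#'
#' Maximises the one-step-ahead log-likelihood over the parameter box
#' \eqn{[0,1] \times [0,1] \times [0, c_{max}]} by derivative-free local
#' search (Nelder-Mead on a logit-transformed unconstrained space) started
#' from an `n_grid^3` lattice of interior points. The likelihood surface is
#' multi-modal, so all starts are refined and the best optimum kept; ties
#' within `tol` are broken toward lexicographically smaller `(w, phi, c)`.
#' The fit also computes the baseline log-likelihood and the BIC statistic
#' comparing the two models.
#'
#' @param session An [igt_session()] with at least 10 trials.
#' @param control An [ev_control()].
#' @return An object of class `"ev_fit"` with components `params`
#'   ([ev_params()]), `loglik_model`, `loglik_baseline`, `bic_stat`,
#'   `n_starts`, `converged`, plus the session and control used.
#' @examples
#' s <- simulate_igt(ev_params(0.3, 0.3, 2), n_trials = 60, seed = 7)
#' fit <- ev_fit(s, ev_control(n_grid = 2))
#' coef(fit)
#' @export
ev_fit <- function(session, control = ev_control()) {
  if (nrow(session) < 10L) stop("session must have at least 10 trials")
  dk <- deck_index(session$deck)
  Tn <- nrow(session)
  nll <- function(z) {
    p <- ev_from_unconstrained(z, control$c_max)
    th <- theta_vector(p[3], Tn, control$theta_variant)
    -ev_loglik_cpp(dk, session$win, session$loss, p[1], p[2], th,
                   control$prob_floor)
  }
  g <- (seq_len(control$n_grid) - 0.5) / control$n_grid
  starts <- expand.grid(w = g, phi = g, c = g * control$c_max)
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    z0 <- ev_to_unconstrained(as.numeric(starts[i, ]), control$c_max)
    opt <- optim(z0, nll, method = "Nelder-Mead",
                 control = list(reltol = control$tol,
                                maxit = control$max_iter))
    p <- ev_from_unconstrained(opt$par, control$c_max)
    cand <- list(par = p, value = opt$value,
                 converged = opt$convergence == 0L)
    if (cand$converged) n_conv <- n_conv + 1L
    if (is.null(best)) {
      best <- cand
    } else if (cand$value < best$value - control$tol) {
      best <- cand
    } else if (abs(cand$value - best$value) <= control$tol) {
      # tie on likelihood: lexicographically smaller (w, phi, c) wins
      d <- which(abs(cand$par - best$par) > 1e-12)
      if (length(d) && cand$par[d[1]] < best$par[d[1]]) best <- cand
    }
  }
  ll_model <- -best$value
  ll_base <- baseline_loglik(session)
  params <- ev_params(unname(best$par[1]), unname(best$par[2]),
                      unname(best$par[3]), c_max = control$c_max)
  structure(list(
    params = params,
    loglik_model = ll_model,
    loglik_baseline = ll_base,
    bic_stat = bic_statistic(ll_model, ll_base, 3, 3, Tn),
    n_starts = nrow(starts),
    n_converged = n_conv,
    converged = n_conv > 0L,
    session = session,
    control = control
  ), class = "ev_fit")
}

#' @export
print.ev_fit <- function(x, digits = 4, ...) {
  cat("rEV model fit (", nrow(x$session), " trials, subject ",
      attr(x$session, "subject_id"), ")\n", sep = "")
  print(round(coef(x), digits))
  cat("logLik (rEV):", format(x$loglik_model, digits = 6),
      " baseline:", format(x$loglik_baseline, digits = 6),
      " BIC stat:", format(x$bic_stat, digits = 4), "\n")
  if (!x$converged) cat("warning: no optimiser start converged\n")
  invisible(x)
}

#' @export
coef.ev_fit <- function(object, ...) {
  c(w = object$params$w, phi = object$params$phi, c = object$params$c)
}

#' @export
logLik.ev_fit <- function(object, ...) {
  structure(object$loglik_model, df = 3L, nobs = nrow(object$session),
            class = "logLik")
}

#' @export
summary.ev_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              loglik_model = object$loglik_model,
              loglik_baseline = object$loglik_baseline,
              bic_stat = object$bic_stat,
              n_trials = nrow(object$session),
              n_starts = object$n_starts,
              n_converged = object$n_converged,
              converged = object$converged,
              theta_variant = object$control$theta_variant)
  class(out) <- "summary.ev_fit"
  out
}

#' @export
print.summary.ev_fit <- function(x, ...) {
  cat("Revised Expectancy-Valence model, one-step-ahead ML fit\n")
  cat(" trials:", x$n_trials, "  theta variant:", x$theta_variant, "\n")
  cat(" parameters:\n")
  print(round(x$coef, 4))
  cat(" logLik rEV:     ", format(x$loglik_model, digits = 6), "\n")
  cat(" logLik baseline:", format(x$loglik_baseline, digits = 6), "\n")
  cat(" BIC statistic:  ", format(x$bic_stat, digits = 4),
      if (x$bic_stat > 0) "(cognitive model preferred)" else
        "(baseline preferred)", "\n")
  cat(" optimiser starts converged:", x$n_converged, "/", x$n_starts, "\n")
  invisible(x)
}

#' One-step-ahead predictions from a fitted rEV model
#'
#' @param object An `"ev_fit"`.
#' @param type `"prob"` for the T x 4 matrix of one-step-ahead choice
#'   probabilities, `"expectancy"` for the post-update expectancy trajectory.
#' @param ... Unused.
#' @return A numeric matrix with one row per trial, columns A-D.
#' @export
predict.ev_fit <- function(object, type = c("prob", "expectancy"), ...) {
  type <- match.arg(type)
  s <- object$session
  p <- object$params
  th <- theta_vector(p$c, nrow(s), object$control$theta_variant)
  tr <- ev_trace_cpp(deck_index(s$deck), s$win, s$loss, p$w, p$phi, th)
  m <- if (type == "prob") tr$prob else tr$expectancy
  dimnames(m) <- list(NULL, c("A", "B", "C", "D"))
  m
}

#' @export
residuals.ev_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  pr <- predict(object, "prob")
  idx <- cbind(seq_len(nrow(pr)), deck_index(object$session$deck))
  p <- pmax(pr[idx], object$control$prob_floor)
  switch(type,
         deviance = sqrt(-2 * log(p)),
         response = 1 - p)
}

#' Simulate IGT sessions from rEV parameters
#'
#' Runs the model generatively: each choice is sampled from the softmax over
#' current expectancies, the outcome is drawn from the chosen deck's cyclic
#' schedule at that deck's next within-deck position, and the chosen deck's
#' expectancy is updated.
#'
#' @param params An [ev_params()].
#' @param decks Deck schedules, default [igt_decks()].
#' @param n_trials Number of trials; default 100.
#' @param seed Optional seed for reproducibility.
#' @param theta_variant Sensitivity variant, as in [ev_control()].
#' @param subject_id Identifier for the simulated session.
#' @return An [igt_session()].
#' @export
simulate_igt <- function(params, decks = igt_decks(), n_trials = 100,
                         seed = NULL, theta_variant = "pow3",
                         subject_id = "sim") {
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  th <- theta_vector(params$c, n_trials, theta_variant)
  gains <- vapply(decks[c("A", "B", "C", "D")], `[[`, numeric(1), "gain")
  losses <- t(vapply(decks[c("A", "B", "C", "D")], `[[`, numeric(10),
                     "losses"))
  sim <- ev_simulate_cpp(as.integer(n_trials), params$w, params$phi, th,
                         gains, losses)
  igt_session(subject_id, c("A", "B", "C", "D")[sim$deck], sim$win, sim$loss)
}

#' @export
simulate.ev_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_igt(object$params, n_trials = nrow(object$session),
                 theta_variant = object$control$theta_variant,
                 subject_id = paste0(attr(object$session, "subject_id"),
                                     "_sim", i)))
}

#' @export
plot.ev_fit <- function(x, which = c("prob", "expectancy"), ...) {
  which <- match.arg(which)
  m <- predict(x, which)
  matplot(m, type = "l", lty = 1, col = c("firebrick", "darkorange",
                                          "forestgreen", "steelblue"),
          xlab = "trial",
          ylab = if (which == "prob") "one-step-ahead P(choice)"
                 else "expectancy", ...)
  legend("topright", legend = c("A", "B", "C", "D"), lty = 1,
         col = c("firebrick", "darkorange", "forestgreen", "steelblue"),
         bty = "n")
  invisible(x)
}

#' Fit many sessions and tabulate the results
#'
#' @param sessions List of [igt_session()] objects.
#' @param control An [ev_control()].
#' @return Data frame with one row per subject: `subject_id`, `w`, `phi`,
#'   `c`, `loglik_model`, `loglik_baseline`, `bic_stat`, `converged`.
#' @export
fit_sessions <- function(sessions, control = ev_control()) {
  rows <- lapply(sessions, function(s) {
    f <- ev_fit(s, control)
    data.frame(subject_id = attr(s, "subject_id"),
               w = f$params$w, phi = f$params$phi, c = f$params$c,
               loglik_model = f$loglik_model,
               loglik_baseline = f$loglik_baseline,
               bic_stat = f$bic_stat, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
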