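test_that("valence is the attention-weighted win/loss combination", {
  expect_equal(ev_valence(100, 0, 0.4), 40)
  expect_equal(ev_valence(100, 1250, 1), 100)
  expect_equal(ev_valence(50, 250, 0), -250)
  expect_error(ev_valence(100, 0, 1.2), "w")
})

test_that("expectancy update is a convex step toward the valence", {
  expect_equal(ev_update_expectancy(0, 50, 0.5), 25)
  expect_equal(ev_update_expectancy(17, -300, 0), 17)
  expect_equal(ev_update_expectancy(17, -300, 1), -300)
  expect_error(ev_update_expectancy(0, 1, -0.1), "phi")
  # result always lies between E_prev and v
  set.seed(1)
  for (i in 1:50) {
    E <- runif(1, -500, 500); v <- runif(1, -500, 500); phi <- runif(1)
    r <- ev_update_expectancy(E, v, phi)
    expect_gte(r, min(E, v))
    expect_lte(r, max(E, v))
  }
})

test_that("sensitivity theta follows the selected variant", {
  expect_equal(ev_theta(0), 0)
  expect_equal(ev_theta(1), 2)
  expect_equal(ev_theta(2), 8)
  expect_equal(ev_theta(2, t = 1:3, variant = "trial_pow"),
               (1:3 / 10)^2)
  # monotone nondecreasing in c for both variants
  cs <- seq(0, 5, by = 0.25)
  expect_true(all(diff(vapply(cs, ev_theta, numeric(1))) >= 0))
  expect_true(all(diff(vapply(cs, ev_theta, numeric(1), t = 20,
                              variant = "trial_pow")) >= 0))
  expect_error(ev_theta(1, variant = "nope"))
  expect_error(ev_theta(-1), "c")
})

test_that("choice probabilities obey the Luce rule", {
  expect_equal(ev_choice_prob(c(300, -200, 5, 0), 0), rep(0.25, 4))
  expect_equal(ev_choice_prob(rep(7, 4), 3.3), rep(0.25, 4))
  expect_equal(ev_choice_prob(c(1, 0, 0, 0), log(2)),
               c(0.4, 0.2, 0.2, 0.2))
  expect_error(ev_choice_prob(c(1, NA, 0, 0), 1), "finite")
  # sums to 1 and shift-invariant, including at extreme sensitivities
  set.seed(2)
  for (i in 1:50) {
    E <- runif(4, -1000, 1000)
    th <- runif(1, 0, 250)
    p <- ev_choice_prob(E, th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, ev_choice_prob(E + 123.45, th), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("likelihood engine matches the brute-force oracle on short sessions", {
  ctl <- ev_control()
  set.seed(3)
  for (i in 1:40) {
    n <- sample(1:5, 1)
    s <- random_session(n)
    w <- runif(1); phi <- runif(1); cons <- runif(1, 0, 5)
    variant <- sample(c("pow3", "trial_pow"), 1)
    got <- ev_loglik(s, ev_params(w, phi, cons),
                     ev_control(theta_variant = variant))
    want <- oracle_loglik(s$deck, s$win, s$loss, w, phi, cons, variant)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # hand-derived 3-trial trace: decks A, A, B with w=.5, phi=.5, c=1
  # t1: uniform 1/4, v=50, E_A=25; t2: theta=2, p_A=1/(1+3e^-50), E_A=37.5;
  # t3: p_B = 1/(e^75+3) ~ 2.6e-33, floored at 1e-10
  s <- play_sequence(c("A", "A", "B"))
  got <- ev_loglik(s, ev_params(0.5, 0.5, 1), ctl)
  want <- log(0.25) - log(1 + 3 * exp(-50)) + log(1e-10)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("degenerate likelihood values have closed forms", {
  s <- random_session(1)
  expect_equal(ev_loglik(s, ev_params(0.3, 0.7, 4)), log(0.25))
  s <- random_session(30)
  expect_equal(ev_loglik(s, ev_params(0.5, 0.5, 0)), 30 * log(0.25))
  expect_error(ev_loglik(igt_session("e", character(0), numeric(0),
                                     numeric(0)), ev_params(.5, .5, 1)),
               "trials")
})

test_that("log-likelihood is monotone in the probability floor", {
  set.seed(4)
  s <- random_session(40)
  p <- ev_params(0.2, 0.6, 3)
  lls <- vapply(c(1e-4, 1e-6, 1e-8, 1e-10, 1e-12), function(fl)
    ev_loglik(s, p, ev_control(prob_floor = fl)), numeric(1))
  expect_true(all(diff(lls) <= 1e-12))
  # independent of the floor when no probability reaches it (c = 0)
  p0 <- ev_params(0.2, 0.6, 0)
  expect_equal(ev_loglik(s, p0, ev_control(prob_floor = 1e-4)),
               ev_loglik(s, p0, ev_control(prob_floor = 1e-12)))
})

test_that("baseline likelihood is the multinomial maximum", {
  sB <- igt_session("b", rep("B", 100), rep(100, 100), rep(0, 100))
  expect_equal(baseline_loglik(sB), 0)
  s4 <- play_sequence(rep(c("A", "B", "C", "D"), 25))
  expect_equal(baseline_loglik(s4), 100 * log(0.25))
  s2 <- play_sequence(rep(c("A", "B"), 50))
  expect_equal(baseline_loglik(s2), 100 * log(0.5))
  # perturbing the proportion vector never increases the log-likelihood
  set.seed(5)
  s <- random_session(60)
  n <- deck_counts(s)
  base_ll <- baseline_loglik(s)
  for (i in 1:30) {
    p <- as.numeric(n) + runif(4, 0, 3)
    p <- p / sum(p)
    ll <- sum(ifelse(n > 0, n * log(p), 0))
    expect_lte(ll, base_ll + 1e-12)
  }
})

test_that("BIC statistic compares cognitive and baseline models", {
  expect_equal(bic_statistic(-100, -100, 3, 3, 100), 0)
  expect_equal(bic_statistic(-100, -120, 3, 3, 77), 40)
  # unequal parameter counts restore the penalty term
  expect_equal(bic_statistic(-100, -120, 5, 3, 100), 40 - 2 * log(100))
  # a constant chooser is fit perfectly by the baseline, beating rEV
  sB <- igt_session("b", rep("B", 100), rep(100, 100), rep(0, 100))
  f <- ev_fit(sB, ev_control(n_grid = 2))
  expect_lt(f$bic_stat, 0)
})

test_that("fitting is deterministic and favours baseline on random choices", {
  set.seed(6)
  s <- random_session(100)
  f1 <- ev_fit(s, ev_control(n_grid = 2, seed = 1L))
  f2 <- ev_fit(s, ev_control(n_grid = 2, seed = 999L))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_true(f1$converged)
  # uniform-random data: consistency near zero, baseline not beaten
  expect_lt(coef(f1)[["c"]], 0.5)
  expect_lte(f1$bic_stat, 1e-6)
  expect_error(ev_fit(random_session(5)), "at least 10")
})

test_that("fitted optimum is never worse than the generating parameters", {
  set.seed(7)
  for (i in 1:5) {
    p <- ev_params(runif(1), runif(1), runif(1, 0, 5))
    s <- simulate_igt(p, n_trials = 80)
    f <- ev_fit(s, ev_control(n_grid = 2))
    expect_gte(f$loglik_model, ev_loglik(s, p, f$control) - 1e-6)
    expect_lte(f$loglik_model, 1e-12)
  }
})

test_that("attention weight is recovered from long loss-rich sessions", {
  # single-session w recovery at T = 500 from (w=.3, phi=.2, c=2):
  # median absolute error across seeds stays within 0.15
  errs <- vapply(1:10, function(seed) {
    s <- simulate_igt(ev_params(0.3, 0.2, 2), n_trials = 500, seed = seed)
    abs(coef(ev_fit(s, ev_control(n_grid = 3)))[["w"]] - 0.3)
  }, numeric(1))
  expect_lte(median(errs), 0.15)
})

test_that("generative simulation honours its contracts", {
  p <- ev_params(0.5, 0.5, 0)
  s <- simulate_igt(p, n_trials = 2000, seed = 8)
  freq <- as.numeric(deck_counts(s)) / 2000
  expect_true(all(abs(freq - 0.25) < 0.04))  # ~3 MC sd
  # loss-attentive consistent agents find the advantageous decks
  s2 <- simulate_igt(ev_params(0, 0.5, 3), n_trials = 100, seed = 9)
  expect_gt(net_score(s2, 41:100), 20)
  # reproducibility
  expect_identical(simulate_igt(p, n_trials = 50, seed = 11),
                   simulate_igt(p, n_trials = 50, seed = 11))
  # outcomes come from the cyclic deck program
  s3 <- simulate_igt(ev_params(0.4, 0.3, 1), n_trials = 200, seed = 12)
  replay <- play_sequence(s3$deck)
  expect_equal(s3$win, replay$win)
  expect_equal(s3$loss, replay$loss)
})

test_that("ev_fit methods expose the fitted model coherently", {
  s <- simulate_igt(ev_params(0.3, 0.4, 2), n_trials = 60, seed = 13)
  f <- ev_fit(s, ev_control(n_grid = 2))
  pr <- predict(f, "prob")
  expect_equal(dim(pr), c(60, 4))
  expect_equal(unname(rowSums(pr)), rep(1, 60), tolerance = 1e-10)
  expect_equal(pr[1, ], c(A = .25, B = .25, C = .25, D = .25))
  # likelihood reassembles from the predicted probabilities
  idx <- cbind(1:60, match(s$deck, c("A", "B", "C", "D")))
  expect_equal(sum(log(pmax(pr[idx], f$control$prob_floor))),
               f$loglik_model, tolerance = 1e-8)
  expect_equal(as.numeric(logLik(f)), f$loglik_model)
  expect_equal(attr(logLik(f), "nobs"), 60L)
  r <- residuals(f)
  expect_equal(r^2, -2 * log(pmax(pr[idx], f$control$prob_floor)),
               tolerance = 1e-10)
  sims <- simulate(f, nsim = 2, seed = 14)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 60)
  expect_output(print(summary(f)), "BIC statistic")
})

test_that("fit_sessions tabulates one row per subject", {
  set.seed(15)
  sess <- lapply(1:3, function(i) random_session(30, paste0("s", i)))
  tab <- fit_sessions(sess, ev_control(n_grid = 2))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$subject_id, c("s1", "s2", "s3"))
  expect_true(all(tab$loglik_model <= 0))
  expect_true(all(tab$loglik_baseline <= 0))
  expect_equal(tab$bic_stat,
               2 * (tab$loglik_model - tab$loglik_baseline))
})
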