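# Independent straight-line re-implementation of the three rEV equations,
# used as a brute-force oracle against the package's likelihood engine.
# Deliberately naive: named vectors, per-trial loop, no shared code.
oracle_loglik <- function(deck, win, loss, w, phi, cons,
                          variant = "pow3", floor = 1e-10) {
  E <- c(A = 0, B = 0, C = 0, D = 0)
  ll <- 0
  for (t in seq_along(deck)) {
    th <- if (variant == "pow3") 3^cons - 1 else (t / 10)^cons
    z <- th * E
    p <- exp(z - max(z))
    p <- p / sum(p)
    ll <- ll + log(max(p[[deck[t]]], floor))
    v <- w * win[t] - (1 - w) * loss[t]
    E[[deck[t]]] <- E[[deck[t]]] + phi * (v - E[[deck[t]]])
  }
  ll
}

# random short session with outcomes drawn from the real deck program
random_session <- function(n_trials, id = "r1") {
  play_sequence(sample(c("A", "B", "C", "D"), n_trials, replace = TRUE),
                subject_id = id)
}
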