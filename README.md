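# igtEV

Cognitive modelling of Iowa Gambling Task (IGT) behavior with the revised
Expectancy-Valence (rEV) learning model, embedded in a reproducible
longitudinal-analysis pipeline for adolescent smoking research.

## The problem

The IGT asks a participant to draw 100 cards from four decks. Decks A and B
pay $100 per card but lose $1250 per 10 cards (net −$250); decks C and D pay
$50 but lose only $250 per 10 cards (net +$250). Learning to prefer C/D is
the behavioral signature of intact affective decision-making, summarised by
the net score (C+D) − (A+B).

The rEV model decomposes that learning into three psychological processes.
On each trial *t* the chosen deck's outcome gets a subjective valence

  v(t) = w·win(t) − (1 − w)·loss(t),

where *w* ∈ [0, 1] is the attention weight to gains. The chosen deck *j*'s
expectancy is updated by the delta rule

  E_j(t) = E_j(t−1) + φ·[v(t) − E_j(t−1)],

with recency φ ∈ [0, 1], and the next choice follows a softmax (Luce) rule

  Pr[j] = exp(θ·E_j) / Σ_k exp(θ·E_k),  θ = 3^c − 1,

with consistency c ∈ [0, 5] (a trial-dependent θ(t) = (t/10)^c variant is
selectable). Each subject's (w, φ, c) is estimated by one-step-ahead maximum
likelihood and compared against a static baseline model (the subject's own
choice proportions) with a BIC statistic; positive values favour the
cognitive model.

Around that core the package provides: the deterministic deck payoff
engine, behavioral net-score metrics (overall and first-40 / last-60 trial
blocks), a calibrated synthetic two-wave cohort generator (covariates, T1/T2
current-smoker status and 7-level smoking quantity, true model parameters,
simulated sessions), and the downstream statistical stage — 2×2 chi-square
tests, pooled t-tests, two-block split-plot ANCOVA contrasts, and adjusted
logistic/linear models predicting follow-up smoking from the IGT measures.

## Worked example

```r
library(igtEV)

## simulate a loss-attentive, fairly consistent learner and refit it
s <- simulate_igt(ev_params(w = 0.25, phi = 0.3, c = 2),
                  n_trials = 100, seed = 42)
net_score(s)
#> [1] 76
block_net_scores(s)
#>   net_1_40 net_41_100
#>         16         60

fit <- ev_fit(s)
summary(fit)
#> Revised Expectancy-Valence model, one-step-ahead ML fit
#>  trials: 100   theta variant: pow3
#>  parameters:
#>      w    phi      c
#> 0.0064 0.9389 3.9269
#>  logLik rEV:      -3.17805
#>  logLik baseline: -74.597
#>  BIC statistic:   142.8 (cognitive model preferred)
#>  optimiser starts converged: 64 / 64
```

The simulated agent learned the advantageous decks (positive net scores,
rising across blocks). The fitted model predicts its choices far better than
the static baseline (BIC statistic +142.8). Note the fitted w is much lower
than the generating 0.25: once a consistent agent locks onto one deck, the
likelihood is flat over a range of w values (the parameter is
set-identified), a behaviour quantified by `recovery_experiment()` and
discussed in the methods vignette.

```r
## a full synthetic cohort and the published-table chi-square
coh <- generate_cohort(cohort_config(), seed = 20160901)
coh
#> Synthetic IGT cohort: 181 subjects with 100-trial sessions
#>  current smokers: T1 14 (7.7%), T2 22 (12.2%), both 6

chisq_2x2(matrix(c(153, 11, 6, 11), 2))
#> Pearson chi-square (no continuity correction)
#>  statistic = 48.53, df = 1, p = 3.257e-12
```

`run_pipeline(run_config())` chains generation → per-subject fitting →
metrics → the full statistical stage, writes all tables, and is
byte-reproducible under a fixed seed. A thin command-line wrapper lives at
`inst/cli/igtev.R` (subcommands `decks`, `cohort`, `fit`, `metrics`,
`analyze`, `run`, `recover`).

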