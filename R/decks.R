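#' Standard IGT deck payoff schedules
#'
#' Constructs the four-deck payoff program of the computerised Iowa Gambling
#' Task. Decks A and B pay $100 per card, decks C and D pay $50; every block
#' of 10 cards loses $1250 in total from A and B but only $250 from C and D,
#' so A/B net \eqn{-250} and C/D net \eqn{+250} per 10 cards. Within A and C
#' the punishments are frequent and small (5 per 10 cards); within B and D a
#' single large punishment occurs per 10 cards. Losses are applied cyclically
#' by within-deck draw position and stored as positive magnitudes.
#'
#' @return A named list of four deck schedules (classes `"deck_schedule"`),
#'   each with elements `label`, `gain` and `losses` (length-10 loss cycle).
#' @examples
#' decks <- igt_decks()
#' decks$A$gain              # 100
#' sum(decks$B$losses)       # 1250
#' @export
igt_decks <- function() {
  sched <- function(label, gain, losses) {
    stopifnot(length(losses) == 10, all(losses >= 0), gain >= 0)
    structure(list(label = label, gain = gain, losses = losses),
              class = "deck_schedule")
  }
  list(
    A = sched("A", 100, c(0, 0, 150, 0, 300, 0, 200, 0, 250, 350)),
    B = sched("B", 100, c(0, 0, 0, 0, 0, 0, 0, 0, 1250, 0)),
    C = sched("C", 50, c(0, 0, 50, 0, 50, 0, 50, 0, 50, 50)),
    D = sched("D", 50, c(0, 0, 0, 0, 0, 0, 0, 0, 0, 250))
  )
}

#' Outcome of drawing a card from a deck
#'
#' Pure lookup into a deck's payoff program: the win is the deck's fixed gain
#' per card and the loss is the entry of the 10-card loss cycle at the given
#' within-deck draw position (1-based count of draws from that deck).
#'
#' @param schedule A `"deck_schedule"` from [igt_decks()] (or a compatible
#'   list with `gain` and a length-10 `losses` cycle).
#' @param position Within-deck draw position, integer \eqn{\ge 1}.
#' @return List with components `win` and `loss` (both nonnegative; the loss
#'   is a positive magnitude).
#' @examples
#' card_outcome(igt_decks()$C, 1)   # win 50, loss 0
#' @export
card_outcome <- function(schedule, position) {
  if (!is.numeric(position) || length(position) != 1L || position < 1 ||
      position != round(position)) {
    stop("'position' must be a single integer >= 1")
  }
  idx <- ((position - 1) %% 10) + 1
  list(win = schedule$gain, loss = schedule$losses[idx])
}

#' Construct an IGT session
#'
#' Bundles one subject's ordered trial sequence (deck choice plus win/loss
#' outcome per trial) with the task bookkeeping defaults: 100 trials and a
#' $2000 starting loan of play money.
#'
#' @param subject_id Subject identifier (scalar).
#' @param deck Character vector of deck choices, values in `A`,`B`,`C`,`D`.
#' @param win,loss Numeric vectors of per-trial win and loss magnitudes
#'   (losses positive).
#' @param starting_cash Starting account balance; default 2000.
#' @return An object of class `"igt_session"`: a data frame with columns
#'   `trial`, `deck`, `win`, `loss` and attributes `subject_id`,
#'   `starting_cash`.
#' @export
igt_session <- function(subject_id, deck, win, loss, starting_cash = 2000) {
  n <- length(deck)
  if (length(win) != n || length(loss) != n)
    stop("'deck', 'win' and 'loss' must have equal length")
  deck <- as.character(deck)
  bad <- !deck %in% c("A", "B", "C", "D")
  if (any(bad))
    stop("invalid deck label(s): ", paste(unique(deck[bad]), collapse = ", "))
  if (any(loss < 0) || any(win < 0))
    stop("wins and losses must be nonnegative magnitudes")
  structure(
    data.frame(trial = seq_len(n), deck = deck, win = as.numeric(win),
               loss = as.numeric(loss), stringsAsFactors = FALSE),
    subject_id = as.character(subject_id),
    starting_cash = starting_cash,
    class = c("igt_session", "data.frame")
  )
}

#' @export
print.igt_session <- function(x, ...) {
  cat("IGT session: subject", attr(x, "subject_id"), "-", nrow(x),
      "trials, final cash", session_net_cash(x), "\n")
  print.data.frame(head(as.data.frame(x), 5L), ...)
  if (nrow(x) > 5L) cat("...", nrow(x) - 5L, "more trials\n")
  invisible(x)
}

#' Final account balance of a session
#'
#' @param session An [igt_session()].
#' @return `starting_cash + sum(win - loss)`.
#' @export
session_net_cash <- function(session) {
  start <- attr(session, "starting_cash")
  if (is.null(start)) start <- 2000
  start + sum(session$win) - sum(session$loss)
}

#' Replay a fixed choice sequence against the deck program
#'
#' Deterministically generates the outcomes a subject would experience when
#' choosing the given deck sequence, tracking each deck's within-deck draw
#' position.
#'
#' @param deck Character vector of deck choices.
#' @param decks Deck schedules, default [igt_decks()].
#' @inheritParams igt_session
#' @return An [igt_session()].
#' @export
play_sequence <- function(deck, decks = igt_decks(), subject_id = "s1",
                          starting_cash = 2000) {
  deck <- as.character(deck)
  pos <- c(A = 0L, B = 0L, C = 0L, D = 0L)
  win <- loss <- numeric(length(deck))
  for (t in seq_along(deck)) {
    d <- deck[t]
    if (!d %in% names(pos)) stop("invalid deck label: ", d)
    pos[d] <- pos[d] + 1L
    out <- card_outcome(decks[[d]], pos[d])
    win[t] <- out$win
    loss[t] <- out$loss
  }
  igt_session(subject_id, deck, win, loss, starting_cash = starting_cash)
}

#' Read and write deck programs as JSON
#'
#' Deck programs are exchanged as `{label: {gain: int, losses: [10 ints]}}`.
#' Any program satisfying the schedule invariants (length-10 nonnegative loss
#' cycle) can be loaded, so non-standard payoff variants are supported.
#'
#' @param decks Named list of deck schedules.
#' @param path File path.
#' @return `read_decks_json` returns a named list of `"deck_schedule"`
#'   objects; `write_decks_json` returns `path` invisibly.
#' @export
write_decks_json <- function(decks, path) {
  obj <- lapply(decks, function(d) list(gain = d$gain, losses = d$losses))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decks_json
#' @export
read_decks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(obj), function(lab) {
    d <- obj[[lab]]
    if (length(d$losses) != 10 || any(d$losses < 0) || d$gain < 0)
      stop("invalid deck program for deck ", lab)
    structure(list(label = lab, gain = d$gain, losses = as.numeric(d$losses)),
              class = "deck_schedule")
  })
  names(out) <- names(obj)
  out
}

#' Read and write IGT sessions as CSV
#'
#' Sessions are stored in long form with columns `subject_id, trial, deck,
#' win, loss` (header required; trials 1..T per subject with no gaps).
#' Malformed rows are rejected with their line numbers.
#'
#' @param sessions A list of [igt_session()] objects.
#' @param path File path.
#' @return `read_sessions_csv` returns a named list of sessions;
#'   `write_sessions_csv` returns `path` invisibly.
#' @export
write_sessions_csv <- function(sessions, path) {
  tabs <- lapply(sessions, function(s) {
    data.frame(subject_id = attr(s, "subject_id"), trial = s$trial,
               deck = s$deck, win = s$win, loss = s$loss,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "deck", "win", "loss")
  if (!all(need %in% names(tab)))
    stop("session file must have columns: ", paste(need, collapse = ", "))
  # line number in file = data row index + 1 (header)
  bad_deck <- which(!tab$deck %in% c("A", "B", "C", "D"))
  if (length(bad_deck))
    stop("invalid deck label '", tab$deck[bad_deck[1]], "' at line ",
         bad_deck[1] + 1L)
  out <- lapply(split(seq_len(nrow(tab)), tab$subject_id), function(idx) {
    rows <- tab[idx, ]
    if (!identical(as.integer(rows$trial), seq_len(nrow(rows)))) {
      gap <- which(as.integer(rows$trial) != seq_len(nrow(rows)))[1]
      stop("subject ", rows$subject_id[1], ": trial indices must be 1..T ",
           "with no gaps (line ", idx[gap] + 1L, ", trial ",
           rows$trial[gap], ")")
    }
    igt_session(rows$subject_id[1], rows$deck, rows$win, rows$loss)
  })
  # preserve file order of first appearance
  out[unique(tab$subject_id)]
}
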