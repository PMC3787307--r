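#' Per-deck selection counts over a trial range
#'
#' @param session An [igt_session()].
#' @param range Integer vector of trial indices (default all trials); must be
#'   nonempty and within 1..T.
#' @return Named integer vector `c(A=, B=, C=, D=)` summing to
#'   `length(range)`.
#' @export
deck_counts <- function(session, range = seq_len(nrow(session))) {
  if (length(range) == 0L) stop("trial range must be nonempty")
  if (any(range < 1) || any(range > nrow(session)))
    stop("trial range must lie within 1..", nrow(session))
  setNames(tabulate(deck_index(session$deck[range]), nbins = 4L),
           c("A", "B", "C", "D"))
}

#' IGT net score over a trial range
#'
#' Number of advantageous selections minus disadvantageous selections,
#' \eqn{(n_C + n_D) - (n_A + n_B)}; positive values indicate advantageous
#' choosing.
#'
#' @inheritParams deck_counts
#' @return Integer net score, bounded by the range length in magnitude.
#' @export
net_score <- function(session, range = seq_len(nrow(session))) {
  n <- deck_counts(session, range)
  unname((n["C"] + n["D"]) - (n["A"] + n["B"]))
}

#' Net scores per trial block
#'
#' Applies [net_score()] to a partition of the session into blocks. The
#' default split at trial 40 mirrors the contrast between decision-making
#' under ambiguity (early trials, contingencies unknown) and under risk
#' (later trials).
#'
#' @param session An [igt_session()].
#' @param blocks List of integer trial ranges partitioning 1..T without
#'   overlap; default `list(1:40, 41:T)`.
#' @return Named numeric vector of per-block net scores.
#' @export
block_net_scores <- function(session, blocks = NULL) {
  T <- nrow(session)
  if (is.null(blocks)) {
    if (T < 41L) stop("default blocks require at least 41 trials")
    blocks <- list(seq_len(40L), seq.int(41L, T))
  }
  all_idx <- sort(unlist(blocks))
  if (anyDuplicated(all_idx)) stop("blocks must not overlap")
  if (!identical(as.integer(all_idx), seq_len(T)))
    stop("blocks must partition trials 1..", T)
  out <- vapply(blocks, function(b) net_score(session, b), numeric(1))
  names(out) <- vapply(blocks, function(b)
    paste0("net_", min(b), "_", max(b)), character(1))
  out
}

#' Behavioral metrics table for a set of sessions
#'
#' @param sessions List of [igt_session()] objects (100 trials each for the
#'   default block split).
#' @param split Trial index ending the first block; default 40.
#' @return Data frame with columns `subject_id`, `n_A`..`n_D`, `net_total`,
#'   and the two block net scores.
#' @export
igt_metrics <- function(sessions, split = 40L) {
  rows <- lapply(sessions, function(s) {
    n <- deck_counts(s)
    T <- nrow(s)
    blocks <- list(seq_len(split), seq.int(split + 1L, T))
    bn <- vapply(blocks, function(b) net_score(s, b), numeric(1))
    data.frame(subject_id = attr(s, "subject_id"),
               n_A = n[["A"]], n_B = n[["B"]], n_C = n[["C"]], n_D = n[["D"]],
               net_total = net_score(s),
               net_first = bn[1], net_last = bn[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
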