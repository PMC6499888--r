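#' Detection response window
#'
#' A repetition sequence counts as detected when there is one and only one
#' button press in the interval from `start_offset_ms` to `end_offset_ms`
#' after the onset of the target's second presentation (the first
#' repetition); that onset defines reaction time zero.
#'
#' @param start_offset_ms,end_offset_ms Window bounds in ms after
#'   second-presentation onset.
#' @return An object of class `"detection_window"`.
#' @examples
#' detection_window()
#' @export
detection_window <- function(start_offset_ms = 200, end_offset_ms = 2500) {
  if (!(0 < start_offset_ms && start_offset_ms < end_offset_ms)) {
    stopf("window requires 0 < start < end")
  }
  structure(list(start_offset_ms = start_offset_ms,
                 end_offset_ms = end_offset_ms),
            class = "detection_window")
}

press_times <- function(presses) {
  if (is.numeric(presses)) return(as.numeric(presses))
  if (is.data.frame(presses) && "time_ms" %in% names(presses)) {
    return(as.numeric(presses$time_ms))
  }
  stopf("presses must be a numeric vector or a data frame with a time_ms column")
}

# Core window scorer.  t2: second-presentation onsets; p: sorted press times.
# A press falling inside several windows is assigned to the sequence whose
# window opens earliest (unique assignment, no double counting).
score_windows <- function(t2, p, start, end) {
  n_seq <- length(t2)
  n_in <- integer(n_seq)
  rt <- rep(NA_real_, n_seq)
  if (length(p) > 0L) {
    ord <- order(t2)
    t2o <- t2[ord]
    inw <- outer(p, t2o, function(pp, tt) pp > tt + start & pp < tt + end)
    has <- rowSums(inw) > 0
    first <- max.col(inw, ties.method = "first")  # earliest window containing the press
    assigned <- ifelse(has, ord[first], NA_integer_)
    n_in <- tabulate(assigned, nbins = n_seq)
    one <- which(n_in == 1L)
    for (i in one) rt[i] <- p[which(assigned == i)] - t2[i]
  }
  list(n_in = n_in, detected = n_in == 1L, rt = rt)
}

#' Score one block with the detection-window rule
#'
#' Applies the one-and-only-one-press rule to every repetition sequence of
#' a stream: a sequence is detected iff exactly one press falls strictly
#' inside its response window; its reaction time is that press time minus
#' the second-presentation onset.  A press that falls inside the windows of
#' two sequences (possible only when windows overlap) is assigned to the
#' earlier sequence only.
#'
#' @param schedule A `"stream_schedule"`.
#' @param presses Sorted press times (numeric vector, ms) or a press-log
#'   data frame with a `time_ms` column.
#' @param window A [detection_window()].
#'
#' @return Data frame with one row per sequence: `sequence_id`,
#'   `cond_group`, `detected`, `rt_ms` (NA unless detected),
#'   `n_in_window`.
#' @examples
#' conds <- c(lapply(1:5, regular_condition), enumerate_irregular_orders()[1:15])
#' s <- build_stream(conds, seed = 1)
#' t2 <- s$sequences[[1]]$onset_times[2]
#' score_block(s, t2 + 500)[1, ]
#' @export
score_block <- function(schedule, presses, window = detection_window()) {
  stopifnot(inherits(schedule, "stream_schedule"),
            inherits(window, "detection_window"))
  p <- press_times(presses)
  if (is.unsorted(p)) stopf("press log must be sorted by time")
  t2 <- vapply(schedule$sequences, function(s) s$onset_times[2L], 0)
  res <- score_windows(t2, p, window$start_offset_ms, window$end_offset_ms)
  data.frame(
    sequence_id = vapply(schedule$sequences, function(s) s$sequence_id, 0L),
    cond_group = vapply(schedule$sequences, condition_group, ""),
    detected = res$detected,
    rt_ms = res$rt,
    n_in_window = res$n_in,
    stringsAsFactors = FALSE
  )
}

#' Score every block of a session
#'
#' @param design A [build_session()] design.
#' @param presses Press-log data frame covering the session (`block`,
#'   `time_ms` columns; e.g. from [simulate_session()]).
#' @param window A [detection_window()].
#' @return Data frame: `participant`, `block`, `sequence_id`,
#'   `cond_group`, `detected`, `rt_ms`, `n_in_window`.
#' @export
score_session <- function(design, presses, window = detection_window()) {
  stopifnot(inherits(design, "session_design"), is.data.frame(presses))
  out <- lapply(design$blocks, function(blk) {
    p <- presses$time_ms[presses$block == blk$block_id]
    sc <- score_block(blk, sort(p), window)
    cbind(data.frame(participant = design$participant_id,
                     block = blk$block_id, stringsAsFactors = FALSE), sc)
  })
  do.call(rbind, out)
}

#' Scramble a press log
#'
#' Replaces the press times with i.i.d. uniform timestamps on
#' `[0, t_max]`, keeping the press count; this is the chance-level null for
#' the detection analysis.
#'
#' @param presses Press times (numeric vector or press-log data frame).
#' @param t_max Upper end of the scramble domain, ms.
#' @param seed Integer seed.
#' @return Sorted numeric vector of scrambled times (or, for a data-frame
#'   input, the same data frame with scrambled, sorted `time_ms`).
#' @export
scramble_log <- function(presses, t_max, seed = NULL) {
  if (t_max <= 0) stopf("t_max must be positive")
  p <- press_times(presses)
  new_t <- with_seed(seed, sort(stats::runif(length(p), 0, t_max)))
  if (is.data.frame(presses)) {
    presses$time_ms <- new_t
    presses
  } else {
    new_t
  }
}

# Scramble domain: the window of the final sequence must be reachable.
scramble_horizon <- function(schedule, window = detection_window()) {
  stream_end_ms(schedule) + window$end_offset_ms
}

#' Scrambled-timestamp chance level for one block
#'
#' Re-scores the block after replacing the press times with uniform random
#' timestamps (press count preserved), giving the detection rate expected
#' by chance.  `n_scrambles = 1` mirrors the single-scramble procedure;
#' larger values average over repeated scrambles to reduce Monte-Carlo
#' noise.
#'
#' @param schedule A `"stream_schedule"`.
#' @param presses Press times for the block.
#' @param window A [detection_window()].
#' @param n_scrambles Number of independent scrambles to average over.
#' @param seed Integer seed.
#' @return Data frame: `cond_group`, `chance_rate`, `n_trials` (sequences
#'   per group in this block).
#' @export
chance_level <- function(schedule, presses, window = detection_window(),
                         n_scrambles = 1L, seed = NULL) {
  stopifnot(inherits(schedule, "stream_schedule"), n_scrambles >= 1L)
  p <- press_times(presses)
  groups <- vapply(schedule$sequences, condition_group, "")
  t2 <- vapply(schedule$sequences, function(s) s$onset_times[2L], 0)
  t_max <- scramble_horizon(schedule, window)
  det <- with_seed(seed, {
    acc <- numeric(length(t2))
    for (k in seq_len(n_scrambles)) {
      sc <- sort(stats::runif(length(p), 0, t_max))
      acc <- acc + score_windows(t2, sc, window$start_offset_ms,
                                 window$end_offset_ms)$detected
    }
    acc / n_scrambles
  })
  agg <- tapply(det, groups, mean)
  n <- tapply(det, groups, length)
  data.frame(cond_group = names(agg),
             chance_rate = as.numeric(agg),
             n_trials = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scrambled-timestamp chance level for a whole session
#'
#' Applies [chance_level()]'s scrambling block by block (each block's press
#' count and duration are its own) and pools trials across blocks, giving
#' one chance rate per condition group.
#'
#' @inheritParams score_session
#' @param n_scrambles Scrambles per block.
#' @param seed Integer seed.
#' @return Data frame: `cond_group`, `chance_rate`, `n_trials`.
#' @export
chance_session <- function(design, presses, window = detection_window(),
                           n_scrambles = 1L, seed = NULL) {
  stopifnot(inherits(design, "session_design"))
  sub <- with_seed(seed, sample.int(2147483646L, length(design$blocks)))
  per_block <- lapply(seq_along(design$blocks), function(b) {
    blk <- design$blocks[[b]]
    p <- presses$time_ms[presses$block == blk$block_id]
    cl <- chance_level(blk, sort(p), window, n_scrambles, seed = sub[b])
    cl$sum_rate <- cl$chance_rate * cl$n_trials
    cl
  })
  all <- do.call(rbind, per_block)
  rate <- tapply(all$sum_rate, all$cond_group, sum) /
    tapply(all$n_trials, all$cond_group, sum)
  data.frame(cond_group = names(rate),
             chance_rate = as.numeric(rate),
             n_trials = as.integer(tapply(all$n_trials, all$cond_group, sum)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-condition detection summary
#'
#' Aggregates a (possibly multi-participant) score table into one row per
#' condition group: detection rate, mean RT of detected trials, trial
#' count, and -- when a chance table is supplied -- the scrambled chance
#' rate and the percentage-point difference
#' `100 * (detection_rate - chance_rate)`, the chance-corrected performance
#' measure.  With several participants, means are taken per participant
#' first and then averaged across participants.
#'
#' @param scores Score table from [score_block()] or [score_session()].
#' @param chance Optional chance table from [chance_level()] /
#'   [chance_session()] (multi-participant chance tables can be stacked
#'   with an extra `participant` column).
#' @return Data frame: `cond_group`, `detection_rate`, `mean_rt_ms`,
#'   `n_trials`, and `chance_rate`, `pp_difference` when `chance` is given.
#' @export
summarize_detection <- function(scores, chance = NULL) {
  if (!"participant" %in% names(scores)) scores$participant <- 1L
  key <- interaction(scores$participant, scores$cond_group, drop = TRUE)
  per <- data.frame(
    participant = tapply(scores$participant, key, `[`, 1L),
    cond_group = tapply(as.character(scores$cond_group), key, `[`, 1L),
    rate = as.numeric(tapply(scores$detected, key, mean)),
    rt = as.numeric(tapply(scores$rt_ms, key, function(x) mean(x, na.rm = TRUE))),
    n = as.integer(tapply(scores$detected, key, length)),
    stringsAsFactors = FALSE
  )
  out <- data.frame(
    cond_group = sort(unique(per$cond_group)),
    stringsAsFactors = FALSE
  )
  out$detection_rate <- as.numeric(tapply(per$rate, per$cond_group, mean)[out$cond_group])
  out$mean_rt_ms <- as.numeric(tapply(per$rt, per$cond_group,
                                      function(x) mean(x, na.rm = TRUE))[out$cond_group])
  out$n_trials <- as.integer(tapply(per$n, per$cond_group, sum)[out$cond_group])
  if (!is.null(chance)) {
    if ("participant" %in% names(chance)) {
      ch <- tapply(chance$chance_rate, chance$cond_group, mean)
    } else {
      ch <- stats::setNames(chance$chance_rate, chance$cond_group)
    }
    out$chance_rate <- as.numeric(ch[out$cond_group])
    out$pp_difference <- 100 * (out$detection_rate - out$chance_rate)
  }
  out
}
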