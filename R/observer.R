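#' Generative parameters of the synthetic observer
#'
#' The synthetic observer emits, for each repetition sequence, at most one
#' genuine detection press: with probability `hit_prob[group]` a press is
#' placed at the onset of the target's second presentation plus a reaction
#' time drawn from a shifted lognormal truncated to (200, 2500) ms.  A
#' detected sequence additionally receives a second in-window press with
#' probability `extra_press_prob` (which, under the one-and-only-one-press
#' scoring rule, turns the detection into a miss).  False alarms follow a
#' homogeneous Poisson process at `fa_rate` presses per second over the
#' stream plus the final response window.  The 4AFC memory response is
#' correct with probability `mem_acc[group]`, otherwise a uniformly chosen
#' foil; confidence (0..4) is drawn from `conf_given_correct` or
#' `conf_given_error`.
#'
#' Condition groups are `"R1"`..`"R5"` (regular, by distractor count) and
#' `"I1"`..`"I5"` (irregular, by the number of distractors before the first
#' repetition).  The default hit probabilities decrease with distractor
#' count, and the defaults jointly calibrate the press stream to about 13.4
#' presses per block with about 2% of sequences receiving more than one
#' in-window response (see the package vignette for the arithmetic).
#'
#' @param hit_prob Named numeric vector over the 10 condition groups:
#'   probability of emitting a detection press for a sequence.
#' @param rt_shift_ms,rt_meanlog,rt_sdlog Shifted-lognormal reaction-time
#'   law (ms), measured from second-presentation onset and truncated to
#'   (200, 2500) ms.
#' @param extra_press_prob Probability that a detected sequence gets a
#'   second press inside its response window.
#' @param fa_rate False-alarm presses per second.
#' @param mem_acc Named numeric vector over condition groups: probability
#'   of a correct 4AFC identification (chance = 0.25).
#' @param mem_rt_shift_ms,mem_rt_meanlog,mem_rt_sdlog Shifted-lognormal law
#'   for memory-response times (ms).
#' @param conf_given_correct,conf_given_error Probability vectors of length
#'   5 over confidence ratings 0..4.
#' @param recency_slope Logit-scale change in memory accuracy per stream
#'   position (0 = no serial-position effect); used to inject a recency
#'   effect when exercising the delay-split analysis.
#'
#' @return An object of class `"observer_params"`.
#' @examples
#' p <- observer_params()
#' p$hit_prob["R1"] > p$hit_prob["R5"]
#' @export
observer_params <- function(
    hit_prob = c(R1 = 0.80, R2 = 0.70, R3 = 0.62, R4 = 0.55, R5 = 0.48,
                 I1 = 0.72, I2 = 0.66, I3 = 0.62, I4 = 0.58, I5 = 0.54),
    rt_shift_ms = 300, rt_meanlog = log(600), rt_sdlog = 0.5,
    extra_press_prob = 0.02,
    fa_rate = 0.0067,
    mem_acc = c(R1 = 0.80, R2 = 0.72, R3 = 0.66, R4 = 0.60, R5 = 0.55,
                I1 = 0.72, I2 = 0.68, I3 = 0.66, I4 = 0.63, I5 = 0.60),
    mem_rt_shift_ms = 500, mem_rt_meanlog = log(1300), mem_rt_sdlog = 0.45,
    conf_given_correct = c(0.05, 0.10, 0.20, 0.30, 0.35),
    conf_given_error = c(0.30, 0.30, 0.25, 0.10, 0.05),
    recency_slope = 0) {
  groups <- condition_groups()
  check_prob_map <- function(x, nm) {
    if (!all(groups %in% names(x))) {
      stopf("%s must be named with all condition groups %s", nm,
            paste(groups, collapse = ", "))
    }
    if (any(x < 0 | x > 1)) stopf("%s values must lie in [0, 1]", nm)
    x[groups]
  }
  hit_prob <- check_prob_map(hit_prob, "hit_prob")
  mem_acc <- check_prob_map(mem_acc, "mem_acc")
  if (extra_press_prob < 0 || extra_press_prob > 1) {
    stopf("extra_press_prob must lie in [0, 1]")
  }
  if (fa_rate < 0) stopf("fa_rate must be non-negative")
  check_conf <- function(x, nm) {
    if (length(x) != 5L || any(x < 0) || abs(sum(x) - 1) > 1e-8) {
      stopf("%s must be a length-5 probability vector over ratings 0..4", nm)
    }
    x
  }
  conf_given_correct <- check_conf(conf_given_correct, "conf_given_correct")
  conf_given_error <- check_conf(conf_given_error, "conf_given_error")
  if (rt_sdlog <= 0 || mem_rt_sdlog <= 0) stopf("lognormal sdlog must be positive")

  structure(
    list(
      hit_prob = hit_prob,
      rt_shift_ms = rt_shift_ms, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
      extra_press_prob = extra_press_prob,
      fa_rate = fa_rate,
      mem_acc = mem_acc,
      mem_rt_shift_ms = mem_rt_shift_ms, mem_rt_meanlog = mem_rt_meanlog,
      mem_rt_sdlog = mem_rt_sdlog,
      conf_given_correct = conf_given_correct,
      conf_given_error = conf_given_error,
      recency_slope = recency_slope
    ),
    class = "observer_params"
  )
}

condition_groups <- function() c(paste0("R", 1:5), paste0("I", 1:5))

#' @export
print.observer_params <- function(x, ...) {
  cat("synthetic observer parameters\n")
  cat("  hit_prob: ", paste(sprintf("%s=%.2f", names(x$hit_prob), x$hit_prob),
                            collapse = " "), "\n", sep = "")
  cat(sprintf("  RT: %g + lognormal(meanlog %.3f, sdlog %.2f) ms, truncated (200, 2500)\n",
              x$rt_shift_ms, x$rt_meanlog, x$rt_sdlog))
  cat(sprintf("  extra_press_prob %.3f, fa_rate %.4f /s\n",
              x$extra_press_prob, x$fa_rate))
  cat("  mem_acc:  ", paste(sprintf("%s=%.2f", names(x$mem_acc), x$mem_acc),
                            collapse = " "), "\n", sep = "")
  invisible(x)
}

# shifted lognormal truncated to (lo, hi), sampled by inverse CDF
rtrunc_shifted_lnorm <- function(n, shift, meanlog, sdlog, lo = 200, hi = 2500) {
  if (n == 0L) return(numeric(0))
  a <- stats::plnorm(max(lo - shift, 0), meanlog, sdlog)
  b <- stats::plnorm(hi - shift, meanlog, sdlog)
  shift + stats::qlnorm(stats::runif(n, a, b), meanlog, sdlog)
}

#' Simulate button presses for one stream
#'
#' For each repetition sequence, with probability `hit_prob` of its
#' condition group, one press is placed at the second-presentation onset
#' plus a truncated shifted-lognormal reaction time; with probability
#' `extra_press_prob` a detected sequence gets a second in-window press.
#' False alarms are a homogeneous Poisson process over
#' `[0, stream end + 2500 ms]` (presses may come after the stream has
#' finished).  Output times are sorted.
#'
#' @param schedule A `"stream_schedule"`.
#' @param params An [observer_params()].
#' @param seed Integer seed for reproducibility.
#' @param participant Participant id recorded in the log.
#'
#' @return A data frame of class `"press_log"` with columns `participant`,
#'   `block`, `time_ms`.
#' @examples
#' conds <- c(lapply(1:5, regular_condition), enumerate_irregular_orders()[1:15])
#' s <- build_stream(conds, seed = 1)
#' log <- simulate_presses(s, observer_params(), seed = 2)
#' @export
simulate_presses <- function(schedule, params = observer_params(), seed = NULL,
                             participant = NA) {
  stopifnot(inherits(schedule, "stream_schedule"),
            inherits(params, "observer_params"))
  times <- with_seed(seed, {
    groups <- vapply(schedule$sequences, condition_group, "")
    t2 <- vapply(schedule$sequences, function(s) s$onset_times[2L], 0)
    n_seq <- length(t2)
    hit <- stats::runif(n_seq) < params$hit_prob[groups]
    rt1 <- rtrunc_shifted_lnorm(sum(hit), params$rt_shift_ms,
                                params$rt_meanlog, params$rt_sdlog)
    first <- t2[hit] + rt1
    extra <- hit & stats::runif(n_seq) < params$extra_press_prob
    rt2 <- rtrunc_shifted_lnorm(sum(extra), params$rt_shift_ms,
                                params$rt_meanlog, params$rt_sdlog)
    second <- t2[extra] + rt2
    horizon <- stream_end_ms(schedule) + 2500
    n_fa <- stats::rpois(1L, params$fa_rate * horizon / 1000)
    fa <- stats::runif(n_fa, 0, horizon)
    sort(c(first, second, fa))
  })
  structure(
    data.frame(participant = if (length(times)) participant else participant[0],
               block = rep(schedule$block_id, length(times)),
               time_ms = times, stringsAsFactors = FALSE),
    class = c("press_log", "data.frame")
  )
}

#' Simulate 4AFC memory responses for one stream
#'
#' Probes the 20 targets of a stream in a fresh random order.  Each probe
#' offers the target and three foils: never-repeated distractor images from
#' the same stream, sampled without replacement and disjoint across the 20
#' probes.  The choice is correct with probability `mem_acc` of the
#' sequence's condition group (optionally tilted by `recency_slope` on the
#' logit scale as a function of stream position), otherwise a uniformly
#' chosen foil.  Confidence is drawn from the conditional distribution
#' matching correctness.
#'
#' @param schedule A `"stream_schedule"`.
#' @param detected_flags Optional logical vector, one flag per sequence
#'   (e.g. the `detected` column of [score_block()]); recorded in the
#'   output but not used by the generative model.
#' @param params An [observer_params()].
#' @param seed Integer seed.
#' @param participant Participant id recorded in the output.
#'
#' @return A data frame with columns `participant`, `block`, `probe_pos`,
#'   `stream_pos`, `target_id`, `foil1`, `foil2`, `foil3`, `choice_id`,
#'   `rt_ms`, `confidence` and (if supplied) `detected`.
#' @export
simulate_memory <- function(schedule, detected_flags = NULL,
                            params = observer_params(), seed = NULL,
                            participant = NA) {
  stopifnot(inherits(schedule, "stream_schedule"),
            inherits(params, "observer_params"))
  n_seq <- length(schedule$sequences)
  if (!is.null(detected_flags) && length(detected_flags) != n_seq) {
    stopf("detected_flags must have one flag per sequence (%d)", n_seq)
  }
  with_seed(seed, {
    groups <- vapply(schedule$sequences, condition_group, "")
    targets <- vapply(schedule$sequences, function(s) s$target_image, 0L)
    acc <- unname(params$mem_acc[groups])
    if (params$recency_slope != 0) {
      p <- pmin(pmax(acc, 1e-6), 1 - 1e-6)
      acc <- stats::plogis(stats::qlogis(p) +
                             params$recency_slope * (seq_len(n_seq) - (n_seq + 1) / 2))
    }
    stream_order <- sample.int(n_seq)             # stream position probed at each probe
    pool <- schedule$events$image_id[schedule$events$role == "distractor"]
    foils <- matrix(sample(pool, 3L * n_seq), nrow = n_seq)  # disjoint across probes

    i <- stream_order                              # per-probe stream position
    correct <- stats::runif(n_seq) < acc[i]
    pick <- sample.int(3L, n_seq, replace = TRUE)
    choice <- ifelse(correct, targets[i], foils[cbind(seq_len(n_seq), pick)])
    rt <- params$mem_rt_shift_ms +
      stats::rlnorm(n_seq, params$mem_rt_meanlog, params$mem_rt_sdlog)
    conf <- integer(n_seq)
    n_corr <- sum(correct)
    conf[correct] <- sample(0:4, n_corr, replace = TRUE,
                            prob = params$conf_given_correct)
    conf[!correct] <- sample(0:4, n_seq - n_corr, replace = TRUE,
                             prob = params$conf_given_error)

    out <- data.frame(
      participant = participant,
      block = schedule$block_id,
      probe_pos = seq_len(n_seq),
      stream_pos = i,
      target_id = targets[i],
      foil1 = foils[, 1L], foil2 = foils[, 2L], foil3 = foils[, 3L],
      choice_id = choice,
      rt_ms = rt,
      confidence = conf,
      stringsAsFactors = FALSE
    )
    if (!is.null(detected_flags)) out$detected <- detected_flags[i]
    out
  })
}

#' Simulate a full session of presses and memory responses
#'
#' Convenience wrapper: simulates presses for every block of a session
#' design, scores them with the detection-window rule to obtain
#' per-sequence detection flags, and simulates the memory task.
#'
#' @param design A [build_session()] design.
#' @param params An [observer_params()].
#' @param seed Integer seed (per-block sub-seeds are derived from it).
#' @param window A [detection_window()] used for the detection flags passed
#'   to the memory simulator.
#'
#' @return A list with `presses` (press-log data frame over all blocks),
#'   `memory` (memory-response data frame) and `scores` (session score
#'   table from [score_session()]).
#' @export
simulate_session <- function(design, params = observer_params(), seed = NULL,
                             window = detection_window()) {
  stopifnot(inherits(design, "session_design"))
  n_blocks <- length(design$blocks)
  sub <- with_seed(seed, sample.int(2147483646L, 2L * n_blocks))
  presses <- vector("list", n_blocks)
  memory <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    blk <- design$blocks[[b]]
    presses[[b]] <- simulate_presses(blk, params, seed = sub[2L * b - 1L],
                                     participant = design$participant_id)
    sc <- score_block(blk, presses[[b]], window)
    memory[[b]] <- simulate_memory(blk, detected_flags = sc$detected,
                                   params = params, seed = sub[2L * b],
                                   participant = design$participant_id)
  }
  presses <- do.call(rbind, presses)
  scores <- score_session(design, presses, window)
  list(presses = presses, memory = do.call(rbind, memory), scores = scores)
}
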