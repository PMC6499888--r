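# 4AFC memory-task scoring and the stream-to-probe delay analysis.

#' Trial-level memory table with condition groups attached
#'
#' Joins a memory-response table onto the session design(s), attaching each
#' probe's condition group and a correctness flag.  Raises an error when a
#' chosen image id is not among the probe's four options.
#'
#' @param responses Memory-response data frame (columns as written by
#'   [simulate_memory()] / [read_memory_responses()]).
#' @param design A `"session_design"` or a list of designs (one per
#'   participant; matched on `participant_id`).
#' @return Data frame: the response columns plus `cond_group` and
#'   `correct`.
#' @export
memory_trials <- function(responses, design) {
  stopifnot(is.data.frame(responses))
  designs <- if (inherits(design, "session_design")) list(design) else design
  lookup <- do.call(rbind, lapply(designs, design_lookup))
  opts <- cbind(responses$target_id, responses$foil1, responses$foil2,
                responses$foil3)
  ok <- responses$choice_id == opts[, 1L] | responses$choice_id == opts[, 2L] |
    responses$choice_id == opts[, 3L] | responses$choice_id == opts[, 4L]
  if (!all(ok)) {
    stopf("row %d: chosen id %s is not among the probe's four options",
          which(!ok)[1L], responses$choice_id[which(!ok)[1L]])
  }
  key_r <- paste(responses$participant, responses$block, responses$stream_pos)
  key_l <- paste(lookup$participant, lookup$block, lookup$stream_pos)
  idx <- match(key_r, key_l)
  if (anyNA(idx)) {
    stopf("row %d: no matching sequence in the design (participant %s, block %s, position %s)",
          which(is.na(idx))[1L], responses$participant[which(is.na(idx))[1L]],
          responses$block[which(is.na(idx))[1L]],
          responses$stream_pos[which(is.na(idx))[1L]])
  }
  if (any(responses$target_id != lookup$target_id[idx])) {
    stopf("target ids in the responses disagree with the design")
  }
  responses$cond_group <- lookup$cond_group[idx]
  responses$correct <- responses$choice_id == responses$target_id
  responses
}

#' Score the 4AFC memory task per condition group
#'
#' Accuracy (proportion of probes where the chosen id equals the target
#' id; chance = 0.25), mean response time and mean confidence per condition
#' group.  With several participants, trials are aggregated within each
#' participant first and the participant means are then averaged.
#'
#' @inheritParams memory_trials
#' @param by_participant If `TRUE`, return the per-participant group means
#'   instead of the across-participant summary.
#' @return Data frame: `cond_group`, `accuracy`, `mean_rt_ms`,
#'   `mean_conf`, `n_trials` (plus `participant` when
#'   `by_participant = TRUE`).
#' @export
score_memory <- function(responses, design, by_participant = FALSE) {
  tr <- memory_trials(responses, design)
  key <- interaction(tr$participant, tr$cond_group, drop = TRUE)
  per <- data.frame(
    participant = tapply(tr$participant, key, `[`, 1L),
    cond_group = tapply(as.character(tr$cond_group), key, `[`, 1L),
    accuracy = as.numeric(tapply(tr$correct, key, mean)),
    mean_rt_ms = as.numeric(tapply(tr$rt_ms, key, mean)),
    mean_conf = as.numeric(tapply(tr$confidence, key, mean)),
    n_trials = as.integer(tapply(tr$correct, key, length)),
    stringsAsFactors = FALSE
  )
  rownames(per) <- NULL
  if (by_participant) return(per)
  grp <- sort(unique(per$cond_group))
  data.frame(
    cond_group = grp,
    accuracy = as.numeric(tapply(per$accuracy, per$cond_group, mean)[grp]),
    mean_rt_ms = as.numeric(tapply(per$mean_rt_ms, per$cond_group, mean)[grp]),
    mean_conf = as.numeric(tapply(per$mean_conf, per$cond_group, mean)[grp]),
    n_trials = as.integer(tapply(per$n_trials, per$cond_group, sum)[grp]),
    stringsAsFactors = FALSE
  )
}

#' Stream-to-probe delay of a memory trial
#'
#' The delay between the appearances of a target in the RSVP stream and in
#' the memory task is the number of intervening targets in the stream plus
#' the number of intervening targets in the memory task, plus one: for
#' stream position `i` and probe position `j` (both 1-based among
#' `n_targets` targets), `delay = n_targets - i + j`.  Delays of 3-20
#' trials form the short bin and 21-37 the long bin; the rare extremes are
#' excluded.
#'
#' @param stream_pos,probe_pos Integer vectors of stream and probe
#'   positions, each in `1..n_targets`.
#' @param n_targets Targets per block.
#' @param short_range,long_range Inclusive delay bounds of the two bins.
#' @return Data frame: `delay`, `bin` (`"short"`, `"long"` or
#'   `"excluded"`).
#' @examples
#' compute_delay(10, 10)          # delay 20, short bin
#' compute_delay(20, 1)           # delay 1, excluded
#' @export
compute_delay <- function(stream_pos, probe_pos, n_targets = 20L,
                          short_range = c(3L, 20L), long_range = c(21L, 37L)) {
  if (any(stream_pos < 1L | stream_pos > n_targets) ||
      any(probe_pos < 1L | probe_pos > n_targets)) {
    stopf("positions must lie in 1..%d", n_targets)
  }
  delay <- n_targets - as.integer(stream_pos) + as.integer(probe_pos)
  bin <- rep("excluded", length(delay))
  bin[delay >= short_range[1L] & delay <= short_range[2L]] <- "short"
  bin[delay >= long_range[1L] & delay <= long_range[2L]] <- "long"
  data.frame(delay = delay, bin = bin, stringsAsFactors = FALSE)
}

#' Short-versus-long delay split of the memory data
#'
#' Assigns every memory trial a stream-to-probe delay (see
#' [compute_delay()]), averages accuracy, RT and confidence per participant
#' within the short and long delay bins, and returns the
#' across-participant short-minus-long differences with BCa bootstrap
#' confidence intervals.  The pooling is condition-unbalanced by
#' construction, since conditions are randomly ordered across the session.
#' Participants lacking trials in either bin are dropped with a warning.
#'
#' @inheritParams memory_trials
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return Data frame with rows `accuracy`, `rt_ms`, `confidence`:
#'   `measure`, `estimate` (mean short - long difference), `lower`,
#'   `upper`, `n_participants`.
#' @export
delay_split <- function(responses, design, n_boot = 2000L, seed = NULL,
                        conf = 0.95) {
  tr <- memory_trials(responses, design)
  d <- compute_delay(tr$stream_pos, tr$probe_pos)
  tr$bin <- d$bin
  tr <- tr[tr$bin != "excluded", , drop = FALSE]

  diffs <- lapply(split(tr, tr$participant), function(x) {
    if (!all(c("short", "long") %in% x$bin)) return(NULL)
    m <- function(v) tapply(v, x$bin, mean)
    acc <- m(x$correct); rt <- m(x$rt_ms); cf <- m(x$confidence)
    data.frame(participant = x$participant[1L],
               accuracy = acc[["short"]] - acc[["long"]],
               rt_ms = rt[["short"]] - rt[["long"]],
               confidence = cf[["short"]] - cf[["long"]],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(diffs, is.null, TRUE))
  if (dropped > 0L) {
    warnf("%d participant(s) dropped from the delay split (empty delay bin)",
          dropped)
  }
  diffs <- do.call(rbind, diffs)
  if (is.null(diffs) || nrow(diffs) == 0L) {
    stopf("no participant has trials in both delay bins")
  }
  sub <- with_seed(seed, sample.int(2147483646L, 3L))
  one <- function(v, s) {
    if (nrow(diffs) >= 2L && stats::sd(v) > 0) {
      ci <- bca_bootstrap(v, n_boot = n_boot, seed = s, conf = conf)
      c(mean(v), ci$lower, ci$upper)
    } else {
      c(mean(v), mean(v), mean(v))
    }
  }
  res <- rbind(one(diffs$accuracy, sub[1L]),
               one(diffs$rt_ms, sub[2L]),
               one(diffs$confidence, sub[3L]))
  data.frame(measure = c("accuracy", "rt_ms", "confidence"),
             estimate = res[, 1L], lower = res[, 2L], upper = res[, 3L],
             n_participants = nrow(diffs),
             stringsAsFactors = FALSE)
}

#' Regular-versus-irregular contrasts for the memory task
#'
#' Applies the same two paired contrasts as the detection analysis to the
#' memory measures: (a) the regular 3-distractor condition against a
#' seeded random subsample of equally many irregular trials, and (b) all
#' regular against all irregular trials.  Differences are
#' Irregular - Regular, one row per participant, for accuracy, RT and
#' confidence.
#'
#' @inheritParams memory_trials
#' @param seed Integer seed for the irregular subsample.
#' @return List with elements `r3_vs_irregular` and
#'   `all_regular_vs_all_irregular`, each a data frame: `participant`,
#'   `n_regular`, `n_irregular`, `diff_accuracy`, `diff_rt_ms`,
#'   `diff_confidence`.
#' @export
memory_contrasts <- function(responses, design, seed = NULL) {
  tr <- memory_trials(responses, design)
  diff_row <- function(p, a, b) {
    data.frame(
      participant = p,
      n_regular = nrow(b),
      n_irregular = nrow(a),
      diff_accuracy = mean(a$correct) - mean(b$correct),
      diff_rt_ms = mean(a$rt_ms) - mean(b$rt_ms),
      diff_confidence = mean(a$confidence) - mean(b$confidence),
      stringsAsFactors = FALSE
    )
  }
  r3 <- with_seed(seed, {
    out <- lapply(split(tr, tr$participant), function(x) {
      reg <- x[x$cond_group == "R3", , drop = FALSE]
      irr <- x[irregular_rows(x$cond_group), , drop = FALSE]
      if (nrow(irr) < nrow(reg)) {
        stopf("participant %s has fewer irregular than R3 trials",
              format(x$participant[1L]))
      }
      sub <- irr[sample.int(nrow(irr), nrow(reg)), , drop = FALSE]
      diff_row(x$participant[1L], sub, reg)
    })
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  })
  all_c <- do.call(rbind, lapply(split(tr, tr$participant), function(x) {
    diff_row(x$participant[1L],
             x[irregular_rows(x$cond_group), , drop = FALSE],
             x[regular_rows(x$cond_group), , drop = FALSE])
  }))
  rownames(all_c) <- NULL
  list(r3_vs_irregular = r3, all_regular_vs_all_irregular = all_c)
}
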