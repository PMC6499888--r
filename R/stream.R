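#' Build one RSVP stream schedule
#'
#' Lays out a single block: 20 repetition sequences, each preceded by a gap
#' of fresh distractors drawn uniformly from
#' `gap_min_images:gap_max_images` (one gap also leads in before the first
#' sequence), and a fixed tail of distractors after the last sequence.
#' Every non-target image id occurs exactly once in the stream; every
#' target occurs exactly six times, all within its own sequence.  Image ids
#' are abstract non-negative integers allocated sequentially in event order
#' starting at `id_start`.
#'
#' @param block_conditions List of 20 `"spacing_condition"` objects, one per
#'   repetition sequence, in stream order.
#' @param timing A [timing_config()].
#' @param seed Integer seed; the same seed reproduces the stream exactly.
#' @param block_id Block index stored in the schedule.
#' @param id_start First image id to allocate.
#'
#' @return An object of class `"stream_schedule"`: a list with `events`
#'   (data frame: `index` 0-based, `onset_ms`, `duration_ms`, `image_id`,
#'   `role`, `sequence_id`), `sequences` (list of 20 repetition sequences
#'   with target id, condition, 0-based `event_indices` and `onset_times`),
#'   `gaps`, `block_id`, `n_events`, `total_duration_ms`, `next_image_id`
#'   and `rng_seed`.
#' @examples
#' conds <- c(lapply(1:5, regular_condition),
#'            enumerate_irregular_orders()[1:15])
#' s <- build_stream(conds, seed = 1)
#' nrow(s$events)
#' @export
build_stream <- function(block_conditions, timing = timing_config(),
                         seed = NULL, block_id = 1L, id_start = 0L) {
  if (!is.list(block_conditions) ||
      !all(vapply(block_conditions, inherits, TRUE, "spacing_condition"))) {
    stopf("block_conditions must be a list of spacing_condition objects")
  }
  n_seq <- length(block_conditions)
  if (n_seq < 1L) stopf("at least one condition required")
  stopifnot(inherits(timing, "timing_config"))

  gaps <- with_seed(seed, {
    sample(timing$gap_min_images:timing$gap_max_images, n_seq, replace = TRUE)
  })

  role_parts <- vector("list", 2L * n_seq + 1L)
  sid_parts <- vector("list", 2L * n_seq + 1L)
  for (i in seq_len(n_seq)) {
    lay <- sequence_layout(block_conditions[[i]])
    r <- rep("distractor", lay$length)
    r[lay$target_pos] <- "target"
    role_parts[[2L * i - 1L]] <- rep("distractor", gaps[i])
    sid_parts[[2L * i - 1L]] <- rep(NA_integer_, gaps[i])
    role_parts[[2L * i]] <- r
    sid_parts[[2L * i]] <- rep(i, lay$length)
  }
  role_parts[[2L * n_seq + 1L]] <- rep("distractor", timing$tail_images)
  sid_parts[[2L * n_seq + 1L]] <- rep(NA_integer_, timing$tail_images)
  role <- unlist(role_parts, use.names = FALSE)
  sid <- unlist(sid_parts, use.names = FALSE)

  n <- length(role)
  is_target <- role == "target"
  ti <- which(is_target)
  first_ti <- ti[!duplicated(sid[ti])]          # first presentation per sequence
  fresh <- !is_target
  fresh[first_ti] <- TRUE                       # first target occurrence gets a new id
  ids <- integer(n)
  ids[fresh] <- as.integer(id_start) + seq_len(sum(fresh)) - 1L
  target_ids <- ids[first_ti]
  ids[ti] <- target_ids[sid[ti]]

  onset <- (seq_len(n) - 1L) * timing$soa_ms
  events <- data.frame(
    index = seq_len(n) - 1L,
    onset_ms = onset,
    duration_ms = timing$image_duration_ms,
    image_id = ids,
    role = role,
    sequence_id = sid,
    stringsAsFactors = FALSE
  )

  sequences <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    ev_idx <- which(is_target & !is.na(sid) & sid == i) - 1L
    sequences[[i]] <- list(
      sequence_id = i,
      target_image = target_ids[i],
      condition = block_conditions[[i]],
      event_indices = ev_idx,
      onset_times = ev_idx * timing$soa_ms
    )
  }

  structure(
    list(
      block_id = as.integer(block_id),
      events = events,
      sequences = sequences,
      gaps = gaps,
      n_events = n,
      total_duration_ms = n * timing$soa_ms,
      next_image_id = as.integer(id_start) + sum(fresh),
      timing = timing,
      rng_seed = seed
    ),
    class = "stream_schedule"
  )
}

# End of the last image, in ms from stream onset.
stream_end_ms <- function(schedule) {
  ev <- schedule$events
  ev$onset_ms[nrow(ev)] + ev$duration_ms[nrow(ev)]
}

#' Validate the structural invariants of a stream schedule
#'
#' Checks that onsets increase with constant SOA, every non-target image id
#' occurs exactly once, every target id occurs exactly six times within its
#' own sequence, and (when the schedule was built with the standard design)
#' that there are 20 sequences and each inter-sequence gap is within the
#' configured bounds.
#'
#' @param schedule A `"stream_schedule"`.
#' @param n_sequences Expected number of repetition sequences.
#' @return The schedule, invisibly; errors on violation.
#' @export
validate_stream_schedule <- function(schedule, n_sequences = 20L) {
  stopifnot(inherits(schedule, "stream_schedule"))
  ev <- schedule$events
  if (nrow(ev) == 0L) stopf("schedule has no events")
  if (length(schedule$sequences) != n_sequences) {
    stopf("schedule has %d sequences, expected %d",
          length(schedule$sequences), n_sequences)
  }
  soa <- schedule$timing$soa_ms
  if (any(abs(diff(ev$onset_ms) - soa) > 1e-9)) {
    stopf("onsets are not spaced by a constant SOA")
  }
  tab <- table(ev$image_id)
  tgt <- vapply(schedule$sequences, function(s) s$target_image, 0L)
  if (!all(tab[as.character(tgt)] == 6L)) {
    stopf("every target id must occur exactly 6 times")
  }
  non_tgt <- setdiff(as.integer(names(tab)), tgt)
  if (!all(tab[as.character(non_tgt)] == 1L)) {
    stopf("every non-target id must occur exactly once")
  }
  for (s in schedule$sequences) {
    rows <- ev$image_id == s$target_image
    if (!all(ev$sequence_id[rows] == s$sequence_id)) {
      stopf("target %d appears outside its own sequence", s$target_image)
    }
    iv <- spacing_intervals(s$condition)
    if (!identical(as.integer(diff(s$event_indices)), iv + 1L)) {
      stopf("sequence %d does not respect its spacing condition", s$sequence_id)
    }
  }
  if (!is.null(schedule$gaps)) {
    if (any(schedule$gaps < schedule$timing$gap_min_images |
            schedule$gaps > schedule$timing$gap_max_images)) {
      stopf("an inter-sequence gap falls outside the configured bounds")
    }
  }
  invisible(schedule)
}

#' @export
print.stream_schedule <- function(x, ...) {
  cat(sprintf("RSVP stream schedule: block %d, %d events (%.1f s), %d sequences\n",
              x$block_id, x$n_events, x$total_duration_ms / 1000,
              length(x$sequences)))
  invisible(x)
}
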