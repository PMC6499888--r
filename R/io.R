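# CSV / JSON plumbing for schedules, press logs, memory responses, configs.

schedule_columns <- c("block", "index", "onset_ms", "duration_ms", "image_id",
                      "role", "sequence_id", "cond_kind", "cond_spec")

#' Write / read a stream schedule as CSV
#'
#' The schedule CSV has one row per event with columns
#' `block,index,onset_ms,duration_ms,image_id,role,sequence_id,cond_kind,cond_spec`
#' (0-based indices, onset at image onset; `cond_spec` is `d=3` or
#' `order=3-1-5-2-4`, filled on every event belonging to a sequence).
#' `read_schedule()` reconstructs the `"stream_schedule"` object and
#' validates its invariants; malformed files raise a parse error naming the
#' offending column or row.
#'
#' @param schedule A `"stream_schedule"`.
#' @param path File path.
#' @param timing Timing configuration assumed when reading; onset spacing
#'   is checked against it.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `"stream_schedule"`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stream_schedule"))
  ev <- schedule$events
  kind_by_seq <- vapply(schedule$sequences, function(s) s$condition$kind, "")
  spec_by_seq <- vapply(schedule$sequences, function(s) condition_spec(s$condition), "")
  sid <- ev$sequence_id
  out <- data.frame(
    block = schedule$block_id,
    index = ev$index,
    onset_ms = format_num(ev$onset_ms),
    duration_ms = format_num(ev$duration_ms),
    image_id = ev$image_id,
    role = ev$role,
    sequence_id = ifelse(is.na(sid), "", as.character(sid)),
    cond_kind = ifelse(is.na(sid), "", kind_by_seq[ifelse(is.na(sid), 1L, sid)]),
    cond_spec = ifelse(is.na(sid), "", spec_by_seq[ifelse(is.na(sid), 1L, sid)]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal text for a double; survives a write/read round trip
format_num <- function(x) formatC(x, digits = 17, format = "g")

#' @rdname write_schedule
#' @export
read_schedule <- function(path, timing = timing_config()) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(sequence_id = "character",
                                   cond_kind = "character",
                                   cond_spec = "character")),
    error = function(e) stopf("cannot parse schedule file '%s': %s", path,
                              conditionMessage(e))
  )
  missing_cols <- setdiff(schedule_columns, names(df))
  if (length(missing_cols) > 0L) {
    stopf("schedule file '%s' is missing column(s) at header (line 1): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("schedule file '%s' has no events", path)
  bad <- which(!df$role %in% c("target", "distractor"))
  if (length(bad) > 0L) {
    stopf("schedule file '%s': invalid role at line %d", path, bad[1L] + 1L)
  }
  sid <- suppressWarnings(as.integer(df$sequence_id))
  sid[df$sequence_id == ""] <- NA_integer_

  seq_ids <- sort(unique(sid[!is.na(sid)]))
  if (length(seq_ids) == 0L) stopf("schedule file '%s' contains no sequences", path)
  sequences <- vector("list", length(seq_ids))
  for (k in seq_along(seq_ids)) {
    i <- seq_ids[k]
    rows <- which(!is.na(sid) & sid == i)
    cond <- parse_condition_spec(df$cond_kind[rows[1L]], df$cond_spec[rows[1L]])
    t_rows <- rows[df$role[rows] == "target"]
    if (length(t_rows) != 6L) {
      stopf("schedule file '%s': sequence %d has %d target events (6 required), near line %d",
            path, i, length(t_rows), rows[1L] + 1L)
    }
    sequences[[k]] <- list(
      sequence_id = i,
      target_image = df$image_id[t_rows[1L]],
      condition = cond,
      event_indices = df$index[t_rows],
      onset_times = df$onset_ms[t_rows]
    )
  }

  schedule <- structure(
    list(
      block_id = as.integer(df$block[1L]),
      events = data.frame(
        index = df$index,
        onset_ms = df$onset_ms,
        duration_ms = df$duration_ms,
        image_id = df$image_id,
        role = df$role,
        sequence_id = sid,
        stringsAsFactors = FALSE
      ),
      sequences = sequences,
      gaps = NULL,
      n_events = nrow(df),
      total_duration_ms = nrow(df) * timing$soa_ms,
      next_image_id = max(df$image_id) + 1L,
      timing = timing,
      rng_seed = NULL
    ),
    class = "stream_schedule"
  )
  validate_stream_schedule(schedule, n_sequences = length(seq_ids))
  if (length(seq_ids) != 20L) {
    stopf("schedule file '%s' has %d sequences; the standard design requires 20",
          path, length(seq_ids))
  }
  schedule
}

#' Write / read a button-press log as CSV
#'
#' Columns: `participant,block,time_ms` with one row per press, times in
#' milliseconds from stream onset.
#'
#' @param presses A press-log data frame (e.g. from [simulate_presses()]).
#' @param path File path.
#' @return `write_press_log()` returns `path` invisibly; `read_press_log()`
#'   a data frame sorted by time within participant and block.
#' @export
write_press_log <- function(presses, path) {
  stopifnot(all(c("participant", "block", "time_ms") %in% names(presses)))
  out <- presses[c("participant", "block", "time_ms")]
  out$time_ms <- format_num(out$time_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_press_log
#' @export
read_press_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "block", "time_ms")
  if (!all(need %in% names(df))) {
    stopf("press log '%s' must have columns %s", path, paste(need, collapse = ","))
  }
  df[order(df$participant, df$block, df$time_ms), , drop = FALSE]
}

memory_columns <- c("participant", "block", "probe_pos", "stream_pos",
                    "target_id", "foil1", "foil2", "foil3", "choice_id",
                    "rt_ms", "confidence")

#' Write / read a memory-response table as CSV
#'
#' Columns:
#' `participant,block,probe_pos,stream_pos,target_id,foil1,foil2,foil3,choice_id,rt_ms,confidence`.
#'
#' @param responses A memory-response data frame (e.g. from
#'   [simulate_memory()]).
#' @param path File path.
#' @return `write_memory_responses()` returns `path` invisibly;
#'   `read_memory_responses()` a data frame.
#' @export
write_memory_responses <- function(responses, path) {
  stopifnot(all(memory_columns %in% names(responses)))
  out <- responses[memory_columns]
  out$rt_ms <- format_num(out$rt_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_memory_responses
#' @export
read_memory_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(memory_columns %in% names(df))) {
    stopf("memory-response file '%s' must have columns %s", path,
          paste(memory_columns, collapse = ","))
  }
  df
}

#' Write / read the design configuration as JSON
#'
#' Records the timing parameters, gap range, tail length, practice-image
#' reservation and seed, so that a design can be rebuilt elsewhere.
#'
#' @param timing A [timing_config()].
#' @param path File path.
#' @param seed,n_practice_images Extra fields stored alongside the timing.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   list with elements `timing`, `seed`, `n_practice_images`.
#' @export
write_config <- function(timing, path, seed = NULL, n_practice_images = 1200L) {
  stopifnot(inherits(timing, "timing_config"))
  cfg <- list(
    image_duration_ms = timing$image_duration_ms,
    blank_duration_ms = timing$blank_duration_ms,
    presentation_rate_hz = timing$presentation_rate_hz,
    gap_min_images = timing$gap_min_images,
    gap_max_images = timing$gap_max_images,
    tail_images = timing$tail_images,
    n_practice_images = n_practice_images,
    seed = seed
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  timing <- timing_config(
    image_duration_ms = cfg$image_duration_ms,
    blank_duration_ms = cfg$blank_duration_ms,
    presentation_rate_hz = cfg$presentation_rate_hz,
    gap_min_images = cfg$gap_min_images,
    gap_max_images = cfg$gap_max_images,
    tail_images = cfg$tail_images
  )
  list(timing = timing, seed = cfg$seed,
       n_practice_images = cfg$n_practice_images)
}
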