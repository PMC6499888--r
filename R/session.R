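#' Build a full session design
#'
#' One session comprises 12 blocks of 20 repetition sequences.  The 240
#' spacing conditions are fixed by design: all 120 permutations of
#' (1, 2, 3, 4, 5) are used exactly once as irregular conditions, and each
#' regular distractor count d in 1..5 is used 24 times, so the session has
#' equally many regular and irregular sequences (120 of each).  The whole
#' 240-condition ledger is shuffled globally and chunked into 12 blocks of
#' 20, so conditions are *not* balanced across blocks.
#'
#' Image ids are allocated sequentially across the session; the first
#' `n_practice_images` ids are reserved for the practice blocks, which are
#' represented only as this count (their structure is out of scope).
#'
#' @param participant_id Identifier stored with the design.
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @param timing A [timing_config()].
#' @param n_practice_images Number of image ids reserved for practice
#'   blocks (a count only; no practice streams are generated).
#' @param n_blocks,sequences_per_block Design dimensions; defaults give the
#'   standard 12 x 20 session and must multiply to 240 (the regular +
#'   irregular ledger size) unless both are overridden consistently.
#'
#' @return An object of class `"session_design"`: list with
#'   `participant_id`, `blocks` (list of [build_stream()] schedules),
#'   `condition_ledger` (240 conditions in presentation order),
#'   `n_practice_images`, `n_image_ids` (total distinct ids including the
#'   practice reservation), `timing` and `rng_seed`.
#' @examples
#' \donttest{
#' d <- build_session("p01", seed = 1)
#' length(d$blocks)
#' }
#' @export
build_session <- function(participant_id, seed, timing = timing_config(),
                          n_practice_images = 1200L,
                          n_blocks = 12L, sequences_per_block = 20L) {
  if (!is_count(n_practice_images) || n_practice_images < 0) {
    stopf("n_practice_images must be a non-negative integer")
  }
  regular <- unlist(lapply(1:5, function(d) {
    replicate(24L, regular_condition(d), simplify = FALSE)
  }), recursive = FALSE)
  irregular <- enumerate_irregular_orders()
  pool <- c(regular, irregular)
  if (n_blocks * sequences_per_block != length(pool)) {
    stopf("n_blocks * sequences_per_block must equal %d", length(pool))
  }

  drawn <- with_seed(seed, {
    list(order = sample.int(length(pool)),
         block_seeds = sample.int(2147483646L, n_blocks))
  })
  ledger <- pool[drawn$order]

  id0 <- as.integer(n_practice_images)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    take <- ((b - 1L) * sequences_per_block + 1L):(b * sequences_per_block)
    blocks[[b]] <- build_stream(ledger[take], timing,
                                seed = drawn$block_seeds[b],
                                block_id = b, id_start = id0)
    id0 <- blocks[[b]]$next_image_id
  }

  structure(
    list(
      participant_id = participant_id,
      blocks = blocks,
      condition_ledger = ledger,
      n_practice_images = as.integer(n_practice_images),
      n_image_ids = id0,
      timing = timing,
      rng_seed = seed
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  n_ev <- sum(vapply(x$blocks, function(b) b$n_events, 0L))
  cat(sprintf("session design: participant %s, %d blocks, %d sequences, %d stream events\n",
              format(x$participant_id), length(x$blocks),
              length(x$condition_ledger), n_ev))
  cat(sprintf("distinct image ids: %d (incl. %d reserved for practice)\n",
              x$n_image_ids, x$n_practice_images))
  invisible(x)
}

# data frame mapping (block, stream position) -> condition group / target,
# used to join memory responses back onto the design.
design_lookup <- function(design) {
  stopifnot(inherits(design, "session_design"))
  do.call(rbind, lapply(design$blocks, function(b) {
    data.frame(
      participant = rep(design$participant_id, length(b$sequences)),
      block = b$block_id,
      stream_pos = vapply(b$sequences, function(s) s$sequence_id, 0L),
      cond_group = vapply(b$sequences, condition_group, ""),
      target_id = vapply(b$sequences, function(s) s$target_image, 0L),
      stringsAsFactors = FALSE
    )
  }))
}
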