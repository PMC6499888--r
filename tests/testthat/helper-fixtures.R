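# Fixtures and independent oracles shared across test files.

# A standard 20-condition block mix: one regular sequence per d plus 15
# irregular orders.
standard_block_conditions <- function() {
  c(lapply(1:5, regular_condition), enumerate_irregular_orders()[1:15])
}

# Observer with certain hits, no extra presses and no false alarms.
perfect_observer <- function() {
  observer_params(
    hit_prob = stats::setNames(rep(1, 10), c(paste0("R", 1:5), paste0("I", 1:5))),
    extra_press_prob = 0, fa_rate = 0
  )
}

# Observer that never presses.
silent_observer <- function() {
  observer_params(
    hit_prob = stats::setNames(rep(0, 10), c(paste0("R", 1:5), paste0("I", 1:5))),
    extra_press_prob = 0, fa_rate = 0
  )
}

# Observer with identical hit probabilities in every condition group
# (regular/irregular exchangeable by construction).
symmetric_observer <- function(p = 0.627) {
  observer_params(
    hit_prob = stats::setNames(rep(p, 10), c(paste0("R", 1:5), paste0("I", 1:5))),
    mem_acc = stats::setNames(rep(0.65, 10), c(paste0("R", 1:5), paste0("I", 1:5)))
  )
}

# Brute-force window scorer: plain double loop over (press, sequence) pairs,
# assigning each press to the earliest-opening window that contains it.
# Independent of score_windows()/score_block().
brute_force_score <- function(t2, presses, start, end) {
  n_seq <- length(t2)
  ord <- order(t2)
  n_in <- integer(n_seq)
  assigned <- rep(NA_integer_, length(presses))
  for (pi in seq_along(presses)) {
    for (si in ord) {
      if (presses[pi] > t2[si] + start && presses[pi] < t2[si] + end) {
        assigned[pi] <- si
        break
      }
    }
    if (!is.na(assigned[pi])) n_in[assigned[pi]] <- n_in[assigned[pi]] + 1L
  }
  rt <- rep(NA_real_, n_seq)
  for (si in seq_len(n_seq)) {
    if (n_in[si] == 1L) rt[si] <- presses[which(assigned == si)] - t2[si]
  }
  list(n_in = n_in, detected = n_in == 1L, rt = rt)
}

# Minimal schedule object carrying arbitrary second-presentation onsets, for
# exercising the scorer on synthetic (possibly overlapping-window) layouts.
fake_schedule <- function(t2, block_id = 1L) {
  n <- length(t2)
  groups <- rep(c(paste0("R", 1:5), paste0("I", 1:5)), length.out = n)
  seqs <- lapply(seq_len(n), function(i) {
    cond <- if (grepl("^R", groups[i])) {
      regular_condition(as.integer(sub("R", "", groups[i])))
    } else {
      ord <- as.integer(sub("I", "", groups[i]))
      irregular_condition(c(ord, setdiff(1:5, ord)))
    }
    d1 <- spacing_intervals(cond)[1L]
    t1 <- t2[i] - (d1 + 1L) * (1000 / 15)
    list(sequence_id = i, target_image = 1000L + i, condition = cond,
         event_indices = NA, onset_times = c(t1, t2[i], rep(NA, 4)))
  })
  ev <- data.frame(index = 0L, onset_ms = 0, duration_ms = 58.3,
                   image_id = 0L, role = "distractor",
                   sequence_id = NA_integer_)
  structure(list(block_id = block_id, events = ev, sequences = seqs,
                 gaps = NULL, n_events = 1L,
                 total_duration_ms = max(t2) + 5000,
                 next_image_id = 1L, timing = timing_config(), rng_seed = NULL),
            class = "stream_schedule")
}

# Independent quadrature oracle for the JZS Bayes factor: marginal
# noncentral-t likelihood under a Cauchy effect-size prior, over delta.
jzs_oracle <- function(t, n, r = sqrt(2) / 2) {
  num <- suppressWarnings(stats::integrate(
    function(d) stats::dt(t, n - 1, ncp = sqrt(n) * d) * stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-10, subdivisions = 1000L
  ))$value
  den <- stats::dt(t, n - 1)
  num / den
}
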