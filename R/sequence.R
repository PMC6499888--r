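# Repetition-sequence assembly.

# 1-based positions of the 6 target presentations within a sequence, and the
# sequence length, for a given spacing condition.
sequence_layout <- function(condition) {
  iv <- spacing_intervals(condition)
  tpos <- cumsum(c(1L, iv + 1L))
  list(target_pos = tpos, length = tpos[6L], intervals = iv)
}

#' Assemble one repetition sequence as an ordered image list
#'
#' Interleaves six presentations of `target` with the supplied distractor
#' ids: gap *i* (between presentations *i* and *i + 1*) receives the
#' condition's *i*-th distractor count.  The list therefore begins and ends
#' with the target.
#'
#' @param condition A `"spacing_condition"`.
#' @param target Image id of the repeated target.
#' @param distractors Image ids filling the gaps, in order; must have
#'   exactly `sum(spacing_intervals(condition))` elements (5 * d for a
#'   regular condition, 15 for an irregular one) and must not contain the
#'   target.
#'
#' @return Integer vector of image ids, of length `6 + sum(intervals)`.
#' @examples
#' make_sequence(regular_condition(1), target = 0, distractors = 1:5)
#' @export
make_sequence <- function(condition, target, distractors) {
  lay <- sequence_layout(condition)
  need <- lay$length - 6L
  if (length(distractors) != need) {
    stopf("condition requires %d distractors, got %d", need, length(distractors))
  }
  if (target %in% distractors) stopf("target id must not appear among distractors")
  if (anyDuplicated(distractors)) stopf("distractor ids must be distinct")
  out <- rep(NA_integer_, lay$length)
  out[lay$target_pos] <- as.integer(target)
  out[-lay$target_pos] <- as.integer(distractors)
  out
}
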