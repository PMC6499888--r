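#' Spacing conditions for repetition sequences
#'
#' A repetition sequence presents one target image six times, leaving a gap
#' of distractor images between consecutive presentations.  In a *regular*
#' condition every one of the five gaps holds the same number `d` of
#' distractors (`d` in 1..5); in an *irregular* condition the five gaps hold
#' 1, 2, 3, 4 and 5 distractors in a prescribed order (a permutation of
#' 1..5), so every irregular sequence has 15 distractors in total.
#'
#' @param d Number of distractors between consecutive target presentations
#'   (integer, 1..5).
#' @param order Integer vector of length 5, a permutation of `1:5`, giving
#'   the distractor counts of the five inter-target gaps in order.
#'
#' @return An object of class `"spacing_condition"`.
#' @examples
#' regular_condition(3)
#' irregular_condition(c(3, 1, 5, 2, 4))
#' @export
regular_condition <- function(d) {
  if (!is_count(d) || d < 1 || d > 5) stopf("d must be an integer in 1..5")
  structure(list(kind = "regular", d = as.integer(d), order = NULL),
            class = "spacing_condition")
}

#' @rdname regular_condition
#' @export
irregular_condition <- function(order) {
  order <- as.integer(order)
  if (length(order) != 5L || !identical(sort(order), 1:5)) {
    stopf("order must be a permutation of 1:5")
  }
  structure(list(kind = "irregular", d = NULL, order = order),
            class = "spacing_condition")
}

#' All irregular spacing orders
#'
#' Enumerates every permutation of the distractor counts (1, 2, 3, 4, 5)
#' exactly once, in lexicographic order, as irregular spacing conditions.
#' A session uses each of the 120 permutations once.
#'
#' @return A list of 120 `"spacing_condition"` objects; the first has order
#'   `c(1, 2, 3, 4, 5)`.
#' @examples
#' length(enumerate_irregular_orders())
#' @export
enumerate_irregular_orders <- function() {
  lapply(permutations_lex(1:5), irregular_condition)
}

# All permutations of a sorted integer vector, lexicographic.
permutations_lex <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- vector("list", factorial(length(v)))
  k <- 0L
  for (i in seq_along(v)) {
    for (rest in permutations_lex(v[-i])) {
      k <- k + 1L
      out[[k]] <- c(v[i], rest)
    }
  }
  out
}

#' Distractor counts of the five inter-target gaps
#'
#' @param condition A `"spacing_condition"`.
#' @return Integer vector of length 5.
#' @export
spacing_intervals <- function(condition) {
  stopifnot(inherits(condition, "spacing_condition"))
  if (condition$kind == "regular") rep(condition$d, 5L) else condition$order
}

#' Condition group label
#'
#' Analysis bin of a spacing condition: regular conditions are keyed by
#' their distractor count (`"R1"`..`"R5"`); irregular conditions are keyed
#' by the number of distractors before the first repetition, i.e. the first
#' gap of the order (`"I1"`..`"I5"`).
#'
#' @param condition A `"spacing_condition"`, or a repetition sequence (the
#'   `sequences` element of a stream schedule), in which case its condition
#'   is used.
#' @return A single string such as `"R3"` or `"I5"`.
#' @examples
#' condition_group(regular_condition(4))
#' condition_group(irregular_condition(c(3, 1, 5, 2, 4)))
#' @export
condition_group <- function(condition) {
  if (!inherits(condition, "spacing_condition") &&
      is.list(condition) && !is.null(condition$condition)) {
    condition <- condition$condition
  }
  stopifnot(inherits(condition, "spacing_condition"))
  if (condition$kind == "regular") {
    paste0("R", condition$d)
  } else {
    paste0("I", condition$order[1L])
  }
}

# Compact text form used in schedule CSV files: "d=3" or "order=3-1-5-2-4".
condition_spec <- function(condition) {
  stopifnot(inherits(condition, "spacing_condition"))
  if (condition$kind == "regular") {
    paste0("d=", condition$d)
  } else {
    paste0("order=", paste(condition$order, collapse = "-"))
  }
}

parse_condition_spec <- function(kind, spec) {
  if (kind == "regular") {
    if (!grepl("^d=[1-5]$", spec)) stopf("malformed regular cond_spec: '%s'", spec)
    regular_condition(as.integer(sub("^d=", "", spec)))
  } else if (kind == "irregular") {
    if (!grepl("^order=[1-5](-[1-5]){4}$", spec)) {
      stopf("malformed irregular cond_spec: '%s'", spec)
    }
    irregular_condition(as.integer(strsplit(sub("^order=", "", spec), "-")[[1L]]))
  } else {
    stopf("unknown cond_kind: '%s'", kind)
  }
}

#' @export
print.spacing_condition <- function(x, ...) {
  if (x$kind == "regular") {
    cat(sprintf("regular spacing: %d distractors between presentations (group %s)\n",
                x$d, condition_group(x)))
  } else {
    cat(sprintf("irregular spacing: order %s (group %s)\n",
                paste(x$order, collapse = "-"), condition_group(x)))
  }
  invisible(x)
}
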