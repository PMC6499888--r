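#' One-way ANOVA over a list of groups
#'
#' Fits the standard between/within decomposition with [stats::aov()]; the
#' usual design here is 5 condition groups of 19 participant means, giving
#' degrees of freedom (4, 90).
#'
#' @param groups List of numeric vectors, one per group (at least 2
#'   groups, each with at least 2 values).
#' @return An object of class `"anova_result"`: list with `F`,
#'   `df_between`, `df_within`, `p`, `group_means`.  When every value is
#'   identical (0/0 F statistic), `F = 0` and `p = 1` with a warning.
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
#' @export
oneway_anova <- function(groups) {
  check_groups(groups)
  df <- groups_to_df(groups)
  if (stats::var(df$value) == 0) {
    warnf("zero between- and within-group variance; defining F = 0")
    return(structure(
      list(F = 0, df_between = length(groups) - 1L,
           df_within = nrow(df) - length(groups), p = 1,
           group_means = vapply(groups, mean, 0)),
      class = "anova_result"
    ))
  }
  fit <- stats::aov(value ~ g, data = df)
  s <- summary(fit)[[1L]]
  f <- s[["F value"]][1L]
  p <- s[["Pr(>F)"]][1L]
  if (!is.finite(f)) {
    warnf("degenerate variance decomposition; defining F = 0")
    f <- 0
    p <- 1
  }
  structure(
    list(F = f,
         df_between = as.integer(s[["Df"]][1L]),
         df_within = as.integer(s[["Df"]][2L]),
         p = p,
         group_means = vapply(groups, mean, 0)),
    class = "anova_result"
  )
}

#' Tukey-Kramer post-hoc pairwise comparisons
#'
#' All pairwise group comparisons based on the studentized range
#' distribution with the pooled within-group variance; unequal group sizes
#' use the Tukey-Kramer harmonic form (as implemented by
#' [stats::TukeyHSD()]).
#'
#' @inheritParams oneway_anova
#' @param conf Confidence level of the pairwise intervals.
#' @return Data frame: `pair` (e.g. `"R3-R1"`), `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @examples
#' tukey_kramer(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
#' @export
tukey_kramer <- function(groups, conf = 0.95) {
  check_groups(groups)
  df <- groups_to_df(groups)
  fit <- stats::aov(value ~ g, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf)$g
  data.frame(
    pair = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("groups must be a list of at least 2 numeric vectors")
  }
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2L)) {
    stopf("every group needs at least 2 values (group %d has %d)",
          which(sizes < 2L)[1L], min(sizes))
  }
  if (!all(vapply(groups, function(g) all(is.finite(g)), TRUE))) {
    stopf("groups must contain only finite values")
  }
  invisible(groups)
}

groups_to_df <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    g = factor(rep(nm, vapply(groups, length, 0L)), levels = nm)
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}
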