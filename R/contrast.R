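# Regular-vs-irregular paired contrasts.  Both contrasts return one row of
# Irregular - Regular differences per participant; statistics (bootstrap CI,
# t-test, Bayes factor) are applied downstream with contrast_report().

regular_rows <- function(g) grepl("^R", g)
irregular_rows <- function(g) grepl("^I", g)

#' Contrast the regular 3-distractor condition against subsampled
#' irregular trials
#'
#' For each participant, takes every trial of the regular 3-distractor
#' condition (group `"R3"`; all irregular sequences have the same length as
#' this condition, 21 images) and a seeded random subsample of equally many
#' irregular trials, and returns the Irregular minus Regular differences in
#' detection rate and mean RT of detected trials.
#'
#' @param scores Score table with columns `participant`, `cond_group`,
#'   `detected`, `rt_ms` (from [score_session()], possibly stacked over
#'   participants).
#' @param seed Integer seed controlling the subsample.
#' @return Data frame with one row per participant: `participant`,
#'   `n_regular`, `n_irregular` (subsample size, equal to `n_regular`),
#'   `diff_detection`, `diff_rt_ms`.
#' @export
contrast_r3_vs_irregular <- function(scores, seed = NULL) {
  if (!"participant" %in% names(scores)) scores$participant <- 1L
  with_seed(seed, {
    out <- lapply(split(scores, scores$participant), function(sc) {
      r3 <- sc[sc$cond_group == "R3", , drop = FALSE]
      irr <- sc[irregular_rows(sc$cond_group), , drop = FALSE]
      if (nrow(irr) < nrow(r3)) {
        stopf("participant %s has fewer irregular (%d) than R3 (%d) trials",
              format(sc$participant[1L]), nrow(irr), nrow(r3))
      }
      sub <- irr[sample.int(nrow(irr), nrow(r3)), , drop = FALSE]
      data.frame(
        participant = sc$participant[1L],
        n_regular = nrow(r3),
        n_irregular = nrow(sub),
        diff_detection = mean(sub$detected) - mean(r3$detected),
        diff_rt_ms = mean(sub$rt_ms, na.rm = TRUE) - mean(r3$rt_ms, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Contrast all regular against all irregular trials
#'
#' For each participant, aggregates all regular trials (120 per session)
#' against all irregular trials (120 per session).  By design both groups
#' contain every inter-repetition interval (1..5 distractors) equally
#' often, and their average sequence length is the same.
#'
#' @inheritParams contrast_r3_vs_irregular
#' @return Data frame with one row per participant: `participant`,
#'   `n_regular`, `n_irregular`, `diff_detection`, `diff_rt_ms`
#'   (Irregular - Regular).
#' @export
contrast_all_regular_vs_all_irregular <- function(scores) {
  if (!"participant" %in% names(scores)) scores$participant <- 1L
  out <- lapply(split(scores, scores$participant), function(sc) {
    reg <- sc[regular_rows(sc$cond_group), , drop = FALSE]
    irr <- sc[irregular_rows(sc$cond_group), , drop = FALSE]
    data.frame(
      participant = sc$participant[1L],
      n_regular = nrow(reg),
      n_irregular = nrow(irr),
      diff_detection = mean(irr$detected) - mean(reg$detected),
      diff_rt_ms = mean(irr$rt_ms, na.rm = TRUE) - mean(reg$rt_ms, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics for a vector of paired differences
#'
#' Convenience wrapper applied to the per-participant differences returned
#' by the contrast functions: mean, BCa bootstrap confidence interval,
#' two-sided one-sample t-test, and JZS Bayes factor.
#'
#' @param differences Numeric vector of paired (Irregular - Regular)
#'   differences, one per participant.
#' @param n_boot Bootstrap iterations for the CI.
#' @param seed Integer seed for the bootstrap.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @param conf Confidence level.
#' @return List: `estimate`, `ci` (length 2), `t`, `df`, `p`, `bf10`,
#'   `bf_label`, `n`.
#' @export
contrast_report <- function(differences, n_boot = 2000L, seed = NULL,
                            prior_scale = sqrt(2) / 2, conf = 0.95) {
  x <- differences[is.finite(differences)]
  ci <- bca_bootstrap(x, n_boot = n_boot, seed = seed, conf = conf)
  tt <- stats::t.test(x)
  bf <- jzs_bf(x, prior_scale = prior_scale)
  list(
    estimate = mean(x),
    ci = c(ci$lower, ci$upper),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    bf10 = bf$bf10,
    bf_label = bf_label(bf$bf10),
    n = length(x)
  )
}

#' Write an analysis report as JSON
#'
#' @param report A named list of [contrast_report()]-style blocks (or any
#'   JSON-serializable structure).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
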