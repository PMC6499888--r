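# Statistical layer: BCa bootstrap, ANOVA, Tukey-Kramer, JZS Bayes factor.

test_that("BCa bootstrap handles degenerate and well-behaved inputs", {
  expect_warning(ci <- bca_bootstrap(rep(3, 10), seed = 1), "identical")
  expect_identical(c(ci$lower, ci$point, ci$upper), c(3, 3, 3))

  set.seed(2)
  x <- rnorm(400, mean = 10, sd = 2)
  ci <- bca_bootstrap(x, n_boot = 2000, seed = 3)
  expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
  # large normal sample: within 5% relative width of the analytic t interval
  tt <- stats::t.test(x)
  width_t <- diff(as.numeric(tt$conf.int))
  expect_lt(abs((ci$upper - ci$lower) - width_t) / width_t, 0.05)
  expect_lt(abs(ci$lower - tt$conf.int[1]), 0.1 * width_t)

  expect_error(bca_bootstrap(5), "at least 2")
})

test_that("BCa bootstrap is seed-deterministic and defaults to 2000 iterations", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9, 3.3, 1.8)
  a <- bca_bootstrap(x, seed = 7)
  b <- bca_bootstrap(x, seed = 7)
  expect_identical(a, b)
  expect_identical(a$n_boot, 2000L)
})

test_that("BCa agrees with the boot package on the same data", {
  skip_if_not_installed("boot")
  set.seed(11)
  x <- rexp(60, rate = 0.5)   # skewed, so bias correction matters
  ours <- bca_bootstrap(x, n_boot = 9999, seed = 12)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 9999)
  bci <- boot::boot.ci(bt, type = "bca")$bca
  width <- bci[5] - bci[4]
  expect_lt(abs(ours$lower - bci[4]), 0.1 * width)
  expect_lt(abs(ours$upper - bci[5]), 0.1 * width)
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  # groups (1,2,3), (2,3,4), (6,7,8): SSB = 42 (df 2), SSW = 6 (df 6),
  # F = (42/2)/(6/6) = 21
  res <- oneway_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
  expect_equal(res$F, 21)
  expect_identical(c(res$df_between, res$df_within), c(2L, 6L))
  expect_equal(res$p, stats::pf(21, 2, 6, lower.tail = FALSE))
  expect_equal(unname(res$group_means), c(2, 3, 7))
})

test_that("ANOVA degrees of freedom follow the 5 x 19 design", {
  set.seed(13)
  groups <- replicate(5, rnorm(19), simplify = FALSE)
  res <- oneway_anova(groups)
  expect_identical(c(res$df_between, res$df_within), c(4L, 90L))
  expect_error(oneway_anova(list(1:3, 5)), "at least 2 values")
  expect_warning(res0 <- oneway_anova(list(rep(1, 3), rep(1, 3))), "F = 0")
  expect_identical(res0$F, 0)
})

test_that("sum-of-squares identity holds to machine precision", {
  set.seed(14)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(5:25, 1), mean = i))
    x <- unlist(groups)
    ss_total <- sum((x - mean(x))^2)
    ns <- vapply(groups, length, 0L)
    ss_between <- sum(ns * (vapply(groups, mean, 0) - mean(x))^2)
    ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    expect_equal(ss_between + ss_within, ss_total, tolerance = 1e-12)
    # and the reported F equals the ratio of the mean squares
    res <- oneway_anova(groups)
    f_manual <- (ss_between / (k - 1)) / (ss_within / (sum(ns) - k))
    expect_equal(res$F, f_manual, tolerance = 1e-10)
  }
})

test_that("Tukey-Kramer p-values behave sanely and match the aov reference", {
  # equal group means: every adjusted p is exactly 1
  g <- list(a = c(1, 2, 3), b = c(3, 1, 2), c = c(2, 3, 1))
  tk <- tukey_kramer(g)
  expect_true(all(tk$p_adj == 1))

  # one well-separated pair among five has the smallest p
  set.seed(15)
  groups <- c(replicate(4, rnorm(10, 0), simplify = FALSE),
              list(rnorm(10, 4)))
  names(groups) <- paste0("g", 1:5)
  tk2 <- tukey_kramer(groups)
  far <- grepl("g5", tk2$pair)
  expect_lt(max(tk2$p_adj[far]), min(tk2$p_adj[!far]))
})

test_that("Tukey-Kramer matches a Monte-Carlo studentized-range null", {
  set.seed(16)
  k <- 5; n <- 10
  groups <- replicate(k, rnorm(n), simplify = FALSE)
  names(groups) <- paste0("g", 1:k)
  tk <- tukey_kramer(groups)
  x <- unlist(groups)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (k * n - k)
  means <- vapply(groups, mean, 0)

  # MC null of the studentized range: k means of n standard normals and an
  # independent pooled variance on k(n-1) df
  B <- 1e5
  m <- matrix(rnorm(B * k, sd = 1 / sqrt(n)), ncol = k)
  s2 <- rchisq(B, df = k * (n - 1)) / (k * (n - 1))
  q_null <- (apply(m, 1, max) - apply(m, 1, min)) / sqrt(s2 / n)

  pairs <- utils::combn(k, 2)
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    q_obs <- abs(means[i] - means[j]) / sqrt(mse / n)
    p_mc <- mean(q_null >= q_obs)
    se <- sqrt(max(p_mc * (1 - p_mc), 1e-6) / B)
    row <- tk$p_adj[tk$pair == paste0("g", j, "-g", i)]
    expect_lt(abs(row - p_mc), max(3 * se, 0.004))
  }
})

test_that("JZS Bayes factor favors the null at t = 0 and grows with |t|", {
  expect_lt(jzs_bf_from_t(0, 19), 1)
  bfs <- vapply(seq(0, 4, by = 0.5), jzs_bf_from_t, 0, n = 19)
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf(rep(2, 5)), "zero variance")
  expect_error(jzs_bf(2), "at least 2")
})

test_that("JZS Bayes factor matches the independent quadrature oracle", {
  for (t in -3:3) {
    for (n in c(10, 19, 50)) {
      got <- jzs_bf_from_t(t, n)
      want <- jzs_oracle(t, n)
      expect_equal(got, want, tolerance = 1e-4)   # 4 significant figures
    }
  }
  # and through the data interface
  x <- c(0.5, 0.1, 0.9, 0.4, 0.2, 0.8, -0.1, 0.6)
  bf <- jzs_bf(x)
  t <- mean(x) / (sd(x) / sqrt(length(x)))
  expect_equal(bf$bf10, jzs_oracle(t, length(x)), tolerance = 1e-4)
  expect_identical(bf$n, 8L)
})

test_that("JZS Bayes factor is consistent under null and effect data", {
  set.seed(17)
  null_bfs <- vapply(1:500, function(k) jzs_bf(rnorm(19))$bf10, 0)
  expect_lt(stats::median(null_bfs), 1)
  eff_bfs <- vapply(1:200, function(k) jzs_bf(rnorm(19, mean = 1))$bf10, 0)
  expect_gt(stats::median(eff_bfs), 3)
})

test_that("evidence labels follow the conventional bands on either side", {
  expect_identical(bf_label(0.279), "moderate evidence for the null")
  expect_identical(bf_label(0.248), "moderate evidence for the null")
  expect_identical(bf_label(0.355), "anecdotal evidence for the null")
  expect_identical(bf_label(20.8), "strong evidence for the alternative")
  expect_identical(bf_label(0.561), "anecdotal evidence for the null")
  expect_identical(bf_label(5), "moderate evidence for the alternative")
})

test_that("contrast_report assembles estimate, CI, t-test and Bayes factor", {
  set.seed(18)
  x <- rnorm(19, mean = 0.02, sd = 0.1)
  rep <- contrast_report(x, n_boot = 999, seed = 19)
  expect_equal(rep$estimate, mean(x))
  expect_lt(rep$ci[1], rep$estimate)
  expect_gt(rep$ci[2], rep$estimate)
  tt <- stats::t.test(x)
  expect_equal(rep$t, unname(tt$statistic))
  expect_equal(rep$p, tt$p.value)
  expect_identical(rep$n, 19L)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(detection = rep), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$detection$bf10, rep$bf10)
})
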