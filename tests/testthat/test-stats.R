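test_that("normality gate routes by per-sample Shapiro-Wilk results", {
  # tiny samples cannot be tested and force the non-parametric route
  g <- normality_gate(list(a = c(1, 2), b = rnorm(20)))
  expect_equal(g$route, "nonparametric")
  expect_true(is.na(g$normality_p[["a"]]))

  # zero-variance samples too
  g <- normality_gate(list(a = rep(1, 10), b = rnorm(20)))
  expect_equal(g$route, "nonparametric")

  expect_error(normality_gate(list(a = numeric(0), b = rnorm(5))),
               "at least one")
  expect_error(normality_gate(list(a = rnorm(5)), alpha = 1.5), "alpha")
})

test_that("the gate accepts normal data and rejects heavy skew", {
  # 3 normal samples of n=50: parametric in the large majority of seeds
  # (expected non-parametric fraction ~ 1 - 0.95^3 ~ 14% under the null)
  set.seed(42)
  routes <- replicate(100, {
    normality_gate(list(a = rnorm(50), b = rnorm(50), c = rnorm(50)))$route
  })
  expect_gt(mean(routes == "parametric"), 0.7)

  # one heavily right-skewed sample (squared exponential) flips the route:
  # Shapiro-Wilk power at this n and skew is essentially 1
  set.seed(43)
  routes <- replicate(50, {
    normality_gate(list(a = rnorm(50), b = rexp(50)^2))$route
  })
  expect_gte(mean(routes == "nonparametric"), 0.95)
})

test_that("omnibus test dispatches to ANOVA or Kruskal-Wallis", {
  # identical rank patterns: H = 0, p = 1
  o <- omnibus_test(list(a = c(1, 2, 3), b = c(1, 2, 3)), "nonparametric")
  expect_equal(o$name, "Kruskal-Wallis H")
  expect_equal(o$statistic, 0)
  expect_equal(o$p, 1)

  expect_error(omnibus_test(list(a = rep(2, 5), b = rep(2, 5)), "parametric"),
               "degenerate")
  expect_error(omnibus_test(list(a = rnorm(5)), "parametric"), "at least 2")

  # a +10 SD shift is detected with near-certain power on both routes
  set.seed(7)
  smp <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30) + 10)
  expect_lt(omnibus_test(smp, "parametric")$p, 0.001)
  expect_lt(omnibus_test(smp, "nonparametric")$p, 0.001)
  expect_equal(omnibus_test(smp, "parametric")$name, "one-way ANOVA")
})

test_that("two-group Kruskal-Wallis equals the squared standardised rank sum", {
  set.seed(99)
  x <- rnorm(8); y <- rnorm(11) + 0.5  # tie-free
  H <- omnibus_test(list(a = x, b = y), "nonparametric")$statistic
  # oracle: z-standardised Wilcoxon rank-sum statistic, no continuity corr.
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  W <- sum(rank(c(x, y))[1:n1])
  z <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-12)
})

test_that("Kruskal-Wallis is invariant under strictly increasing transforms", {
  set.seed(123)
  smp <- list(a = rexp(20), b = rexp(20) * 2, c = rexp(20))
  h0 <- omnibus_test(smp, "nonparametric")
  h1 <- omnibus_test(lapply(smp, function(v) log(v + 1)), "nonparametric")
  h2 <- omnibus_test(lapply(smp, function(v) v^3), "nonparametric")
  expect_equal(h1$statistic, h0$statistic)
  expect_equal(h2$p, h0$p)
})

test_that("exact Mann-Whitney p matches full permutation enumeration", {
  set.seed(55)
  x <- round(rnorm(6, 0, 2), 3); y <- round(rnorm(6, 1, 2), 3)
  stopifnot(!any(duplicated(c(x, y))))
  ph <- posthoc_pairwise(list(gx = x, gy = y), "nonparametric")
  # oracle: enumerate all choose(12,6) group assignments of the pooled
  # values; two-sided p by the doubling convention
  pool <- c(x, y); n <- 6
  idx <- utils::combn(12, n)
  r <- rank(pool)
  Us <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  u_obs <- sum(r[1:6]) - n * (n + 1) / 2
  p_exact <- min(1, 2 * min(mean(Us <= u_obs), mean(Us >= u_obs)))
  expect_equal(ph$raw_p, p_exact, tolerance = 1e-12)
})

test_that("post hoc comparisons honour reference mode and Bonferroni", {
  set.seed(31)
  smp <- setNames(lapply(1:6, function(i) rnorm(25, mean = i / 4)),
                  paste0("g", 1:6))
  all_pairs <- posthoc_pairwise(smp, "nonparametric")
  expect_equal(nrow(all_pairs), 15)
  expect_equal(attr(all_pairs, "m_comparisons"), 15)

  ref <- posthoc_pairwise(smp, "nonparametric", reference = "g6")
  expect_equal(nrow(ref), 5)
  expect_equal(attr(ref, "m_comparisons"), 5)
  expect_true(all(ref$label_b == "g6"))
  expect_true(all(ref$adjusted_p >= ref$raw_p - 1e-15))
  expect_true(all(ref$adjusted_p <= 1))
  # Bonferroni is min(1, m * raw): a raw p of 0.3 with m = 5 caps at 1
  expect_equal(pmin(1, 5 * ref$raw_p), ref$adjusted_p)

  expect_error(posthoc_pairwise(smp, "nonparametric", reference = "nope"),
               "reference label")

  # parametric route: Tukey family-wise p, still monotone vs raw
  tk <- posthoc_pairwise(smp, "parametric")
  expect_equal(nrow(tk), 15)
  expect_true(all(tk$adjusted_p >= tk$raw_p - 1e-12))

  # identical groups give p ~ 1 before and after adjustment
  same <- posthoc_pairwise(list(a = 1:20 + 0.5, b = 1:20 + 0.4),
                           "nonparametric")
  expect_gt(same$raw_p, 0.5)
  expect_gte(same$adjusted_p, same$raw_p)
})

test_that("asterisk labels use strict boundaries", {
  expect_equal(significance_label(c(0.0005, 0.005, 0.02, 0.05, 0.5)),
               c("***", "**", "*", "ns", "ns"))
  expect_equal(significance_label(c(0.001, 0.01)), c("**", "*"))
  expect_error(significance_label(1.2), "\\[0, 1\\]")
  expect_error(significance_label(-0.1), "\\[0, 1\\]")
})

test_that("compare_samples composes gate, omnibus and gated post hoc", {
  set.seed(2024)
  smp <- list(a = rexp(60), b = rexp(60) + 2, c = rexp(60))
  cmp <- compare_samples(smp, reference = "a")
  expect_s3_class(cmp, "binding_comparison")
  expect_equal(cmp$route, "nonparametric")
  expect_lt(cmp$omnibus_p, 0.05)
  expect_equal(nrow(cmp$pairwise), 2)
  expect_true(all(cmp$pairwise$label_b == "a"))
  expect_false(cmp$posthoc_forced)

  # null data: post hoc not run unless forced, and then flagged
  set.seed(3030)
  null_smp <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  cmp0 <- compare_samples(null_smp, alpha = 1e-6)
  expect_null(cmp0$pairwise)
  expect_false(cmp0$posthoc_run)
  cmpf <- compare_samples(null_smp, alpha = 1e-6, force_posthoc = TRUE)
  expect_true(cmpf$posthoc_forced)
  expect_equal(nrow(cmpf$pairwise), 3)

  expect_error(compare_samples(list(a = rnorm(5))), "at least 2")
  expect_error(compare_samples(list(a = rnorm(5), a = rnorm(5))),
               "duplicate sample labels")
})

test_that("two-sample comparison agrees with its own pairwise conclusion", {
  set.seed(88)
  x <- rexp(40); y <- rexp(40) + 3
  cmp <- compare_samples(list(a = x, b = y))
  expect_equal(nrow(cmp$pairwise), 1)
  # omnibus and the single pairwise test must point the same way
  expect_equal(cmp$omnibus_p < 0.05, cmp$pairwise$adjusted_p < 0.05)
  same <- compare_samples(list(a = x, b = x + 1e-9))
  expect_gt(same$omnibus_p, 0.05)
})

test_that("comparison reports serialise to JSON and TSV", {
  dir <- withr::local_tempdir()
  set.seed(5)
  cmp <- compare_samples(list(a = rexp(30), b = rexp(30) + 1), reference = "a")
  jp <- file.path(dir, "report.json"); tp <- file.path(dir, "report.tsv")
  write_comparison(cmp, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$omnibus_p, cmp$omnibus_p)
  expect_equal(back$route, cmp$route)
  tsv <- readr::read_tsv(tp, show_col_types = FALSE)
  expect_equal(tsv$adjusted_p, cmp$pairwise$adjusted_p)
})
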