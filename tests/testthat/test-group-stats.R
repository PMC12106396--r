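test_that("the selection rule picks the branch the assumptions support", {
  # heavy ties from a 2-point distribution fail the normality check
  ties <- list(a = c(1, 1, 2, 2, 1, 2, 1, 1), b = c(2, 2, 1, 1, 2, 1, 2, 2))
  expect_identical(choose_test(ties)$chosen, "nonparametric")
  # constant groups: zero variance, warning, nonparametric branch
  expect_warning(d <- choose_test(list(a = rep(1, 5), b = rep(1, 5))),
                 "zero variance")
  expect_identical(d$chosen, "nonparametric")
  expect_error(choose_test(list(a = 1, b = c(1, 2))), "at least 2")
  expect_error(choose_test(list(a = c(1, 2))), "2 groups")
})

test_that("under a common normal the parametric branch is chosen at the rate the checks imply", {
  # four independent checks at alpha = 0.05 (three Shapiro-Wilk, one
  # Levene) pass jointly with probability near 0.95^4 = 0.81
  hits <- vapply(1:100, function(s) {
    g <- withr::with_seed(s, list(a = rnorm(50), b = rnorm(50), c = rnorm(50)))
    choose_test(g)$chosen == "parametric"
  }, logical(1))
  expect_gte(mean(hits), 0.70)
  expect_lte(mean(hits), 0.93)
})

test_that("identical groups give null statistics in both branches", {
  cmp <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(cmp$nonparametric$p, 1)
  expect_equal(cmp$parametric$statistic, 0)
  expect_equal(cmp$parametric$p, 1)
  # Kruskal-Wallis on identical groups: H = 0, p = 1
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(unname(kw$statistic), 0)
  expect_equal(kw$p, 1)
})

test_that("exact Wilcoxon p equals full enumeration of rank assignments", {
  # {1,2} vs {3,4}: 6 assignments, extreme rank sum on both tails
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p, 1 / 3,
               tolerance = 1e-12)
  # spot-checks against a combn enumeration oracle
  enum_p <- function(x, y) {
    pooled <- c(x, y); n <- length(x)
    r <- rank(pooled)
    obs <- sum(r[seq_len(n)])
    all_sums <- apply(utils::combn(length(pooled), n), 2,
                      function(i) sum(r[i]))
    mu <- n * (length(pooled) + 1) / 2
    mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-9)
  }
  for (seed in 1:6) {
    x <- withr::with_seed(seed, sample(100, 4))
    y <- withr::with_seed(seed + 50, sample(200, 5))
    got <- wilcoxon_rank_sum(x, y)
    expect_true(got$exact)
    expect_equal(got$p, enum_p(x, y), tolerance = 1e-12,
                 label = sprintf("seed %d", seed))
  }
  # ties disable the exact path but still return a valid p
  res <- wilcoxon_rank_sum(c(1, 1, 2), c(2, 3, 3))
  expect_false(res$exact)
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("exact Kruskal-Wallis enumeration matches a hand-computed case", {
  # perfectly separated groups: only the 3! block orderings reach max H
  s <- list(a = c(1, 2), b = c(10, 20), c = c(100, 200))
  kw <- kruskal_wallis(s)
  expect_true(kw$exact)
  expect_equal(kw$p, 6 / 90, tolerance = 1e-12)  # 6!/(2!2!2!) = 90
  # large groups fall back to the chi-squared approximation
  big <- withr::with_seed(2, list(a = rnorm(30), b = rnorm(30),
                                  c = rnorm(30)))
  expect_false(kruskal_wallis(big)$exact)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  s <- withr::with_seed(8, list(a = rnorm(6), b = rnorm(6) + 1, c = rnorm(6)))
  f <- function(v) exp(3 * v) + 5
  kw1 <- kruskal_wallis(s)
  kw2 <- kruskal_wallis(lapply(s, f))
  expect_equal(kw2$statistic, kw1$statistic, tolerance = 1e-12)
  expect_equal(kw2$p, kw1$p, tolerance = 1e-12)
  w1 <- wilcoxon_rank_sum(s$a, s$b)
  w2 <- wilcoxon_rank_sum(f(s$a), f(s$b))
  expect_equal(w2$p, w1$p, tolerance = 1e-12)
})

test_that("both branches are always reported side by side", {
  s <- withr::with_seed(21, list(n = rnorm(4, 10), o = rnorm(4, 10.5),
                                 c = rnorm(4, 11)))
  cmp <- compare_groups(s)
  expect_named(cmp$parametric, c("method", "statistic", "p"))
  expect_true(all(c("method", "statistic", "p") %in% names(cmp$nonparametric)))
  expect_match(cmp$parametric$method, "ANOVA")
  expect_match(cmp$nonparametric$method, "Kruskal")
  expect_true(cmp$chosen %in% c("parametric", "nonparametric"))
  expect_true(all(vapply(cmp$assumptions$normality_p, is.numeric, TRUE)))
  # pairwise runs reuse the same rule, uncorrected
  pw <- compare_groups_pairwise(s)
  expect_length(pw, 3)
  expect_named(pw, c("n vs o", "n vs c", "o vs c"))
  expect_match(pw[[1]]$parametric$method, "t-test")
})
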