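# ROC/AUC, Youden, stratification, chi-square, rank tests, ratios,
# dichotomization and logistic regression — each against closed forms or
# exhaustive oracles.

test_that("roc_curve: separation, null behaviour, pair-enumeration oracle", {
  r <- roc_curve(c(1, 2, 9, 10), c("PR", "PR", "CR", "CR"))
  expect_equal(r$auc, 1)
  expect_true(r$auc >= r$auc_ci95[1] && r$auc <= r$auc_ci95[2])

  set.seed(12)
  n <- 2000
  sc <- rnorm(n); y <- rbinom(n, 1, 0.5)
  rn <- roc_curve(sc, y)
  se <- sqrt((n / 2 + 1) / 12 / (n / 2)^2) * sqrt(2)   # rough null AUC se
  expect_lt(abs(rn$auc - 0.5), 3 * max(se, 0.02))

  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    s10 <- sample(1:5, 10, replace = TRUE)            # forced ties
    y10 <- rbinom(10, 1, 0.5)
    if (length(unique(y10)) < 2) y10[1:2] <- c(0, 1)
    expect_equal(roc_curve(s10, y10)$auc, oracle_auc(s10, y10))
  }
  expect_error(roc_curve(c(1, 2), c("CR", "CR")), "both classes")
  expect_error(roc_curve(c(1, Inf), c("CR", "PR")), "non-finite")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(44)
  sc <- rnorm(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  a1 <- roc_curve(sc, y)$auc
  expect_equal(roc_curve(exp(sc), y)$auc, a1)
  expect_equal(roc_curve(2 * sc - 7, y)$auc, a1)
})

test_that("youden_cutoff: toy example, tie rule, exhaustive-search oracle", {
  r <- roc_curve(c(0.1, 0.2, 0.8, 0.9), c("PR", "PR", "CR", "CR"))
  cut <- youden_cutoff(r)
  expect_equal(as.numeric(cut), 0.8)            # highest attainable threshold
  expect_equal(attr(cut, "youden_j"), 1)

  expect_warning(
    cut2 <- youden_cutoff(roc_curve(c(3, 2, 1, 0), c("PR", "PR", "CR", "CR"))),
    "not positive")

  for (seed in c(91, 92, 93)) {
    set.seed(seed)
    sc <- round(rnorm(20), 1); y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    cut <- suppressWarnings(youden_cutoff(roc_curve(sc, y)))
    expect_equal(attr(cut, "youden_j"), oracle_max_youden(sc, y))
    # stratifying at the returned cutoff attains the maximal J
    rep <- stratify_and_test(sc, y, as.numeric(cut))
    expect_equal(rep$sensitivity + rep$specificity - 1,
                 oracle_max_youden(sc, y))
  }
})

test_that("published immune 2x2: sens 0.882, spec 0.769, chi2 13.03, p<0.001", {
  # reconstruct scores that produce the printed table at cutoff 0.307
  scores <- c(rep(0.1, 2), rep(0.2, 10), rep(0.8, 15), rep(0.9, 3))
  labels <- c(rep("CR", 2), rep("PR", 10), rep("CR", 15), rep("PR", 3))
  rep <- stratify_and_test(scores, labels, 0.307)
  expect_identical(unclass(rep$table),
                   unclass(two_by_two(2, 10, 15, 3)))
  expect_equal(round(rep$sensitivity, 3), 0.882)
  expect_equal(round(rep$specificity, 3), 0.769)
  expect_equal(rep$chi2, 13.03, tolerance = 5e-4)
  expect_lt(rep$p, 0.001)
  expect_identical(unname(rep$cr_rate_percent), c(17, 83))
})

test_that("chi_square_2x2: independence, hand value, algebraic oracle", {
  expect_equal(chi_square_2x2(two_by_two(10, 10, 10, 10))$statistic, 0)
  expect_equal(chi_square_2x2(two_by_two(10, 10, 10, 10))$p, 1)
  h <- chi_square_2x2(two_by_two(10, 2, 3, 15))
  expect_equal(h$statistic, 13.03, tolerance = 5e-4)
  expect_error(chi_square_2x2(two_by_two(0, 0, 3, 5)), "zero margin")
  # (ad - bc)^2 N / margins identity on random tables
  set.seed(19)
  for (i in 1:1000) {
    m <- matrix(rpois(4, 8) + 1, 2)
    stat <- chi_square_2x2(m)$statistic
    alg <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 * sum(m) /
      prod(rowSums(m)) / prod(colSums(m))
    expect_equal(stat, alg, tolerance = 1e-9)
  }
  # Yates correction available behind the flag
  y <- chi_square_2x2(two_by_two(7, 12, 10, 1), correct = TRUE)
  expect_lt(chi_square_2x2(two_by_two(7, 12, 10, 1))$statistic - y$statistic,
            10)
  expect_gt(y$p, chi_square_2x2(two_by_two(7, 12, 10, 1))$p)
})

test_that("rank_sum_test: identity, exact small-sample oracle, invariance", {
  x <- c(1, 2, 3, 4)
  expect_gte(rank_sum_test(x, x)$p, 0.99)
  # complete separation at n = m = 4: exact two-sided p = 2 / C(8,4)
  sep <- rank_sum_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(sep$p, 2 / choose(8, 4), tolerance = 1e-12)
  # monotone-transform invariance
  set.seed(55)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  expect_equal(rank_sum_test(a, b)$p, rank_sum_test(exp(a), exp(b))$p)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("hematological ratios and dichotomization behave per contract", {
  rec <- list(plt_baseline = 200, anc_baseline = 4, amc_baseline = 0.5,
              alc_baseline = 2, plt_10f = 170, anc_10f = 3.6,
              amc_10f = 0.45, alc_10f = 1)
  r <- hematological_ratios(rec, "baseline")
  expect_equal(unname(r), c(2, 50, 100, 4))
  # reciprocal identity
  expect_equal(r[["lmr"]] * (rec$amc_baseline / rec$alc_baseline), 1)
  rec$alc_10f <- 0
  r2 <- hematological_ratios(rec, "10f")
  expect_true(is.na(r2[["nlr"]]) && is.na(r2[["plr"]]))
  expect_false(is.na(r2[["pnr"]]))

  set.seed(66)
  y <- rbinom(100, 1, 0.5)
  cov <- data.frame(good = y + rnorm(100, 0, 0.2), flat = rep(1, 100))
  expect_warning(d <- dichotomize_covariates(cov, y), "flat")
  expect_false("flat" %in% names(d))
  expect_gt(mean(d$good$high == (y == 1)), 0.9)
  # boundary convention: value >= cutoff => high
  v <- cov$good
  expect_identical(d$good$high, v >= d$good$cutoff)
})

test_that("logistic_regression: OR identity, intercept-only, coverage", {
  # binary covariate: OR equals the 2x2 cross-product ratio ad/bc
  g <- rep(c(0, 1), c(16, 14))
  y <- c(rep(1, 4), rep(0, 12), rep(1, 10), rep(0, 4))
  fit <- logistic_regression(data.frame(g = g), y, multivariate = NULL)
  expect_equal(fit$univariate$or, (10 * 12) / (4 * 4), tolerance = 1e-6)

  # intercept-only: predicted probability = prevalence
  m0 <- glm(y ~ 1, family = binomial)
  expect_equal(unique(round(fitted(m0), 10)), round(mean(y), 10))

  # 95% CI covers OR = 1 for a null covariate about 95% of the time
  set.seed(99)
  cover <- 0
  for (i in 1:200) {
    yy <- rbinom(120, 1, 0.5)
    xx <- rnorm(120)
    u <- logistic_regression(data.frame(x = xx), yy,
                             multivariate = NULL)$univariate
    if (u$ci_lo <= 1 && u$ci_hi >= 1) cover <- cover + 1
  }
  expect_gt(cover / 200, 0.90)
  expect_lt(cover / 200, 0.99)
})
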