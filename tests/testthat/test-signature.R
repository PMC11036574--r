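# Reference immune score, normalization, screening, LASSO-CV behaviour and
# the classifier builders.

test_that("reference immune-score model is pinned and linear", {
  m <- immune_score_model()
  expect_identical(m$intercept, 0.4569)
  expect_identical(m$coef_delta_cd8, 0.0041)
  expect_identical(m$coef_delta_cd68, -0.0009)
  expect_identical(m$cutoff, 0.307)

  expect_equal(immune_score(0, 0), 0.4569)
  expect_equal(immune_score(100, 100), 0.7769)
  # algebraic inversion: the dCD8 putting the score exactly at the cutoff
  d8 <- (0.307 - 0.4569) / 0.0041
  expect_equal(immune_score(d8, 0), 0.307)
  expect_error(immune_score(NA, 0), "finite")
})

test_that("zscore_normalize: hand example, idempotence, constant columns", {
  z <- zscore_normalize(data.frame(a = c(1, 2, 3)))
  expect_equal(z$table$a, c(-1, 0, 1))           # sample sd = 1
  expect_equal(z$params$mean, 2)
  expect_equal(z$params$sd, 1)
  # population-vs-sample check on a column with sd != 1
  z2 <- zscore_normalize(data.frame(a = c(0, 10, 20)))
  expect_equal(sd(z2$table$a), 1, tolerance = 1e-12)
  expect_equal(mean(z2$table$a), 0, tolerance = 1e-12)
  # already-normalized input passes through unchanged
  z3 <- zscore_normalize(z2$table)
  expect_equal(z3$table$a, z2$table$a, tolerance = 1e-9)
  expect_warning(zscore_normalize(data.frame(a = 1:5, b = rep(2, 5))), "\\bb\\b")
  expect_error(zscore_normalize(data.frame(a = 1)), "single-row")
})

test_that("univariate screening: signal retained, boundary alpha, calibration", {
  set.seed(14)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  strong <- y + rnorm(n, 0, 0.1)
  noise <- rnorm(n)
  scr <- univariate_screen(data.frame(strong = strong, noise = noise), y)
  expect_true("strong" %in% scr$retained)
  # alpha = 1 retains everything
  scr1 <- univariate_screen(data.frame(a = rnorm(n), b = rnorm(n)), y, alpha = 1)
  expect_identical(sort(scr1$retained), c("a", "b"))
  expect_error(univariate_screen(data.frame(a = rnorm(4)), rep(1, 4)),
               "both classes")
  # type-I calibration: ~alpha of 300 pure-noise features retained
  set.seed(15)
  noise_tab <- as.data.frame(matrix(rnorm(n * 300), n, 300))
  rate <- length(univariate_screen(noise_tab, y, alpha = 0.2)$retained) / 300
  expect_lt(abs(rate - 0.2), 0.08)
})

test_that("LASSO limits: full shrinkage and the unpenalized oracle", {
  set.seed(3)
  n <- 300
  x <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(x) <- paste0("f", 1:4)
  y <- rbinom(n, 1, plogis(0.5 * x$f1 - 0.8 * x$f3))
  # huge lambda: all coefficients zero, intercept = log-odds of prevalence
  m_big <- fit_lasso_cv(x, y, lambda_grid = c(50, 40), seed = 1)
  expect_length(m_big$coefficients, 0L)
  expect_equal(m_big$intercept, qlogis(mean(y)), tolerance = 1e-6)
  # lambda -> 0: matches glm to 1e-3 (grid entirely near zero so that the
  # CV choice cannot move away from the unpenalized limit)
  m_small <- fit_lasso_cv(x, y, lambda_grid = c(2e-6, 1e-6), seed = 1)
  ref <- glm(y ~ ., data = x, family = binomial)
  expect_equal(unname(m_small$coefficients[paste0("f", 1:4)]),
               unname(coef(ref)[-1]), tolerance = 1e-3)
  expect_equal(m_small$intercept, unname(coef(ref)[1]), tolerance = 1e-3)
})

test_that("CV folds are stratified, exhaustive and seed-reproducible", {
  y <- rep(c(0, 1), c(30, 20))
  f1 <- radimmune:::.stratified_folds(y, 10L, seed = 4)
  f2 <- radimmune:::.stratified_folds(y, 10L, seed = 4)
  expect_identical(f1, f2)
  expect_identical(sort(unique(f1)), 1:10)
  for (k in 1:10) expect_identical(sort(unique(y[f1 == k])), c(0, 1))
  expect_identical(length(f1), 50L)              # every row in exactly one fold
})

test_that("same seed gives identical lambda* and support; scoring is affine", {
  set.seed(6)
  n <- 120
  x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- paste0("f", 1:8)
  y <- rbinom(n, 1, plogis(1.5 * x$f2))
  a <- fit_lasso_cv(x, y, seed = 11)
  b <- fit_lasso_cv(x, y, seed = 11)
  expect_identical(a$lambda, b$lambda)
  expect_identical(names(a$coefficients), names(b$coefficients))

  # affine scoring through stored normalization: slope = coef / sd per unit
  z <- zscore_normalize(x)
  m <- fit_lasso_cv(z$table, y, seed = 11, normalization_params = z$params)
  if (length(m$coefficients)) {
    f <- names(m$coefficients)[1]
    row <- x[1, , drop = FALSE]
    row2 <- row; row2[[f]] <- row2[[f]] + 2
    sds <- setNames(z$params$sd, z$params$feature)
    expect_equal(signature_score(m, row2) - signature_score(m, row),
                 2 * unname(m$coefficients[f]) / unname(sds[f]),
                 tolerance = 1e-9)
  }
})

test_that("fold-safe CV renormalizes per fold without changing the contract", {
  set.seed(26)
  n <- 100
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- paste0("f", 1:6)
  y <- rbinom(n, 1, plogis(1.5 * x$f1))
  z <- zscore_normalize(x)
  m <- fit_lasso_cv(z$table, y, seed = 7, fold_safe = TRUE,
                    normalization_params = z$params)
  expect_s3_class(m, "signature_model")
  expect_true(is.finite(m$lambda))
  expect_identical(nrow(m$cv_deviance_path), 100L)
  # same-seed determinism holds in fold-safe mode too
  m2 <- fit_lasso_cv(z$table, y, seed = 7, fold_safe = TRUE,
                     normalization_params = z$params)
  expect_identical(m$lambda, m2$lambda)
})

test_that("immunomarker classifier: sign recovery and de-normalized identity", {
  tab <- marker_cohort(300, seed = 51)
  m <- suppressWarnings(build_immunomarker_classifier(tab, seed = 2))
  expect_s3_class(m, "signature_model")
  raw <- m$formula_raw
  expect_gt(raw$coefficients[["delta_cd8"]], 0)
  if ("delta_cd68" %in% names(raw$coefficients))
    expect_lt(raw$coefficients[["delta_cd68"]], 0)
  # de-normalized formula reproduces the model score on training rows
  deltas <- marker_deltas(tab)
  direct <- raw$intercept +
    as.matrix(deltas[, names(raw$coefficients), drop = FALSE]) %*%
    raw$coefficients
  expect_equal(as.numeric(direct), signature_score(m, deltas), tolerance = 1e-9)
})

test_that("labels independent of markers give a near-null model", {
  # Minimum-criteria CV-lambda rarely lands exactly at full shrinkage (the
  # deviance path is flat-noisy near the null), so the honest null property
  # is a tiny support — median 1 of 13 markers, with exact zeros occurring —
  # rather than an all-zero model in the majority of runs (measured 9/30).
  sizes <- integer(0)
  for (s in 1:10) {
    set.seed(600 + s)
    tab <- marker_cohort(150, seed = 700 + s)
    tab$response <- sample(c("CR", "PR"), 150, replace = TRUE)  # severed link
    m <- suppressWarnings(build_immunomarker_classifier(tab, seed = s))
    sizes <- c(sizes, length(m$coefficients))
  }
  expect_lte(median(sizes), 2)
  expect_gte(sum(sizes == 0L), 1L)
  expect_lte(max(sizes), 6L)
})

test_that("radiomics signature builder: determinism and permutation null", {
  set.seed(77)
  n <- 80
  ft <- as.data.frame(matrix(rnorm(n * 30), n, 30))
  names(ft) <- sprintf("feat%02d", 1:30)
  cls <- rbinom(n, 1, plogis(2 * ft$feat01 - 2 * ft$feat02))
  m1 <- suppressWarnings(build_radiomics_signature(ft, cls, seed = 5))
  m2 <- suppressWarnings(build_radiomics_signature(ft, cls, seed = 5))
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(names(m1$coefficients), names(m2$coefficients))
  expect_lte(length(m1$coefficients), m1$n_screened)

  # permuted labels: CV deviance at lambda* no better than intercept-only
  set.seed(78)
  yperm <- sample(cls)
  mp <- suppressWarnings(build_radiomics_signature(ft, yperm, seed = 5))
  p0 <- mean(yperm)
  dev0 <- -2 * mean(yperm * log(p0) + (1 - yperm) * log(1 - p0))
  dev_star <- min(mp$cv_deviance_path$deviance)
  expect_gt(dev_star, dev0 - 0.15)               # within noise of the null
})

test_that("signature model JSON round trip preserves scoring", {
  tab <- marker_cohort(100, seed = 61)
  m <- suppressWarnings(build_immunomarker_classifier(tab, seed = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_signature_model(m, f)
  m2 <- read_signature_model(f)
  deltas <- marker_deltas(tab)
  expect_equal(signature_score(m2, deltas), signature_score(m, deltas),
               tolerance = 1e-12)
  expect_equal(m2$lambda, m$lambda)
})
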