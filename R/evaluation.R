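# Evaluation arithmetic: ROC / AUC with DeLong confidence intervals, Youden
# cutoffs, score-group stratification with Pearson chi-square, rank tests,
# hematological ratios and covariate dichotomization, and the univariate /
# multivariate logistic-regression table.
#
# Conventions: CR is the positive class; a patient is called positive (high)
# when score >= cutoff; Pearson chi-square is uncorrected by default (the
# published group-comparison p-values match the uncorrected statistic, not the
# Yates-corrected one).

#' Empirical ROC curve with AUC and DeLong 95% CI
#'
#' Thresholds are the distinct observed scores (plus -Inf); sensitivity and
#' specificity use the `score >= threshold => positive` convention. AUC is the
#' Mann-Whitney statistic (ties count 1/2), identical to the trapezoidal area.
#' The 95% CI is DeLong's by default, or a percentile bootstrap.
#'
#' @param scores Numeric scores, higher = more CR-like.
#' @param labels Binary labels; `"CR"` (or `TRUE`/1) is positive.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return `roc_curve` object: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `auc_ci95`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                      n_boot = 2000L) {
  ci_method <- match.arg(ci_method)
  if (!all(is.finite(scores))) stop("non-finite scores")
  y <- .as_binary(labels)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) stop("labels must contain both classes")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1L) / npos, 0)
  spec <- vapply(thr, function(t) sum(scores < t & y == 0L) / nneg, 0)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  # Mann-Whitney with ties = 1/2 (placement values; also used by DeLong)
  v_pos <- vapply(pos, function(s) (sum(s > neg) + 0.5 * sum(s == neg)) / nneg, 0)
  v_neg <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / npos, 0)
  auc <- mean(v_pos)
  ci <- if (ci_method == "delong") {
    se <- sqrt(stats::var(v_pos) / npos + stats::var(v_neg) / nneg)
    auc + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    bs <- replicate(n_boot, {
      i <- sample(length(scores), replace = TRUE)
      yi <- y[i]
      if (length(unique(yi)) < 2L) return(NA_real_)
      p <- scores[i][yi == 1L]; q <- scores[i][yi == 0L]
      mean(vapply(p, function(s) (sum(s > q) + 0.5 * sum(s == q)) / length(q), 0))
    })
    unname(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_ci95 = ci, n_pos = npos, n_neg = nneg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg>\n",
              x$auc, x$auc_ci95[1L], x$auc_ci95[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' The attainable threshold maximizing sensitivity + specificity - 1; ties are
#' broken toward the higher threshold. A non-positive maximal J (anti- or
#' non-predictive scores) is returned with a warning.
#'
#' @param roc A [roc_curve()].
#' @return The cutoff (numeric scalar), with attribute `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  finite <- is.finite(roc$thresholds)
  j <- roc$sensitivity + roc$specificity - 1
  jf <- j[finite]; tf <- roc$thresholds[finite]
  best <- max(jf)
  cut <- max(tf[jf >= best - 1e-12])
  if (best <= 0) warning("maximal Youden J is not positive (J = ",
                         signif(best, 3), "); scores are not predictive")
  structure(cut, youden_j = best)
}

#' Two-by-two stratification table
#'
#' @param cr_low,pr_low,cr_high,pr_high Non-negative integer counts.
#' @return `two_by_two` object (matrix groups x outcomes).
#' @export
two_by_two <- function(cr_low, pr_low, cr_high, pr_high) {
  m <- matrix(c(cr_low, pr_low, cr_high, pr_high), nrow = 2L, byrow = TRUE,
              dimnames = list(group = c("low", "high"),
                              outcome = c("CR", "PR")))
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  structure(m, class = c("two_by_two", "matrix"))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson statistic `sum((O-E)^2 / E)` with df = 1 by default;
#' Yates continuity correction behind the `correct` flag.
#'
#' @param table A [two_by_two()] or plain 2x2 matrix of counts.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p`, `df`, `expected`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: zero margin")
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  d <- abs(m - e)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L, expected = e)
}

#' Stratify patients at a cutoff and test the association
#'
#' Groups patients at `score >= cutoff` (high) and tabulates against the CR/PR
#' outcome. Sensitivity is CR correctly called high over all CR; specificity
#' is PR correctly called low over all PR. The association test is the
#' (default uncorrected) Pearson chi-square; with an empty group the test is
#' undefined and reported as `NA` with a warning.
#'
#' @param scores Numeric scores.
#' @param labels CR/PR labels (CR positive).
#' @param cutoff Numeric threshold.
#' @param correct Yates correction flag, passed to [chi_square_2x2()].
#' @return `stratification_report`: `cutoff`, `table` ([two_by_two()]),
#'   `chi2`, `p`, `sensitivity`, `specificity`, `cr_rate` (per group),
#'   `cr_rate_percent` (half-up rounded display values).
#' @export
stratify_and_test <- function(scores, labels, cutoff, correct = FALSE) {
  y <- .as_binary(labels)
  high <- scores >= cutoff
  tab <- two_by_two(cr_low = sum(!high & y == 1L), pr_low = sum(!high & y == 0L),
                    cr_high = sum(high & y == 1L), pr_high = sum(high & y == 0L))
  chi <- if (any(rowSums(tab) == 0)) {
    warning("empty score group: chi-square undefined")
    list(statistic = NA_real_, p = NA_real_)
  } else chi_square_2x2(tab, correct = correct)
  sens <- tab["high", "CR"] / sum(tab[, "CR"])
  spec <- tab["low", "PR"] / sum(tab[, "PR"])
  cr_rate <- tab[, "CR"] / rowSums(tab)
  structure(list(cutoff = cutoff, table = tab,
                 chi2 = chi$statistic, p = chi$p,
                 sensitivity = sens, specificity = spec,
                 cr_rate = cr_rate,
                 cr_rate_percent = .round_half_up(100 * cr_rate)),
            class = "stratification_report")
}

# round-half-up (printed percentages like 83% use commercial rounding)
.round_half_up <- function(x) floor(x + 0.5)

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("<stratification at cutoff %.4g>\n", x$cutoff))
  print(unclass(x$table))
  cat(sprintf("sens %.3f  spec %.3f  chi2 %.3f  p %.4g\n",
              x$sensitivity, x$specificity, x$chi2, x$p))
  cat(sprintf("CR rate: low %d%%, high %d%%\n",
              x$cr_rate_percent[1L], x$cr_rate_percent[2L]))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Exact p when both samples are smaller than 50 and tie-free,
#' otherwise the normal approximation with continuity correction (the base-R
#' policy, documented here as this package's convention).
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (W) and `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Hematological ratios at a timepoint
#'
#' NLR = ANC/ALC, PNR = PLT/ANC, PLR = PLT/ALC, LMR = ALC/AMC. A zero
#' denominator flags the affected ratios as `NA`.
#'
#' @param record One-row data.frame (clinical schema) or a list with the
#'   blood-count fields.
#' @param timepoint `"baseline"` or `"10f"`.
#' @return Named numeric vector `c(nlr, pnr, plr, lmr)`.
#' @export
hematological_ratios <- function(record, timepoint = c("baseline", "10f")) {
  timepoint <- match.arg(timepoint)
  g <- function(stub) as.numeric(record[[paste0(stub, "_", timepoint)]])
  plt <- g("plt"); anc <- g("anc"); amc <- g("amc"); alc <- g("alc")
  safe <- function(num, den) if (is.na(den) || den <= 0) NA_real_ else num / den
  c(nlr = safe(anc, alc), pnr = safe(plt, anc),
    plr = safe(plt, alc), lmr = safe(alc, amc))
}

#' Dichotomize covariates at their Youden-optimal cutoffs
#'
#' For each covariate column: ROC against the outcome, Youden cutoff, then a
#' binary high/low assignment (`value >= cutoff => high`). Constant covariates
#' cannot be dichotomized and are skipped with a warning.
#'
#' @param covariates Numeric data.frame (patients x covariates).
#' @param labels CR/PR labels.
#' @return List per covariate: `cutoff`, `youden_j`, `high` (logical vector).
#' @export
dichotomize_covariates <- function(covariates, labels) {
  covs <- as.data.frame(covariates)
  out <- list()
  for (nm in names(covs)) {
    v <- covs[[nm]]
    if (length(unique(v)) < 2L) {
      warning("constant covariate skipped: ", nm)
      next
    }
    roc <- roc_curve(v, labels)
    cut <- suppressWarnings(youden_cutoff(roc))
    out[[nm]] <- list(cutoff = as.numeric(cut),
                      youden_j = attr(cut, "youden_j"),
                      high = v >= as.numeric(cut))
  }
  out
}

#' Univariate and multivariate logistic regression table
#'
#' Maximum-likelihood logistic fits with Wald odds ratios and 95% CIs: one
#' single-covariate model per column, plus one joint model over
#' `multivariate` (default: all covariates). Covariates with detected
#' separation are flagged and their CI reported as unbounded.
#'
#' @param design data.frame of covariates (numeric, logical or two-level).
#' @param labels CR/PR labels (CR = 1).
#' @param multivariate Character vector of columns for the joint fit, or
#'   `NULL` to skip it.
#' @return List with `univariate` (data.frame: covariate, or, ci_lo, ci_hi,
#'   p, separation) and `multivariate` (same shape, or `NULL`).
#' @export
logistic_regression <- function(design, labels, multivariate = names(design)) {
  y <- .as_binary(labels)
  x <- as.data.frame(design)
  row_of <- function(fit, keep) {
    sm <- summary(fit)$coefficients
    sep <- !fit$converged | any(abs(stats::coef(fit)[-1L]) > 15)
    rows <- sm[keep, , drop = FALSE]
    data.frame(covariate = rownames(rows),
               or = exp(rows[, 1L]),
               ci_lo = if (sep) 0 else exp(rows[, 1L] - 1.96 * rows[, 2L]),
               ci_hi = if (sep) Inf else exp(rows[, 1L] + 1.96 * rows[, 2L]),
               p = rows[, 4L],
               separation = sep, stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(names(x), function(nm) {
    fit <- suppressWarnings(stats::glm(y ~ ., data = x[, nm, drop = FALSE],
                                       family = stats::binomial()))
    row_of(fit, setdiff(rownames(summary(fit)$coefficients), "(Intercept)"))
  }))
  multi <- NULL
  if (!is.null(multivariate) && length(multivariate)) {
    fit <- suppressWarnings(stats::glm(y ~ ., data = x[, multivariate, drop = FALSE],
                                       family = stats::binomial()))
    multi <- row_of(fit, setdiff(rownames(summary(fit)$coefficients),
                                 "(Intercept)"))
  }
  list(univariate = uni, multivariate = multi)
}
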