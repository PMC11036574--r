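# Classifier construction: z-score normalization, univariate screening at
# p < 0.2, LASSO-penalized logistic regression with stratified ten-fold
# cross-validation — plus the fixed published immune-score reference model.
#
# Lambda selection uses the minimum mean cross-validated binomial deviance
# ("minimum criteria"), not the 1-SE rule; ties go to the largest (sparsest)
# lambda. Normalization uses full-cohort statistics before CV — faithful to
# the original analysis; the leakage is documented and `fold_safe = TRUE`
# renormalizes inside each training fold instead.

#' The fixed reference immune-score model
#'
#' The published linear model over the 10F-minus-baseline changes in
#' infiltrating CD8+ T cells and CD68+ macrophages, with its Youden-index
#' cutoff. These constants are never refit.
#'
#' @return List with `intercept` (0.4569), `coef_delta_cd8` (0.0041),
#'   `coef_delta_cd68` (-0.0009) and `cutoff` (0.307).
#' @export
immune_score_model <- function() {
  list(intercept = 0.4569, coef_delta_cd8 = 0.0041,
       coef_delta_cd68 = -0.0009, cutoff = 0.307)
}

#' Evaluate the reference immune score
#'
#' `0.4569 + 0.0041 * delta_cd8 - 0.0009 * delta_cd68`, a linear score (not a
#' probability): patients at or above 0.307 form the high-score
#' (immune-inflamed) group.
#'
#' @param delta_cd8 Change in CD8+ T-cell count (10F minus baseline).
#' @param delta_cd68 Change in CD68+ macrophage count (10F minus baseline).
#' @return Numeric score(s).
#' @export
immune_score <- function(delta_cd8, delta_cd68) {
  if (!all(is.finite(delta_cd8)) || !all(is.finite(delta_cd68)))
    stop("immune_score requires finite inputs")
  m <- immune_score_model()
  m$intercept + m$coef_delta_cd8 * delta_cd8 + m$coef_delta_cd68 * delta_cd68
}

#' Z-score normalize a feature table
#'
#' Centers every column to mean 0 and scales to sd 1 (sample sd, n-1
#' denominator). Constant columns cannot be scaled: they are dropped with a
#' warning naming them.
#'
#' @param table Numeric data.frame or matrix (patients x features).
#' @return List: `table` (normalized data.frame), `params` (data.frame with
#'   `feature`, `mean`, `sd` for every retained column).
#' @export
zscore_normalize <- function(table) {
  x <- as.data.frame(table)
  if (nrow(x) < 2L) stop("cannot normalize a single-row table")
  mu <- vapply(x, mean, 0)
  sd_ <- vapply(x, stats::sd, 0)
  const <- sd_ <= .Machine$double.eps * pmax(1, abs(mu))
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]; sd_ <- sd_[!const]
  }
  z <- as.data.frame(mapply(function(col, m, s) (col - m) / s, x, mu, sd_,
                            SIMPLIFY = FALSE))
  rownames(z) <- rownames(table)
  list(table = z,
       params = data.frame(feature = names(x), mean = unname(mu),
                           sd = unname(sd_), stringsAsFactors = FALSE))
}

#' Univariate screening of features
#'
#' Fits one single-predictor logistic regression per feature and keeps those
#' with Wald slope p-value below `alpha`. Features with (quasi-)perfect
#' separation have meaningless Wald p-values: they are retained with the
#' p-value flagged `NA` in `p_values` (a perfectly separating feature is the
#' strongest possible candidate, not a discard).
#'
#' @param table Numeric feature table (patients x features).
#' @param labels Binary labels (logical, 0/1, or a two-level factor; for
#'   character input `"CR"` is the positive class).
#' @param alpha Retention threshold on p (default 0.2).
#' @param test `"wald"` (default) or `"lrt"` (likelihood-ratio).
#' @return List of class `screening_result`: `p_values` (named numeric),
#'   `retained` (character), `alpha`.
#' @export
univariate_screen <- function(table, labels, alpha = 0.2,
                              test = c("wald", "lrt")) {
  test <- match.arg(test)
  y <- .as_binary(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  x <- as.data.frame(table)
  pv <- vapply(x, function(f) {
    fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
    sep <- !fit$converged || any(abs(stats::coef(fit)[-1L]) > 15)
    if (sep) return(NA_real_)
    if (test == "wald") {
      summary(fit)$coefficients[2L, 4L]
    } else {
      null <- stats::glm(y ~ 1, family = stats::binomial())
      stats::pchisq(null$deviance - fit$deviance, df = 1L, lower.tail = FALSE)
    }
  }, 0)
  retained <- names(pv)[is.na(pv) | pv < alpha]
  structure(list(p_values = pv, retained = retained, alpha = alpha),
            class = "screening_result")
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == "CR")
}

# stratified, seed-reproducible, exhaustive fold assignment
.stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

.binomial_deviance <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' LASSO logistic regression with cross-validated lambda
#'
#' L1-penalized logistic regression (via glmnet) over a decreasing grid of 100
#' log-spaced lambda values from `lambda_max` (the smallest lambda that zeroes
#' every coefficient) down to `1e-4 * lambda_max`. `lambda*` minimizes the
#' mean cross-validated binomial deviance over stratified folds (minimum
#' criteria); among ties the largest lambda wins. The final model is refit on
#' all rows at `lambda*`.
#'
#' @param table Normalized numeric feature table (patients x features).
#' @param labels Binary labels (see [univariate_screen()]).
#' @param n_folds Folds (default 10); reduced with a warning to the minority-
#'   class size when needed so every fold keeps both classes.
#' @param lambda_grid Optional explicit decreasing lambda grid.
#' @param seed Integer seed for the fold assignment.
#' @param normalization_params Optional params from [zscore_normalize()],
#'   stored for later de-normalized scoring.
#' @param label_definition Free-text record of what the binary outcome is.
#' @param fold_safe When `TRUE`, each CV fold re-standardizes its training
#'   columns and applies those statistics to its validation rows, removing the
#'   full-cohort normalization leakage from the lambda choice (off by default:
#'   the reproduced analysis normalized once on the full cohort).
#' @return A `signature_model`: `intercept`, `coefficients` (named, nonzero
#'   only), `lambda`, `cv_deviance_path` (data.frame lambda/deviance),
#'   `normalization_params`, `label_definition`, `seed`, `n_features_in`.
#' @export
fit_lasso_cv <- function(table, labels, n_folds = 10L, lambda_grid = NULL,
                         seed = 1L, normalization_params = NULL,
                         label_definition = "CR vs PR", fold_safe = FALSE) {
  x <- as.matrix(table)
  y <- .as_binary(labels)
  if (nrow(x) < n_folds) stop("fewer rows than folds")
  n_minority <- min(table(y))
  if (n_minority < 2L)
    stop("minority class has fewer than 2 members; cross-validation impossible")
  if (n_minority < n_folds) {
    # keep both classes in every fold by shrinking the fold count
    warning(sprintf(paste("minority class (%d) smaller than n_folds (%d);",
                          "using %d stratified folds"),
                    n_minority, n_folds, n_minority))
    n_folds <- n_minority
  }
  if (is.null(lambda_grid)) {
    # smallest lambda with all-zero coefficients: max |x'(y - ybar)| / n
    lmax <- max(abs(crossprod(x, y - mean(y)))) / length(y)
    lmax <- max(lmax, 1e-6)
    lambda_grid <- exp(seq(log(lmax), log(1e-4 * lmax), length.out = 100L))
  }
  if (is.unsorted(rev(lambda_grid)) || length(lambda_grid) < 2L)
    stop("lambda_grid must be a decreasing grid with >= 2 values")
  fold <- .stratified_folds(y, n_folds, seed)
  dev <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (fold_safe) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2L, stats::sd)
      sdv[sdv <= .Machine$double.eps] <- 1       # constant-in-fold guard
      xtr <- sweep(sweep(xtr, 2L, mu, `-`), 2L, sdv, `/`)
      xte <- sweep(sweep(xte, 2L, mu, `-`), 2L, sdv, `/`)
    }
    fit <- glmnet::glmnet(xtr, y[tr], family = "binomial",
                          lambda = lambda_grid, standardize = FALSE)
    p <- stats::predict(fit, newx = xte, type = "response",
                        s = lambda_grid, exact = FALSE)
    dev[k, ] <- vapply(seq_along(lambda_grid),
                       function(j) .binomial_deviance(y[!tr], p[, j]), 0)
  }
  mean_dev <- colMeans(dev)
  best <- which(mean_dev <= min(mean_dev) + 1e-12)[1L]   # grid is decreasing:
  lambda_star <- lambda_grid[best]                        # first hit = largest
  final <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda_grid,
                          standardize = FALSE)
  beta <- as.numeric(stats::predict(final, type = "coefficients",
                                    s = lambda_star, exact = FALSE))
  names(beta) <- c("(Intercept)", colnames(x))
  nz <- beta[-1L][beta[-1L] != 0]
  structure(list(intercept = unname(beta[1L]),
                 coefficients = nz,
                 lambda = lambda_star,
                 cv_deviance_path = data.frame(lambda = lambda_grid,
                                               deviance = mean_dev),
                 normalization_params = normalization_params,
                 label_definition = label_definition,
                 seed = seed,
                 n_features_in = ncol(x)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model: %d/%d nonzero features, lambda = %.4g, %s>\n",
              length(x$coefficients), x$n_features_in, x$lambda,
              x$label_definition))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Score patients with a fitted signature model
#'
#' Linear score `intercept + sum(coef * z(x))`. When the model stores
#' normalization parameters, `newdata` is expected in raw units and is
#' standardized with the stored (training) means and sds first.
#'
#' @param model A `signature_model`.
#' @param newdata data.frame/matrix containing at least the model's features.
#' @return Numeric score per row.
#' @export
signature_score <- function(model, newdata) {
  stopifnot(inherits(model, "signature_model"))
  nd <- as.data.frame(newdata)
  feats <- names(model$coefficients)
  if (!length(feats)) return(rep(model$intercept, nrow(nd)))
  missing_f <- setdiff(feats, names(nd))
  if (length(missing_f))
    stop("newdata lacks model features: ", paste(missing_f, collapse = ", "))
  x <- as.matrix(nd[, feats, drop = FALSE])
  if (!is.null(model$normalization_params)) {
    np <- model$normalization_params
    rownames(np) <- np$feature
    x <- sweep(sweep(x, 2L, np[feats, "mean"], `-`), 2L, np[feats, "sd"], `/`)
  }
  as.numeric(model$intercept + x %*% model$coefficients)
}

#' De-normalize a signature model to a raw-unit formula
#'
#' Rewrites `intercept + sum(coef_z * (x - mean)/sd)` as
#' `intercept' + sum(coef' * x)` so the model can be printed as a closed-form
#' score over raw measurements, analogous to the published immune-score
#' formula.
#'
#' @param model A `signature_model` with normalization parameters.
#' @return List with `intercept` and named `coefficients` in raw units.
#' @export
denormalized_formula <- function(model) {
  stopifnot(inherits(model, "signature_model"))
  if (is.null(model$normalization_params))
    return(list(intercept = model$intercept,
                coefficients = model$coefficients))
  np <- model$normalization_params
  rownames(np) <- np$feature
  feats <- names(model$coefficients)
  raw_coef <- model$coefficients / np[feats, "sd"]
  list(intercept = model$intercept -
         sum(model$coefficients * np[feats, "mean"] / np[feats, "sd"]),
       coefficients = raw_coef)
}

#' Build the immunomarker classifier
#'
#' Pipeline over the marker-delta panel (changes of the immune biomarkers
#' after 10 fractions): z-score normalization, then LASSO logistic regression
#' with stratified ten-fold cross-validation against the CR/PR label. The
#' fitted model is returned together with its de-normalized closed-form
#' formula.
#'
#' @param records Clinical table (see [read_clinical_table()]) with a
#'   `response` column.
#' @param seed Integer seed.
#' @param n_folds CV folds.
#' @return `signature_model` with an extra `formula_raw` element.
#' @export
build_immunomarker_classifier <- function(records, seed = 1L, n_folds = 10L) {
  if (!"response" %in% names(records))
    stop("records have no response labels; supervised fit refused")
  deltas <- marker_deltas(records)
  z <- zscore_normalize(deltas)
  model <- fit_lasso_cv(z$table, records$response, n_folds = n_folds,
                        seed = seed, normalization_params = z$params,
                        label_definition = "CR vs PR (immunomarker panel)")
  model$formula_raw <- denormalized_formula(model)
  model
}

#' Build the radiomics signature
#'
#' The published construction: univariate screening of the 97 features at
#' p < `alpha`, z-score normalization of the survivors, then LASSO logistic
#' regression with stratified ten-fold cross-validation.
#'
#' @param feature_table 97-column feature table (a `patient_id` column is
#'   allowed and ignored).
#' @param target_labels Binary target: immune class (`"high"`/`"low"`,
#'   logical, or 0/1) or response (`"CR"`/`"PR"`), per `label_definition`.
#' @param seed Integer seed.
#' @param alpha Screening threshold (default 0.2).
#' @param n_folds CV folds.
#' @param label_definition Record of the outcome fit.
#' @return `signature_model` with extra elements `screening`
#'   (the [univariate_screen()] result) and `n_screened`.
#' @export
build_radiomics_signature <- function(feature_table, target_labels, seed = 1L,
                                      alpha = 0.2, n_folds = 10L,
                                      label_definition = "immune class (high vs low)") {
  ft <- as.data.frame(feature_table)
  ft$patient_id <- NULL
  y <- if (is.character(target_labels) && any(target_labels %in% c("high", "low")))
    as.integer(target_labels == "high") else .as_binary(target_labels)
  scr <- univariate_screen(ft, y, alpha = alpha)
  kept <- ft[, scr$retained, drop = FALSE]
  if (!ncol(kept)) stop("no features survive screening at alpha = ", alpha)
  z <- zscore_normalize(kept)
  model <- fit_lasso_cv(z$table, y, n_folds = n_folds, seed = seed,
                        normalization_params = z$params,
                        label_definition = label_definition)
  model$screening <- scr
  model$n_screened <- length(scr$retained)
  model
}

#' Serialize / deserialize a signature model as JSON
#'
#' @param model A `signature_model`.
#' @param path Output (input) JSON path.
#' @return `path` (for write); a `signature_model` (for read).
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              lambda = model$lambda,
              normalization_params = model$normalization_params,
              label_definition = model$label_definition,
              seed = model$seed,
              n_features_in = model$n_features_in,
              cv_deviance_path = model$cv_deviance_path)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 lambda = obj$lambda,
                 cv_deviance_path = obj$cv_deviance_path,
                 normalization_params = obj$normalization_params,
                 label_definition = obj$label_definition,
                 seed = obj$seed,
                 n_features_in = obj$n_features_in),
            class = "signature_model")
}
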