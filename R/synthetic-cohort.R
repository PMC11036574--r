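# Seedable synthetic cohort: CT volumes + VOI masks + clinical table with the
# latent two-class structure the downstream analysis assumes.
#
# Latent model: each patient is "hot" (immune-inflamed: CD8+ infiltration
# rises, CD68+ macrophages fall after 10 fractions) or "cold" (the reverse).
# The latent class drives (a) the marker-delta distributions, (b) the CR
# probability through the fixed reference immune score, and (c) the image
# texture: the in-tumor HU noise field of cold tumors is smoothed over a
# longer correlation length, scaled by `texture_effect`.
#
# Randomness: each patient gets a private seed derived from (cohort seed,
# patient index), split further by purpose (markers / blood / volume), so
# adding a field to one block never perturbs draws in another.

#' Synthetic cohort configuration
#'
#' Defaults describe a cohort emulating a 30-patient chemoradiotherapy study:
#' 60% latent-hot patients, marker-delta distributions that straddle the
#' published 0.307 immune-score cutoff, a logistic response model centred
#' midway between the class-mean immune scores, and native CT spacing of
#' 1.0 x 1.0 x 5.0 mm.
#'
#' @param n_patients Number of patients (positive integer).
#' @param seed Integer seed; identical `(config, seed)` reproduces the cohort
#'   bit-for-bit.
#' @param hot_fraction Probability a patient is latent-hot.
#' @param delta_cd8_params,delta_cd68_params Named list `list(hot = c(mean,
#'   sd), cold = c(mean, sd))` of class-conditional normal parameters for the
#'   marker changes (cells per evaluated field).
#' @param response_slope Logistic steepness linking immune score to P(CR);
#'   0 makes the response label a fair coin.
#' @param response_center Immune score at which P(CR) = 0.5.
#' @param texture_effect Non-negative class separation of image texture
#'   (extra Gaussian smoothing length, in voxels, applied to cold tumors).
#' @param n_noise_markers Additional class-independent IFN-responsive marker
#'   deltas (defaults to 11, completing the 13-marker panel).
#' @param grid_shape Integer length-3 volume grid.
#' @param voxel_spacing_mm Numeric length-3 spacing, default `c(1, 1, 5)`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 30L,
                          seed = 1L,
                          hot_fraction = 0.6,
                          delta_cd8_params = list(hot = c(mean = 150, sd = 60),
                                                  cold = c(mean = -30, sd = 40)),
                          delta_cd68_params = list(hot = c(mean = -50, sd = 60),
                                                   cold = c(mean = 80, sd = 70)),
                          response_slope = 5,
                          response_center = 0.69,
                          texture_effect = 1.5,
                          n_noise_markers = 11L,
                          grid_shape = c(48L, 48L, 16L),
                          voxel_spacing_mm = c(1, 1, 5)) {
  stopifnot(length(grid_shape) == 3L, length(voxel_spacing_mm) == 3L)
  if (n_patients < 1) stop("n_patients must be a positive integer")
  if (hot_fraction < 0 || hot_fraction > 1) stop("hot_fraction must be in [0,1]")
  if (response_slope < 0) stop("response_slope must be non-negative")
  if (texture_effect < 0) stop("texture_effect must be non-negative")
  for (p in list(delta_cd8_params, delta_cd68_params)) {
    stopifnot(all(c("hot", "cold") %in% names(p)))
    if (any(vapply(p, function(v) v[["sd"]], 0) <= 0))
      stop("marker delta sd values must be strictly positive")
  }
  if (any(grid_shape < 16L))
    stop("grid_shape too small to contain the sampled tumor ellipsoid")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 hot_fraction = hot_fraction,
                 delta_cd8_params = delta_cd8_params,
                 delta_cd68_params = delta_cd68_params,
                 response_slope = response_slope,
                 response_center = response_center,
                 texture_effect = texture_effect,
                 n_noise_markers = as.integer(n_noise_markers),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "cohort_config")
}

NOISE_MARKER_NAMES <- c("pdl1", "serpinb9", "cd47", "irf1", "stat1", "hla_a",
                        "hla_bc", "b2m", "tap1", "lmp2", "lmp7")

# deterministic per-(patient, purpose) seed below 2^31
.patient_seed <- function(cohort_seed, i, purpose) {
  (abs(cohort_seed) %% 100000L) * 10000L + i * 10L + purpose
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# separable 3D Gaussian smoothing with edge renormalization
.gauss_smooth3d <- function(arr, sigma) {
  if (all(sigma <= 1e-8)) return(arr)
  dims <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- dims[ax]
    # build banded smoothing matrix with renormalized truncated edges
    sm <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1L & j <= n
      sm[cbind(idx[ok], j[ok])] <- k[off + r + 1L]
    }
    sm <- sm / rowSums(sm)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- sm %*% matrix(a, nrow = da[1L])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate one synthetic tumor volume and mask
#'
#' Foreground is an ellipsoid (half-axes sampled within fixed bounds, jittered
#' center) filled with a soft-tissue HU baseline plus a correlated Gaussian
#' noise field; the smoothing length is class-dependent (cold tumors get
#' `texture_effect` extra voxels of smoothing), which is what the texture
#' features downstream detect. Background is fat-like HU with independent
#' noise, so foreground and background are distinct.
#'
#' @param latent_class `"hot"` or `"cold"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this draw.
#' @return List with `volume` ([ct_volume()]) and `mask` ([roi_mask()]).
#' @export
generate_tumor_volume <- function(latent_class, config, seed) {
  stopifnot(latent_class %in% c("hot", "cold"))
  set.seed(seed)
  g <- config$grid_shape
  for (attempt in 1:10) {
    ax <- stats::runif(1, 7, 11)            # half-axes, voxels
    ay <- stats::runif(1, 7, 11)
    az <- stats::runif(1, 2.5, 4.5)         # thick slices: few in z
    ctr <- (g + 1) / 2 + stats::runif(3, -1.5, 1.5)
    fits <- ctr[1] - ax >= 1 && ctr[1] + ax <= g[1] &&
            ctr[2] - ay >= 1 && ctr[2] + ay <= g[2] &&
            ctr[3] - az >= 1 && ctr[3] + az <= g[3]
    if (fits) break
    if (attempt == 10) stop("tumor ellipsoid does not fit the grid after 10 draws")
  }
  xs <- (seq_len(g[1]) - ctr[1]) / ax
  ys <- (seq_len(g[2]) - ctr[2]) / ay
  zs <- (seq_len(g[3]) - ctr[3]) / az
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  lab <- array(as.integer(d2 <= 1), dim = g)

  smooth_extra <- if (latent_class == "cold") config$texture_effect else 0
  sigma <- c(0.5, 0.5, 0.25) + smooth_extra * c(1, 1, 0.5)
  noise <- array(stats::rnorm(prod(g), 0, 30), dim = g)
  sm <- .gauss_smooth3d(noise, sigma)
  # restore unit marginal sd so classes differ in correlation, not variance
  sm <- sm / stats::sd(sm) * 30
  background <- -80 + array(stats::rnorm(prod(g), 0, 10), dim = g)
  hu <- ifelse(lab == 1L, 45 + sm, background)
  hu <- array(hu, dim = g)
  list(volume = ct_volume(hu, config$voxel_spacing_mm),
       mask = roi_mask(lab, config$voxel_spacing_mm))
}

#' Generate a synthetic cohort
#'
#' Draws the latent class, marker counts, blood counts, response label and
#' tumor image for each patient. CR labels follow
#' `Bernoulli(sigmoid(response_slope * (immune_score - response_center)))`
#' where the immune score is the fixed reference model evaluated on the
#' realized marker deltas.
#'
#' @param config A [cohort_config()].
#' @param with_volumes Set `FALSE` to skip image synthesis (markers/labels
#'   only; much faster for statistical simulations).
#' @return List of `synthetic_patient` lists, each with `patient_id`,
#'   `latent_class`, `record` (one-row data.frame), and — when requested —
#'   `volume` and `mask`. The bound clinical table is in
#'   `attr(, "clinical_table")`.
#' @export
generate_cohort <- function(config, with_volumes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- vector("list", config$n_patients)
  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(.patient_seed(config$seed, i, 1L))   # markers + class + response
    cls <- if (stats::runif(1) < config$hot_fraction) "hot" else "cold"
    p8 <- config$delta_cd8_params[[cls]]
    p68 <- config$delta_cd68_params[[cls]]
    cd8_base <- round(stats::rlnorm(1, log(250), 0.3))
    cd68_base <- round(stats::rlnorm(1, log(200), 0.3))
    cd8_10f <- max(0, round(cd8_base + stats::rnorm(1, p8[["mean"]], p8[["sd"]])))
    cd68_10f <- max(0, round(cd68_base + stats::rnorm(1, p68[["mean"]], p68[["sd"]])))
    score <- immune_score(cd8_10f - cd8_base, cd68_10f - cd68_base)
    p_cr <- if (config$response_slope == 0) 0.5 else
      .sigmoid(config$response_slope * (score - config$response_center))
    response <- if (stats::runif(1) < p_cr) "CR" else "PR"
    noise_deltas <- stats::rnorm(config$n_noise_markers, 0, 20)

    set.seed(.patient_seed(config$seed, i, 2L))   # blood + clinical covariates
    blood <- function(meanv) stats::rlnorm(1, log(meanv), 0.25)
    plt0 <- blood(250); anc0 <- blood(3.5); amc0 <- blood(0.5); alc0 <- blood(1.8)
    atten <- function(x, f) x * f * stats::rlnorm(1, 0, 0.1)
    plt1 <- atten(plt0, 0.85); anc1 <- atten(anc0, 0.9)
    amc1 <- atten(amc0, 0.9); alc1 <- atten(alc0, 0.5)
    age <- round(stats::rnorm(1, 55, 10))
    figo <- sample(1:4, 1, prob = c(0.15, 0.35, 0.35, 0.15))
    size <- round(stats::rlnorm(1, log(4.5), 0.3), 1)
    lnpos <- stats::runif(1) < 0.45

    rec <- data.frame(
      patient_id = sprintf("P%03d", i),
      cd8_baseline = cd8_base, cd8_10f = cd8_10f,
      cd68_baseline = cd68_base, cd68_10f = cd68_10f,
      plt_baseline = plt0, anc_baseline = anc0,
      amc_baseline = amc0, alc_baseline = alc0,
      plt_10f = plt1, anc_10f = anc1, amc_10f = amc1, alc_10f = alc1,
      age_years = age, figo_stage = figo, tumor_size_cm = size,
      ln_positive = lnpos, response = response,
      stringsAsFactors = FALSE)
    for (k in seq_len(config$n_noise_markers))
      rec[[paste0("delta_", NOISE_MARKER_NAMES[k])]] <- noise_deltas[k]

    pat <- list(patient_id = rec$patient_id, latent_class = cls, record = rec)
    if (with_volumes) {
      tv <- generate_tumor_volume(cls, config, .patient_seed(config$seed, i, 3L))
      pat$volume <- tv$volume
      pat$mask <- tv$mask
    }
    patients[[i]] <- pat
    rows[[i]] <- rec
  }
  tab <- do.call(rbind, rows)
  tab$latent_class <- vapply(patients, `[[`, "", "latent_class")
  attr(patients, "clinical_table") <- tab
  patients
}

#' Write a cohort to disk
#'
#' One NIfTI volume and one NIfTI mask per patient, a cohort CSV in the fixed
#' clinical schema, and a JSON manifest listing every file with its MD5
#' checksum.
#'
#' @param patients Output of [generate_cohort()] (with volumes).
#' @param dir Output directory (created if absent).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create cohort directory: ", dir)
  files <- character(0)
  for (p in patients) {
    if (is.null(p$volume)) stop("patient ", p$patient_id, " has no volume")
    vf <- file.path(dir, paste0(p$patient_id, "_volume.nii.gz"))
    mf <- file.path(dir, paste0(p$patient_id, "_mask.nii.gz"))
    write_nifti(p$volume$intensities, vf, p$volume$spacing_mm,
                p$volume$origin_mm, datatype = "float64")
    write_nifti(p$mask$labels, mf, p$mask$spacing_mm,
                p$mask$origin_mm, datatype = "uint8")
    files <- c(files, vf, mf)
  }
  csvf <- file.path(dir, "cohort.csv")
  tab <- attr(patients, "clinical_table")
  if (length(patients) == 0L) {
    tab <- data.frame(matrix(nrow = 0, ncol = length(CLINICAL_MANDATORY) + 1))
    names(tab) <- c(CLINICAL_MANDATORY, "response")
  } else {
    tab$latent_class <- NULL      # latent truth never leaves the generator CSV
  }
  utils::write.csv(tab, csvf, row.names = FALSE)
  files <- c(files, csvf)
  manifest <- list(
    n_patients = length(patients),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
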