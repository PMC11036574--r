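# Feature registry and the one-call extractor.
#
# The registry (inst/extdata/feature_registry.json) is the single source of
# truth for the 97-feature bank: name, category and formula identifier, in
# emission order. `extract_all` validates its output against the registry, so
# names are stable across runs and versions.

.registry_cache <- new.env(parent = emptyenv())

#' The 97-feature registry
#'
#' @param path Optional registry JSON path (defaults to the installed copy).
#' @return data.frame with columns `name`, `category` (intensity / geometric /
#'   textural), `formula`, in emission order.
#' @export
feature_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_cache$df)) return(.registry_cache$df)
    path <- system.file("extdata", "feature_registry.json",
                        package = "radimmune", mustWork = TRUE)
  }
  reg <- jsonlite::fromJSON(path)
  df <- as.data.frame(reg$features, stringsAsFactors = FALSE)
  counts <- table(df$category)
  stopifnot(nrow(df) == 97L,
            counts[["intensity"]] == 24L,
            counts[["geometric"]] == 20L,
            counts[["textural"]] == 53L)
  .registry_cache$df <- df
  df
}

#' Feature-extraction configuration
#'
#' @param n_bins Gray levels for quantization (default 64, equal-width over
#'   the in-mask HU range).
#' @param glcm_aggregate `"merged"` (sum the 13 directional GLCMs, then
#'   compute features once) or `"average"`.
#' @param margin_voxels Bounding-box margin used when cropping the VOI.
#' @param resample_isotropic Reserved flag; the native anisotropic grid is
#'   used throughout (`FALSE`, matching the reproduced protocol) and isotropic
#'   resampling is not implemented.
#' @return A `feature_config` list.
#' @export
feature_config <- function(n_bins = 64L,
                           glcm_aggregate = c("merged", "average"),
                           margin_voxels = 0L,
                           resample_isotropic = FALSE) {
  if (isTRUE(resample_isotropic))
    stop("isotropic resampling is not implemented; features are computed on ",
         "the native grid")
  structure(list(n_bins = as.integer(n_bins),
                 glcm_aggregate = match.arg(glcm_aggregate),
                 margin_voxels = as.integer(margin_voxels),
                 resample_isotropic = FALSE),
            class = "feature_config")
}

#' Extract all 97 radiomics features
#'
#' Crops the (volume, mask) pair to the VOI bounding box, then emits the fixed
#' registry order: 24 intensity, 20 geometric, 53 textural features.
#'
#' @param volume A [ct_volume()].
#' @param mask A congruent [roi_mask()].
#' @param config A [feature_config()].
#' @return Named numeric vector of length 97 with a `category` attribute
#'   (character vector aligned with the values).
#' @export
extract_all <- function(volume, mask, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  voi <- extract_voi(volume, mask, config$margin_voxels)
  fo <- intensity_features(voi$volume, voi$mask, n_bins = config$n_bins)
  sh <- geometric_features(voi$mask)
  q <- quantize(voi$volume, voi$mask, n_bins = config$n_bins)
  tm <- build_texture_matrices(q)
  tx <- textural_features(tm, aggregate = config$glcm_aggregate)
  out <- c(fo, sh, tx)
  reg <- feature_registry()
  if (!identical(names(out), reg$name))
    stop("feature bank does not match the registry; registry is authoritative")
  attr(out, "category") <- reg$category
  out
}

#' Extract a cohort feature table
#'
#' @param patients Output of [generate_cohort()] (with volumes), or a list of
#'   lists with `patient_id`, `volume`, `mask`.
#' @param config A [feature_config()].
#' @return data.frame: one row per patient, `patient_id` column plus the 97
#'   named feature columns.
#' @export
extract_feature_table <- function(patients, config = feature_config()) {
  rows <- lapply(patients, function(p) {
    if (is.null(p$volume) || is.null(p$mask))
      stop("missing volume/mask for patient ", p$patient_id)
    extract_all(p$volume, p$mask, config)
  })
  df <- as.data.frame(do.call(rbind, rows))
  cbind(patient_id = vapply(patients, `[[`, "", "patient_id"), df)
}
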