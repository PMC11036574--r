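# Volume / mask data model and clinical-table I/O.
#
# Conventions (fixed, documented here once):
#   * arrays are indexed [x, y, z]; voxel indices are 1-based in R code,
#     geometry is always computed in physical mm via `spacing_mm`;
#   * no resampling: features are computed on the native anisotropic grid
#     (default 1.0 x 1.0 x 5.0 mm);
#   * mask dialect: any strictly positive voxel is foreground;
#   * grid-match tolerance between a mask and its volume: 1e-3 mm on spacing.

SPACING_TOL_MM <- 1e-3

#' Construct a CT volume
#'
#' @param intensities 3D numeric array of Hounsfield units.
#' @param spacing_mm Numeric length-3 voxel spacing (x, y, z) in mm.
#' @param origin_mm Numeric length-3 position of the first voxel in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing_mm = c(1, 1, 5),
                      origin_mm = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("expected 3D volume, got ", length(dim(intensities)), "D")
  if (!all(is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite voxel at index (%d, %d, %d)",
                 bad[1L], bad[2L], bad[3L]))
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive reals")
  structure(list(intensities = intensities,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' Construct a binary region-of-interest mask
#'
#' Any strictly positive label is treated as foreground (exported label
#' conventions vary across planning systems).
#'
#' @param labels 3D numeric/integer array.
#' @param spacing_mm,origin_mm Grid metadata, as for [ct_volume()].
#' @return An object of class `roi_mask` with 0/1 integer labels.
#' @export
roi_mask <- function(labels, spacing_mm = c(1, 1, 5), origin_mm = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L)
    stop("expected 3D mask, got ", length(dim(labels)), "D")
  lab <- array(as.integer(labels > 0), dim = dim(labels))
  if (sum(lab) < 1L) stop("empty VOI: mask has no foreground voxels")
  structure(list(labels = lab, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "roi_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s, spacing %s mm, HU range [%.1f, %.1f]>\n",
              paste(dim(x$intensities), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, %d foreground voxels>\n",
              paste(dim(x$labels), collapse = "x"), sum(x$labels)))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' @param path Path to a 3D `.nii` / `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  img <- read_nifti(path)
  if (length(img$dim) != 3L)
    stop("expected 3D volume, got ", length(img$dim), "D: ", path)
  ct_volume(img$data, spacing_mm = img$spacing, origin_mm = img$origin)
}

#' Read a VOI mask and validate it against its reference volume
#'
#' @param path Path to a NIfTI mask on the same grid as `reference`.
#' @param reference The [ct_volume()] the mask annotates.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  img <- read_nifti(path)
  if (length(img$dim) != 3L)
    stop("expected 3D mask, got ", length(img$dim), "D: ", path)
  if (!identical(img$dim, dim(reference$intensities)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(img$dim, collapse = "x"),
                 paste(dim(reference$intensities), collapse = "x")))
  if (any(abs(img$spacing - reference$spacing_mm) > SPACING_TOL_MM))
    stop("mask voxel spacing differs from volume spacing beyond 1e-3 mm")
  roi_mask(img$data, spacing_mm = reference$spacing_mm,
           origin_mm = reference$origin_mm)
}

#' Crop a (volume, mask) pair to the VOI bounding box
#'
#' Takes the tight bounding box of the mask foreground, dilates it by
#' `margin_voxels` along every axis, clips to the grid, and crops both arrays.
#' Foreground voxel count is preserved exactly; the physical origin is shifted
#' so geometry stays consistent.
#'
#' @param volume A [ct_volume()].
#' @param mask A congruent [roi_mask()].
#' @param margin_voxels Non-negative integer margin added to the box.
#' @return List with elements `volume` and `mask`, cropped.
#' @export
extract_voi <- function(volume, mask, margin_voxels = 0L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "roi_mask"),
            margin_voxels >= 0)
  if (!identical(dim(volume$intensities), dim(mask$labels)))
    stop("volume and mask grids differ")
  idx <- which(mask$labels == 1L, arr.ind = TRUE)
  dims <- dim(mask$labels)
  lo <- pmax(apply(idx, 2L, min) - margin_voxels, 1L)
  hi <- pmin(apply(idx, 2L, max) + margin_voxels, dims)
  sl <- lapply(1:3, function(a) lo[a]:hi[a])
  newvol <- volume$intensities[sl[[1L]], sl[[2L]], sl[[3L]], drop = FALSE]
  newlab <- mask$labels[sl[[1L]], sl[[2L]], sl[[3L]], drop = FALSE]
  neworigin <- volume$origin_mm + (lo - 1L) * volume$spacing_mm
  list(volume = ct_volume(newvol, volume$spacing_mm, neworigin),
       mask = roi_mask(newlab, mask$spacing_mm, neworigin))
}

# --- clinical table ----------------------------------------------------------

# Fixed cohort CSV schema (one row per patient; extra columns pass through).
CLINICAL_MANDATORY <- c(
  "patient_id", "cd8_baseline", "cd8_10f", "cd68_baseline", "cd68_10f",
  "plt_baseline", "anc_baseline", "amc_baseline", "alc_baseline",
  "plt_10f", "anc_10f", "amc_10f", "alc_10f",
  "age_years", "figo_stage", "tumor_size_cm", "ln_positive"
)
COUNT_COLUMNS <- c(
  "cd8_baseline", "cd8_10f", "cd68_baseline", "cd68_10f",
  "plt_baseline", "anc_baseline", "amc_baseline", "alc_baseline",
  "plt_10f", "anc_10f", "amc_10f", "alc_10f"
)

#' Read a cohort clinical table
#'
#' Reads the fixed per-patient CSV schema: marker counts at baseline and 10F,
#' blood counts (PLT/ANC/AMC/ALC, 10^9/L) at both timepoints, age, FIGO stage,
#' tumor size, nodal status, and (optionally) the CR/PR response label. Unknown
#' columns are preserved as passthrough covariates.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one row per patient; attribute
#'   `has_response` records whether the `response` column was present.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLINICAL_MANDATORY, names(df))
  if (length(missing_cols))
    stop("clinical table missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  for (cc in COUNT_COLUMNS) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] < 0)
    if (length(bad))
      stop(sprintf("row %d: column '%s' must be a finite non-negative number",
                   bad[1L], cc))
  }
  has_response <- "response" %in% names(df)
  if (has_response) {
    ok <- df$response %in% c("CR", "PR")
    if (!all(ok))
      stop("row ", which(!ok)[1L], ": response must be 'CR' or 'PR'")
  }
  df$ln_positive <- as.logical(df$ln_positive)
  attr(df, "has_response") <- has_response
  df
}

#' Marker deltas (10F minus baseline) for the immune classifier
#'
#' Returns the per-patient changes of the immune biomarkers: always
#' `delta_cd8` and `delta_cd68`, plus any passthrough columns named
#' `delta_*` (e.g. the additional IFN-responsive markers emitted by the
#' synthetic generator), giving the 13-marker design when present.
#'
#' @param records Clinical table from [read_clinical_table()].
#' @return Numeric data.frame of marker deltas, rownames = patient ids.
#' @export
marker_deltas <- function(records) {
  out <- data.frame(delta_cd8 = records$cd8_10f - records$cd8_baseline,
                    delta_cd68 = records$cd68_10f - records$cd68_baseline)
  extra <- grep("^delta_", names(records), value = TRUE)
  for (e in extra) out[[e]] <- records[[e]]
  rownames(out) <- records$patient_id
  out
}
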