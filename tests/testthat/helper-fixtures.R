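# In-code fixtures: tiny volumes, masks and cohorts built at test time.

make_volume <- function(values, dims = NULL, spacing = c(1, 1, 5)) {
  if (is.null(dims)) dims <- dim(values) else values <- array(values, dim = dims)
  ct_volume(values, spacing_mm = spacing)
}

make_mask <- function(dims, where = NULL, spacing = c(1, 1, 5)) {
  lab <- array(0L, dim = dims)
  if (is.null(where)) lab[] <- 1L else lab[where] <- 1L
  roi_mask(lab, spacing_mm = spacing)
}

# cube mask of side `s` centered in a grid of size `n`
cube_mask <- function(n = 10L, s = 3L, spacing = c(1, 1, 1)) {
  lab <- array(0L, dim = c(n, n, n))
  lo <- (n - s) %/% 2L + 1L
  lab[lo:(lo + s - 1L), lo:(lo + s - 1L), lo:(lo + s - 1L)] <- 1L
  roi_mask(lab, spacing_mm = spacing)
}

# digitized ball of radius r (voxels) at isotropic spacing
ball_mask <- function(r, spacing = c(1, 1, 1)) {
  n <- 2L * r + 5L
  ctr <- (n + 1) / 2
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  d2 <- (co[, 1] - ctr)^2 + (co[, 2] - ctr)^2 + (co[, 3] - ctr)^2
  lab <- array(as.integer(d2 <= r^2), dim = c(n, n, n))
  roi_mask(lab, spacing_mm = spacing)
}

# random small VOI for oracle comparisons: <= ~64 foreground voxels
random_small_voi <- function(seed, ng = 4L) {
  set.seed(seed)
  dims <- c(sample(3:5, 1), sample(3:5, 1), sample(3:4, 1))
  lab <- array(rbinom(prod(dims), 1, 0.7), dim = dims)
  if (sum(lab) < 2L) lab[c(1L, 2L)] <- 1L
  hu <- array(sample(0:(ng * 10), prod(dims), replace = TRUE), dim = dims)
  list(volume = ct_volume(hu, c(1, 1, 1)), mask = roi_mask(lab, c(1, 1, 1)),
       ng = ng)
}

# fast marker-only cohort table
marker_cohort <- function(n, seed, ...) {
  coh <- generate_cohort(cohort_config(n_patients = n, seed = seed, ...),
                         with_volumes = FALSE)
  attr(coh, "clinical_table")
}
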