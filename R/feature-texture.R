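# Texture matrices (GLCM, GLRLM, GLSZM) and the 53 textural features.
#
# Conventions:
#   * 13 unique lattice directions at voxel distance 1 (the 26-neighborhood
#     halved by central symmetry); offsets are voxel-lattice offsets on the
#     native anisotropic grid (no resampling);
#   * the GLCM is symmetrized (each pair counted in both orders) and the 13
#     directional matrices are summed into one ("merged" aggregation) before
#     features are computed; per-direction averaging is available via
#     `aggregate = "average"` (features averaged over directions);
#   * GLRLM runs accumulate over the same 13 directions into one matrix;
#   * GLSZM zones are 26-connected constant-level regions;
#   * pairs, runs and zones never cross the mask boundary (background voxels
#     carry level 0 and break every structure).

OFFSETS_13 <- matrix(c(1, 0, 0,   0, 1, 0,   0, 0, 1,
                       1, 1, 0,   1, -1, 0,  1, 0, 1,
                       1, 0, -1,  0, 1, 1,   0, 1, -1,
                       1, 1, 1,   1, 1, -1,  1, -1, 1,
                       1, -1, -1), ncol = 3L, byrow = TRUE)

# single-offset symmetric GLCM counts from a level array (0 = background)
.glcm_one <- function(lev, ng, off) {
  d <- dim(lev)
  src <- lapply(1:3, function(a) {
    r <- seq_len(d[a])
    r[r + off[a] >= 1L & r + off[a] <= d[a]]
  })
  if (any(vapply(src, length, 0L) == 0L)) return(matrix(0, ng, ng))
  la <- lev[src[[1L]], src[[2L]], src[[3L]], drop = FALSE]
  lb <- lev[src[[1L]] + off[1L], src[[2L]] + off[2L], src[[3L]] + off[3L],
            drop = FALSE]
  ok <- la > 0L & lb > 0L
  a <- la[ok]; b <- lb[ok]
  if (!length(a)) return(matrix(0, ng, ng))
  counts <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
  m <- matrix(counts, ng, ng, byrow = TRUE)
  m + t(m)
}

# GLRLM over one direction: maximal constant-level runs, vectorized via
# line-ordering + rle; background (level 0) breaks runs and is dropped.
.glrlm_one <- function(lev, ng, off) {
  d <- dim(lev)
  idx <- arrayInd(seq_along(lev), d)
  a <- which(off != 0L)[1L]
  t_pos <- idx[, a] * sign(off[a])
  base <- idx - outer(t_pos, off)               # constant along each line
  b1 <- base[, 1L] - min(base[, 1L])
  b2 <- base[, 2L] - min(base[, 2L])
  b3 <- base[, 3L] - min(base[, 3L])
  r1 <- max(b1) + 1L; r2 <- max(b2) + 1L
  key <- b1 + b2 * r1 + b3 * r1 * r2
  o <- order(key, t_pos)
  y <- as.vector(lev)[o]
  newline <- c(TRUE, diff(key[o]) != 0)
  runstart <- newline | c(TRUE, y[-1L] != y[-length(y)])
  rid <- cumsum(runstart)
  rl <- tabulate(rid)
  rlev <- y[runstart]
  keep <- rlev > 0L
  rl <- rl[keep]; rlev <- rlev[keep]
  if (!length(rl)) return(matrix(0, ng, 0L))
  nr <- max(rl)
  m <- matrix(0, ng, nr)
  tab <- tabulate((rlev - 1L) * nr + rl, nbins = ng * nr)
  matrix(tab, ng, nr, byrow = TRUE)
}

# GLSZM: 26-connected constant-level zones (frontier-vectorized BFS)
.glszm <- function(lev, ng) {
  d <- dim(lev)
  fg <- which(lev > 0L)
  if (!length(fg)) return(matrix(0, ng, 0L))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  coord <- arrayInd(fg, d)
  cmap <- array(0L, d); cmap[fg] <- seq_along(fg)   # linear -> fg index
  visited <- logical(length(fg))
  levfg <- lev[fg]
  zones_lev <- integer(0); zones_size <- integer(0)
  for (s in seq_along(fg)) {
    if (visited[s]) next
    target <- levfg[s]
    visited[s] <- TRUE
    frontier <- s
    size <- 1L
    while (length(frontier)) {
      fc <- coord[frontier, , drop = FALSE]
      nx <- fc[rep(seq_len(nrow(fc)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(fc)), , drop = FALSE]
      ok <- nx[, 1L] >= 1L & nx[, 1L] <= d[1L] &
            nx[, 2L] >= 1L & nx[, 2L] <= d[2L] &
            nx[, 3L] >= 1L & nx[, 3L] <= d[3L]
      nx <- nx[ok, , drop = FALSE]
      lin <- nx[, 1L] + (nx[, 2L] - 1L) * d[1L] + (nx[, 3L] - 1L) * d[1L] * d[2L]
      fi <- cmap[lin]
      fi <- unique(fi[fi > 0L])
      fi <- fi[!visited[fi] & levfg[fi] == target]
      visited[fi] <- TRUE
      frontier <- fi
      size <- size + length(fi)
    }
    zones_lev <- c(zones_lev, target)
    zones_size <- c(zones_size, size)
  }
  ns <- max(zones_size)
  tab <- tabulate((zones_lev - 1L) * ns + zones_size, nbins = ng * ns)
  matrix(tab, ng, ns, byrow = TRUE)
}

#' Build the three texture matrices
#'
#' @param q A [quantize()]d VOI.
#' @param offsets Integer matrix of direction offsets (rows), default the 13
#'   unique 3D lattice directions at distance 1.
#' @return List of class `texture_matrices`: `glcm` (Ng x Ng symmetric counts,
#'   merged over directions), `glcm_dirs` (list of per-direction symmetric
#'   GLCMs), `glrlm` (Ng x Nr counts over all directions), `glszm`
#'   (Ng x Ns zone counts), `n_directions`.
#' @export
build_texture_matrices <- function(q, offsets = OFFSETS_13) {
  stopifnot(inherits(q, "quantized_voi"))
  ng <- q$n_bins
  lev <- q$levels
  glcm_dirs <- apply(offsets, 1L, function(off) .glcm_one(lev, ng, as.integer(off)),
                     simplify = FALSE)
  glcm <- Reduce(`+`, glcm_dirs)
  rl <- lapply(seq_len(nrow(offsets)), function(k)
    .glrlm_one(lev, ng, as.integer(offsets[k, ])))
  nr <- max(vapply(rl, ncol, 0L))
  glrlm <- matrix(0, ng, nr)
  for (m in rl) if (ncol(m)) glrlm[, seq_len(ncol(m))] <-
    glrlm[, seq_len(ncol(m))] + m
  structure(list(glcm = glcm, glcm_dirs = glcm_dirs, glrlm = glrlm,
                 glszm = .glszm(lev, ng), n_directions = nrow(offsets)),
            class = "texture_matrices")
}

# 0 log 0 := 0, log base 2
.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# the 24 GLCM features from one symmetric count matrix
.glcm_features <- function(cm) {
  ng <- nrow(cm)
  tot <- sum(cm)
  if (tot == 0) cm[1L, 1L] <- tot <- 1          # degenerate guard
  p <- cm / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # difference |i-j| and sum i+j marginal distributions
  dk <- 0:(ng - 1L)
  pd <- vapply(dk, function(k) sum(p[abs(i - j) == k]), 0)
  sk <- 2:(2L * ng)
  ps <- vapply(sk, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(dk * pd)
  hxy <- -sum(.xlog2(p))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pxy > 0, log2(pxy), 0))
  hxy2 <- -sum(.xlog2(pxy))
  hx <- -sum(.xlog2(px)); hy <- -sum(.xlog2(py))
  denom <- max(hx, hy)
  corr <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_joint_average = mux,
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * p),
    glcm_cluster_shade = sum((i + j - mux - muy)^3 * p),
    glcm_cluster_tendency = sum((i + j - mux - muy)^2 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = -sum(.xlog2(pd)),
    glcm_difference_variance = sum((dk - da)^2 * pd),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = hxy,
    glcm_imc1 = if (denom > 0) (hxy - hxy1) / denom else 0,
    glcm_imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    glcm_idm = sum(p / (1 + (i - j)^2)),
    glcm_idmn = sum(p / (1 + ((i - j) / ng)^2)),
    glcm_id = sum(p / (1 + abs(i - j))),
    glcm_idn = sum(p / (1 + abs(i - j) / ng)),
    glcm_inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    glcm_maximum_probability = max(p),
    glcm_sum_average = sum(sk * ps),
    glcm_sum_entropy = -sum(.xlog2(ps)),
    glcm_sum_squares = sum((i - mux)^2 * p))
}

# the 16 GLRLM features
.glrlm_features <- function(rm) {
  if (!ncol(rm) || sum(rm) == 0) rm <- matrix(1, nrow(rm), 1L)
  nr <- sum(rm)
  np <- sum(sweep(rm, 2L, seq_len(ncol(rm)), `*`))
  i <- row(rm); j <- col(rm)
  p <- rm / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  ri <- rowSums(rm); rj <- colSums(rm)
  c(glrlm_sre = sum(rm / j^2) / nr,
    glrlm_lre = sum(rm * j^2) / nr,
    glrlm_gln = sum(ri^2) / nr,
    glrlm_glnn = sum(ri^2) / nr^2,
    glrlm_rln = sum(rj^2) / nr,
    glrlm_rlnn = sum(rj^2) / nr^2,
    glrlm_rp = nr / np,
    glrlm_lglre = sum(rm / i^2) / nr,
    glrlm_hglre = sum(rm * i^2) / nr,
    glrlm_srlgle = sum(rm / (i^2 * j^2)) / nr,
    glrlm_srhgle = sum(rm * i^2 / j^2) / nr,
    glrlm_lrlgle = sum(rm * j^2 / i^2) / nr,
    glrlm_lrhgle = sum(rm * i^2 * j^2) / nr,
    glrlm_glv = sum((i - mu_i)^2 * p),
    glrlm_rv = sum((j - mu_j)^2 * p),
    glrlm_re = -sum(.xlog2(p)))
}

# the 13 GLSZM features
.glszm_features <- function(zm) {
  if (!ncol(zm) || sum(zm) == 0) zm <- matrix(1, nrow(zm), 1L)
  nz <- sum(zm)
  np <- sum(sweep(zm, 2L, seq_len(ncol(zm)), `*`))
  i <- row(zm); j <- col(zm)
  zi <- rowSums(zm); zj <- colSums(zm)
  c(glszm_sae = sum(zm / j^2) / nz,
    glszm_lae = sum(zm * j^2) / nz,
    glszm_gln = sum(zi^2) / nz,
    glszm_glnn = sum(zi^2) / nz^2,
    glszm_szn = sum(zj^2) / nz,
    glszm_sznn = sum(zj^2) / nz^2,
    glszm_zp = nz / np,
    glszm_lglze = sum(zm / i^2) / nz,
    glszm_hglze = sum(zm * i^2) / nz,
    glszm_salgle = sum(zm / (i^2 * j^2)) / nz,
    glszm_sahgle = sum(zm * i^2 / j^2) / nz,
    glszm_lalgle = sum(zm * j^2 / i^2) / nz,
    glszm_lahgle = sum(zm * i^2 * j^2) / nz)
}

#' Textural features (53)
#'
#' 24 gray-level co-occurrence, 16 run-length and 13 size-zone features from
#' the normalized texture matrices. Degenerate matrices (single nonzero cell,
#' e.g. a constant VOI) use documented limits — correlation and the
#' informational measures are 0, entropies 0 — never NaN.
#'
#' @param m A [build_texture_matrices()] result.
#' @param aggregate `"merged"` (default): GLCM features from the summed
#'   matrix; `"average"`: features computed per direction then averaged.
#' @return Named numeric vector of 53 features.
#' @export
textural_features <- function(m, aggregate = c("merged", "average")) {
  stopifnot(inherits(m, "texture_matrices"))
  aggregate <- match.arg(aggregate)
  gl <- if (aggregate == "merged") .glcm_features(m$glcm) else {
    per <- vapply(m$glcm_dirs, .glcm_features, numeric(24L))
    rowMeans(per)
  }
  out <- c(gl, .glrlm_features(m$glrlm), .glszm_features(m$glszm))
  stopifnot(all(is.finite(out)))
  out
}
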