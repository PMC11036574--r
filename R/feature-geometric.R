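# Shape (geometric) features, all in physical units (mm) via the voxel
# spacing. Surface area comes from a marching-tetrahedra triangulation of the
# binary mask (midpoint interpolation at isolevel 0.5): unlike voxel-face
# counting, the triangulated area converges to the analytic surface as
# resolution grows, which sphericity-type features require.

# 6-tetrahedra decomposition of the unit cube around main diagonal v1-v8
# (cube vertex order: (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),
#  (0,1,1),(1,1,1) -> indices 1..8)
.TET_DECOMP <- matrix(c(1, 2, 4, 8,
                        1, 4, 3, 8,
                        1, 3, 7, 8,
                        1, 7, 5, 8,
                        1, 5, 6, 8,
                        1, 6, 2, 8), ncol = 4L, byrow = TRUE)
.CUBE_OFFS <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0,
                       0, 0, 1, 1, 0, 1, 0, 1, 1, 1, 1, 1),
                     ncol = 3L, byrow = TRUE)

.tri_area <- function(a, b, c) {
  u <- b - a; v <- c - a
  cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  0.5 * sqrt(sum(cr^2))
}

# vectorized triangle areas: p1, p2, p3 are n x 3 matrices
.vtri_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cr1 <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cr2 <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cr3 <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cr1^2 + cr2^2 + cr3^2)
}

# Mesh surface area (mm^2) by marching tetrahedra on the antialiased
# indicator: each dual-grid corner takes the mean of its 8 adjacent voxel
# labels, and the 0.5-isosurface is triangulated with linear interpolation
# along tet edges. Unlike meshing the raw binary field, this converges to the
# analytic surface for smooth shapes. Structures thinner than one voxel have
# no corners above 0.5 and yield an empty mesh: those fall back to the
# exposed-voxel-face area so the estimate is always positive.
.mesh_surface_area <- function(labels, spacing) {
  dims <- dim(labels)
  pad <- array(0L, dim = dims + 2L)
  pad[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)] <- labels
  pd <- dim(pad)
  sub <- function(o)
    pad[(1L + o[1L]):(pd[1L] + o[1L] - 1L),
        (1L + o[2L]):(pd[2L] + o[2L] - 1L),
        (1L + o[3L]):(pd[3L] + o[3L] - 1L)]
  # corner field on the dual grid: mean of the 8 voxels around each corner
  cf <- Reduce(`+`, lapply(seq_len(8L), function(k) sub(.CUBE_OFFS[k, ]))) / 8
  cd <- dim(cf)
  # dual cubes whose 8 corners straddle the 0.5 level
  subc <- function(o)
    cf[(1L + o[1L]):(cd[1L] + o[1L] - 1L),
       (1L + o[2L]):(cd[2L] + o[2L] - 1L),
       (1L + o[3L]):(cd[3L] + o[3L] - 1L)]
  cornv <- lapply(seq_len(8L), function(k) subc(.CUBE_OFFS[k, ]))
  inside <- lapply(cornv, function(a) a > 0.5)
  nin <- Reduce(`+`, inside)
  mixed <- which(nin > 0L & nin < 8L)
  total <- 0
  if (length(mixed)) {
    V <- vapply(cornv, function(a) a[mixed], numeric(length(mixed)))
    if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
    P <- sweep(.CUBE_OFFS, 2L, spacing, `*`)    # tet vertex offsets, mm
    interp <- function(a, b, sel) {
      # 0.5-crossing on edge a->b (vertex column ids), rows `sel`
      tt <- (0.5 - V[sel, a]) / (V[sel, b] - V[sel, a])
      outer(rep(1, length(sel)), P[a, ]) +
        tt * outer(rep(1, length(sel)), P[b, ] - P[a, ])
    }
    for (t in seq_len(6L)) {
      vid <- .TET_DECOMP[t, ]
      ins <- vapply(vid, function(k) V[, k] > 0.5, logical(nrow(V)))
      if (is.null(dim(ins))) ins <- matrix(ins, nrow = 1L)
      code <- ins[, 1L] + 2L * ins[, 2L] + 4L * ins[, 3L] + 8L * ins[, 4L]
      for (cs in unique(code)) {
        if (cs == 0L || cs == 15L) next
        sel <- which(code == cs)
        io <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
        tin <- vid[io]; tout <- vid[!io]
        if (length(tin) == 1L || length(tin) == 3L) {
          apex <- if (length(tin) == 1L) tin else tout
          oth <- if (length(tin) == 1L) tout else tin
          total <- total + sum(.vtri_area(interp(apex, oth[1L], sel),
                                          interp(apex, oth[2L], sel),
                                          interp(apex, oth[3L], sel)))
        } else {
          # quad with cyclic order ac, ad, bd, bc; split into two triangles
          mac <- interp(tin[1L], tout[1L], sel)
          mad <- interp(tin[1L], tout[2L], sel)
          mbd <- interp(tin[2L], tout[2L], sel)
          mbc <- interp(tin[2L], tout[1L], sel)
          total <- total + sum(.vtri_area(mac, mad, mbd)) +
            sum(.vtri_area(mac, mbd, mbc))
        }
      }
    }
  }
  if (total <= 0) {
    # sub-voxel-thin mask: exposed voxel-face area
    shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    face <- c(spacing[2L] * spacing[3L], spacing[2L] * spacing[3L],
              spacing[1L] * spacing[3L], spacing[1L] * spacing[3L],
              spacing[1L] * spacing[2L], spacing[1L] * spacing[2L])
    core <- pad[2:(pd[1L] - 1L), 2:(pd[2L] - 1L), 2:(pd[3L] - 1L)]
    for (s in seq_len(6L)) {
      o <- shifts[s, ]
      nbr <- pad[(2L + o[1L]):(pd[1L] - 1L + o[1L]),
                 (2L + o[2L]):(pd[2L] - 1L + o[2L]),
                 (2L + o[3L]):(pd[3L] - 1L + o[3L])]
      total <- total + sum(core == 1L & nbr == 0L) * face[s]
    }
  }
  total
}

# max pairwise distance among point rows (mm), chunked to bound memory
.max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  chunk <- 512L
  g2 <- rowSums(pts^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    cross <- pts[s:e, , drop = FALSE] %*% t(pts)
    d2 <- outer(g2[s:e], rep(1, n)) + outer(rep(1, length(s:e)), g2) - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Shape features (20)
#'
#' Geometric descriptors of the VOI computed in physical mm from the voxel
#' spacing: volume, mesh surface area and derived compactness measures,
#' maximum 3D and in-plane diameters, principal-axis lengths from the second
#' moments of the voxel-center point cloud (population convention, length =
#' 4*sqrt(eigenvalue)), bounding-box measures, the equivalent-sphere diameter
#' and the centroid offset from the bounding-box center. In-plane diameters
#' project voxel centers onto the named plane before taking the largest
#' pairwise distance. Degenerate limits: a single-eigenvalue-zero VOI (plane,
#' rod, single voxel) has elongation/flatness taken as the ratio convention
#' sqrt(lambda_k / lambda_1) with 0/0 defined as 1.
#'
#' @param mask A [roi_mask()].
#' @param spacing_mm Voxel spacing; defaults to the mask's.
#' @return Named numeric vector of 20 features, prefix `shape_`.
#' @export
geometric_features <- function(mask, spacing_mm = mask$spacing_mm) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- as.numeric(spacing_mm)
  idx <- which(mask$labels == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  cellvol <- prod(sp)
  vol <- n * cellvol
  area <- .mesh_surface_area(mask$labels, sp)

  pts <- sweep(idx - 1L, 2L, sp, `*`)           # voxel centers, mm
  centroid <- colMeans(pts)
  # surface voxels only for diameters (6-neighborhood exposure)
  lab <- mask$labels
  dims <- dim(lab)
  padl <- array(0L, dims + 2L)
  padl[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)] <- lab
  nb6 <- array(0L, dims)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(6L)) {
    o <- shifts[s, ]
    nb6 <- nb6 + padl[(2:(dims[1L] + 1L)) + o[1L],
                      (2:(dims[2L] + 1L)) + o[2L],
                      (2:(dims[3L] + 1L)) + o[3L]]
  }
  boundary <- which(lab == 1L & nb6 < 6L, arr.ind = TRUE)
  bpts <- sweep(boundary - 1L, 2L, sp, `*`)
  max3d <- .max_pairwise_dist(bpts)
  plane_diam <- function(keep) {
    pp <- unique(bpts[, keep, drop = FALSE])
    .max_pairwise_dist(pp)
  }
  dax <- plane_diam(c(1L, 2L))                  # axial (x-y)
  dcor <- plane_diam(c(1L, 3L))                 # coronal (x-z)
  dsag <- plane_diam(c(2L, 3L))                 # sagittal (y-z)

  cen <- sweep(pts, 2L, centroid, `-`)
  covm <- crossprod(cen) / n                    # population second moments
  ev <- sort(pmax(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  axlen <- 4 * sqrt(ev)
  elong <- if (ev[1L] > 0) sqrt(ev[2L] / ev[1L]) else 1
  flat <- if (ev[1L] > 0) sqrt(ev[3L] / ev[1L]) else 1

  lo <- apply(idx, 2L, min); hi <- apply(idx, 2L, max)
  bbox_edges <- (hi - lo + 1L) * sp
  bboxvol <- prod(bbox_edges)
  bbox_center <- ((lo - 1L) + (hi - 1L)) / 2 * sp
  eqd <- 2 * (3 * vol / (4 * pi))^(1 / 3)
  req <- eqd / 2

  c(shape_voxel_volume = vol,
    shape_surface_area = area,
    shape_surface_to_volume = area / vol,
    shape_sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    shape_compactness1 = vol / (sqrt(pi) * area^1.5),
    shape_compactness2 = 36 * pi * vol^2 / area^3,
    shape_spherical_disproportion = area / (4 * pi * req^2),
    shape_max_3d_diameter = max3d,
    shape_max_diameter_axial = dax,
    shape_max_diameter_coronal = dcor,
    shape_max_diameter_sagittal = dsag,
    shape_major_axis_length = axlen[1L],
    shape_minor_axis_length = axlen[2L],
    shape_least_axis_length = axlen[3L],
    shape_elongation = elong,
    shape_flatness = flat,
    shape_bbox_volume = bboxvol,
    shape_extent = vol / bboxvol,
    shape_equivalent_sphere_diameter = eqd,
    shape_centroid_offset = sqrt(sum((centroid - bbox_center)^2)))
}
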