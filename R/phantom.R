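#' CTV size classes
#'
#' Breast size is stratified by CTV volume with cutoffs at 300 ml and 600 ml:
#' small < 300 ml, 300 ml <= medium <= 600 ml, large > 600 ml. Each class
#' carries a default CTV volume target used by the phantom generator.
#'
#' @param label one of `"small"`, `"medium"`, `"large"`.
#' @return list with `label` and `ctv_volume_target` (ml).
#' @export
size_class <- function(label = c("small", "medium", "large")) {
  label <- match.arg(label)
  target <- switch(label, small = 200, medium = 450, large = 800)
  list(label = label, ctv_volume_target = target)
}

#' Classify a CTV volume into a size class label
#' @param ctv_ml CTV volume in ml.
#' @return `"small"` (< 300 ml), `"medium"` (300-600 ml) or `"large"` (> 600 ml).
#' @export
classify_ctv_volume <- function(ctv_ml) {
  if (ctv_ml < 300) "small" else if (ctv_ml <= 600) "medium" else "large"
}

# Voxelize an ellipsoid given centre (mm), orthonormal frame (rows = axes in
# patient coords) and semi-axes (mm) along those frame axes.
ellipsoid_mask <- function(grid, center, semi, frame = diag(3)) {
  cc <- axis_coords(grid)
  x <- cc[[1]]; y <- cc[[2]]; z <- cc[[3]]
  dx <- x - center[1]; dy <- y - center[2]; dz <- z - center[3]
  # coordinates in the ellipsoid frame, separable accumulation
  q <- array(0, grid$shape)
  for (a in 1:3) {
    ua <- outer(outer(dx * frame[a, 1], dy * frame[a, 2], `+`), dz * frame[a, 3], `+`)
    q <- q + (ua / semi[a])^2
  }
  q <= 1
}

#' Generate a synthetic left-breast planning phantom
#'
#' Builds a voxel phantom emulating a supine left-sided whole-breast
#' irradiation case: an elliptic-cylinder torso (Body), a breast CTV modelled
#' as an ellipsoid centred on the anterior-left chest surface (roughly half of
#' it protruding), ipsilateral and contralateral lungs, a heart displaced
#' toward the left, and a mirrored contralateral breast. All shape parameters
#' are drawn from seeded uniform jitter within anatomically plausible ranges,
#' and the CTV semi-axes are rescaled once against the voxelized count so the
#' CTV volume lands within +/-10% of the size-class target. The PTV is derived
#' with [expand_to_ptv()] (5 mm isotropic margin, 4 mm skin crop).
#'
#' @param size class label (`"small"`, `"medium"`, `"large"`) or a
#'   [size_class()] object.
#' @param seed integer seed; the phantom is bit-reproducible for a fixed seed
#'   and grid.
#' @param grid a [voxel_grid]; the default 96 x 76 x 44 lattice at
#'   4 x 4 x 3 mm spans a 384 x 304 x 132 mm field of view.
#' @param ptv_margin_mm,skin_crop_mm PTV expansion margin and skin crop (mm).
#'
#' @return list with `grid`, `structures` (a [structure_set] with Body, CTV,
#'   PTV, LungIpsi, LungContra, Heart, BreastContra) and `provenance`
#'   (seed, size class, sampled shape parameters, achieved CTV volume).
#' @export
generate_phantom <- function(size = "medium", seed = 1,
                             grid = voxel_grid(c(96, 76, 44)),
                             ptv_margin_mm = 5, skin_crop_mm = 4) {
  if (is.character(size)) size <- size_class(size)
  if (!is.list(size) || is.null(size$ctv_volume_target))
    stop("unknown size class")
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed))
    stats::runif(12)
  })
  jit <- function(i, lo, hi) lo + rng[i] * (hi - lo)

  ext <- grid$shape * grid$spacing
  ctr <- grid$origin + (grid$shape - 1) * grid$spacing / 2

  # torso: elliptic cylinder along z, centred in-plane, full z extent
  ax <- jit(1, 140, 165)          # right-left semi-axis, mm
  ay <- jit(2, 90, 110)           # anterior-posterior semi-axis, mm
  if (2 * ax > ext[1] - 2 * grid$spacing[1] || 2 * ay > ext[2] - 60)
    stop("grid too small to contain the torso cross-section")
  cc <- axis_coords(grid)
  tor2d <- outer(((cc[[1]] - ctr[1]) / ax)^2, ((cc[[2]] - ctr[2] - 20) / ay)^2, `+`) <= 1
  torso <- array(tor2d, grid$shape)  # recycled along z
  tcy <- ctr[2] + 20                 # torso centre is pushed slightly posterior

  # breast CTV: ellipsoid centred on the anterior-left torso surface
  theta <- jit(3, 35, 50) * pi / 180     # azimuth from anterior toward the left
  bc <- c(ctr[1] + ax * sin(theta), tcy - ay * cos(theta), ctr[3])
  nrm <- c(sin(theta) / ax, -cos(theta) / ay, 0)
  nrm <- nrm / sqrt(sum(nrm^2))          # outward surface normal
  t1 <- c(-nrm[2], nrm[1], 0)            # in-plane tangent
  t2 <- c(0, 0, 1)
  frame <- rbind(nrm, t1, t2)
  # aspect jitter, then solve the normal semi-axis from the volume target
  k1 <- jit(4, 1.05, 1.35)               # tangential/normal ratio
  k2 <- jit(5, 1.10, 1.45)               # SI/normal ratio
  vol_mm3 <- size$ctv_volume_target * 1000
  h <- (vol_mm3 / (4 / 3 * pi * k1 * k2))^(1 / 3)
  semi <- c(h, h * k1, h * k2)
  ctv <- ellipsoid_mask(grid, bc, semi, frame)
  # one voxelization correction pass toward the analytic target
  got <- mask_volume_ml(ctv, grid)
  if (got > 0) {
    semi <- semi * (size$ctv_volume_target / got)^(1 / 3)
    ctv <- ellipsoid_mask(grid, bc, semi, frame)
  }
  if (sum(ctv) == 0) stop("grid too small to contain the target CTV volume")

  # contralateral breast: mirrored, with its own (smaller) jitter
  bc2 <- c(2 * ctr[1] - bc[1], bc[2], bc[3])
  frame2 <- frame; frame2[, 1] <- -frame2[, 1]
  semi2 <- semi * jit(6, 0.8, 1.0)
  breast_contra <- ellipsoid_mask(grid, bc2, semi2, frame2)

  body <- torso | ctv | breast_contra

  # lungs: ellipsoids in the posterior thorax, clipped well inside the torso
  chest <- erode_ball(torso, 12, grid)
  zc <- ctr[3]
  lsx <- jit(7, 42, 52); lsy <- jit(8, 48, 60); lsz <- 0.46 * ext[3]
  lung_l <- ellipsoid_mask(grid, c(ctr[1] + 0.45 * ax, tcy + 0.12 * ay, zc),
                           c(lsx, lsy, lsz)) & chest
  lung_r <- ellipsoid_mask(grid, c(ctr[1] - 0.45 * ax, tcy + 0.12 * ay, zc),
                           c(lsx, lsy, lsz)) & chest

  # heart: ellipsoid displaced toward the left, anterior to the lungs
  hs <- c(jit(9, 40, 48), jit(10, 36, 44), jit(11, 40, 50))
  heart <- ellipsoid_mask(grid, c(ctr[1] + 0.18 * ax, tcy - 0.18 * ay, zc - 0.08 * ext[3]),
                          hs) & chest
  lung_l <- lung_l & !heart
  lung_r <- lung_r & !heart

  # enforce pairwise disjointness against the target and between OARs
  for (nm in c("lung_l", "lung_r", "heart", "breast_contra")) {
    m <- get(nm); assign(nm, m & !ctv)
  }
  breast_contra <- breast_contra & !(lung_l | lung_r | heart)

  ptv <- expand_to_ptv(ctv, body, grid,
                       margin_mm = ptv_margin_mm, skin_crop_mm = skin_crop_mm)

  ss <- structure_set(grid, list(
    Body = body, CTV = ctv, PTV = ptv,
    LungIpsi = lung_l, LungContra = lung_r,
    Heart = heart, BreastContra = breast_contra))

  prov <- list(seed = as.integer(seed), size_class = size$label,
               ctv_volume_target_ml = size$ctv_volume_target,
               ctv_volume_ml = mask_volume_ml(ctv, grid),
               torso_semi_axes_mm = c(ax, ay),
               breast_center_mm = bc, breast_semi_axes_mm = semi,
               breast_azimuth_deg = theta * 180 / pi,
               ptv_margin_mm = ptv_margin_mm, skin_crop_mm = skin_crop_mm,
               spacing_mm = grid$spacing, shape = grid$shape)
  list(grid = grid, structures = ss, provenance = prov)
}

#' Expand a CTV to a PTV with skin crop
#'
#' The PTV is the CTV dilated by a discretized Euclidean ball of
#' `margin_mm`, intersected with the Body, minus all voxels within
#' `skin_crop_mm` of the body surface (implemented as a ball erosion of Body,
#' with positions outside the grid counting as outside the body).
#'
#' @param ctv,body logical arrays on `grid`; `ctv` must be non-empty and
#'   contained in `body`.
#' @param grid a [voxel_grid].
#' @param margin_mm isotropic expansion margin (default 5 mm).
#' @param skin_crop_mm minimum distance kept from the body surface (default 4 mm).
#' @return logical PTV array.
#' @export
expand_to_ptv <- function(ctv, body, grid, margin_mm = 5, skin_crop_mm = 4) {
  ctv <- ctv != 0; body <- body != 0
  if (!any(ctv)) stop("empty CTV")
  if (any(ctv & !body)) stop("CTV extends outside the body")
  ptv <- dilate_ball(ctv, margin_mm, grid) & body
  if (skin_crop_mm > 0) ptv <- ptv & erode_ball(body, skin_crop_mm, grid)
  ptv
}

#' Posterior ring structures behind the PTV
#'
#' Ring_1 and Ring_2 are dose-falloff control shells obtained by translating
#' the PTV posteriorly (the +y patient axis) in voxel steps: Ring_1 collects
#' voxels reached by posterior shifts up to `ring1_extent_mm`, Ring_2 those
#' reached by shifts in `(ring1_extent_mm, ring2_extent_mm]`. Both are clipped
#' to the body and made disjoint from the PTV and from each other.
#'
#' @param ptv,body logical arrays on `grid`.
#' @param grid a [voxel_grid].
#' @param ring1_extent_mm,ring2_extent_mm posterior extents in mm,
#'   `0 < ring1 < ring2`; defaults 10 and 20 mm.
#' @return list with logical arrays `Ring_1`, `Ring_2`.
#' @export
make_rings <- function(ptv, body, grid, ring1_extent_mm = 10, ring2_extent_mm = 20) {
  ptv <- ptv != 0; body <- body != 0
  if (!any(ptv)) stop("empty PTV")
  if (!(ring2_extent_mm > ring1_extent_mm && ring1_extent_mm > 0))
    stop("extents must satisfy 0 < ring1_extent_mm < ring2_extent_mm")
  sy <- grid$spacing[2]
  if (ring1_extent_mm < sy)
    stop("ring1_extent_mm smaller than one voxel step; no posterior shift possible")
  n2 <- floor(ring2_extent_mm / sy)
  if (n2 > grid$shape[2]) stop("ring extent exceeds the grid")
  acc1 <- array(FALSE, grid$shape); acc2 <- array(FALSE, grid$shape)
  for (j in seq_len(n2)) {
    sh <- shift_mask(ptv, c(0L, j, 0L))
    if (j * sy <= ring1_extent_mm) acc1 <- acc1 | sh else acc2 <- acc2 | sh
  }
  ring1 <- acc1 & body & !ptv
  ring2 <- acc2 & body & !ptv & !ring1
  list(Ring_1 = ring1, Ring_2 = ring2)
}

#' Add ring structures to a structure set
#'
#' Convenience wrapper: computes [make_rings()] from the set's PTV and Body
#' and returns the augmented set.
#'
#' @param ss a [structure_set] containing PTV and Body.
#' @inheritParams make_rings
#' @return the structure set with `Ring_1` and `Ring_2` added.
#' @export
add_rings <- function(ss, ring1_extent_mm = 10, ring2_extent_mm = 20) {
  r <- make_rings(get_mask(ss, "PTV"), get_mask(ss, "Body"), ss$grid,
                  ring1_extent_mm, ring2_extent_mm)
  ss$masks$Ring_1 <- r$Ring_1
  ss$masks$Ring_2 <- r$Ring_2
  ss
}
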