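#' Regular voxel lattice in patient coordinates
#'
#' A `voxel_grid` describes a regular 3-D lattice in the patient coordinate
#' system used throughout the package: axis 1 runs right to left, axis 2
#' anterior to posterior, axis 3 inferior to superior. The centre of voxel
#' `(i, j, k)` (1-based array indices) is `origin + (i-1, j-1, k-1) * spacing`,
#' in millimetres. Masks and dose are stored as plain 3-D arrays with the
#' grid's `shape`.
#'
#' @param shape integer vector of length 3, number of voxels per axis.
#' @param spacing numeric vector of length 3, voxel pitch in mm. The default
#'   uses 4 mm in-plane and a 3 mm slice pitch along the superior-inferior
#'   axis, the slice thickness of the planning CT protocol being emulated.
#' @param origin numeric vector of length 3, centre of voxel (1,1,1) in mm.
#'
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = c(4, 4, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("'shape' must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (length(origin) != 3L)
    stop("'origin' must have length 3")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, extent %.0f x %.0f x %.0f mm\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$shape[1] * x$spacing[1], x$shape[2] * x$spacing[2],
              x$shape[3] * x$spacing[3]))
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#' @param grid a [voxel_grid].
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Volume of a binary mask
#'
#' @param mask logical (or 0/1) array on `grid`.
#' @param grid a [voxel_grid].
#' @return volume in millilitres (`count * voxel volume / 1000`).
#' @export
mask_volume_ml <- function(mask, grid) {
  stopifnot(all(dim(mask) == grid$shape))
  sum(mask != 0) * voxel_volume_mm3(grid) / 1000
}

#' Volume of a binary mask in cubic centimetres
#' @inheritParams mask_volume_ml
#' @return volume in cc (numerically equal to ml).
#' @export
mask_volume_cc <- mask_volume_ml

#' Physical centres of masked voxels
#'
#' @param grid a [voxel_grid].
#' @param mask optional logical array; if omitted, all voxels.
#' @return N x 3 matrix of voxel-centre coordinates in mm.
#' @export
voxel_centers <- function(grid, mask = NULL) {
  if (is.null(mask)) {
    idx <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                                 j = seq_len(grid$shape[2]),
                                 k = seq_len(grid$shape[3])))
  } else {
    stopifnot(all(dim(mask) == grid$shape))
    idx <- which(mask != 0, arr.ind = TRUE)
    colnames(idx) <- c("i", "j", "k")
  }
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Coordinate vectors of voxel centres along each axis
#' @param grid a [voxel_grid].
#' @return list of three numeric vectors (mm).
#' @export
axis_coords <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Surface voxels of a binary mask
#'
#' A voxel belongs to the surface if it is in the mask and at least one of its
#' six face neighbours is outside the mask (voxels on the grid boundary count
#' as surface).
#'
#' @param mask logical array.
#' @return logical array of the same shape.
#' @export
mask_surface <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    n <- d[ax]
    pad <- array(FALSE, d)
    src <- vector("list", 3); dst <- vector("list", 3)
    for (a in 1:3) { src[[a]] <- seq_len(d[a]); dst[[a]] <- seq_len(d[a]) }
    if (by == 1L) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
    else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
    pad[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    acc & pad
  }
  for (ax in 1:3) for (by in c(1L, -1L)) interior <- shift_and(interior, ax, by)
  mask & !interior
}

# Offsets (in voxel index steps) whose centre distance is <= radius_mm.
# Used by both the ball dilation and the ball erosion.
ball_offsets <- function(radius_mm, spacing) {
  r <- abs(radius_mm)
  n <- floor(r / spacing)
  off <- expand.grid(di = -n[1]:n[1], dj = -n[2]:n[2], dk = -n[3]:n[3])
  d2 <- (off$di * spacing[1])^2 + (off$dj * spacing[2])^2 + (off$dk * spacing[3])^2
  as.matrix(off[d2 <= r^2 + 1e-9, , drop = FALSE])
}

# Shift a logical array by integer voxel offsets, padding with `fill`.
shift_mask <- function(mask, off, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      src[[a]] <- seq_len(d[a] - o); dst[[a]] <- (o + 1):d[a]
    } else {
      if (-o >= d[a]) return(out)
      src[[a]] <- (1 - o):d[a]; dst[[a]] <- seq_len(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dilate a mask by a discretized Euclidean ball
#'
#' A voxel is in the dilation if its centre lies within `radius_mm` of the
#' centre of some mask voxel (centre-to-centre Euclidean distance, anisotropic
#' spacing respected).
#'
#' @param mask logical array.
#' @param radius_mm dilation radius in mm.
#' @param grid the [voxel_grid] carrying the spacing.
#' @return logical array.
#' @export
dilate_ball <- function(mask, radius_mm, grid) {
  mask <- mask != 0
  if (radius_mm <= 0) return(mask)
  off <- ball_offsets(radius_mm, grid$spacing)
  out <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off[r, ], fill = FALSE)
  out
}

#' Erode a mask by a discretized Euclidean ball
#'
#' A voxel survives the erosion if every voxel centre within `radius_mm` of it
#' is inside the mask; positions beyond the grid boundary count as outside.
#'
#' @inheritParams dilate_ball
#' @return logical array.
#' @export
erode_ball <- function(mask, radius_mm, grid) {
  mask <- mask != 0
  if (radius_mm <= 0) return(mask)
  off <- ball_offsets(radius_mm, grid$spacing)
  out <- array(TRUE, dim(mask))
  for (r in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off[r, ], fill = FALSE)
  out & mask
}

#' Bundle named binary masks sharing one grid
#'
#' @param grid a [voxel_grid].
#' @param masks named list of logical arrays, all with the grid's shape.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(grid, masks) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(masks), length(names(masks)) == length(masks))
  for (nm in names(masks)) {
    if (!all(dim(masks[[nm]]) == grid$shape))
      stop(sprintf("mask '%s' does not match the grid shape", nm))
    masks[[nm]] <- masks[[nm]] != 0
  }
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set on ")
  print(x$grid)
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %8.1f ml\n", nm, mask_volume_ml(x$masks[[nm]], x$grid)))
  invisible(x)
}

#' Fetch one mask from a structure set
#' @param ss a [structure_set].
#' @param name structure name.
#' @return logical array.
#' @export
get_mask <- function(ss, name) {
  if (!name %in% names(ss$masks))
    stop(sprintf("structure '%s' not present in the structure set", name))
  ss$masks[[name]]
}
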