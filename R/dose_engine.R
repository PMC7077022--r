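#' Dose-engine configuration
#'
#' Parameters of the simplified divergent pencil-beam engine. This engine is a
#' transparent, analytically testable stand-in for a clinical dose algorithm:
#' plans computed with it are internally consistent but not dosimetrically
#' comparable to plans from a commercial system.
#'
#' @param mu_eff_per_mm effective linear attenuation coefficient (1/mm),
#'   default 0.005, a 6 MV-like effective value in water.
#' @param beamlet_size_mm beamlet grid pitch on the isocenter plane (mm),
#'   default 5.
#' @param lateral_sigma_mm Gaussian lateral spread of one pencil beam (mm),
#'   default 3.
#' @param sad_mm source-axis distance (mm), default 1000.
#' @param parallel logical; `TRUE` switches to a parallel-geometry test mode
#'   (no divergence, no inverse-square factor) used for closed-form checks.
#' @param rel_cutoff lateral Gaussian sparsity cutoff relative to its peak;
#'   contributions below it are dropped (default 1e-3).
#' @return list with class `dose_engine_config`.
#' @export
dose_engine_config <- function(mu_eff_per_mm = 0.005, beamlet_size_mm = 5,
                               lateral_sigma_mm = 3, sad_mm = 1000,
                               parallel = FALSE, rel_cutoff = 1e-3) {
  if (any(c(mu_eff_per_mm, beamlet_size_mm, lateral_sigma_mm, sad_mm, rel_cutoff) <= 0))
    stop("all dose-engine parameters must be strictly positive")
  structure(list(mu_eff_per_mm = mu_eff_per_mm, beamlet_size_mm = beamlet_size_mm,
                 lateral_sigma_mm = lateral_sigma_mm, sad_mm = sad_mm,
                 parallel = isTRUE(parallel), rel_cutoff = rel_cutoff),
            class = "dose_engine_config")
}

# Beamlet lattice inside the jaw rectangle: centres in collimator-frame BEV
# coordinates, pitch <= beamlet_size_mm so the jaws are tiled exactly.
beamlet_lattice <- function(jaws, beamlet_size_mm) {
  wx <- jaws[["X2"]] - jaws[["X1"]]
  wy <- jaws[["Y2"]] - jaws[["Y1"]]
  if (wx <= 0 || wy <= 0) stop("zero-area jaws")
  nx <- max(1L, ceiling(wx / beamlet_size_mm))
  ny <- max(1L, ceiling(wy / beamlet_size_mm))
  px <- wx / nx; py <- wy / ny
  xs <- jaws[["X1"]] + (seq_len(nx) - 0.5) * px
  ys <- jaws[["Y1"]] + (seq_len(ny) - 0.5) * py
  list(nx = nx, ny = ny, pitch = c(px, py),
       centers = cbind(x = rep(xs, times = ny), y = rep(ys, each = nx)))
}

#' Per-beamlet dose-influence matrix for one field
#'
#' Partitions the field's jaw rectangle into beamlets and, for each beamlet,
#' casts the divergent central ray from the source through the beamlet centre,
#' depositing dose per unit beamlet weight at every body voxel within the
#' lateral Gaussian cutoff (see [dose_engine_config()]). Voxels outside the
#' body receive nothing.
#'
#' @param field a `beam_field` from [build_fields()].
#' @param grid a [voxel_grid].
#' @param body logical body mask (non-empty).
#' @param config a [dose_engine_config()].
#' @param density optional relative-density array on the grid (e.g. a reduced
#'   value inside the lungs); by default the body is water-equivalent
#'   (density 1 everywhere inside). Only radiological depth is affected.
#' @return object of class `dose_influence`: `field` (name), `nx`, `ny`,
#'   `pitch` (mm), `centers` (beamlet BEV coordinates), `matrix` (sparse
#'   body-voxel x beamlet matrix, Gy per unit weight), `body_index` (linear
#'   indices of body voxels in grid order).
#' @export
beamlet_influence <- function(field, grid, body, config = dose_engine_config(),
                              density = NULL) {
  body <- body != 0
  if (!any(body)) stop("empty body mask")
  if (!is.null(density)) stopifnot(all(dim(density) == grid$shape))
  lat <- beamlet_lattice(field$jaws_mm, config$beamlet_size_mm)
  fr <- beam_frame(field$gantry_deg, field$collimator_deg, field$isocenter_mm,
                   field$sad_mm)
  bw <- matrix(rep(field$isocenter_mm, each = nrow(lat$centers)), ncol = 3) +
    lat$centers[, 1] %o% fr$e1c + lat$centers[, 2] %o% fr$e2c
  if (!config$parallel) {
    # degenerate geometry guard: source must sit outside the body
    si <- round((fr$source - grid$origin) / grid$spacing) + 1
    if (all(si >= 1) && all(si <= grid$shape) && body[si[1], si[2], si[3]])
      stop("degenerate geometry: source inside the body")
  }
  vx <- voxel_centers(grid, body)
  tr <- beamlet_influence_cpp(grid$origin, grid$spacing, grid$shape,
                              as.logical(body), vx, fr$source, fr$b, bw,
                              config$sad_mm, config$mu_eff_per_mm,
                              config$lateral_sigma_mm, config$parallel,
                              config$rel_cutoff,
                              if (is.null(density)) numeric(0) else as.numeric(density))
  m <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(nrow(vx), nrow(lat$centers)))
  structure(list(field = field$name, nx = lat$nx, ny = lat$ny,
                 pitch = lat$pitch, centers = lat$centers, matrix = m,
                 body_index = which(body)),
            class = "dose_influence")
}

#' Total dose from fluence maps
#'
#' Linear superposition `dose = sum_f A_f w_f` of the per-field influence
#' matrices weighted by the (vectorized) fluence maps.
#'
#' @param influences list of [beamlet_influence()] results (one grid).
#' @param fluences list of nonnegative weight maps (matrix `nx x ny` or vector
#'   of length `nx * ny`), one per influence.
#' @param grid the shared [voxel_grid].
#' @return 3-D dose array (Gy) on the grid; zero outside the body.
#' @export
compute_dose <- function(influences, fluences, grid) {
  if (length(influences) != length(fluences))
    stop("one fluence map per influence matrix required")
  dose_vec <- NULL
  for (k in seq_along(influences)) {
    inf <- influences[[k]]
    w <- as.numeric(fluences[[k]])
    if (length(w) != ncol(inf$matrix))
      stop(sprintf("fluence shape mismatch for field %s", inf$field))
    contrib <- as.numeric(inf$matrix %*% w)
    dose_vec <- if (is.null(dose_vec)) contrib else dose_vec + contrib
  }
  dose <- array(0, grid$shape)
  dose[influences[[1]]$body_index] <- dose_vec
  dose
}
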