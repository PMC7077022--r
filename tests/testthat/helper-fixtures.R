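# Shared fixtures: everything is generated in code at test time.

# coarse lattice used where a full phantom is needed cheaply
coarse_grid <- function() voxel_grid(c(48, 38, 22), spacing = c(8, 8, 6))

coarse_phantom <- function(size = "medium", seed = 1)
  generate_phantom(size, seed = seed, grid = coarse_grid())

# a tiny water slab completely filling a small grid, for dose closed forms
slab_case <- function(shape = c(9, 31, 9), spacing = c(2, 2, 2)) {
  g <- voxel_grid(shape, spacing = spacing, origin = c(0, 0, 0))
  body <- array(TRUE, g$shape)
  list(grid = g, body = body,
       iso = g$origin + (g$shape - 1) * g$spacing / 2)
}

# one anterior field with explicit jaws on a slab
slab_field <- function(case, jaws = c(X1 = -4, X2 = 4, Y1 = -4, Y2 = 4),
                       gantry = 0, collimator = 0) {
  autotangent:::new_field("F1", "major", gantry, collimator, case$iso, jaws)
}

# independent exhaustive angle-area oracle: full per-pair recomputation with
# explicit rotation matrices (deliberately different formulation from the
# package's vectorized scan)
oracle_field_areas <- function(pts, iso, gantry_window, sad = 1000) {
  coll <- c(330:359, 0:30)
  out <- matrix(NA_real_, length(gantry_window), length(coll),
                dimnames = list(gantry_window, coll))
  rotz <- function(a) {
    r <- a * pi / 180
    matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
  }
  for (gi in seq_along(gantry_window)) {
    Rg <- rotz(gantry_window[gi])
    src <- iso + sad * drop(Rg %*% c(0, -1, 0))
    ax <- drop(Rg %*% c(1, 0, 0))     # BEV x at collimator 0
    az <- c(0, 0, 1)
    bb <- (iso - src) / sad           # unit beam direction
    v <- sweep(pts, 2, src)
    tt <- v %*% bb
    px <- (v %*% ax) * (sad / tt)
    py <- (v %*% az) * (sad / tt)
    for (ci in seq_along(coll)) {
      r <- coll[ci] * pi / 180
      xc <- cos(r) * px + sin(r) * py
      yc <- -sin(r) * px + cos(r) * py
      out[gi, ci] <- (max(xc) - min(xc)) * (max(yc) - min(yc))
    }
  }
  out
}

# brute-force voxel set oracles
brute_ball_dilate <- function(mask, radius, grid) {
  pts <- voxel_centers(grid, mask)
  all_pts <- voxel_centers(grid)
  out <- array(FALSE, grid$shape)
  for (r in seq_len(nrow(all_pts))) {
    d2 <- colSums((t(pts) - all_pts[r, ])^2)
    if (any(d2 <= radius^2 + 1e-9)) out[r] <- TRUE
  }
  out
}
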