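#' Hypofractionated whole-breast prescription
#'
#' @param total_dose_gy total prescription dose in Gy (default 42.56).
#' @param fractions number of daily fractions (default 16).
#' @return list with class `prescription`; `per_fraction_gy` is derived.
#' @export
prescription <- function(total_dose_gy = 42.56, fractions = 16) {
  if (total_dose_gy <= 0 || fractions <= 0) stop("prescription must be positive")
  structure(list(total_dose_gy = total_dose_gy, fractions = as.integer(fractions),
                 per_fraction_gy = total_dose_gy / fractions),
            class = "prescription")
}

# IEC 61217 coplanar geometry, patient axes right->left, anterior->posterior,
# inferior->superior. Gantry 0 = beam from anterior; 90 = from patient left.
# Unit vector from isocenter toward the source:
gantry_unit <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  c(sin(g), -cos(g), 0)
}

# Beam frame: source position, beam direction b (source -> isocenter) and the
# collimator-rotated in-plane axes e1c, e2c on the isocenter plane.
beam_frame <- function(gantry_deg, collimator_deg, isocenter_mm, sad_mm = 1000) {
  u <- gantry_unit(gantry_deg)
  g <- gantry_deg * pi / 180
  e1 <- c(cos(g), sin(g), 0)   # BEV x before collimator rotation
  e2 <- c(0, 0, 1)             # BEV y = patient superior
  ph <- collimator_deg * pi / 180
  list(source = isocenter_mm + sad_mm * u,
       b = -u,
       e1 = e1, e2 = e2,
       e1c = cos(ph) * e1 + sin(ph) * e2,
       e2c = -sin(ph) * e1 + cos(ph) * e2,
       sad = sad_mm)
}

#' Centroid of a PTV mask
#'
#' The treatment isocenter is placed at the unweighted mean of the PTV voxel
#' centres.
#'
#' @param ptv logical array (non-empty).
#' @param grid a [voxel_grid].
#' @return 3-vector in mm.
#' @export
ptv_centroid <- function(ptv, grid) {
  if (!any(ptv != 0)) stop("empty PTV")
  colMeans(voxel_centers(grid, ptv))
}

#' Beam's-eye-view projection of points
#'
#' Divergent central projection from the source (at `sad_mm` from the
#' isocenter along the gantry direction) onto the plane through the isocenter
#' perpendicular to the beam axis, expressed in the collimator-rotated
#' in-plane frame. Points on the isocenter plane are fixed; points upstream
#' (closer to the source) are magnified by `sad / t` where `t` is the distance
#' from the source along the beam axis.
#'
#' @param points_mm N x 3 matrix (or 3-vector) of points in patient mm.
#' @param gantry_deg,collimator_deg beam angles in degrees.
#' @param isocenter_mm 3-vector, mm.
#' @param sad_mm source-axis distance, mm (default 1000).
#' @return N x 2 matrix of in-plane coordinates (mm).
#' @export
bev_project <- function(points_mm, gantry_deg, collimator_deg, isocenter_mm,
                        sad_mm = 1000) {
  p <- matrix(points_mm, ncol = 3)
  fr <- beam_frame(gantry_deg, collimator_deg, isocenter_mm, sad_mm)
  v <- sweep(p, 2, fr$source)
  t <- drop(v %*% fr$b)
  if (any(t <= 0)) stop("point at or behind the source; projection undefined")
  s <- fr$sad / t
  cbind(x = drop(v %*% fr$e1c) * s, y = drop(v %*% fr$e2c) * s)
}

#' Fit jaws around projected points
#'
#' Axis-aligned bounding rectangle of the BEV points, expanded by `margin_mm`
#' on every side.
#'
#' @param points_2d N x 2 matrix of BEV coordinates (mm).
#' @param margin_mm flash margin added on each side (default 0).
#' @return named vector `(X1, X2, Y1, Y2)` with `X1 < X2`, `Y1 < Y2` (equal
#'   for degenerate point sets).
#' @export
fit_jaws <- function(points_2d, margin_mm = 0) {
  p <- matrix(points_2d, ncol = 2)
  if (nrow(p) == 0) stop("empty point list")
  c(X1 = min(p[, 1]) - margin_mm, X2 = max(p[, 1]) + margin_mm,
    Y1 = min(p[, 2]) - margin_mm, Y2 = max(p[, 2]) + margin_mm)
}

#' Field area of a jaw rectangle
#' @param jaws vector `(X1, X2, Y1, Y2)` in mm.
#' @return area in mm^2.
#' @export
jaw_area <- function(jaws) {
  (jaws[["X2"]] - jaws[["X1"]]) * (jaws[["Y2"]] - jaws[["Y1"]])
}

# Collimator window 330..359 then 0..30, as iterated
collimator_window <- function() c(330:359, 0:30)

# circular deviation of a collimator angle from 0
circ_dev <- function(a) pmin(a %% 360, 360 - a %% 360)

# Exhaustive (gantry x collimator) scan for one major field.
# Returns the full trace and the tie-broken argmin.
scan_field_angles <- function(pts, isocenter_mm, gantry_window, sad_mm,
                              margin_mm, gantry_ref) {
  coll <- collimator_window()
  ph <- coll * pi / 180
  cph <- cos(ph); sph <- sin(ph)
  ng <- length(gantry_window); nc <- length(coll)
  areas <- matrix(NA_real_, ng, nc)
  for (gi in seq_len(ng)) {
    g <- gantry_window[gi]
    fr <- beam_frame(g, 0, isocenter_mm, sad_mm)
    v <- sweep(pts, 2, fr$source)
    t <- drop(v %*% fr$b)
    s <- sad_mm / t
    px <- drop(v %*% fr$e1) * s
    py <- drop(v %*% fr$e2) * s
    # collimator rotation of the projected cloud, all angles at once
    xc <- outer(px, cph) + outer(py, sph)
    yc <- outer(py, cph) - outer(px, sph)
    dx <- apply(xc, 2, max) - apply(xc, 2, min) + 2 * margin_mm
    dy <- apply(yc, 2, max) - apply(yc, 2, min) + 2 * margin_mm
    areas[gi, ] <- dx * dy
  }
  trace <- data.frame(gantry = rep(gantry_window, times = nc),
                      collimator = rep(coll, each = ng),
                      area = as.vector(areas))
  dev <- abs(trace$gantry - gantry_ref) + circ_dev(trace$collimator)
  ord <- order(trace$area, dev, trace$gantry, trace$collimator)
  best <- trace[ord[1], ]
  list(gantry = best$gantry, collimator = best$collimator, area = best$area,
       trace = trace)
}

#' Exhaustive tangential angle search
#'
#' For each major field, every integer gantry angle in its window (F1:
#' 270-330, F2: 90-150) is combined with every integer collimator angle in
#' 330-359 and 0-30 (61 x 61 = 3721 pairs per field). For each pair the PTV
#' surface voxel centres are projected into the BEV, jaws are fitted, and the
#' field area is recorded; the pair with the smallest area wins. Ties are
#' broken toward the conventional tangents (gantry 300 for F1, 120 for F2,
#' collimator 0), then toward the lower gantry, then the lower collimator.
#'
#' @param ptv logical PTV array.
#' @param grid a [voxel_grid].
#' @param isocenter_mm 3-vector, mm (typically [ptv_centroid()]).
#' @param sad_mm source-axis distance (default 1000 mm).
#' @param margin_mm jaw flash margin passed to the fit (default 0).
#' @return list with `f1`, `f2` (each `gantry`, `collimator`, `area`, `jaws`)
#'   and `trace`, a data frame of every evaluation (`field`, `gantry`,
#'   `collimator`, `area`; 7442 rows).
#' @export
search_tangential_angles <- function(ptv, grid, isocenter_mm,
                                     sad_mm = 1000, margin_mm = 0) {
  if (!any(ptv != 0)) stop("empty PTV")
  pts <- voxel_centers(grid, mask_surface(ptv))
  f1 <- scan_field_angles(pts, isocenter_mm, 270:330, sad_mm, margin_mm, 300)
  f2 <- scan_field_angles(pts, isocenter_mm, 90:150, sad_mm, margin_mm, 120)
  jaws1 <- fit_jaws(bev_project(pts, f1$gantry, f1$collimator, isocenter_mm, sad_mm),
                    margin_mm)
  jaws2 <- fit_jaws(bev_project(pts, f2$gantry, f2$collimator, isocenter_mm, sad_mm),
                    margin_mm)
  trace <- rbind(cbind(field = "F1", f1$trace), cbind(field = "F2", f2$trace))
  list(f1 = list(gantry = f1$gantry, collimator = f1$collimator,
                 area = f1$area, jaws = jaws1),
       f2 = list(gantry = f2$gantry, collimator = f2$collimator,
                 area = f2$area, jaws = jaws2),
       trace = trace)
}

new_field <- function(name, role, gantry, collimator, isocenter, jaws,
                      sad = 1000) {
  structure(list(name = name, role = role,
                 gantry_deg = gantry %% 360, collimator_deg = collimator %% 360,
                 isocenter_mm = isocenter, jaws_mm = jaws, sad_mm = sad,
                 fluence = NULL),
            class = "beam_field")
}

#' @export
print.beam_field <- function(x, ...) {
  cat(sprintf("%s (%s): gantry %g, collimator %g, jaws [%.1f, %.1f] x [%.1f, %.1f] mm (%.0f mm^2)\n",
              x$name, x$role, x$gantry_deg, x$collimator_deg,
              x$jaws_mm[["X1"]], x$jaws_mm[["X2"]], x$jaws_mm[["Y1"]],
              x$jaws_mm[["Y2"]], jaw_area(x$jaws_mm)))
  invisible(x)
}

#' Build the six tangential fields
#'
#' Constructs the two major fields F1/F2 at the searched angles with jaws
#' fitted to the projected PTV, and the four minor fields at fixed gantry
#' offsets: F3 = F1+15, F4 = F1+30, F5 = F1+45, F6 = F2-15 (mod 360), each
#' with the collimator copied from its parent major field. Minor-field jaws
#' are first fitted to the PTV, then the inner X jaw (the jaw edge on the
#' chest-wall side of the projected isocenter) is repositioned to
#' `inner_jaw_mm` beyond the isocenter projection, which trims the deep edge
#' of the minor fields.
#'
#' @param f1_angles,f2_angles lists with `gantry` and `collimator` (degrees),
#'   e.g. the `f1`/`f2` elements of [search_tangential_angles()].
#' @param ptv logical PTV array.
#' @param grid a [voxel_grid].
#' @param isocenter_mm 3-vector, mm.
#' @param inner_jaw_mm inner-jaw opening beyond the isocenter (default 15 mm).
#' @param sad_mm source-axis distance (default 1000 mm).
#' @param margin_mm jaw flash margin (default 0).
#' @return list of six `beam_field` objects named F1..F6.
#' @export
build_fields <- function(f1_angles, f2_angles, ptv, grid, isocenter_mm,
                         inner_jaw_mm = 15, sad_mm = 1000, margin_mm = 0) {
  pts <- voxel_centers(grid, mask_surface(ptv))
  fit_for <- function(g, c) {
    fit_jaws(bev_project(pts, g, c, isocenter_mm, sad_mm), margin_mm)
  }
  angset <- list(
    F1 = list(g = f1_angles$gantry, c = f1_angles$collimator, role = "major"),
    F2 = list(g = f2_angles$gantry, c = f2_angles$collimator, role = "major"),
    F3 = list(g = f1_angles$gantry + 15, c = f1_angles$collimator, role = "minor"),
    F4 = list(g = f1_angles$gantry + 30, c = f1_angles$collimator, role = "minor"),
    F5 = list(g = f1_angles$gantry + 45, c = f1_angles$collimator, role = "minor"),
    F6 = list(g = f2_angles$gantry - 15, c = f2_angles$collimator, role = "minor"))
  fields <- list()
  for (nm in names(angset)) {
    a <- angset[[nm]]
    g <- a$g %% 360
    jaws <- fit_for(g, a$c)
    if (a$role == "minor") {
      # which X side faces the chest wall: project a posterior probe point
      probe <- bev_project(isocenter_mm + c(0, 100, 0), g, a$c, isocenter_mm, sad_mm)
      if (probe[1, 1] >= 0) {
        jaws[["X2"]] <- inner_jaw_mm
        if (jaws[["X1"]] > jaws[["X2"]]) jaws[["X1"]] <- jaws[["X2"]]
      } else {
        jaws[["X1"]] <- -inner_jaw_mm
        if (jaws[["X2"]] < jaws[["X1"]]) jaws[["X2"]] <- jaws[["X1"]]
      }
      if (g > 15 && g < 75)
        warning(sprintf("%s gantry %g enters near the contralateral side", nm, g))
    }
    fields[[nm]] <- new_field(nm, a$role, g, a$c, isocenter_mm, jaws, sad_mm)
  }
  fields
}
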