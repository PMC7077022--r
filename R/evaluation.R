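#' Cumulative dose-volume histogram
#'
#' Voxel-counting cumulative DVH: `V(d)` is the percentage of the structure's
#' volume receiving at least `d` Gy, tabulated on dose bin edges of width
#' `bin_width_gy` from 0 to just past the maximum dose.
#'
#' @param dose 3-D dose array (Gy).
#' @param mask logical structure mask (non-empty).
#' @param bin_width_gy dose bin width (default 0.01 Gy).
#' @param structure optional structure name carried in the result.
#' @return object of class `dvh`: `structure`, `dose_bins_gy` (edges),
#'   `cum_volume_pct`, and the raw voxel `doses` used for exact quantiles.
#' @export
dvh <- function(dose, mask, bin_width_gy = 0.01, structure = NA_character_) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  d <- as.numeric(dose[mask])
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  # V(edge) = % of voxels with dose >= edge, via the sorted-dose ECDF
  sd <- sort(d)
  below <- findInterval(edges, sd, left.open = TRUE)  # voxels with dose < edge
  v <- 100 * (length(d) - below) / length(d)
  structure(list(structure = structure, dose_bins_gy = edges,
                 cum_volume_pct = v, doses = d),
            class = "dvh")
}

#' Volume receiving at least a dose (Vd)
#'
#' @param x a [dvh()].
#' @param dose_gy dose level (Gy).
#' @return percentage of the structure volume with dose `>= dose_gy` (exact
#'   voxel counting, not the binned curve).
#' @export
volume_at_dose <- function(x, dose_gy) {
  100 * mean(x$doses >= dose_gy)
}

#' Dose to the hottest x% of the volume (Dx)
#'
#' Exact-quantile convention: the largest dose `d` such that at least
#' `volume_pct` of the structure receives `>= d`. With this convention
#' `V(Dx) >= x` and `V(Dx + e) <= x` hold exactly, and a uniform dose returns
#' that dose for every `x`. Set `interpolate = TRUE` for the binned-curve
#' linear-interpolation inverse instead.
#'
#' @param x a [dvh()].
#' @param volume_pct volume percentage in (0, 100].
#' @param interpolate use linear interpolation on the binned cumulative curve.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(x, volume_pct, interpolate = FALSE) {
  if (volume_pct <= 0 || volume_pct > 100) stop("volume_pct must be in (0, 100]")
  if (!interpolate) {
    n <- length(x$doses)
    k <- max(1L, ceiling(n * volume_pct / 100))
    return(sort(x$doses, decreasing = TRUE)[k])
  }
  v <- x$cum_volume_pct; e <- x$dose_bins_gy
  i <- max(which(v >= volume_pct))
  if (i == length(e)) return(e[i])
  if (v[i] == v[i + 1]) return(e[i])
  e[i] + (v[i] - volume_pct) / (v[i] - v[i + 1]) * (e[i + 1] - e[i])
}

#' Plan-quality metrics
#'
#' Computes the standard evaluation scalars for a whole-breast plan:
#' body V110% (hotspot), PTV V95% (coverage), homogeneity index
#' `HI = D5% / D95%` on the PTV, conformity index `CI = BV95% / PTV volume`
#' with BV95% the body volume receiving at least 95% of prescription,
#' ipsilateral-lung V16Gy, V4Gy and mean dose, heart V20Gy and mean dose,
#' contralateral-breast V5Gy and maximum dose, and the MU proxy.
#'
#' @param dose 3-D dose array (Gy).
#' @param structures a [structure_set] with Body, PTV, LungIpsi, Heart and
#'   BreastContra.
#' @param rx a [prescription()].
#' @param mu MU proxy carried through (default `NA`).
#' @return list of class `plan_metrics`.
#' @export
plan_metrics <- function(dose, structures, rx, mu = NA_real_) {
  grid <- structures$grid
  d_rx <- rx$total_dose_gy
  dv <- function(name) dvh(dose, get_mask(structures, name), structure = name)
  body <- dv("Body"); ptv <- dv("PTV"); lung <- dv("LungIpsi")
  heart <- dv("Heart"); cbreast <- dv("BreastContra")
  ptv_vol <- mask_volume_ml(get_mask(structures, "PTV"), grid)
  body_vol <- mask_volume_ml(get_mask(structures, "Body"), grid)
  bv95 <- volume_at_dose(body, 0.95 * d_rx) / 100 * body_vol
  d5 <- dose_at_volume(ptv, 5); d95 <- dose_at_volume(ptv, 95)
  structure(list(
    body_v110_pct = volume_at_dose(body, 1.10 * d_rx),
    ptv_v95_pct = volume_at_dose(ptv, 0.95 * d_rx),
    hi = d5 / d95,
    ci = bv95 / ptv_vol,
    lung_ipsi_v16gy_pct = volume_at_dose(lung, 16),
    lung_ipsi_v4gy_pct = volume_at_dose(lung, 4),
    lung_ipsi_mean_gy = mean(lung$doses),
    heart_v20gy_pct = volume_at_dose(heart, 20),
    heart_mean_gy = mean(heart$doses),
    breast_contra_v5gy_pct = volume_at_dose(cbreast, 5),
    breast_contra_max_gy = max(cbreast$doses),
    mu = mu), class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("PTV V95 %.1f%%, HI %.3f, CI %.3f, body V110 %.2f%%\n",
              x$ptv_v95_pct, x$hi, x$ci, x$body_v110_pct))
  cat(sprintf("Lung V16 %.1f%% V4 %.1f%% mean %.2f Gy | heart V20 %.2f%% mean %.2f Gy | contra breast V5 %.2f%% max %.2f Gy | MU %.0f\n",
              x$lung_ipsi_v16gy_pct, x$lung_ipsi_v4gy_pct, x$lung_ipsi_mean_gy,
              x$heart_v20gy_pct, x$heart_mean_gy,
              x$breast_contra_v5gy_pct, x$breast_contra_max_gy, x$mu))
  invisible(x)
}

#' Normalize one DVH's dose axis to another's V95-defining dose
#'
#' Finds the dose at which each cumulative curve crosses 95% volume and
#' rescales the dose axis of `dvh_other` by the ratio so both curves cross
#' 95% at the same dose; used to compare PTV DVHs between plans.
#'
#' @param dvh_ref,dvh_other [dvh()] objects (typically PTV).
#' @return the rescaled `dvh_other`.
#' @export
normalize_to_v95 <- function(dvh_ref, dvh_other) {
  d_ref <- dose_at_volume(dvh_ref, 95)
  d_oth <- dose_at_volume(dvh_other, 95)
  if (!is.finite(d_ref) || !is.finite(d_oth) || d_ref <= 0 || d_oth <= 0)
    stop("V95-defining dose undefined (degenerate DVH)")
  s <- d_ref / d_oth
  out <- dvh_other
  out$dose_bins_gy <- dvh_other$dose_bins_gy * s
  out$doses <- dvh_other$doses * s
  out
}

#' Mean DVH curve with confidence band
#'
#' Resamples every curve onto a common dose grid (linear interpolation; 100%
#' below each curve's support, 0% beyond its maximum dose) and returns the
#' per-bin mean with a t-based confidence interval of the mean.
#'
#' @param dvhs list of at least two [dvh()] objects.
#' @param ci_level confidence level (default 0.95).
#' @param bin_width_gy resampling bin width (default 0.05 Gy).
#' @return data frame with `dose_gy`, `mean_pct`, `lower_pct`, `upper_pct`.
#' @export
mean_dvh_band <- function(dvhs, ci_level = 0.95, bin_width_gy = 0.05) {
  if (length(dvhs) < 2) stop("at least two DVH curves required")
  dmax <- max(vapply(dvhs, function(x) max(x$dose_bins_gy), numeric(1)))
  gridd <- seq(0, dmax, by = bin_width_gy)
  vals <- vapply(dvhs, function(x)
    stats::approx(x$dose_bins_gy, x$cum_volume_pct, xout = gridd,
                  yleft = 100, yright = 0, rule = 2)$y,
    numeric(length(gridd)))
  vals <- matrix(vals, nrow = length(gridd))
  n <- ncol(vals)
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * s / sqrt(n)
  data.frame(dose_gy = gridd, mean_pct = m,
             lower_pct = pmax(m - half, 0), upper_pct = pmin(m + half, 100))
}

#' Plot mean DVH bands
#'
#' Base-graphics plot of one or more [mean_dvh_band()] results.
#'
#' @param bands named list of band data frames.
#' @param main plot title.
#' @param cols line colours (recycled).
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plot_dvh_band <- function(bands, main = "Mean DVH with confidence band",
                          cols = c("#c0392b", "#27ae60", "#2980b9", "#8e44ad")) {
  if (!is.list(bands) || is.data.frame(bands)) bands <- list(band = bands)
  dmax <- max(vapply(bands, function(b) max(b$dose_gy), numeric(1)))
  plot(NULL, xlim = c(0, dmax), ylim = c(0, 100), xlab = "Dose [Gy]",
       ylab = "Volume [%]", main = main)
  cols <- rep(cols, length.out = length(bands))
  for (k in seq_along(bands)) {
    b <- bands[[k]]
    graphics::polygon(c(b$dose_gy, rev(b$dose_gy)),
                      c(b$lower_pct, rev(b$upper_pct)),
                      col = grDevices::adjustcolor(cols[k], alpha.f = 0.25),
                      border = NA)
    graphics::lines(b$dose_gy, b$mean_pct, col = cols[k], lwd = 2)
  }
  graphics::legend("topright", legend = names(bands), col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Paired two-tailed t-test
#'
#' Classical paired t statistic with `n - 1` degrees of freedom. If every
#' pairwise difference is zero the comparison is degenerate and `p = 1` is
#' reported; a nonzero constant difference (zero variance, nonzero mean) has
#' an undefined t statistic and raises an error.
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @return list: `t`, `p`, `df`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least two pairs")
  d <- a - b
  out <- list(mean_a = mean(a), sd_a = stats::sd(a),
              mean_b = mean(b), sd_b = stats::sd(b), mean_diff = mean(d))
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(c(out, list(t = 0, p = 1, df = length(a) - 1, degenerate = TRUE)))
    stop("zero variance of differences with nonzero mean: t undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  c(out, list(t = unname(tt$statistic), p = tt$p.value,
              df = unname(tt$parameter), degenerate = FALSE))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with `(k - 1, N - k)` degrees of
#' freedom. If the data carry no variance at all (all groups constant and
#' equal) the degenerate result `F = 0, p = 1` is reported.
#'
#' @param groups list of at least two numeric vectors, each with >= 2 values.
#' @return list: `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least two values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- nlevels(g); n <- length(y)
  if (stats::var(y) == 0)
    return(list(F = 0, p = 1, df1 = k - 1, df2 = n - k, degenerate = TRUE))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
       degenerate = FALSE)
}
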