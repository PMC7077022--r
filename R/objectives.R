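#' A single dose-volume objective
#'
#' @param structure structure name the objective applies to.
#' @param kind one of `"lower_dv"`, `"upper_dv"`, `"mean_upper"`, `"max_upper"`.
#' @param dose_gy dose threshold in Gy (>= 0).
#' @param volume_pct volume threshold in percent for the dose-volume kinds
#'   (ignored for `mean_upper`/`max_upper`).
#' @param weight nonnegative penalty weight.
#' @return list with class `dv_objective`.
#' @export
objective <- function(structure, kind = c("lower_dv", "upper_dv", "mean_upper", "max_upper"),
                      dose_gy, volume_pct = NA_real_, weight = 1) {
  kind <- match.arg(kind)
  if (dose_gy < 0) stop("dose_gy must be >= 0")
  if (weight < 0) stop("weight must be >= 0")
  if (kind %in% c("lower_dv", "upper_dv")) {
    if (is.na(volume_pct) || volume_pct < 0 || volume_pct > 100)
      stop("volume_pct in [0, 100] required for dose-volume objectives")
  }
  structure(list(structure = structure, kind = kind, dose_gy = dose_gy,
                 volume_pct = volume_pct, weight = weight),
            class = "dv_objective")
}

#' Bundle objectives into a template
#'
#' At least one `lower_dv` objective on the PTV must be present.
#'
#' @param objectives list of [objective()]s.
#' @return list with class `objective_template`.
#' @export
objective_template <- function(objectives) {
  stopifnot(is.list(objectives), length(objectives) > 0)
  ok <- vapply(objectives, function(o)
    inherits(o, "dv_objective") && o$structure == "PTV" && o$kind == "lower_dv",
    logical(1))
  if (!any(ok)) stop("template must contain at least one PTV lower_dv objective")
  structure(list(objectives = objectives), class = "objective_template")
}

#' Default whole-breast objective template
#'
#' A configurable default driving the fluence optimization: PTV coverage and
#' hotspot control, posterior ring falloff, and organ-at-risk sparing levels
#' in line with routine whole-breast constraints. All entries can be replaced
#' by passing a custom [objective_template()] to [autoplan()].
#'
#' @param rx a [prescription()] (default 42.56 Gy / 16 fractions).
#' @return an [objective_template()] with entries for PTV (lower and upper),
#'   Ring_1, Ring_2, LungIpsi, Heart and BreastContra.
#' @export
default_objective_template <- function(rx = prescription()) {
  d <- rx$total_dose_gy
  objective_template(list(
    objective("PTV", "lower_dv", d, 98, 100),
    objective("PTV", "upper_dv", 1.05 * d, 0, 80),
    objective("Ring_1", "max_upper", 0.95 * d, weight = 30),
    objective("Ring_2", "max_upper", 0.80 * d, weight = 20),
    objective("LungIpsi", "mean_upper", 6, weight = 20),
    objective("Heart", "mean_upper", 1.5, weight = 20),
    objective("BreastContra", "max_upper", 3, weight = 20)))
}

# Value and gradient of one objective on the dose vector of its structure.
# Returns list(value, grad) with grad the derivative w.r.t. those doses.
obj_term <- function(d, o) {
  n <- length(d)
  w <- o$weight
  switch(o$kind,
    lower_dv = {
      vnow <- 100 * mean(d >= o$dose_gy)
      if (vnow >= o$volume_pct) return(list(value = 0, grad = numeric(n)))
      viol <- pmax(o$dose_gy - d, 0)
      list(value = w * mean(viol^2), grad = -2 * w * viol / n)
    },
    upper_dv = {
      vnow <- 100 * mean(d > o$dose_gy)
      if (vnow <= o$volume_pct) return(list(value = 0, grad = numeric(n)))
      viol <- pmax(d - o$dose_gy, 0)
      list(value = w * mean(viol^2), grad = 2 * w * viol / n)
    },
    mean_upper = {
      e <- max(mean(d) - o$dose_gy, 0)
      list(value = w * e^2, grad = rep(2 * w * e / n, n))
    },
    max_upper = {
      viol <- pmax(d - o$dose_gy, 0)
      list(value = w * mean(viol^2), grad = 2 * w * viol / n)
    })
}

#' Composite objective value of a dose distribution
#'
#' Sum over the template's objectives of `weight` times the mean squared
#' violation over the structure's voxels: `lower_dv` penalizes voxels below
#' the dose threshold when the structure's volume above it is under
#' `volume_pct`; `upper_dv` symmetrically; `mean_upper` penalizes the squared
#' positive excess of the structure mean; `max_upper` penalizes every voxel's
#' positive excess.
#'
#' @param dose 3-D dose array (Gy) on the structure set's grid.
#' @param structures a [structure_set].
#' @param template an [objective_template()].
#' @return nonnegative scalar (Gy^2).
#' @export
objective_value <- function(dose, structures, template) {
  stopifnot(all(dim(dose) == structures$grid$shape))
  total <- 0
  for (o in template$objectives) {
    m <- get_mask(structures, o$structure)
    if (!any(m)) stop(sprintf("objective references empty structure '%s'", o$structure))
    total <- total + obj_term(dose[m], o)$value
  }
  if (!is.finite(total)) stop("non-finite objective value")
  total
}
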