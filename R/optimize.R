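#' Hotspot handling policy
#'
#' After the first optimization pass the volume of the region above the
#' hotspot isodose level is measured; if it exceeds `trigger_volume_cc` the
#' hotspot structure is added to the objective template and the plan is
#' re-optimized exactly once (`max_reoptimizations` is 1 by design).
#'
#' @param isodose_level_pct hotspot isodose level in percent of prescription
#'   (default 105).
#' @param trigger_volume_cc trigger volume in cc (default 0.5).
#' @param max_reoptimizations number of re-optimization passes (fixed default 1).
#' @return list with class `hotspot_policy`.
#' @export
hotspot_policy <- function(isodose_level_pct = 105, trigger_volume_cc = 0.5,
                           max_reoptimizations = 1) {
  if (isodose_level_pct <= 100) stop("isodose_level_pct must exceed 100")
  if (trigger_volume_cc < 0) stop("trigger_volume_cc must be >= 0")
  structure(list(isodose_level_pct = isodose_level_pct,
                 trigger_volume_cc = trigger_volume_cc,
                 max_reoptimizations = as.integer(max_reoptimizations)),
            class = "hotspot_policy")
}

#' Hotspot structure from a dose distribution
#'
#' The hotspot mask collects voxels with dose strictly above
#' `isodose_level_pct` percent of the total prescription (a voxel at exactly
#' the level is excluded).
#'
#' @param dose 3-D dose array (Gy).
#' @param grid a [voxel_grid].
#' @param rx a [prescription()].
#' @param policy a [hotspot_policy()].
#' @return list with `mask` (logical array) and `volume_cc`.
#' @export
make_hotspot_structure <- function(dose, grid, rx, policy = hotspot_policy()) {
  level <- policy$isodose_level_pct / 100 * rx$total_dose_gy
  mask <- dose > level
  list(mask = mask, volume_cc = mask_volume_cc(mask, grid))
}

# quadratic neighbour-difference smoothing operator for one fluence lattice:
# sparse edge-difference matrix over the nx x ny beamlet grid (4-neighbourhood)
fluence_diff_matrix <- function(nx, ny) {
  vid <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0)
  if (nx > 1) {
    a <- as.vector(outer(1:(nx - 1), 1:ny, vid)); ii <- c(ii, a); jj <- c(jj, a + 1L)
  }
  if (ny > 1) {
    a <- as.vector(outer(1:nx, 1:(ny - 1), vid)); ii <- c(ii, a); jj <- c(jj, a + nx)
  }
  ne <- length(ii)
  if (ne == 0) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(0, nx * ny)))
  Matrix::sparseMatrix(i = rep(seq_len(ne), 2), j = c(ii, jj),
                       x = c(rep(1, ne), rep(-1, ne)), dims = c(ne, nx * ny))
}

# map template structures to index vectors within the body-voxel ordering
structure_body_indices <- function(structures, template, body_index) {
  nms <- unique(vapply(template$objectives, `[[`, character(1), "structure"))
  out <- list()
  for (nm in nms) {
    m <- get_mask(structures, nm)
    idx <- match(which(m), body_index)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0)
      stop(sprintf("objective structure '%s' has no voxels inside the body", nm))
    out[[nm]] <- idx
  }
  out
}

#' Fluence-map optimization by projected gradient descent
#'
#' Minimizes the composite dose-volume objective plus a quadratic
#' neighbour-difference smoothing term over nonnegative beamlet weights.
#' Weights start from a uniform positive level scaled so that the mean PTV
#' dose matches the leading PTV target, and are updated by gradient steps
#' with backtracking (a step is only accepted if the objective does not
#' increase, so the logged objective sequence is monotone non-increasing).
#'
#' @param influences list of [beamlet_influence()] results (shared body order).
#' @param structures a [structure_set] containing every structure named in the
#'   template.
#' @param template an [objective_template()].
#' @param opts list of options: `max_iter` (default 200), `tol` (relative
#'   objective change, default 1e-5), `smoothing_weight` (default 1e-3),
#'   `init` (optional warm-start fluence list).
#' @return list with class `fluence_opt`: `fluences` (per-field `nx x ny`
#'   matrices), `value` (final objective), `log` (data frame `iter`,
#'   `objective`, `step`), `dose_vec` (final body-voxel doses), `converged`.
#' @export
optimize_fluence <- function(influences, structures, template, opts = list()) {
  max_iter <- opts$max_iter %||% 200
  tol <- opts$tol %||% 1e-5
  lambda <- opts$smoothing_weight %||% 1e-3
  body_index <- influences[[1]]$body_index
  sidx <- structure_body_indices(structures, template, body_index)

  A <- do.call(cbind, lapply(influences, `[[`, "matrix"))
  nb_per <- vapply(influences, function(x) ncol(x$matrix), integer(1))
  blocks <- rep(seq_along(influences), nb_per)
  D <- do.call(Matrix::bdiag, lapply(influences, function(x) fluence_diff_matrix(x$nx, x$ny)))
  DtD <- Matrix::crossprod(D)

  nvox <- nrow(A)
  eval_all <- function(w, need_grad = TRUE) {
    dose <- as.numeric(A %*% w)
    val <- 0
    gd <- if (need_grad) numeric(nvox) else NULL
    for (nm in names(sidx)) {
      idx <- sidx[[nm]]
      d <- dose[idx]
      for (o in template$objectives) {
        if (o$structure != nm) next
        tm <- obj_term(d, o)
        val <- val + tm$value
        if (need_grad) gd[idx] <- gd[idx] + tm$grad
      }
    }
    sm <- as.numeric(D %*% w)
    val <- val + lambda * sum(sm^2)
    if (!is.finite(val)) stop("non-finite objective (dose engine misconfiguration?)")
    gw <- if (need_grad)
      as.numeric(Matrix::crossprod(A, gd)) + 2 * lambda * as.numeric(DtD %*% w)
    else NULL
    list(value = val, grad = gw, dose = dose)
  }

  # uniform positive initialization scaled to the leading PTV lower target
  if (!is.null(opts$init)) {
    w <- unlist(lapply(opts$init, as.numeric), use.names = FALSE)
    if (length(w) != ncol(A)) stop("warm-start fluence shape mismatch")
    w <- pmax(w, 0)
  } else {
    ptv_lower <- Filter(function(o) o$structure == "PTV" && o$kind == "lower_dv",
                        template$objectives)
    target <- ptv_lower[[1]]$dose_gy
    unit_dose <- as.numeric(A %*% rep(1, ncol(A)))
    m0 <- mean(unit_dose[sidx[["PTV"]]])
    if (!is.finite(m0) || m0 <= 0) stop("PTV receives no dose from any beamlet")
    w <- rep(target / m0, ncol(A))
  }

  cur <- eval_all(w)
  log_iter <- numeric(0); log_obj <- numeric(0); log_step <- numeric(0)
  log_iter[1] <- 0; log_obj[1] <- cur$value; log_step[1] <- NA
  alpha <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gn2 <- sum(cur$grad^2)
    if (gn2 == 0) { converged <- TRUE; break }
    dir <- cur$grad
    accepted <- FALSE
    a <- alpha
    for (bt in 1:40) {
      w_new <- pmax(w - a * dir, 0)
      nxt <- eval_all(w_new)
      if (nxt$value <= cur$value) { accepted <- TRUE; break }
      a <- a / 2
    }
    if (!accepted) break
    rel <- (cur$value - nxt$value) / max(cur$value, .Machine$double.eps)
    w <- w_new; cur <- nxt
    alpha <- a * 2
    log_iter <- c(log_iter, it); log_obj <- c(log_obj, cur$value)
    log_step <- c(log_step, a)
    if (rel < tol) { converged <- TRUE; break }
  }

  fl <- split(w, blocks)
  fluences <- lapply(seq_along(influences), function(k)
    matrix(fl[[k]], influences[[k]]$nx, influences[[k]]$ny))
  names(fluences) <- vapply(influences, `[[`, character(1), "field")
  structure(list(fluences = fluences, value = cur$value,
                 log = data.frame(iter = log_iter, objective = log_obj, step = log_step),
                 dose_vec = cur$dose, converged = converged),
            class = "fluence_opt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monitor-unit proxy
#'
#' Relative surrogate for plan monitor units: `calibration` times the sum over
#' fields of the fluence integral (the sum of all beamlet weights). It scales
#' linearly with fluence and is comparable between plans computed with the
#' same engine settings, but is not an absolute machine MU.
#'
#' @param fluences list of nonnegative fluence maps.
#' @param calibration scalar multiplier (default 1).
#' @return scalar MU proxy.
#' @export
mu_proxy <- function(fluences, calibration = 1) {
  w <- unlist(lapply(fluences, as.numeric), use.names = FALSE)
  if (any(w < 0)) stop("negative beamlet weights")
  calibration * sum(w)
}

#' Automated six-field tangential plan
#'
#' Runs the full auto-planning sequence on one phantom: create the posterior
#' ring structures, place the isocenter at the PTV centroid, search the
#' tangential gantry/collimator angles exhaustively, build the six fields,
#' compute per-beamlet dose influence, optimize fluence against the objective
#' template, and apply the hotspot rule: if the volume above the hotspot
#' isodose level exceeds the policy trigger, the hotspot structure is appended
#' to the template as a `max_upper` objective and the optimization is repeated
#' exactly once (warm-started from the first pass); otherwise the plan is
#' complete after one pass. Both the pre- and post-loop hotspot volumes are
#' recorded.
#'
#' @param phantom a list with `grid` and `structures` (e.g. from
#'   [generate_phantom()]); rings are added if absent.
#' @param rx a [prescription()].
#' @param template an [objective_template()]; default
#'   [default_objective_template()].
#' @param policy a [hotspot_policy()].
#' @param engine a [dose_engine_config()].
#' @param opts optimizer options, see [optimize_fluence()].
#' @param hotspot_weight weight of the appended hotspot objective (default 150).
#' @param normalize logical; renormalize the plan after each optimization pass
#'   so that the PTV D95 equals the prescription (the usual clinical coverage
#'   normalization; all fluence weights are scaled by one factor). The hotspot
#'   rule is evaluated on the normalized dose. Default `TRUE`.
#' @param trace logical; keep the full angle-search trace in the plan.
#' @param ring_extents_mm posterior extents of Ring_1/Ring_2 (default 10/20 mm).
#' @param inner_jaw_mm minor-field inner jaw opening (default 15 mm).
#' @return object of class `breast_autoplan`: fields, fluences, dose array,
#'   metrics ([plan_metrics()]), hotspot record, optimization logs, search
#'   results and provenance.
#' @export
autoplan <- function(phantom, rx = prescription(),
                     template = default_objective_template(rx),
                     policy = hotspot_policy(),
                     engine = dose_engine_config(),
                     opts = list(), hotspot_weight = 150, normalize = TRUE,
                     trace = FALSE, ring_extents_mm = c(10, 20),
                     inner_jaw_mm = 15) {
  grid <- phantom$grid
  ss <- phantom$structures
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("autoplan stage '%s': %s", label, conditionMessage(e)), call. = FALSE))
  }
  for (nm in c("Body", "CTV", "PTV", "LungIpsi", "LungContra", "Heart", "BreastContra"))
    get_mask(ss, nm)

  if (!all(c("Ring_1", "Ring_2") %in% names(ss$masks)))
    ss <- stage("rings", add_rings(ss, ring_extents_mm[1], ring_extents_mm[2]))

  ptv <- get_mask(ss, "PTV"); body <- get_mask(ss, "Body")
  iso <- stage("isocenter", ptv_centroid(ptv, grid))
  search <- stage("angle_search",
                  search_tangential_angles(ptv, grid, iso, sad_mm = engine$sad_mm))
  fields <- stage("fields",
                  build_fields(search$f1, search$f2, ptv, grid, iso,
                               inner_jaw_mm = inner_jaw_mm, sad_mm = engine$sad_mm))
  influences <- stage("influence",
                      lapply(fields, beamlet_influence, grid = grid,
                             body = body, config = engine))

  opt1 <- stage("optimize", optimize_fluence(influences, ss, template, opts))
  dose1 <- compute_dose(influences, opt1$fluences, grid)
  hs1 <- make_hotspot_structure(dose1, grid, rx, policy)

  passes <- 1L
  opt_final <- opt1
  dose <- dose1
  template_final <- template
  hs_post <- hs1
  if (hs1$volume_cc > policy$trigger_volume_cc && policy$max_reoptimizations >= 1) {
    ss$masks$Hotspot105 <- hs1$mask
    template_final <- objective_template(c(template$objectives, list(
      objective("Hotspot105", "max_upper",
                policy$isodose_level_pct / 100 * rx$total_dose_gy,
                weight = hotspot_weight))))
    opts2 <- opts
    opts2$init <- opt1$fluences
    opt_final <- stage("reoptimize", optimize_fluence(influences, ss, template_final, opts2))
    dose <- compute_dose(influences, opt_final$fluences, grid)
    hs_post <- make_hotspot_structure(dose, grid, rx, policy)
    passes <- 2L
  }

  # terminal coverage normalization: one global fluence rescale so the PTV
  # D95 equals the prescription (the hotspot loop above runs at optimizer
  # scale so its pre/post volumes are directly comparable)
  norm_scale <- 1
  if (normalize) {
    dp <- dose[ptv]
    d95 <- sort(dp, decreasing = TRUE)[ceiling(0.95 * length(dp))]
    if (d95 > 0) {
      norm_scale <- rx$total_dose_gy / d95
      opt_final$fluences <- lapply(opt_final$fluences, `*`, norm_scale)
      dose <- dose * norm_scale
    }
  }
  hs_delivered <- make_hotspot_structure(dose, grid, rx, policy)

  mu <- mu_proxy(opt_final$fluences)
  metrics <- stage("metrics", plan_metrics(dose, ss, rx, mu))

  cfg <- list(prescription = unclass(rx), policy = unclass(policy),
              engine = unclass(engine), ring_extents_mm = ring_extents_mm,
              inner_jaw_mm = inner_jaw_mm, hotspot_weight = hotspot_weight,
              normalize = normalize,
              opts = opts[setdiff(names(opts), "init")],
              phantom = phantom$provenance)
  prov <- list(config = cfg, config_hash = config_hash(cfg),
               isocenter_mm = iso,
               f1 = search$f1[c("gantry", "collimator", "area")],
               f2 = search$f2[c("gantry", "collimator", "area")])

  structure(list(grid = grid, structures = ss, prescription = rx,
                 fields = fields, fluences = opt_final$fluences, dose = dose,
                 metrics = metrics, mu = mu,
                 hotspot = list(pre_cc = hs1$volume_cc, post_cc = hs_post$volume_cc,
                                delivered_cc = hs_delivered$volume_cc,
                                norm_scale = norm_scale,
                                triggered = passes == 2L, passes = passes,
                                completed = if (passes == 1L) "step 6 -> 8" else "step 7 -> 8"),
                 opt_logs = if (passes == 2L) list(opt1$log, opt_final$log) else list(opt1$log),
                 template = template_final, policy = policy,
                 search = if (trace) search else search[c("f1", "f2")],
                 provenance = prov),
            class = "breast_autoplan")
}

#' @export
print.breast_autoplan <- function(x, ...) {
  cat(sprintf("breast_autoplan: %d fields, %d optimization pass(es), completed at %s\n",
              length(x$fields), x$hotspot$passes, x$hotspot$completed))
  cat(sprintf("  F1 gantry/collimator %g/%g, F2 %g/%g\n",
              x$provenance$f1$gantry, x$provenance$f1$collimator,
              x$provenance$f2$gantry, x$provenance$f2$collimator))
  cat(sprintf("  V105 pre %.3f cc, post %.3f cc; PTV V95 %.1f%%, HI %.3f, CI %.3f, MU proxy %.0f\n",
              x$hotspot$pre_cc, x$hotspot$post_cc,
              x$metrics$ptv_v95_pct, x$metrics$hi, x$metrics$ci, x$mu))
  invisible(x)
}
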