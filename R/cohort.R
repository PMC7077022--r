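#' Run a synthetic cohort of autoplans
#'
#' Generates `n_per_class` phantoms in each of the three CTV size classes
#' (seeds derived deterministically from `base_seed`), plans each with
#' [autoplan()], and assembles per-plan metrics plus cohort summaries:
#' mean, SD, min and max per metric, and a one-way ANOVA of each
#' organ-at-risk metric across the size classes.
#'
#' @param n_per_class number of phantoms per size class (>= 2 for the ANOVA).
#' @param base_seed integer; phantom seeds are `base_seed + 0, 1, 2, ...`.
#' @param grid a [voxel_grid] shared by all phantoms.
#' @param rx,template,policy,engine,opts forwarded to [autoplan()].
#' @param progress print one line per plan.
#' @return list of class `autoplan_cohort`: `metrics` (one row per plan),
#'   `summary` (mean/SD/min/max per metric), `anova` (per-metric F and p
#'   across size classes), `plans` (the plan objects).
#' @export
run_cohort <- function(n_per_class = 2, base_seed = 1,
                       grid = voxel_grid(c(64, 52, 30), spacing = c(6, 6, 4.5)),
                       rx = prescription(),
                       template = default_objective_template(rx),
                       policy = hotspot_policy(),
                       engine = dose_engine_config(beamlet_size_mm = 10),
                       opts = list(), progress = FALSE) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  classes <- c("small", "medium", "large")
  rows <- list(); plans <- list()
  k <- 0L
  for (cl in classes) for (r in seq_len(n_per_class)) {
    seed <- base_seed + k
    ph <- generate_phantom(cl, seed = seed, grid = grid)
    pl <- autoplan(ph, rx = rx, template = template, policy = policy,
                   engine = engine, opts = opts)
    id <- sprintf("%s_%02d", cl, r)
    rows[[id]] <- metrics_row(pl, id = id)
    plans[[id]] <- pl
    if (progress)
      message(sprintf("%s: PTV V95 %.1f%%, CI %.2f, passes %d",
                      id, pl$metrics$ptv_v95_pct, pl$metrics$ci, pl$hotspot$passes))
    k <- k + 1L
  }
  metrics <- do.call(rbind, rows)
  num_cols <- c("body_v110_pct", "ptv_v95_pct", "hi", "ci",
                "lung_ipsi_v16gy_pct", "lung_ipsi_v4gy_pct", "lung_ipsi_mean_gy",
                "heart_v20gy_pct", "heart_mean_gy",
                "breast_contra_v5gy_pct", "breast_contra_max_gy", "mu")
  summ <- do.call(rbind, lapply(num_cols, function(cn) {
    v <- metrics[[cn]]
    data.frame(metric = cn, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v))
  }))
  an <- NULL
  if (n_per_class >= 2) {
    an <- do.call(rbind, lapply(num_cols, function(cn) {
      g <- split(metrics[[cn]], metrics$size_class)
      res <- one_way_anova(g)
      data.frame(metric = cn, F = res$F, p = res$p,
                 df1 = res$df1, df2 = res$df2)
    }))
  }
  structure(list(metrics = metrics, summary = summ, anova = an, plans = plans),
            class = "autoplan_cohort")
}

#' Write cohort outputs to CSV
#'
#' Emits `metrics.csv` (one row per plan), `summary.csv` (mean/SD/min/max)
#' and, when available, `anova.csv` (stratified F tests) into `dir`.
#'
#' @param cohort an `autoplan_cohort`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             summary = file.path(dir, "summary.csv"))
  utils::write.csv(cohort$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(cohort$summary, paths["summary"], row.names = FALSE)
  if (!is.null(cohort$anova)) {
    paths["anova"] <- file.path(dir, "anova.csv")
    utils::write.csv(cohort$anova, paths["anova"], row.names = FALSE)
  }
  invisible(paths)
}
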