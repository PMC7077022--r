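#' Cache dose-influence matrices on disk
#'
#' Writes each field's sparse influence matrix in MatrixMarket format
#' (`<field>.mtx`) plus a JSON manifest (`manifest.json`) with the beamlet
#' lattice, pitch, body-voxel indices and the configuration hash, so a set of
#' matrices can be reloaded without re-running the engine.
#'
#' @param influences list of [beamlet_influence()] results.
#' @param dir output directory (created if needed).
#' @param config optional engine config stored (hashed) in the manifest.
#' @return invisibly, the manifest path.
#' @export
save_influences <- function(influences, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(fields = list(),
                   config = if (!is.null(config)) unclass(config) else NULL,
                   config_hash = if (!is.null(config)) config_hash(unclass(config)) else NULL)
  for (inf in influences) {
    fn <- paste0(inf$field, ".mtx")
    Matrix::writeMM(inf$matrix, file.path(dir, fn))
    manifest$fields[[inf$field]] <- list(
      file = fn, nx = inf$nx, ny = inf$ny, pitch = inf$pitch,
      centers_x = inf$centers[, 1], centers_y = inf$centers[, 2],
      body_index = inf$body_index)
  }
  mp <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, null = "null")), mp)
  invisible(mp)
}

#' Reload cached influence matrices
#'
#' @param dir directory written by [save_influences()].
#' @return list of `dose_influence` objects in manifest order.
#' @export
load_influences <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mp, simplifyVector = TRUE)
  out <- list()
  for (nm in names(manifest$fields)) {
    fd <- manifest$fields[[nm]]
    m <- methods::as(Matrix::readMM(file.path(dir, fd$file)), "CsparseMatrix")
    out[[nm]] <- structure(list(
      field = nm, nx = as.integer(fd$nx), ny = as.integer(fd$ny),
      pitch = as.numeric(fd$pitch),
      centers = cbind(x = as.numeric(fd$centers_x), y = as.numeric(fd$centers_y)),
      matrix = m, body_index = as.integer(fd$body_index)),
      class = "dose_influence")
  }
  out
}

#' Write DVH curves to CSV
#'
#' Long format: one row per (structure, dose bin) with the cumulative volume.
#'
#' @param dvhs list of [dvh()] objects (named, or carrying `structure`).
#' @param path output CSV.
#' @return invisibly `path`.
#' @export
write_dvh_csv <- function(dvhs, path) {
  if (inherits(dvhs, "dvh")) dvhs <- list(dvhs)
  rows <- lapply(seq_along(dvhs), function(k) {
    h <- dvhs[[k]]
    nm <- if (!is.null(names(dvhs)) && nzchar(names(dvhs)[k])) names(dvhs)[k]
          else if (!is.na(h$structure)) h$structure else paste0("structure_", k)
    data.frame(structure = nm, dose_gy = h$dose_bins_gy,
               volume_pct = h$cum_volume_pct)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the optimization convergence log(s) of a plan to CSV
#'
#' One row per accepted iteration, with a `pass` column (1 = initial
#' optimization, 2 = hotspot re-optimization).
#'
#' @param plan a `breast_autoplan`.
#' @param path output CSV.
#' @return invisibly `path`.
#' @export
write_convergence_log <- function(plan, path) {
  logs <- lapply(seq_along(plan$opt_logs), function(k)
    cbind(pass = k, plan$opt_logs[[k]]))
  utils::write.csv(do.call(rbind, logs), path, row.names = FALSE)
  invisible(path)
}
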