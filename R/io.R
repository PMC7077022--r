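#' Write structure masks as NIfTI volumes
#'
#' One file per structure, named `<structure>.nii.gz`, with the grid spacing
#' in the pixel dimensions and the grid origin in the translation column of
#' the stored affine. Array axes are written as-is (right-left,
#' anterior-posterior, inferior-superior).
#'
#' @param ss a [structure_set].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_structures <- function(ss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(ss$masks)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(ss$masks[[nm]] * 1L, ss$grid, p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Write one scalar volume (mask or dose) as NIfTI
#'
#' @param values 3-D array on `grid`.
#' @param grid a [voxel_grid].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(values, grid, path) {
  stopifnot(all(dim(values) == grid$shape))
  img <- RNifti::asNifti(values)
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read one scalar volume written by [write_volume()]
#'
#' @param path NIfTI file.
#' @return list with `values` (3-D array) and `grid` (a [voxel_grid]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vals <- array(as.numeric(img), dim(img))
  grid <- voxel_grid(dim(img), spacing = abs(diag(aff)[1:3]), origin = aff[1:3, 4])
  list(values = vals, grid = grid)
}

#' Read a directory of structure masks
#'
#' @param dir directory of `.nii`/`.nii.gz` files, filename = structure name.
#' @return a [structure_set].
#' @export
read_structures <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0) stop("no NIfTI files in ", dir)
  masks <- list(); grid <- NULL
  for (f in files) {
    v <- read_volume(f)
    if (is.null(grid)) grid <- v$grid
    nm <- sub("\\.nii(\\.gz)?$", "", basename(f))
    masks[[nm]] <- v$values != 0
  }
  structure_set(grid, masks)
}

#' Write / read a phantom configuration
#'
#' Structured YAML with size class, seed, spacing, shape and (optionally)
#' recorded torso dimensions.
#'
#' @param config list (e.g. the `provenance` of [generate_phantom()]).
#' @param path YAML file path.
#' @return invisibly `path`; `read_phantom_config` returns the list.
#' @export
write_phantom_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) yaml::read_yaml(path)

#' Deterministic hash of a configuration list
#'
#' MD5 of the canonical JSON serialization; embedded in every output artifact
#' so reruns can be matched to their configuration.
#'
#' @param config a list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                           null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a plan to JSON
#'
#' Writes field geometry, fluence maps, metrics, hotspot record, the objective
#' template used and the provenance block. Deterministic for identical plans
#' (no timestamps).
#'
#' @param plan a `breast_autoplan`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when `path` is given).
#' @export
plan_to_json <- function(plan, path = NULL) {
  fields <- lapply(plan$fields, function(f)
    list(name = f$name, role = f$role, gantry_deg = f$gantry_deg,
         collimator_deg = f$collimator_deg, isocenter_mm = f$isocenter_mm,
         jaws_mm = as.list(f$jaws_mm), sad_mm = f$sad_mm))
  fl <- lapply(plan$fluences, function(m)
    list(nx = nrow(m), ny = ncol(m), weights = as.numeric(m)))
  obj <- list(prescription = unclass(plan$prescription),
              fields = fields, fluences = fl,
              metrics = unclass(plan$metrics), mu = plan$mu,
              hotspot = plan$hotspot,
              template = lapply(plan$template$objectives, unclass),
              provenance = plan$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Write the angle-search trace to CSV
#'
#' @param plan a `breast_autoplan` run with `trace = TRUE`, or a search result
#'   from [search_tangential_angles()].
#' @param path output CSV.
#' @return invisibly `path`.
#' @export
write_search_trace <- function(plan, path) {
  tr <- if (inherits(plan, "breast_autoplan")) plan$search$trace else plan$trace
  if (is.null(tr)) stop("no trace recorded (rerun with trace = TRUE)")
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' One-row data frame of plan metrics
#'
#' Table-style layout (one plan per row) used by the cohort writers.
#'
#' @param plan a `breast_autoplan`.
#' @param id plan identifier.
#' @return data frame with one row.
#' @export
metrics_row <- function(plan, id = "plan") {
  m <- plan$metrics
  data.frame(id = id,
             size_class = plan$provenance$config$phantom$size_class %||% NA,
             seed = plan$provenance$config$phantom$seed %||% NA,
             ctv_ml = plan$provenance$config$phantom$ctv_volume_ml %||% NA,
             f1_gantry = plan$provenance$f1$gantry,
             f1_collimator = plan$provenance$f1$collimator,
             f2_gantry = plan$provenance$f2$gantry,
             f2_collimator = plan$provenance$f2$collimator,
             body_v110_pct = m$body_v110_pct, ptv_v95_pct = m$ptv_v95_pct,
             hi = m$hi, ci = m$ci,
             lung_ipsi_v16gy_pct = m$lung_ipsi_v16gy_pct,
             lung_ipsi_v4gy_pct = m$lung_ipsi_v4gy_pct,
             lung_ipsi_mean_gy = m$lung_ipsi_mean_gy,
             heart_v20gy_pct = m$heart_v20gy_pct,
             heart_mean_gy = m$heart_mean_gy,
             breast_contra_v5gy_pct = m$breast_contra_v5gy_pct,
             breast_contra_max_gy = m$breast_contra_max_gy,
             mu = m$mu,
             v105_pre_cc = plan$hotspot$pre_cc,
             v105_post_cc = plan$hotspot$post_cc,
             passes = plan$hotspot$passes,
             config_hash = plan$provenance$config_hash,
             stringsAsFactors = FALSE)
}
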