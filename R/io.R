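# File formats: NIfTI volumes, Matrix Market adjacency, TSV tables,
# plain-text YAML configuration.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file.
#' @return List with `data` (3D array), `voxel_size` (mm per axis), and
#'   `affine` (4x4 voxel-to-world matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI header in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img),
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a NIfTI volume
#'
#' @param data 3D array.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm (default 2).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = 2) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(voxel_size, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Respaces the voxel grid to `target_mm`, using trilinear interpolation
#' for intensity images and nearest-neighbour for label volumes.  Label
#' arrays (integer storage) must use nearest-neighbour: interpolating
#' region ids is meaningless and is rejected.
#'
#' @param volume 3D array (integer storage mode marks a label volume).
#' @param current_mm Current isotropic spacing.
#' @param target_mm Target isotropic spacing (> 0).
#' @param method `"trilinear"` or `"nearest"`.
#' @return Resampled 3D array.
#' @export
resample_isotropic <- function(volume, current_mm, target_mm,
                               method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot_scalar_number(target_mm, "target_mm", 0, strict_lower = TRUE)
  stopifnot_scalar_number(current_mm, "current_mm", 0, strict_lower = TRUE)
  if (method == "trilinear" && is.integer(volume))
    stop("trilinear interpolation requested for an integer label volume; use method = \"nearest\"",
         call. = FALSE)
  if (current_mm == target_mm) return(volume)
  dm <- dim(volume)
  new_dm <- pmax(1L, as.integer(round(dm * current_mm / target_mm)))
  # voxel-centre coordinates of the new grid expressed on the old grid
  src <- lapply(1:3, function(ax)
    ((seq_len(new_dm[ax]) - 0.5) * target_mm / current_mm) + 0.5)
  out <- array(if (method == "nearest" && is.integer(volume)) 0L else 0, new_dm)
  if (method == "nearest") {
    ix <- pmin(pmax(round(src[[1]]), 1), dm[1])
    iy <- pmin(pmax(round(src[[2]]), 1), dm[2])
    iz <- pmin(pmax(round(src[[3]]), 1), dm[3])
    out[] <- volume[cbind(rep(ix, times = new_dm[2] * new_dm[3]),
                          rep(rep(iy, each = new_dm[1]), times = new_dm[3]),
                          rep(iz, each = new_dm[1] * new_dm[2]))]
    return(out)
  }
  clampf <- function(v, hi) pmin(pmax(v, 1), hi)
  x0 <- clampf(floor(src[[1]]), dm[1]); x1 <- clampf(x0 + 1, dm[1])
  y0 <- clampf(floor(src[[2]]), dm[2]); y1 <- clampf(y0 + 1, dm[2])
  z0 <- clampf(floor(src[[3]]), dm[3]); z1 <- clampf(z0 + 1, dm[3])
  fx <- clampf(src[[1]], dm[1]) - x0
  fy <- clampf(src[[2]], dm[2]) - y0
  fz <- clampf(src[[3]], dm[3]) - z0
  for (k in seq_len(new_dm[3])) for (j in seq_len(new_dm[2])) {
    wz <- fz[k]; wy <- fy[j]
    c00 <- volume[x0, y0[j], z0[k]] * (1 - fx) + volume[x1, y0[j], z0[k]] * fx
    c10 <- volume[x0, y1[j], z0[k]] * (1 - fx) + volume[x1, y1[j], z0[k]] * fx
    c01 <- volume[x0, y0[j], z1[k]] * (1 - fx) + volume[x1, y0[j], z1[k]] * fx
    c11 <- volume[x0, y1[j], z1[k]] * (1 - fx) + volume[x1, y1[j], z1[k]] * fx
    out[, j, k] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
      (c01 * (1 - wy) + c11 * wy) * wz
  }
  out
}

#' Write a network to disk
#'
#' Writes the binarised adjacency in Matrix Market sparse format, the node
#' table (id, origin, label, grey-matter volume) as TSV, and the threshold
#' calibration as YAML.
#'
#' @param network A `gmnet` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "gmnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(network$adjacency, sparse = TRUE),
                  file.path(dir, "adjacency.mtx"))
  cb <- network$cubes
  node_table <- data.frame(node_id = cb$index,
                           origin_x = cb$origin[, 1], origin_y = cb$origin[, 2],
                           origin_z = cb$origin[, 3], label = cb$label,
                           gm_volume = cb$gm_volume)
  write.table(node_table, file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  thr <- network$threshold
  yaml::write_yaml(list(threshold = thr$threshold, alpha = thr$alpha,
                        n_permutations = thr$n_permutations,
                        n_pairs = thr$n_pairs,
                        per_edge_level = thr$per_edge_level,
                        seed = thr$seed),
                   file.path(dir, "threshold.yaml"))
  invisible(dir)
}

#' Read a network written by [write_network()]
#'
#' @param dir Directory containing `adjacency.mtx` and `nodes.tsv`.
#' @return List with `adjacency` (0/1 matrix), `nodes` (data frame), and
#'   `threshold` (list, when present).
#' @export
read_network <- function(dir) {
  adj <- as.matrix(Matrix::readMM(file.path(dir, "adjacency.mtx")))
  storage.mode(adj) <- "integer"
  nodes <- read.table(file.path(dir, "nodes.tsv"), header = TRUE, sep = "\t")
  thr_path <- file.path(dir, "threshold.yaml")
  thr <- if (file.exists(thr_path)) yaml::read_yaml(thr_path) else NULL
  list(adjacency = adj, nodes = nodes, threshold = thr)
}

#' Write a cohort configuration to YAML
#'
#' The file round-trips losslessly through [read_cohort_config()].
#'
#' @param config `gmnet_cohort_config`.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "gmnet_cohort_config"))
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file written by [write_cohort_config()].
#' @return Validated `gmnet_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("n_per_group", "tau_group_means", "age_mean"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(cohort_config, raw)
}

#' Write a synthetic cohort to disk
#'
#' Writes each subject's grey-matter image and the shared atlas as NIfTI,
#' the subject table and per-region SUVR table as TSV, and the generating
#' configuration as YAML.
#'
#' @param cohort `gmnet_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gmnet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- cohort$config$voxel_size_mm
  atlas <- cohort$atlas
  storage.mode(atlas) <- "double"   # NIfTI writers expect numeric data
  write_volume(atlas, file.path(dir, "atlas.nii.gz"), vox)
  for (s in cohort$subjects)
    if (!is.null(s$gm_image))
      write_volume(s$gm_image, file.path(dir, paste0(s$subject_id, "_gm.nii.gz")),
                   vox)
  write.table(cohort$table, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  suvr <- t(vapply(cohort$subjects, function(s) s$region_suvr,
                   numeric(cohort$config$n_regions)))
  suvr_tab <- data.frame(subject_id = cohort$table$subject_id, suvr,
                         check.names = FALSE)
  names(suvr_tab) <- c("subject_id",
                       paste0("suvr_region", seq_len(cohort$config$n_regions)))
  write.table(suvr_tab, file.path(dir, "region_suvr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$region_table, file.path(dir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_cohort_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
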