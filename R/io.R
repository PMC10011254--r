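#' Read and write voxel volumes as NIfTI-1
#'
#' Thin wrappers around the RNifti package carrying the `(dz, dy, dx)` cm
#' spacing into and out of the NIfTI header (which stores spacing in mm,
#' fastest-varying axis first).
#'
#' @param x a [voxel_volume()] or a logical mask with known spacing.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing spacing override for plain arrays/masks, cm.
#' @return `write_volume()`: the path, invisibly. `read_volume()`: a
#'   [voxel_volume()].
#' @export
write_volume <- function(x, path, spacing = attr(x, "spacing")) {
  if (is.null(spacing)) stop("'spacing' is required")
  # NIfTI stores x fastest; our arrays are (z, y, x)
  arr <- aperm(array(as.numeric(x), dim(x)), c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing) * 10
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp_mm <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1))
  voxel_volume(arr, spacing = rev(sp_mm[1:3]) / 10)
}

#' Write all phantom-case artifacts
#'
#' Writes activity, the degraded PET image (if present), the static and
#' motion-union ground-truth masks, and the tissue label map as NIfTI-1
#' files `<prefix>_activity.nii.gz` etc.
#'
#' @param case a `phantom_case`.
#' @param prefix output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(case, prefix) {
  stopifnot(inherits(case, "phantom_case"))
  sp <- vox_spacing(case$activity)
  paths <- c(activity = paste0(prefix, "_activity.nii.gz"),
             gt_static = paste0(prefix, "_gt_static.nii.gz"),
             gt_motion = paste0(prefix, "_gt_motion.nii.gz"),
             labels = paste0(prefix, "_labels.nii.gz"))
  write_volume(case$activity, paths["activity"])
  write_volume(case$gt_static, paths["gt_static"], spacing = sp)
  write_volume(case$gt_motion, paths["gt_motion"], spacing = sp)
  write_volume(case$labels, paths["labels"], spacing = sp)
  if (!is.null(case$pet_image)) {
    paths["pet"] <- paste0(prefix, "_pet.nii.gz")
    write_volume(case$pet_image, paths["pet"])
  }
  invisible(paths)
}

#' Write study reports to disk
#'
#' Writes the long-form metrics records, TRT table, summary tables and
#' statistical results of a study as CSV plus one machine-readable JSON.
#'
#' @param study a `pet_study` from [run_study()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "pet_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$records, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$trt, file.path(dir, "trt.csv"), row.names = FALSE)
  utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$trt_summary, file.path(dir, "trt_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$cases, file.path(dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = study$summary, trt_summary = study$trt_summary,
         stats = study$stats,
         config = study$config[setdiff(names(study$config),
                                       c("seg", "extra"))]),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
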