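# File interfaces: NIfTI grids with JSON sidecars, CSV feature tables,
# YAML study configuration. Grid axes are documented as row-major, 0-based,
# in pixel units.

#' Write a parameter map as NIfTI plus JSON sidecar
#'
#' @param map a `parameter_map`.
#' @param path output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @param pixdim pixel spacing in mm (default c(1.5, 1.5)).
#' @return `path`, invisibly.
#' @export
write_parameter_map <- function(map, path, pixdim = c(1.5, 1.5)) {
  img <- RNifti::asNifti(map$grid, pixdim = pixdim)
  RNifti::writeNifti(img, path)
  side <- list(name = map$name, units = map$units,
               axes = "row-major, 0-based, pixel units",
               n_valid = sum(map$valid_mask))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE)
  RNifti::writeNifti(RNifti::asNifti(map$valid_mask * 1, pixdim = pixdim),
                     sub("\\.nii(\\.gz)?$", "_valid.nii\\1", path))
  invisible(path)
}

#' Read a parameter map written by [write_parameter_map()]
#' @param path the NIfTI path.
#' @return a `parameter_map`.
#' @export
read_parameter_map <- function(path) {
  grid <- as.matrix(RNifti::readNifti(path))
  side <- jsonlite::read_json(sidecar_path(path))
  vpath <- sub("\\.nii(\\.gz)?$", "_valid.nii\\1", path)
  valid <- if (file.exists(vpath))
    as.matrix(RNifti::readNifti(vpath)) > 0 else NULL
  parameter_map(side$name, grid, side$units, valid)
}

#' Write an ROI mask as NIfTI plus JSON sidecar
#' @param mask a `roi_mask`.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param pixdim pixel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path, pixdim = c(1.5, 1.5)) {
  RNifti::writeNifti(RNifti::asNifti(mask$grid * 1, pixdim = pixdim), path)
  jsonlite::write_json(list(lesion_id = mask$lesion_id,
                            dilation_level = mask$dilation_level,
                            axes = "row-major, 0-based, pixel units"),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ROI mask written by [write_roi_mask()]
#' @param path the NIfTI path.
#' @return a `roi_mask`.
#' @export
read_roi_mask <- function(path) {
  grid <- as.matrix(RNifti::readNifti(path)) > 0
  side <- jsonlite::read_json(sidecar_path(path))
  roi_mask(grid, side$lesion_id, side$dilation_level)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read a feature table as CSV
#'
#' Canonical feature names in the header; metadata columns (`lesion_id`,
#' `dilation_level`, `label`) pass through unchanged.
#'
#' @param table feature data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a YAML study configuration
#'
#' The file's `phantom` mapping holds [phantom_config()] arguments
#' (`counts` as a name: count mapping).
#'
#' @param path YAML file path.
#' @return a `phantom_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y$phantom
  if (!is.null(args$counts)) args$counts <- unlist(args$counts)
  if (!is.null(args$noise_sd)) args$noise_sd <- unlist(args$noise_sd)
  if (!is.null(args$image_shape)) args$image_shape <- unlist(args$image_shape)
  do.call(phantom_config, args)
}
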