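## Field and map output: NIfTI parameter maps and legacy-ASCII VTK images
## for visualisation.

#' Write a voxel field as a NIfTI volume
#'
#' @param arr 3-D array (NA replaced by \code{naValue})
#' @param spacing voxel spacing in mm
#' @param path output path (.nii or .nii.gz)
#' @param naValue value used outside the domain (default 0)
#' @return the path, invisibly
#' @export
writeFieldNifti <- function(arr, spacing, path, naValue = 0) {
  arr[is.na(arr)] <- naValue
  img <- RNifti::asNifti(arr, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label/mask volume from NIfTI
#'
#' @param path NIfTI file
#' @return list with \code{labels} (integer array) and \code{spacing} (mm)
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim(img))
  list(labels = arr, spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Write voxel fields as a legacy-ASCII VTK structured-points file
#'
#' Minimal VTK writer for visualising pressure/velocity/drug fields in
#' ParaView and friends; one or more scalar fields on the same grid.
#'
#' @param fields named list of 3-D arrays (same dimensions; NA written as
#'   \code{naValue})
#' @param spacing voxel spacing (mm)
#' @param path output path (.vtk)
#' @param naValue fill value outside the domain
#' @return the path, invisibly
#' @export
writeVtkImage <- function(fields, spacing, path, naValue = 0) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  dims <- dim(fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ipcFlow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", spacing[1], spacing[2], spacing[3]),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (nm in names(fields)) {
    arr <- fields[[nm]]
    stopifnot(all(dim(arr) == dims))
    arr[is.na(arr)] <- naValue
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(format(as.vector(arr), digits = 8, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}
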