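# File interfaces: activity images and sinograms as NIfTI-1 or headerless
# CSV (sinograms with a JSON sidecar describing the geometry); ROI sets
# as JSON layouts.

#' @noRd
.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Write an activity image
#'
#' NIfTI-1 for .nii/.nii.gz paths, headerless CSV otherwise.
#'
#' @param image activity matrix.
#' @param path destination file.
#' @return The path, invisibly.
#' @export
writeActivityImage <- function(image, path) {
  if (.isNifti(path)) {
    RNifti::writeNifti(RNifti::asNifti(array(image, dim = c(dim(image), 1L))),
                       path)
  } else {
    utils::write.table(image, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read an activity image
#'
#' @param path a NIfTI-1 (.nii/.nii.gz) or headerless CSV file.
#' @return Activity matrix.
#' @export
readActivityImage <- function(path) {
  if (.isNifti(path)) {
    a <- RNifti::readNifti(path)
    matrix(as.numeric(a), dim(a)[1L], dim(a)[2L])
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

#' Write a sinogram with its geometry sidecar
#'
#' The counts go to \code{path} (NIfTI-1 or CSV); a JSON sidecar
#' (same path with extension .json) records nAngles, nBins and the
#' angular range.
#'
#' @param sinogram counts matrix (nAngles x nBins).
#' @param path destination file.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return The path, invisibly.
#' @export
writeSinogram <- function(sinogram, path, sidecar = TRUE) {
  writeActivityImage(sinogram, path)
  if (sidecar) {
    meta <- list(nAngles = nrow(sinogram), nBins = ncol(sinogram),
                 angularRangeDeg = 180)
    jsonlite::write_json(meta, paste0(sub("\\.gz$", "", path), ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a sinogram
#'
#' @param path file written by \code{\link{writeSinogram}}.
#' @return Counts matrix.
#' @export
readSinogram <- function(path) readActivityImage(path)

#' Write an ROI set layout as JSON
#'
#' Serializes the geometric layout (mask bounding boxes / disc centers are
#' not reconstructible from boolean masks, so the set is stored as run
#' lengths of each mask) plus the recorded true contrasts.
#'
#' @param rois an \linkS4class{ROISet}.
#' @param path destination .json file.
#' @return The path, invisibly.
#' @export
writeRoiSet <- function(rois, path) {
  enc <- function(m) which(m)  # linear indices, column-major
  obj <- list(imageSize = rois@imageSize,
              regional = lapply(rois@regional, enc),
              crc = lapply(rois@crc, enc),
              background = enc(rois@background),
              trueContrast = as.list(rois@trueContrast))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read an ROI set from JSON
#'
#' @param path file written by \code{\link{writeRoiSet}}.
#' @return An \linkS4class{ROISet}.
#' @export
readRoiSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$imageSize)
  dec <- function(idx) {
    m <- matrix(FALSE, n, n)
    m[as.integer(idx)] <- TRUE
    m
  }
  new("ROISet",
      regional = lapply(obj$regional, dec),
      crc = lapply(obj$crc, dec),
      background = dec(obj$background),
      trueContrast = unlist(obj$trueContrast),
      imageSize = n)
}
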