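## NIfTI-1 image I/O (echo as 3rd array dimension, protocol in a JSON
## sidecar, since NIfTI-1 has no standard multi-echo timing field) and
## deterministic CSV table I/O with a provenance comment header.

.sidecarPath <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a multi-echo image as NIfTI-1 plus JSON sidecar
#'
#' The voxel array is stored as a 3-D NIfTI volume (row, col, echo); the
#' acquisition protocol and mask are stored in a JSON sidecar next to the
#' image (`<stem>.json`).
#'
#' @param image a [MultiEchoImage-class]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
writeMultiEchoNifti <- function(image, path) {
  stopifnot(is(image, "MultiEchoImage"))
  RNifti::writeNifti(RNifti::asNifti(image@data), path)
  jsonlite::write_json(
    list(protocol = protocolToList(image@protocol),
         mask_rle = list(lengths = rle(as.vector(image@mask))$lengths,
                         values = rle(as.vector(image@mask))$values)),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-echo image from NIfTI-1
#'
#' @param path path to a 3-D NIfTI file (row, col, echo)
#' @param protocol optional protocol; when `NULL` it is read from the JSON
#'   sidecar written by [writeMultiEchoNifti()]
#' @return a [MultiEchoImage-class]
#' @export
readMultiEchoNifti <- function(path, protocol = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  arr <- array(as.numeric(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  side <- .sidecarPath(path)
  mask <- NULL
  if (is.null(protocol)) {
    if (!file.exists(side))
      stop("no protocol given and no sidecar found at ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    protocol <- protocolFromList(as.list(meta$protocol))
    if (!is.null(meta$mask_rle))
      mask <- matrix(inverse.rle(structure(
        list(lengths = as.integer(meta$mask_rle$lengths),
             values = as.logical(meta$mask_rle$values)),
        class = "rle")), dim(arr)[1], dim(arr)[2])
  }
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D (row, col, echo) volume, got ",
         length(dim(arr)), "-D")
  if (dim(arr)[3] != protocol@nEchoes)
    stop(sprintf("echo dimension of %s is %d but protocol has %d echoes",
                 path, dim(arr)[3], protocol@nEchoes))
  multiEchoImage(arr, protocol, mask = mask)
}

#' Write an ROI label map as integer NIfTI-1
#' @param labels a [ROILabels-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeROILabels <- function(labels, path) {
  stopifnot(is(labels, "ROILabels"))
  RNifti::writeNifti(RNifti::asNifti(labels@labels), path,
                     datatype = "int16")
  invisible(path)
}

#' Read an ROI label map from NIfTI-1
#' @param path path to an integer NIfTI file
#' @return a [ROILabels-class]
#' @export
readROILabels <- function(path) {
  img <- RNifti::readNifti(path)
  roiLabels(matrix(as.integer(img), dim(img)[1], dim(img)[2]))
}

#' Write a result table as CSV with a provenance header
#'
#' Columns are written in their existing (deterministic) order, floats at
#' full precision, with comment lines recording the package version, the
#' seed and a hash of the configuration. The decimal separator is always
#' `.` regardless of locale.
#'
#' @param records a data.frame
#' @param path output path
#' @param seed optional integer seed to record
#' @param config optional configuration object to hash into the header
#' @return `path`, invisibly
#' @seealso [readTable()]
#' @export
writeTable <- function(records, path, seed = NULL, config = NULL) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# renalTVF %s", as.character(packageVersion("renalTVF"))),
             con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", rlang::hash(config)), con)
  formatted <- withr::with_options(
    list(OutDec = "."),
    format(records, digits = 17, trim = TRUE, scientific = FALSE))
  write.csv(formatted, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [writeTable()]
#' @param path CSV path
#' @return data.frame (comment header lines are skipped)
#' @export
readTable <- function(path) {
  read.csv(path, comment.char = "#")
}
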