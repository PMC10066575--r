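# Readers and writers for the plain-text formats used around the
# pipeline: TSV tables, 6-column motion files, component-label tables,
# time-course matrices and NIfTI volumes.

#' Write / read a TSV table
#'
#' @param x data.frame.
#' @param path File path.
#' @return `path` (write) or a data.frame (read).
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Motion-parameter text files
#'
#' One frame per line, six whitespace-separated values: three
#' translations in mm then three rotations in radians.
#'
#' @param motion Frames x 6 matrix.
#' @param path File path.
#' @return `path` / frames x 6 matrix.
#' @export
writeMotionFile <- function(motion, path) {
  utils::write.table(format(motion, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeMotionFile
#' @export
readMotionFile <- function(path) {
  m <- as.matrix(utils::read.table(path))
  .stopIfNot(ncol(m) == 6, "motion file must have 6 columns")
  dimnames(m) <- NULL
  m
}

#' Component time-course TSV (frames x components, header row)
#'
#' @param courses Frames x K matrix with component column names.
#' @param path File path.
#' @return `path` / matrix.
#' @export
writeTimecourses <- function(courses, path) {
  writeTSV(as.data.frame(courses), path)
}

#' @rdname writeTimecourses
#' @export
readTimecourses <- function(path) as.matrix(readTSV(path))

#' Component-label TSV (columns component_id, subsystem)
#'
#' @param labels Named character vector (write) or path (read).
#' @param path File path.
#' @return `path` / named character vector.
#' @export
writeComponentLabels <- function(labels, path) {
  writeTSV(data.frame(component_id = names(labels),
                      subsystem = unname(labels)), path)
}

#' @rdname writeComponentLabels
#' @export
readComponentLabels <- function(path) {
  tab <- readTSV(path)
  .stopIfNot(all(c("component_id", "subsystem") %in% names(tab)),
             "label file needs columns component_id, subsystem")
  stats::setNames(tab$subsystem, tab$component_id)
}

#' NIfTI volume IO
#'
#' @param arr 3-D or 4-D array.
#' @param path `.nii` / `.nii.gz` path.
#' @param voxelSize Voxel size in mm (length 3).
#' @return `path` / array.
#' @export
writeVolumeNIfTI <- function(arr, path, voxelSize = c(1, 1, 1)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxelSize,
                           rep(1, length(dim(arr)) - 3))[seq_len(length(dim(arr)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @export
readVolumeNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxelSize") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Serialize a connectivity profile set to a long TSV
#'
#' @param profiles Named list (by subject) of averaged
#'   [ConnectivityProfile-class] objects (`NULL` entries are skipped).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    if (is.null(p)) return(NULL)
    wide <- stats::setNames(p@pairs$connectivity,
                            paste0(p@pairs$sysA, "_", p@pairs$sysB))
    data.frame(subject = id, t(wide), nfq = nfqValue(p),
               n_sessions = p@nSessionsUsed)
  })
  writeTSV(do.call(rbind, rows), path)
}
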