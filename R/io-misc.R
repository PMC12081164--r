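#' Read / write a triangulated surface as ASCII Wavefront OBJ
#'
#' Only \code{v} and triangular \code{f} records are used; other records are
#' ignored on read.
#'
#' @param path file path.
#' @return \code{readSurfaceObj}: a \code{CorticalSurface}.
#' @export
readSurfaceObj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  CorticalSurface(v, f)
}

#' @param surface a \code{CorticalSurface}.
#' @rdname readSurfaceObj
#' @export
writeSurfaceObj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", surface@vertices[, 1],
                     surface@vertices[, 2], surface@vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", surface@faces[, 1], surface@faces[, 2],
                     surface@faces[, 3]), con)
  invisible(path)
}

#' Read / write a labeled head volume as NIfTI-1
#'
#' @param path file path (.nii or .nii.gz).
#' @return \code{readHeadVolume}: a \code{HeadVolume}.
#' @export
readHeadVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  vox <- sqrt(sum(aff[1:3, 1]^2))   # isotropic by construction
  HeadVolume(array(as.integer(img), dim = dim(img)), voxelSize = vox,
             affine = aff)
}

#' @param volume a \code{HeadVolume}.
#' @rdname readHeadVolume
#' @export
writeHeadVolume <- function(volume, path) {
  h <- volume@voxelSize
  img <- RNifti::asNifti(volume@labels, pixdim = c(h, h, h))
  img <- RNifti::`sform<-`(img, structure(volume@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write an event table as TSV
#'
#' Columns: label, onset (s), duration (s).
#'
#' @param path file path.
#' @return \code{readEventsTsv}: a data.frame.
#' @export
readEventsTsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "onset", "duration") %in% names(ev)))
    stop("event TSV must have columns label, onset, duration")
  ev
}

#' @param events event data.frame.
#' @rdname readEventsTsv
#' @export
writeEventsTsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
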