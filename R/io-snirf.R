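## SNIRF (.snirf, HDF5 dialect) reader/writer, continuous-wave subset:
## data element 1, stim, probe and landmarks. Matrices are written with
## rhdf5's native orientation, so write/read round trips are exact.

#' Read a SNIRF file
#'
#' Reads the continuous-wave subset of a SNIRF (.snirf) container: the first
#' data element, the probe block (positions, wavelengths, landmarks) and all
#' stim groups. Additional data elements and aux groups beyond the first are
#' ignored with a warning.
#'
#' @param path path to a .snirf file.
#' @return an \code{\linkS4class{OpticalRecording}}.
#' @export
readSnirf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ls <- rhdf5::h5ls(path)
  full <- paste(ls$group, ls$name, sep = "/")
  full <- sub("^//", "/", full)
  if (!any(full == "/nirs" | grepl("^/nirs/", full)))
    stop("SNIRF format error: missing /nirs group")
  if (!any(full == "/nirs/data1"))
    stop("SNIRF format error: missing /nirs/data1")
  needed <- c("/nirs/data1/dataTimeSeries", "/nirs/data1/time",
              "/nirs/probe/wavelengths", "/nirs/probe/sourcePos3D",
              "/nirs/probe/detectorPos3D")
  for (nm in needed)
    if (!any(full == nm))
      stop("SNIRF format error: missing ", nm)

  extra <- grep("^/nirs/data[2-9]", full, value = TRUE)
  if (length(extra))
    warning("ignoring unsupported SNIRF data elements: ",
            paste(unique(sub("^(/nirs/data[0-9]+).*", "\\1", extra)),
                  collapse = ", "))
  aux <- grep("^/nirs/aux", full, value = TRUE)
  if (length(aux))
    warning("ignoring SNIRF aux group(s)")

  wl <- as.numeric(rhdf5::h5read(path, "/nirs/probe/wavelengths"))
  if (length(wl) < 2L)
    stop("SNIRF validation error: fewer than 2 wavelengths")
  srcPos <- asPositionMatrix(rhdf5::h5read(path, "/nirs/probe/sourcePos3D"))
  detPos <- asPositionMatrix(rhdf5::h5read(path, "/nirs/probe/detectorPos3D"))

  landmarks <- NULL
  if (any(full == "/nirs/probe/landmarkPos3D")) {
    lm <- rhdf5::h5read(path, "/nirs/probe/landmarkPos3D")
    lm <- matrix(as.numeric(lm), ncol = ncol(lm))
    if (any(full == "/nirs/probe/landmarkLabels"))
      rownames(lm) <- as.character(rhdf5::h5read(path,
                                                 "/nirs/probe/landmarkLabels"))
    landmarks <- lm[, 1:3, drop = FALSE]
  }

  mlNames <- unique(sub("^/nirs/data1/(measurementList[0-9]+).*", "\\1",
                        grep("^/nirs/data1/measurementList[0-9]+",
                             full, value = TRUE)))
  if (!length(mlNames))
    stop("SNIRF format error: missing /nirs/data1/measurementList")
  ord <- order(as.integer(sub("measurementList", "", mlNames)))
  mlNames <- mlNames[ord]
  channels <- do.call(rbind, lapply(mlNames, function(g) {
    rd <- function(f) as.integer(rhdf5::h5read(
      path, paste0("/nirs/data1/", g, "/", f)))
    data.frame(source = rd("sourceIndex"), detector = rd("detectorIndex"),
               wavelength = rd("wavelengthIndex"))
  }))

  times <- as.numeric(rhdf5::h5read(path, "/nirs/data1/time"))
  dts <- rhdf5::h5read(path, "/nirs/data1/dataTimeSeries")
  dts <- matrix(as.numeric(dts), nrow = nrow(dts))
  ## SNIRF stores time x channel; accept either orientation by matching dims
  if (nrow(dts) == length(times) && ncol(dts) == nrow(channels)) {
    intens <- t(dts)
  } else if (ncol(dts) == length(times) && nrow(dts) == nrow(channels)) {
    intens <- dts
  } else stop("SNIRF format error: dataTimeSeries dimensions do not match ",
              "time and measurementList")

  stimNames <- unique(sub("^/nirs/(stim[0-9]+).*", "\\1",
                          grep("^/nirs/stim[0-9]+", full, value = TRUE)))
  ev <- data.frame(label = character(), onset = numeric(),
                   duration = numeric())
  for (g in stimNames[order(as.integer(sub("stim", "", stimNames)))]) {
    nm <- as.character(rhdf5::h5read(path, paste0("/nirs/", g, "/name")))
    dat <- rhdf5::h5read(path, paste0("/nirs/", g, "/data"))
    dat <- matrix(as.numeric(dat), nrow = NROW(dat))
    if (ncol(dat) < 2L && nrow(dat) == 3L) dat <- t(dat)
    if (nrow(dat))
      ev <- rbind(ev, data.frame(label = nm, onset = dat[, 1],
                                 duration = dat[, 2]))
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL

  pr <- Probe(srcPos, detPos, wl, channels = channels, landmarks = landmarks)
  OpticalRecording(pr, times, intens, events = ev)
}

#' Write a SNIRF file
#'
#' Writes the continuous-wave SNIRF subset consumed by \code{readSnirf}:
#' one data element, the probe block and one stim group per event label.
#'
#' @param recording an \code{OpticalRecording}.
#' @param path output path (overwritten if present).
#' @return \code{path}, invisibly.
#' @export
writeSnirf <- function(recording, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  meta <- c(SubjectID = "synthetic", MeasurementDate = "unknown",
            MeasurementTime = "unknown", LengthUnit = "mm",
            TimeUnit = "s", FrequencyUnit = "Hz")
  for (nm in names(meta))
    rhdf5::h5write(unname(meta[nm]), path, paste0("nirs/metaDataTags/", nm))

  pr <- recording@probe
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(pr@wavelengths, path, "nirs/probe/wavelengths")
  rhdf5::h5write(unname(pr@sourcePos), path, "nirs/probe/sourcePos3D")
  rhdf5::h5write(unname(pr@detectorPos), path, "nirs/probe/detectorPos3D")
  if (!is.null(pr@landmarks)) {
    rhdf5::h5write(unname(pr@landmarks), path, "nirs/probe/landmarkPos3D")
    rhdf5::h5write(rownames(pr@landmarks), path, "nirs/probe/landmarkLabels")
  }

  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5write(t(recording@intensities), path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write(recording@times, path, "nirs/data1/time")
  ch <- pr@channels
  for (i in seq_len(nrow(ch))) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(ch$source[i], path, paste0(g, "/sourceIndex"))
    rhdf5::h5write(ch$detector[i], path, paste0(g, "/detectorIndex"))
    rhdf5::h5write(ch$wavelength[i], path, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(1L, path, paste0(g, "/dataType"))
    rhdf5::h5write(1L, path, paste0(g, "/dataTypeIndex"))
  }

  ev <- recording@events
  labs <- unique(ev$label)
  for (i in seq_along(labs)) {
    g <- sprintf("nirs/stim%d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(labs[i], path, paste0(g, "/name"))
    sel <- ev[ev$label == labs[i], , drop = FALSE]
    rhdf5::h5write(cbind(sel$onset, sel$duration, rep(1, nrow(sel))),
                   path, paste0(g, "/data"))
  }
  invisible(path)
}
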