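## Homer (.nirs) files are MATLAB Level-5 MAT containers. No MAT reader is
## available among the package's dependencies, so a minimal MAT v5 codec is
## implemented here, restricted to what .nirs files need: little-endian,
## uncompressed double arrays, character arrays and scalar structs.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L

pad8 <- function(raw) {
  r <- length(raw) %% 8L
  if (r) c(raw, raw(8L - r)) else raw
}

matTag <- function(type, nbytes) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.integer(c(type, nbytes)), con, size = 4, endian = "little")
  out <- rawConnectionValue(con); close(con)
  out
}

matSub <- function(type, dataRaw) {
  pad8(c(matTag(type, length(dataRaw)), dataRaw))
}

rawDoubles <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.double(x), con, size = 8, endian = "little")
  out <- rawConnectionValue(con); close(con)
  out
}

rawInts <- function(x, size) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.integer(x), con, size = size, endian = "little")
  out <- rawConnectionValue(con); close(con)
  out
}

matArrayHeader <- function(class, dims, name) {
  c(matSub(MI_UINT32, rawInts(c(class, 0L), 4)),
    matSub(MI_INT32, rawInts(dims, 4)),
    matSub(MI_INT8, charToRaw(name)))
}

matNumericElement <- function(name, x) {
  x <- as.matrix(x)
  body <- c(matArrayHeader(MX_DOUBLE, dim(x), name),
            matSub(MI_DOUBLE, rawDoubles(x)))
  c(matTag(MI_MATRIX, length(body)), body)
}

matCharElement <- function(name, s) {
  codes <- utf8ToInt(s)
  body <- c(matArrayHeader(MX_CHAR, c(1L, length(codes)), name),
            matSub(MI_UINT16, rawInts(codes, 2)))
  c(matTag(MI_MATRIX, length(body)), body)
}

matStructElement <- function(name, fields) {
  fn <- names(fields)
  nameRaw <- raw(0)
  for (f in fn) {
    b <- charToRaw(f)
    if (length(b) > 31L) stop("struct field name too long: ", f)
    nameRaw <- c(nameRaw, b, raw(32L - length(b)))
  }
  sub <- raw(0)
  for (f in fn) {
    v <- fields[[f]]
    el <- if (is.character(v)) matCharElement("", v)
          else matNumericElement("", v)
    sub <- c(sub, el)
  }
  body <- c(matArrayHeader(MX_STRUCT, c(1L, 1L), name),
            matSub(MI_INT32, rawInts(32L, 4)),
            matSub(MI_INT8, nameRaw),
            sub)
  c(matTag(MI_MATRIX, length(body)), body)
}

writeMat5 <- function(path, vars) {
  desc <- sprintf("MATLAB 5.0 MAT-file, created by nirsdot on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  hdr <- c(hdr, raw(8))                       # subsystem offset
  hdr <- c(hdr, rawInts(0x0100, 2), charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    el <- if (is.character(v)) matCharElement(nm, v)
          else if (is.list(v)) matStructElement(nm, v)
          else matNumericElement(nm, v)
    body <- c(body, el)
  }
  writeBin(c(hdr, body), path)
  invisible(path)
}

## ---- reader ----

matReadCtx <- function(raw) {
  env <- new.env(parent = emptyenv())
  env$raw <- raw; env$pos <- 1L
  env
}

ctxRead <- function(ctx, n) {
  if (n == 0L) return(raw(0))
  out <- ctx$raw[ctx$pos:(ctx$pos + n - 1L)]
  ctx$pos <- ctx$pos + n
  out
}

readIntLE <- function(raw, size, signed = TRUE) {
  readBin(raw, "integer", n = length(raw) %/% size, size = size,
          endian = "little", signed = if (size < 4) signed else TRUE)
}

## Reads one data sub-element (tag + payload), honoring the small format.
readSubElement <- function(ctx) {
  t1 <- readIntLE(ctxRead(ctx, 4L), 4)
  small <- bitwAnd(t1, -65536L) != 0L      # upper 16 bits nonzero
  if (small) {
    type <- bitwAnd(t1, 65535L)
    nbytes <- bitwShiftR(t1, 16L)
    data <- ctxRead(ctx, 4L)[seq_len(nbytes)]
  } else {
    type <- t1
    nbytes <- readIntLE(ctxRead(ctx, 4L), 4)
    data <- ctxRead(ctx, nbytes)
    r <- nbytes %% 8L
    if (r) ctxRead(ctx, 8L - r)
  }
  list(type = type, data = data)
}

decodeNumeric <- function(sub) {
  switch(as.character(sub$type),
    "9" = readBin(sub$data, "double", n = length(sub$data) %/% 8,
                  size = 8, endian = "little"),
    "7" = readBin(sub$data, "double", n = length(sub$data) %/% 4,
                  size = 4, endian = "little"),
    "5" = as.double(readIntLE(sub$data, 4)),
    "6" = as.double(readIntLE(sub$data, 4)),
    "3" = as.double(readIntLE(sub$data, 2)),
    "4" = as.double(readIntLE(sub$data, 2, signed = FALSE)),
    "1" = as.double(readIntLE(sub$data, 1)),
    "2" = as.double(readIntLE(sub$data, 1, signed = FALSE)),
    stop("unsupported MAT numeric storage type ", sub$type))
}

## Parses a full miMATRIX payload; returns list(name=, value=).
parseMatrixPayload <- function(payload) {
  ctx <- matReadCtx(payload)
  flags <- readSubElement(ctx)
  class <- bitwAnd(readIntLE(flags$data[1:4], 4), 255L)
  dims <- readIntLE(readSubElement(ctx)$data, 4)
  name <- rawToChar(readSubElement(ctx)$data)
  if (class == MX_DOUBLE || class %in% c(7L, 8L, 9L, 10L, 11L, 12L, 13L)) {
    vals <- decodeNumeric(readSubElement(ctx))
    value <- array(vals, dim = dims)
    if (length(dims) == 2L) value <- matrix(vals, dims[1], dims[2])
  } else if (class == MX_CHAR) {
    sub <- readSubElement(ctx)
    codes <- if (sub$type == MI_UINT16) readIntLE(sub$data, 2, signed = FALSE)
             else readIntLE(sub$data, 1, signed = FALSE)
    value <- intToUtf8(codes)
  } else if (class == MX_STRUCT) {
    fieldLen <- readIntLE(readSubElement(ctx)$data, 4)
    namesRaw <- readSubElement(ctx)$data
    nf <- length(namesRaw) %/% fieldLen
    fn <- vapply(seq_len(nf), function(i) {
      b <- namesRaw[((i - 1L) * fieldLen + 1L):(i * fieldLen)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    value <- vector("list", nf); names(value) <- fn
    for (i in seq_len(nf)) {
      el <- readSubElement(ctx)
      if (el$type != MI_MATRIX)
        stop("malformed MAT struct field")
      value[[i]] <- parseMatrixPayload(el$data)$value
    }
  } else stop("unsupported MAT array class ", class)
  list(name = name, value = value)
}

readMat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file: ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM")
    stop("unsupported MAT file byte order: ", endian)
  ctx <- matReadCtx(raw)
  ctxRead(ctx, 128L)
  out <- list()
  while (ctx$pos <= length(raw)) {
    el <- readSubElement(ctx)
    if (el$type == MI_COMPRESSED)
      stop("compressed MAT elements are not supported")
    if (el$type != MI_MATRIX) next
    p <- parseMatrixPayload(el$data)
    out[[p$name]] <- p$value
  }
  out
}

#' Read a Homer .nirs file
#'
#' Parses the MAT-file variables \code{d} (time x channel intensities),
#' \code{t} (times), \code{SD} (probe struct) and \code{s} (stimulus
#' columns). Consecutive nonzero runs in each \code{s} column become one
#' event whose duration spans the run.
#'
#' @param path path to a .nirs file.
#' @return an \code{\linkS4class{OpticalRecording}}.
#' @export
readNirsMat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vars <- readMat5(path)
  for (nm in c("d", "t"))
    if (is.null(vars[[nm]]))
      stop(".nirs format error: missing variable ", nm)
  if (is.null(vars$SD) || !is.list(vars$SD))
    stop(".nirs format error: missing SD structure")
  SD <- vars$SD
  for (nm in c("Lambda", "SrcPos", "DetPos", "MeasList"))
    if (is.null(SD[[nm]]))
      stop(".nirs format error: SD structure lacks field ", nm)
  ml <- SD$MeasList
  channels <- data.frame(source = as.integer(ml[, 1]),
                         detector = as.integer(ml[, 2]),
                         wavelength = as.integer(ml[, 4]))
  pr <- Probe(SD$SrcPos, SD$DetPos, as.numeric(SD$Lambda),
              channels = channels)
  times <- as.numeric(vars$t)
  intens <- t(vars$d)

  ev <- data.frame(label = character(), onset = numeric(),
                   duration = numeric())
  s <- vars$s
  if (!is.null(s)) {
    s <- as.matrix(s)
    for (j in seq_len(ncol(s))) {
      on <- which(s[, j] != 0)
      if (!length(on)) next
      runStart <- on[c(TRUE, diff(on) > 1L)]
      runEnd <- on[c(diff(on) > 1L, TRUE)]
      ev <- rbind(ev, data.frame(label = sprintf("stim%d", j),
                                 onset = times[runStart],
                                 duration = times[runEnd] - times[runStart]))
    }
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  OpticalRecording(pr, times, intens, events = ev)
}

#' Write a Homer .nirs file
#'
#' Emits uncompressed MAT v5 variables \code{d}, \code{t}, \code{s},
#' \code{SD} and \code{aux}. Each event label becomes one \code{s} column
#' set to 1 over the samples it covers.
#'
#' @param recording an \code{OpticalRecording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNirsMat <- function(recording, path) {
  pr <- recording@probe
  ch <- pr@channels
  times <- recording@times
  ev <- recording@events
  labs <- unique(ev$label)
  s <- matrix(0, length(times), max(1L, length(labs)))
  for (j in seq_along(labs)) {
    sel <- ev[ev$label == labs[j], , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      idx <- which(times >= sel$onset[i] - 1e-9 &
                   times <= sel$onset[i] + sel$duration[i] + 1e-9)
      s[idx, j] <- 1
    }
  }
  SD <- list(
    Lambda = matrix(pr@wavelengths, nrow = 1),
    SrcPos = unname(pr@sourcePos),
    DetPos = unname(pr@detectorPos),
    MeasList = cbind(ch$source, ch$detector, rep(1, nrow(ch)),
                     ch$wavelength),
    nSrcs = matrix(nrow(pr@sourcePos)),
    nDets = matrix(nrow(pr@detectorPos))
  )
  writeMat5(path, list(
    d = t(recording@intensities),
    t = matrix(times, ncol = 1),
    s = s,
    SD = SD,
    aux = matrix(0, length(times), 1)
  ))
}
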