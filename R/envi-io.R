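#' Write a cube or matrix as an ENVI band-sequential raster
#'
#' Writes a flat binary data file plus a text \code{.hdr} header
#' (samples/lines/bands, interleave bsq, IEEE float, band wavelengths).
#' Matrices are written as single-band rasters; logical masks as byte
#' rasters.
#'
#' @param x a \linkS4class{SpectralCube}, numeric matrix or logical matrix.
#' @param path output path of the data file (header is \code{path.hdr}).
#' @param wavelengths optional wavelength vector for matrix input.
#' @return \code{path}, invisibly.
#' @export
writeENVI <- function(x, path, wavelengths = NULL) {
  if (is(x, "SpectralCube")) {
    vals <- cubeValues(x)
    wavelengths <- wavelengths(x)
  } else if (is.logical(x)) {
    vals <- array(as.integer(x), c(dim(x), 1L))
  } else if (is.matrix(x)) {
    vals <- array(x, c(dim(x), 1L))
  } else stop("cannot write object of class ", class(x)[1L])
  d <- dim(vals)
  byte <- is.logical(x)
  con <- file(path, "wb")
  on.exit(close(con))
  # bsq: full band planes in sequence, row-major within a plane
  for (b in seq_len(d[3L]))
    if (byte)
      writeBin(as.integer(t(vals[, , b])), con, size = 1L)
    else
      writeBin(as.numeric(t(vals[, , b])), con, size = 8L)
  hdr <- c("ENVI",
           paste0("samples = ", d[2L]),
           paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", if (byte) 1L else 5L),
           "interleave = bsq",
           "byte order = 0")
  if (!is.null(wavelengths))
    hdr <- c(hdr, paste0("wavelength = {",
                         paste(format(wavelengths, trim = TRUE),
                               collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parseENVIHeader <- function(hdrPath) {
  lines <- readLines(hdrPath, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (length(m) == 0L) stop("header field missing: ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  wl <- NULL
  m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (length(m) == 1L) {
    inner <- sub(".*\\{", "", sub("\\}.*", "", m))
    wl <- as.numeric(strsplit(inner, ",")[[1L]])
  }
  list(samples = getNum("samples"), lines = getNum("lines"),
       bands = getNum("bands"), dataType = getNum("data type"),
       wavelengths = wl)
}

#' Read an ENVI band-sequential raster
#'
#' @param path data-file path (expects \code{path.hdr} alongside).
#' @param pixelSize pixel size (micrometres) for the returned cube.
#' @param treatment treatment tag for the returned cube.
#' @return a \linkS4class{SpectralCube} (single-band files yield a cube
#'   with one band and no wavelength axis requirement).
#' @export
readENVI <- function(path, pixelSize = 53, treatment = "raw") {
  hdr <- parseENVIHeader(paste0(path, ".hdr"))
  n <- hdr$samples * hdr$lines * hdr$bands
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- if (hdr$dataType == 1L)
    as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE))
  else if (hdr$dataType == 4L)
    readBin(con, "numeric", n, size = 4L)
  else
    readBin(con, "numeric", n, size = 8L)
  vals <- array(0, c(hdr$lines, hdr$samples, hdr$bands))
  per <- hdr$lines * hdr$samples
  for (b in seq_len(hdr$bands))
    vals[, , b] <- matrix(raw[((b - 1L) * per + 1L):(b * per)],
                          hdr$lines, hdr$samples, byrow = TRUE)
  wl <- if (is.null(hdr$wavelengths)) seq_len(hdr$bands) else
    hdr$wavelengths
  SpectralCube(vals, wl, pixelSize, treatment = treatment)
}
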