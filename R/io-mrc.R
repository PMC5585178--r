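# MRC2014 volume / stack input and output. Axis convention: the first array
# index is the MRC fast axis (x, columns), the third is sections (z);
# mode 2 (32-bit float) is written, modes 0/1/2 are read.

#' Read an MRC file
#'
#' @param path path to an MRC2014 file (modes 0, 1, 2).
#' @param stack if `TRUE` the nz sections are interpreted as a stack of 2D
#'   projections (the array is still returned as nx x ny x nz; combine with
#'   angles via [tilt_series()]).
#' @return a 3D numeric array with attributes `voxel_size` (cella/mx, NA when
#'   absent from the header) and `is_stack`. A 2D file yields nz = 1.
#' @export
read_mrc <- function(path, stack = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  fsize <- file.info(path)$size
  if (fsize < 1024) {
    stop(errorCondition(
      sprintf("malformed MRC header: file is %d bytes, header needs 1024", fsize),
      class = c("format_error", "error")
    ))
  }
  con <- file(path, "rb")
  on.exit(close(con))

  read_header <- function(endian) {
    seek(con, 0)
    h <- list()
    h$dims <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$mode <- readBin(con, "integer", 1, size = 4, endian = endian)
    h$nstart <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$mgrid <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$cella <- readBin(con, "numeric", 3, size = 4, endian = endian)
    h$cellb <- readBin(con, "numeric", 3, size = 4, endian = endian)
    h$map_axes <- readBin(con, "integer", 3, size = 4, endian = endian)
    h$dstats <- readBin(con, "numeric", 3, size = 4, endian = endian)
    h$ispg <- readBin(con, "integer", 1, size = 4, endian = endian)
    h$nsymbt <- readBin(con, "integer", 1, size = 4, endian = endian)
    h
  }

  # machine stamp at byte offset 212 decides endianness; fall back to
  # plausibility of the little-endian header
  seek(con, 212)
  stamp <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  endian <- if (length(stamp) == 2 && stamp[1] == 0x11) "big" else "little"
  h <- read_header(endian)
  plausible <- function(h) {
    all(is.finite(h$dims)) && all(h$dims > 0) && h$mode %in% c(0L, 1L, 2L) &&
      h$nsymbt >= 0
  }
  if (!plausible(h)) {
    endian <- if (endian == "little") "big" else "little"
    h <- read_header(endian)
    if (!plausible(h)) {
      stop(errorCondition(
        sprintf("malformed MRC header: dims=(%s) mode=%d at offset 0-15",
                paste(h$dims, collapse = ","), h$mode),
        class = c("format_error", "error")
      ))
    }
  }
  if (!h$mode %in% c(0L, 1L, 2L)) {
    stop(errorCondition(paste0("unsupported MRC mode: ", h$mode),
                        class = c("unsupported_mode", "error")))
  }
  n <- prod(as.double(h$dims))
  bytes <- c(`0` = 1, `1` = 2, `2` = 4)[as.character(h$mode)]
  expected <- 1024 + h$nsymbt + n * bytes
  if (fsize < expected) {
    stop(errorCondition(
      sprintf("truncated MRC file: %d bytes, expected %d (data offset %d)",
              fsize, expected, 1024 + h$nsymbt),
      class = c("format_error", "error")
    ))
  }
  seek(con, 1024 + h$nsymbt)
  data <- switch(as.character(h$mode),
    `0` = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE,
                             endian = endian)),
    `1` = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = endian)),
    `2` = readBin(con, "numeric", n, size = 4, endian = endian)
  )
  if (length(data) < n) {
    stop(errorCondition("truncated MRC data section",
                        class = c("format_error", "error")))
  }
  out <- array(data, dim = h$dims)
  vs <- if (h$mgrid[1] > 0 && h$cella[1] > 0) h$cella[1] / h$mgrid[1] else NA_real_
  attr(out, "voxel_size") <- vs
  attr(out, "is_stack") <- isTRUE(stack)
  out
}

#' Write an MRC file (mode 2)
#'
#' @param data a 2D/3D numeric array, a [tilt_series()] (its projections are
#'   written as a stack) or a `tomo_reconstruction` (its `N^3` volume is
#'   written).
#' @param path output path.
#' @param voxel_size physical length per voxel, stored in the header cell
#'   dimensions (defaults to the object's pixel size where known, else 1).
#' @return `path`, invisibly. Write-then-read round trips are bit-exact for
#'   float32 data.
#' @export
write_mrc <- function(data, path, voxel_size = NULL) {
  if (inherits(data, "tilt_series")) {
    voxel_size <- voxel_size %||% data$pixel_size
    data <- data$projections
  } else if (inherits(data, "tomo_reconstruction")) {
    data <- data$volume
  }
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop_invalid("'data' must be a 2D or 3D array")
  if (!all(is.finite(data))) stop_invalid("'data' has non-finite values")
  voxel_size <- voxel_size %||% 1
  d <- dim(data)
  data <- as.numeric(data)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * voxel_size)         # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(0L)                     # ispg
  wi(0L)                     # nsymbt
  wi(integer(25))            # extra (words 25-49)
  wf(c(0, 0, 0))             # origin (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)      # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # machine stamp, LE
  wf(sd(data))               # rms
  wi(1L)                     # nlabl
  lab <- sprintf("%-80s", "fouriertomo")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720, eos = NULL)
  wf(data)
  invisible(path)
}

#' Read a multi-page TIFF as a projection stack
#'
#' Convenience reader (requires the optional `tiff` package); returns an
#' `N x N x J` array suitable for [tilt_series()].
#'
#' @param path path to a TIFF file.
#' @return a 3D numeric array.
#' @export
read_tiff_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_invalid("reading TIFF requires the 'tiff' package")
  }
  # integer-format TIFFs come back normalized to [0, 1], float TIFFs as
  # stored; either is fine for reconstruction, which is scale-free
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  # TIFF rows are y; transpose so the first index is x as in MRC
  arr <- vapply(pages, function(p) t(p), matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  array(arr, c(dim(arr)[1], dim(arr)[2], length(pages)))
}
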