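# Plain-text Euler angle files: one row per projection, "phi theta psi" in
# degrees, whitespace separated; '#' lines are comments. A single-column
# file is single-tilt shorthand (theta only, phi = psi = 0).

#' Read Euler angles from a text file
#'
#' @param path path to the angles file.
#' @return a `J x 3` matrix with columns `phi`, `theta`, `psi` (degrees).
#' @export
read_angles <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    stop(errorCondition("angles file has no data lines",
                        class = c("format_error", "error")))
  }
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop(errorCondition(
        sprintf("angles file line %d: non-numeric token", i),
        class = c("format_error", "error")
      ))
    }
    vals
  })
  ncols <- lengths(rows)
  bad <- which(ncols != ncols[1] | !ncols %in% c(1L, 3L))
  if (length(bad) > 0 || !ncols[1] %in% c(1L, 3L)) {
    i <- if (length(bad) > 0) bad[1] else 1L
    stop(errorCondition(
      sprintf("angles file line %d: expected %s columns, got %d",
              keep[i], if (ncols[1] %in% c(1L, 3L)) ncols[1] else "1 or 3",
              ncols[i]),
      class = c("format_error", "error")
    ))
  }
  m <- do.call(rbind, rows)
  if (ncol(m) == 1L) m <- cbind(0, m[, 1], 0)
  colnames(m) <- c("phi", "theta", "psi")
  m
}

#' Write Euler angles to a text file
#'
#' Writes `phi theta psi` rows at 6 decimal places; read/write round trips
#' are exact at that precision.
#'
#' @param angles a `J x 3` matrix of Euler triples, or a length-`J` vector of
#'   single-tilt angles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angles <- function(angles, path) {
  angles <- as_euler_angles(angles)
  writeLines(sprintf("%.6f %.6f %.6f", angles[, 1], angles[, 2], angles[, 3]),
             path)
  invisible(path)
}
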