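# Scan and ROI file formats.
#
# Scans are stored as plain-text PGM (portable graymap, magic "P2") with
# maxval 65535: a standard, dependency-free container for single-plane
# 16-bit grayscale rasters that round-trips exactly. ROI mask sets are
# stored as a run-length-encoded JSON sidecar.

#' Read / write a 16-bit grayscale scan (plain PGM, P2)
#'
#' @param scan A `uw_scan`.
#' @param path File path.
#' @param pixel_size,label Metadata attached on read (PGM itself stores
#'   only the raster).
#' @return `write_scan_pgm` returns `path` invisibly; `read_scan_pgm`
#'   returns a `uw_scan`.
#' @export
write_scan_pgm <- function(scan, path) {
  px <- scan$pixels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), "65535"), con)
  # row-major, one image row per line
  writeLines(apply(px, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_scan_pgm
#' @export
read_scan_pgm <- function(path, pixel_size = NA_real_, label = "pre") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!identical(lines[1], "P2"))
    uw_stop("not a plain (P2) PGM file", "uw_format_error")
  toks <- tryCatch(scan(text = lines[-1], what = numeric(), quiet = TRUE),
                   error = function(e)
                     uw_stop("malformed PGM: non-numeric pixel data",
                             "uw_format_error"))
  nc <- toks[1]; nr <- toks[2]; maxval <- toks[3]
  if (maxval > 65535)
    uw_stop("PGM maxval exceeds 16-bit range", "uw_format_error")
  vals <- toks[-(1:3)]
  if (length(vals) != nr * nc)
    uw_stop("PGM pixel count does not match header", "uw_format_error")
  uw_scan(matrix(vals, nrow = nr, ncol = nc, byrow = TRUE),
          pixel_size = pixel_size, label = label)
}

#' Read / write an ROI mask set (run-length JSON)
#'
#' Masks are encoded column-major as `[start, length]` runs of TRUE pixels:
#' `{"shape": [nr, nc], "rois": {"name": [[start, len], ...], ...}}`.
#'
#' @param rois A [uw_roiset()].
#' @param path File path (.json).
#' @return `write_roiset` returns `path` invisibly; `read_roiset` returns a
#'   `uw_roiset`.
#' @export
write_roiset <- function(rois, path) {
  shp <- dim(rois[[1]])
  enc <- lapply(unclass(rois), function(m) {
    v <- as.vector(m)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    mat <- cbind(starts[keep], r$lengths[keep])
    apply(mat, 1, function(row) as.list(row), simplify = FALSE)
  })
  jsonlite::write_json(list(shape = shp, rois = enc), path, digits = NA)
  invisible(path)
}

#' @rdname write_roiset
#' @export
read_roiset <- function(path) {
  obj <- jsonlite::read_json(path)
  shp <- as.integer(unlist(obj$shape))
  masks <- lapply(obj$rois, function(runs) {
    v <- logical(prod(shp))
    for (run in runs) {
      s <- as.integer(run[[1]]); l <- as.integer(run[[2]])
      v[s:(s + l - 1L)] <- TRUE
    }
    matrix(v, nrow = shp[1], ncol = shp[2])
  })
  uw_roiset(masks)
}
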