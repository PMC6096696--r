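#' Read and write raster images
#'
#' Images are exchanged as `h x w x 3` arrays in `[0, 1]` (greyscale matrices
#' are promoted). PNG is written at 8 bits/channel via the png package; PPM is
#' written as binary P6 (or plain-text P3 with `ascii = TRUE`) with
#' round-half-to-even 8-bit quantisation. Both round-trip bit-exactly at
#' 8 bits.
#'
#' @param image An `h x w x 3` array (or `h x w` matrix) in `[0, 1]`, or a
#'   `macchia_stimulus`.
#' @param path File path; `write_image()` picks the format from the extension
#'   (`.png`, `.ppm`).
#' @param ascii Write PPM as plain-text P3 instead of binary P6.
#' @return `write_image()` returns `path` invisibly; `read_image()` returns an
#'   `h x w x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path, ascii = FALSE) {
  if (inherits(image, "macchia_stimulus")) image <- image$image
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext == "ppm") {
    write_ppm(image, path, ascii = ascii)
  } else {
    abort("Unsupported image extension; use .png or .ppm.")
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext == "ppm") {
    read_ppm(path)
  } else {
    abort("Unsupported image extension; use .png or .ppm.")
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

quantise8 <- function(x) {
  # round half to even, as base round() does
  as.integer(round(pmin(1, pmax(0, x)) * 255))
}

write_ppm <- function(image, path, ascii = FALSE) {
  h <- dim(image)[1]; w <- dim(image)[2]
  # interleave channels pixel by pixel, row-major
  q <- quantise8(aperm(image, c(3, 2, 1)))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(q, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(q), con)
  }
  invisible(path)
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    out <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) break
      if (grepl("\\s", ch)) {
        if (length(out)) break else next
      }
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      out <- c(out, ch)
    }
    paste(out, collapse = "")
  }
  magic <- tok()
  if (!magic %in% c("P3", "P6")) abort("Not a PPM file (missing P3/P6 magic).")
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  if (anyNA(c(w, h, mx)) || w < 1 || h < 1) abort("Malformed PPM header.")
  nvals <- 3L * w * h
  vals <- if (magic == "P6") {
    as.integer(readBin(con, "raw", nvals))
  } else {
    v <- scan(con, what = integer(), n = nvals, quiet = TRUE)
    if (length(v) < nvals) abort("Truncated P3 pixel data.")
    v
  }
  arr <- aperm(array(vals / mx, dim = c(3, w, h)), c(3, 2, 1))
  arr
}

#' Read and write response tables
#'
#' Response CSVs carry one row per setting with the schema
#' `observer_id, condition, edge, gamut, pair, replicate, contrast, rt_s`
#' (`schema_version` 1). `read_responses()` validates the required columns and
#' errors naming any missing one.
#'
#' @param data A response tibble (see [simulate_session()]).
#' @param path CSV path.
#' @return `read_responses()` returns a tibble; `write_responses()` returns
#'   `path` invisibly.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("observer_id", "condition", "pair", "contrast")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(paste0("Response file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(d$contrast < 0 | d$contrast > 1)) {
    abort("Response file has contrast values outside [0, 1].")
  }
  d
}

#' Write per-dot stimulus metadata
#'
#' CSV sidecar for a rendered stimulus: dot id, centre, radius, side, encoded
#' colour and the sampled hue / CWK coefficients where applicable.
#'
#' @param stim A `macchia_stimulus`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dot_metadata <- function(stim, path) {
  stopifnot(inherits(stim, "macchia_stimulus"))
  readr::write_csv(
    dplyr::select(stim$dots, "dot", "x", "y", "radius", "side",
                  "r", "g", "b", "hue", "c", "w", "k"),
    path
  )
  invisible(path)
}
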