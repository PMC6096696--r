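#' Display calibration
#'
#' Bundles the photometric description of the display every colour computation
#' refers to: the luminances of the three primaries at full drive, their CIE xy
#' chromaticities, the white point, and the transfer (gamma) curve.
#'
#' The default luminances are in the measured ratio R:G:B = 69:197:53 cd/m2;
#' chromaticities default to the sRGB / ITU-R BT.709 primaries with a D65 white,
#' the generic-display convention, and the transfer curve is a pure power law
#' with exponent 2.2 (the piecewise sRGB curve is available via
#' `transfer = "srgb"`).
#'
#' @param primary_luminances Numeric length 3, luminances (cd/m2) of the R, G,
#'   B primaries at full drive. All strictly positive.
#' @param primary_chromaticities 3x2 numeric matrix of CIE xy chromaticities,
#'   rows R, G, B, entries in `[0, 1]`.
#' @param white_xy CIE xy chromaticity of the display white, length 2.
#' @param gamma Positive exponent of the power-law transfer curve.
#' @param transfer `"power"` for a pure gamma curve, `"srgb"` for the piecewise
#'   sRGB encoding (in which case `gamma` is ignored on decode).
#'
#' @return An object of class `display_calibration`.
#' @examples
#' cal <- display_calibration()
#' luminance(c(1, 1, 1), cal) # white, 319 cd/m2
#' @export
display_calibration <- function(primary_luminances = c(69, 197, 53),
                                primary_chromaticities = srgb_chromaticities(),
                                white_xy = c(0.3127, 0.3290),
                                gamma = 2.2,
                                transfer = c("power", "srgb")) {
  transfer <- match.arg(transfer)
  primary_luminances <- as.numeric(primary_luminances)
  white_xy <- as.numeric(white_xy)
  primary_chromaticities <- as.matrix(primary_chromaticities)
  if (length(primary_luminances) != 3 || any(!is.finite(primary_luminances)) ||
      any(primary_luminances <= 0)) {
    abort("`primary_luminances` must be three strictly positive numbers.")
  }
  if (!all(dim(primary_chromaticities) == c(3, 2)) ||
      any(primary_chromaticities < 0) || any(primary_chromaticities > 1)) {
    abort("`primary_chromaticities` must be a 3x2 matrix with entries in [0, 1].")
  }
  if (length(white_xy) != 2 || any(white_xy < 0) || any(white_xy > 1)) {
    abort("`white_xy` must be an xy pair in [0, 1].")
  }
  if (!is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be a positive number.")
  }
  dimnames(primary_chromaticities) <- list(c("R", "G", "B"), c("x", "y"))
  structure(
    list(
      primary_luminances = primary_luminances,
      primary_chromaticities = primary_chromaticities,
      white_xy = white_xy,
      gamma = gamma,
      transfer = transfer
    ),
    class = "display_calibration"
  )
}

#' @export
print.display_calibration <- function(x, ...) {
  cat("<display_calibration>\n")
  cat(sprintf("  primaries (cd/m2): R %.4g  G %.4g  B %.4g\n",
              x$primary_luminances[1], x$primary_luminances[2],
              x$primary_luminances[3]))
  cat(sprintf("  white xy: (%.4f, %.4f)   transfer: %s (gamma %.3g)\n",
              x$white_xy[1], x$white_xy[2], x$transfer, x$gamma))
  invisible(x)
}

#' sRGB / BT.709 primary chromaticities
#'
#' @return A 3x2 matrix of CIE xy pairs (rows R, G, B).
#' @export
srgb_chromaticities <- function() {
  matrix(c(0.64, 0.33,
           0.30, 0.60,
           0.15, 0.06),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("R", "G", "B"), c("x", "y")))
}

#' Read or write a calibration config file
#'
#' Calibrations are exchanged as plain-text YAML with keys `gamma`, `transfer`,
#' `white_xy`, `primaries_xy` (three xy pairs, rows R, G, B) and
#' `primary_luminances_cdm2`.
#'
#' @param path Path to the config file.
#' @return `read_calibration()` returns a [display_calibration()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("gamma", "white_xy", "primaries_xy", "primary_luminances_cdm2")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("Calibration config is missing key(s): ",
                 paste(missing, collapse = ", ")))
  }
  display_calibration(
    primary_luminances = unlist(cfg$primary_luminances_cdm2),
    primary_chromaticities = do.call(rbind, cfg$primaries_xy),
    white_xy = unlist(cfg$white_xy),
    gamma = cfg$gamma,
    transfer = cfg$transfer %||% "power"
  )
}

#' @rdname read_calibration
#' @param cal A [display_calibration()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "display_calibration"))
  yaml::write_yaml(
    list(
      gamma = cal$gamma,
      transfer = cal$transfer,
      white_xy = as.numeric(cal$white_xy),
      primaries_xy = lapply(seq_len(3), function(i)
        as.numeric(cal$primary_chromaticities[i, ])),
      primary_luminances_cdm2 = as.numeric(cal$primary_luminances)
    ),
    path
  )
  invisible(path)
}

# XYZ column matrix of the primaries, scaled so encoded white (1,1,1) maps to
# the calibration white point with Y = 1.  Used by rgb_to_lab().
rgb_xyz_matrix <- function(cal) {
  xy <- cal$primary_chromaticities
  # columns: XYZ of each primary at unit Y
  P <- rbind(xy[, "x"] / xy[, "y"],
             rep(1, 3),
             (1 - xy[, "x"] - xy[, "y"]) / xy[, "y"])
  w <- c(cal$white_xy[1] / cal$white_xy[2],
         1,
         (1 - cal$white_xy[1] - cal$white_xy[2]) / cal$white_xy[2])
  s <- tryCatch(solve(P, w), error = function(e)
    abort("Primary chromaticities give a singular RGB->XYZ matrix."))
  if (any(!is.finite(s))) {
    abort("Primary chromaticities give a singular RGB->XYZ matrix.")
  }
  P %*% diag(s)
}

white_xyz <- function(cal) {
  c(cal$white_xy[1] / cal$white_xy[2],
    1,
    (1 - cal$white_xy[1] - cal$white_xy[2]) / cal$white_xy[2])
}
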