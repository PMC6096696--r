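#' The six cardinal colours
#'
#' The full-intensity display colours at the chromatic corners of the RGB cube,
#' indexed on the natural six-step colour circle Y = 0, G = 1, C = 2, B = 3,
#' M = 4, R = 5.
#'
#' @return A tibble with columns `name`, `hue`, `r`, `g`, `b`.
#' @examples
#' cardinal_colours()
#' @export
cardinal_colours <- function() {
  tibble(
    name = c("Y", "G", "C", "B", "M", "R"),
    hue = 0:5,
    r = c(1, 0, 0, 0, 1, 1),
    g = c(1, 1, 1, 0, 0, 0),
    b = c(0, 0, 1, 1, 1, 0)
  )
}

#' Look up cardinal colours as an RGB matrix
#'
#' @param name Character vector of cardinal letters (Y, G, C, B, M, R).
#' @return A `length(name)` x 3 matrix of encoded RGB coordinates.
#' @export
cardinal_rgb <- function(name) {
  cc <- cardinal_colours()
  idx <- match(toupper(name), cc$name)
  if (anyNA(idx)) {
    abort(paste0("Unknown cardinal colour(s): ",
                 paste(unique(name[is.na(idx)]), collapse = ", ")))
  }
  m <- as.matrix(cc[idx, c("r", "g", "b")])
  rownames(m) <- cc$name[idx]
  m
}

# Coerce colours to an n x 3 numeric matrix.  Accepts a length-3 vector, an
# n x 3 matrix, a data frame with r/g/b columns, or cardinal letters.
as_rgb_matrix <- function(x, check_range = TRUE) {
  if (is.character(x)) {
    m <- cardinal_rgb(x)
  } else if (is.data.frame(x)) {
    if (!all(c("r", "g", "b") %in% names(x))) {
      abort("Colour data frames need columns `r`, `g`, `b`.")
    }
    m <- cbind(x$r, x$g, x$b)
  } else if (is.matrix(x)) {
    if (ncol(x) != 3) abort("Colour matrices must have 3 columns.")
    m <- x
  } else if (is.numeric(x) && length(x) == 3) {
    m <- matrix(x, nrow = 1)
  } else {
    abort("Cannot interpret `x` as RGB colours.")
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("r", "g", "b")
  if (check_range && (anyNA(m) || any(m < 0) || any(m > 1))) {
    abort("RGB components must lie in [0, 1].")
  }
  m
}

#' Gamma decoding and encoding
#'
#' `decode_gamma()` maps display-encoded coordinates to linear light;
#' `encode_gamma()` is its inverse. With the default calibration this is a pure
#' power law with exponent 2.2; with `transfer = "srgb"` the piecewise sRGB
#' curve is used.
#'
#' @param x Colours: a length-3 vector, an n x 3 matrix, a data frame with
#'   `r`, `g`, `b` columns, or cardinal letters.
#' @param cal A [display_calibration()].
#' @return An n x 3 numeric matrix.
#' @examples
#' decode_gamma(c(0.5, 0, 0), display_calibration())
#' @export
decode_gamma <- function(x, cal = display_calibration()) {
  m <- as_rgb_matrix(x)
  if (cal$transfer == "srgb") {
    lo <- m <= 0.04045
    m[lo] <- m[lo] / 12.92
    m[!lo] <- ((m[!lo] + 0.055) / 1.055)^2.4
    m
  } else {
    m^cal$gamma
  }
}

#' @rdname decode_gamma
#' @export
encode_gamma <- function(x, cal = display_calibration()) {
  m <- as_rgb_matrix(x)
  if (cal$transfer == "srgb") {
    lo <- m <= 0.0031308
    m[lo] <- m[lo] * 12.92
    m[!lo] <- 1.055 * m[!lo]^(1 / 2.4) - 0.055
    m
  } else {
    m^(1 / cal$gamma)
  }
}

#' Photometric luminance of display colours
#'
#' Decodes the transfer curve and takes the dot product of the linear-light
#' components with the calibrated primary luminances, so luminance is additive
#' over primaries: yellow = R + G.
#'
#' @inheritParams decode_gamma
#' @return Numeric vector of luminances in cd/m2.
#' @examples
#' luminance("Y", display_calibration()) # 69 + 197 = 266
#' @export
luminance <- function(x, cal = display_calibration()) {
  lin <- decode_gamma(x, cal)
  as.numeric(lin %*% cal$primary_luminances)
}

#' @rdname luminance
#' @return `luminance_fraction()` returns the luminance as a fraction of the
#'   display white's luminance, in `[0, 1]` for in-gamut colours.
#' @export
luminance_fraction <- function(x, cal = display_calibration()) {
  luminance(x, cal) / sum(cal$primary_luminances)
}

#' Michelson contrast
#'
#' `|I1 - I2| / (I1 + I2)` for two mean intensities; the response variable of
#' the matching task.
#'
#' @param i1,i2 Non-negative mean intensities (vectorised).
#' @return Contrast values in `[0, 1]`.
#' @examples
#' michelson_contrast(266, 53) # approx 0.67, the yellow-blue luminance contrast
#' @export
michelson_contrast <- function(i1, i2) {
  if (any(i1 < 0) || any(i2 < 0)) abort("Intensities must be non-negative.")
  s <- i1 + i2
  if (any(s == 0)) abort("Michelson contrast is undefined when both intensities are zero.")
  abs(i1 - i2) / s
}

#' Euclidean distance in the RGB cube
#'
#' Distance between encoded (gamma-domain) coordinates, taken raw with no
#' decoding. For cardinal pairs the distances are 1, sqrt(2) ~ 1.4 and
#' sqrt(3) ~ 1.7 for one, two and three differing channels.
#'
#' @param a,b Colours (any form accepted by [decode_gamma()]); rows recycled to
#'   a common length.
#' @return Numeric vector of distances in `[0, sqrt(3)]`.
#' @examples
#' rgb_cube_distance("Y", "B") # sqrt(3)
#' @export
rgb_cube_distance <- function(a, b) {
  ma <- as_rgb_matrix(a)
  mb <- as_rgb_matrix(b)
  n <- max(nrow(ma), nrow(mb))
  ma <- ma[rep_len(seq_len(nrow(ma)), n), , drop = FALSE]
  mb <- mb[rep_len(seq_len(nrow(mb)), n), , drop = FALSE]
  unname(sqrt(rowSums((ma - mb)^2)))
}

#' Colour strength by the maximum rule
#'
#' The strength of a colour is its maximum encoded RGB coordinate; it equals 1
#' for every cardinal colour, which is how blue can counterbalance yellow
#' despite being five times less luminous.
#'
#' @inheritParams decode_gamma
#' @return Numeric vector of strengths in `[0, 1]`.
#' @export
max_rule <- function(x) {
  m <- as_rgb_matrix(x)
  apply(m, 1, max)
}

#' Cyclic distance on the six-step colour circle
#'
#' @param h1,h2 Hue indices (numeric, taken mod 6) or cardinal letters.
#' @return Step distances in `[0, 3]`.
#' @examples
#' colour_circle_distance("Y", "B") # 3: complementary
#' @export
colour_circle_distance <- function(h1, h2) {
  h1 <- as_hue_index(h1)
  h2 <- as_hue_index(h2)
  d <- abs(h1 - h2) %% 6
  pmin(d, 6 - d)
}

as_hue_index <- function(h) {
  if (is.character(h)) {
    cc <- cardinal_colours()
    idx <- match(toupper(h), cc$name)
    if (anyNA(idx)) abort("Unknown cardinal letter in hue input.")
    cc$hue[idx]
  } else {
    as.numeric(h) %% 6
  }
}

#' Hue index to full colour
#'
#' Piecewise-linear interpolation along the hexagon of cardinal colours
#' (the periodic sequence Y G C B M R): integer indices give the cardinals,
#' fractional indices ramp the single channel that differs between the two
#' flanking cardinals, linearly in encoded RGB.
#'
#' @param h Hue indices on the six-step circle (numeric, taken mod 6) or
#'   cardinal letters.
#' @return An n x 3 matrix of encoded RGB coordinates.
#' @examples
#' hue_to_rgb(0.5) # halfway along the yellow-green edge: (0.5, 1, 0)
#' @export
hue_to_rgb <- function(h) {
  h <- as_hue_index(h)
  cc <- as.matrix(cardinal_colours()[, c("r", "g", "b")])
  lo <- floor(h) %% 6
  frac <- h - floor(h)
  m <- cc[lo + 1, , drop = FALSE] * (1 - frac) +
    cc[(lo + 1) %% 6 + 1, , drop = FALSE] * frac
  colnames(m) <- c("r", "g", "b")
  rownames(m) <- NULL
  m
}

# 2-D hexagon-plane position of colours: primaries sit at unit vectors at
# angles 60 deg * hue, and the map is linear in the channels, so each secondary
# lands exactly on its own unit vector and greys collapse to the origin.
hexagon_position <- function(x) {
  m <- as_rgb_matrix(x)
  ang <- c(R = 5, G = 1, B = 3) * pi / 3
  ex <- cos(ang)
  ey <- sin(ang)
  cbind(x = m %*% ex, y = m %*% ey)
}
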