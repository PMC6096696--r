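#' Side assignment across the transition
#'
#' `assign_sides_hard()` classifies each dot left or right by the location of
#' its centre relative to the vertical midline. `assign_sides_soft()` instead
#' ramps the probability of being designated *right* linearly from 0 to 1
#' across a vertical strip centred on the midline; outside the strip the
#' designation is deterministic. Only the designation is probabilistic — dot
#' colours are drawn from the designated side's gamut either way.
#'
#' @param layout A tibble with an `x` column (dot centres).
#' @param midline Abscissa of the transition.
#' @param strip_width Full width of the soft boundary strip, in pixels.
#' @return `layout` with a `side` column (`"left"` / `"right"`).
#' @export
assign_sides_hard <- function(layout, midline) {
  dplyr::mutate(layout, side = ifelse(.data$x < midline, "left", "right"))
}

#' @rdname assign_sides_hard
#' @export
assign_sides_soft <- function(layout, midline, strip_width) {
  if (strip_width <= 0) abort("`strip_width` must be positive.")
  p_right <- pmin(1, pmax(0, (layout$x - (midline - strip_width / 2)) / strip_width))
  dplyr::mutate(layout,
                side = ifelse(runif(dplyr::n()) < p_right, "right", "left"))
}

#' Achromatic intensity dither
#'
#' Normal perturbation around a mean grey level, with a fixed standard
#' deviation expressed as a fraction of the full black-white scale (default
#' 0.20), clipped to `[0, 1]`.
#'
#' @param n Number of draws.
#' @param mean Mean intensity in `[0, 1]`.
#' @param sd Standard deviation as a fraction of full scale.
#' @return Numeric vector of intensities in `[0, 1]`.
#' @export
sample_achromatic <- function(n, mean, sd = 0.20) {
  if (mean < 0 || mean > 1) abort("`mean` must be in [0, 1].")
  pmin(1, pmax(0, rnorm(n, mean, sd)))
}

#' Skewed colour/white/black coefficients
#'
#' Ostwald-style coefficients (colour content c, white content w, black
#' content k with c + w + k = 1): three independent U(0, 1) draws, the first
#' multiplied by a skew factor (default 4, favouring saturated colours), then
#' normalised by the common sum.
#'
#' @param n Number of triplets.
#' @param skew Skew factor (>= 1) applied to the colour coordinate.
#' @return A tibble with columns `c`, `w`, `k`, each row summing to 1 exactly.
#' @export
sample_cwk <- function(n, skew = 4) {
  if (skew < 1) abort("`skew` must be >= 1.")
  u <- matrix(runif(3 * n), ncol = 3)
  u[, 1] <- u[, 1] * skew
  s <- rowSums(u)
  tibble(c = u[, 1] / s, w = u[, 2] / s, k = u[, 3] / s)
}

#' Mix a full colour with white and black
#'
#' Realises `Q = c F + w W + k K` by additive mixture: by default in linear
#' light (decoded, mixed, re-encoded); `mixing = "encoded"` mixes the raw
#' encoded coordinates instead, for ablation.
#'
#' @param cwk A tibble from [sample_cwk()] (columns `c`, `w`, `k`).
#' @param full The full colour: a cardinal letter or an RGB triple.
#' @param cal A [display_calibration()].
#' @param mixing `"linear"` or `"encoded"`.
#' @return An n x 3 matrix of encoded RGB colours.
#' @export
cwk_to_colour <- function(cwk, full, cal = display_calibration(),
                          mixing = c("linear", "encoded")) {
  mixing <- match.arg(mixing)
  f <- as_rgb_matrix(full)
  if (nrow(f) == 1) f <- f[rep(1, nrow(cwk)), , drop = FALSE]
  if (mixing == "linear") {
    lin <- decode_gamma(f, cal) * cwk$c + cwk$w # white is (1,1,1), black 0
    encode_gamma(pmin(pmax(lin, 0), 1), cal)
  } else {
    pmin(pmax(f * cwk$c + cwk$w, 0), 1)
  }
}

#' Triangular hue dither on the colour circle
#'
#' Draws hues from the symmetric triangular density centred on `mean_h` and
#' extending `spread` steps to each side (default one step — the palette of
#' analogous colours), wrapped mod 6.
#'
#' @param n Number of draws.
#' @param mean_h Mean hue (index or cardinal letter).
#' @param spread Half-width in colour-circle steps.
#' @return Numeric vector of hue indices in `[0, 6)`.
#' @export
sample_hue_triangular <- function(n, mean_h, spread = 1) {
  if (spread < 0) abort("`spread` must be non-negative.")
  m <- as_hue_index(mean_h)
  (m + spread * (runif(n) - runif(n))) %% 6
}

#' Specify a bipartite pointillist stimulus
#'
#' Describes one stimulus: two abutting squares of pointillist texture whose
#' dots take colours from one of three gamuts, separated by a hard or soft
#' transition.
#'
#' @param pair For chromatic gamuts, two cardinal letters (left, right); for
#'   the achromatic gamut, two mean intensities in `[0, 1]`.
#' @param gamut `"achromatic"`, `"monochromatic"` or `"polychromatic"`.
#' @param edge `"hard"` or `"soft"`.
#' @param square_size Side of each square, pixels.
#' @param dots_per_square Target dot count per square.
#' @param uncovered_fraction Target fraction of background left visible.
#' @param boundary_width Soft-edge strip width as a fraction of the square
#'   side.
#' @param dither_sd Achromatic dither SD as a fraction of full scale.
#' @param skew CWK skew factor.
#' @param hue_spread Polychromatic hue half-width, colour-circle steps.
#' @param background Background colour (encoded RGB triple).
#' @param mixing CWK mixing domain, see [cwk_to_colour()].
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `stimulus_spec`.
#' @examples
#' spec <- stimulus_spec(c("Y", "B"), gamut = "polychromatic", seed = 7)
#' @export
stimulus_spec <- function(pair,
                          gamut = c("monochromatic", "polychromatic", "achromatic"),
                          edge = c("hard", "soft"),
                          square_size = 128,
                          dots_per_square = 600,
                          uncovered_fraction = 0.25,
                          boundary_width = 0.2,
                          dither_sd = 0.20,
                          skew = 4,
                          hue_spread = 1,
                          background = c(0.8, 0.8, 0.8),
                          mixing = "linear",
                          seed = NULL) {
  gamut <- match.arg(gamut)
  edge <- match.arg(edge)
  if (gamut == "achromatic") {
    pair <- as.numeric(pair)
    if (length(pair) != 2 || any(pair < 0) || any(pair > 1)) {
      abort("Achromatic `pair` must be two mean intensities in [0, 1].")
    }
  } else {
    pair <- toupper(as.character(pair))
    if (length(pair) != 2) abort("`pair` must name two cardinal colours.")
    cardinal_rgb(pair) # validates
  }
  if (uncovered_fraction <= 0 || uncovered_fraction >= 1) {
    abort("`uncovered_fraction` must be in (0, 1).")
  }
  if (boundary_width <= 0 || boundary_width > 1) {
    abort("`boundary_width` must be in (0, 1].")
  }
  if (2 * dots_per_square < 10) abort("Need at least 10 dots.")
  structure(
    list(pair = pair, gamut = gamut, edge = edge,
         square_size = square_size, dots_per_square = dots_per_square,
         uncovered_fraction = uncovered_fraction,
         boundary_width = boundary_width, dither_sd = dither_sd,
         skew = skew, hue_spread = hue_spread,
         background = as.numeric(background), mixing = mixing, seed = seed),
    class = "stimulus_spec"
  )
}

#' Render a pointillist stimulus
#'
#' Runs the full generation pipeline: uniform seed points over the union of
#' the two squares, Voronoi dot layout, radius calibration to the target
#' uncovered fraction, hard or soft side designation, per-dot colour sampling
#' from the spec's gamut, and rasterisation (hard disks painted in layout
#' order over the background). Fully reproducible from the spec's seed.
#'
#' @param spec A [stimulus_spec()].
#' @param cal A [display_calibration()].
#' @return An object of class `macchia_stimulus`: a list with `image` (an
#'   `height x width x 3` array in `[0, 1]`), `dots` (per-dot metadata tibble:
#'   centre, radius, side, colour, sampled hue and CWK coefficients) and
#'   `spec`.
#' @examples
#' stim <- render_stimulus(stimulus_spec(c("Y", "B"), dots_per_square = 60,
#'                                       square_size = 48, seed = 1))
#' dim(stim$image)
#' @export
render_stimulus <- function(spec, cal = display_calibration()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  run <- function() render_stimulus_impl(spec, cal)
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, run()) else run()
}

render_stimulus_impl <- function(spec, cal) {
  size <- spec$square_size
  width <- 2 * size
  height <- size
  n <- 2 * spec$dots_per_square
  pts <- sample_points(n, width, height)
  layout <- voronoi_layout(pts, width, height)
  fac <- calibrate_fill(layout, width, height, spec$uncovered_fraction)
  layout$radius <- layout$radius_unit * fac
  layout <- if (spec$edge == "hard") {
    assign_sides_hard(layout, size)
  } else {
    assign_sides_soft(layout, size, spec$boundary_width * size)
  }
  layout$hue <- NA_real_
  layout$c <- NA_real_
  layout$w <- NA_real_
  layout$k <- NA_real_
  cols <- matrix(NA_real_, n, 3)
  for (s in c("left", "right")) {
    idx <- which(layout$side == s)
    m <- length(idx)
    if (m == 0) next
    mean_side <- spec$pair[if (s == "left") 1 else 2]
    if (spec$gamut == "achromatic") {
      g <- sample_achromatic(m, as.numeric(mean_side), spec$dither_sd)
      cols[idx, ] <- cbind(g, g, g)
    } else if (spec$gamut == "monochromatic") {
      cwk <- sample_cwk(m, spec$skew)
      cols[idx, ] <- cwk_to_colour(cwk, mean_side, cal, spec$mixing)
      layout$c[idx] <- cwk$c; layout$w[idx] <- cwk$w; layout$k[idx] <- cwk$k
    } else {
      hue <- sample_hue_triangular(m, mean_side, spec$hue_spread)
      cwk <- sample_cwk(m, spec$skew)
      cols[idx, ] <- cwk_to_colour(cwk, hue_to_rgb(hue), cal, spec$mixing)
      layout$hue[idx] <- hue
      layout$c[idx] <- cwk$c; layout$w[idx] <- cwk$w; layout$k[idx] <- cwk$k
    }
  }
  layout$r <- cols[, 1]; layout$g <- cols[, 2]; layout$b <- cols[, 3]
  img <- rasterise_dots(layout, width, height, spec$background)
  structure(list(image = img, dots = layout, spec = spec),
            class = "macchia_stimulus")
}

rasterise_dots <- function(layout, width, height, background) {
  img <- array(rep(background, each = height * width), dim = c(height, width, 3))
  for (i in seq_len(nrow(layout))) {
    r <- layout$radius[i]
    if (r <= 0) next
    cx <- layout$x[i]; cy <- layout$y[i]
    x0 <- max(1L, floor(cx - r) + 1L); x1 <- min(width, ceiling(cx + r))
    y0 <- max(1L, floor(cy - r) + 1L); y1 <- min(height, ceiling(cy + r))
    if (x0 > x1 || y0 > y1) next
    xc <- (x0:x1) - 0.5
    yc <- (y0:y1) - 0.5
    inside <- outer(yc - cy, xc - cx, function(a, b) a^2 + b^2) <= r^2
    for (ch in 1:3) {
      plane <- img[y0:y1, x0:x1, ch]
      plane[inside] <- layout[[c("r", "g", "b")[ch]]][i]
      img[y0:y1, x0:x1, ch] <- plane
    }
  }
  img
}

#' @export
print.macchia_stimulus <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<macchia_stimulus> %s, %s edge, %s gamut, %dx%d px, %d dots\n",
              paste(s$pair, collapse = "-"), s$edge, s$gamut,
              2 * s$square_size, s$square_size, nrow(x$dots)))
  invisible(x)
}
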