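#' Tone mappings for monochrome rendering
#'
#' A recipe for turning a colour image into a single grey channel. Four kinds
#' are supported:
#' * `luminance` — the photometric luminance fraction of each pixel;
#' * `max_rule` — the maximum encoded RGB coordinate (all cardinal colours
#'   map to the same tone);
#' * `hue_diameter` — the signed projection of each pixel's hexagon-plane
#'   position onto the diameter through `axis_hue`, rescaled to `[0, 1]`; the
#'   axis colour and its complement land on opposite ends of the scale, and
#'   `dark_accents` flips which end is light. Pixels off the diameter project
#'   orthogonally onto it;
#' * `channel_mixer` — a free weighted sum of the encoded channels, clipped.
#'
#' @param kind One of `"luminance"`, `"max_rule"`, `"hue_diameter"`,
#'   `"channel_mixer"`.
#' @param axis_hue Hue index or cardinal letter (hue_diameter only).
#' @param weights Numeric length 3 (channel_mixer only).
#' @param dark_accents Put the axis colour at the dark end (hue_diameter).
#' @return An object of class `tone_mapping`.
#' @export
tone_mapping <- function(kind = c("luminance", "max_rule", "hue_diameter",
                                  "channel_mixer"),
                         axis_hue = "Y", weights = NULL,
                         dark_accents = FALSE) {
  kind <- match.arg(kind)
  if (kind == "channel_mixer") {
    if (is.null(weights) || length(weights) != 3 || any(!is.finite(weights))) {
      abort("`channel_mixer` needs three finite weights.")
    }
  }
  structure(list(kind = kind, axis_hue = as_hue_index(axis_hue),
                 weights = weights, dark_accents = dark_accents),
            class = "tone_mapping")
}

#' Convert a colour image to greyscale
#'
#' Applies a [tone_mapping()] per pixel. Input is an `h x w x 3` array of
#' encoded RGB in `[0, 1]` (as produced by [render_stimulus()] or
#' [read_image()]); output is an `h x w` matrix in `[0, 1]`.
#'
#' @param image An `h x w x 3` array, or a `macchia_stimulus`.
#' @param mapping A [tone_mapping()].
#' @param cal A [display_calibration()].
#' @return An `h x w` numeric matrix in `[0, 1]`.
#' @examples
#' stim <- render_stimulus(stimulus_spec(c("Y", "B"), square_size = 32,
#'                                       dots_per_square = 30, seed = 1))
#' g <- to_grayscale(stim, tone_mapping("max_rule"))
#' range(g)
#' @export
to_grayscale <- function(image, mapping = tone_mapping(),
                         cal = display_calibration()) {
  if (inherits(image, "macchia_stimulus")) image <- image$image
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be an h x w x 3 array.")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  g <- switch(mapping$kind,
    luminance = luminance_fraction(px, cal),
    max_rule = pmax(px[, 1], px[, 2], px[, 3]),
    hue_diameter = {
      pos <- hexagon_position(px)
      axis <- c(cos(mapping$axis_hue * pi / 3), sin(mapping$axis_hue * pi / 3))
      t <- pos[, 1] * axis[1] + pos[, 2] * axis[2] # in [-1, 1]
      tone <- (t + 1) / 2
      if (mapping$dark_accents) 1 - tone else tone
    },
    channel_mixer = pmin(1, pmax(0, px %*% mapping$weights))
  )
  matrix(g, nrow = h, ncol = w)
}
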