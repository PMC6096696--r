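#' Uniform random dot seeds
#'
#' Seed locations for the pointillist texture, drawn uniformly over the
#' stimulus rectangle (the union of the two squares).
#'
#' @param n Number of points (>= 1; `n = 0` gives an empty tibble).
#' @param width,height Region extent in pixels; the region is
#'   `[0, width) x [0, height)` with a top-left origin.
#' @return A tibble with columns `x`, `y`.
#' @export
sample_points <- function(n, width, height) {
  if (width <= 0 || height <= 0) abort("Region must have positive extent.")
  if (n == 0) return(tibble(x = numeric(), y = numeric()))
  tibble(x = runif(n, 0, width), y = runif(n, 0, height))
}

# Sutherland-Hodgman clip of polygon `poly` (k x 2 matrix) against the
# half-plane {p : nrm . p <= c}.
clip_halfplane <- function(poly, nrm, cval) {
  k <- nrow(poly)
  if (k == 0) return(poly)
  f <- poly %*% nrm - cval
  inside <- f <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (xor(inside[i], inside[j])) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of seed i, clipped to the bounding rectangle: intersect
# half-planes towards neighbours in distance order, stopping once no farther
# neighbour can cut the current polygon (half its distance exceeds the
# farthest cell vertex).
voronoi_cell <- function(i, xs, ys, width, height) {
  px <- xs[i]; py <- ys[i]
  poly <- matrix(c(0, 0, width, 0, width, height, 0, height),
                 ncol = 2, byrow = TRUE)
  d2 <- (xs - px)^2 + (ys - py)^2
  ord <- order(d2)
  ord <- ord[ord != i]
  for (j in ord) {
    maxv2 <- max((poly[, 1] - px)^2 + (poly[, 2] - py)^2)
    if (d2[j] / 4 >= maxv2) break
    nrm <- c(xs[j] - px, ys[j] - py)
    mid <- c((xs[j] + px) / 2, (ys[j] + py) / 2)
    poly <- clip_halfplane(poly, nrm, sum(nrm * mid))
    if (nrow(poly) < 3) break
  }
  poly
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Voronoi dot layout
#'
#' Builds the Voronoi tessellation of the seed points (cells clipped to the
#' region rectangle), places one circular dot per cell at the cell's
#' barycentre, and sets its radius to the shortest barycentre-to-vertex
#' distance times `common_factor`.
#'
#' @param points Tibble with `x`, `y` columns (see [sample_points()]).
#' @param width,height Region extent in pixels.
#' @param common_factor Radius multiplier shared by all dots; calibrate it with
#'   [calibrate_fill()] to hit a target uncovered fraction.
#' @return A tibble with columns `dot`, `x`, `y` (barycentres), `radius_unit`
#'   (shortest vertex distance) and `radius` (`radius_unit * common_factor`).
#' @export
voronoi_layout <- function(points, width, height, common_factor = 1) {
  n <- nrow(points)
  if (n < 4) abort("Need at least 4 points for a dot layout.")
  if (anyDuplicated(points[, c("x", "y")])) {
    abort("Degenerate tessellation: duplicate seed points.")
  }
  xs <- points$x; ys <- points$y
  cent <- matrix(NA_real_, n, 2)
  rmin <- numeric(n)
  for (i in seq_len(n)) {
    poly <- voronoi_cell(i, xs, ys, width, height)
    if (nrow(poly) < 3) {
      abort("Degenerate tessellation: a cell collapsed (collinear or duplicate points?).")
    }
    ctr <- polygon_centroid(poly)
    cent[i, ] <- ctr
    rmin[i] <- sqrt(min((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2))
  }
  tibble(
    dot = seq_len(n),
    x = cent[, 1],
    y = cent[, 2],
    radius_unit = rmin,
    radius = rmin * common_factor
  )
}

#' Rasterised uncovered fraction of a layout
#'
#' Fraction of region pixels not covered by any dot; overlapping dots count
#' once. Pixels are unit squares sampled at their centres.
#'
#' @param layout A tibble from [voronoi_layout()] (uses `x`, `y`, `radius`).
#' @param width,height Region extent in pixels.
#' @return The uncovered fraction in `[0, 1]`.
#' @export
uncovered_fraction <- function(layout, width, height) {
  w <- as.integer(round(width)); h <- as.integer(round(height))
  covered <- matrix(FALSE, nrow = h, ncol = w)
  for (i in seq_len(nrow(layout))) {
    r <- layout$radius[i]
    if (r <= 0) next
    cx <- layout$x[i]; cy <- layout$y[i]
    x0 <- max(1L, floor(cx - r) + 1L); x1 <- min(w, ceiling(cx + r))
    y0 <- max(1L, floor(cy - r) + 1L); y1 <- min(h, ceiling(cy + r))
    if (x0 > x1 || y0 > y1) next
    xc <- (x0:x1) - 0.5
    yc <- (y0:y1) - 0.5
    dx2 <- outer(yc - cy, xc - cx, function(a, b) a^2 + b^2)
    covered[y0:y1, x0:x1] <- covered[y0:y1, x0:x1] | (dx2 <= r^2)
  }
  1 - mean(covered)
}

#' Calibrate the common radius factor for a target fill
#'
#' Bisection on the shared radius multiplier until the rasterised uncovered
#' fraction is within `tol` of the target. Uncovered area is monotone
#' non-increasing in the factor, so bisection is exact up to raster noise.
#'
#' @inheritParams uncovered_fraction
#' @param target_uncovered Desired uncovered fraction, in (0.01, 0.99).
#' @param tol Acceptable deviation from the target (default 0.02).
#' @param max_factor Upper end of the search interval (default 2).
#' @return The calibrated common factor (a scalar).
#' @export
calibrate_fill <- function(layout, width, height, target_uncovered,
                           tol = 0.02, max_factor = 2) {
  if (target_uncovered <= 0.01 || target_uncovered >= 0.99) {
    abort("`target_uncovered` must be in (0.01, 0.99).")
  }
  base <- layout
  unc <- function(f) {
    base$radius <- base$radius_unit * f
    uncovered_fraction(base, width, height)
  }
  lo <- 0; hi <- max_factor
  u_hi <- unc(hi)
  if (u_hi > target_uncovered + tol) {
    abort("Target uncovered fraction unreachable with factor <= max_factor.")
  }
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    u <- unc(mid)
    if (abs(u - target_uncovered) <= tol) return(mid)
    if (u > target_uncovered) lo <- mid else hi <- mid
  }
  abort("Fill calibration did not converge to the requested tolerance.")
}
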