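#' Convert display RGB to CIE L*a*b*
#'
#' Decodes the transfer curve, maps linear RGB to CIE XYZ through the matrix
#' built from the calibrated primary chromaticities (scaled so encoded white
#' maps exactly to the white point), and converts to L*a*b* against that white.
#'
#' @inheritParams decode_gamma
#' @return An n x 3 matrix with columns `L`, `a`, `b`.
#' @examples
#' rgb_to_lab(c(1, 1, 1)) # (100, ~0, ~0)
#' @export
rgb_to_lab <- function(x, cal = display_calibration()) {
  lin <- decode_gamma(x, cal)
  M <- rgb_xyz_matrix(cal)
  xyz <- lin %*% t(M)
  xyz_to_lab(xyz, white_xyz(cal))
}

xyz_to_lab <- function(xyz, white) {
  t0 <- (6 / 29)^3
  f <- function(t) {
    ifelse(t > t0, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  }
  fx <- f(xyz[, 1] / white[1])
  fy <- f(xyz[, 2] / white[2])
  fz <- f(xyz[, 3] / white[3])
  cbind(L = 116 * fy - 16,
        a = 500 * (fx - fy),
        b = 200 * (fy - fz))
}

#' CIEDE2000 colour difference
#'
#' The full CIE DE2000 formula (lightness, chroma and hue terms with the
#' rotation term) between pairs of L*a*b* colours. Symmetric, non-negative and
#' zero exactly on identical inputs, but famously not a metric: it violates the
#' triangle inequality on some routes (see [triangle_inequality_mc()]).
#'
#' @param lab1,lab2 n x 3 matrices (or length-3 vectors) of L*a*b* coordinates.
#' @param kL,kC,kH Parametric weighting factors, all defaulting to 1.
#' @return Numeric vector of colour differences.
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485)) # 2.0425
#' @export
ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  as_lab <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE, nrow = 1)
    x <- as.matrix(x)
    if (ncol(x) != 3) abort("Lab inputs must have 3 columns.")
    storage.mode(x) <- "double"
    x
  }
  m1 <- as_lab(lab1)
  m2 <- as_lab(lab2)
  n <- max(nrow(m1), nrow(m2))
  m1 <- m1[rep_len(seq_len(nrow(m1)), n), , drop = FALSE]
  m2 <- m2[rep_len(seq_len(nrow(m2)), n), , drop = FALSE]

  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hp <- function(a, b) {
    h <- atan2(b, a) * 180 / pi
    h[h < 0] <- h[h < 0] + 360
    h[a == 0 & b == 0] <- 0
    h
  }
  h1p <- hp(a1p, b1)
  h2p <- hp(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p

  dhp <- h2p - h1p
  dhp[dhp > 180] <- dhp[dhp > 180] - 360
  dhp[dhp < -180] <- dhp[dhp < -180] + 360
  dhp[C1p * C2p == 0] <- 0
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2

  hsum <- h1p + h2p
  hbp <- hsum / 2
  big <- abs(h1p - h2p) > 180
  hbp[big & hsum < 360] <- hbp[big & hsum < 360] + 180
  hbp[big & hsum >= 360] <- hbp[big & hsum >= 360] - 180
  hbp[C1p * C2p == 0] <- hsum[C1p * C2p == 0]

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / (kL * SL))^2 +
         (dCp / (kC * SC))^2 +
         (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' @rdname ciede2000
#' @description `delta_e00()` is a convenience wrapper taking display RGB
#'   colours and a calibration instead of Lab coordinates.
#' @inheritParams decode_gamma
#' @param a,b Colours in any form accepted by [decode_gamma()].
#' @export
delta_e00 <- function(a, b, cal = display_calibration(), kL = 1, kC = 1, kH = 1) {
  ciede2000(rgb_to_lab(a, cal), rgb_to_lab(b, cal), kL, kC, kH)
}
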