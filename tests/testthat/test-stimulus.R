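test_that("hard edges classify dots strictly by centre abscissa", {
  lay <- tibble::tibble(x = c(49.999, 50.001, 10, 90), y = rep(5, 4))
  sided <- assign_sides_hard(lay, 50)
  expect_equal(sided$side, c("left", "right", "left", "right"))
  all_left <- assign_sides_hard(lay, 100)
  expect_true(all(all_left$side == "left"))
})

test_that("soft edges ramp the designation probability linearly over the strip", {
  n <- 4000
  at <- function(x) {
    lay <- tibble::tibble(x = rep(x, n), y = 1)
    mean(assign_sides_soft(lay, 50, 20)$side == "right")
  }
  withr::with_seed(13, {
    expect_equal(at(40), 0)            # left border of the strip
    expect_equal(at(60), 1)            # right border
    expect_equal(at(50), 0.5, tolerance = 0.05)
    expect_equal(at(55), 0.75, tolerance = 0.05) # 3/4 across
    expect_equal(at(5), 0)             # far outside: deterministic
  })
  expect_error(assign_sides_soft(tibble::tibble(x = 1), 50, 0), "positive")
})

test_that("achromatic dither has the stated spread and stays on scale", {
  expect_equal(sample_achromatic(5, 0.4, sd = 0), rep(0.4, 5))
  withr::with_seed(14, {
    x <- sample_achromatic(20000, 0.5, sd = 0.20)
    expect_true(all(x >= 0 & x <= 1))
    expect_equal(sd(x), 0.20, tolerance = 0.02)
  })
  expect_error(sample_achromatic(5, 1.2), "\\[0, 1\\]")
})

test_that("cwk coefficients sum to one exactly and the skew favours colour", {
  withr::with_seed(15, {
    q4 <- sample_cwk(5000, skew = 4)
    expect_equal(q4$c + q4$w + q4$k, rep(1, 5000))
    expect_true(all(q4$c >= 0 & q4$w >= 0 & q4$k >= 0))
    expect_gt(mean(q4$c), mean(q4$w))
    expect_equal(mean(q4$w), mean(q4$k), tolerance = 0.01)
    q1 <- sample_cwk(5000, skew = 1)
    expect_equal(mean(q1$c), 1 / 3, tolerance = 0.01)
    expect_equal(mean(q1$w), 1 / 3, tolerance = 0.01)
  })
  expect_error(sample_cwk(5, skew = 0.5), ">= 1")
})

test_that("cwk mixing reproduces the pure poles and stays on the colour plane", {
  poles <- tibble::tibble(c = c(1, 0, 0), w = c(0, 1, 0), k = c(0, 0, 1))
  out <- cwk_to_colour(poles, "R", cal_default)
  expect_equal(out[1, ], c(r = 1, g = 0, b = 0))
  expect_equal(out[2, ], c(r = 1, g = 1, b = 1))
  expect_equal(out[3, ], c(r = 0, g = 0, b = 0))

  # every mixed dot solves Q = c F + w W + k K in linear light with residual ~0
  withr::with_seed(16, {
    q <- sample_cwk(200)
    col <- cwk_to_colour(q, "C", cal_default)
    lin <- decode_gamma(col, cal_default)
    flin <- decode_gamma(cardinal_rgb("C"), cal_default)[1, ]
    # channels where F is 0 recover w; channels where F is 1 recover c + w
    w_hat <- unname(lin[, 1])
    c_hat <- unname(lin[, 2]) - w_hat
    expect_equal(w_hat, q$w, tolerance = 1e-9)
    expect_equal(c_hat, q$c, tolerance = 1e-9)
    expect_equal(unname(lin[, 3]), unname(lin[, 2]), tolerance = 1e-9)
    expect_equal(flin, c(r = 0, g = 1, b = 1))
    invisible(NULL)
  })
})

test_that("triangular hue dither stays within one step and peaks at the mean", {
  withr::with_seed(17, {
    h <- sample_hue_triangular(20000, "Y", spread = 1)
    dist <- pmin(h %% 6, 6 - h %% 6) # circular distance from yellow (0)
    expect_true(all(dist <= 1 + 1e-12))
    # mode at the mean: the central bin dominates the shoulder bins
    central <- mean(dist < 0.2)
    shoulder <- mean(dist > 0.8)
    expect_gt(central, 2 * shoulder)
    expect_equal(sample_hue_triangular(5, 2, spread = 0), rep(2, 5))
  })
})

test_that("rendering is seed-deterministic with in-gamut dots and target fill", {
  spec <- stimulus_spec(c("Y", "B"), gamut = "polychromatic", edge = "hard",
                        square_size = 64, dots_per_square = 70, seed = 42)
  stim1 <- render_stimulus(spec)
  stim2 <- render_stimulus(spec)
  expect_identical(stim1$image, stim2$image)
  expect_identical(stim1$dots, stim2$dots)
  expect_equal(dim(stim1$image), c(64, 128, 3))
  expect_true(all(stim1$image >= 0 & stim1$image <= 1))

  # dots respect the hard midline
  expect_true(all(stim1$dots$side[stim1$dots$x < 64] == "left"))
  expect_true(all(stim1$dots$side[stim1$dots$x >= 64] == "right"))

  # polychromatic hues stay within one step of each side's mean hue
  dl <- stim1$dots[stim1$dots$side == "left", ]
  dr <- stim1$dots[stim1$dots$side == "right", ]
  expect_true(all(colour_circle_distance(dl$hue, 0) <= 1 + 1e-12)) # yellow
  expect_true(all(colour_circle_distance(dr$hue, 3) <= 1 + 1e-12)) # blue

  # realised uncovered fraction within the calibration tolerance
  expect_lt(abs(uncovered_fraction(stim1$dots, 128, 64) - 0.25), 0.02 + 1e-9)
})

test_that("an achromatic spec without dither realises its nominal contrast", {
  spec <- stimulus_spec(c(0.6, 0.2), gamut = "achromatic", edge = "hard",
                        square_size = 48, dots_per_square = 50,
                        dither_sd = 0, seed = 3)
  stim <- render_stimulus(spec)
  means <- tapply(stim$dots$r, stim$dots$side, mean)
  expect_equal(as.numeric(means[c("left", "right")]), c(0.6, 0.2))
  expect_equal(michelson_contrast(means[["left"]], means[["right"]]),
               michelson_contrast(0.6, 0.2))
  # grey dots: all three channels equal
  expect_equal(stim$dots$r, stim$dots$g)
  expect_equal(stim$dots$r, stim$dots$b)
})

test_that("monochromatic dots lie on the colour-white-black plane in linear light", {
  spec <- stimulus_spec(c("G", "M"), gamut = "monochromatic", edge = "soft",
                        square_size = 48, dots_per_square = 50, seed = 8)
  stim <- render_stimulus(spec)
  lin <- decode_gamma(as.matrix(stim$dots[, c("r", "g", "b")]), cal_default)
  for (i in seq_len(nrow(stim$dots))) {
    full <- decode_gamma(cardinal_rgb(
      if (stim$dots$side[i] == "left") "G" else "M"), cal_default)[1, ]
    # solve lin = c * full + w for (c, w) on the two distinct channel levels
    w_hat <- mean(lin[i, full == 0])
    c_hat <- mean(lin[i, full == 1]) - w_hat
    resid <- lin[i, ] - (c_hat * full + w_hat)
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("stimulus specs validate their fields", {
  expect_error(stimulus_spec(c("Y", "Q")), "Unknown cardinal")
  expect_error(stimulus_spec(c(0.5, 1.4), gamut = "achromatic"), "\\[0, 1\\]")
  expect_error(stimulus_spec(c("Y", "B"), uncovered_fraction = 1.2), "\\(0, 1\\)")
  expect_error(stimulus_spec(c("Y", "B"), dots_per_square = 2), "at least 10")
})
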