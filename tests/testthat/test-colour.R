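test_that("gamma decoding is a fixed-point-preserving power law with an exact inverse", {
  expect_equal(decode_gamma(c(0, 0, 0))[1, ], c(r = 0, g = 0, b = 0))
  expect_equal(decode_gamma(c(1, 1, 1))[1, ], c(r = 1, g = 1, b = 1))
  expect_equal(decode_gamma(c(0.5, 0, 0))[1, "r"], c(r = 0.5^2.2))
  expect_error(decode_gamma(c(1.2, 0, 0)), "\\[0, 1\\]")

  withr::with_seed(1, {
    m <- matrix(runif(60), ncol = 3)
    expect_equal(encode_gamma(decode_gamma(m)), as_rgb_matrix_test(m),
                 tolerance = 1e-12)
    srgb <- display_calibration(transfer = "srgb")
    expect_equal(encode_gamma(decode_gamma(m, srgb), srgb),
                 as_rgb_matrix_test(m), tolerance = 1e-12)
  })
})

test_that("luminance is additive over primaries and matches the printed ratios", {
  expect_equal(luminance("Y", cal_default), 69 + 197)
  expect_equal(luminance(c(0, 0, 0), cal_default), 0)
  expect_equal(luminance(c(1, 1, 1), cal_default), 319)

  # additivity in linear light: lum(encode(lin_a + lin_b)) = lum(a) + lum(b)
  withr::with_seed(2, {
    a <- matrix(runif(30, 0, 0.7), ncol = 3)
    b <- matrix(runif(30, 0, 0.3), ncol = 3)
    mix <- encode_gamma(decode_gamma(a) + decode_gamma(b))
    expect_equal(luminance(mix, cal_default),
                 luminance(a, cal_default) + luminance(b, cal_default),
                 tolerance = 1e-9)
  })
})

test_that("luminance fractions reproduce yellow 83% and blue 17% of white", {
  expect_equal(round(100 * luminance_fraction("Y", cal_default)), 83)
  expect_equal(round(100 * luminance_fraction("B", cal_default)), 17)
  expect_equal(luminance_fraction(c(1, 1, 1), cal_default), 1)
  expect_equal(round(luminance("Y", cal_default) / luminance("B", cal_default)), 5)
})

test_that("michelson contrast has the defining identities and domain errors", {
  expect_equal(michelson_contrast(266, 53), 213 / 319)
  expect_lt(michelson_contrast(266, 53), 0.70)
  expect_equal(michelson_contrast(0.4, 0.4), 0)
  expect_equal(michelson_contrast(1, 0), 1)
  expect_error(michelson_contrast(0, 0), "undefined")
  expect_error(michelson_contrast(-1, 2), "non-negative")
})

test_that("rgb cube distance is a metric with the cardinal band values", {
  expect_equal(rgb_cube_distance("Y", "B"), sqrt(3))
  expect_equal(rgb_cube_distance("Y", "G"), 1)
  expect_equal(rgb_cube_distance("C", "C"), 0)

  withr::with_seed(3, {
    for (i in 1:50) {
      abc <- matrix(runif(9), ncol = 3)
      dab <- rgb_cube_distance(abc[1, ], abc[2, ])
      dbc <- rgb_cube_distance(abc[2, ], abc[3, ])
      dac <- rgb_cube_distance(abc[1, ], abc[3, ])
      expect_gte(dab, 0)
      expect_equal(dab, rgb_cube_distance(abc[2, ], abc[1, ]))
      expect_lte(dac, dab + dbc + 1e-12)
    }
  })

  # strictly increasing in colour-circle distance for the cardinal pairs
  cp <- cardinal_pairs()
  d_cube <- rgb_cube_distance(cp$left, cp$right)
  d_circ <- colour_circle_distance(cp$left, cp$right)
  expect_equal(sort(unique(d_cube)), c(1, sqrt(2), sqrt(3)))
  expect_equal(d_cube, c(1, sqrt(2), sqrt(3))[d_circ])
})

test_that("colour circle distance is the cyclic step metric", {
  expect_equal(colour_circle_distance("Y", "B"), 3)
  expect_equal(colour_circle_distance("R", "Y"), 1)
  expect_equal(colour_circle_distance(2.5, 2.5), 0)
  expect_equal(colour_circle_distance(0.5, 5.5), 1)
  expect_equal(colour_circle_distance("G", "M"), colour_circle_distance("M", "G"))
})

test_that("the maximum rule assigns equal unit strength to every cardinal", {
  expect_equal(unname(max_rule(cardinal_colours())), rep(1, 6))
  expect_equal(unname(max_rule(c(0, 0, 0))), 0)
  expect_equal(unname(max_rule(c(0.2, 0.7, 0.1))), 0.7)
})

test_that("hue interpolation walks the cardinal hexagon", {
  expect_equal(hue_to_rgb(0)[1, ], c(r = 1, g = 1, b = 0))
  expect_equal(hue_to_rgb(3)[1, ], c(r = 0, g = 0, b = 1))
  expect_equal(hue_to_rgb(0.5)[1, ], c(r = 0.5, g = 1, b = 0))
  expect_equal(hue_to_rgb("M"), hue_to_rgb(4))
  expect_equal(hue_to_rgb(6.25), hue_to_rgb(0.25))
  # integer indices give exactly the cardinals, and adjacent cardinals differ
  # in a single channel so the edge ramps stay in gamut
  h <- seq(0, 6, by = 0.1)
  m <- hue_to_rgb(h)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(apply(m, 1, max) == 1))
})
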