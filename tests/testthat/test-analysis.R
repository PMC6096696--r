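test_that("normalisation leaves identical observers untouched", {
  obs <- injected_panel(offsets = c(0, 0, 0), gains = c(1, 1, 1))
  sess <- simulate_session(observers = obs, truth = ground_truth("rgb_cube"),
                           seed = 31)
  norm <- normalize_observers(sess)
  f <- observer_fits(norm)
  expect_equal(f$slope, rep(1, 3), tolerance = 1e-9)
  expect_equal(f$intercept, rep(0, 3), tolerance = 1e-9)
  expect_equal(norm$normalized_contrast, norm$contrast, tolerance = 1e-9)
})

test_that("an exact affine observer is inverted exactly", {
  # two reference observers pin the cell medians to the latent; a third is
  # exactly 2 x median + 0.1
  obs <- injected_panel(offsets = c(0, 0, 0.1), gains = c(1, 1, 2))
  # compress the latent band so the doubled observer stays inside [0, 1]
  truth <- ground_truth("linear_nt_nv", scale = 0.5, shift = 0.05)
  sess <- simulate_session(observers = obs, truth = truth, seed = 32)
  norm <- normalize_observers(sess)
  f <- observer_fits(norm)
  expect_equal(f$slope[f$observer_id == "obs03"], 2, tolerance = 1e-9)
  expect_equal(f$intercept[f$observer_id == "obs03"], 0.1, tolerance = 1e-9)
  third <- norm[norm$observer_id == "obs03", ]
  expect_equal(third$normalized_contrast, third$cell_median, tolerance = 1e-9)
})

test_that("normalisation shrinks idiosyncratic spread and is idempotent", {
  withr::with_seed(33, {
    obs <- observer_panel(offset_sd = 0.08, gain_log_sd = 0.25, noise_sd = 0.02)
    sess <- simulate_session(observers = obs, truth = ground_truth("linear_nt_nv"))
    norm <- normalize_observers(sess)
    spread <- function(x, col) {
      g <- dplyr::group_by(x, .data$condition, .data$pair)
      mean(dplyr::summarise(g, s = sd(.data[[col]]), .groups = "drop")$s)
    }
    expect_lt(spread(norm, "normalized_contrast"), spread(norm, "contrast"))
  })

  # idempotence is exact once responses are noise-free affine maps
  obs0 <- injected_panel(offsets = c(-0.05, 0, 0.08), gains = c(0.8, 1, 1.3))
  sess0 <- simulate_session(observers = obs0,
                            truth = ground_truth("linear_nt_nv"), seed = 44)
  n1 <- normalize_observers(sess0)
  n2 <- normalize_observers(dplyr::mutate(n1, contrast = normalized_contrast))
  expect_equal(n2$normalized_contrast, n1$normalized_contrast,
               tolerance = 1e-9)
})

test_that("constant observers are flagged as undefined", {
  obs <- injected_panel(offsets = c(0, 0.2), gains = c(1, 0))
  sess <- simulate_session(observers = obs, truth = ground_truth("rgb_cube"),
                           seed = 34)
  expect_error(normalize_observers(sess), "constant responses")
  expect_error(normalize_observers(dplyr::filter(sess, observer_id == "obs01")),
               "at least 2")
})

test_that("concordance recovers perfect, reversed and null agreement", {
  base <- simulate_session(
    observers = injected_panel(offsets = 0, gains = 1),
    truth = ground_truth("rgb_cube"), seed = 35)
  twin <- dplyr::mutate(base, observer_id = "obs02")
  mirror <- dplyr::mutate(base, observer_id = "obs03",
                          contrast = 1 - contrast)
  d <- dplyr::bind_rows(base, twin, mirror)
  conc <- concordance(d, by_condition = FALSE)
  expect_equal(conc$tau[conc$obs1 == "obs01" & conc$obs2 == "obs02"], 1)
  expect_equal(conc$tau[conc$obs1 == "obs01" & conc$obs2 == "obs03"], -1)

  withr::with_seed(36, {
    rand <- dplyr::bind_rows(
      dplyr::mutate(base, contrast = runif(dplyr::n())),
      dplyr::mutate(twin, contrast = runif(dplyr::n()))
    )
    rconc <- concordance(rand, by_condition = FALSE)
    expect_lt(abs(rconc$tau[1]), 0.25)
    expect_false(isTRUE(rconc$significant[1] && abs(rconc$tau[1]) > 0.5))
    expect_true(is.na(rconc$tau_masked[1]) || rconc$significant[1])
  })

  tiny <- dplyr::filter(d, pair %in% c("YG", "YC"), condition == "he-mg")
  expect_error(concordance(tiny), "Fewer than 3 matched cells")
})

test_that("pair summaries are order statistics with the class ordering", {
  sess <- simulate_session(truth = ground_truth("linear_nt_nv"), seed = 37)
  s <- summarize_pairs(sess, response = "contrast")
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_equal(nrow(s), 4 * 15)

  # constant cell collapses the quartiles
  const <- dplyr::mutate(sess, contrast = 0.4)
  sc <- summarize_pairs(const, response = "contrast")
  expect_true(all(sc$q1 == 0.4 & sc$median == 0.4 & sc$q3 == 0.4))

  # quartiles invariant under within-cell permutation
  perm <- dplyr::slice_sample(sess, prop = 1)
  expect_equal(dplyr::arrange(summarize_pairs(perm, response = "contrast"),
                              condition, pair),
               dplyr::arrange(s, condition, pair))

  # complementary class sits above analogous under the linear truth
  cls <- summarize_classes(sess, response = "contrast")
  expect_gt(cls$median[cls$class == "complementary"],
            cls$median[cls$class == "analogous"])
})

test_that("pair matrices are symmetric, zero-diagonal and banded for the cube model", {
  pm <- pair_matrix(model_predictions("rgb_cube"))
  expect_equal(pm$values, t(pm$values))
  expect_equal(unname(diag(pm$values)), rep(0, 6))
  off <- pm$grey[upper.tri(pm$grey)]
  expect_equal(length(unique(round(off, 9))), 3) # three cyclic bands
  expect_equal(range(off), c(0, 1))
  expect_equal(pm$values["Y", "B"], sqrt(3))

  flat <- pair_matrix(tibble::tibble(pair = cardinal_pairs()$pair,
                                     prediction = 0.5))
  expect_equal(unique(flat$grey[upper.tri(flat$grey)]), 1)

  expect_error(pair_matrix(tibble::tibble(pair = "YG", prediction = 1)),
               "every one of the 15")
})

test_that("model predictions carry the printed landmark values", {
  lum <- model_predictions("luminance_contrast")
  expect_equal(lum$prediction[lum$pair == "YB"], 213 / 319)
  expect_lt(max(lum$prediction), 0.70)

  cube <- model_predictions("rgb_cube")
  expect_equal(cube$prediction[cube$pair %in% c("YB", "GM", "CR")],
               rep(sqrt(3), 3))

  circ <- model_predictions("colour_circle")
  expect_equal(circ$prediction[circ$pair == "YG"], 1)

  de <- model_predictions("ciede2000")
  expect_true(all(de$prediction > 0))

  # an equiluminant pair is predicted exactly invisible by luminance contrast
  eq_cal <- display_calibration(primary_luminances = c(100, 100, 53))
  lum_eq <- model_predictions("luminance_contrast", cal = eq_cal)
  expect_equal(lum_eq$prediction[lum_eq$pair == "CM"], 0) # C = G+B, M = R+B
})

test_that("model comparison has the rank/linear invariances", {
  obs <- model_predictions("rgb_cube")
  d <- tibble::tibble(observer_id = "obs01", condition = "he-mg",
                      pair = obs$pair, contrast = obs$prediction / 2)
  cmp <- compare_models(d, response = "contrast", models = "rgb_cube")
  expect_equal(cmp$kendall_tau, rep(1, 2)) # pooled + condition
  expect_equal(cmp$pearson_r, rep(1, 2))

  anti <- dplyr::mutate(d, contrast = 1 - contrast)
  cmpa <- compare_models(anti, response = "contrast", models = "rgb_cube")
  expect_equal(cmpa$kendall_tau, rep(-1, 2))

  # tau is invariant under strictly monotone prediction transforms, r is not
  withr::with_seed(38, {
    sess <- simulate_session(truth = ground_truth("rgb_cube"))
    med <- dplyr::summarise(dplyr::group_by(sess, pair),
                            observed = median(contrast), .groups = "drop")
    pred <- model_predictions("ciede2000")$prediction
    tau1 <- cor(med$observed, pred, method = "kendall")
    tau2 <- cor(med$observed, exp(2 * pred / max(pred)), method = "kendall")
    expect_equal(tau1, tau2)
    r1 <- cor(med$observed, pred)
    r2 <- cor(med$observed, exp(2 * pred / max(pred)))
    expect_false(isTRUE(all.equal(r1, r2)))
  })

  # zero-variance predictions: Pearson flagged NA, tau still computed
  flat_pred <- tibble::tibble(pair = obs$pair, model = "flat", prediction = 1)
  expect_warning(
    cz <- compare_models(d, response = "contrast", predictions = flat_pred),
    "zero-variance"
  )
  expect_true(all(is.na(cz$pearson_r)))
})

test_that("triangle-inequality violations are rare, reproducible and rule-consistent", {
  r1 <- withr::with_seed(39, triangle_inequality_mc(20000))
  r2 <- withr::with_seed(40, triangle_inequality_mc(20000))
  expect_true(r1$fraction >= 0 && r1$fraction <= 1)
  pooled_se <- sqrt(r1$se^2 + r2$se^2)
  expect_lt(abs(r1$fraction - r2$fraction), 3 * pooled_se)

  # the any-of-three rule counts about three times as many triples
  r_any <- withr::with_seed(39, triangle_inequality_mc(20000, rule = "any"))
  expect_gt(r_any$fraction, 2 * r1$fraction)
  expect_lt(r_any$fraction, 4 * r1$fraction)
  expect_error(triangle_inequality_mc(10), "at least 1000")
})

test_that("hexagon weights normalise to unit mean with the cube ordering", {
  hex <- hexagon_summary("Y", model_predictions("rgb_cube"))
  expect_equal(mean(hex$weight), 1)
  w <- setNames(hex$weight, hex$other)
  expect_gt(w[["B"]], w[["C"]])
  expect_gt(w[["C"]], w[["G"]])
  expect_equal(w[["G"]], w[["R"]]) # both one step from yellow

  flat <- hexagon_summary("Y", tibble::tibble(pair = cardinal_pairs()$pair,
                                              prediction = 2))
  expect_equal(flat$weight, rep(1, 5))
})
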