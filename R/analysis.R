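#' Normalise responses for observer offset and gain
#'
#' For each observer, fits a least-squares line of that observer's responses
#' against the cross-observer median for the same (condition, pair) cell, then
#' inverts it: `normalized = (response - intercept) / slope`. A single pass is
#' made — the reference medians are computed once from the input and not
#' recomputed. Observers whose responses are constant have no defined slope
#' and raise an error.
#'
#' @param data Response tibble with columns `observer_id`, `condition`, `pair`
#'   and the response.
#' @param response Response column name (string); defaults to `"contrast"`.
#' @return The input augmented with `cell_median` and `normalized_contrast`;
#'   the per-observer lines are attached as attribute `"observer_fits"` and
#'   retrievable with [observer_fits()].
#' @examples
#' norm <- normalize_observers(simulate_session(seed = 2))
#' observer_fits(norm)
#' @export
normalize_observers <- function(data, response = "contrast") {
  needed <- c("observer_id", "condition", "pair", response)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (dplyr::n_distinct(data$observer_id) < 2) {
    abort("Need at least 2 observers to normalise.")
  }
  # allow re-normalising an already-augmented table
  drop <- setdiff(c("cell_median", "normalized_contrast"), response)
  data <- data[setdiff(names(data), drop)]
  # per (observer, cell) median, then cross-observer median per cell
  per_obs <- dplyr::summarise(
    dplyr::group_by(data, .data$observer_id, .data$condition, .data$pair),
    .obs_med = median(.data[[response]]), .groups = "drop"
  )
  ref <- dplyr::summarise(
    dplyr::group_by(per_obs, .data$condition, .data$pair),
    cell_median = median(.data$.obs_med), .groups = "drop"
  )
  out <- dplyr::left_join(data, ref, by = c("condition", "pair"))
  fits <- purrr::map_dfr(split(out, out$observer_id), function(d) {
    y <- d[[response]]
    m <- d$cell_median
    if (stats::sd(y) == 0) {
      abort(paste0("Observer ", d$observer_id[1],
                   " has constant responses; slope undefined."))
    }
    slope <- stats::cov(y, m) / stats::var(m)
    tibble(observer_id = d$observer_id[1],
           slope = slope,
           intercept = mean(y) - slope * mean(m))
  })
  if (any(!is.finite(fits$slope)) || any(abs(fits$slope) < 1e-12)) {
    abort("An observer's slope against the cell medians is degenerate.")
  }
  out <- dplyr::left_join(out, fits, by = "observer_id")
  out$normalized_contrast <- (out[[response]] - out$intercept) / out$slope
  out$slope <- NULL
  out$intercept <- NULL
  attr(out, "observer_fits") <- fits
  out
}

#' @rdname normalize_observers
#' @param x A table returned by `normalize_observers()`.
#' @export
observer_fits <- function(x) {
  f <- attr(x, "observer_fits")
  if (is.null(f)) abort("`x` carries no observer fits; run normalize_observers().")
  f
}

#' Inter-observer concordance (Kendall's tau)
#'
#' Tie-corrected Kendall tau-b between every pair of observers on their
#' matched (condition, pair) cell medians, pooled and per condition.
#' Significance uses `stats::cor.test` (normal approximation under ties),
#' two-sided at the 5% level; `tau_masked` is `NA` where not significant.
#'
#' @inheritParams normalize_observers
#' @param by_condition Also break the table down by condition.
#' @return A tibble with `condition` (`"pooled"` first), `obs1`, `obs2`,
#'   `tau`, `p_value`, `significant`, `tau_masked`, `n_cells`.
#' @examples
#' conc <- concordance(simulate_session(seed = 3))
#' median(conc$tau[conc$condition == "pooled"])
#' @export
concordance <- function(data, response = "contrast", by_condition = TRUE) {
  obs <- sort(unique(data$observer_id))
  if (length(obs) < 2) abort("Need at least 2 observers.")
  cells <- dplyr::summarise(
    dplyr::group_by(data, .data$observer_id, .data$condition, .data$pair),
    value = median(.data[[response]]), .groups = "drop"
  )
  one_block <- function(d, label) {
    wide <- tidyr::pivot_wider(d, id_cols = c("condition", "pair"),
                               names_from = "observer_id",
                               values_from = "value")
    purrr::map_dfr(utils::combn(obs, 2, simplify = FALSE), function(p) {
      x <- wide[[p[1]]]
      y <- wide[[p[2]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) abort("Fewer than 3 matched cells for an observer pair.")
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "kendall",
                                      exact = FALSE))
      tibble(condition = label, obs1 = p[1], obs2 = p[2],
             tau = unname(ct$estimate), p_value = ct$p.value,
             n_cells = sum(ok))
    })
  }
  res <- one_block(cells, "pooled")
  if (by_condition) {
    for (cond in sort(unique(cells$condition))) {
      res <- dplyr::bind_rows(
        res, one_block(dplyr::filter(cells, .data$condition == cond), cond))
    }
  }
  dplyr::mutate(res,
                significant = .data$p_value < 0.05,
                tau_masked = ifelse(.data$significant, .data$tau, NA_real_))
}

#' Quartile summaries per condition and pair
#'
#' (Q1, median, Q3) of the responses for every (condition, pair) cell, joined
#' with the pair's transition class. `summarize_classes()` aggregates across
#' pairs of the same class.
#'
#' @inheritParams normalize_observers
#' @return A tibble with `condition`, `pair`, `class`, `q1`, `median`, `q3`,
#'   `n`.
#' @examples
#' summarize_pairs(simulate_session(seed = 4), response = "contrast")
#' @export
summarize_pairs <- function(data, response = NULL) {
  response <- response %||%
    (if ("normalized_contrast" %in% names(data)) "normalized_contrast" else "contrast")
  cls <- dplyr::select(transition_structure(), "pair", "class")
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$condition, .data$pair),
    q1 = unname(quantile(.data[[response]], 0.25)),
    median = median(.data[[response]]),
    q3 = unname(quantile(.data[[response]], 0.75)),
    n = dplyr::n(), .groups = "drop"
  )
  dplyr::relocate(dplyr::left_join(out, cls, by = "pair"),
                  "class", .after = "pair")
}

#' @rdname summarize_pairs
#' @export
summarize_classes <- function(data, response = NULL) {
  response <- response %||%
    (if ("normalized_contrast" %in% names(data)) "normalized_contrast" else "contrast")
  cls <- dplyr::select(transition_structure(), "pair", "class")
  d <- dplyr::left_join(data, cls, by = "pair")
  dplyr::summarise(
    dplyr::group_by(d, .data$class),
    q1 = unname(quantile(.data[[response]], 0.25)),
    median = median(.data[[response]]),
    q3 = unname(quantile(.data[[response]], 0.75)),
    n = dplyr::n(), .groups = "drop"
  )
}

#' Pair values as a 6 x 6 cardinal array
#'
#' Arranges one value per unordered cardinal pair into the symmetric 6 x 6
#' array indexed by hue (Y G C B M R), zero on the diagonal, together with a
#' grey version in which the off-diagonal range is affinely mapped onto the
#' full grey scale (min -> 0, max -> 1). The array is doubly periodic: its
#' secondary diagonals collect pairs of equal colour-circle distance.
#'
#' @param values A tibble with columns `pair` and a value column, covering all
#'   15 pairs (e.g. a [summarize_pairs()] condition slice or
#'   [model_predictions()]).
#' @param value Value column name (string); defaults to `"median"` if present,
#'   else `"prediction"`.
#' @return An object of class `pair_matrix`: list with `values`, `grey` (6 x 6
#'   matrices) and `scaling` (off-diagonal min/max).
#' @examples
#' pm <- pair_matrix(model_predictions("rgb_cube"))
#' pm$values["Y", "B"]
#' @export
pair_matrix <- function(values, value = NULL) {
  value <- value %||%
    (if ("median" %in% names(values)) "median" else "prediction")
  cp <- cardinal_pairs()
  v <- values[[value]][match(cp$pair, values$pair)]
  if (anyNA(v)) abort("`values` must contain every one of the 15 cardinal pairs.")
  nm <- cardinal_colours()$name
  m <- matrix(0, 6, 6, dimnames = list(nm, nm))
  for (i in seq_len(15)) {
    m[cp$left[i], cp$right[i]] <- v[i]
    m[cp$right[i], cp$left[i]] <- v[i]
  }
  off <- m[upper.tri(m)]
  rng <- range(off)
  grey <- m
  if (diff(rng) > 0) {
    grey[] <- (m - rng[1]) / diff(rng)
  } else {
    grey[] <- 1
  }
  diag(grey) <- 0
  structure(list(values = m, grey = grey, scaling = rng),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, digits = 3, ...) {
  cat("<pair_matrix> values (diagonal zero):\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Model predictions per cardinal pair
#'
#' The three confronted models plus the colour-circle rule, evaluated on the
#' nominal full-intensity cardinal colours of each pair:
#' `luminance_contrast` is the Michelson contrast of the two luminances,
#' `ciede2000` the colour difference of the pair via [rgb_to_lab()],
#' `rgb_cube` the Euclidean distance of the raw encoded coordinates, and
#' `colour_circle` the cyclic step distance.
#'
#' @param model One of `"luminance_contrast"`, `"ciede2000"`, `"rgb_cube"`,
#'   `"colour_circle"`.
#' @param pairs Pair table as from [cardinal_pairs()].
#' @param cal A [display_calibration()].
#' @return A tibble with `pair`, `model`, `prediction`.
#' @examples
#' model_predictions("luminance_contrast")
#' @export
model_predictions <- function(model = c("rgb_cube", "luminance_contrast",
                                        "ciede2000", "colour_circle"),
                              pairs = cardinal_pairs(),
                              cal = display_calibration()) {
  model <- match.arg(model)
  l <- pairs$left
  r <- pairs$right
  pred <- switch(model,
    luminance_contrast = michelson_contrast(luminance(l, cal), luminance(r, cal)),
    ciede2000 = delta_e00(l, r, cal),
    rgb_cube = rgb_cube_distance(l, r),
    colour_circle = colour_circle_distance(l, r)
  )
  tibble(pair = pairs$pair, model = model, prediction = pred)
}

#' Compare model predictions with observed settings
#'
#' Kendall tau-b and Pearson r between the observed cell medians and each
#' model's predictions, per condition and pooled (pooled = medians over all
#' conditions). Zero-variance predictions leave Pearson r as `NA` with a
#' warning; tau-b is still computed.
#'
#' @inheritParams normalize_observers
#' @param models Character vector of model names (see [model_predictions()]).
#' @param cal A [display_calibration()].
#' @param predictions Optional tibble of precomputed predictions (columns
#'   `pair`, `model`, `prediction`) used instead of `models`.
#' @return A tibble with `model`, `condition`, `kendall_tau`, `pearson_r`,
#'   `n_pairs`.
#' @examples
#' compare_models(simulate_session(seed = 5))
#' @export
compare_models <- function(data, response = NULL,
                           models = c("luminance_contrast", "ciede2000",
                                      "rgb_cube"),
                           cal = display_calibration(),
                           predictions = NULL) {
  response <- response %||%
    (if ("normalized_contrast" %in% names(data)) "normalized_contrast" else "contrast")
  med <- dplyr::summarise(
    dplyr::group_by(data, .data$condition, .data$pair),
    observed = median(.data[[response]]), .groups = "drop"
  )
  pooled <- dplyr::summarise(
    dplyr::group_by(data, .data$pair),
    observed = median(.data[[response]]), .groups = "drop"
  )
  pooled$condition <- "pooled"
  med <- dplyr::bind_rows(pooled[, c("condition", "pair", "observed")], med)
  pred_tbl <- predictions %||%
    purrr::map_dfr(models, model_predictions, cal = cal)
  purrr::map_dfr(unique(pred_tbl$model), function(mn) {
    pr <- dplyr::filter(pred_tbl, .data$model == mn)
    d <- dplyr::left_join(med, pr[, c("pair", "prediction")], by = "pair")
    dplyr::summarise(
      dplyr::group_by(d, .data$condition),
      model = mn,
      kendall_tau = suppressWarnings(
        cor(.data$observed, .data$prediction, method = "kendall")),
      pearson_r = {
        if (stats::sd(.data$prediction) == 0) {
          warn(paste0("Model ", mn, " has zero-variance predictions; Pearson r undefined."))
          NA_real_
        } else {
          cor(.data$observed, .data$prediction)
        }
      },
      n_pairs = dplyr::n(), .groups = "drop"
    )
  })
}

#' Monte-Carlo probe of CIEDE2000 triangle-inequality violations
#'
#' Samples ordered triples of colours uniformly in the encoded RGB cube,
#' converts them to L*a*b* under the calibration, and checks the triangle
#' inequality on the three pairwise CIEDE2000 distances. With the default
#' `rule = "ordered"`, a triple (P, Q, R) counts as a violation when the
#' direct route P-R exceeds the detour P-Q-R through the middle colour — the
#' sense in which the green-cyan-magenta detour beats the direct
#' green-magenta route. `rule = "any"` counts a triple when any one distance
#' exceeds the sum of the other two (by symmetry about three times as
#' frequent).
#'
#' @param n Number of triples (>= 1000).
#' @param cal A [display_calibration()].
#' @param rule `"ordered"` or `"any"`, see above.
#' @param batch Triples per vectorised batch (memory control).
#' @return A one-row tibble with `n`, `violations`, `fraction` and the
#'   binomial `se`.
#' @examples
#' withr::with_seed(1, triangle_inequality_mc(2000))
#' @export
triangle_inequality_mc <- function(n = 100000, cal = display_calibration(),
                                   rule = c("ordered", "any"),
                                   batch = 20000) {
  rule <- match.arg(rule)
  if (n < 1000) abort("Use at least 1000 triples.")
  total <- 0
  done <- 0
  while (done < n) {
    m <- min(batch, n - done)
    p <- rgb_to_lab(matrix(runif(3 * m), ncol = 3), cal)
    q <- rgb_to_lab(matrix(runif(3 * m), ncol = 3), cal)
    r <- rgb_to_lab(matrix(runif(3 * m), ncol = 3), cal)
    dpq <- ciede2000(p, q)
    dqr <- ciede2000(q, r)
    dpr <- ciede2000(p, r)
    viol <- if (rule == "ordered") {
      dpr > dpq + dqr
    } else {
      (dpr > dpq + dqr) | (dpq > dpr + dqr) | (dqr > dpq + dpr)
    }
    total <- total + sum(viol)
    done <- done + m
  }
  frac <- total / n
  tibble(n = n, violations = total, fraction = frac,
         se = sqrt(frac * (1 - frac) / n))
}

#' Hexagon panel weights for one fiducial colour
#'
#' Connection weights from a fiducial cardinal colour to the five others,
#' proportional to the supplied values and normalised so the mean weight is 1
#' (constant average thickness across panels).
#'
#' @param fiducial A cardinal letter.
#' @param values A tibble with `pair` and a value column covering the
#'   fiducial's five pairs (e.g. [model_predictions()]).
#' @param value Value column name; defaults as in [pair_matrix()].
#' @return A tibble with `fiducial`, `other`, `value`, `weight`
#'   (`mean(weight) == 1`).
#' @examples
#' hexagon_summary("Y", model_predictions("rgb_cube"))
#' @export
hexagon_summary <- function(fiducial, values, value = NULL) {
  value <- value %||%
    (if ("median" %in% names(values)) "median" else "prediction")
  fiducial <- toupper(fiducial)
  cp <- cardinal_pairs()
  sel <- cp$left == fiducial | cp$right == fiducial
  cp <- cp[sel, ]
  v <- values[[value]][match(cp$pair, values$pair)]
  if (anyNA(v)) abort("`values` must cover all five pairs of the fiducial.")
  other <- ifelse(cp$left == fiducial, cp$right, cp$left)
  tibble(fiducial = fiducial, other = other, value = v,
         weight = if (mean(v) > 0) v / mean(v) else rep(1, length(v)))
}
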