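#' Synthetic observer panel
#'
#' Draws a panel of observers with idiosyncratic response characteristics: an
#' additive offset, a multiplicative gain (log-normal around 1), Gaussian
#' response noise and an optional response-step quantisation. These are the
#' idiosyncrasies the normalisation stage of the analysis is designed to
#' remove.
#'
#' @param n_observers Number of observers (default 5).
#' @param offset_sd SD of the normal offsets, contrast units.
#' @param gain_log_sd SD of log gain.
#' @param noise_sd Response noise SD, contrast units.
#' @param step Response quantisation step in contrast units (0 = off; the
#'   live staircase moved in 0.10 steps, but pooled settings are finer).
#' @param centre Centre the panel so the consensus (median) observer is the
#'   identity map. Only idiosyncrasies *relative to the panel consensus* are
#'   identifiable — the consensus defines the response scale — so centring
#'   anchors that scale to the latent one.
#' @param pivot Contrast level about which gain idiosyncrasies pivot
#'   (default 0.42, the middle of the typical response band): an observer's
#'   scaling expands or compresses responses around the operating range, not
#'   around zero contrast.
#' @return A tibble with columns `observer_id`, `offset`, `gain`, `noise_sd`,
#'   `step`; the response map is `offset + gain * latent`.
#' @examples
#' withr::with_seed(1, observer_panel())
#' @export
observer_panel <- function(n_observers = 5, offset_sd = 0.05,
                           gain_log_sd = 0.15, noise_sd = 0.05, step = 0,
                           centre = TRUE, pivot = 0.42) {
  if (n_observers < 1) abort("Need at least one observer.")
  offset <- rnorm(n_observers, 0, offset_sd)
  gain <- rlnorm(n_observers, 0, gain_log_sd)
  if (centre && n_observers > 1) {
    gain <- gain / median(gain)
    offset <- offset - median(offset)
  }
  # express gain as a pivot about the operating level: offset absorbs
  # -(gain - 1) * pivot so that gain stretches the response band in place
  offset <- offset - (gain - 1) * pivot
  tibble(
    observer_id = sprintf("obs%02d", seq_len(n_observers)),
    offset = offset,
    gain = gain,
    noise_sd = noise_sd,
    step = step
  )
}

#' Latent ground-truth distinctiveness
#'
#' The latent distinctiveness a synthetic observer responds to, computed from
#' one of four generating models on the nominal cardinal colours of each pair
#' and affinely mapped to Michelson contrast.
#'
#' `ground_truth()` bundles the model choice with the affine map. When `scale`
#' / `shift` are `NULL` they are auto-calibrated so the 15 cardinal-pair
#' latents span `[0.30, 0.55]` — the global band of pooled settings — except
#' for `linear_nt_nv`, which is already in contrast units and uses the
#' identity map.
#'
#' @param model One of `"rgb_cube"`, `"luminance_contrast"`, `"ciede2000"`,
#'   `"linear_nt_nv"`.
#' @param scale,shift Affine map from model value to contrast; `NULL` for the
#'   defaults above.
#' @param fit Coefficients used by `linear_nt_nv` (a [distinctiveness_fit()]).
#' @return `ground_truth()` returns a `ground_truth` object;
#'   `latent_distinctiveness()` a tibble with `pair` and `latent` (clipped to
#'   `[0, 1]`).
#' @examples
#' latent_distinctiveness(ground_truth("rgb_cube"))
#' @export
ground_truth <- function(model = c("rgb_cube", "luminance_contrast",
                                   "ciede2000", "linear_nt_nv"),
                         scale = NULL, shift = NULL,
                         fit = distinctiveness_fit()) {
  model <- match.arg(model)
  structure(list(model = model, scale = scale, shift = shift, fit = fit),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param truth A `ground_truth` object.
#' @param pairs Pair table as from [cardinal_pairs()].
#' @param cal A [display_calibration()].
#' @export
latent_distinctiveness <- function(truth = ground_truth(),
                                   pairs = cardinal_pairs(),
                                   cal = display_calibration()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$model == "linear_nt_nv") {
    ts <- transition_structure(pairs)
    raw <- predict_distinctiveness(truth$fit, ts)
    scale <- truth$scale %||% 1
    shift <- truth$shift %||% 0
  } else {
    raw <- model_predictions(truth$model, pairs = pairs, cal = cal)$prediction
    if (is.null(truth$scale) || is.null(truth$shift)) {
      rng <- range(raw)
      scale <- if (diff(rng) > 0) (0.55 - 0.30) / diff(rng) else 0
      shift <- 0.30 - scale * rng[1]
    } else {
      scale <- truth$scale
      shift <- truth$shift
    }
  }
  tibble(pair = pairs$pair,
         latent = pmin(1, pmax(0, scale * raw + shift)))
}

#' Simulate a matching session
#'
#' Generates the response table of a full session: every observer visits every
#' condition (hard/soft edge crossed with monochromatic/polychromatic gamut)
#' and every cardinal pair, `replicates` times — with the defaults, 4
#' conditions x 15 pairs x 4 replicates = 240 responses per observer. Each
#' response is `clip(offset + gain * latent + noise)`, optionally quantised to
#' the observer's response step; response times are log-normal with a median
#' in the 7-12 s band and are never analysed.
#'
#' @param observers An [observer_panel()] tibble.
#' @param truth A [ground_truth()].
#' @param replicates Visits per (observer, condition, pair) cell.
#' @param conditions Tibble of conditions with `edge` and `gamut` columns;
#'   defaults to the 2 x 2 design.
#' @param cal A [display_calibration()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `observer_id`, `condition`, `edge`, `gamut`,
#'   `pair`, `replicate`, `contrast`, `rt_s`.
#' @examples
#' sess <- simulate_session(seed = 11)
#' dplyr::count(sess, observer_id)
#' @export
simulate_session <- function(observers = NULL,
                             truth = ground_truth(),
                             replicates = 4,
                             conditions = default_conditions(),
                             cal = display_calibration(),
                             seed = NULL) {
  run <- function() {
    obs <- observers %||% observer_panel()
    lat <- latent_distinctiveness(truth, cal = cal)
    grid <- tidyr::expand_grid(
      observer_id = obs$observer_id,
      condition = paste0(substr(conditions$edge, 1, 1), "e-",
                         substr(conditions$gamut, 1, 1), "g")[
                           seq_len(nrow(conditions))],
      pair = lat$pair,
      replicate = seq_len(replicates)
    )
    cond_key <- setNames(seq_len(nrow(conditions)),
                         paste0(substr(conditions$edge, 1, 1), "e-",
                                substr(conditions$gamut, 1, 1), "g"))
    grid <- dplyr::mutate(
      grid,
      edge = conditions$edge[cond_key[.data$condition]],
      gamut = conditions$gamut[cond_key[.data$condition]]
    )
    grid <- dplyr::left_join(grid, lat, by = "pair")
    grid <- dplyr::left_join(grid, obs, by = "observer_id")
    resp <- grid$offset + grid$gain * grid$latent +
      rnorm(nrow(grid), 0, grid$noise_sd)
    q <- grid$step > 0
    resp[q] <- round(resp[q] / grid$step[q]) * grid$step[q]
    grid$contrast <- pmin(1, pmax(0, resp))
    grid$rt_s <- rlnorm(nrow(grid), log(9), 0.35)
    dplyr::select(grid, "observer_id", "condition", "edge", "gamut",
                  "pair", "replicate", "contrast", "rt_s")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' @rdname simulate_session
#' @export
default_conditions <- function() {
  tidyr::expand_grid(edge = c("hard", "soft"),
                     gamut = c("monochromatic", "polychromatic"))
}
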