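#' The linear transition/veil distinctiveness model
#'
#' Distinctiveness of a bipartition is modelled as
#' `D = a0 + a_t * N_t + a_v * N_v`, where `N_t` counts RGB channel transitions
#' and `N_v` counts veils. The default coefficients (0.406, 0.025, -0.083) are
#' the fitted values for the pooled normalised settings.
#'
#' @param a0 Intercept, contrast units.
#' @param a_t Contrast per channel transition.
#' @param a_v Contrast per veil.
#' @return An object of class `distinctiveness_fit`.
#' @examples
#' predict_distinctiveness(distinctiveness_fit(), transition_structure())
#' @export
distinctiveness_fit <- function(a0 = 0.406, a_t = 0.025, a_v = -0.083) {
  structure(
    list(
      coefficients = c(a0 = a0, a_t = a_t, a_v = a_v),
      median_abs_error = NA_real_,
      max_abs_error = NA_real_,
      n = NA_integer_,
      model = NULL
    ),
    class = "distinctiveness_fit"
  )
}

#' @export
print.distinctiveness_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<distinctiveness_fit>  D = %.3f %+.3f N_t %+.3f N_v\n",
              co["a0"], co["a_t"], co["a_v"]))
  if (!is.na(x$median_abs_error)) {
    cat(sprintf("  median |resid| %.4f, max |resid| %.4f (n = %d)\n",
                x$median_abs_error, x$max_abs_error, x$n))
  }
  invisible(x)
}

#' Fit the distinctiveness model to a response table
#'
#' Ordinary least squares of observed distinctiveness on (1, `N_t`, `N_v`).
#' Each row of `data` is one response; the transition structure is joined on
#' the `pair` column. With `extended = TRUE` the design matrix instead carries
#' an indicator per channel-transition type (RK, GK, BK) and per veil colour —
#' the "dozen free parameters" refinement, off by default.
#'
#' @param data A tibble with columns `pair` and the response.
#' @param response Name of the response column (string). Defaults to
#'   `"normalized_contrast"` if present, else `"contrast"`.
#' @param extended Use the per-channel/per-veil design matrix.
#' @return A `distinctiveness_fit` with coefficients, residual diagnostics
#'   (median and maximum absolute residual) and the underlying `lm`.
#' @examples
#' d <- dplyr::mutate(transition_structure(),
#'                    contrast = 0.406 + 0.025 * n_transitions - 0.083 * n_veils)
#' fit_distinctiveness(d)
#' @export
fit_distinctiveness <- function(data, response = NULL, extended = FALSE) {
  response <- response %||%
    (if ("normalized_contrast" %in% names(data)) "normalized_contrast" else "contrast")
  if (!response %in% names(data)) {
    abort(paste0("Response column `", response, "` not found."))
  }
  ts <- transition_structure()
  d <- dplyr::left_join(
    dplyr::select(data, "pair", y = dplyr::all_of(response)),
    dplyr::select(ts, "pair", "n_transitions", "n_veils", "channels"),
    by = "pair"
  )
  if (anyNA(d$n_transitions)) {
    abort("Some rows have a `pair` that is not a cardinal pair.")
  }
  if (extended) {
    X <- extended_design(d)
    fit <- lm(d$y ~ X)
  } else {
    if (nrow(unique(d[, c("n_transitions", "n_veils")])) < 3) {
      abort("Need at least 3 distinct (N_t, N_v) combinations to fit.")
    }
    fit <- lm(y ~ n_transitions + n_veils, data = d)
    if (anyNA(coef(fit))) abort("Rank-deficient design; cannot fit.")
  }
  res <- stats::residuals(fit)
  out <- distinctiveness_fit()
  out$coefficients <- if (extended) {
    coef(fit)
  } else {
    setNames(coef(fit), c("a0", "a_t", "a_v"))
  }
  out$median_abs_error <- median(abs(res))
  out$max_abs_error <- max(abs(res))
  out$n <- nrow(d)
  out$model <- fit
  out$extended <- extended
  out
}

# indicators per transition type (RK/GK/BK) and per veil colour (R/G/B veil)
extended_design <- function(d) {
  feats <- purrr::map(d$channels, function(ch) {
    tr <- ch$kind == "transition"
    vl <- ch$kind == "veil"
    c(t_R = as.numeric(tr[1]), t_G = as.numeric(tr[2]), t_B = as.numeric(tr[3]),
      v_R = as.numeric(vl[1]), v_G = as.numeric(vl[2]), v_B = as.numeric(vl[3]))
  })
  do.call(rbind, feats)
}

#' Predict distinctiveness for transition structures
#'
#' @param fit A `distinctiveness_fit`.
#' @param structure A tibble with `n_transitions` and `n_veils` columns (e.g.
#'   from [transition_structure()]), or values passed via `n_transitions` /
#'   `n_veils` directly.
#' @param n_transitions,n_veils Alternative numeric inputs.
#' @return Numeric vector of predicted distinctiveness in contrast units.
#' @examples
#' predict_distinctiveness(distinctiveness_fit(), n_transitions = 3, n_veils = 0)
#' @export
predict_distinctiveness <- function(fit = distinctiveness_fit(),
                                    structure = NULL,
                                    n_transitions = NULL, n_veils = NULL) {
  stopifnot(inherits(fit, "distinctiveness_fit"))
  if (!is.null(structure)) {
    n_transitions <- structure$n_transitions
    n_veils <- structure$n_veils
  }
  if (is.null(n_transitions) || is.null(n_veils)) {
    abort("Provide `structure` or both `n_transitions` and `n_veils`.")
  }
  co <- fit$coefficients
  as.numeric(co["a0"] + co["a_t"] * n_transitions + co["a_v"] * n_veils)
}

#' Tidy a distinctiveness fit
#'
#' @param x A `distinctiveness_fit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per coefficient (`term`, `estimate`, and
#'   `std.error` when the fit carries data); `glance()` gives one row of fit
#'   diagnostics.
#' @method tidy distinctiveness_fit
#' @export
tidy.distinctiveness_fit <- function(x, ...) {
  est <- tibble(term = names(x$coefficients),
                estimate = unname(x$coefficients))
  if (!is.null(x$model)) {
    # noiseless inputs interpolate exactly; the perfect-fit warning is benign
    se <- suppressWarnings(summary(x$model))$coefficients[, "Std. Error"]
    est$std.error <- unname(se)[seq_len(nrow(est))]
  }
  est
}

#' @rdname tidy.distinctiveness_fit
#' @method glance distinctiveness_fit
#' @export
glance.distinctiveness_fit <- function(x, ...) {
  tibble(
    median_abs_error = x$median_abs_error,
    max_abs_error = x$max_abs_error,
    n = x$n,
    r.squared = if (!is.null(x$model)) {
      suppressWarnings(summary(x$model))$r.squared
    } else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
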