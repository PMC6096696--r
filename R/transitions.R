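#' The 15 unordered cardinal colour pairs
#'
#' All pairs of distinct cardinal colours, in the canonical order
#' YG, YC, YB, YM, YR, GC, GB, GM, GR, CB, CM, CR, BM, BR, MR.
#'
#' @return A tibble with columns `pair`, `left`, `right`.
#' @export
cardinal_pairs <- function() {
  tibble(
    pair = c("YG", "YC", "YB", "YM", "YR", "GC", "GB", "GM", "GR",
             "CB", "CM", "CR", "BM", "BR", "MR"),
    left = c("Y", "Y", "Y", "Y", "Y", "G", "G", "G", "G",
             "C", "C", "C", "B", "B", "M"),
    right = c("G", "C", "B", "M", "R", "C", "B", "M", "R",
              "B", "M", "R", "M", "R", "R")
  )
}

#' Decompose a cardinal colour pair into channel transitions and veils
#'
#' Compares the two colours channel by channel. A channel that switches between
#' 0 and 1 is a *transition* (with polarity the sign of right minus left); a
#' channel fully on at both sides is a *veil*; a channel off at both sides is
#' *absent*. Pairs with 1, 2 or 3 transitions are classed *analogous*,
#' *incongruent* or *complementary* — equivalently 1, 2 or 3 steps along the
#' colour circle.
#'
#' @param left,right Cardinal letters (Y, G, C, B, M, R), distinct.
#' @return A one-row tibble with columns `pair`, `left`, `right`,
#'   `n_transitions`, `n_veils`, `class`, `pol_r`, `pol_g`, `pol_b` and a
#'   list-column `channels` (a 3-row tibble: `channel`, `left_value`,
#'   `right_value`, `kind`, `polarity`).
#' @examples
#' decompose_transition("Y", "G") # one transition (red channel), a green veil
#' @export
decompose_transition <- function(left, right) {
  stopifnot(length(left) == 1, length(right) == 1)
  l <- cardinal_rgb(left)[1, ]
  r <- cardinal_rgb(right)[1, ]
  if (all(l == r)) {
    abort("Degenerate pair: the two colours must be distinct cardinals.")
  }
  kind <- dplyr::case_when(
    l != r ~ "transition",
    l == 1 ~ "veil",
    TRUE ~ "absent"
  )
  pol <- sign(r - l)
  channels <- tibble(
    channel = c("R", "G", "B"),
    left_value = unname(l),
    right_value = unname(r),
    kind = kind,
    polarity = unname(pol)
  )
  nt <- sum(kind == "transition")
  tibble(
    pair = paste0(toupper(left), toupper(right)),
    left = toupper(left),
    right = toupper(right),
    n_transitions = nt,
    n_veils = sum(kind == "veil"),
    class = c("analogous", "incongruent", "complementary")[nt],
    pol_r = pol[1],
    pol_g = pol[2],
    pol_b = pol[3],
    channels = list(channels)
  )
}

#' Transition structure of the cardinal pairs
#'
#' Applies [decompose_transition()] to a table of pairs (all 15 by default).
#'
#' @param pairs A tibble with `left`, `right` columns, as from
#'   [cardinal_pairs()].
#' @return A tibble, one row per pair, in the layout of
#'   [decompose_transition()].
#' @examples
#' transition_structure()
#' @export
transition_structure <- function(pairs = cardinal_pairs()) {
  purrr::map2_dfr(pairs$left, pairs$right, decompose_transition)
}

#' Polarity profile of a transition structure
#'
#' The ordered (R, G, B) signs of right minus left. Swapping the pair negates
#' the profile; complementary pairs are grouped by their relative polarities.
#'
#' @param x A one-row tibble from [decompose_transition()], or a multi-row
#'   tibble from [transition_structure()].
#' @return An n x 3 matrix of polarities in \{-1, 0, 1\}.
#' @export
polarity_profile <- function(x) {
  stopifnot(all(c("pol_r", "pol_g", "pol_b") %in% names(x)))
  m <- cbind(R = x$pol_r, G = x$pol_g, B = x$pol_b)
  rownames(m) <- x$pair
  m
}

#' Write a transition-structure table to CSV
#'
#' Serialises the scalar columns (pair, counts, class, polarity profile) for
#' downstream plotting.
#'
#' @param x A tibble from [transition_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(x, path) {
  readr::write_csv(
    dplyr::select(x, "pair", "left", "right", "n_transitions", "n_veils",
                  "class", "pol_r", "pol_g", "pol_b"),
    path
  )
  invisible(path)
}
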