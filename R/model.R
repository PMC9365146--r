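#' Diversity weight: how far group intelligence reduces environmental
#' complexity
#'
#' The weight `w_div(g) = max(g) * tanh(g / (max(g) - g))^alpha`, floored at
#' 1 so that the representational-diversity need never exceeds
#' `S_cpx + E_cpx`. The tanh saturation makes `w_div` flat near `g = 0`
#' (the floor region), rise once g clears an alpha-dependent threshold, and
#' saturate at `max(g)`. At `g = max(g)` the singular tanh argument is
#' resolved by the continuous limit, `w_div = max(g)`; `tanh(.)^0` is taken
#' as 1 so `alpha = 0` gives the unrestricted weight.
#'
#' @param g Group-mean general intelligence, in `[0, max_g]`; vectorised.
#' @param alpha Cognitive-tool restriction, `>= 0`.
#' @param max_g Scale maximum (default 10).
#' @return Numeric vector in `[1, max_g]`, non-decreasing in `g`.
#' @examples
#' ability_weight(5, alpha = 1)  # 10 * tanh(1)
#' @export
ability_weight <- function(g, alpha, max_g = 10) {
  check_scalar_nonneg(alpha, "alpha")
  check_range(g, 0, max_g, "g")
  raw <- saturating_weight(g, alpha, max_g)
  pmax(1, raw)
}

#' Gap-closure weight: how far theory of mind closes representational gaps
#'
#' `w_gap(ToM) = max(ToM) * tanh(ToM / (max(ToM) - ToM))^beta`. Same
#' saturating form as [ability_weight()] but with no lower floor: a group
#' with no ToM closes no gaps at all. Larger `beta` pushes the minimum ToM
#' needed before gaps start to close upward.
#'
#' @param tom Group-mean theory of mind, in `[0, max_tom]`; vectorised.
#' @param beta Cognitive-tool restriction on group culture, `>= 0`.
#' @param max_tom Scale maximum (default 10).
#' @return Numeric vector in `[0, max_tom]`, non-decreasing in `tom`.
#' @export
gap_weight <- function(tom, beta, max_tom = 10) {
  check_scalar_nonneg(beta, "beta")
  check_range(tom, 0, max_tom, "tom")
  saturating_weight(tom, beta, max_tom)
}

# Shared saturating form M * tanh(x / (M - x))^p with the two edge
# conventions: x = M -> tanh(Inf) = 1 (continuous limit), p = 0 -> 1.
saturating_weight <- function(x, p, M) {
  ratio <- ifelse(x >= M, Inf, x / (M - x))
  base <- tanh(ratio)
  if (p == 0) rep(M, length(x)) else M * base^p
}

#' Need for representational diversity
#'
#' `R_div = S_cpx + E_cpx / w_div(g)`: the diversity of system
#' representations a group needs to address an action situation. Social
#' complexity enters undamped; the environmental component shrinks as group
#' intelligence rises. Bounded by
#' `S_cpx + E_cpx / max(g) <= R_div <= S_cpx + E_cpx`.
#'
#' @param params A [gpsa_params()] object.
#' @param g Group-mean general intelligence; vectorised.
#' @return Numeric vector, non-increasing in `g`.
#' @export
diversity_need <- function(params, g) {
  params <- validate_gpsa_params(params)
  params$s_cpx + params$e_cpx / ability_weight(g, params$alpha, params$max_g)
}

#' Harnessed diversity balance
#'
#' `R_hdg = R_div - ToM * w_gap(ToM) / (max(ToM) / 2)`: the representational
#' gap left after the group's theory of mind has been spent closing gaps.
#' Positive values mean unclosed gaps; negative values mean surplus capacity
#' to exploit diversity. The value is clipped to `[-20, 20]`; under the
#' default scale maxima the clip is provably inactive (both terms already
#' live in `[0, 20]`).
#'
#' @param params A [gpsa_params()] object.
#' @param g,tom Group-mean intelligence and theory of mind; vectorised
#'   (recycled against each other).
#' @param clip Clip the result into `[-20, 20]`? Default `TRUE`.
#' @return Numeric vector in `[-20, 20]` (when clipped).
#' @export
harnessed_diversity <- function(params, g, tom, clip = TRUE) {
  params <- validate_gpsa_params(params)
  wg <- gap_weight(tom, params$beta, params$max_tom)
  raw <- diversity_need(params, g) - tom * wg / (params$max_tom / 2)
  if (clip) pmin(20, pmax(-20, raw)) else raw
}

#' Group problem-solving ability score
#'
#' The headline `[0, 1]` score
#' `GPSA = 1 - (E_cpx + S_cpx + R_hdg + 20) / 60`, where 20 and 60 are
#' normalisation constants tied to the `[0, 10]` complexity scales. GPSA is
#' non-decreasing in `g` and `tom` and non-increasing in `e_cpx`, `s_cpx`,
#' `alpha` and `beta`.
#'
#' @inheritParams harnessed_diversity
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' p <- gpsa_params(5, 5, 1, 1)
#' gpsa_score(p, g = 5, tom = 5)
#' @export
gpsa_score <- function(params, g, tom) {
  params <- validate_gpsa_params(params)
  if (params$e_cpx > 10 || params$s_cpx > 10) {
    stop("normalisation assumes complexities in [0, 10]; got E_cpx = ",
         params$e_cpx, ", S_cpx = ", params$s_cpx, call. = FALSE)
  }
  rhdg <- harnessed_diversity(params, g, tom)
  1 - (params$e_cpx + params$s_cpx + rhdg + 20) / 60
}

#' All model components at once
#'
#' Evaluate the diversity weight, diversity need, gap weight, harnessed
#' diversity and GPSA for each `(g, tom)` pair, as one tibble row per pair.
#'
#' @inheritParams harnessed_diversity
#' @return A tibble with columns `g`, `tom`, `w_div`, `r_div`, `w_gap`,
#'   `r_hdg`, `gpsa`.
#' @export
gpsa_components <- function(params, g, tom) {
  params <- validate_gpsa_params(params)
  n <- max(length(g), length(tom))
  g <- rep_len(g, n); tom <- rep_len(tom, n)
  tibble::tibble(
    g = g, tom = tom,
    w_div = ability_weight(g, params$alpha, params$max_g),
    r_div = diversity_need(params, g),
    w_gap = gap_weight(tom, params$beta, params$max_tom),
    r_hdg = harnessed_diversity(params, g, tom),
    gpsa = gpsa_score(params, g, tom)
  )
}

check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop("`", name, "` must be numeric with no missing values", call. = FALSE)
  }
  if (any(x < lo | x > hi)) {
    stop("`", name, "` must lie in [", lo, ", ", hi, "]", call. = FALSE)
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("`", name, "` must be a single number >= 0", call. = FALSE)
  }
  invisible(x)
}
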