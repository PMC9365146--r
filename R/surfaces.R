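#' Evaluate the GPSA surface on a (g, ToM) grid
#'
#' Tabulates [gpsa_score()] over the Cartesian product of the two grids for
#' one fixed parameter set. Rows index `g`, columns index `tom`.
#'
#' @param params A [gpsa_params()] object.
#' @param g_grid,tom_grid Strictly increasing grids within the scale ranges.
#' @return A `gpsa_surface`: list with `g_values`, `tom_values`, a
#'   `|g| x |tom|` matrix `values`, and `meta` describing the parameters.
#' @examples
#' s <- evaluate_surface(gpsa_params(5, 5, 1, 1))
#' range(s$values)
#' @export
evaluate_surface <- function(params,
                             g_grid = seq(0, params$max_g, by = 0.1),
                             tom_grid = seq(0, params$max_tom, by = 0.1)) {
  params <- validate_gpsa_params(params)
  check_grid(g_grid, "g_grid"); check_grid(tom_grid, "tom_grid")
  vals <- outer(g_grid, tom_grid,
                function(g, t) gpsa_score(params, g, t))
  new_surface(g_grid, tom_grid, vals,
              meta = c(as.data.frame(params), list(averaged = FALSE)))
}

#' GPSA surface averaged over cognitive-tool settings
#'
#' Averages the GPSA surface over a set of `(alpha, beta)` combinations —
#' by default the integer grid `{1, ..., 10}^2` (100 combinations) — for
#' fixed complexities. This marginalises out the cognitive-tool moderators
#' so the surface shows the effect of `g` and `ToM` alone.
#'
#' @param e_cpx,s_cpx Complexities in `[0, 10]`.
#' @param g_grid,tom_grid Evaluation grids.
#' @param alpha_set,beta_set Non-empty sets of tool values in `[1, 10]`.
#' @param max_g,max_tom Scale maxima.
#' @return A `gpsa_surface` with `meta$averaged = TRUE`.
#' @export
tool_averaged_surface <- function(e_cpx, s_cpx,
                                  g_grid = seq(0, max_g, by = 0.1),
                                  tom_grid = seq(0, max_tom, by = 0.1),
                                  alpha_set = 1:10, beta_set = 1:10,
                                  max_g = 10, max_tom = 10) {
  if (length(alpha_set) == 0L || length(beta_set) == 0L) {
    stop("`alpha_set` and `beta_set` must be non-empty", call. = FALSE)
  }
  check_grid(g_grid, "g_grid"); check_grid(tom_grid, "tom_grid")
  acc <- matrix(0, length(g_grid), length(tom_grid))
  for (a in alpha_set) for (b in beta_set) {
    p <- gpsa_params(e_cpx, s_cpx, a, b, max_g, max_tom)
    acc <- acc + evaluate_surface(p, g_grid, tom_grid)$values
  }
  vals <- acc / (length(alpha_set) * length(beta_set))
  new_surface(g_grid, tom_grid, vals,
              meta = list(e_cpx = e_cpx, s_cpx = s_cpx,
                          alpha = "averaged", beta = "averaged",
                          alpha_set = alpha_set, beta_set = beta_set,
                          averaged = TRUE))
}

#' Environmental-component reduction curve
#'
#' The series `E_cpx / w_div(g)` along a g grid: how group intelligence
#' shrinks the environmental share of the representational-diversity need.
#' Flat at `E_cpx` while the `w_div >= 1` floor is active, then falling to
#' `E_cpx / max(g)`.
#'
#' @param e_cpx Environmental complexity in `[0, 10]`.
#' @param alpha Cognitive-tool restriction, `>= 0`.
#' @param g_grid Evaluation grid (default step 0.1 on `[0, max_g]`).
#' @param max_g Scale maximum.
#' @return A tibble with columns `g` and `value`, non-increasing in `g`.
#' @export
complexity_reduction_curve <- function(e_cpx, alpha,
                                       g_grid = seq(0, max_g, by = 0.1),
                                       max_g = 10) {
  check_range(e_cpx, 0, 10, "e_cpx")
  check_grid(g_grid, "g_grid")
  tibble::tibble(g = g_grid,
                 value = e_cpx / ability_weight(g_grid, alpha, max_g))
}

#' Gap-closure curve
#'
#' The series `w_gap(ToM)` along a ToM grid: rises from 0 (no ToM, no gap
#' closure) to `max(ToM)`, with `beta` setting how much ToM is needed
#' before closure begins.
#'
#' @param beta Cognitive-tool restriction on group culture, `>= 0`.
#' @param tom_grid Evaluation grid.
#' @param max_tom Scale maximum.
#' @return A tibble with columns `tom` and `value`, non-decreasing.
#' @export
gap_closure_curve <- function(beta,
                              tom_grid = seq(0, max_tom, by = 0.1),
                              max_tom = 10) {
  check_grid(tom_grid, "tom_grid")
  tibble::tibble(tom = tom_grid,
                 value = gap_weight(tom_grid, beta, max_tom))
}

#' First grid point where the diversity-weight floor releases
#'
#' Scans a [complexity_reduction_curve()] for the first g at which
#' `E_cpx / w_div` drops below `E_cpx`, i.e. where `w_div` exceeds its
#' floor of 1. This is the model's operational reading of the in-text
#' minimum-intelligence thresholds, resolved to one grid step.
#'
#' @param curve A tibble from [complexity_reduction_curve()].
#' @param e_cpx The environmental complexity the curve was built with.
#' @return The first `g` with `value < e_cpx`, or `NA` if none.
#' @export
floor_release_g <- function(curve, e_cpx) {
  stopifnot(is.data.frame(curve), all(c("g", "value") %in% names(curve)))
  if (e_cpx <= 0) stop("threshold undefined for e_cpx <= 0", call. = FALSE)
  hit <- which(curve$value < e_cpx)
  if (length(hit) == 0L) NA_real_ else curve$g[hit[1L]]
}

#' Long-format view of a surface
#'
#' @param x A `gpsa_surface`.
#' @param ... Unused.
#' @return A tibble with columns `g`, `tom`, `gpsa`, `e_cpx`, `s_cpx`,
#'   `alpha`, `beta` (the tool columns read `"averaged"` for averaged
#'   surfaces).
#' @export
as.data.frame.gpsa_surface <- function(x, ...) {
  grid <- expand.grid(g = x$g_values, tom = x$tom_values,
                      KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    g = grid$g, tom = grid$tom, gpsa = as.vector(x$values),
    e_cpx = x$meta$e_cpx, s_cpx = x$meta$s_cpx,
    alpha = as.character(x$meta$alpha), beta = as.character(x$meta$beta)
  )
}

#' Write a surface as a long-format CSV
#'
#' @param x A `gpsa_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}

#' @export
print.gpsa_surface <- function(x, ...) {
  cat(sprintf("<gpsa_surface> %d x %d grid, gpsa in [%.4f, %.4f]\n",
              length(x$g_values), length(x$tom_values),
              min(x$values), max(x$values)))
  invisible(x)
}

new_surface <- function(g_values, tom_values, values, meta) {
  stopifnot(nrow(values) == length(g_values),
            ncol(values) == length(tom_values))
  structure(list(g_values = g_values, tom_values = tom_values,
                 values = values, meta = meta),
            class = "gpsa_surface")
}

check_grid <- function(x, name) {
  if (length(x) == 0L) stop("`", name, "` is empty", call. = FALSE)
  if (length(x) > 1L && any(diff(x) <= 0)) {
    stop("`", name, "` must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}
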