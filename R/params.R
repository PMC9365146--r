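#' Action-situation parameters
#'
#' Bundle the slow-loop parameters of one action situation: environmental
#' complexity `e_cpx`, social complexity `s_cpx`, and the two cognitive-tool
#' moderators `alpha` (restriction on building functionally relevant system
#' representations, e.g. education and monitoring technology) and `beta`
#' (restriction on positive group culture, e.g. distrust and fractured
#' narratives). `max_g` and `max_tom` are the theoretical scale maxima for
#' group-mean general intelligence and theory of mind; the data-rescaling
#' convention fixes both at 10.
#'
#' @param e_cpx Environmental complexity, in `[0, 10]` for a normalised score.
#' @param s_cpx Social complexity, in `[0, 10]` for a normalised score.
#' @param alpha Cognitive-tool restriction on system representation, `>= 0`;
#'   fits constrain it to `[1, 10]`.
#' @param beta Cognitive-tool restriction on group culture, `>= 0`; fits
#'   constrain it to `[1, 10]`.
#' @param max_g,max_tom Scale maxima for g and ToM, `> 0` (default 10).
#'
#' @return An object of class `gpsa_params` (a named list).
#' @examples
#' gpsa_params(e_cpx = 5, s_cpx = 5, alpha = 1, beta = 1)
#' @export
gpsa_params <- function(e_cpx, s_cpx, alpha, beta, max_g = 10, max_tom = 10) {
  p <- list(e_cpx = as.numeric(e_cpx), s_cpx = as.numeric(s_cpx),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            max_g = as.numeric(max_g), max_tom = as.numeric(max_tom))
  validate_gpsa_params(structure(p, class = "gpsa_params"))
}

validate_gpsa_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("e_cpx", "s_cpx", "alpha", "beta", "max_g", "max_tom")) {
    if (!num1(p[[nm]])) stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (p$e_cpx < 0 || p$s_cpx < 0) stop("complexities must be >= 0", call. = FALSE)
  if (p$alpha < 0 || p$beta < 0) stop("`alpha` and `beta` must be >= 0", call. = FALSE)
  if (p$max_g <= 0 || p$max_tom <= 0) stop("scale maxima must be > 0", call. = FALSE)
  p
}

#' @export
print.gpsa_params <- function(x, ...) {
  cat("<gpsa_params>",
      sprintf("  E_cpx = %.5f, S_cpx = %.5f", x$e_cpx, x$s_cpx),
      sprintf("  alpha = %.5f, beta  = %.5f", x$alpha, x$beta),
      sprintf("  scale maxima: g <= %g, ToM <= %g", x$max_g, x$max_tom),
      sep = "\n")
  invisible(x)
}

#' @export
as.data.frame.gpsa_params <- function(x, ...) {
  data.frame(e_cpx = x$e_cpx, s_cpx = x$s_cpx, alpha = x$alpha, beta = x$beta)
}
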