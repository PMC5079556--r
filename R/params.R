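#' Cellular-automaton spread parameters
#'
#' Bundles the constants of the heterogeneous ("full") fire-spread model:
#' the nominal spread probability under flat terrain and reference
#' vegetation, the slope coefficient of the exponential slope gain, the
#' cell side length, and the lookup tables translating vegetation
#' categories into multiplicative-effect values.
#'
#' The defaults are the values calibrated against observed Mediterranean
#' island wildfires: `p0 = 0.58`, `a = 0.078`, with density effects
#' sparse = -0.4, moderate = 0, dense = 0.3 and type effects
#' agricultural = -0.3, other woodland/shrub = 0, pine = 0.4.
#'
#' @param p0 Nominal spread probability in (0, 1]: the probability that
#'   fire propagates between neighbouring cells of moderate density and
#'   unremarkable type on flat terrain with no wind.
#' @param a Slope coefficient (> 0) of the gain factor `exp(a * theta_s)`,
#'   where `theta_s` is the slope angle in radians.
#' @param cell_side Side length of a (square) lattice cell in meters.
#' @param density_effects Named numeric vector mapping density categories
#'   to their multiplicative effect `s3`; the probability is scaled by
#'   `1 + s3`.
#' @param type_effects Named numeric vector mapping vegetation-type
#'   categories to their effect `s2`; the probability is scaled by
#'   `1 + s2`.
#'
#' @return An object of class `ca_params`.
#' @examples
#' p <- ca_params()
#' p$p0   # 0.58
#' @export
ca_params <- function(p0 = 0.58,
                      a = 0.078,
                      cell_side = 10,
                      density_effects = c(sparse = -0.4, moderate = 0,
                                          dense = 0.3),
                      type_effects = c(agricultural = -0.3, other = 0,
                                       pine = 0.4)) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 > 1)
    stop("`p0` must be a single probability in (0, 1]", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("`a` must be a single positive number", call. = FALSE)
  if (!is.numeric(cell_side) || length(cell_side) != 1L || cell_side <= 0)
    stop("`cell_side` must be a single positive length in meters",
         call. = FALSE)
  if (is.null(names(density_effects)) || any(!nzchar(names(density_effects))))
    stop("`density_effects` must be a fully named numeric vector",
         call. = FALSE)
  if (is.null(names(type_effects)) || any(!nzchar(names(type_effects))))
    stop("`type_effects` must be a fully named numeric vector",
         call. = FALSE)
  structure(
    list(p0 = p0, a = a, cell_side = cell_side,
         density_effects = density_effects, type_effects = type_effects),
    class = "ca_params")
}

#' @export
print.ca_params <- function(x, ...) {
  cat("CA fire-spread parameters\n")
  cat(sprintf("  p0 = %g, a = %g, cell side = %g m\n",
              x$p0, x$a, x$cell_side))
  cat("  density effects:",
      paste(sprintf("%s=%g", names(x$density_effects), x$density_effects),
            collapse = ", "), "\n")
  cat("  type effects:   ",
      paste(sprintf("%s=%g", names(x$type_effects), x$type_effects),
            collapse = ", "), "\n")
  invisible(x)
}

stopifnot_params <- function(params) {
  if (!inherits(params, "ca_params"))
    stop("expected a `ca_params` object; see `ca_params()`", call. = FALSE)
  params
}
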