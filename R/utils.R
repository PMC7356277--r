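# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used when reporting relative efficiencies
#' to two decimals. `base::round()` rounds half to even, which would turn
#' e.g. 0.775 into 0.78 or 0.77 depending on binary representation.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.9667, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(fmt, ...)
  invisible(TRUE)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Bounded Nelder-Mead via a quadratic penalty outside the box, followed by an
# L-BFGS-B polish. `fn` takes the full parameter vector on the natural scale.
optim_boxed <- function(par, fn, lower, upper,
                        control = list(maxit = 2000, reltol = 1e-12)) {
  pen_fn <- function(p) {
    viol <- pmax(0, lower - p) + pmax(0, p - upper)
    fn(pmin(pmax(p, lower), upper)) + 1e6 * sum(viol^2)
  }
  nm <- stats::optim(par, pen_fn, method = "Nelder-Mead", control = control)
  p0 <- pmin(pmax(nm$par, lower), upper)
  polish <- tryCatch(
    stats::optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 1e3)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= nm$value) polish else
    list(par = p0, value = fn(p0), convergence = nm$convergence)
}
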