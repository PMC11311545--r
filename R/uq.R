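#' An uncertain quantity
#'
#' The atom of every computation in idmsquant: a scalar value together with
#' its standard uncertainty and the number of repeat observations it summarises.
#' Units are carried by context (mg for blend masses, mg/kg for mass fractions,
#' dimensionless for signal ratios).
#'
#' @param value Scalar value.
#' @param u Standard uncertainty, same units as `value`. Must be >= 0.
#' @param n_repeats Number of repeat determinations behind `u` (>= 1). Whether
#'   `u` is interpreted as the dispersion of a single observation or scaled to a
#'   standard error of the mean is decided where the quantity is consumed (see
#'   the `repeat_scaling` argument of [gum_budget()] and [monte_carlo()]).
#'
#' @return An object of class `"uq"`.
#' @examples
#' uq(10.0, 0.14)
#' relative_u(uq(10.0, 0.14))
#' @export
uq <- function(value, u = 0, n_repeats = 1L) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u))
  if (u < 0) stop("standard uncertainty `u` must be non-negative", call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  if (length(n_repeats) != 1L || is.na(n_repeats) || n_repeats < 1L) {
    stop("`n_repeats` must be a single integer >= 1", call. = FALSE)
  }
  structure(list(value = as.numeric(value), u = as.numeric(u),
                 n_repeats = n_repeats),
            class = "uq")
}

#' @export
print.uq <- function(x, ...) {
  cat(format(x$value), "±", format(x$u))
  if (x$n_repeats > 1L) cat(" (n = ", x$n_repeats, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname uq
#' @param x Object to test or coerce.
#' @export
is_uq <- function(x) inherits(x, "uq")

#' @rdname uq
#' @export
as_uq <- function(x) {
  if (is_uq(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(uq(x))
  stop("cannot coerce to an uncertain quantity", call. = FALSE)
}

#' Relative standard uncertainty
#'
#' @param q An [uq()] object.
#' @return `q$u / abs(q$value)`.
#' @export
relative_u <- function(q) {
  q <- as_uq(q)
  if (q$value == 0) {
    stop("relative uncertainty undefined for a zero-valued quantity",
         call. = FALSE)
  }
  q$u / abs(q$value)
}

# effective standard uncertainty entering a propagation
u_eff <- function(q, repeat_scaling = TRUE) {
  if (repeat_scaling) q$u / sqrt(q$n_repeats) else q$u
}
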