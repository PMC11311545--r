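#' Standard-addition blend series
#'
#' A matched standard-addition IDMS experiment: one binary blend (sample x +
#' labeled spike y) and several ternary blends (sample + spike + unlabeled
#' reference z of known content), each weighed gravimetrically and measured
#' for its isotopologue signal ratio. The analyte content follows from the
#' intercept/slope ratio of the linearized series, see [linearize()] and
#' [msa_fit()].
#'
#' @param blends A data frame with one row per blend and columns `blend_id`,
#'   `m_x`, `u_m_x`, `m_y`, `u_m_y`, `m_z`, `u_m_z` (masses in mg; `m_z = 0`
#'   marks the binary blend), `r_obs`, `u_r_obs` (signal ratio A1/A2 and its
#'   standard deviation) and `n_repeats` (repeat injections behind `r_obs`).
#'   Missing uncertainty columns default to 0, missing `n_repeats` to 1,
#'   missing `blend_id` to the row number.
#' @param w_z Mass fraction of the analyte in the reference solution z
#'   (mg/kg), an [uq()] (bare numerics are promoted). For a validation series
#'   where sample and reference come from the same stock, use `uq(1)` and read
#'   the result as the dimensionless ratio w_X/w_Z with target value 1.
#' @param isotopes Optional list with elements `M_x`, `M_y` (molar masses,
#'   g/mol) and `x_x1`, `x_x2`, `x_y1`, `x_y2` (isotopologue amount fractions
#'   of the analyte (1) and the label (2) in sample and spike). Only needed
#'   for [linearize_general()] when the labeled and unlabeled isotopologue
#'   signals overlap; `NULL` selects the no-overlap simplification
#'   (`x_y1 = 0`, `x_x2 = 0`, `x_x1 = x_y2 = 1`).
#'
#' @return An object of class `"addition_series"`: a list with elements
#'   `blends` (tibble), `w_z` (uq) and `isotopes`.
#' @examples
#' series <- mel_pt_series()
#' linearize(series)
#' @export
addition_series <- function(blends, w_z, isotopes = NULL) {
  stopifnot(is.data.frame(blends))
  b <- tibble::as_tibble(blends)
  if (!all(c("m_x", "m_y", "m_z", "r_obs") %in% names(b))) {
    stop("`blends` needs columns m_x, m_y, m_z, r_obs", call. = FALSE)
  }
  if (!"blend_id" %in% names(b)) b$blend_id <- as.character(seq_len(nrow(b)))
  for (uc in c("u_m_x", "u_m_y", "u_m_z", "u_r_obs")) {
    if (!uc %in% names(b)) b[[uc]] <- 0
  }
  if (!"n_repeats" %in% names(b)) b$n_repeats <- 1L
  b$n_repeats <- as.integer(b$n_repeats)
  b <- b[c("blend_id", "m_x", "u_m_x", "m_y", "u_m_y", "m_z", "u_m_z",
           "r_obs", "u_r_obs", "n_repeats")]

  if (nrow(b) < 2L) stop("need at least 2 blends", call. = FALSE)
  bad <- which(b$m_x <= 0 | b$m_y <= 0 | b$m_z < 0 | b$r_obs <= 0)
  if (length(bad)) {
    stop("invalid blend in row ", bad[1],
         ": masses must be positive (m_z >= 0) and r_obs > 0", call. = FALSE)
  }
  if (any(c(b$u_m_x, b$u_m_y, b$u_m_z, b$u_r_obs) < 0)) {
    stop("uncertainty columns must be non-negative", call. = FALSE)
  }
  if (any(b$n_repeats < 1L)) stop("n_repeats must be >= 1", call. = FALSE)
  if (!any(b$m_z == 0)) stop("series needs a binary blend (m_z = 0)", call. = FALSE)
  if (!any(b$m_z > 0)) stop("series needs at least one ternary blend", call. = FALSE)
  x <- b$m_z / b$m_x
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct m_z/m_x values for the regression",
         call. = FALSE)
  }
  if (!is.null(isotopes)) {
    need <- c("M_x", "M_y", "x_x1", "x_x2", "x_y1", "x_y2")
    if (!all(need %in% names(isotopes))) {
      stop("`isotopes` needs elements ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    fr <- unlist(isotopes[c("x_x1", "x_x2", "x_y1", "x_y2")])
    if (any(fr < 0 | fr > 1)) {
      stop("amount fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(blends = b, w_z = as_uq(w_z), isotopes = isotopes),
            class = "addition_series")
}

#' @export
print.addition_series <- function(x, ...) {
  cat("<addition_series> ", nrow(x$blends), " blends, w_z = ",
      format(x$w_z$value), " ± ", format(x$w_z$u), "\n", sep = "")
  print(x$blends)
  invisible(x)
}

#' Linearize a standard-addition series (no signal overlap)
#'
#' Maps each blend to a point of the linear standard-addition relation
#' \eqn{y_i = a_1 x_i + a_0} with \eqn{x_i = m_{z,i}/m_{x,i}} and
#' \eqn{y_i = (m_{y,i}/m_{x,i}) \cdot r_i}{y_i = (m_y/m_x) r_i}, where
#' \eqn{r_i} is the observed signal ratio A1/A2. (In terms of the inverted
#' blend isotopologue amount ratio \eqn{R_{b,i} = f_{inst} A_2/A_1} this is
#' \eqn{(m_y/m_x)/R_{b,i}}; the multiplicative instrument factor
#' \eqn{f_{inst}} moves into slope and intercept and cancels in
#' \eqn{a_0/a_1}.) The binary blend maps to \eqn{x = 0}.
#'
#' @param series An [addition_series()].
#' @return A tibble with columns `blend_id`, `x`, `y`.
#' @export
linearize <- function(series) {
  stopifnot(inherits(series, "addition_series"))
  b <- series$blends
  if (any(b$r_obs <= 0)) stop("r_obs must be > 0", call. = FALSE)
  tibble::tibble(blend_id = b$blend_id,
                 x = b$m_z / b$m_x,
                 y = (b$m_y / b$m_x) * b$r_obs)
}

#' Linearize with isotopologue signal overlap
#'
#' General form of [linearize()] for spike or sample materials whose
#' isotopologue signals overlap: the y-axis value of blend i becomes
#' \deqn{y_i = \frac{m_{y,i}}{m_{x,i}} \cdot
#'   \frac{x_{y2} - R_{b,i} x_{y1}}{R_{b,i} x_{x1} - x_{x2}}}
#' with \eqn{R_{b,i} = A_2/A_1} the inverted observed ratio and the amount
#' fractions taken from `series$isotopes`. With `x_y1 = 0`, `x_x2 = 0` and
#' `x_x1 = x_y2 = 1` this reduces exactly to [linearize()].
#'
#' @inheritParams linearize
#' @return A tibble with columns `blend_id`, `x`, `y`.
#' @export
linearize_general <- function(series) {
  stopifnot(inherits(series, "addition_series"))
  iso <- series$isotopes
  if (is.null(iso)) {
    iso <- list(x_x1 = 1, x_x2 = 0, x_y1 = 0, x_y2 = 1)
  }
  b <- series$blends
  r_inv <- 1 / b$r_obs   # A2/A1
  den <- r_inv * iso$x_x1 - iso$x_x2
  if (any(den <= 0)) {
    stop("spike/sample overlap inconsistent with ratio: ",
         "denominator R_b*x_x1 - x_x2 <= 0", call. = FALSE)
  }
  tibble::tibble(blend_id = b$blend_id,
                 x = b$m_z / b$m_x,
                 y = (b$m_y / b$m_x) * (iso$x_y2 - r_inv * iso$x_y1) / den)
}

#' Fit the standard-addition regression
#'
#' Ordinary (unweighted) least squares of y on x with intercept, fitted with
#' [stats::lm()]. Standard errors use the residual variance on n - 2 degrees
#' of freedom. The binary blend enters as an ordinary x = 0 point; the
#' intercept is not pinned to it.
#'
#' @param points A data frame with columns `x` and `y` (at least 2 distinct
#'   x values), e.g. from [linearize()].
#' @return An object of class `"addition_fit"`: a list with elements `a0`,
#'   `a1`, `se_a0`, `se_a1`, `cov_a0a1`, `r2`, `residuals`, `points` and the
#'   underlying `lm` object (`fit`).
#' @export
fit_addition <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (length(unique(points$x)) < 2L) {
    stop("singular design: need at least 2 distinct x values", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = points)
  cf <- stats::coef(fit)
  # summary.lm warns on numerically perfect fits; degenerate designs are
  # legitimate here (noiseless simulations, two-point series)
  vc <- if (nrow(points) > 2L) suppressWarnings(stats::vcov(fit)) else
    matrix(NA_real_, 2, 2)
  r2 <- if (nrow(points) > 2L) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(a0 = unname(cf[1]), a1 = unname(cf[2]),
                 se_a0 = sqrt(vc[1, 1]), se_a1 = sqrt(vc[2, 2]),
                 cov_a0a1 = vc[1, 2], r2 = r2,
                 residuals = unname(stats::residuals(fit)),
                 points = tibble::as_tibble(points), fit = fit),
            class = "addition_fit")
}

#' @export
print.addition_fit <- function(x, ...) {
  cat("<addition_fit> a0 =", format(x$a0), " a1 =", format(x$a1),
      " a0/a1 =", format(x$a0 / x$a1), " r2 =", format(x$r2), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a standard-addition fit
#'
#' @param x An `addition_fit`.
#' @param ... Unused.
#' @return One row per coefficient with `term`, `estimate`, `std.error`.
#' @export
tidy.addition_fit <- function(x, ...) {
  tibble::tibble(term = c("a0", "a1"),
                 estimate = c(x$a0, x$a1),
                 std.error = c(x$se_a0, x$se_a1))
}

#' @rdname tidy.addition_fit
#' @export
glance.addition_fit <- function(x, ...) {
  tibble::tibble(a0 = x$a0, a1 = x$a1, a0_over_a1 = x$a0 / x$a1,
                 r.squared = x$r2, nobs = nrow(x$points))
}

#' @rdname tidy.addition_fit
#' @export
augment.addition_fit <- function(x, ...) {
  out <- x$points
  out$.fitted <- x$a0 + x$a1 * out$x
  out$.resid <- x$residuals
  out
}

#' Mass fraction from a standard-addition fit
#'
#' The analyte content of the sample follows from intercept and slope as
#' \eqn{w_X = (a_0/a_1) \, w_Z}. Molar-mass and amount-fraction factors are
#' common to \eqn{a_0} and \eqn{a_1} and cancel in the ratio, as does the
#' multiplicative instrument bias.
#'
#' @param fit An [fit_addition()] result.
#' @param w_z Mass fraction of the analyte in the reference solution
#'   (mg/kg), [uq()] or numeric.
#' @return Mass fraction of the analyte in the sample (mg/kg), scalar.
#' @export
msa_mass_fraction <- function(fit, w_z) {
  stopifnot(inherits(fit, "addition_fit"))
  if (fit$a1 == 0) {
    stop("no addition signal: slope a1 is zero", call. = FALSE)
  }
  (fit$a0 / fit$a1) * as_uq(w_z)$value
}

#' Full standard-addition pipeline
#'
#' Convenience wrapper: [linearize()] (or [linearize_general()] when isotope
#' data are present), [fit_addition()], [msa_mass_fraction()]. Blends can be
#' excluded by id to compare fits with and without suspected outliers; the
#' exclusion is reported, never automatic.
#'
#' @param series An [addition_series()].
#' @param exclude Character vector of `blend_id`s to leave out of the fit.
#' @return A list of class `"msa_result"` with elements `fit`
#'   (`addition_fit`), `w_x`, `a0_over_a1`, `excluded` and `series`.
#' @examples
#' msa_fit(mel_pt_series())
#' @export
msa_fit <- function(series, exclude = NULL) {
  stopifnot(inherits(series, "addition_series"))
  pts <- if (is.null(series$isotopes)) linearize(series) else
    linearize_general(series)
  if (!is.null(exclude)) {
    keep <- !pts$blend_id %in% exclude
    if (sum(keep) < 2L) stop("too few blends left after exclusion", call. = FALSE)
    pts <- pts[keep, ]
  }
  fit <- fit_addition(pts)
  structure(list(fit = fit, w_x = msa_mass_fraction(fit, series$w_z),
                 a0_over_a1 = fit$a0 / fit$a1,
                 excluded = exclude %||% character(),
                 series = series),
            class = "msa_result")
}

#' @export
print.msa_result <- function(x, ...) {
  cat("<msa_result> w_x =", format(x$w_x),
      " (a0/a1 =", format(x$a0_over_a1), ")\n")
  if (length(x$excluded)) {
    cat("  excluded blends:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ratio-matching summary of a blend series
#'
#' Ternary blends are prepared so spike and reference keep the observed
#' signal ratios of all blends nearly constant; a large spread signals a
#' preparation mismatch that weakens the constant-ratio assumption of the
#' standard-addition design. The RSD flag is advisory and never blocks
#' computation.
#'
#' @param series An [addition_series()].
#' @param rsd_max Advisory threshold on the relative standard deviation.
#' @return A one-row tibble: `n`, `mean`, `sd` (n-1 denominator), `rsd`,
#'   `matched` (`rsd <= rsd_max`).
#' @export
matching_report <- function(series, rsd_max = 0.02) {
  stopifnot(inherits(series, "addition_series"))
  r <- series$blends$r_obs
  if (length(r) < 2L) stop("need at least 2 blends", call. = FALSE)
  m <- mean(r)
  s <- stats::sd(r)
  tibble::tibble(n = length(r), mean = m, sd = s, rsd = s / m,
                 matched = s / m <= rsd_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
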