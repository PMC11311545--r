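#' A measurement model for uncertainty evaluation
#'
#' Couples a named set of uncertain input quantities to a deterministic model
#' function, the common currency of [gum_budget()] and [monte_carlo()].
#'
#' @param inputs A data frame with columns `name`, `value`, `u` and optionally
#'   `n_repeats` (default 1), one row per input quantity; or a named list of
#'   [uq()] objects.
#' @param fn A function taking a named numeric vector (one element per input,
#'   in the order of `inputs`) and returning a named numeric vector of model
#'   outputs. Must be deterministic and evaluable at the mean vector.
#' @param output_names Optional character vector naming the outputs; defaults
#'   to the names returned by `fn` at the mean vector.
#' @param fn_matrix Optional vectorized form of `fn`: takes a draws matrix
#'   (one column per input) and returns a matrix with one column per output.
#'   Used by [monte_carlo()] when present; must agree with `fn` row by row.
#'
#' @return An object of class `"model_spec"`.
#' @examples
#' m <- model_spec(
#'   data.frame(name = c("x", "y"), value = c(1, 2), u = c(3, 4)),
#'   function(v) c(sum = v[["x"]] + v[["y"]])
#' )
#' gum_budget(m)
#' @export
model_spec <- function(inputs, fn, output_names = NULL, fn_matrix = NULL) {
  if (is.list(inputs) && !is.data.frame(inputs)) {
    stopifnot(!is.null(names(inputs)))
    inputs <- tibble::tibble(
      name = names(inputs),
      value = unname(vapply(inputs, function(q) as_uq(q)$value, numeric(1))),
      u = unname(vapply(inputs, function(q) as_uq(q)$u, numeric(1))),
      n_repeats = unname(vapply(inputs, function(q) as_uq(q)$n_repeats,
                                integer(1)))
    )
  }
  inputs <- tibble::as_tibble(inputs)
  stopifnot(all(c("name", "value", "u") %in% names(inputs)))
  if (is.null(inputs$n_repeats)) inputs$n_repeats <- 1L
  inputs$n_repeats <- as.integer(inputs$n_repeats)
  stopifnot(is.function(fn))
  if (any(inputs$u < 0)) stop("input uncertainties must be >= 0", call. = FALSE)
  if (any(inputs$n_repeats < 1L)) stop("n_repeats must be >= 1", call. = FALSE)
  if (anyDuplicated(inputs$name)) stop("input names must be unique", call. = FALSE)

  v0 <- stats::setNames(inputs$value, inputs$name)
  y0 <- fn(v0)
  if (!is.numeric(y0) || any(!is.finite(y0))) {
    stop("model is not finite at the mean input vector", call. = FALSE)
  }
  if (is.null(output_names)) {
    output_names <- names(y0) %||% paste0("y", seq_along(y0))
  }
  structure(list(inputs = inputs, fn = fn, output_names = output_names,
                 fn_matrix = fn_matrix, mean_output = unname(y0)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", nrow(x$inputs), " inputs -> ",
      paste(x$output_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' First-order GUM uncertainty budget
#'
#' Propagates the standard uncertainties of the model inputs to each output by
#' first-order Taylor expansion. Sensitivity coefficients
#' \eqn{c_i = \partial f/\partial x_i} are computed by central finite
#' differences with step \eqn{h_i = \max(|x_i|, 1)\cdot 10^{-6}}; the combined
#' standard uncertainty is \eqn{u_c = \sqrt{\sum (c_i u_i)^2}} and each
#' input's contribution index is its share \eqn{(c_i u_i)^2/u_c^2} of the
#' combined variance.
#'
#' With `repeat_scaling = TRUE` (the default) an input summarising
#' `n_repeats` repeat observations enters with the standard error of its mean,
#' \eqn{u_i/\sqrt{n}}. Published budget tables often fold this factor into the
#' printed sensitivity coefficient instead (0.58 for n = 3, 0.71 for n = 2);
#' contributions and indices are identical either way.
#'
#' @param model A [model_spec()].
#' @param k Coverage factor for the expanded uncertainty `U = k * u_c`.
#' @param repeat_scaling Scale each `u` by `1/sqrt(n_repeats)`.
#' @return An object of class `"gum_budget"`: list with `terms` (tibble:
#'   `output`, `term`, `value`, `u`, `u_eff`, `c_i`, `contribution`, `index`)
#'   and `combined` (tibble: `output`, `estimate`, `u_c`, `k`, `U`).
#'   [tidy()] returns `terms`, [glance()] returns `combined`.
#' @export
gum_budget <- function(model, k = 2, repeat_scaling = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  inp <- model$inputs
  v0 <- stats::setNames(inp$value, inp$name)
  y0 <- model$fn(v0)
  n_out <- length(model$output_names)
  n_in <- nrow(inp)

  ueff <- if (repeat_scaling) inp$u / sqrt(inp$n_repeats) else inp$u
  sens <- matrix(NA_real_, n_in, n_out)
  for (i in seq_len(n_in)) {
    h <- max(abs(v0[i]), 1) * 1e-6
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    yp <- model$fn(vp)
    ym <- model$fn(vm)
    if (any(!is.finite(yp)) || any(!is.finite(ym))) {
      stop("model output not finite when perturbing input `", inp$name[i],
           "`", call. = FALSE)
    }
    sens[i, ] <- (yp - ym) / (2 * h)
  }

  terms <- purrr::map_dfr(seq_len(n_out), function(j) {
    contrib <- (sens[, j] * ueff)^2
    uc2 <- sum(contrib)
    tibble::tibble(output = model$output_names[j], term = inp$name,
                   value = inp$value, u = inp$u, u_eff = ueff,
                   c_i = sens[, j], contribution = contrib,
                   index = if (uc2 > 0) contrib / uc2 else 0)
  })
  combined <- purrr::map_dfr(seq_len(n_out), function(j) {
    uc <- sqrt(sum((sens[, j] * ueff)^2))
    tibble::tibble(output = model$output_names[j], estimate = unname(y0[j]),
                   u_c = uc, k = k, U = k * uc)
  })
  structure(list(terms = terms, combined = combined, k = k),
            class = "gum_budget")
}

#' @export
print.gum_budget <- function(x, ...) {
  cat("<gum_budget>\n")
  print(x$combined)
  invisible(x)
}

#' @rdname gum_budget
#' @param x A `gum_budget`.
#' @param ... Unused.
#' @export
tidy.gum_budget <- function(x, ...) x$terms

#' @rdname gum_budget
#' @export
glance.gum_budget <- function(x, ...) x$combined

#' Monte Carlo uncertainty evaluation
#'
#' Draws every model input independently from a Gaussian centred at its value
#' and evaluates the model per draw (for the standard-addition model this
#' re-fits the nested regression in every draw), then summarises each output
#' distribution by mean, standard deviation (n - 1), median and the empirical
#' 2.5/97.5 percentiles (linear-interpolation quantile convention,
#' [stats::quantile()] type 7).
#'
#' By default each input is drawn with its per-observation standard
#' uncertainty (`repeat_scaling = FALSE`); set `repeat_scaling = TRUE` to draw
#' with the standard error of the mean instead, as in [gum_budget()].
#'
#' Draws on which the model fails (an error, or a non-finite output) are
#' rejected and counted rather than clipped, preserving the shape of skewed
#' output distributions; more than 1% rejections raises a warning recorded in
#' the result.
#'
#' @param model A [model_spec()].
#' @param n_draws Number of draws (>= 100).
#' @param seed Integer seed; identical seed and `n_draws` give bit-identical
#'   results.
#' @param retain_samples Keep the draw-level output matrix (needed by
#'   [autoplot.mcs_result()]).
#' @param repeat_scaling Draw with `u/sqrt(n_repeats)` instead of `u`.
#' @return An object of class `"mcs_result"`: list with `summary` (tibble:
#'   `output`, `mean`, `sd`, `median`, `q2.5`, `q97.5`), `n_draws`,
#'   `n_rejected`, `seed`, `rejection_warning` and (optionally) `samples`.
#' @export
monte_carlo <- function(model, n_draws = 10000, seed = 42,
                        retain_samples = FALSE, repeat_scaling = FALSE) {
  stopifnot(inherits(model, "model_spec"))
  n_draws <- as.integer(n_draws)
  if (n_draws < 100L) stop("`n_draws` must be at least 100", call. = FALSE)
  inp <- model$inputs
  udraw <- if (repeat_scaling) inp$u / sqrt(inp$n_repeats) else inp$u

  set.seed(as.integer(seed))
  n_in <- nrow(inp)
  draws <- matrix(stats::rnorm(n_draws * n_in,
                               mean = rep(inp$value, each = n_draws),
                               sd = rep(udraw, each = n_draws)),
                  nrow = n_draws, ncol = n_in,
                  dimnames = list(NULL, inp$name))

  n_out <- length(model$output_names)
  if (!is.null(model$fn_matrix)) {
    out <- model$fn_matrix(draws)
    ok <- stats::complete.cases(out) & apply(is.finite(out), 1L, all)
  } else {
    out <- matrix(NA_real_, n_draws, n_out)
    for (d in seq_len(n_draws)) {
      y <- tryCatch(model$fn(draws[d, ]), error = function(e) NULL)
      if (!is.null(y) && all(is.finite(y))) out[d, ] <- y
    }
    ok <- stats::complete.cases(out)
  }
  n_rej <- sum(!ok)
  rej_warn <- n_rej > 0.01 * n_draws
  if (rej_warn) {
    warning(sprintf("%d of %d draws rejected (> 1%%)", n_rej, n_draws))
  }
  out <- out[ok, , drop = FALSE]
  colnames(out) <- model$output_names

  summ <- purrr::map_dfr(seq_len(n_out), function(j) {
    s <- out[, j]
    q <- stats::quantile(s, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(output = model$output_names[j], mean = mean(s),
                   sd = stats::sd(s), median = q[2], q2.5 = q[1],
                   q97.5 = q[3])
  })
  structure(list(summary = summ, n_draws = n_draws, n_rejected = n_rej,
                 seed = as.integer(seed), rejection_warning = rej_warn,
                 samples = if (retain_samples) out else NULL),
            class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat("<mcs_result> ", x$n_draws, " draws (", x$n_rejected,
      " rejected), seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname monte_carlo
#' @param x An `mcs_result`.
#' @param ... Unused.
#' @export
tidy.mcs_result <- function(x, ...) x$summary

#' @rdname monte_carlo
#' @export
glance.mcs_result <- function(x, ...) {
  tibble::tibble(n_draws = x$n_draws, n_rejected = x$n_rejected,
                 seed = x$seed, rejection_warning = x$rejection_warning)
}

#' Measurement model of an exact-matching double IDMS pair
#'
#' Wraps the ratio-of-ratios estimator of [emd_mass_fraction()] as a
#' [model_spec()] with the seven blend quantities as inputs and the sample
#' mass fraction `w_x` as output. Includes a vectorized evaluator, so
#' [monte_carlo()] handles draw counts up to 10^6 quickly.
#'
#' @param pair An [emd_pair()].
#' @return A [model_spec()].
#' @examples
#' glance(gum_budget(emd_model(mel_pt_emd_pair())))
#' @export
emd_model <- function(pair) {
  stopifnot(inherits(pair, "emd_pair"))
  model_spec(
    inputs = pair,
    fn = function(v) c(w_x = emd_eval(v)),
    output_names = "w_x",
    fn_matrix = function(m) {
      bad <- m[, "m_x"] <= 0 | m[, "m_y"] <= 0 | m[, "m_zc"] <= 0 |
        m[, "m_yc"] <= 0 | m[, "r_b"] <= 0 | m[, "r_bc"] <= 0
      wx <- m[, "w_zc"] * (m[, "m_y"] / m[, "m_x"]) *
        (m[, "m_zc"] / m[, "m_yc"]) * (m[, "r_b"] / m[, "r_bc"])
      wx[bad] <- NA_real_
      matrix(wx, ncol = 1, dimnames = list(NULL, "w_x"))
    }
  )
}

#' Measurement model of a standard-addition series
#'
#' Builds the nested-regression measurement model of an MSA-IDMS experiment:
#' the inputs are every blend mass, every observed signal ratio and the
#' reference mass fraction `w_z`; the model function re-linearizes the series,
#' re-fits the ordinary least-squares line and returns `a0`, `a1`, `a0/a1`
#' and `w_x = (a0/a1) w_z`. Under [monte_carlo()] the regression is therefore
#' re-fitted for every draw. Draws with slope `a1 <= 0` carry no addition
#' signal and are rejected.
#'
#' @param series An [addition_series()].
#' @return A [model_spec()] with outputs `a0`, `a1`, `a0_over_a1`, `w_x`.
#' @examples
#' mcs <- monte_carlo(msa_model(mel_pt_series()), n_draws = 1000, seed = 1)
#' tidy(mcs)
#' @export
msa_model <- function(series) {
  stopifnot(inherits(series, "addition_series"))
  b <- series$blends
  nb <- nrow(b)
  iso <- series$isotopes
  inputs <- tibble::tibble(
    name = c(paste0("m_x_", b$blend_id), paste0("m_y_", b$blend_id),
             paste0("m_z_", b$blend_id), paste0("r_", b$blend_id), "w_z"),
    value = c(b$m_x, b$m_y, b$m_z, b$r_obs, series$w_z$value),
    u = c(b$u_m_x, b$u_m_y, b$u_m_z, b$u_r_obs, series$w_z$u),
    n_repeats = c(rep(1L, 3L * nb), b$n_repeats, series$w_z$n_repeats)
  )
  ix <- seq_len(nb); iy <- nb + ix; iz <- 2L * nb + ix; ir <- 3L * nb + ix
  iw <- 4L * nb + 1L
  fn <- function(v) {
    m_x <- v[ix]; m_y <- v[iy]; m_z <- v[iz]; r <- v[ir]
    if (any(m_x <= 0 | m_y <= 0 | r <= 0)) stop("invalid draw")
    x <- m_z / m_x
    y <- if (is.null(iso)) {
      (m_y / m_x) * r
    } else {
      r_inv <- 1 / r
      den <- r_inv * iso$x_x1 - iso$x_x2
      if (any(den <= 0)) stop("invalid draw")
      (m_y / m_x) * (iso$x_y2 - r_inv * iso$x_y1) / den
    }
    cf <- stats::lm.fit(cbind(1, x), y)$coefficients
    a0 <- cf[[1]]; a1 <- cf[[2]]
    if (!is.finite(a1) || a1 <= 0) stop("no addition signal in draw")
    c(a0 = a0, a1 = a1, a0_over_a1 = a0 / a1, w_x = a0 / a1 * v[iw])
  }
  model_spec(inputs, fn,
             output_names = c("a0", "a1", "a0_over_a1", "w_x"))
}
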