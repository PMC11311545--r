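#' One-sample t-test against a target value
#'
#' Validation experiments built from a single stock solution have a known
#' target (w_X/w_Z = 1); this test compares the mean of repeated results to
#' that target. The statistic is \eqn{t = (\bar{x} - \mu_0)/(s/\sqrt{n})},
#' compared two-sided against the `alpha` quantile of the t distribution.
#'
#' @param values Numeric vector of results (length >= 2).
#' @param target Target value (default 1).
#' @param alpha Quantile at which the critical value is taken (default 0.975,
#'   i.e. a two-sided 5% test).
#' @param dof_override Degrees of freedom for the critical value; defaults to
#'   `length(values) - 1`.
#' @return One-row tibble: `n`, `mean`, `sd`, `t`, `dof`, `t_crit`,
#'   `p_value`, `pass` (`|t| < t_crit`). A zero sd with mean != target yields
#'   an infinite t and `pass = FALSE`.
#' @examples
#' target_ttest(c(1.01, 0.99, 1.02, 1.00), target = 1)
#' @export
target_ttest <- function(values, target = 1, alpha = 0.975,
                         dof_override = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  dof <- dof_override %||% (n - 1L)
  t_crit <- stats::qt(alpha, df = dof)
  if (s == 0) {
    t <- if (m == target) 0 else Inf * sign(m - target)
  } else {
    t <- (m - target) / (s / sqrt(n))
  }
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df = dof) else 0
  tibble::tibble(n = n, mean = m, sd = s, t = t, dof = dof, t_crit = t_crit,
                 p_value = p, pass = abs(t) < t_crit)
}

#' Bias and uncertainty components from replicate structure
#'
#' Separates the dispersion of repeated target-ratio results (w_X/w_Z, target
#' 1) into an instrument component and a preparation component: the pooled
#' within-set standard deviation of repeated measurements of the same blend
#' set estimates u(inst); the standard deviation of the set means estimates
#' the combined u(inst + prep), since re-preparing the whole set re-draws the
#' preparation errors. The preparation component alone is recovered as
#' \eqn{u(prep)^2 = \max(0, s^2_{between} - s^2_{within}/\bar{n})}; a negative
#' raw estimate is truncated to zero and flagged.
#'
#' @param data A data frame of results.
#' @param value Column holding the measured w_X/w_Z values (tidy-eval).
#' @param set Column identifying the preparation set each value belongs to
#'   (tidy-eval).
#' @return One-row tibble: `bias` (mean deviation from 1), `u_inst`,
#'   `u_inst_prep` (NA with a single set), `u_prep`, `n_sets`, `truncated`.
#' @examples
#' d <- data.frame(set = 1, w = c(1.003, 1.004, 1.005))
#' bias_report(d, w, set)
#' @export
bias_report <- function(data, value, set) {
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(set), data)
  stopifnot(is.numeric(v), length(v) == length(g), length(v) >= 2L)
  sets <- split(v, g)
  n_sets <- length(sets)
  n_i <- lengths(sets)
  # pooled within-set variance over sets with >= 2 members
  rep_sets <- sets[n_i >= 2L]
  if (length(rep_sets)) {
    ssq <- sum(vapply(rep_sets, function(x) sum((x - mean(x))^2), numeric(1)))
    dof <- sum(lengths(rep_sets) - 1L)
    var_within <- ssq / dof
  } else {
    var_within <- NA_real_
  }
  set_means <- vapply(sets, mean, numeric(1))
  if (n_sets >= 2L) {
    var_between <- stats::var(set_means)
    u_inst_prep <- sqrt(var_between)
  } else {
    var_between <- NA_real_
    u_inst_prep <- NA_real_
  }
  truncated <- FALSE
  u_prep <- NA_real_
  if (n_sets >= 2L && !is.na(var_within)) {
    raw <- var_between - var_within / mean(n_i)
    truncated <- raw < 0
    u_prep <- sqrt(max(0, raw))
  }
  tibble::tibble(bias = mean(v) - 1,
                 u_inst = if (is.na(var_within)) NA_real_ else sqrt(var_within),
                 u_inst_prep = u_inst_prep, u_prep = u_prep,
                 n_sets = n_sets, truncated = truncated)
}

#' Response linearity of the isotopologue ratio
#'
#' IDMS requires the measured area ratio to respond linearly to the
#' gravimetric mass ratio: a straight line through the origin, with r^2 above
#' a fixed threshold. The intercept is fitted freely and reported; passing
#' through the origin is asserted as `|intercept| < 3 se(intercept)`, not
#' imposed.
#'
#' @param mass_ratios,area_ratios Equal-length numeric vectors (n >= 3).
#' @param r2_min Linearity acceptance threshold on r^2.
#' @return One-row tibble: `slope`, `intercept`, `se_intercept`, `r2`,
#'   `pass` (`r2 > r2_min`), `origin_consistent`.
#' @examples
#' linearity(1:5, 2 * (1:5) + rnorm(5, 0, 1e-4))
#' @export
linearity <- function(mass_ratios, area_ratios, r2_min = 0.999) {
  stopifnot(is.numeric(mass_ratios), is.numeric(area_ratios),
            length(mass_ratios) == length(area_ratios),
            length(mass_ratios) >= 3L)
  if (length(unique(mass_ratios)) < 2L) {
    stop("singular design: mass ratios are all identical", call. = FALSE)
  }
  fit <- stats::lm(area_ratios ~ mass_ratios)
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(sm)
  tibble::tibble(slope = cf["mass_ratios", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 se_intercept = cf["(Intercept)", "Std. Error"],
                 r2 = sm$r.squared,
                 pass = sm$r.squared > r2_min,
                 origin_consistent = abs(cf["(Intercept)", "Estimate"]) <
                   3 * cf["(Intercept)", "Std. Error"])
}
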