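#' Scenario for a synthetic standard-addition experiment
#'
#' Describes a gravimetric IDMS experiment well enough to simulate it:
#' true analyte content, reference and spike solutions, the target blend
#' design, and the noise structure of balance and instrument. Defaults mirror
#' a typical matrix experiment: weighing repeatability of 0.1% relative,
#' signal-ratio repeatability of 2% relative, no drift, no instrument bias.
#'
#' @param true_w_x True analyte mass fraction of the simulated sample (mg/kg).
#' @param w_z Mass fraction of the reference solution (mg/kg); also accepts
#'   an [uq()].
#' @param blend_design Data frame with columns `m_x`, `m_y`, `m_z`: target
#'   masses (mg) of sample, spike and reference per blend. The default
#'   follows the matrix design used throughout: constant ~500 mg sample,
#'   ~100 mg spike, reference additions 0/50/100/150 mg.
#' @param w_y Mass fraction of the analyte's labeled isotopologue in the
#'   spike solution (mg/kg). `NULL` (default) picks the value that matches
#'   the binary blend's signal ratio to 1, the matched design.
#' @param weighing_rsd Relative standard deviation of each weighing.
#' @param ratio_rsd Relative standard deviation of a single signal-ratio
#'   measurement (typical instrument repeatability 0.02-0.03).
#' @param f_inst Multiplicative instrumental bias on every measured ratio.
#' @param drift_per_injection Relative linear drift per injection; injections
#'   run through the whole blend sequence once per repeat.
#' @param n_ratio_repeats Repeat injections per blend.
#' @param seed Integer seed; simulation is deterministic given the scenario.
#' @return An object of class `"simulation_scenario"`.
#' @examples
#' sc <- simulation_scenario(true_w_x = 12.4, w_z = 10.08, seed = 1)
#' msa_fit(simulate_series(sc))
#' @export
simulation_scenario <- function(true_w_x, w_z,
                                blend_design = default_blend_design(),
                                w_y = NULL,
                                weighing_rsd = 1e-3, ratio_rsd = 0.02,
                                f_inst = 1, drift_per_injection = 0,
                                n_ratio_repeats = 3L, seed = 42L) {
  stopifnot(is.numeric(true_w_x), true_w_x > 0)
  stopifnot(is.data.frame(blend_design),
            all(c("m_x", "m_y", "m_z") %in% names(blend_design)))
  if (!any(blend_design$m_z > 0)) {
    stop("blend design needs at least one ternary blend (m_z > 0)",
         call. = FALSE)
  }
  if (!any(blend_design$m_z == 0)) {
    stop("blend design needs a binary blend (m_z = 0)", call. = FALSE)
  }
  stopifnot(weighing_rsd >= 0, ratio_rsd >= 0, f_inst > 0)
  if (is.null(w_y)) {
    b1 <- which(blend_design$m_z == 0)[1]
    w_y <- true_w_x * blend_design$m_x[b1] / blend_design$m_y[b1]
  }
  structure(list(true_w_x = true_w_x, w_z = as_uq(w_z), w_y = w_y,
                 blend_design = tibble::as_tibble(blend_design),
                 weighing_rsd = weighing_rsd, ratio_rsd = ratio_rsd,
                 f_inst = f_inst, drift_per_injection = drift_per_injection,
                 n_ratio_repeats = as.integer(n_ratio_repeats),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' @rdname simulation_scenario
#' @param n_blends Number of blends; reference additions are spread evenly
#'   from 0 to `m_z_max`.
#' @param m_x,m_y,m_z_max Target masses (mg).
#' @export
default_blend_design <- function(n_blends = 4, m_x = 500, m_y = 100,
                                 m_z_max = 150) {
  tibble::tibble(m_x = rep(m_x, n_blends), m_y = rep(m_y, n_blends),
                 m_z = seq(0, m_z_max, length.out = n_blends))
}

#' @rdname simulation_scenario
#' @details `matched_blend_design()` grows the spike in step with the
#'   reference addition (`m_y = m_x + m_z`), which keeps the signal ratios of
#'   all blends near-constant when sample and reference have similar content
#'   -- the matched preparation the standard-addition design calls for.
#'   `default_blend_design()` keeps the spike constant, as typical for a
#'   matrix sample measured against a more concentrated spike.
#' @export
matched_blend_design <- function(n_blends = 4, m_x = 50, m_z_max = 150) {
  m_z <- seq(0, m_z_max, length.out = n_blends)
  tibble::tibble(m_x = rep(m_x, n_blends), m_y = m_x + m_z, m_z = m_z)
}

#' Simulate a standard-addition blend series
#'
#' Realises one experiment from a [simulation_scenario()]: target masses
#' acquire Gaussian weighing noise; the ideal signal ratio of each blend is
#' the analyte-to-label mass ratio
#' \eqn{r = (w_X m_x + w_Z m_z)/(w_Y m_y)}{r = (w_X m_x + w_Z m_z)/(w_Y m_y)}
#' (the inversion of the linear standard-addition relation at the true
#' content); each injection observes
#' `ideal * f_inst * (1 + drift * injection_index) + N(0, ratio_rsd * ideal)`,
#' and repeats are averaged with their standard deviation recorded.
#' Injections run through the full blend sequence once per repeat, so drift
#' accumulates across the run as it would in a real sequence.
#'
#' @param scenario A [simulation_scenario()].
#' @param record_u How the ratio uncertainty column of the generated series
#'   is filled: `"empirical"` (default) records the standard deviation of the
#'   repeat injections, as an analyst would; `"nominal"` records the
#'   scenario's true per-observation dispersion `ratio_rsd * r_obs`, useful
#'   for studies that should isolate the propagation machinery from the
#'   noise of few-repeat sd estimates.
#' @return An [addition_series()]; with a single repeat, `u_r_obs` is always
#'   the nominal `ratio_rsd * r_obs` since no empirical spread exists.
#' @export
simulate_series <- function(scenario, record_u = c("empirical", "nominal")) {
  record_u <- match.arg(record_u)
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  d <- scenario$blend_design
  nb <- nrow(d)
  nrep <- scenario$n_ratio_repeats
  m_x <- stats::rnorm(nb, d$m_x, scenario$weighing_rsd * d$m_x)
  m_y <- stats::rnorm(nb, d$m_y, scenario$weighing_rsd * d$m_y)
  m_z <- ifelse(d$m_z > 0,
                stats::rnorm(nb, d$m_z, scenario$weighing_rsd * d$m_z), 0)
  ideal <- (scenario$true_w_x * m_x + scenario$w_z$value * m_z) /
    (scenario$w_y * m_y)
  r_mat <- matrix(NA_real_, nb, nrep)
  for (k in seq_len(nrep)) {
    inj <- (k - 1L) * nb + seq_len(nb)
    drift_fac <- 1 + scenario$drift_per_injection * inj
    r_mat[, k] <- ideal * scenario$f_inst * drift_fac +
      stats::rnorm(nb, 0, scenario$ratio_rsd * ideal)
  }
  r_obs <- rowMeans(r_mat)
  u_r <- if (nrep >= 2L && record_u == "empirical")
    apply(r_mat, 1L, stats::sd) else scenario$ratio_rsd * r_obs
  addition_series(
    tibble::tibble(blend_id = as.character(seq_len(nb)),
                   m_x = m_x, u_m_x = scenario$weighing_rsd * m_x,
                   m_y = m_y, u_m_y = scenario$weighing_rsd * m_y,
                   m_z = m_z, u_m_z = scenario$weighing_rsd * m_z,
                   r_obs = r_obs, u_r_obs = u_r, n_repeats = nrep),
    w_z = scenario$w_z
  )
}

#' Simulate a matched exact-matching double IDMS pair
#'
#' Generates a sample blend and a calibration blend from the same noise model
#' as [simulate_series()], matched so both signal ratios sit near 1. The
#' calibration blend mixes the reference solution (content `w_z`) with spike;
#' the sample blend mixes the simulated sample (content `true_w_x`) with
#' spike.
#'
#' @param scenario A [simulation_scenario()]; the first binary row of its
#'   blend design provides the sample/spike target masses.
#' @return An [emd_pair()].
#' @export
simulate_emd_pair <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 1L)
  d <- scenario$blend_design
  b1 <- which(d$m_z == 0)[1]
  tm_x <- d$m_x[b1]; tm_y <- d$m_y[b1]
  # calibration blend matched: m_zc chosen so w_z*m_zc ~= true_w_x*m_x
  tm_zc <- scenario$true_w_x * tm_x / scenario$w_z$value
  rsd_w <- scenario$weighing_rsd
  m_x <- stats::rnorm(1, tm_x, rsd_w * tm_x)
  m_y <- stats::rnorm(1, tm_y, rsd_w * tm_y)
  m_zc <- stats::rnorm(1, tm_zc, rsd_w * tm_zc)
  m_yc <- stats::rnorm(1, tm_y, rsd_w * tm_y)
  r_b_ideal <- scenario$true_w_x * m_x / (scenario$w_y * m_y)
  r_bc_ideal <- scenario$w_z$value * m_zc / (scenario$w_y * m_yc)
  r_b <- scenario$f_inst *
    (r_b_ideal + stats::rnorm(1, 0, scenario$ratio_rsd * r_b_ideal))
  r_bc <- scenario$f_inst *
    (r_bc_ideal + stats::rnorm(1, 0, scenario$ratio_rsd * r_bc_ideal))
  emd_pair(m_x = uq(m_x, rsd_w * m_x), m_y = uq(m_y, rsd_w * m_y),
           m_zc = uq(m_zc, rsd_w * m_zc), m_yc = uq(m_yc, rsd_w * m_yc),
           r_b = uq(r_b, scenario$ratio_rsd * r_b),
           r_bc = uq(r_bc, scenario$ratio_rsd * r_bc),
           w_zc = scenario$w_z)
}

#' Bias of recovered content under instrumental drift
#'
#' Replicates simulated experiments over a grid of drift magnitudes and
#' design sizes and reports the mean signed bias of the recovered content.
#' Standard-addition sequences are long, so drift acts like a trend across
#' the fitted points and biases slope and intercept; denser designs and more
#' repeats dilute it.
#'
#' @param grid Data frame with columns `drift` (relative drift per
#'   injection), `n_blends` and `n_repeats`.
#' @param true_w_x,w_z True sample content and reference content (mg/kg).
#' @param n_replicates Simulated experiments per grid cell.
#' @param ratio_rsd,weighing_rsd Noise levels passed to the scenario.
#' @param seed Integer seed.
#' @return The grid with columns `mean_bias` (mean of
#'   `w_x_hat/true_w_x - 1`), `se_bias` (Monte Carlo standard error) and
#'   `n_replicates` appended.
#' @export
drift_study <- function(grid, true_w_x = 12.4, w_z = 10.08,
                        n_replicates = 200, ratio_rsd = 0.02,
                        weighing_rsd = 1e-3, seed = 42L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("drift", "n_blends", "n_repeats") %in% names(grid)))
  purrr::pmap_dfr(grid, function(drift, n_blends, n_repeats) {
    bias <- vapply(seq_len(n_replicates), function(rep) {
      sc <- simulation_scenario(
        true_w_x = true_w_x, w_z = w_z,
        blend_design = matched_blend_design(n_blends = n_blends),
        weighing_rsd = weighing_rsd, ratio_rsd = ratio_rsd,
        drift_per_injection = drift, n_ratio_repeats = n_repeats,
        seed = seed + 7919L * rep + 104729L * n_blends + 1299709L * n_repeats
      )
      msa_fit(simulate_series(sc))$w_x / true_w_x - 1
    }, numeric(1))
    tibble::tibble(drift = drift, n_blends = n_blends, n_repeats = n_repeats,
                   mean_bias = mean(bias),
                   se_bias = stats::sd(bias) / sqrt(n_replicates),
                   n_replicates = n_replicates)
  })
}
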