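#' Exact-matching double IDMS blend pair
#'
#' Bundles the gravimetric masses and observed signal ratios of one sample
#' blend (sample X + isotopically labeled spike Y) and one calibration blend
#' (primary standard Z + spike Y), together with the mass fraction of the
#' analyte in the primary standard solution. This is the complete input of the
#' double-IDMS ratio-of-ratios estimator, see [emd_mass_fraction()].
#'
#' Signal ratios are stored as A1/A2: the signal of the analyte with natural
#' isotopic composition over the signal of its labeled isotopologue.
#'
#' @param m_x Mass of sample X in the sample blend (mg).
#' @param m_y Mass of spike Y in the sample blend (mg).
#' @param m_zc Mass of primary standard solution Z in the calibration blend (mg).
#' @param m_yc Mass of spike Y in the calibration blend (mg).
#' @param r_b Observed signal ratio A1/A2 of the sample blend.
#' @param r_bc Observed signal ratio A1/A2 of the calibration blend.
#' @param w_zc Mass fraction of the analyte in the primary standard solution
#'   (mg/kg).
#'
#' All arguments are [uq()] objects (bare numerics are promoted with u = 0).
#'
#' @return An object of class `"emd_pair"`.
#' @examples
#' pair <- emd_pair(m_x = uq(500, 0.144), m_y = uq(594, 0.229),
#'                  m_zc = uq(595, 0.172), m_yc = uq(598, 0.173),
#'                  r_b = uq(1.02, 0.025), r_bc = uq(0.97, 0.030),
#'                  w_zc = uq(10.0, 0.14))
#' emd_mass_fraction(pair)
#' @export
emd_pair <- function(m_x, m_y, m_zc, m_yc, r_b, r_bc, w_zc) {
  qs <- lapply(list(m_x = m_x, m_y = m_y, m_zc = m_zc, m_yc = m_yc,
                    r_b = r_b, r_bc = r_bc, w_zc = w_zc), as_uq)
  pos <- c("m_x", "m_y", "m_zc", "m_yc", "r_b", "r_bc")
  for (nm in pos) {
    if (qs[[nm]]$value <= 0) {
      stop("`", nm, "` must be strictly positive", call. = FALSE)
    }
  }
  if (qs$w_zc$value < 0) stop("`w_zc` must be non-negative", call. = FALSE)
  structure(qs, class = "emd_pair")
}

#' @export
print.emd_pair <- function(x, ...) {
  cat("<emd_pair>\n")
  print(as_quantity_tbl(x))
  invisible(x)
}

# long tibble view of a set of named uq's
as_quantity_tbl <- function(x) {
  tibble::tibble(
    quantity = names(x),
    value = vapply(x, function(q) q$value, numeric(1)),
    u = vapply(x, function(q) q$u, numeric(1)),
    n_repeats = vapply(x, function(q) q$n_repeats, integer(1))
  )
}

#' Double-IDMS mass fraction (exact matching)
#'
#' Point value of the analyte mass fraction in the sample by the
#' ratio-of-ratios double-IDMS estimator
#' \deqn{w_X = w_{Zc} \cdot \frac{m_Y}{m_X} \cdot \frac{m_{Zc}}{m_{Yc}} \cdot
#'   \frac{R_B}{R_{Bc}}}{w_X = w_Zc (m_Y/m_X)(m_Zc/m_Yc)(R_B/R_Bc)}
#' Any multiplicative instrumental bias common to both measured ratios cancels
#' in \eqn{R_B/R_{Bc}}, which is what the exact-matching design exploits.
#' The factors are evaluated in exactly this grouping.
#'
#' @param pair An [emd_pair()].
#' @return The mass fraction of the analyte in the sample (mg/kg), scalar.
#' @export
emd_mass_fraction <- function(pair) {
  stopifnot(inherits(pair, "emd_pair"))
  v <- vapply(pair, function(q) q$value, numeric(1))
  emd_eval(v)
}

# Plain-vector kernel shared with the uncertainty engine; names as emd_pair.
emd_eval <- function(v) {
  if (any(v[c("m_x", "m_y", "m_zc", "m_yc", "r_b", "r_bc")] <= 0)) {
    stop("masses and signal ratios must be strictly positive", call. = FALSE)
  }
  v[["w_zc"]] * (v[["m_y"]] / v[["m_x"]]) * (v[["m_zc"]] / v[["m_yc"]]) *
    (v[["r_b"]] / v[["r_bc"]])
}

#' Exact-matching window check
#'
#' Flags the two measured blend ratios against the matching window (default
#' 0.95 to 1.15) inside which the exact-matching design keeps the measurement
#' uncertainty and instrumental bias minimal, and reports how far the ratio of
#' ratios R_B/R_Bc deviates from unity. A failed window check never raises:
#' it is quality information, not a computational error.
#'
#' @param pair An [emd_pair()].
#' @param window_low,window_high Bounds of the matching window.
#' @return A tibble with one row per check: columns `quantity`, `value`,
#'   `in_window` (NA for the ratio of ratios, which has no window) and
#'   `deviation_from_unity` (NA for the two blend ratios).
#' @export
emd_matching_check <- function(pair, window_low = 0.95, window_high = 1.15) {
  stopifnot(inherits(pair, "emd_pair"))
  if (window_low >= window_high) {
    stop("`window_low` must be below `window_high`", call. = FALSE)
  }
  r_b <- pair$r_b$value
  r_bc <- pair$r_bc$value
  rr <- r_b / r_bc
  tibble::tibble(
    quantity = c("r_b", "r_bc", "r_b/r_bc"),
    value = c(r_b, r_bc, rr),
    in_window = c(r_b >= window_low & r_b <= window_high,
                  r_bc >= window_low & r_bc <= window_high,
                  NA),
    deviation_from_unity = c(NA, NA, rr - 1)
  )
}

#' Pair a bracketed measurement sequence
#'
#' In an exact-matching run the sample blend (label `"B"`) and calibration
#' blend (label `"Bc"`) are injected alternately; every subsequent pair of
#' injections yields one ratio of ratios R_B/R_Bc. The sequence may start with
#' either label. An odd trailing measurement is dropped with a warning.
#'
#' @param measurements A data frame with columns `label` (`"B"` or `"Bc"`) and
#'   `ratio` (measured signal ratio A1/A2, > 0), in injection order.
#' @return A tibble with one row per pair: `pair`, `r_b`, `r_bc`, `ratio`
#'   (= r_b/r_bc). The mean and sd over pairs are attached as attributes
#'   `mean` and `sd` (sd is 0 for a single pair).
#' @examples
#' seqn <- data.frame(label = c("B", "Bc", "B", "Bc"),
#'                    ratio = c(1.02, 0.97, 1.03, 0.98))
#' bracketed_pairs(seqn)
#' @export
bracketed_pairs <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("label", "ratio") %in% names(measurements)))
  lab <- as.character(measurements$label)
  ratio <- measurements$ratio
  n <- length(lab)
  if (n < 2L) stop("need at least two measurements", call. = FALSE)
  if (!all(lab %in% c("B", "Bc"))) {
    stop("labels must be \"B\" or \"Bc\"", call. = FALSE)
  }
  if (any(ratio <= 0)) stop("ratios must be strictly positive", call. = FALSE)
  same <- which(lab[-1] == lab[-n])
  if (length(same)) {
    stop("measurements ", same[1], " and ", same[1] + 1L,
         " carry the same label; a bracketed sequence must alternate",
         call. = FALSE)
  }
  if (n %% 2L == 1L) {
    warning("odd trailing measurement at position ", n, " dropped")
    lab <- lab[-n]
    ratio <- ratio[-n]
    n <- n - 1L
  }
  first <- lab[seq(1L, n, by = 2L)]
  r1 <- ratio[seq(1L, n, by = 2L)]
  r2 <- ratio[seq(2L, n, by = 2L)]
  r_b <- ifelse(first == "B", r1, r2)
  r_bc <- ifelse(first == "B", r2, r1)
  out <- tibble::tibble(pair = seq_along(r_b), r_b = r_b, r_bc = r_bc,
                        ratio = r_b / r_bc)
  attr(out, "mean") <- mean(out$ratio)
  attr(out, "sd") <- if (nrow(out) > 1L) stats::sd(out$ratio) else 0
  out
}
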