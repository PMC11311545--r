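#' Read a blend table
#'
#' Reads the plain CSV dialect used for blend tables. Two kinds exist:
#'
#' * `kind = "msa"`: one row per blend with columns `blend_id`, `m_x_mg`,
#'   `u_m_x_mg`, `m_y_mg`, `u_m_y_mg`, `m_z_mg`, `u_m_z_mg`, `r_obs`,
#'   `u_r_obs`, `n_repeats`.
#' * `kind = "emd"`: one row per quantity with columns `role`
#'   (`sample_blend`, `calib_blend` or `reference`), `quantity` (`m_x`,
#'   `m_y`, `m_zc`, `m_yc`, `r_b`, `r_bc`, `w_zc`), `value`, `u`,
#'   `n_repeats`.
#'
#' Files are UTF-8 with a decimal point; masses in mg, mass fractions in
#' mg/kg, ratios dimensionless.
#'
#' @param path Path to the CSV file.
#' @param kind `"msa"` or `"emd"`.
#' @param w_z For `kind = "msa"` only: the reference-solution mass fraction
#'   as an [uq()] or numeric. When supplied, the fully assembled
#'   [addition_series()] is returned; otherwise the validated blends tibble
#'   (the reference content is not part of the per-blend table).
#' @return For `"emd"`, an [emd_pair()]. For `"msa"`, a blends tibble or an
#'   [addition_series()] (see `w_z`).
#' @examples
#' read_blend_table(idms_example("msa_mel_pt.csv"), "msa", w_z = uq(10.08, 0.02))
#' @export
read_blend_table <- function(path, kind = c("msa", "emd"), w_z = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(tbl) == 0L) stop("empty blend table: ", path, call. = FALSE)

  if (kind == "msa") {
    need <- c("blend_id", "m_x_mg", "u_m_x_mg", "m_y_mg", "u_m_y_mg",
              "m_z_mg", "u_m_z_mg", "r_obs", "u_r_obs", "n_repeats")
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    bad <- which(tbl$m_x_mg <= 0 | tbl$m_y_mg <= 0 | tbl$m_z_mg < 0)
    if (length(bad)) {
      stop("non-positive mass in row ", bad[1], call. = FALSE)
    }
    blends <- tibble::tibble(
      blend_id = as.character(tbl$blend_id),
      m_x = tbl$m_x_mg, u_m_x = tbl$u_m_x_mg,
      m_y = tbl$m_y_mg, u_m_y = tbl$u_m_y_mg,
      m_z = tbl$m_z_mg, u_m_z = tbl$u_m_z_mg,
      r_obs = tbl$r_obs, u_r_obs = tbl$u_r_obs,
      n_repeats = as.integer(tbl$n_repeats)
    )
    if (is.null(w_z)) return(blends)
    return(addition_series(blends, w_z = w_z))
  }

  need <- c("role", "quantity", "value", "u", "n_repeats")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  want <- c("m_x", "m_y", "m_zc", "m_yc", "r_b", "r_bc", "w_zc")
  miss_q <- setdiff(want, tbl$quantity)
  if (length(miss_q)) {
    stop("missing quantity row(s): ", paste(miss_q, collapse = ", "),
         call. = FALSE)
  }
  q <- function(nm) {
    row <- tbl[tbl$quantity == nm, ][1, ]
    uq(row$value, row$u, row$n_repeats)
  }
  emd_pair(m_x = q("m_x"), m_y = q("m_y"), m_zc = q("m_zc"),
           m_yc = q("m_yc"), r_b = q("r_b"), r_bc = q("r_bc"),
           w_zc = q("w_zc"))
}

#' Write a blend table
#'
#' Serializes an [addition_series()] (or a blends tibble) or an [emd_pair()]
#' to the CSV dialect of [read_blend_table()]. A written file parses back to
#' an identical object.
#'
#' @param x An `addition_series`, blends tibble, or `emd_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blend_table <- function(x, path) {
  if (inherits(x, "emd_pair")) {
    role <- c(m_x = "sample_blend", m_y = "sample_blend",
              m_zc = "calib_blend", m_yc = "calib_blend",
              r_b = "sample_blend", r_bc = "calib_blend",
              w_zc = "reference")
    tbl <- as_quantity_tbl(x)
    out <- tibble::tibble(role = unname(role[tbl$quantity]),
                          quantity = tbl$quantity, value = tbl$value,
                          u = tbl$u, n_repeats = tbl$n_repeats)
    readr::write_csv(out, path)
    return(invisible(path))
  }
  b <- if (inherits(x, "addition_series")) x$blends else tibble::as_tibble(x)
  out <- tibble::tibble(blend_id = b$blend_id,
                        m_x_mg = b$m_x, u_m_x_mg = b$u_m_x,
                        m_y_mg = b$m_y, u_m_y_mg = b$u_m_y,
                        m_z_mg = b$m_z, u_m_z_mg = b$u_m_z,
                        r_obs = b$r_obs, u_r_obs = b$u_r_obs,
                        n_repeats = b$n_repeats)
  readr::write_csv(out, path)
  invisible(path)
}

#' Paths to the shipped worked-example blend tables
#'
#' The package ships four blend tables from a melamine/cyanuric-acid
#' measurement campaign on infant formula: one exact-matching double-IDMS
#' pair and three standard-addition series. `idms_example()` lists them;
#' `idms_example(name)` returns the full path.
#'
#' @param name File name of an example table, e.g. `"msa_mel_pt.csv"`.
#' @return A path, or the vector of available names when `name` is `NULL`.
#' @examples
#' idms_example()
#' @export
idms_example <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "idmsquant")))
  }
  p <- system.file("extdata", name, package = "idmsquant")
  if (p == "") stop("no example table named ", name, call. = FALSE)
  p
}

#' Worked-example data sets
#'
#' Ready-built objects for the shipped worked examples:
#'
#' * `mel_pt_emd_pair()`: exact-matching double-IDMS blend pair for melamine
#'   in a proficiency-test infant-formula sample (reference content
#'   10.0 mg/kg).
#' * `mel_solution_series()` / `cya_solution_series()`: standard-addition
#'   validation series of pure melamine / cyanuric-acid solutions where the
#'   sample and reference come from one stock, so the target for a0/a1 is 1;
#'   `w_z` is the dimensionless unit content. Ratios carry 3 repeats.
#' * `mel_pt_series()`: standard-addition series of melamine in the
#'   proficiency-test sample, reference solution 10.08 mg/kg (u = 0.020),
#'   ratios with a relative standard uncertainty of 2% from 2 repeats.
#'
#' @return An [emd_pair()] or [addition_series()].
#' @examples
#' emd_mass_fraction(mel_pt_emd_pair())
#' msa_fit(mel_pt_series())$w_x
#' @name worked_examples
NULL

#' @rdname worked_examples
#' @export
mel_pt_emd_pair <- function() {
  read_blend_table(idms_example("emd_mel_pt.csv"), kind = "emd")
}

#' @rdname worked_examples
#' @export
mel_solution_series <- function() {
  read_blend_table(idms_example("msa_mel_solution.csv"), kind = "msa",
                   w_z = uq(1, 0))
}

#' @rdname worked_examples
#' @export
cya_solution_series <- function() {
  read_blend_table(idms_example("msa_cya_solution.csv"), kind = "msa",
                   w_z = uq(1, 0))
}

#' @rdname worked_examples
#' @export
mel_pt_series <- function() {
  read_blend_table(idms_example("msa_mel_pt.csv"), kind = "msa",
                   w_z = uq(10.080, 0.020))
}

#' Budget table in conventional report columns
#'
#' Re-expresses a [gum_budget()] in the column layout customary in published
#' uncertainty budgets: relative sensitivity coefficients with the repeat
#' factor folded in (so a 3-repeat ratio shows c = 0.58), relative variance
#' contributions scaled by 1e5, and percentage indices.
#'
#' @param budget A [gum_budget()].
#' @param output Which model output to tabulate (default: the first).
#' @return A tibble with columns `Measurand`, `Mean`, `u`, `c_i`,
#'   `ci2_ur2_1e5`, `Index`.
#' @export
budget_report <- function(budget, output = NULL) {
  stopifnot(inherits(budget, "gum_budget"))
  output <- output %||% budget$combined$output[1]
  tm <- budget$terms[budget$terms$output == output, ]
  est <- budget$combined$estimate[budget$combined$output == output]
  c_rel <- tm$c_i * tm$value / est * (tm$u_eff / ifelse(tm$u > 0, tm$u, 1))
  tibble::tibble(Measurand = tm$term, Mean = tm$value, u = tm$u,
                 c_i = c_rel,
                 ci2_ur2_1e5 = 1e5 * tm$contribution / est^2,
                 Index = tm$index)
}
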