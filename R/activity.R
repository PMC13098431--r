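# Enzyme-kinetics arithmetic used alongside the ensemble analysis: specific
# activity from a linear product time course, fold changes between variants
# or substrates, and turnover numbers.

#' Specific activity from a product time course
#'
#' Ordinary least-squares slope of product concentration (mM) against time
#' (min) over the linear window, divided by the enzyme concentration
#' (mg/ml).  Because 1 mM = 1 umol/ml, the quotient is directly in
#' U/mg (1 U = 1 umol product per minute); the result is reported in mU/mg.
#'
#' @param time_min sampling times in minutes.
#' @param product_mM product concentrations in mM.
#' @param enzyme_mg_ml enzyme concentration in mg/ml (> 0).
#' @param window optional integer index range of the linear segment
#'   (default: all points).  At least 3 points are required.
#' @return A list of class `activity_result`: `slope` (mM/min),
#'   `specific_activity` (mU/mg), `enzyme_conc` (mg/ml), `r_squared`.
#' @export
specific_activity <- function(time_min, product_mM, enzyme_mg_ml,
                              window = NULL) {
  if (enzyme_mg_ml <= 0) stop("enzyme concentration must be positive",
                              call. = FALSE)
  if (length(time_min) != length(product_mM))
    stop("time and product vectors must have equal length", call. = FALSE)
  idx <- window %||% seq_along(time_min)
  if (length(idx) < 3L)
    stop("insufficient data: need at least 3 points in the linear window",
         call. = FALSE)
  fit <- stats::lm(product_mM[idx] ~ time_min[idx])
  slope <- unname(stats::coef(fit)[2L])
  structure(list(
    slope = slope,
    specific_activity = 1000 * slope / enzyme_mg_ml,
    enzyme_conc = enzyme_mg_ml,
    # summary.lm warns on an exactly linear time course; that case is fine
    r_squared = suppressWarnings(summary(fit)$r.squared)
  ), class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("slope %.4g mM/min at %.3g mg/ml -> %.4g mU/mg\n",
              x$slope, x$enzyme_conc, x$specific_activity))
  invisible(x)
}

#' Fold change between two activities
#'
#' Ratio `a / b` with a display value rounded to 2 significant figures, the
#' convention used when quoting "12-fold" style changes.  A zero or negative
#' denominator is below the detection convention and yields an error (report
#' such activities as not detectable instead of dividing).
#'
#' @param a,b activities in the same unit (e.g. mU/mg); `b > 0`.
#' @return List with `ratio` (exact) and `display` (2 significant figures).
#' @export
fold_change <- function(a, b) {
  if (!is.finite(b) || b <= 0)
    stop("fold change undefined: denominator activity is not detectable",
         call. = FALSE)
  ratio <- a / b
  list(ratio = ratio, display = signif(ratio, 2))
}

#' Turnover number from specific activity
#'
#' `k = specific activity x molar mass`: mU/mg is nmol min^-1 mg^-1, so
#' multiplying by the molar mass in g/mol and dividing by 1e6 gives min^-1.
#' The molar mass is an explicit input; it is never guessed from other data.
#'
#' @param specific_activity_mU_mg specific activity in mU/mg.
#' @param molar_mass_g_mol protein molar mass in g/mol.
#' @return Turnover number in min^-1.
#' @export
turnover_number <- function(specific_activity_mU_mg, molar_mass_g_mol) {
  if (molar_mass_g_mol <= 0) stop("molar mass must be positive",
                                  call. = FALSE)
  specific_activity_mU_mg * molar_mass_g_mol / 1e6
}
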