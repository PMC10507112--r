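#' Adhesion fraction
#'
#' Fraction of cells remaining adhered after washing, relative to the
#' total cell count of unwashed control wells. Counting noise can push the
#' ratio above 1; such values are reported raw with a warning.
#'
#' @param adhered Cell count recovered from washed wells.
#' @param control_total Cell count from unwashed control wells (> 0).
#' @return The adhered fraction (vectorised).
#' @examples
#' adhesion_fraction(50, 100)  # 0.5
#' @export
adhesion_fraction <- function(adhered, control_total) {
  if (any(adhered < 0)) abort("`adhered` must be non-negative.")
  if (any(control_total <= 0)) abort("`control_total` must be positive.")
  out <- adhered / control_total
  if (any(out > 1)) {
    warn("Adhesion fraction above 1 (counting noise); reported raw.")
  }
  out
}

#' Screen coverage (cells per guide)
#'
#' Cells per library guide, the planning number behind statements like
#' "about 500 cells per sgRNA" for 3e7 integrations over a 57,050-guide
#' library. Reported both raw and rounded to one significant figure.
#'
#' @param n_cells Number of cells with successful integrations.
#' @param library_size Number of guides in the library (> 0).
#' @return A tibble `coverage`, `coverage_reported` (1 significant figure).
#' @examples
#' screen_coverage(3e7, 57050)
#' @export
screen_coverage <- function(n_cells, library_size) {
  if (any(n_cells < 0)) abort("`n_cells` must be non-negative.")
  if (any(library_size <= 0)) abort("`library_size` must be positive.")
  cov <- n_cells / library_size
  tibble(coverage = cov, coverage_reported = signif(cov, 1))
}
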