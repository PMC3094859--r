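#' Canine intramyocardial injection reference tables
#'
#' Reference data from a 19-injection canine study of free
#' In-111-tropolone delivered into normal left-ventricular myocardium,
#' 9 injections epicardially (thoracotomy) and 10 endocardially
#' (catheter), shipped as plain-text fixtures.
#'
#' \code{canine_fit_table()} returns the per-dog biexponential washout
#' parameters: normalized amplitude percentages \code{a_pct},
#' \code{c_pct}, rate-constant magnitudes \code{b_per_hour},
#' \code{d_per_hour}, and the half-lives as printed in the study report
#' (\code{t_half_*_printed}; these were tabulated from rounded rates and
#' can differ from ln2/rate by ~1 h). Epicardial dog 3 washed out
#' monoexponentially and has NA short-component entries.
#'
#' \code{canine_hwb_table()} returns heart:wholebody percentages over the
#' six serial wholebody sessions of injection day (session 1 at 0 h,
#' session 6 at 5 h; intermediate sessions are ordinal, their exact times
#' were not recorded). Missing sessions are NA.
#'
#' @return data frames (see above).
#' @name canine_reference
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "spectac")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' @rdname canine_reference
#' @export
canine_fit_table <- function() {
  utils::read.csv(fixture_path("canine_biexp_fits.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname canine_reference
#' @export
canine_hwb_table <- function() {
  utils::read.csv(fixture_path("canine_hwb_ratios.csv"),
                  stringsAsFactors = FALSE)
}
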