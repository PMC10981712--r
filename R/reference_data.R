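#' Published summary statistics for the reference soil survey
#'
#' Per-element descriptive statistics (minimum, maximum, mean, standard
#' deviation, printed coefficient of variation) of the 84-sample asbestos-mine
#' soil survey that the packaged defaults emulate, together with the local
#' non-agricultural-land background values used as \eqn{C_0}. Units are
#' mg/kg dry soil. These printed statistics serve as calibration targets for
#' the synthetic generator and as inputs for desk-scale index calculations;
#' they are not a substitute for per-sample data.
#'
#' The background value printed for Hg (11.48 mg/kg) is implausibly high for
#' uncontaminated soil but is the value the survey's own ecological-risk
#' arithmetic uses, so it is reproduced as-is; override via
#' [reference_set()] if a different background is preferred.
#'
#' @return A data.frame with one row per element: `element`, `min`, `max`,
#'   `mean`, `sd`, `cv_printed`, `background`.
#' @seealso [source_material_stats()], [default_reference_set()]
#' @export
survey_reference_stats <- function() {
  data.frame(
    element = .DEFAULT_ELEMENTS,
    min  = c(1.29, 0.002, 0.04, 2.72, 24.91, 4.00, 16.58, 15.25),
    max  = c(206.10, 0.103, 0.29, 175.38, 1826.35, 117.74, 122.20, 1951.19),
    mean = c(21.79, 0.010, 0.09, 16.62, 580.04, 20.25, 41.72, 636.93),
    sd   = c(31.54, 0.011, 0.04, 18.30, 559.74, 13.82, 15.95, 632.68),
    cv_printed = c(1.45, 1.18, 0.38, 1.10, 0.97, 0.68, 0.38, 0.99),
    background = c(7.94, 11.48, 0.10, 14.67, 40.54, 15.23, 48.00, 18.53),
    stringsAsFactors = FALSE
  )
}

#' Published summary statistics for asbestos source materials
#'
#' Per-element descriptive statistics of the four sampled asbestos pollution
#' source materials (ore, tailings, finished products, dust) from the same
#' survey, mg/kg. The mean row is the default profile of the asbestos factor
#' in [default_source_model()]: a Cr/Ni-dominant signature
#' (Cr 1339.17, Ni 1788.33 mg/kg).
#'
#' @return A data.frame with one row per element: `element`, `min`, `max`,
#'   `mean`, `sd`, `cv_printed`.
#' @export
source_material_stats <- function() {
  data.frame(
    element = .DEFAULT_ELEMENTS,
    min  = c(8.87, 0.016, 0.038, 3.39, 890, 4, 13, 1600),
    max  = c(17.1, 0.022, 0.094, 13.2, 1560, 16, 20, 2000),
    mean = c(14.73, 0.02, 0.07, 6.23, 1339.17, 10.33, 13.33, 1788.33),
    sd   = c(2.10, 0.00, 0.02, 2.93, 218.50, 3.50, 2.29, 135.70),
    cv_printed = c(0.14, 0.10, 0.27, 0.47, 0.16, 0.34, 0.17, 0.08),
    stringsAsFactors = FALSE
  )
}
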