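#' Geo-accumulation index
#'
#' \eqn{I_{geo} = \log_2[C_i / (k \cdot C_0)]} per sample and element, with
#' the five-class grading: \eqn{I_{geo} \le 0} none; (0, 1] slight; (1, 2]
#' moderate; (2, 3] severe; > 3 extremely severe. Upper bounds are inclusive.
#' A positive index indicates enrichment beyond what lithogenic variation of
#' the background (absorbed by \eqn{k}) can explain.
#'
#' @param panel A [sample_panel()] with all concentrations > 0 (run
#'   [substitute_nondetects()] first if the panel has censored cells).
#' @param refs A [reference_set()] covering the panel's elements.
#' @param labels Grade labels, lowest to highest (length 5).
#' @return An object of class `igeo_result`: `value` and `grade` matrices
#'   (samples x elements).
#' @export
compute_igeo <- function(panel, refs,
                         labels = c("none", "slight", "moderate", "severe",
                                    "extremely_severe")) {
  stopifnot(inherits(panel, "sample_panel"), inherits(refs, "reference_set"))
  if (length(labels) != 5L) stop("`labels` must have length 5")
  check_elements(panel, refs)
  conc <- panel$conc
  if (anyNA(conc) || any(conc <= 0))
    stop("all concentrations must be > 0; run substitute_nondetects() first")
  c0 <- refs$background[panel$elements]
  value <- log2(sweep(conc, 2, refs$igeo_k * c0, "/"))
  # upper bounds inclusive (exactly 1 -> slight), hence left.open = TRUE
  idx <- findInterval(value, c(0, 1, 2, 3), left.open = TRUE) + 1L
  grade <- matrix(labels[idx], nrow(value), ncol(value),
                  dimnames = dimnames(value))
  structure(list(value = value, grade = grade, labels = labels),
            class = "igeo_result")
}

#' Single-element potential ecological risk
#'
#' Hakanson's \eqn{E_r = T_r \cdot C_i / C_0} per sample and element, graded
#' as: < 40 slight; [40, 80) moderate; [80, 160) strong; [160, 320) very
#' strong; >= 320 extremely strong (lower bounds inclusive).
#'
#' @inheritParams compute_igeo
#' @return An object of class `eco_risk`: `er` and `er_grade` matrices, plus
#'   the `refs` used (consumed by [compute_ri()]).
#' @export
compute_er <- function(panel, refs) {
  stopifnot(inherits(panel, "sample_panel"), inherits(refs, "reference_set"))
  check_elements(panel, refs)
  conc <- panel$conc
  if (anyNA(conc))
    stop("panel has missing values; run substitute_nondetects() first")
  els <- panel$elements
  er <- sweep(conc, 2, refs$toxicity_coefficient[els] / refs$background[els],
              "*")
  grade <- matrix(.ER_LABELS[findInterval(er, c(40, 80, 160, 320)) + 1L],
                  nrow(er), ncol(er), dimnames = dimnames(er))
  structure(list(er = er, er_grade = grade, refs = refs,
                 sample_id = panel$sample_id),
            class = "eco_risk")
}

.ER_LABELS <- c("slight", "moderate", "strong", "very_strong",
                "extremely_strong")
.RI_LABELS <- c("low", "moderate", "high", "extremely_high")

#' Comprehensive potential ecological risk index
#'
#' \eqn{RI = \sum_i E_r^i} per sample, graded against thresholds re-scaled to
#' the panel's toxicity-coefficient total (see [derive_ri_thresholds()]).
#'
#' @param eco An `eco_risk` object from [compute_er()].
#' @param grading Optional [derive_ri_thresholds()] result; defaults to
#'   thresholds derived from the reference set attached to `eco`.
#' @return `eco` with `ri` (per-sample sum, exact), `ri_grade` and `grading`
#'   added.
#' @export
compute_ri <- function(eco, grading = NULL) {
  stopifnot(inherits(eco, "eco_risk"))
  if (is.null(grading)) grading <- derive_ri_thresholds(eco$refs)
  ri <- rowSums(eco$er)
  cuts <- c(grading$level1, grading$level2, grading$level3)
  eco$ri <- ri
  eco$ri_grade <- .RI_LABELS[findInterval(ri, cuts) + 1L]
  eco$grading <- grading
  eco
}

#' Re-scaled RI grading thresholds
#'
#' Hakanson's first-level RI threshold of 150 was set for a pollutant set
#' whose toxicity coefficients total 133, giving a per-unit-toxicity grading
#' value of 150/133. For a different panel the first-level threshold is that
#' unit value times the panel's \eqn{\sum T_r}, rounded half-up to an
#' integer; each subsequent level doubles the previous (rounded) one. For the
#' default eight-element panel (\eqn{\sum T_r = 98}) this yields 111 / 222 /
#' 444.
#'
#' @param refs A [reference_set()] (its toxicity coefficients define the
#'   panel).
#' @return An object of class `ri_grading` with `unit_value` (150/133),
#'   `level1`, `level2`, `level3`.
#' @export
derive_ri_thresholds <- function(refs) {
  stopifnot(inherits(refs, "reference_set"))
  tr_sum <- sum(refs$toxicity_coefficient)
  if (!length(refs$toxicity_coefficient) || tr_sum <= 0)
    stop("reference set has no toxicity coefficients")
  unit <- 150 / 133
  level1 <- floor(unit * tr_sum + 0.5)  # round half-up
  structure(list(unit_value = unit, tr_sum = tr_sum,
                 level1 = level1, level2 = 2 * level1, level3 = 4 * level1),
            class = "ri_grading")
}

#' @export
print.ri_grading <- function(x, ...) {
  cat(sprintf(
    "<ri_grading> sum(T_r) = %g; thresholds %g / %g / %g (unit value %.4f)\n",
    x$tr_sum, x$level1, x$level2, x$level3, x$unit_value))
  invisible(x)
}

#' Descriptive summary of a sample panel
#'
#' Per-element minimum, maximum, mean, sample standard deviation (n - 1),
#' coefficient of variation (sd/mean), exceedance factor
#' \eqn{(\bar{C} - C_0)/C_0}, and the proportion of samples above background.
#'
#' @inheritParams compute_igeo
#' @return A data.frame with one row per element.
#' @export
summarize_panel <- function(panel, refs) {
  stopifnot(inherits(panel, "sample_panel"), inherits(refs, "reference_set"))
  check_elements(panel, refs)
  if (n_samples(panel) < 2) stop("need at least 2 samples to summarize")
  conc <- panel$conc
  if (anyNA(conc))
    stop("panel has missing values; run substitute_nondetects() first")
  c0 <- refs$background[panel$elements]
  mn <- colMeans(conc)
  sd <- apply(conc, 2, stats::sd)
  data.frame(
    element = panel$elements,
    min = apply(conc, 2, min),
    max = apply(conc, 2, max),
    mean = mn,
    sd = sd,
    cv = ifelse(mn == 0, 0, sd / mn),
    exceedance_factor = (mn - c0) / c0,
    prop_above_background = colMeans(sweep(conc, 2, c0, ">")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Grade proportions across samples
#'
#' Tabulates, per element, the fraction of samples in each grade — the
#' summary conventionally reported alongside index maps.
#'
#' @param grade A grade matrix (samples x elements) from [compute_igeo()] or
#'   [compute_er()].
#' @param levels Grade labels in order.
#' @return A data.frame: element x grade proportions (rows sum to 1).
#' @export
grade_proportions <- function(grade, levels = NULL) {
  if (is.null(levels)) levels <- unique(as.vector(grade))
  out <- t(apply(grade, 2, function(g)
    table(factor(g, levels = levels)) / length(g)))
  data.frame(element = colnames(grade), as.data.frame.matrix(out),
             row.names = NULL, check.names = FALSE)
}

check_elements <- function(panel, refs) {
  miss <- setdiff(panel$elements, refs$elements)
  if (length(miss))
    stop("reference set missing element(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
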