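#' Exposure model for a receptor
#'
#' Collects the distribution specifications of every exposure parameter used
#' in the average-daily-dose equations for one receptor (child or adult):
#' soil ingestion rate `R_ingest` (mg/d), exposure frequency `EF` (d/y),
#' exposure duration `ED` (y), inhalation rate `R_inhal` (m3/d), particle
#' emission factor `PEF` (m3/kg), body weight `BW` (kg), averaging time `AT`
#' (d), exposed skin area `SA` (cm2), skin adherence factor `AF` (mg/cm2)
#' and dermal absorption fraction `ABF` (dimensionless).
#'
#' @param receptor `"child"` or `"adult"`.
#' @param R_ingest,EF,ED,R_inhal,PEF,BW,AT,SA,AF,ABF [dist_spec] objects.
#' @return An object of class `exposure_model`.
#' @seealso [default_exposure_model()] for the packaged parameter values.
#' @export
exposure_model <- function(receptor, R_ingest, EF, ED, R_inhal, PEF, BW, AT,
                           SA, AF, ABF) {
  receptor <- match.arg(receptor, c("child", "adult"))
  params <- list(R_ingest = R_ingest, EF = EF, ED = ED, R_inhal = R_inhal,
                 PEF = PEF, BW = BW, AT = AT, SA = SA, AF = AF, ABF = ABF)
  for (nm in names(params))
    if (!inherits(params[[nm]], "dist_spec"))
      stop("parameter '", nm, "' must be a dist_spec")
  structure(c(list(receptor = receptor), params), class = "exposure_model")
}

#' Packaged default exposure models
#'
#' Receptor-specific exposure parameters for a residential scenario near a
#' mining site, as used by the reference survey's probabilistic assessment:
#'
#' \tabular{lll}{
#'   parameter \tab child \tab adult \cr
#'   R_ingest (mg/d) \tab triangular(66, 103, 161) \tab triangular(14, 30, 52) \cr
#'   EF (d/y) \tab point 350 \tab point 350 \cr
#'   ED (y) \tab uniform(0, 10) \tab uniform(0, 50) \cr
#'   R_inhal (m3/d) \tab point 7.6 \tab point 20 \cr
#'   PEF (m3/kg) \tab point 1.36e9 \tab point 1.36e9 \cr
#'   BW (kg) \tab lognormal GM 16.68, GSD 1.48 \tab lognormal GM 57.03, GSD 1.18 \cr
#'   AT (d) \tab point 2190 \tab point 9125 \cr
#'   SA (cm2) \tab lognormal GM 7422, GSD 1.25 \tab lognormal GM 18182, GSD 1.1 \cr
#'   AF (mg/cm2) \tab lognormal GM 0.65, GSD 1.2 \tab see below \cr
#'   ABF (-) \tab point 0.001 \tab point 0.001
#' }
#'
#' The adult AF pair (0.49, 0.54) cannot be a GM/GSD pair (a GSD below 1 is
#' impossible), so it is read as an arithmetic mean/SD pair; by default it
#' becomes a normal truncated at zero, or with
#' `af_interpretation = "lognormal"` a moment-matched lognormal with that
#' arithmetic mean and SD. The choice is reported via a message.
#'
#' Note `AT` equals `ED`-range-midpoint years times 365 (2190 = 6 x 365,
#' 9125 = 25 x 365): the same averaging time is used for carcinogenic and
#' non-carcinogenic endpoints, exactly as in the source table (no 70-year
#' lifetime override).
#'
#' @param receptor `"child"` or `"adult"`.
#' @param af_interpretation How to read the adult AF pair:
#'   `"normal_trunc"` (default) or `"lognormal"`.
#' @return An `exposure_model`.
#' @export
default_exposure_model <- function(receptor = c("child", "adult"),
                                   af_interpretation = c("normal_trunc",
                                                         "lognormal")) {
  receptor <- match.arg(receptor)
  af_interpretation <- match.arg(af_interpretation)
  if (receptor == "child") {
    exposure_model("child",
      R_ingest = dist_triangular(66, 103, 161),
      EF = dist_point(350),
      ED = dist_uniform(0, 10),
      R_inhal = dist_point(7.6),
      PEF = dist_point(1.36e9),
      BW = dist_lognormal(16.68, 1.48),
      AT = dist_point(2190),
      SA = dist_lognormal(7422, 1.25),
      AF = dist_lognormal(0.65, 1.2),
      ABF = dist_point(0.001))
  } else {
    af <- if (af_interpretation == "normal_trunc") {
      dist_normal_trunc(0.49, 0.54)
    } else {
      # moment-matched lognormal with arithmetic mean 0.49 and SD 0.54
      sdlog <- sqrt(log(1 + (0.54 / 0.49)^2))
      dist_lognormal(0.49 * exp(-sdlog^2 / 2), exp(sdlog))
    }
    message("adult AF pair (0.49, 0.54) interpreted as ", af_interpretation)
    exposure_model("adult",
      R_ingest = dist_triangular(14, 30, 52),
      EF = dist_point(350),
      ED = dist_uniform(0, 50),
      R_inhal = dist_point(20),
      PEF = dist_point(1.36e9),
      BW = dist_lognormal(57.03, 1.18),
      AT = dist_point(9125),
      SA = dist_lognormal(18182, 1.1),
      AF = af,
      ABF = dist_point(0.001))
  }
}

#' Load an exposure model from a YAML config file
#'
#' Layout: a top-level key per receptor, each parameter a mapping with
#' `family` and `params`, e.g.
#' \preformatted{
#' child:
#'   R_ingest: {family: triangular, params: [66, 103, 161]}
#'   EF:       {family: point, params: [350]}
#' }
#'
#' @param path YAML file, or `"default"` for [default_exposure_model()].
#' @param receptor `"child"` or `"adult"`.
#' @return An `exposure_model`.
#' @export
load_exposure_model <- function(path, receptor = c("child", "adult")) {
  receptor <- match.arg(receptor)
  if (identical(path, "default")) return(default_exposure_model(receptor))
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[[receptor]]))
    stop("config has no '", receptor, "' section")
  specs <- lapply(cfg[[receptor]], as_dist_spec)
  do.call(exposure_model, c(list(receptor = receptor), specs))
}

.PATHWAYS <- c("ingest", "inhal", "dermal")

#' Toxicity reference values (RfD and SF)
#'
#' Per-element, per-pathway reference doses (RfD, mg/(kg d)) and carcinogenic
#' slope factors (SF, (kg d)/mg). `NA` marks values not established for a
#' pathway; such pathways are skipped in the corresponding risk sum.
#'
#' @param rfd,sf Numeric matrices, elements x pathways
#'   (`ingest`, `inhal`, `dermal`); `NA` allowed.
#' @return An object of class `toxicity_reference`.
#' @export
toxicity_reference <- function(rfd, sf) {
  rfd <- as.matrix(rfd); sf <- as.matrix(sf)
  for (m in list(rfd, sf)) {
    if (!identical(colnames(m), .PATHWAYS))
      stop("columns must be: ", paste(.PATHWAYS, collapse = ", "))
    if (any(!is.na(m) & m <= 0)) stop("present toxicity values must be > 0")
  }
  if (!identical(rownames(rfd), rownames(sf)))
    stop("rfd and sf must cover the same elements in the same order")
  structure(list(rfd = rfd, sf = sf, elements = rownames(rfd)),
            class = "toxicity_reference")
}

#' Packaged default toxicity reference
#'
#' Standard RfD/SF values for the eight-element panel; dashes in published
#' compilations (no established value) appear as `NA` and the corresponding
#' pathway is excluded from HQ/CR sums. Cu, Hg and Zn have no slope factors
#' at all and contribute 0 to total carcinogenic risk.
#'
#' @return A [toxicity_reference()].
#' @export
default_toxicity_reference <- function() {
  els <- .DEFAULT_ELEMENTS
  rfd <- matrix(NA_real_, length(els), 3,
                dimnames = list(els, .PATHWAYS))
  sf <- rfd
  #                 ingest    inhal     dermal
  rfd["As", ] <- c(3.00e-4, 1.23e-4, 1.23e-4)
  rfd["Cd", ] <- c(1.00e-3, 1.00e-5, 1.00e-5)
  rfd["Cu", ] <- c(4.00e-2, 4.02e-2, 1.20e-2)
  rfd["Cr", ] <- c(3.00e-3, 2.86e-5, 6.00e-5)
  rfd["Hg", ] <- c(3.00e-4, 8.57e-5, 2.10e-5)
  rfd["Ni", ] <- c(2.00e-2, 2.06e-2, 5.40e-3)
  rfd["Pb", ] <- c(3.50e-3, 3.52e-3, 5.25e-4)
  rfd["Zn", ] <- c(3.00e-1, 3.00e-1, 6.00e-2)
  sf["As", ] <- c(1.5, 1.51, 3.66)
  sf["Cd", ] <- c(6.1, 6.30, NA)
  sf["Cr", ] <- c(8.50e-3, 4.20, NA)
  sf["Ni", ] <- c(NA, 8.4e-1, NA)
  sf["Pb", ] <- c(8.50e-3, NA, NA)
  toxicity_reference(rfd, sf)
}

#' Average daily dose by pathway
#'
#' Computes the three pathway doses for one element:
#' \deqn{ADD_{ingest} = C \cdot R_{ingest} \cdot EF \cdot ED / (BW \cdot AT) \cdot 10^{-6}}
#' \deqn{ADD_{dermal} = C \cdot SA \cdot AF \cdot ABF \cdot EF \cdot ED / (BW \cdot AT) \cdot 10^{-6}}
#' \deqn{ADD_{inhal} = C \cdot R_{inhal} \cdot EF \cdot ED / (PEF \cdot BW \cdot AT)}
#'
#' Unit bridging: `EF` (d/y) times `ED` (y) gives total exposure days, which
#' divides directly by the averaging time `AT` in days — no additional factor
#' of 365 (the packaged `AT` values are already `ED`-midpoint years x 365).
#'
#' @param C Concentration (mg/kg); scalar or a vector of per-draw values.
#' @param draws A data.frame of exposure-parameter draws with one column per
#'   parameter of [exposure_model()] (as from [generate_exposure_population()]).
#' @return A matrix with columns `ingest`, `inhal`, `dermal`
#'   (mg/(kg d)), one row per draw.
#' @examples
#' d <- data.frame(R_ingest = 100, EF = 350, ED = 10, R_inhal = 7.6,
#'                 PEF = 1.36e9, BW = 20, AT = 3650, SA = 7422,
#'                 AF = 0.65, ABF = 0.001)
#' compute_add(100, d)[, "ingest"]  # 4.795e-4
#' @export
compute_add <- function(C, draws) {
  need <- c("R_ingest", "EF", "ED", "R_inhal", "PEF", "BW", "AT", "SA", "AF",
            "ABF")
  miss <- setdiff(need, names(draws))
  if (length(miss))
    stop("draws missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(C < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  with(draws, {
    if (any(BW <= 0) || any(AT <= 0) || any(PEF <= 0))
      stop("nonpositive BW, AT or PEF draw")
    days <- EF * ED            # total exposure days
    denom <- BW * AT
    cbind(
      ingest = C * R_ingest * days / denom * 1e-6,
      inhal  = C * R_inhal * days / (PEF * denom),
      dermal = C * SA * AF * ABF * days / denom * 1e-6
    )
  })
}

#' Hazard quotient and hazard index
#'
#' \eqn{HQ_i = \sum_j ADD_{ij} / RfD_{ij}} over pathways with an established
#' RfD; \eqn{HI = \sum_i HQ_i}. An element with no RfD on any pathway is
#' excluded with a warning.
#'
#' @param add Named list (per element) of ADD matrices from [compute_add()].
#' @param tox A [toxicity_reference()].
#' @return List with `hq` (draws x elements matrix) and `hi` (vector).
#' @export
compute_hq_hi <- function(add, tox) {
  stopifnot(inherits(tox, "toxicity_reference"))
  els <- names(add)
  hq <- sapply(els, function(el) {
    rfd <- tox$rfd[el, ]
    ok <- !is.na(rfd)
    if (!any(ok)) {
      warning("element ", el, " has no RfD on any pathway; excluded from HI")
      return(rep(0, nrow(add[[el]])))
    }
    as.vector(add[[el]][, names(rfd)[ok], drop = FALSE] %*% (1 / rfd[ok]))
  })
  if (is.null(dim(hq))) hq <- matrix(hq, nrow = 1, dimnames = list(NULL, els))
  list(hq = hq, hi = rowSums(hq))
}

#' Carcinogenic risk and total carcinogenic risk
#'
#' \eqn{CR_i = \sum_j ADD_{ij} \cdot SF_{ij}} over pathways with an
#' established slope factor; \eqn{TCR = \sum_i CR_i}. Elements with no slope
#' factor contribute exactly 0.
#'
#' @inheritParams compute_hq_hi
#' @return List with `cr` (draws x elements matrix) and `tcr` (vector).
#' @export
compute_cr_tcr <- function(add, tox) {
  stopifnot(inherits(tox, "toxicity_reference"))
  els <- names(add)
  cr <- sapply(els, function(el) {
    sf <- tox$sf[el, ]
    ok <- !is.na(sf)
    if (!any(ok)) return(rep(0, nrow(add[[el]])))
    as.vector(add[[el]][, names(sf)[ok], drop = FALSE] %*% sf[ok])
  })
  if (is.null(dim(cr))) cr <- matrix(cr, nrow = 1, dimnames = list(NULL, els))
  list(cr = cr, tcr = rowSums(cr))
}

#' Monte Carlo probabilistic health-risk assessment
#'
#' Per iteration, one survey sample row is drawn uniformly at random (so
#' element concentrations co-vary as observed), or — with
#' `conc_mode = "lognormal"` — each element is drawn independently from a
#' lognormal fitted to the panel; all exposure parameters are drawn
#' independently from their distribution specs. Pathway doses, HQ/HI and
#' CR/TCR are evaluated on every iteration and summarized by their mean and
#' 5th/50th/95th percentiles.
#'
#' Risk classification attached to the summaries: CR or TCR at most 1e-6 is
#' negligible, up to 1e-4 tolerable, above 1e-4 intolerable; HQ or HI at most
#' 1 is negligible.
#'
#' @param panel A [sample_panel()] with no missing values.
#' @param model An [exposure_model()].
#' @param tox A [toxicity_reference()].
#' @param iterations Number of Monte Carlo iterations (default 10000; a
#'   warning is issued below 1000).
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @param conc_mode `"empirical"` (default) or `"lognormal"`.
#' @param keep_draws Keep the raw per-iteration HQ/CR matrices (for audit).
#' @return An object of class `risk_summary`: `summary` (long data.frame:
#'   element, quantity, mean, p5, p50, p95, classification), `aggregate`
#'   (HI and TCR rows), `receptor`, `iterations`, `seed`, and optionally
#'   `draws`.
#' @export
run_monte_carlo <- function(panel, model, tox, iterations = 10000,
                            seed = 1L,
                            conc_mode = c("empirical", "lognormal"),
                            keep_draws = FALSE) {
  stopifnot(inherits(panel, "sample_panel"),
            inherits(model, "exposure_model"),
            inherits(tox, "toxicity_reference"))
  conc_mode <- match.arg(conc_mode)
  if (iterations < 1) stop("iterations must be >= 1")
  if (iterations < 1000)
    warning("fewer than 1000 iterations gives unstable percentiles")
  if (anyNA(panel$conc))
    stop("panel has missing values; run substitute_nondetects() first")
  miss <- setdiff(panel$elements, tox$elements)
  if (length(miss))
    stop("toxicity reference missing element(s): ",
         paste(miss, collapse = ", "))

  set.seed(seed)
  n <- iterations
  conc <- if (conc_mode == "empirical") {
    panel$conc[sample.int(n_samples(panel), n, replace = TRUE), , drop = FALSE]
  } else {
    vapply(panel$elements, function(el) {
      x <- panel$conc[, el]
      x <- x[x > 0]
      stats::rlnorm(n, mean(log(x)), stats::sd(log(x)))
    }, numeric(n))
  }
  pars <- c("R_ingest", "EF", "ED", "R_inhal", "PEF", "BW", "AT", "SA", "AF",
            "ABF")
  draws <- as.data.frame(lapply(stats::setNames(pars, pars), function(p)
    sample_parameter(model[[p]], n)))

  add <- lapply(stats::setNames(panel$elements, panel$elements), function(el)
    compute_add(conc[, el], draws))
  nc <- compute_hq_hi(add, tox)
  ca <- compute_cr_tcr(add, tox)

  qs <- function(x) c(mean = mean(x), p5 = unname(stats::quantile(x, 0.05)),
                      p50 = unname(stats::quantile(x, 0.50)),
                      p95 = unname(stats::quantile(x, 0.95)))
  rows <- list()
  for (el in panel$elements) {
    for (pw in .PATHWAYS)
      rows[[length(rows) + 1L]] <-
        data.frame(element = el, quantity = paste0("ADD_", pw),
                   t(qs(add[[el]][, pw])))
    rows[[length(rows) + 1L]] <-
      data.frame(element = el, quantity = "HQ", t(qs(nc$hq[, el])))
    rows[[length(rows) + 1L]] <-
      data.frame(element = el, quantity = "CR", t(qs(ca$cr[, el])))
  }
  summary <- do.call(rbind, rows)
  summary$classification <- classify_risk(summary$quantity, summary$mean)
  aggregate <- rbind(
    data.frame(quantity = "HI", t(qs(nc$hi))),
    data.frame(quantity = "TCR", t(qs(ca$tcr))))
  aggregate$classification <- classify_risk(aggregate$quantity,
                                            aggregate$mean)
  out <- list(summary = summary, aggregate = aggregate,
              receptor = model$receptor, iterations = iterations,
              seed = seed, conc_mode = conc_mode)
  if (keep_draws) out$draws <- list(add = add, hq = nc$hq, hi = nc$hi,
                                    cr = ca$cr, tcr = ca$tcr)
  class(out) <- "risk_summary"
  out
}

classify_risk <- function(quantity, mean_value) {
  ifelse(quantity %in% c("CR", "TCR"),
         ifelse(mean_value <= 1e-6, "negligible",
                ifelse(mean_value <= 1e-4, "tolerable", "intolerable")),
         ifelse(quantity %in% c("HQ", "HI"),
                ifelse(mean_value <= 1, "negligible", "concern"),
                NA_character_))
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("<risk_summary> receptor = %s, %d iterations, seed %d\n",
              x$receptor, x$iterations, x$seed))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
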