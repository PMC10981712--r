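#' Distribution specifications for Monte Carlo inputs
#'
#' A `dist_spec` describes how one exposure parameter is sampled. Families:
#' \describe{
#'   \item{point}{a degenerate constant, `dist_point(value)`;}
#'   \item{uniform}{`dist_uniform(low, high)`. Draws of exactly `low` are
#'     rejected and redrawn, so `dist_uniform(0, 10)` is effectively the
#'     half-open interval (0, 10] and never yields a degenerate
#'     zero-exposure draw;}
#'   \item{triangular}{`dist_triangular(min, mode, max)`, sampled by inverse
#'     CDF;}
#'   \item{lognormal}{`dist_lognormal(gm, gsd)` parameterized by geometric
#'     mean and geometric standard deviation (the exposure-literature
#'     convention), `gm > 0`, `gsd > 1`;}
#'   \item{normal_trunc}{`dist_normal_trunc(mean, sd)`, a normal truncated at
#'     zero by rejection; used where a printed mean/SD pair cannot be a
#'     GM/GSD pair (e.g. an SD below 1 in GSD position).}
#' }
#'
#' @param value,low,high,min,mode,max,gm,gsd,mean,sd Family parameters.
#' @return An object of class `dist_spec`.
#' @name dist_spec
NULL

new_dist_spec <- function(family, params) {
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.finite(value))
  new_dist_spec("point", c(value = value))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high) {
  if (!(low <= high)) stop("uniform: need low <= high")
  new_dist_spec("uniform", c(low = low, high = high))
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max) {
  if (!(min <= mode && mode <= max))
    stop("triangular: need min <= mode <= max")
  new_dist_spec("triangular", c(min = min, mode = mode, max = max))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(gm, gsd) {
  if (gm <= 0) stop("lognormal: geometric mean must be > 0")
  if (gsd <= 1) stop("lognormal: geometric SD must be > 1")
  new_dist_spec("lognormal", c(gm = gm, gsd = gsd))
}

#' @rdname dist_spec
#' @export
dist_normal_trunc <- function(mean, sd) {
  if (sd < 0) stop("normal_trunc: sd must be >= 0")
  new_dist_spec("normal_trunc", c(mean = mean, sd = sd))
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(names(x$params), signif(x$params, 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Build a dist_spec from a plain list (config parsing)
#'
#' Accepts `list(family = "triangular", params = c(14, 30, 52))` as read from
#' YAML.
#' @param x A list with `family` and `params`.
#' @return A `dist_spec`.
#' @export
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (!is.list(x) || is.null(x$family)) stop("cannot interpret as dist_spec")
  p <- as.numeric(unlist(x$params))  # YAML may deliver "1.36e9" as text
  switch(x$family,
    point        = dist_point(p[[1]]),
    uniform      = dist_uniform(p[[1]], p[[2]]),
    triangular   = dist_triangular(p[[1]], p[[2]], p[[3]]),
    lognormal    = dist_lognormal(p[[1]], p[[2]]),
    normal_trunc = dist_normal_trunc(p[[1]], p[[2]]),
    stop("unknown distribution family: ", x$family))
}

#' Draw Monte Carlo samples from a distribution specification
#'
#' Uses R's global RNG stream; pass `seed` to make an isolated call
#' reproducible, or set the seed once upstream when drawing many parameters
#' jointly (as [run_monte_carlo()] does).
#'
#' @param spec A [dist_spec].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed applied before drawing.
#' @return Numeric vector of length `n`; all draws are positive for the
#'   packaged exposure parameters.
#' @examples
#' sample_parameter(dist_point(350), 3)
#' @export
sample_parameter <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "dist_spec")) stop("`spec` must be a dist_spec")
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- spec$params
  switch(spec$family,
    point = rep(p[["value"]], n),
    uniform = {
      x <- stats::runif(n, p[["low"]], p[["high"]])
      # exclude draws exactly at the lower bound (half-open interval)
      while (any(hit <- x == p[["low"]]) && p[["low"]] < p[["high"]])
        x[hit] <- stats::runif(sum(hit), p[["low"]], p[["high"]])
      x
    },
    triangular = {
      u <- stats::runif(n)
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      if (a == b) rep(a, n) else {
        fc <- (m - a) / (b - a)
        ifelse(u < fc,
               a + sqrt(u * (b - a) * (m - a)),
               b - sqrt((1 - u) * (b - a) * (b - m)))
      }
    },
    lognormal = stats::rlnorm(n, meanlog = log(p[["gm"]]),
                              sdlog = log(p[["gsd"]])),
    normal_trunc = {
      x <- stats::rnorm(n, p[["mean"]], p[["sd"]])
      while (any(bad <- x <= 0))
        x[bad] <- stats::rnorm(sum(bad), p[["mean"]], p[["sd"]])
      x
    },
    stop("unknown distribution family: ", spec$family))
}

# Closed-form mean of a dist_spec (used in tests and calibration checks).
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    point = p[["value"]],
    uniform = (p[["low"]] + p[["high"]]) / 2,
    triangular = (p[["min"]] + p[["mode"]] + p[["max"]]) / 3,
    lognormal = p[["gm"]] * exp(log(p[["gsd"]])^2 / 2),
    normal_trunc = {
      m <- p[["mean"]]; s <- p[["sd"]]
      if (s == 0) return(m)
      a <- -m / s  # truncation point in standard units
      m + s * stats::dnorm(a) / (1 - stats::pnorm(a))
    })
}
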