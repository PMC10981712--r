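#' Reference values for pollution-index calculation
#'
#' Bundles the per-element geochemical background values \eqn{C_0} (mg/kg),
#' the Hakanson toxicity response coefficients \eqn{T_r}, and the
#' geo-accumulation correction coefficient \eqn{k} (conventionally 1.5, which
#' absorbs lithogenic variation of the background).
#'
#' @param background Named numeric vector of background values, all > 0.
#' @param toxicity_coefficient Named numeric vector of \eqn{T_r}, all > 0,
#'   covering the same elements.
#' @param igeo_k Correction coefficient for the geo-accumulation index
#'   (default 1.5).
#' @return An object of class `reference_set`.
#' @seealso [default_reference_set()], [load_reference_set()]
#' @export
reference_set <- function(background, toxicity_coefficient, igeo_k = 1.5) {
  if (is.null(names(background)) || is.null(names(toxicity_coefficient)))
    stop("`background` and `toxicity_coefficient` must be named by element")
  elements <- names(background)
  miss <- setdiff(elements, names(toxicity_coefficient))
  if (length(miss))
    stop("toxicity coefficient missing for: ", paste(miss, collapse = ", "))
  toxicity_coefficient <- toxicity_coefficient[elements]
  if (any(!is.finite(background)) || any(background <= 0))
    stop("all background values must be finite and > 0")
  if (any(!is.finite(toxicity_coefficient)) || any(toxicity_coefficient <= 0))
    stop("all toxicity coefficients must be finite and > 0")
  if (!is.numeric(igeo_k) || length(igeo_k) != 1L || igeo_k <= 0)
    stop("`igeo_k` must be a single positive number")
  structure(list(background = background,
                 toxicity_coefficient = toxicity_coefficient,
                 igeo_k = igeo_k, elements = elements),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>", length(x$elements), "elements, k =", x$igeo_k, "\n")
  print(data.frame(element = x$elements, background = x$background,
                   T_r = x$toxicity_coefficient, row.names = NULL))
  invisible(x)
}

#' Packaged default reference set
#'
#' Background values are the local non-agricultural-land soil backgrounds of
#' the reference survey area (see [survey_reference_stats()]); toxicity
#' coefficients are the standard Hakanson values
#' Hg 40, Cd 30, As 10, Pb 5, Cu 5, Ni 5, Cr 2, Zn 1 (sum 98 for this panel).
#'
#' @return A [reference_set()].
#' @export
default_reference_set <- function() {
  stats <- survey_reference_stats()
  bg <- stats$background
  names(bg) <- stats$element
  tr <- c(As = 10, Hg = 40, Cd = 30, Pb = 5, Cr = 2, Cu = 5, Zn = 1, Ni = 5)
  reference_set(bg, tr[stats$element])
}

#' Load a reference set from a YAML config file
#'
#' Expected layout:
#' \preformatted{
#' background:
#'   As: 7.94
#'   ...
#' toxicity_coefficient:
#'   As: 10
#'   ...
#' igeo_k: 1.5
#' }
#'
#' @param path YAML file path, or the string `"default"` for the packaged set.
#' @param elements Elements that must be covered (default: the canonical
#'   panel). Missing elements raise an error naming them.
#' @return A [reference_set()].
#' @export
load_reference_set <- function(path, elements = default_elements()) {
  if (identical(path, "default")) {
    rs <- default_reference_set()
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    for (field in c("background", "toxicity_coefficient"))
      if (is.null(cfg[[field]])) stop("config missing '", field, "' section")
    rs <- reference_set(unlist(cfg$background),
                        unlist(cfg$toxicity_coefficient),
                        igeo_k = if (is.null(cfg$igeo_k)) 1.5 else cfg$igeo_k)
  }
  miss <- setdiff(elements, rs$elements)
  if (length(miss))
    stop("reference set missing element(s): ", paste(miss, collapse = ", "))
  rs
}
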