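#' Construct a soil sample panel
#'
#' A `sample_panel` holds a samples-by-elements concentration matrix (mg/kg
#' dry soil) together with censoring metadata: a logical matrix flagging
#' below-detection cells and the corresponding detection limits. Censored
#' cells may carry `NA` concentration until [substitute_nondetects()] fills
#' them with 5/6 of the detection limit.
#'
#' @param conc Numeric matrix or data.frame, samples x elements. Column names
#'   must be element symbols.
#' @param censored Logical matrix of the same shape (default: all `FALSE`).
#' @param detection_limit Numeric matrix of the same shape, or a named
#'   per-element vector recycled across samples. Required (positive) wherever
#'   `censored` is `TRUE`; may be `NA` elsewhere.
#' @param sample_id Character vector of sample identifiers (default
#'   `"S1"..."Sn"`).
#' @param zone Optional per-sample zone label (one of mining, beneficiation,
#'   residue, residential, bare, other).
#' @return An object of class `sample_panel` with fields `conc`, `censored`,
#'   `detection_limit`, `sample_id`, `zone`, `elements`.
#' @examples
#' p <- sample_panel(matrix(c(10, 20), 1,
#'                   dimnames = list(NULL, c("Cr", "Ni"))))
#' n_samples(p)
#' @export
sample_panel <- function(conc, censored = NULL, detection_limit = NULL,
                         sample_id = NULL, zone = NULL) {
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  if (is.null(colnames(conc)) || anyDuplicated(colnames(conc)))
    stop("`conc` must have unique element column names")
  n <- nrow(conc)
  p <- ncol(conc)
  elements <- colnames(conc)

  if (is.null(censored)) censored <- matrix(FALSE, n, p)
  censored <- as.matrix(censored)
  if (!identical(dim(censored), dim(conc)))
    stop("`censored` must match the shape of `conc`")
  storage.mode(censored) <- "logical"
  censored[is.na(censored)] <- FALSE

  if (is.null(detection_limit)) {
    detection_limit <- matrix(NA_real_, n, p)
  } else if (is.null(dim(detection_limit))) {
    dl <- detection_limit[elements]
    if (length(detection_limit) == p && is.null(names(detection_limit)))
      dl <- detection_limit
    detection_limit <- matrix(rep(as.numeric(dl), each = n), n, p)
  }
  detection_limit <- as.matrix(detection_limit)
  storage.mode(detection_limit) <- "double"
  if (!identical(dim(detection_limit), dim(conc)))
    stop("`detection_limit` must match the shape of `conc`")

  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n) stop("`sample_id` length must equal nrow(conc)")
  if (!is.null(zone)) {
    zone <- as.character(zone)
    if (length(zone) == 1L) zone <- rep(zone, n)
    if (length(zone) != n) stop("`zone` length must equal nrow(conc)")
    bad <- setdiff(unique(zone), .ZONES)
    if (length(bad))
      stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  }

  dimnames(conc) <- dimnames(censored) <- dimnames(detection_limit) <-
    list(sample_id, elements)

  # invariants
  neg <- which(!is.na(conc) & conc < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative concentration at sample '%s', element '%s'",
                 sample_id[neg[1, 1]], elements[neg[1, 2]]))
  bad_na <- which(is.na(conc) & !censored, arr.ind = TRUE)
  if (nrow(bad_na))
    stop(sprintf(
      "missing concentration at sample '%s', element '%s' not flagged censored",
      sample_id[bad_na[1, 1]], elements[bad_na[1, 2]]))
  bad_dl <- which(censored & (is.na(detection_limit) | detection_limit <= 0),
                  arr.ind = TRUE)
  if (nrow(bad_dl))
    stop(sprintf(
      "censored cell at sample '%s', element '%s' lacks a positive detection limit",
      sample_id[bad_dl[1, 1]], elements[bad_dl[1, 2]]))

  structure(
    list(conc = conc, censored = censored, detection_limit = detection_limit,
         sample_id = sample_id, zone = zone, elements = elements),
    class = "sample_panel")
}

.ZONES <- c("mining", "beneficiation", "residue", "residential", "bare",
            "other")

#' @export
print.sample_panel <- function(x, ...) {
  cat(sprintf("<sample_panel> %d samples x %d elements (%s)\n",
              nrow(x$conc), length(x$elements),
              paste(x$elements, collapse = ", ")))
  nc <- sum(x$censored)
  if (nc) cat(sprintf("  %d censored cell(s) below detection\n", nc))
  if (!is.null(x$zone))
    cat("  zones:", paste(names(table(x$zone)), table(x$zone),
                          sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @rdname sample_panel
#' @param x A `sample_panel`.
#' @export
n_samples <- function(x) nrow(x$conc)

#' @export
as.data.frame.sample_panel <- function(x, ...) {
  out <- data.frame(sample_id = x$sample_id, stringsAsFactors = FALSE)
  if (!is.null(x$zone)) out$zone <- x$zone
  cbind(out, as.data.frame(x$conc, row.names = seq_len(nrow(x$conc))))
}

#' Read a sample table from CSV
#'
#' Reads a wide table (one row per sample, one column per element) or a long
#' table (`sample_id`, `element`, `value`). Non-detects are recognized in two
#' equivalent conventions, both of which may appear in one file:
#' a `"<0.5"` sentinel string in the concentration cell (detection limit 0.5),
#' or a paired logical column `<element>_cens` in which case the concentration
#' column carries the detection limit for flagged rows.
#'
#' @param path Path to a CSV file.
#' @param elements Element columns expected; defaults to any of the canonical
#'   panel found in the file (wide) or present in the `element` column (long).
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @return A [sample_panel()].
#' @export
read_sample_table <- function(path, elements = NULL,
                              format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!nrow(raw) || !ncol(raw)) stop("empty sample table: ", path)

  if (format == "auto")
    format <- if (all(c("element", "value") %in% names(raw))) "long" else "wide"
  if (format == "long") {
    need <- c("sample_id", "element", "value")
    if (!all(need %in% names(raw)))
      stop("long format requires columns: ", paste(need, collapse = ", "))
    ids <- unique(raw$sample_id)
    els <- if (is.null(elements)) unique(raw$element) else elements
    wide <- data.frame(sample_id = ids, stringsAsFactors = FALSE,
                       check.names = FALSE)
    if ("zone" %in% names(raw))
      wide$zone <- raw$zone[match(ids, raw$sample_id)]
    for (el in els) {
      sub <- raw[raw$element == el, ]
      wide[[el]] <- sub$value[match(ids, sub$sample_id)]
    }
    raw <- wide
  }

  if (is.null(elements))
    elements <- intersect(names(raw), .DEFAULT_ELEMENTS)
  if (!length(elements))
    stop("no element columns found in ", path)
  missing_el <- setdiff(elements, names(raw))
  if (length(missing_el))
    stop("missing element column(s): ", paste(missing_el, collapse = ", "))

  n <- nrow(raw)
  conc <- cens <- dl <- matrix(NA_real_, n, length(elements),
                               dimnames = list(NULL, elements))
  cens <- matrix(FALSE, n, length(elements), dimnames = list(NULL, elements))
  for (el in elements) {
    v <- trimws(raw[[el]])
    below <- grepl("^<", v)
    num <- suppressWarnings(as.numeric(sub("^<", "", v)))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in row %d, element %s",
                   v[bad[1]], bad[1], el))
    flagcol <- paste0(el, "_cens")
    flagged <- if (flagcol %in% names(raw))
      tolower(trimws(raw[[flagcol]])) %in% c("true", "t", "1", "yes") else
      rep(FALSE, n)
    cens[, el] <- below | flagged
    dl[cens[, el], el] <- num[cens[, el]]
    conc[!cens[, el], el] <- num[!cens[, el]]
    neg <- which(conc[, el] < 0)
    if (length(neg))
      stop(sprintf("negative concentration in row %d, element %s", neg[1], el))
  }
  sid <- if ("sample_id" %in% names(raw)) raw$sample_id else NULL
  zone <- if ("zone" %in% names(raw)) raw$zone else NULL
  sample_panel(conc, censored = cens, detection_limit = dl,
               sample_id = sid, zone = zone)
}

#' Write a sample table to CSV
#'
#' Writes the wide canonical format; censored cells are written as
#' `"<DL"` sentinels so that [read_sample_table()] round-trips the panel,
#' including censoring flags and detection limits, at full precision.
#'
#' @param panel A [sample_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(panel, path) {
  stopifnot(inherits(panel, "sample_panel"))
  out <- data.frame(sample_id = panel$sample_id, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(panel$zone)) out$zone <- panel$zone
  for (el in panel$elements) {
    v <- format(panel$conc[, el], digits = 17, trim = TRUE, scientific = FALSE)
    cen <- panel$censored[, el]
    v[cen] <- paste0("<", format(panel$detection_limit[cen, el], digits = 17,
                                 trim = TRUE, scientific = FALSE))
    out[[el]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substitute non-detects at 5/6 of the detection limit
#'
#' Replaces every censored concentration with `(5/6) * detection_limit`, the
#' convention used before index calculation and PMF uncertainty construction.
#' Censoring flags are retained so downstream uncertainty rules can still
#' identify below-detection cells. Idempotent.
#'
#' @param panel A [sample_panel()].
#' @return A `sample_panel` with censored cells filled.
#' @examples
#' p <- sample_panel(matrix(NA_real_, 1, 1, dimnames = list(NULL, "Hg")),
#'                   censored = matrix(TRUE), detection_limit = 0.6)
#' substitute_nondetects(p)$conc[1, 1]  # 0.5
#' @export
substitute_nondetects <- function(panel) {
  stopifnot(inherits(panel, "sample_panel"))
  cen <- panel$censored
  if (any(cen)) {
    panel$conc[cen] <- (5 / 6) * panel$detection_limit[cen]
  }
  panel
}
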