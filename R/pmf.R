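#' Uncertainty matrix for PMF
#'
#' Builds the per-cell uncertainty \eqn{U_{ij}} from the measured
#' concentrations with the standard concentration-based rule:
#' \deqn{u = \sqrt{(ef \cdot c)^2 + (0.5 \cdot MDL)^2}}
#' for cells above detection, while censored cells take both working value
#' and uncertainty equal to \eqn{(5/6) \cdot MDL}. The rule is an adopted
#' convention of receptor modelling practice (the survey this package
#' emulates does not publish its uncertainty formula), with the error
#' fraction `ef` configurable.
#'
#' @param panel A [sample_panel()].
#' @param error_fraction Relative measurement error fraction (default 0.10).
#' @param mdl Named per-element method detection limits (mg/kg). Defaults to
#'   the largest detection limit recorded in the panel for each element;
#'   elements with censored cells must have an MDL from one source or the
#'   other.
#' @return An object of class `uncertainty_matrix`: `u` (positive matrix),
#'   `conc` (working concentrations with non-detects substituted),
#'   `error_fraction`, `mdl`.
#' @export
build_uncertainty <- function(panel, error_fraction = 0.10, mdl = NULL) {
  stopifnot(inherits(panel, "sample_panel"))
  if (!is.numeric(error_fraction) || error_fraction < 0)
    stop("`error_fraction` must be >= 0")
  els <- panel$elements
  panel_mdl <- suppressWarnings(
    apply(panel$detection_limit, 2, max, na.rm = TRUE))
  panel_mdl[!is.finite(panel_mdl)] <- NA_real_
  if (!is.null(mdl)) {
    if (is.null(names(mdl))) stop("`mdl` must be named by element")
    panel_mdl[names(mdl)] <- mdl
  }
  need <- els[colSums(panel$censored) > 0]
  bad <- need[is.na(panel_mdl[need]) | panel_mdl[need] <= 0]
  if (length(bad))
    stop("no positive MDL available for censored element(s): ",
         paste(bad, collapse = ", "))
  if (any(!is.na(panel_mdl) & panel_mdl <= 0))
    stop("MDL values must be > 0")

  conc <- substitute_nondetects(panel)$conc
  mdlm <- matrix(rep(panel_mdl, each = nrow(conc)), nrow(conc),
                 dimnames = dimnames(conc))
  mdlm[is.na(mdlm)] <- 0  # no MDL recorded: uncertainty is purely proportional
  u <- sqrt((error_fraction * conc)^2 + (0.5 * mdlm)^2)
  u[panel$censored] <- (5 / 6) * mdlm[panel$censored]
  if (any(u <= 0))
    stop("nonpositive uncertainty; zero concentrations need a positive MDL")
  structure(list(u = u, conc = conc, error_fraction = error_fraction,
                 mdl = panel_mdl),
            class = "uncertainty_matrix")
}

#' Construct an uncertainty matrix directly
#'
#' Escape hatch for custom uncertainty schemes (e.g. unit uncertainties,
#' under which the PMF objective reduces to the plain squared Frobenius
#' error). Most users should use [build_uncertainty()].
#'
#' @param conc Working concentration matrix (no missing values).
#' @param u Positive uncertainty matrix of the same shape, or a scalar
#'   recycled to all cells.
#' @return An `uncertainty_matrix`.
#' @export
uncertainty_matrix <- function(conc, u) {
  conc <- as.matrix(conc)
  if (anyNA(conc)) stop("`conc` must have no missing values")
  if (length(u) == 1L) u <- matrix(u, nrow(conc), ncol(conc))
  u <- as.matrix(u)
  if (!identical(dim(u), dim(conc))) stop("`u` must match `conc` in shape")
  if (any(!is.finite(u)) || any(u <= 0)) stop("all uncertainties must be > 0")
  dimnames(u) <- dimnames(conc)
  structure(list(u = u, conc = conc, error_fraction = NA_real_,
                 mdl = NULL),
            class = "uncertainty_matrix")
}

# One run of alternating weighted multiplicative updates from a given start.
# Minimizes sum(w * (x - g f)^2) with w fixed; returns the Q trace so callers
# can assert monotone descent.
.pmf_inner <- function(x, w, g, f, tol = 1e-8, maxit = 5000,
                       check_nonneg = FALSE) {
  eps <- 1e-12
  wx <- w * x
  q_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    wxf <- w * (g %*% f)
    g <- g * ((wx %*% t(f)) / (wxf %*% t(f) + eps))
    wxf <- w * (g %*% f)
    f <- f * ((t(g) %*% wx) / (t(g) %*% wxf + eps))
    if (check_nonneg && (any(g < 0) || any(f < 0)))
      stop("nonnegativity violated during PMF update")
    q <- sum(w * (x - g %*% f)^2)
    trace <- c(trace, q)
    if (is.finite(q_prev) && abs(q_prev - q) <= tol * max(q_prev, eps)) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  list(g = g, f = f, q = q, trace = trace, converged = converged)
}

.pmf_init <- function(x, k) {
  n <- nrow(x); p <- ncol(x)
  scale <- sqrt(mean(x) / k)
  list(g = matrix(stats::runif(n * k, 0.1, 1) * scale, n, k),
       f = matrix(stats::runif(k * p, 0.1, 1) * scale, k, p))
}

#' Fit an uncertainty-weighted positive matrix factorization
#'
#' Decomposes the samples-x-elements concentration matrix \eqn{X} into
#' nonnegative contributions \eqn{G} (samples x factors) and profiles
#' \eqn{F} (factors x elements) by minimizing
#' \deqn{Q = \sum_{ij} (e_{ij}/U_{ij})^2, \quad e = X - GF,}
#' using alternating weighted multiplicative least-squares updates with
#' multiple random restarts. In robust mode, cells whose scaled residual
#' exceeds 4 in magnitude are iteratively downweighted (effective
#' uncertainty inflated by \eqn{\sqrt{|e/u|/4}}), and both \eqn{Q_{true}}
#' (original uncertainties) and \eqn{Q_{robust}} are reported.
#'
#' After fitting, factor contributions are normalized to mean 1 so profile
#' rows are expressed in mg/kg per unit contribution.
#'
#' @param panel A [sample_panel()].
#' @param unc An [build_uncertainty()] result matching the panel.
#' @param k Number of factors, `1 <= k < min(samples, elements)`.
#' @param restarts Random restarts (default 20); the solution with the
#'   lowest objective is kept.
#' @param seed Integer seed; restart `r` uses stream `seed + r - 1`.
#' @param robust Enable robust re-weighting (default `TRUE`).
#' @param tol Relative convergence tolerance on Q (default 1e-8).
#' @param maxit Maximum update iterations per (re)weighting pass.
#' @param check_nonneg Assert nonnegativity of G and F at every iteration
#'   (slow; used by the test suite).
#' @param warm_starts Optional list of `list(g, f)` starting points run in
#'   addition to the random restarts.
#' @return An object of class `pmf_solution`: `g`, `f`, `q_true`,
#'   `q_robust`, `r2` (per element and `overall`), `scaled_residuals` (w.r.t.
#'   the original uncertainties), `factor_count`, `restart_seed`,
#'   `converged`, `q_trace`, plus the inputs `x` and `u`.
#' @export
fit_pmf <- function(panel, unc, k, restarts = 20, seed = 1L, robust = TRUE,
                    tol = 1e-8, maxit = 5000, check_nonneg = FALSE,
                    warm_starts = NULL) {
  stopifnot(inherits(panel, "sample_panel"),
            inherits(unc, "uncertainty_matrix"))
  x <- unc$conc
  u <- unc$u
  if (!identical(dim(x), dim(u))) stop("uncertainty does not match panel")
  if (k < 1 || k >= min(dim(x)))
    stop("factor count k must satisfy 1 <= k < min(samples, elements)")
  if (restarts < 1) stop("need at least one restart")

  starts <- list()
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    starts[[r]] <- c(.pmf_init(x, k), list(seed = seed + r - 1L))
  }
  for (ws in warm_starts)
    starts[[length(starts) + 1L]] <- list(g = ws$g, f = ws$f, seed = NA)

  best <- NULL
  for (st in starts) {
    fit <- .pmf_run_one(x, u, st$g, st$f, robust, tol, maxit, check_nonneg)
    fit$restart_seed <- st$seed
    score <- if (robust) fit$q_robust else fit$q_true
    if (is.null(best) || score < best$score) {
      fit$score <- score
      best <- fit
    }
  }

  # normalize contributions to mean 1; profiles become mg/kg per unit
  g <- best$g; f <- best$f
  s <- colMeans(g)
  pos <- s > 0
  g[, pos] <- sweep(g[, pos, drop = FALSE], 2, s[pos], "/")
  f[pos, ] <- sweep(f[pos, , drop = FALSE], 1, s[pos], "*")
  dimnames(g) <- list(rownames(x), paste0("factor", seq_len(k)))
  dimnames(f) <- list(paste0("factor", seq_len(k)), colnames(x))

  xhat <- g %*% f
  res <- (x - xhat) / u
  r2_el <- vapply(seq_len(ncol(x)), function(j) {
    ss_tot <- sum((x[, j] - mean(x[, j]))^2)
    1 - sum((x[, j] - xhat[, j])^2) / ss_tot
  }, numeric(1))
  names(r2_el) <- colnames(x)
  r2_overall <- 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)

  structure(list(
    g = g, f = f, q_true = best$q_true, q_robust = best$q_robust,
    r2 = c(r2_el, overall = r2_overall), scaled_residuals = res,
    factor_count = k, restart_seed = best$restart_seed,
    converged = best$converged, q_trace = best$trace,
    x = x, u = u, robust = robust, elements = colnames(x)),
    class = "pmf_solution")
}

.pmf_run_one <- function(x, u, g, f, robust, tol, maxit, check_nonneg) {
  w <- 1 / u^2
  fit <- .pmf_inner(x, w, g, f, tol, maxit, check_nonneg)
  u_eff <- u
  if (robust) {
    for (round in seq_len(20)) {
      res <- (x - fit$g %*% fit$f) / u
      u_new <- u
      out <- abs(res) > 4
      u_new[out] <- u[out] * sqrt(abs(res[out]) / 4)
      q_prev <- sum(((x - fit$g %*% fit$f) / u_eff)^2)
      u_eff <- u_new
      fit2 <- .pmf_inner(x, 1 / u_eff^2, fit$g, fit$f, tol, maxit,
                         check_nonneg)
      fit2$trace <- c(fit$trace, fit2$trace)
      fit <- fit2
      if (abs(q_prev - fit$q) <= tol * max(q_prev, 1e-12)) break
    }
  }
  gf <- fit$g %*% fit$f
  list(g = fit$g, f = fit$f,
       q_true = sum(((x - gf) / u)^2),
       q_robust = sum(((x - gf) / u_eff)^2),
       trace = fit$trace, converged = fit$converged)
}

#' @export
print.pmf_solution <- function(x, ...) {
  cat(sprintf(
    "<pmf_solution> k = %d, Q_true = %.4g, Q_robust = %.4g (ratio %.3f)%s\n",
    x$factor_count, x$q_true, x$q_robust, x$q_robust / x$q_true,
    if (x$converged) "" else " [not converged]"))
  cat("profiles (mg/kg per unit contribution):\n")
  print(signif(x$f, 4))
  invisible(x)
}

#' Goodness-of-fit diagnostics for a PMF solution
#'
#' Reports the fraction of scaled residuals within \[-3, +3\], per-element
#' and overall \eqn{R^2} between observed and reconstructed concentrations,
#' and the \eqn{Q_{robust}/Q_{true}} ratio, with pass/fail flags against the
#' conventional thresholds (residual fraction >= 0.955, overall
#' \eqn{R^2 >= 0.98} by default).
#'
#' @param sol A [fit_pmf()] solution.
#' @param resid_fraction_min,r2_min Acceptance thresholds.
#' @return A list: `resid_fraction`, `r2_element`, `r2_overall`, `q_ratio`,
#'   `pass_residuals`, `pass_r2`, `pass`.
#' @export
diagnose_fit <- function(sol, resid_fraction_min = 0.955, r2_min = 0.98) {
  stopifnot(inherits(sol, "pmf_solution"))
  frac <- mean(abs(sol$scaled_residuals) <= 3)
  r2_el <- sol$r2[sol$elements]
  r2_all <- sol$r2[["overall"]]
  list(resid_fraction = frac,
       r2_element = r2_el,
       r2_overall = r2_all,
       q_ratio = sol$q_robust / sol$q_true,
       pass_residuals = frac >= resid_fraction_min,
       pass_r2 = is.finite(r2_all) && r2_all >= r2_min,
       pass = frac >= resid_fraction_min && is.finite(r2_all) &&
         r2_all >= r2_min)
}

#' Source-contribution percentages
#'
#' Per element j, the share of factor k is the mean reconstructed mass that
#' factor contributes, \eqn{\overline{g_k} f_{kj}}, as a percentage of the
#' mean reconstructed concentration of j. The overall share of a factor is
#' its mass-weighted mean across elements. Shares sum to 100 per element and
#' overall.
#'
#' @param sol A [fit_pmf()] solution.
#' @return A list: `element_share` (factors x elements, percent) and
#'   `overall_share` (per factor, percent). Elements whose reconstructed
#'   concentration is zero get `NA` shares and a warning.
#' @export
contribution_percentages <- function(sol) {
  stopifnot(inherits(sol, "pmf_solution"))
  gbar <- colMeans(sol$g)
  mass <- gbar * sol$f               # k x p mean reconstructed mass
  tot <- colSums(mass)
  if (any(tot == 0))
    warning("zero reconstructed concentration for element(s): ",
            paste(sol$elements[tot == 0], collapse = ", "))
  share <- sweep(mass, 2, tot, "/") * 100
  share[, tot == 0] <- NA_real_
  rownames(share) <- paste0("factor", seq_len(nrow(share)))
  overall <- rowSums(mass) / sum(mass) * 100
  names(overall) <- rownames(share)
  list(element_share = share, overall_share = overall)
}

#' Match fitted factors to reference profiles
#'
#' Resolves the permutation ambiguity of a factorization by best-matching
#' fitted profile rows to reference profile rows (exhaustive assignment
#' search, maximizing total cosine similarity). Because panel elements span
#' orders of magnitude, profiles are compared in element-scaled space by
#' default: each element is divided by its mean working concentration, so
#' every element carries comparable weight in the similarity (trace elements
#' such as Hg would otherwise be invisible next to Cr or Ni).
#'
#' @param sol A [fit_pmf()] solution.
#' @param f_ref Reference profile matrix (factors x elements, same columns).
#' @param scale Per-element scale divisor; default the mean working
#'   concentration of each element. Use `scale = 1` for raw-space cosines.
#' @return A list: `perm` (for each reference factor, the index of the
#'   matched fitted factor), `cosine` (per matched pair), `mean_cosine`,
#'   `min_cosine`.
#' @export
match_factors <- function(sol, f_ref, scale = NULL) {
  stopifnot(inherits(sol, "pmf_solution"))
  f_ref <- as.matrix(f_ref)
  if (nrow(f_ref) != sol$factor_count)
    stop("reference must have one row per fitted factor")
  if (is.null(scale)) scale <- colMeans(sol$x)
  fs <- sweep(sol$f, 2, scale, "/")
  rs <- sweep(f_ref, 2, scale, "/")
  k <- nrow(fs)
  cossim <- function(a, b) {
    d <- sqrt(sum(a^2) * sum(b^2))
    if (d == 0) 0 else sum(a * b) / d
  }
  cm <- outer(seq_len(k), seq_len(k),
              Vectorize(function(i, j) cossim(fs[i, ], rs[j, ])))
  perms <- .permutations(k)
  tot <- vapply(perms, function(pm)
    sum(cm[cbind(pm, seq_len(k))]), numeric(1))
  best <- perms[[which.max(tot)]]
  cos <- cm[cbind(best, seq_len(k))]
  names(cos) <- rownames(f_ref)
  list(perm = best, cosine = cos, mean_cosine = mean(cos),
       min_cosine = min(cos))
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (sub in .permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[sub])
    }
  }
  out
}

#' Explore the number of factors
#'
#' Fits PMF over a range of factor counts and tabulates the best-of-restarts
#' objective values and diagnostics for analyst review; no automatic choice
#' is made. Each k beyond the first also warm-starts from the best (k-1)
#' solution augmented with a small extra factor, so the reported best Q is
#' non-increasing in k (nested-model property).
#'
#' @inheritParams fit_pmf
#' @param k_range Integer vector of factor counts to try (e.g. `3:6`).
#' @return A list: `table` (data.frame of k, q_true, q_robust, q_drop,
#'   resid_fraction, r2_overall, converged) and `solutions` (per k).
#' @export
select_factor_count <- function(panel, unc, k_range, restarts = 20,
                                seed = 1L, robust = TRUE, tol = 1e-8,
                                maxit = 5000) {
  k_range <- sort(unique(as.integer(k_range)))
  sols <- list()
  prev <- NULL
  rows <- list()
  for (k in k_range) {
    ws <- NULL
    if (!is.null(prev) && prev$factor_count == k - 1L) {
      set.seed(seed + 10000L + k)
      n <- nrow(prev$g); p <- ncol(prev$f)
      tiny <- 1e-6 * mean(unc$conc)
      ws <- list(list(g = cbind(prev$g, matrix(stats::runif(n), n, 1) * tiny),
                      f = rbind(prev$f, matrix(stats::runif(p), 1, p) * tiny)))
    }
    sol <- fit_pmf(panel, unc, k, restarts = restarts, seed = seed,
                   robust = robust, tol = tol, maxit = maxit,
                   warm_starts = ws)
    d <- diagnose_fit(sol)
    rows[[as.character(k)]] <- data.frame(
      k = k, q_true = sol$q_true, q_robust = sol$q_robust,
      resid_fraction = d$resid_fraction, r2_overall = d$r2_overall,
      converged = sol$converged)
    sols[[as.character(k)]] <- sol
    prev <- sol
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  score <- if (robust) tab$q_robust else tab$q_true
  tab$q_drop <- c(NA, -diff(score))  # Q-vs-k slope for the analyst
  list(table = tab, solutions = sols)
}
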