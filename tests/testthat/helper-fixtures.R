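# Shared fixtures built in code.

# Panel of n identical rows at given per-element concentrations.
constant_panel <- function(values, n = 1) {
  m <- matrix(rep(values, each = n), n, length(values),
              dimnames = list(NULL, names(values)))
  sample_panel(m)
}

# Three-sample panel whose per-element sample mean and sample SD equal the
# given moments exactly: {m - d/2, m - d/2, m + d} with d = s / sqrt(3/4).
# Keeps all values positive even when s > m (right-skewed construction).
moment_panel <- function(means, sds) {
  d <- sds / sqrt(0.75)
  m <- rbind(means - d / 2, means - d / 2, means + d)
  colnames(m) <- names(means)
  stopifnot(all(m > 0))
  sample_panel(m)
}

survey_moment_panel <- function() {
  st <- survey_reference_stats()
  moment_panel(stats::setNames(st$mean, st$element),
               stats::setNames(st$sd, st$element))
}

# Fully degenerate (point-valued) exposure model for closed-form checks.
point_exposure_model <- function(receptor = "child", R_ingest = 100,
                                 EF = 350, ED = 10, R_inhal = 7.6,
                                 PEF = 1.36e9, BW = 20, AT = 3650,
                                 SA = 7422, AF = 0.65, ABF = 0.001) {
  exposure_model(receptor,
                 R_ingest = dist_point(R_ingest), EF = dist_point(EF),
                 ED = dist_point(ED), R_inhal = dist_point(R_inhal),
                 PEF = dist_point(PEF), BW = dist_point(BW),
                 AT = dist_point(AT), SA = dist_point(SA),
                 AF = dist_point(AF), ABF = dist_point(ABF))
}

# Small random nonnegative factorization problem (exact low rank).
random_rank_k <- function(n, p, k, seed = 1, noise = 0) {
  set.seed(seed)
  g <- matrix(runif(n * k, 0.2, 2), n, k)
  f <- matrix(runif(k * p, 0.5, 5), k, p)
  x <- g %*% f
  if (noise > 0) x <- x + matrix(abs(rnorm(n * p, 0, noise)), n, p)
  colnames(x) <- default_elements()[seq_len(p)]
  list(x = x, g = g, f = f, panel = sample_panel(x))
}
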