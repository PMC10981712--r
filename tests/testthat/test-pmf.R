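test_that("uncertainty construction follows the concentration-based rule", {
  p <- sample_panel(matrix(10, 1, 1, dimnames = list(NULL, "Cr")))
  u <- build_uncertainty(p, error_fraction = 0.1, mdl = c(Cr = 1))
  expect_equal(u$u[1, 1], sqrt((0.1 * 10)^2 + 0.5^2))  # 1.118
  # censored cell: value and uncertainty both 5/6 MDL
  pc <- sample_panel(matrix(NA_real_, 1, 1, dimnames = list(NULL, "Hg")),
                     censored = matrix(TRUE), detection_limit = 1.2)
  uc <- build_uncertainty(pc, 0.1)
  expect_equal(uc$conc[1, 1], 1.0)
  expect_equal(uc$u[1, 1], 1.0)
  # zero error fraction leaves the MDL floor
  u0 <- build_uncertainty(p, 0, mdl = c(Cr = 1))
  expect_equal(u0$u[1, 1], 0.5)
  expect_true(all(u0$u > 0))
  # nonpositive MDL is rejected
  expect_error(build_uncertainty(
    sample_panel(matrix(1, 1, 1, dimnames = list(NULL, "Hg"))),
    0.1, mdl = c(Hg = -1)), "MDL")
})

test_that("a noiseless rank-1 panel is factorized exactly", {
  rk <- random_rank_k(20, 5, 1, seed = 31)
  unc <- uncertainty_matrix(rk$x, 1)
  sol <- fit_pmf(rk$panel, unc, 1, restarts = 5, seed = 3)
  expect_lt(sol$q_true, 1e-12)
  expect_lt(max(abs(sol$g %*% sol$f - rk$x) / rk$x), 1e-6)
  d <- diagnose_fit(sol)
  expect_equal(d$resid_fraction, 1)
  expect_equal(d$r2_overall, 1, tolerance = 1e-9)
})

test_that("fits are deterministic under a fixed seed", {
  rk <- random_rank_k(15, 6, 2, seed = 37, noise = 0.05)
  unc <- uncertainty_matrix(rk$x, 1)
  s1 <- fit_pmf(rk$panel, unc, 2, restarts = 3, seed = 41)
  s2 <- fit_pmf(rk$panel, unc, 2, restarts = 3, seed = 41)
  expect_identical(s1$q_true, s2$q_true)
  expect_identical(s1$g, s2$g)
  expect_identical(s1$f, s2$f)
})

test_that("the objective decreases monotonically within a restart", {
  rk <- random_rank_k(25, 8, 3, seed = 43, noise = 0.1)
  unc <- uncertainty_matrix(rk$x, 1)
  sol <- fit_pmf(rk$panel, unc, 3, restarts = 2, seed = 47, robust = FALSE,
                 check_nonneg = TRUE)
  tr <- sol$q_trace
  expect_true(all(diff(tr) <= 1e-12 * pmax(tr[-length(tr)], 1)))
  expect_true(all(sol$g >= 0))
  expect_true(all(sol$f >= 0))
})

test_that("robust mode downweights outliers and reports both objectives", {
  rk <- random_rank_k(20, 6, 2, seed = 53, noise = 0.02)
  x <- rk$x
  x[3, 2] <- x[3, 2] * 5      # gross outlier
  p <- sample_panel(x)
  unc <- uncertainty_matrix(x, 0.1 * abs(x) + 0.1)
  sol <- fit_pmf(p, unc, 2, restarts = 5, seed = 59, robust = TRUE)
  expect_lte(sol$q_robust, sol$q_true)
  expect_lt(diagnose_fit(sol)$q_ratio, 1)
})

test_that("unit-uncertainty PMF matches a generic NMF oracle within 1%", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  rk <- random_rank_k(20, 8, 3, seed = 61, noise = 0.1)
  unc <- uncertainty_matrix(rk$x, 1)
  sol <- fit_pmf(rk$panel, unc, 3, restarts = 10, seed = 67, robust = FALSE)
  xcsv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rk$x, xcsv, row.names = FALSE)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, pandas as pd",
    "from sklearn.decomposition import NMF",
    "x = pd.read_csv(sys.argv[1]).values",
    "best = min(",
    "    float(np.sum((x - (m := NMF(3, init='random', random_state=s,",
    "        max_iter=5000, tol=1e-10)).fit_transform(x) @ m.components_)**2))",
    "    for s in range(8))",
    "print(repr(best))"), script)
  out <- system2("python", c(script, xcsv), stdout = TRUE)
  oracle <- as.numeric(out[length(out)])
  expect_equal(sol$q_true, oracle, tolerance = 0.01)
})

test_that("the default three-source survey is recovered from data", {
  mod <- default_source_model(n_samples = 200, seed = 11, noise_sigma = 0.1)
  sim <- generate_panel(mod)
  unc <- build_uncertainty(sim$panel)
  sol <- fit_pmf(sim$panel, unc, 3, restarts = 20, seed = 5)
  m <- match_factors(sol, sim$f)
  expect_gt(m$mean_cosine, 0.95)
  # the asbestos-matched factor dominates Cr and Ni, as in the field pattern
  shares <- contribution_percentages(sol)
  asb <- m$perm[[1]]
  expect_gt(shares$element_share[asb, "Cr"], 70)
  expect_gt(shares$element_share[asb, "Ni"], 70)
})

test_that("contribution shares are normalized percentages", {
  rk <- random_rank_k(15, 6, 2, seed = 71, noise = 0.05)
  unc <- uncertainty_matrix(rk$x, 1)
  sol <- fit_pmf(rk$panel, unc, 2, restarts = 3, seed = 73)
  sh <- contribution_percentages(sol)
  expect_equal(unname(colSums(sh$element_share)), rep(100, 6),
               tolerance = 1e-6)
  expect_equal(sum(sh$overall_share), 100, tolerance = 1e-6)
  # single factor: everything is 100%
  sol1 <- fit_pmf(rk$panel, unc, 1, restarts = 2, seed = 79)
  sh1 <- contribution_percentages(sol1)
  expect_equal(unname(sh1$element_share[1, ]), rep(100, 6))
  expect_equal(unname(sh1$overall_share), 100)
})

test_that("factor-count exploration reports a non-increasing objective", {
  mod <- default_source_model(n_samples = 120, seed = 83, noise_sigma = 0.1)
  sim <- generate_panel(mod)
  unc <- build_uncertainty(sim$panel)
  sel <- select_factor_count(sim$panel, unc, 3:6, restarts = 5, seed = 89)
  expect_equal(sel$table$k, 3:6)
  expect_true(all(diff(sel$table$q_robust) <= 1e-8 * sel$table$q_robust[-4]))
  # the largest drop happens entering the true factor count
  sel2 <- select_factor_count(sim$panel, unc, 2:4, restarts = 5, seed = 89)
  expect_gt(sel2$table$q_drop[2], sel2$table$q_drop[3])
  # width-1 range gives a single-row table
  sel1 <- select_factor_count(sim$panel, unc, 3, restarts = 2, seed = 97)
  expect_equal(nrow(sel1$table), 1)
})

test_that("degenerate reconstructions are flagged by the diagnostics", {
  # an all-constant reconstruction of varying data has R^2 <= 0 and fails
  x <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2,
              dimnames = list(NULL, c("Cr", "Ni")))
  xhat <- matrix(mean(x), 4, 2)
  r2_el <- vapply(1:2, function(j)
    1 - sum((x[, j] - xhat[, j])^2) / sum((x[, j] - mean(x[, j]))^2),
    numeric(1))
  sol <- structure(list(
    g = matrix(1, 4, 1), f = matrix(mean(x), 1, 2),
    q_true = 1, q_robust = 1,
    r2 = c(Cr = r2_el[1], Ni = r2_el[2],
           overall = 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)),
    scaled_residuals = x - xhat,
    factor_count = 1L, elements = c("Cr", "Ni"), x = x,
    u = matrix(1, 4, 2)), class = "pmf_solution")
  d <- diagnose_fit(sol)
  expect_lte(d$r2_overall, 0)
  expect_true(all(d$r2_element < 0))
  expect_false(d$pass_r2)
  expect_false(d$pass)
})

test_that("invalid factor counts are rejected", {
  rk <- random_rank_k(6, 4, 2, seed = 101)
  unc <- uncertainty_matrix(rk$x, 1)
  expect_error(fit_pmf(rk$panel, unc, 4, restarts = 1, seed = 1), "k")
  expect_error(fit_pmf(rk$panel, unc, 0, restarts = 1, seed = 1), "k")
})
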