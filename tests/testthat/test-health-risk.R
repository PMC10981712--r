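tox <- default_toxicity_reference()

test_that("distribution families sample correctly", {
  expect_equal(sample_parameter(dist_point(350), 3), rep(350, 3))
  u <- sample_parameter(dist_uniform(0, 50), 1e5, seed = 2)
  expect_true(all(u > 0 & u <= 50))
  expect_equal(mean(u), 25, tolerance = 0.01)
  tr <- sample_parameter(dist_triangular(14, 30, 52), 1e5, seed = 3)
  expect_equal(mean(tr), (14 + 30 + 52) / 3, tolerance = 0.01)
  expect_true(all(tr >= 14 & tr <= 52))
  ln <- sample_parameter(dist_lognormal(16.68, 1.48), 1e5, seed = 4)
  expect_equal(exp(mean(log(ln))), 16.68, tolerance = 0.01 * 16.68)
  nt <- sample_parameter(dist_normal_trunc(0.49, 0.54), 1e5, seed = 5)
  expect_true(all(nt > 0))
  expect_error(sample_parameter(dist_point(1), 0), ">= 1")
  expect_error(dist_triangular(5, 2, 10), "min <= mode")
  expect_error(dist_lognormal(10, 0.9), "> 1")
})

test_that("average daily doses match the hand-evaluated closed form", {
  d <- data.frame(R_ingest = 100, EF = 350, ED = 10, R_inhal = 7.6,
                  PEF = 1.36e9, BW = 20, AT = 3650, SA = 7422, AF = 0.65,
                  ABF = 0.001)
  add <- compute_add(100, d)
  # independent hand evaluation: EF*ED = total exposure days over AT days
  expect_equal(unname(add[1, "ingest"]),
               100 * 100 * 350 * 10 / (20 * 3650) * 1e-6)
  expect_equal(unname(add[1, "ingest"]), 4.795e-4, tolerance = 1e-4)
  expect_equal(unname(add[1, "dermal"]),
               100 * 7422 * 0.65 * 0.001 * 350 * 10 / (20 * 3650) * 1e-6)
  expect_equal(unname(add[1, "inhal"]),
               100 * 7.6 * 350 * 10 / (1.36e9 * 20 * 3650))
  # linearity and homogeneity in concentration
  expect_equal(unname(compute_add(0, d)), unname(add * 0))
  expect_equal(unname(compute_add(200, d)), unname(2 * add))
})

test_that("hazard quotients sum ADD/RfD over pathways with an RfD", {
  add <- list(As = cbind(ingest = 3e-4, inhal = 0, dermal = 0))
  out <- compute_hq_hi(add, tox)
  expect_equal(unname(out$hq[1, "As"]), 1)        # RfD ingest = 3e-4
  expect_equal(out$hi, 1)
  add0 <- list(As = cbind(ingest = 0, inhal = 0, dermal = 0))
  expect_equal(compute_hq_hi(add0, tox)$hi, 0)
  # additivity over elements
  add2 <- list(As = cbind(ingest = 0.3 * 3e-4, inhal = 0, dermal = 0),
               Cd = cbind(ingest = 0.7 * 1e-3, inhal = 0, dermal = 0))
  expect_equal(compute_hq_hi(add2, tox)$hi, 1.0)
})

test_that("carcinogenic risk skips pathways without a slope factor", {
  one <- cbind(ingest = 1e-5, inhal = 1e-5, dermal = 1e-5)
  # Cu has no SF at all: contributes exactly zero
  expect_equal(unname(compute_cr_tcr(list(Cu = one), tox)$cr[1, "Cu"]), 0)
  # Cd: dermal SF absent, oral + inhalation included
  expect_equal(unname(compute_cr_tcr(list(Cd = one), tox)$cr[1, "Cd"]),
               1e-5 * 6.1 + 1e-5 * 6.30)
  # simple product
  expect_equal(unname(compute_cr_tcr(
    list(As = cbind(ingest = 1e-5, inhal = 0, dermal = 0)), tox)$cr[1, "As"]),
    1.5e-5)
})

test_that("degenerate Monte Carlo equals the deterministic closed form", {
  p <- constant_panel(c(As = 100))
  rs <- suppressWarnings(
    run_monte_carlo(p, point_exposure_model(), tox, iterations = 50,
                    seed = 7))
  # independent hand calculation of the three doses
  days <- 350 * 10; denom <- 20 * 3650
  addi <- 100 * 100 * days / denom * 1e-6
  addh <- 100 * 7.6 * days / (1.36e9 * denom)
  addd <- 100 * 7422 * 0.65 * 0.001 * days / denom * 1e-6
  hq <- addi / 3e-4 + addh / 1.23e-4 + addd / 1.23e-4
  cr <- addi * 1.5 + addh * 1.51 + addd * 3.66
  s <- rs$summary
  for (col in c("mean", "p5", "p50", "p95")) {
    expect_equal(s[s$quantity == "HQ", col], hq)
    expect_equal(s[s$quantity == "CR", col], cr)
  }
  expect_equal(rs$aggregate$mean[rs$aggregate$quantity == "HI"], hq)
  expect_equal(rs$aggregate$mean[rs$aggregate$quantity == "TCR"], cr)
})

test_that("fixed seeds reproduce the whole summary bitwise", {
  p <- constant_panel(c(As = 21.79, Cr = 580.04), n = 5)
  r1 <- run_monte_carlo(p, default_exposure_model("adult"), tox, 2000,
                        seed = 11)
  r2 <- run_monte_carlo(p, default_exposure_model("adult"), tox, 2000,
                        seed = 11)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$aggregate, r2$aggregate)
})

test_that("children receive higher soil doses and risks than adults", {
  p <- constant_panel(c(As = 21.79))
  rc <- run_monte_carlo(p, default_exposure_model("child"), tox, 10000,
                        seed = 13)
  ra <- run_monte_carlo(p, default_exposure_model("adult"), tox, 10000,
                        seed = 13)
  gi <- function(r, q) r$summary$mean[r$summary$quantity == q]
  expect_gt(gi(rc, "ADD_ingest"), gi(ra, "ADD_ingest"))
  expect_gt(gi(rc, "CR"), gi(ra, "CR"))
})

test_that("mean TCR scales linearly with a global concentration factor", {
  base <- c(As = 21.79, Cr = 580.04, Cd = 0.09, Ni = 636.93)
  p1 <- constant_panel(base, n = 3)
  p10 <- constant_panel(10 * base, n = 3)
  em <- default_exposure_model("child")
  r1 <- run_monte_carlo(p1, em, tox, 10000, seed = 17)
  r10 <- run_monte_carlo(p10, em, tox, 10000, seed = 17)
  t1 <- r1$aggregate$mean[r1$aggregate$quantity == "TCR"]
  t10 <- r10$aggregate$mean[r10$aggregate$quantity == "TCR"]
  expect_equal(t10 / t1, 10, tolerance = 1e-10)  # matched draws: exact
  # and across independent seeds, within Monte Carlo error
  r10b <- run_monte_carlo(p10, em, tox, 10000, seed = 18)
  t10b <- r10b$aggregate$mean[r10b$aggregate$quantity == "TCR"]
  expect_equal(t10b / t1, 10, tolerance = 0.1)
})

test_that("raising any concentration never lowers mean HI or TCR", {
  base <- c(As = 21.79, Cr = 580.04, Ni = 636.93)
  em <- default_exposure_model("adult")
  r0 <- run_monte_carlo(constant_panel(base, 2), em, tox, 5000, seed = 19)
  for (el in names(base)) {
    up <- base; up[el] <- up[el] * 2
    r1 <- run_monte_carlo(constant_panel(up, 2), em, tox, 5000, seed = 19)
    expect_gte(r1$aggregate$mean[1], r0$aggregate$mean[1])  # HI
    expect_gte(r1$aggregate$mean[2], r0$aggregate$mean[2])  # TCR
  }
})

test_that("summary percentiles are stable across seeds at 10k iterations", {
  mod <- default_source_model(n_samples = 60, seed = 23)
  p <- substitute_nondetects(generate_panel(mod)$panel)
  em <- default_exposure_model("child")
  runs <- lapply(c(29, 31, 37), function(s)
    run_monte_carlo(p, em, tox, 10000, seed = s)$aggregate)
  means <- sapply(runs, function(a) a$mean[a$quantity == "TCR"])
  p95s <- sapply(runs, function(a) a$p95[a$quantity == "TCR"])
  expect_lt(diff(range(means)) / mean(means), 0.10)  # +/-5% about centre
  expect_lt(diff(range(p95s)) / mean(p95s), 0.20)    # +/-10% about centre
  # percentile ordering invariant
  for (a in runs) expect_true(all(a$p5 <= a$p50 & a$p50 <= a$p95))
})

test_that("exposure model validates inputs and loads from YAML", {
  expect_error(default_exposure_model("dog"))
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "child:",
    "  R_ingest: {family: triangular, params: [66, 103, 161]}",
    "  EF: {family: point, params: [350]}",
    "  ED: {family: uniform, params: [0, 10]}",
    "  R_inhal: {family: point, params: [7.6]}",
    "  PEF: {family: point, params: [1.36e9]}",
    "  BW: {family: lognormal, params: [16.68, 1.48]}",
    "  AT: {family: point, params: [2190]}",
    "  SA: {family: lognormal, params: [7422, 1.25]}",
    "  AF: {family: lognormal, params: [0.65, 1.2]}",
    "  ABF: {family: point, params: [0.001]}"), cfg)
  em <- load_exposure_model(cfg, "child")
  expect_s3_class(em, "exposure_model")
  expect_equal(em$BW$params[["gm"]], 16.68)
  expect_error(load_exposure_model(cfg, "adult"), "adult")
})
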