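# Monte Carlo sampling of coherent-scattering angles.

test_that("sampling is bit-identical for a fixed configuration and seed", {
  cfg <- sampling_config(14, 7.5, n_photons = 1, seed = 13)
  b1 <- sample_angles(cfg)
  b2 <- sample_angles(cfg)
  expect_identical(b1$angles, b2$angles)
  expect_length(b1$angles, 1L)

  cfg2 <- sampling_config(25, 5, n_photons = 5000, seed = 4)
  expect_identical(sample_angles(cfg2)$angles, sample_angles(cfg2)$angles)
  # a different seed gives a different draw
  cfg3 <- sampling_config(25, 5, n_photons = 5000, seed = 5)
  expect_false(identical(sample_angles(cfg2)$angles,
                         sample_angles(cfg3)$angles))
})

test_that("sampled angles stay in [0, pi] and acceptance is in (1/2, 1]", {
  for (E in c(2.5, 10)) {
    b <- sample_angles(sampling_config(11, E, n_photons = 20000, seed = 2))
    expect_true(all(b$angles >= 0 & b$angles <= pi))
    expect_gt(b$acceptance_rate, 0.5)
    expect_lte(b$acceptance_rate, 1)
  }
})

test_that("deterministic density integrates to one and matches brute force", {
  cfg <- sampling_config(25, 10, n_photons = 1, n_bins = 50)
  pdf <- deterministic_pdf(cfg)
  widths <- diff(pdf$bin_edges)
  expect_true(all(pdf$density >= 0))
  expect_equal(sum(pdf$density * widths), 1, tolerance = 1e-9)

  # constant form factor: density proportional to (1 + cos^2) sin
  flat_cfg <- sampling_config(1, 0.01, n_photons = 1, n_bins = 50)
  pdf_flat <- deterministic_pdf(flat_cfg)
  centers <- (pdf_flat$bin_edges[-1] + pdf_flat$bin_edges[-51]) / 2
  want <- (1 + cos(centers)^2) * sin(centers)
  ratio <- pdf_flat$density / want
  expect_lt(diff(range(ratio)) / mean(ratio), 2e-3)

  # brute-force Riemann construction, 1e6 points over [0, pi]
  cfg2 <- sampling_config(1, 2.5, n_photons = 1, n_bins = 50)
  pdf2 <- deterministic_pdf(cfg2)
  kin <- cfg2$kin
  n <- 1e6
  th <- (seq_len(n) - 0.5) * pi / n
  g <- rayleigh_dcs(th, kin, get_params(1)) * sin(th)
  bins <- findInterval(th, pdf2$bin_edges, all.inside = TRUE)
  brute <- tapply(g, bins, sum)
  brute <- brute / sum(brute) / diff(pdf2$bin_edges)
  expect_equal(unname(pdf2$density), unname(as.numeric(brute)),
               tolerance = 1e-4)
})

test_that("sampler goodness of fit against the deterministic density", {
  cfg <- sampling_config(1, 2.5, n_photons = 2e5, seed = 17, n_bins = 50)
  nm <- noise_metric(sample_angles(cfg), deterministic_pdf(cfg))
  # reduced chi-square near 1; p-value guards against gross distortion
  p <- stats::pchisq(nm$chi2, df = nm$dof, lower.tail = FALSE)
  expect_gt(p, 1e-4)
  expect_lt(nm$reduced, 1.6)
  expect_gt(nm$reduced, 0.5)
  expect_equal(nm$chi2, sum(nm$residuals^2), tolerance = 1e-12)
  expect_identical(nm$dof, nm$n_bins_used - 1L)
})

test_that("low-energy limit reproduces the pure Thomson distribution", {
  b <- sample_angles(sampling_config(14, 0.01, n_photons = 1e5, seed = 8))
  ks <- suppressWarnings(stats::ks.test(b$angles, oracle_thomson_cdf))
  # 1% critical value of the one-sample KS statistic at n = 1e5
  expect_lt(unname(ks$statistic), 1.628 / sqrt(1e5))
})

test_that("histograms built from expected counts give near-zero chi-square", {
  cfg <- sampling_config(11, 5, n_photons = 1e5, n_bins = 40, seed = 1)
  ref <- deterministic_pdf(cfg)
  widths <- diff(ref$bin_edges)
  expected <- ref$density * widths * cfg$n_photons
  centers <- (ref$bin_edges[-1] + ref$bin_edges[-41]) / 2
  angles <- rep(centers, times = round(expected))
  fake <- structure(list(angles = angles,
                         config = sampling_config(11, 5,
                                                  n_photons = length(angles),
                                                  n_bins = 40),
                         acceptance_rate = 1),
                    class = "sample_batch")
  nm <- noise_metric(fake, ref)
  expect_lt(nm$reduced, 0.01)  # only count-rounding survives
})

test_that("sampling histograms converge to the deterministic density", {
  cfg_small <- sampling_config(25, 7.5, n_photons = 1e4, seed = 6)
  cfg_big <- sampling_config(25, 7.5, n_photons = 1e6, seed = 6)
  ref <- deterministic_pdf(cfg_small)
  dev_of <- function(b) {
    sp <- sampled_pdf(b)
    max(abs(sp$density - ref$density))
  }
  expect_lt(dev_of(sample_angles(cfg_big)), dev_of(sample_angles(cfg_small)))
})

test_that("sparse-table LIT sampling is noisier than the analytic function", {
  seeds <- 1:6
  tab10 <- generate_fixture(11, n_points = 10, q_range = c(0, 16))
  ref <- deterministic_pdf(sampling_config(11, 5, n_photons = 1))
  chi <- function(seed, mode, table = NULL) {
    cfg <- sampling_config(11, 5, n_photons = 5e4, seed = seed, mode = mode,
                           table = table)
    noise_metric(sample_angles(cfg), ref)$reduced
  }
  a <- vapply(seeds, chi, numeric(1), mode = "analytic")
  l <- vapply(seeds, chi, numeric(1), mode = "table_lit", table = tab10)
  expect_true(all(l > a))
})

test_that("paired mode comparison reports direction and A/A seed noise", {
  rep <- compare_modes(11, 5, n_photons = 5e4, seeds = 1:6)
  expect_lte(rep$median_analytic, rep$median_table)
  expect_identical(nrow(rep$per_seed), 6L)
  expect_true(rep$p_sign >= 0 && rep$p_sign <= 1)
  expect_error(compare_modes(11, 5, 1000, seeds = 1:3), "at least 5")

  # A/A: two analytic arms differing only by seed offset are exchangeable
  ref <- deterministic_pdf(sampling_config(11, 5, n_photons = 1))
  chi <- function(seed) {
    cfg <- sampling_config(11, 5, n_photons = 2e4, seed = seed)
    noise_metric(sample_angles(cfg), ref)$reduced
  }
  arm1 <- vapply(1:8, chi, numeric(1))
  arm2 <- vapply(101:108, chi, numeric(1))
  p <- stats::binom.test(sum(arm1 < arm2), 8, 0.5,
                         alternative = "greater")$p.value
  expect_gt(p, 0.05)
})

test_that("configuration validation catches the usual mistakes", {
  expect_error(sampling_config(11, 5, n_photons = 0), "at least 1")
  expect_error(sampling_config(11, 5, 100, mode = "table_lit"),
               "requires an")
  short_tab <- generate_fixture(11, n_points = 20, q_range = c(0, 2))
  expect_error(sampling_config(11, 10, 100, mode = "table_lit",
                               table = short_tab), "covers q in")
  expect_error(scatter_kinematics(-5), "positive")
})
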