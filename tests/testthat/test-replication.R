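test_that("observed replication requires nominal significance and matching direction", {
  d <- default_design()
  expect_equal(observed_replication_rate(
    paired_zscores(c(6, -6, 6), c(3, -3, 0.1), design = d), d), 2 / 3)
  expect_equal(observed_replication_rate(
    paired_zscores(c(8, -7, 9), c(8, -7, 9), design = d), d), 1)
  expect_equal(observed_replication_rate(
    paired_zscores(c(8, -7, 9), -c(8, -7, 9), design = d), d), 0)
  # a replication z of exactly zero is a failure, whatever alpha
  expect_equal(observed_replication_rate(
    paired_zscores(6, 0, design = d), d), 0)
  expect_error(observed_replication_rate(
    paired_zscores(0.5, 0.5, design = d), d), "undefined")
})

test_that("expected replication rate equals the nominal level under the pure-noise model", {
  d <- default_design()
  data <- paired_zscores(c(6, -7, 12), c(1, 2, 3), design = d)
  vc0 <- variance_components(0)
  expect_equal(expected_replication_rate(data, d, vc0), 0.05,
               tolerance = 1e-14)
  expect_equal(expected_replication_rate(data, d, vc0,
                                         direction_aware = TRUE), 0.025,
               tolerance = 1e-14)
  da <- study_design(2000, 1000, 1e6, replication_alpha = 0.2)
  expect_equal(expected_replication_rate(data, da, vc0), 0.2,
               tolerance = 1e-14)
})

test_that("expected rate averages two-tailed conditional exceedance probabilities", {
  d <- default_design()
  vc <- vc_from_sigma(0.022, 0.015, 0.01)
  x <- c(6, -5.8, 7.4, -9)
  data <- paired_zscores(x, c(2, -1, 3, -4), design = d)
  cond <- conditional_replication(x, d, vc)
  z_a <- qnorm(0.975)
  s <- sqrt(cond$variance)
  manual <- mean(pnorm((z_a - cond$mean) / s, lower.tail = FALSE) +
                   pnorm((-z_a - cond$mean) / s))
  expect_equal(expected_replication_rate(data, d, vc), manual,
               tolerance = 1e-14)
  # conditional mean exactly at the replication cut with unit variance:
  # P = 1/2 plus the tiny opposite tail
  expect_equal(pnorm((z_a - z_a) / 1, lower.tail = FALSE) + pnorm(-2 * z_a),
               0.5 + pnorm(-2 * qnorm(0.975)), tolerance = 1e-15)
})

test_that("direction-aware expected rate never exceeds the direction-agnostic rate", {
  cfg <- simulation_config(n_variants = 1e5, sigma_g = 0.022,
                           sigma_c1 = 0.03, sigma_c2 = 0.022, seed = 31)
  r <- simulate_pair(cfg)
  d <- as_study_design(cfg)
  vc <- vc_from_sigma(0.022, 0.03, 0.022)
  p_both <- predict_replication(r$data, d, vc)$replication_prob
  p_dir <- predict_replication(r$data, d, vc,
                               direction_aware = TRUE)$replication_prob
  expect_true(all(p_dir <= p_both))
  expect_true(all(p_both >= 0 & p_both <= 1))
})

test_that("variance decomposition splits the discovery signal and sums to one", {
  expect_equal(variance_explained(vc_from_sigma(0.02, 0)),
               c(pg = 1, pc1 = 0))
  expect_equal(variance_explained(vc_from_sigma(0.025, 0.025)),
               c(pg = 0.5, pc1 = 0.5))
  pv <- variance_explained(vc_from_sigma(0.018, 0.03))
  expect_equal(unname(pv["pc1"]), 0.0009 / (0.000324 + 0.0009),
               tolerance = 1e-12)
  expect_equal(unname(sum(pv)), 1, tolerance = 1e-12)
  expect_error(variance_explained(variance_components(0, 0, 0.01)),
               "undefined")
})

test_that("rising discovery confounding shrinks predictions and replication probabilities", {
  d <- default_design()
  x <- 6.5
  sc1_grid <- seq(0, 0.05, length.out = 12)
  means <- sapply(sc1_grid, function(sc1)
    conditional_replication(x, d, vc_from_sigma(0.022, sc1, 0.01))$mean)
  expect_true(all(diff(abs(means)) < 0))
  # replication probability falls with sigma_c1 in the regime where the
  # conditional mean clears the replication cut
  sc1_above <- seq(0, 0.012, length.out = 8)
  probs <- sapply(sc1_above, function(sc1) {
    vc <- vc_from_sigma(0.022, sc1, 0.01)
    expect_gt(abs(conditional_replication(x, d, vc)$mean), qnorm(0.975))
    expected_replication_rate(paired_zscores(x, 1, design = d), d, vc)
  })
  expect_true(all(diff(probs) < 0))
})

test_that("expected rates at true parameters are calibrated against observed rates", {
  # end-to-end: simulate at known parameters, compare expected vs observed
  # within binomial error
  for (s in list(c(0.022, 0.026, 0.018), c(0.03, 0.018, 0.03))) {
    cfg <- simulation_config(sigma_g = s[1], sigma_c1 = s[2],
                             sigma_c2 = s[3], seed = 77)
    r <- simulate_pair(cfg)
    d <- as_study_design(cfg)
    vc <- vc_from_sigma(s[1], s[2], s[3])
    expected <- expected_replication_rate(r$data, d, vc,
                                          direction_aware = TRUE)
    se <- sqrt(expected * (1 - expected) / r$n_significant)
    expect_lt(abs(r$observed_rate - expected), 3 * se)
  }
})

test_that("the study report is internally consistent", {
  cfg <- simulation_config(sigma_g = 0.026, sigma_c1 = 0.022,
                           sigma_c2 = 0.018, n_variants = 5e5, seed = 41)
  r <- simulate_pair(cfg)
  d <- as_study_design(cfg)
  fit_wc <- fit_simulation(r, fit_options(model = "WC_ONLY"))
  fit_wcc <- fit_simulation(r)
  rep <- build_report(r$data, d, fit_wc, fit_wcc)
  expect_equal(rep$prop_var_genetic + rep$prop_var_confounding, 1,
               tolerance = 1e-12)
  expect_equal(rep$expected_count_wc,
               rep$expected_rate_wc * rep$n_significant)
  expect_equal(rep$expected_count_wcc,
               rep$expected_rate_wcc * rep$n_significant)
  expect_equal(rep$n_significant, r$n_significant)
  expect_error(build_report(r$data, d, fit_wcc, fit_wcc), "WC_ONLY")

  # JSON round trip preserves every headline number
  tmp <- tempfile(fileext = ".json")
  write_report(rep, tmp, provenance = list(seed = 41))
  got <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(got$observed_rate, rep$observed_rate)
  expect_equal(got$expected_rate_wcc, rep$expected_rate_wcc)
  expect_equal(got$vc_wcc$var_genetic, rep$vc_wcc$var_genetic)
  expect_equal(got$schema_version, "1.0")
})

test_that("models coincide at the no-confounding boundary", {
  cfg <- simulation_config(sigma_g = 0.026, seed = 53)
  r <- simulate_pair(cfg)
  d <- as_study_design(cfg)
  fit_wc <- fit_simulation(r, fit_options(model = "WC_ONLY"))
  fit_wcc <- fit_simulation(r)
  rep <- build_report(r$data, d, fit_wc, fit_wcc)
  expect_lt(abs(rep$expected_rate_wc - rep$expected_rate_wcc), 0.02)
  expect_lt(rep$prop_var_confounding, 0.1)
})

test_that("estimated confounding share anticorrelates with observed replication across a grid", {
  sig_values <- c(0.018, 0.022, 0.026, 0.03)
  combos <- expand.grid(sg = sig_values, sc1 = sig_values, sc2 = sig_values)
  pc1 <- obs <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- simulation_config(sigma_g = combos$sg[i], sigma_c1 = combos$sc1[i],
                             sigma_c2 = combos$sc2[i], seed = 61)
    r <- simulate_pair(cfg, keep = "none", stream = c(i, 1))
    fit <- fit_simulation(r)
    pc1[i] <- variance_explained(fit$estimate)["pc1"]
    obs[i] <- r$observed_rate
  }
  expect_lt(cor(pc1, obs, method = "spearman"), -0.5)
})
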