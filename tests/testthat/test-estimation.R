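test_that("negative log-likelihood matches closed forms and the brute-force oracle", {
  d <- default_design(n_total = 50)
  vc0 <- variance_components(0)
  origin <- paired_zscores(0, 0, design = d)
  # independent standard normals at the origin: 2 * (1/2) log(2 pi)
  expect_equal(negative_log_likelihood(origin, d, vc0, "COMPLETE"),
               log(2 * pi), tolerance = 1e-12)

  # 50-variant instance vs explicit matrix-inversion evaluation, both modes
  cfg <- simulation_config(n_variants = 50, sigma_g = 0.03, sigma_c1 = 0.02,
                           sigma_c2 = 0.02, discovery_threshold = 0.05,
                           seed = 5)
  dd <- as_study_design(cfg)
  data <- simulate_pair(cfg, keep = "all")$data
  for (vc in list(vc_from_sigma(0.03, 0.02, 0.02),
                  vc_from_sigma(0.01, 0.04, 0.001),
                  variance_components(0))) {
    for (mode in c("COMPLETE", "SIGNIFICANT_ONLY")) {
      got <- negative_log_likelihood(data, dd, vc, mode)
      want <- brute_force_nll(data, dd, vc, mode)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the truncation term vanishes when every tested variant is significant", {
  # all |z1| far above the cut: |A| = N and the two modes agree exactly
  d <- default_design(n_total = 4)
  data <- paired_zscores(c(10, -12, 15, -9), c(3, -4, 5, -2), design = d)
  vc <- vc_from_sigma(0.02, 0.01, 0.01)
  expect_identical(negative_log_likelihood(data, d, vc, "COMPLETE"),
                   negative_log_likelihood(data, d, vc, "SIGNIFICANT_ONLY"))
  # but N < |A| is rejected
  d_bad <- default_design(n_total = 3)
  expect_error(negative_log_likelihood(data, d_bad, vc, "SIGNIFICANT_ONLY"),
               "n_variants_total")
})

test_that("complete-data MLE recovers the generating parameters at scale", {
  cfg <- simulation_config(sigma_g = 0.022, sigma_c1 = 0.026,
                           sigma_c2 = 0.018, seed = 97)
  fit <- fit_simulation(simulate_pair(cfg, keep = "none"))
  expect_true(fit$converged)
  truth <- c(0.022, 0.026, 0.018)^2
  est <- c(fit$estimate$var_genetic, fit$estimate$var_conf_discovery,
           fit$estimate$var_conf_replication)
  expect_true(all(abs(est - truth) / truth < 0.10))
  # fit_simulation is the same estimator as fit_mle on the full table
  r <- simulate_pair(simulation_config(n_variants = 5e4, sigma_g = 0.03,
                                       sigma_c1 = 0.02, sigma_c2 = 0.02,
                                       seed = 3), keep = "all")
  f1 <- fit_mle(r$data, as_study_design(r$config))
  f2 <- fit_simulation(r)
  expect_equal(f1$nll, f2$nll, tolerance = 1e-9)
  expect_equal(f1$estimate$var_genetic, f2$estimate$var_genetic,
               tolerance = 1e-6)
})

test_that("confounding estimates stay near zero when the truth has none", {
  cfg <- simulation_config(sigma_g = 0.026, seed = 13)
  fit <- fit_simulation(simulate_pair(cfg, keep = "none"))
  expect_lt(fit$estimate$var_conf_discovery,
            0.10 * fit$estimate$var_genetic)
  expect_lt(fit$estimate$var_conf_replication,
            0.10 * fit$estimate$var_genetic)
})

test_that("significant-only fitting is consistent and requires significant variants", {
  cfg <- simulation_config(sigma_g = 0.022, sigma_c1 = 0.026,
                           sigma_c2 = 0.018, seed = 29)
  r <- simulate_pair(cfg, keep = "significant")
  fit <- fit_mle(r$data, as_study_design(cfg),
                 fit_options(data_completeness = "SIGNIFICANT_ONLY"))
  expect_true(fit$converged)
  truth <- c(0.022, 0.026, 0.018)^2
  est <- c(fit$estimate$var_genetic, fit$estimate$var_conf_discovery,
           fit$estimate$var_conf_replication)
  expect_true(all(abs(est - truth) / truth < 0.25))
  # matches the sufficient-statistic route exactly
  fs <- fit_simulation(r, fit_options(data_completeness = "SIGNIFICANT_ONLY"))
  expect_equal(fit$nll, fs$nll, tolerance = 1e-9)
  # degenerate: no significant variants at all
  null_data <- paired_zscores(c(0.5, -0.2), c(0.1, 0.3),
                              design = default_design())
  expect_error(fit_mle(null_data, default_design(),
                       fit_options(data_completeness = "SIGNIFICANT_ONLY")),
               "significant")
})

test_that("fit_mle attains the optimum found by refined grid search", {
  cfg <- simulation_config(n_variants = 100, sigma_g = 0.03, sigma_c1 = 0.02,
                           sigma_c2 = 0.02, discovery_threshold = 0.05,
                           seed = 8)
  d <- as_study_design(cfg)
  data <- simulate_pair(cfg, keep = "all")$data
  fit <- fit_mle(data, d, fit_options(n_restarts = 3, seed = 1))
  gs <- grid_search_nll(data, d)
  expect_lt(abs(fit$nll - gs$nll), 1e-6)
  # MLE optimality on the realized objective: no grid point beats the fit
  grid <- list(vc_from_sigma(0.03, 0.02, 0.02),
               vc_from_sigma(0.02, 0.02, 0.02),
               variance_components(1e-4))
  expect_true(all(profile_objective(data, d, grid) >= fit$nll - 1e-8))
})

test_that("constant all-zero data drives every variance component to zero", {
  d <- study_design(2000, 1000, 100, discovery_threshold = 0.5)
  data <- paired_zscores(rep(0, 100), rep(0, 100), design = d)
  fit <- fit_mle(data, d)
  expect_lt(fit$estimate$var_genetic, 1e-8)
  expect_lt(fit$estimate$var_conf_discovery, 1e-8)
  expect_lt(fit$estimate$var_conf_replication, 1e-8)
})

test_that("likelihood and fit are invariant to variant order", {
  cfg <- simulation_config(n_variants = 500, sigma_g = 0.03, sigma_c1 = 0.02,
                           sigma_c2 = 0.01, discovery_threshold = 0.05,
                           seed = 17)
  d <- as_study_design(cfg)
  data <- simulate_pair(cfg, keep = "all")$data
  set.seed(99)
  perm <- sample(nrow(data))
  data_perm <- paired_zscores(data$z_discovery[perm],
                              data$z_replication[perm], design = d)
  vc <- vc_from_sigma(0.02, 0.02, 0.02)
  expect_identical(negative_log_likelihood(data, d, vc),
                   negative_log_likelihood(data_perm, d, vc))
  f1 <- fit_mle(data, d, fit_options(seed = 4))
  f2 <- fit_mle(data_perm, d, fit_options(seed = 4))
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$nll, f2$nll)
})
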