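# Shared fixtures: the canonical simulation frame (N1 = 2000, N2 = 1000,
# genome-wide discovery threshold) at various scales.

default_design <- function(n_total = 1e6) {
  study_design(n_discovery = 2000, n_replication = 1000,
               n_variants_total = n_total)
}

# Random valid parameter draws for property-style loops.
random_vc <- function(rng_seed, sigma_max = 0.05) {
  set.seed(rng_seed)
  vc_from_sigma(runif(1, 0, sigma_max), runif(1, 0, sigma_max),
                runif(1, 0, sigma_max))
}

# Brute-force bivariate normal NLL by explicit matrix inversion, the
# independent oracle for the sufficient-statistic implementation.
brute_force_nll <- function(data, design, vc,
                            completeness = "COMPLETE") {
  S <- joint_distribution(design, vc)$variance
  Sinv <- solve(S)
  ld <- determinant(S, logarithm = TRUE)$modulus
  dens <- function(z1, z2) {
    z <- c(z1, z2)
    -log(2 * pi) - 0.5 * as.numeric(ld) - 0.5 * drop(t(z) %*% Sinv %*% z)
  }
  z_star <- z_cutpoint(design$discovery_threshold)
  sig <- abs(data$z_discovery) > z_star
  if (completeness == "COMPLETE") {
    keep <- rep(TRUE, nrow(data))
    trunc_term <- 0
  } else {
    keep <- sig
    sd1 <- sqrt(S[1, 1])
    p_not <- pnorm(z_star, sd = sd1) - pnorm(-z_star, sd = sd1)
    trunc_term <- (design$n_variants_total - sum(sig)) * log(p_not)
  }
  -(trunc_term + sum(mapply(dens, data$z_discovery[keep],
                            data$z_replication[keep])))
}

# Exhaustive grid search over (sigma_g, sigma_c1, sigma_c2), repeatedly
# refined around the incumbent; independent check of fit_mle's optimum.
grid_search_nll <- function(data, design, completeness = "COMPLETE",
                            s_max = 0.1, n_points = 11, n_refine = 6) {
  lo <- c(0, 0, 0); hi <- rep(s_max, 3)
  best <- NULL
  for (round in seq_len(n_refine)) {
    axes <- lapply(1:3, function(i) seq(lo[i], hi[i], length.out = n_points))
    pts <- expand.grid(axes[[1]], axes[[2]], axes[[3]])
    vals <- apply(pts, 1, function(s)
      negative_log_likelihood(data, design,
                              vc_from_sigma(s[1], s[2], s[3]), completeness))
    k <- which.min(vals)
    best <- list(par = as.numeric(pts[k, ]), nll = vals[k])
    step <- (hi - lo) / (n_points - 1)
    lo <- pmax(best$par - step, 0)
    hi <- best$par + step
  }
  best
}
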