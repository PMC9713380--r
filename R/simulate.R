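#' Configuration of one simulated study pair
#'
#' Parameters of the generative model for a discovery/replication pair.
#' Defaults are the simulation conditions used throughout the package's
#' own studies: N1 = 2,000, N2 = 1,000, one million independent variants,
#' genome-wide discovery threshold 5e-8 and nominal replication level 0.05.
#' The effect-size parameters are given in sigma (standard deviation)
#' units, the scale on which simulation grids are specified; they are
#' squared internally wherever the model formulas consume variances.
#'
#' @param n_discovery,n_replication Study sample sizes.
#' @param n_variants Number of independent variants to simulate.
#' @param sigma_g Standard deviation of the shared genetic effect.
#' @param sigma_c1,sigma_c2 Standard deviations of the study-specific
#'   confounding effects.
#' @param discovery_threshold,replication_alpha Two-sided p-value
#'   thresholds.
#' @param seed Integer base seed; every simulation derives its own stream
#'   deterministically from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_discovery = 2000, n_replication = 1000,
                              n_variants = 1e6,
                              sigma_g = 0, sigma_c1 = 0, sigma_c2 = 0,
                              discovery_threshold = 5e-8,
                              replication_alpha = 0.05,
                              seed = 1L) {
  stopifnot(
    "n_variants must be >= 1" = n_variants >= 1,
    "sigmas must be nonnegative" = all(c(sigma_g, sigma_c1, sigma_c2) >= 0),
    "thresholds must lie in (0,1)" =
      discovery_threshold > 0 && discovery_threshold < 1 &&
      replication_alpha > 0 && replication_alpha < 1,
    "seed must be a single integer" =
      is.numeric(seed) && length(seed) == 1L && seed == round(seed)
  )
  structure(
    list(n_discovery = n_discovery, n_replication = n_replication,
         n_variants = n_variants, sigma_g = sigma_g, sigma_c1 = sigma_c1,
         sigma_c2 = sigma_c2, discovery_threshold = discovery_threshold,
         replication_alpha = replication_alpha, seed = as.numeric(seed)),
    class = "simulation_config"
  )
}

#' Study design implied by a simulation configuration
#'
#' @param config A [simulation_config()].
#' @return The matching [study_design()] (with `n_variants_total` equal to
#'   the number of simulated variants).
#' @export
as_study_design <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  study_design(config$n_discovery, config$n_replication, config$n_variants,
               config$discovery_threshold, config$replication_alpha)
}

#' Simulate one discovery/replication study pair
#'
#' Draws, for each variant k, a genetic effect `lambda_k ~ N(0, sigma_g^2)`
#' and study-specific confounding effects `delta1_k ~ N(0, sigma_c1^2)`,
#' `delta2_k ~ N(0, sigma_c2^2)`, then z-scores scaled for each study's
#' sample size: `z1 ~ N(sqrt(N1) (lambda + delta1), 1)` and
#' `z2 ~ N(sqrt(N2) (lambda + delta2), 1)`. Significance is called at the
#' two-sided discovery threshold and the observed replication rate scored
#' at the nominal replication level with matching direction of effect.
#' Output is fully determined by the configuration (including its seed and
#' the stream indices).
#'
#' @param config A [simulation_config()].
#' @param keep `"significant"` (default) retains z-scores of
#'   discovery-significant variants only — the sufficient data for
#'   truncated-likelihood fitting; `"all"` retains every variant; `"none"`
#'   retains only counts, rates and latent summaries.
#' @param stream Two nonnegative integers identifying the stream within a
#'   grid (combination index, replicate index); `c(0, 0)` for standalone
#'   runs.
#' @return An object of class `simulation_result`: a list with the
#'   `config`, `n_significant`, `n_nonsignificant`, `observed_rate`
#'   (`NA` with `rate_defined = FALSE` when no variant is significant),
#'   the retained [paired_zscores()] in `data` (or `NULL`), `suff` with
#'   the likelihood's sufficient statistics over all variants and over the
#'   significant subset (see [fit_simulation()]), and `latent_summary`
#'   with the empirical means and variances of the drawn latent effects.
#' @export
#' @examples
#' simulate_pair(simulation_config(n_variants = 1e4, sigma_g = 0.03, seed = 1))
simulate_pair <- function(config, keep = c("significant", "all", "none"),
                          stream = c(0, 0)) {
  stopifnot(inherits(config, "simulation_config"),
            length(stream) == 2L, all(stream >= 0))
  keep <- match.arg(keep)
  z_star <- z_cutpoint(config$discovery_threshold)
  raw <- .sim_pair_cpp(config$n_variants, config$n_discovery,
                       config$n_replication, config$sigma_g, config$sigma_c1,
                       config$sigma_c2, z_star, keep == "all",
                       config$seed, stream[1], stream[2])
  n_sig <- as.integer(raw$n_significant)

  if (keep == "all") {
    sig <- raw$significant
    z1_sig <- raw$z1[sig]
    z2_sig <- raw$z2[sig]
    data <- paired_zscores(raw$z1, raw$z2, is_significant = sig)
  } else {
    z1_sig <- raw$z1
    z2_sig <- raw$z2
    data <- if (keep == "significant" && n_sig > 0) {
      paired_zscores(z1_sig, z2_sig,
                     variant_ids = paste0("v", raw$index),
                     is_significant = rep(TRUE, n_sig))
    } else if (keep == "significant") {
      NULL
    } else {
      NULL
    }
  }

  if (n_sig > 0) {
    z_alpha <- z_cutpoint(config$replication_alpha)
    rate <- mean(sign(z1_sig) * z2_sig > z_alpha)
    rate_defined <- TRUE
  } else {
    rate <- NA_real_
    rate_defined <- FALSE
  }

  structure(
    list(config = config, stream = as.numeric(stream),
         n_significant = n_sig,
         n_nonsignificant = config$n_variants - n_sig,
         observed_rate = rate, rate_defined = rate_defined,
         data = data, suff = raw$suff, latent_summary = raw$latent),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulated pair: %s variants, sigma_g = %g, sigma_c1 = %g, sigma_c2 = %g\n",
    format(x$config$n_variants, big.mark = ","), x$config$sigma_g,
    x$config$sigma_c1, x$config$sigma_c2))
  cat(sprintf("  significant in discovery: %d\n", x$n_significant))
  cat(sprintf("  observed replication rate: %s\n",
              if (x$rate_defined) sprintf("%.3f", x$observed_rate)
              else "undefined (no significant variants)"))
  invisible(x)
}

#' Run a simulation grid
#'
#' Repeats [simulate_pair()] over a grid of effect-size standard
#' deviations. With `confounded = TRUE` the grid is the full cross of
#' `sigma_values` over (sigma_g, sigma_c1, sigma_c2) — `length(sigma_values)^3`
#' combinations; with `confounded = FALSE` both confounding components are
#' fixed at zero and the grid runs over sigma_g alone. Each replicate's
#' random stream is derived deterministically from the base seed, the
#' combination index and the replicate index, so any subset of the grid
#' reproduces bit-identically in isolation.
#'
#' @param sigma_values Nonempty numeric vector of sigma values, e.g.
#'   `c(0.018, 0.022, 0.026, 0.03)`.
#' @param n_reps Replicates per combination.
#' @param base A [simulation_config()] supplying everything except the
#'   sigmas (sample sizes, variant count, thresholds, seed).
#' @param confounded Cross all three sigmas (`TRUE`) or genetic only.
#' @param keep Passed to [simulate_pair()]; default `"none"` keeps the
#'   per-simulation summaries only, which is what [grid_summary()] needs.
#' @return A list of `simulation_result` objects of class
#'   `simulation_grid`, in combination-major order.
#' @export
#' @examples
#' g <- run_grid(c(0.018, 0.03), n_reps = 2,
#'               base = simulation_config(n_variants = 1e4, seed = 3))
#' length(g)  # 2^3 combinations x 2 reps = 16
run_grid <- function(sigma_values, n_reps,
                     base = simulation_config(),
                     confounded = TRUE,
                     keep = c("none", "significant", "all")) {
  stopifnot("sigma_values must be a nonempty numeric vector" =
              is.numeric(sigma_values) && length(sigma_values) >= 1L,
            "n_reps must be >= 1" = n_reps >= 1,
            inherits(base, "simulation_config"))
  keep <- match.arg(keep)
  combos <- if (confounded) {
    expand.grid(sigma_g = sigma_values, sigma_c1 = sigma_values,
                sigma_c2 = sigma_values, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(sigma_g = sigma_values, sigma_c1 = 0, sigma_c2 = 0)
  }
  out <- vector("list", nrow(combos) * n_reps)
  idx <- 0L
  for (ci in seq_len(nrow(combos))) {
    cfg <- base
    cfg$sigma_g <- combos$sigma_g[ci]
    cfg$sigma_c1 <- combos$sigma_c1[ci]
    cfg$sigma_c2 <- combos$sigma_c2[ci]
    for (ri in seq_len(n_reps)) {
      idx <- idx + 1L
      out[[idx]] <- simulate_pair(cfg, keep = keep, stream = c(ci, ri))
    }
  }
  structure(out, class = c("simulation_grid", "list"))
}

#' Summarize a simulation grid
#'
#' @param results A list of `simulation_result` objects (e.g. from
#'   [run_grid()]).
#' @return A list with three elements: `simulations`, a `data.frame` with
#'   one row per simulation (sigmas, stream, `n_significant`,
#'   `observed_rate`, `rate_defined`); `per_combination`, min/mean/max of
#'   counts and defined rates per sigma combination plus the number of
#'   undefined-rate replicates; and `global`, the same statistics pooled
#'   over all simulations. Undefined rates (no significant variants) are
#'   excluded from rate summaries and counted explicitly, never propagated
#'   as `NaN`.
#' @export
grid_summary <- function(results) {
  stopifnot("results must be a nonempty list of simulation_result" =
              length(results) >= 1L &&
              all(vapply(results, inherits, TRUE, "simulation_result")))
  sims <- do.call(rbind, lapply(results, function(r) {
    data.frame(sigma_g = r$config$sigma_g, sigma_c1 = r$config$sigma_c1,
               sigma_c2 = r$config$sigma_c2, seed = r$config$seed,
               combo = r$stream[1], rep = r$stream[2],
               n_significant = r$n_significant,
               observed_rate = r$observed_rate,
               rate_defined = r$rate_defined)
  }))
  key <- interaction(sims$sigma_g, sims$sigma_c1, sims$sigma_c2, drop = TRUE)
  per <- do.call(rbind, lapply(split(sims, key), function(d) {
    rates <- d$observed_rate[d$rate_defined]
    data.frame(
      sigma_g = d$sigma_g[1], sigma_c1 = d$sigma_c1[1],
      sigma_c2 = d$sigma_c2[1], n_reps = nrow(d),
      min_significant = min(d$n_significant),
      mean_significant = mean(d$n_significant),
      max_significant = max(d$n_significant),
      min_rate = if (length(rates)) min(rates) else NA_real_,
      mean_rate = if (length(rates)) mean(rates) else NA_real_,
      max_rate = if (length(rates)) max(rates) else NA_real_,
      n_undefined_rate = sum(!d$rate_defined)
    )
  }))
  rownames(per) <- NULL
  rates <- sims$observed_rate[sims$rate_defined]
  global <- list(
    n_simulations = nrow(sims),
    min_significant = min(sims$n_significant),
    mean_significant = mean(sims$n_significant),
    max_significant = max(sims$n_significant),
    min_rate = if (length(rates)) min(rates) else NA_real_,
    mean_rate = if (length(rates)) mean(rates) else NA_real_,
    max_rate = if (length(rates)) max(rates) else NA_real_,
    n_undefined_rate = sum(!sims$rate_defined)
  )
  list(simulations = sims, per_combination = per, global = global)
}
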