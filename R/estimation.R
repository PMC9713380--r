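#' Options controlling maximum-likelihood fitting
#'
#' @param model `"WC_PLUS_CONFOUNDING"` (all three variance components free)
#'   or `"WC_ONLY"` (confounding fixed at zero, only the genetic variance
#'   free).
#' @param data_completeness `"COMPLETE"` when z-scores for all tested
#'   variants are supplied, `"SIGNIFICANT_ONLY"` when only
#'   discovery-significant variants are available and the remaining
#'   `N - |A|` variants enter through their probability of non-significance.
#' @param max_iterations Maximum optimizer iterations per restart.
#' @param tolerance Relative convergence tolerance on the objective.
#' @param n_restarts Number of optimizer starts; the first uses a
#'   moment-matched initialization, later ones jitter it multiplicatively.
#' @param seed Integer seed for the restart jitter.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(model = c("WC_PLUS_CONFOUNDING", "WC_ONLY"),
                        data_completeness = c("COMPLETE", "SIGNIFICANT_ONLY"),
                        max_iterations = 2000L,
                        tolerance = 1e-8,
                        n_restarts = 3L,
                        seed = 1L) {
  model <- match.arg(model)
  data_completeness <- match.arg(data_completeness)
  stopifnot(max_iterations >= 1, tolerance > 0, n_restarts >= 1)
  structure(
    list(model = model, data_completeness = data_completeness,
         max_iterations = as.integer(max_iterations), tolerance = tolerance,
         n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
    class = "fit_options"
  )
}

# Sufficient statistics of the zero-mean bivariate Gaussian likelihood:
# the log-likelihood of n paired z-scores depends on the data only through
# n and the sums of z1^2, z2^2 and z1*z2, so objective evaluations are O(1)
# whatever the number of variants. Terms are sorted before summation so
# the statistics (hence the likelihood and the fit) are bit-identical
# under any permutation of the variants.
suff_stats <- function(z1, z2) {
  list(n = length(z1),
       s11 = sum(sort(z1 * z1)), s22 = sum(sort(z2 * z2)),
       s12 = sum(sort(z1 * z2)))
}

nll_from_stats <- function(st, v1, v2, cv) {
  det <- v1 * v2 - cv^2
  st$n * log(2 * pi) + 0.5 * st$n * log(det) +
    0.5 * (v2 * st$s11 - 2 * cv * st$s12 + v1 * st$s22) / det
}

# log P(|s1| <= z_star) under the discovery marginal N(0, v1).
log_p_not_significant <- function(z_star, v1) {
  # 1 - 2 P(s1 > z_star); expm1 keeps precision when the tail is tiny
  log1p(-2 * pnorm(z_star / sqrt(v1), lower.tail = FALSE))
}

nll_internal <- function(st_sig, n_nonsig, z_star, design, vc, truncated) {
  n1 <- design$n_discovery
  n2 <- design$n_replication
  v1 <- n1 * (vc$var_genetic + vc$var_conf_discovery) + 1
  v2 <- n2 * (vc$var_genetic + vc$var_conf_replication) + 1
  cv <- sqrt(n1 * n2) * vc$var_genetic
  out <- nll_from_stats(st_sig, v1, v2, cv)
  if (truncated && n_nonsig > 0)
    out <- out - n_nonsig * log_p_not_significant(z_star, v1)
  out
}

#' Negative log-likelihood of the bivariate z-score model
#'
#' With complete data the likelihood is the product over variants of the
#' bivariate normal density of [joint_distribution()]. When only
#' discovery-significant variants are observed, each of the `N - |A|`
#' unobserved variants contributes its probability of non-significance
#' `P(|s1| <= z*)` under the discovery marginal, and the observed variants
#' contribute the joint density; when every tested variant is supplied the
#' truncation term vanishes and the two modes agree exactly.
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()]; in `SIGNIFICANT_ONLY` mode its
#'   `n_variants_total` is the `N` of the truncation term.
#' @param vc A [variance_components()].
#' @param completeness `"COMPLETE"` or `"SIGNIFICANT_ONLY"`.
#' @return The negative log-likelihood (a single finite number).
#' @export
negative_log_likelihood <- function(data, design, vc,
                                    completeness = c("COMPLETE",
                                                     "SIGNIFICANT_ONLY")) {
  completeness <- match.arg(completeness)
  stopifnot(inherits(data, "paired_zscores"),
            inherits(design, "study_design"),
            inherits(vc, "variance_components"),
            all(is.finite(data$z_discovery)),
            all(is.finite(data$z_replication)))
  z_star <- z_cutpoint(design$discovery_threshold)
  if (completeness == "COMPLETE") {
    st <- suff_stats(data$z_discovery, data$z_replication)
    return(nll_internal(st, 0, z_star, design, vc, truncated = FALSE))
  }
  sig <- abs(data$z_discovery) > z_star
  n_a <- sum(sig)
  if (design$n_variants_total < n_a)
    stop("n_variants_total (N) is smaller than the number of significant variants |A|")
  st <- suff_stats(data$z_discovery[sig], data$z_replication[sig])
  nll_internal(st, design$n_variants_total - n_a, z_star, design, vc,
               truncated = TRUE)
}

#' Maximum-likelihood estimation of the variance components
#'
#' Minimizes [negative_log_likelihood()] over the variance components.
#' Nonnegativity is enforced by optimizing over standard deviations
#' (sigma) and squaring, so the search is smooth and unconstrained. The
#' three-parameter model is fitted with Nelder-Mead from a moment-matched
#' start (`sigma_g0 = sqrt(max((mean(z1^2) - 1)/N1, 1e-10))`, confounding
#' components at half that), with `n_restarts - 1` additional starts
#' jittered multiplicatively by Uniform(0.5, 2); the one-parameter
#' Winner's-Curse-only model is fitted by golden-section search, which is
#' reliable in one dimension where Nelder-Mead is not. The best restart by
#' objective value is kept.
#'
#' @param data A [paired_zscores()] table. In `SIGNIFICANT_ONLY` mode only
#'   discovery-significant variants (recomputed from the design threshold)
#'   enter the density term.
#' @param design A [study_design()].
#' @param options A [fit_options()].
#' @return An object of class `gwrep_fit`: a list with elements `estimate`
#'   ([variance_components()]), `nll`, `converged`, `n_significant`,
#'   `model`, `data_completeness` and `diagnostics`.
#' @export
#' @examples
#' d <- study_design(2000, 1000, 2000)
#' sim <- simulate_pair(simulation_config(n_variants = 2000, sigma_g = 0.03,
#'                                        seed = 7), keep = "all")
#' fit_mle(sim$data, d, fit_options(n_restarts = 1))
fit_mle <- function(data, design, options = fit_options()) {
  stopifnot(inherits(data, "paired_zscores"),
            inherits(design, "study_design"),
            inherits(options, "fit_options"),
            nrow(data) >= 1L)
  z_star <- z_cutpoint(design$discovery_threshold)
  truncated <- options$data_completeness == "SIGNIFICANT_ONLY"
  sig <- abs(data$z_discovery) > z_star
  n_sig <- sum(sig)
  if (truncated) {
    if (n_sig == 0L)
      stop("SIGNIFICANT_ONLY fitting requires at least one discovery-significant variant")
    if (design$n_variants_total < n_sig)
      stop("n_variants_total (N) is smaller than the number of significant variants |A|")
    st <- suff_stats(data$z_discovery[sig], data$z_replication[sig])
    n_nonsig <- design$n_variants_total - n_sig
  } else {
    st <- suff_stats(data$z_discovery, data$z_replication)
    n_nonsig <- 0
  }

  fit_core(st, n_nonsig, z_star, design, options,
           msq = st$s11 / st$n, n_sig = n_sig)
}

# Shared optimizer over the sufficient statistics of the relevant variant
# set; msq is the zero-mean empirical second moment of the discovery
# z-scores used for the moment-matched start.
fit_core <- function(st, n_nonsig, z_star, design, options, msq, n_sig) {
  truncated <- options$data_completeness == "SIGNIFICANT_ONLY"
  objective <- function(s) {
    vc <- variance_components(s[1]^2,
                              if (length(s) > 1L) s[2]^2 else 0,
                              if (length(s) > 1L) s[3]^2 else 0)
    nll_internal(st, n_nonsig, z_star, design, vc, truncated)
  }

  # moment-matched start: empirical variance of z1 minus unit noise
  s_g0 <- sqrt(max((msq - 1) / design$n_discovery, 1e-10))

  if (options$model == "WC_ONLY") {
    opt <- optimize(function(s) objective(s), interval = c(0, 50 * s_g0 + 0.1),
                    tol = 1e-10)
    est <- variance_components(opt$minimum^2, 0, 0)
    fit <- list(nll = opt$objective, converged = TRUE,
                diagnostics = list(method = "golden-section",
                                   restarts = 1L, codes = 0L))
  } else {
    start0 <- c(s_g0, s_g0 / 2, s_g0 / 2)
    jitters <- restart_jitters(options$n_restarts, options$seed)
    best <- NULL
    codes <- integer(0)
    for (r in seq_len(options$n_restarts)) {
      res <- optim(start0 * jitters[[r]], objective, method = "Nelder-Mead",
                   control = list(maxit = options$max_iterations,
                                  reltol = options$tolerance))
      codes <- c(codes, res$convergence)
      if (is.null(best) || res$value < best$value) best <- res
    }
    est <- variance_components(best$par[1]^2, best$par[2]^2, best$par[3]^2)
    fit <- list(nll = best$value,
                converged = any(codes == 0L) &&
                  best$convergence == 0L,
                diagnostics = list(method = "Nelder-Mead",
                                   restarts = options$n_restarts,
                                   codes = codes))
  }

  structure(
    list(estimate = est, nll = fit$nll, converged = fit$converged,
         n_significant = as.integer(n_sig), model = options$model,
         data_completeness = options$data_completeness,
         diagnostics = fit$diagnostics),
    class = "gwrep_fit"
  )
}

#' Fit variance components directly from a simulation result
#'
#' Equivalent to running [fit_mle()] on the simulated z-score table, but
#' uses the sufficient statistics accumulated during simulation (the
#' zero-mean bivariate Gaussian likelihood depends on the data only
#' through sums of squares and cross-products), so it works even when the
#' simulation retained no per-variant data and costs the same whatever
#' the number of variants.
#'
#' @param result A [simulate_pair()] result.
#' @param options A [fit_options()]; `data_completeness = "COMPLETE"` uses
#'   every simulated variant, `"SIGNIFICANT_ONLY"` uses the
#'   discovery-significant subset plus the non-significance probability of
#'   the rest.
#' @return A `gwrep_fit`, as from [fit_mle()].
#' @export
fit_simulation <- function(result, options = fit_options()) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(options, "fit_options"))
  design <- as_study_design(result$config)
  z_star <- z_cutpoint(design$discovery_threshold)
  sf <- result$suff
  n_sig <- result$n_significant
  if (options$data_completeness == "SIGNIFICANT_ONLY") {
    if (n_sig == 0L)
      stop("SIGNIFICANT_ONLY fitting requires at least one discovery-significant variant")
    st <- list(n = n_sig, s11 = sf$s11_sig, s22 = sf$s22_sig,
               s12 = sf$s12_sig)
    n_nonsig <- sf$n - n_sig
    msq <- sf$s11_sig / n_sig
  } else {
    st <- list(n = sf$n, s11 = sf$s11_all, s22 = sf$s22_all,
               s12 = sf$s12_all)
    n_nonsig <- 0
    msq <- sf$s11_all / sf$n
  }
  fit_core(st, n_nonsig, z_star, design, options, msq = msq, n_sig = n_sig)
}

# Deterministic multiplicative jitters for optimizer restarts; the global
# RNG state is left untouched.
restart_jitters <- function(n_restarts, seed) {
  jitters <- vector("list", n_restarts)
  jitters[[1L]] <- c(1, 1, 1)
  if (n_restarts > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    for (r in 2:n_restarts) jitters[[r]] <- runif(3, 0.5, 2)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  jitters
}

#' @export
print.gwrep_fit <- function(x, ...) {
  cat(sprintf("MLE fit (%s, %s data): nll = %.6f, converged = %s\n",
              x$model, x$data_completeness, x$nll, x$converged))
  print(x$estimate)
  cat(sprintf("  significant variants |A| = %d\n", x$n_significant))
  invisible(x)
}

#' Evaluate the likelihood objective on a parameter grid
#'
#' Diagnostic helper: the negative log-likelihood at each supplied set of
#' variance components, e.g. to verify that [fit_mle()] attains at least
#' the best grid value.
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()].
#' @param grid A list of [variance_components()].
#' @param completeness Passed to [negative_log_likelihood()].
#' @return Numeric vector of objective values, one per grid point.
#' @export
profile_objective <- function(data, design, grid,
                              completeness = c("COMPLETE",
                                               "SIGNIFICANT_ONLY")) {
  completeness <- match.arg(completeness)
  stopifnot("grid must be a nonempty list of variance_components" =
              is.list(grid) && length(grid) >= 1L &&
              all(vapply(grid, inherits, TRUE, "variance_components")))
  vapply(grid, function(vc)
    negative_log_likelihood(data, design, vc, completeness), numeric(1))
}
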