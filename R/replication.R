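#' Observed replication rate
#'
#' Fraction of discovery-significant variants whose replication statistic
#' meets the nominal two-sided threshold with the same direction of effect
#' as in discovery: `sign(z1) * z2 > qnorm(1 - alpha/2)`. A replication
#' z-score of exactly zero counts as a failure.
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()]; supplies both thresholds.
#' @return The observed rate, a number in \[0, 1\].
#' @export
#' @examples
#' d <- study_design(2000, 1000, 1e6)
#' observed_replication_rate(paired_zscores(c(6, -6, 6), c(3, -3, 0.1),
#'                                          design = d), d)  # 2/3
observed_replication_rate <- function(data, design) {
  stopifnot(inherits(data, "paired_zscores"), inherits(design, "study_design"))
  sig <- abs(data$z_discovery) > z_cutpoint(design$discovery_threshold)
  if (!any(sig))
    stop("no discovery-significant variants: the observed replication rate is undefined")
  z_alpha <- z_cutpoint(design$replication_alpha)
  z1 <- data$z_discovery[sig]
  z2 <- data$z_replication[sig]
  mean(sign(z1) * z2 > z_alpha)
}

# Per-variant replication probability under the conditional model.
replication_probability <- function(x, design, vc, direction_aware = FALSE) {
  cond <- conditional_replication(x, design, vc)
  s <- sqrt(cond$variance)
  z_alpha <- z_cutpoint(design$replication_alpha)
  if (direction_aware) {
    pnorm((z_alpha - sign(x) * cond$mean) / s, lower.tail = FALSE)
  } else {
    pnorm((z_alpha - cond$mean) / s, lower.tail = FALSE) +
      pnorm((-z_alpha - cond$mean) / s)
  }
}

#' Expected replication rate under the fitted model
#'
#' Averages, over discovery-significant variants, the probability that the
#' replication statistic exceeds the nominal two-sided threshold under the
#' conditional distribution given the observed discovery statistic:
#' \eqn{r = (1/|A|) \sum_k P(|s_2| > z_\alpha \mid s_1 = x_k)}. The default is
#' direction-agnostic, counting both tails; `direction_aware = TRUE`
#' instead counts only the tail on the discovered direction,
#' `P(sign(x_k) s2 > z_alpha | s1 = x_k)`, matching the rule used for the
#' observed rate.
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()].
#' @param vc A [variance_components()] (typically an MLE from [fit_mle()];
#'   use zero confounding components for the Winner's-Curse-only model).
#' @param direction_aware Count only the discovered direction's tail.
#' @return The expected rate, a number in \[0, 1\].
#' @export
expected_replication_rate <- function(data, design, vc,
                                      direction_aware = FALSE) {
  stopifnot(inherits(data, "paired_zscores"),
            inherits(design, "study_design"),
            inherits(vc, "variance_components"))
  sig <- abs(data$z_discovery) > z_cutpoint(design$discovery_threshold)
  if (!any(sig))
    stop("no discovery-significant variants: the expected replication rate is undefined")
  mean(replication_probability(data$z_discovery[sig], design, vc,
                               direction_aware))
}

#' Genetic vs confounding variance decomposition of the discovery signal
#'
#' The non-noise variance of discovery z-scores splits into a genetic and
#' a discovery-confounding share: `pg = sigma_g^2 / (sigma_g^2 +
#' sigma_c1^2)` and `pc1 = sigma_c1^2 / (sigma_g^2 + sigma_c1^2)`, which
#' always sum to one. The sample size cancels.
#'
#' @param vc A [variance_components()] with `var_genetic +
#'   var_conf_discovery > 0`.
#' @return Named numeric vector `c(pg = ..., pc1 = ...)`.
#' @export
#' @examples
#' variance_explained(vc_from_sigma(0.018, 0.03))  # pc1 ~ 0.735
variance_explained <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  tot <- vc$var_genetic + vc$var_conf_discovery
  if (tot <= 0)
    stop("variance decomposition undefined: sigma_g^2 + sigma_c1^2 must be > 0")
  c(pg = vc$var_genetic / tot, pc1 = vc$var_conf_discovery / tot)
}

#' Per-variant replication predictions
#'
#' Predicted replication mean, standard deviation, confidence interval and
#' replication probability for every variant, under a given set of
#' variance components.
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()].
#' @param vc A [variance_components()].
#' @param level Confidence level for the interval; default 0.95.
#' @param direction_aware Passed to the replication probability.
#' @return A `data.frame` with one row per variant: `variant_id`,
#'   `z_discovery`, `z_replication`, `is_significant`, `predicted_mean`,
#'   `predicted_sd`, `ci_lower`, `ci_upper`, `replication_prob`.
#' @export
predict_replication <- function(data, design, vc, level = 0.95,
                                direction_aware = FALSE) {
  stopifnot(inherits(data, "paired_zscores"),
            inherits(design, "study_design"),
            inherits(vc, "variance_components"))
  data <- flag_significant(data, design)
  cond <- conditional_replication(data$z_discovery, design, vc)
  ci <- confidence_interval(data$z_discovery, design, vc, level)
  data.frame(
    variant_id = data$variant_id,
    z_discovery = data$z_discovery,
    z_replication = data$z_replication,
    is_significant = data$is_significant,
    predicted_mean = cond$mean,
    predicted_sd = sqrt(cond$variance),
    ci_lower = ci[, "lower"],
    ci_upper = ci[, "upper"],
    replication_prob = replication_probability(data$z_discovery, design, vc,
                                               direction_aware),
    stringsAsFactors = FALSE
  )
}

#' Study-level replication report
#'
#' Assembles the headline quantities for one discovery/replication pair:
#' observed replication, expected replication under the
#' Winner's-Curse-only and Winner's-Curse-plus-confounding fits, expected
#' counts, and the genetic/confounding variance decomposition of the
#' discovery signal.
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()].
#' @param fit_wc A `gwrep_fit` with `model == "WC_ONLY"`.
#' @param fit_wcc A `gwrep_fit` with `model == "WC_PLUS_CONFOUNDING"`.
#' @param direction_aware Rule used for the expected rates; the default
#'   (direction-agnostic) matches the model's replication-probability
#'   formula.
#' @return An object of class `replication_report`.
#' @export
build_report <- function(data, design, fit_wc, fit_wcc,
                         direction_aware = FALSE) {
  stopifnot(inherits(data, "paired_zscores"),
            inherits(design, "study_design"),
            inherits(fit_wc, "gwrep_fit"), inherits(fit_wcc, "gwrep_fit"),
            fit_wc$model == "WC_ONLY",
            fit_wcc$model == "WC_PLUS_CONFOUNDING")
  if (fit_wc$n_significant != fit_wcc$n_significant)
    stop("the two fits disagree on |A|; were they run on the same data and design?")
  sig <- abs(data$z_discovery) > z_cutpoint(design$discovery_threshold)
  n_sig <- sum(sig)
  if (n_sig != fit_wc$n_significant)
    stop("fits were not produced from this data/design combination")
  obs <- observed_replication_rate(data, design)
  exp_wc <- expected_replication_rate(data, design, fit_wc$estimate,
                                      direction_aware)
  exp_wcc <- expected_replication_rate(data, design, fit_wcc$estimate,
                                       direction_aware)
  pv <- variance_explained(fit_wcc$estimate)
  structure(
    list(
      n_significant = as.integer(n_sig),
      observed_rate = obs,
      expected_rate_wc = exp_wc,
      expected_rate_wcc = exp_wcc,
      expected_count_wc = exp_wc * n_sig,
      expected_count_wcc = exp_wcc * n_sig,
      prop_var_genetic = unname(pv["pg"]),
      prop_var_confounding = unname(pv["pc1"]),
      vc_wc = fit_wc$estimate,
      vc_wcc = fit_wcc$estimate,
      direction_aware = direction_aware,
      design = design
    ),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Replication report\n")
  cat(sprintf("  significant in discovery: %d\n", x$n_significant))
  cat(sprintf("  observed replication:     %d (%.1f%%)\n",
              round(x$observed_rate * x$n_significant),
              100 * x$observed_rate))
  cat(sprintf("  expected, WC only:        %.1f (%.1f%%)\n",
              x$expected_count_wc, 100 * x$expected_rate_wc))
  cat(sprintf("  expected, WC+confounding: %.1f (%.1f%%)\n",
              x$expected_count_wcc, 100 * x$expected_rate_wcc))
  cat(sprintf("  discovery variance: %.1f%% genetic, %.1f%% confounding\n",
              100 * x$prop_var_genetic, 100 * x$prop_var_confounding))
  invisible(x)
}

#' Serialize a replication report to JSON
#'
#' @param report A [build_report()] result.
#' @param path Output file path.
#' @param provenance Optional named list (input paths, seeds, ...) stored
#'   verbatim under `"provenance"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "replication_report"))
  vc_list <- function(vc) list(var_genetic = vc$var_genetic,
                               var_conf_discovery = vc$var_conf_discovery,
                               var_conf_replication = vc$var_conf_replication)
  out <- list(
    schema_version = "1.0",
    n_significant = report$n_significant,
    observed_rate = report$observed_rate,
    expected_rate_wc = report$expected_rate_wc,
    expected_rate_wcc = report$expected_rate_wcc,
    expected_count_wc = report$expected_count_wc,
    expected_count_wcc = report$expected_count_wcc,
    prop_var_genetic = report$prop_var_genetic,
    prop_var_confounding = report$prop_var_confounding,
    vc_wc = vc_list(report$vc_wc),
    vc_wcc = vc_list(report$vc_wcc),
    direction_aware = report$direction_aware,
    design = list(
      n_discovery = report$design$n_discovery,
      n_replication = report$design$n_replication,
      n_variants_total = report$design$n_variants_total,
      discovery_threshold = report$design$discovery_threshold,
      replication_alpha = report$design$replication_alpha
    )
  )
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
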