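#' Describe a discovery/replication study pair
#'
#' The fixed experimental frame of a two-stage GWAS: the two sample sizes,
#' the number of variants tested in the discovery study, and the two-sided
#' significance thresholds used to call a variant significant in discovery
#' and successfully replicated.
#'
#' @param n_discovery Number of individuals in the discovery study (N1).
#' @param n_replication Number of individuals in the replication study (N2).
#' @param n_variants_total Total number of variants tested in the discovery
#'   study, including variants whose statistics were never reported. Needed
#'   for the truncated (significant-only) likelihood.
#' @param discovery_threshold Two-sided p-value threshold for discovery
#'   significance; default `5e-8`, the conventional genome-wide level.
#' @param replication_alpha Two-sided p-value threshold for calling a
#'   replication successful; default `0.05`.
#'
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design(2000, 1000, 1e6)
study_design <- function(n_discovery, n_replication, n_variants_total,
                         discovery_threshold = 5e-8,
                         replication_alpha = 0.05) {
  stopifnot(
    "n_discovery must be a single integer >= 2" =
      is.numeric(n_discovery) && length(n_discovery) == 1L && n_discovery >= 2,
    "n_replication must be a single integer >= 2" =
      is.numeric(n_replication) && length(n_replication) == 1L && n_replication >= 2,
    "n_variants_total must be a single integer >= 1" =
      is.numeric(n_variants_total) && length(n_variants_total) == 1L &&
        n_variants_total >= 1,
    "discovery_threshold must lie strictly in (0, 1)" =
      is.numeric(discovery_threshold) && length(discovery_threshold) == 1L &&
        discovery_threshold > 0 && discovery_threshold < 1,
    "replication_alpha must lie strictly in (0, 1)" =
      is.numeric(replication_alpha) && length(replication_alpha) == 1L &&
        replication_alpha > 0 && replication_alpha < 1
  )
  structure(
    list(
      n_discovery = as.numeric(n_discovery),
      n_replication = as.numeric(n_replication),
      n_variants_total = as.numeric(n_variants_total),
      discovery_threshold = discovery_threshold,
      replication_alpha = replication_alpha
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:\n")
  cat(sprintf("  discovery   N1 = %s, threshold t = %g (|z| > %.4f)\n",
              format(x$n_discovery, big.mark = ","), x$discovery_threshold,
              z_cutpoint(x$discovery_threshold)))
  cat(sprintf("  replication N2 = %s, alpha = %g (|z| > %.4f)\n",
              format(x$n_replication, big.mark = ","), x$replication_alpha,
              z_cutpoint(x$replication_alpha)))
  cat(sprintf("  variants tested N = %s\n",
              format(x$n_variants_total, big.mark = ",")))
  invisible(x)
}

#' Variance components of the effect-size model
#'
#' The three variance parameters of the model: the variance of the shared
#' genetic effect and the variances of the study-specific confounding
#' effects in discovery and replication. A Winner's-Curse-only model has
#' both confounding components equal to zero.
#'
#' @param var_genetic Variance of the genetic effect (sigma_g^2), >= 0.
#' @param var_conf_discovery Variance of discovery-specific confounding
#'   (sigma_c1^2), >= 0. Default 0.
#' @param var_conf_replication Variance of replication-specific confounding
#'   (sigma_c2^2), >= 0. Default 0.
#'
#' @return An object of class `variance_components`.
#' @seealso [vc_from_sigma()] to specify the parameters on the standard
#'   deviation scale.
#' @export
#' @examples
#' variance_components(0.022^2, 0.026^2, 0.018^2)
variance_components <- function(var_genetic,
                                var_conf_discovery = 0,
                                var_conf_replication = 0) {
  vals <- c(var_genetic, var_conf_discovery, var_conf_replication)
  stopifnot(
    "variance components must be three single finite numbers" =
      is.numeric(vals) && length(vals) == 3L && all(is.finite(vals)),
    "variance components must be nonnegative" = all(vals >= 0)
  )
  structure(
    list(
      var_genetic = as.numeric(var_genetic),
      var_conf_discovery = as.numeric(var_conf_discovery),
      var_conf_replication = as.numeric(var_conf_replication)
    ),
    class = "variance_components"
  )
}

#' Variance components from standard deviations
#'
#' Convenience constructor on the sigma (standard deviation) scale, the
#' scale on which simulation grids are usually specified.
#'
#' @param sigma_g,sigma_c1,sigma_c2 Nonnegative standard deviations of the
#'   genetic and study-specific confounding effects.
#' @return An object of class `variance_components`.
#' @export
vc_from_sigma <- function(sigma_g, sigma_c1 = 0, sigma_c2 = 0) {
  stopifnot("sigmas must be nonnegative" =
              all(c(sigma_g, sigma_c1, sigma_c2) >= 0))
  variance_components(sigma_g^2, sigma_c1^2, sigma_c2^2)
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components: sigma_g^2 = %.6g, sigma_c1^2 = %.6g, sigma_c2^2 = %.6g\n",
    x$var_genetic, x$var_conf_discovery, x$var_conf_replication))
  invisible(x)
}

#' Paired discovery/replication z-scores
#'
#' Container for per-variant association z-scores from a discovery study
#' and the matching replication study, with discovery-significance flags.
#' When a [study_design()] is supplied the flags are computed from the
#' two-sided discovery threshold; they are always recomputable from the
#' z-scores and the design.
#'
#' @param z_discovery,z_replication Finite numeric vectors of equal length.
#' @param variant_ids Optional character vector of identifiers; defaults to
#'   `v1`, `v2`, ...
#' @param design Optional [study_design()] used to flag significance.
#' @param is_significant Optional logical vector; ignored when `design` is
#'   given.
#'
#' @return A `data.frame` of class `paired_zscores` with columns
#'   `variant_id`, `z_discovery`, `z_replication`, `is_significant`.
#' @export
#' @examples
#' d <- study_design(2000, 1000, 1e6)
#' paired_zscores(c(6, -1), c(2.5, 0.3), design = d)
paired_zscores <- function(z_discovery, z_replication, variant_ids = NULL,
                           design = NULL, is_significant = NULL) {
  stopifnot(
    "z vectors must be numeric, finite and of equal positive length" =
      is.numeric(z_discovery) && is.numeric(z_replication) &&
        length(z_discovery) == length(z_replication) &&
        length(z_discovery) >= 1L &&
        all(is.finite(z_discovery)) && all(is.finite(z_replication))
  )
  n <- length(z_discovery)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(n))
  stopifnot("variant_ids length must match z vectors" =
              length(variant_ids) == n)
  if (!is.null(design)) {
    stopifnot(inherits(design, "study_design"))
    is_significant <- abs(z_discovery) > z_cutpoint(design$discovery_threshold)
  } else if (is.null(is_significant)) {
    is_significant <- rep(NA, n)
  }
  stopifnot("is_significant length must match z vectors" =
              length(is_significant) == n)
  structure(
    data.frame(
      variant_id = as.character(variant_ids),
      z_discovery = as.numeric(z_discovery),
      z_replication = as.numeric(z_replication),
      is_significant = as.logical(is_significant),
      stringsAsFactors = FALSE
    ),
    class = c("paired_zscores", "data.frame")
  )
}

#' Recompute discovery-significance flags
#'
#' @param data A [paired_zscores()] table.
#' @param design A [study_design()].
#' @return `data` with `is_significant` recomputed from the design's
#'   discovery threshold.
#' @export
flag_significant <- function(data, design) {
  stopifnot(inherits(data, "paired_zscores"), inherits(design, "study_design"))
  data$is_significant <-
    abs(data$z_discovery) > z_cutpoint(design$discovery_threshold)
  data
}

#' Two-sided z cut-point for a p-value threshold
#'
#' The z value such that a two-sided p-value falls below `p` exactly when
#' `|z|` exceeds it: `qnorm(1 - p/2)`.
#'
#' @param p Two-sided p-value threshold in (0, 1).
#' @return Positive numeric cut-point.
#' @export
#' @examples
#' z_cutpoint(5e-8)  # ~5.45
z_cutpoint <- function(p) {
  stopifnot("p must lie in (0,1)" = is.numeric(p) && all(p > 0 & p < 1))
  qnorm(p / 2, lower.tail = FALSE)
}

#' Two-sided p-value of a z-score
#'
#' Computed in log space so genome-wide hits beyond the resolution of the
#' normal CDF (|z| > ~38) still return the correct order of magnitude on
#' the log scale rather than underflowing silently.
#'
#' @param z Numeric vector of z-scores.
#' @param log.p Return the natural log of the p-value.
#' @return Two-sided p-values (or their logs).
#' @export
two_sided_p <- function(z, log.p = FALSE) {
  lp <- log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}
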