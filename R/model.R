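#' Gaussian distribution specification
#'
#' Lightweight container for a univariate or bivariate normal law. The
#' bivariate case stores a length-2 mean and a 2x2 symmetric covariance
#' matrix.
#'
#' @param mean Numeric mean (length 1 or 2).
#' @param variance Positive variance, or a 2x2 symmetric positive-definite
#'   covariance matrix for the bivariate case.
#' @return An object of class `gaussian_spec`.
#' @export
gaussian_spec <- function(mean, variance) {
  if (is.matrix(variance)) {
    stopifnot(
      "bivariate mean must have length 2" = length(mean) == 2L,
      "covariance must be 2x2" = all(dim(variance) == c(2L, 2L)),
      "covariance must be symmetric" =
        isTRUE(all.equal(variance[1, 2], variance[2, 1])),
      "covariance must be positive-definite" =
        variance[1, 1] > 0 && variance[2, 2] > 0 &&
          variance[1, 1] * variance[2, 2] - variance[1, 2]^2 > 0
    )
  } else {
    stopifnot("variance must be strictly positive" = all(variance > 0))
  }
  structure(list(mean = mean, variance = variance), class = "gaussian_spec")
}

#' @export
print.gaussian_spec <- function(x, ...) {
  if (is.matrix(x$variance)) {
    cat("Bivariate normal: mean", paste(signif(x$mean, 6), collapse = ", "),
        "\ncovariance:\n")
    print(x$variance)
  } else if (length(x$mean) > 1L) {
    cat(sprintf("Normal (vectorized over %d points): variance %.6g\n",
                length(x$mean), x$variance))
  } else {
    cat(sprintf("Normal: mean %.6g, variance %.6g\n", x$mean, x$variance))
  }
  invisible(x)
}

#' Marginal distribution of discovery z-scores
#'
#' Integrating the latent genetic and discovery confounding effects out of
#' the sampling model gives `s1 ~ N(0, N1 sigma_g^2 + N1 sigma_c1^2 + 1)`.
#' With zero confounding this reduces to the Winner's-Curse-only marginal
#' `N(0, N1 sigma_g^2 + 1)`.
#'
#' @param design A [study_design()].
#' @param vc A [variance_components()].
#' @return A univariate [gaussian_spec()].
#' @export
#' @examples
#' marginal_discovery(study_design(2000, 1000, 1e6), vc_from_sigma(0.018, 0.018))
marginal_discovery <- function(design, vc) {
  stopifnot(inherits(design, "study_design"),
            inherits(vc, "variance_components"))
  gaussian_spec(
    mean = 0,
    variance = design$n_discovery * (vc$var_genetic + vc$var_conf_discovery) + 1
  )
}

#' Marginal distribution of replication z-scores
#'
#' `s2 ~ N(0, N2 sigma_g^2 + N2 sigma_c2^2 + 1)`.
#'
#' @inheritParams marginal_discovery
#' @return A univariate [gaussian_spec()].
#' @export
marginal_replication <- function(design, vc) {
  stopifnot(inherits(design, "study_design"),
            inherits(vc, "variance_components"))
  gaussian_spec(
    mean = 0,
    variance = design$n_replication *
      (vc$var_genetic + vc$var_conf_replication) + 1
  )
}

#' Joint distribution of discovery and replication z-scores
#'
#' The shared genetic effect induces covariance `sqrt(N1 N2) sigma_g^2`
#' between the two studies' statistics; study-specific confounding inflates
#' each marginal variance without contributing to the covariance:
#' \deqn{(s_1, s_2) \sim N_2\!\left(0,
#'   \begin{pmatrix} N_1\sigma_g^2 + N_1\sigma_{c1}^2 + 1 &
#'                   \sqrt{N_1 N_2}\,\sigma_g^2 \\
#'                   \sqrt{N_1 N_2}\,\sigma_g^2 &
#'                   N_2\sigma_g^2 + N_2\sigma_{c2}^2 + 1 \end{pmatrix}\right)}
#'
#' @inheritParams marginal_discovery
#' @return A bivariate [gaussian_spec()].
#' @export
joint_distribution <- function(design, vc) {
  stopifnot(inherits(design, "study_design"),
            inherits(vc, "variance_components"))
  v1 <- design$n_discovery * (vc$var_genetic + vc$var_conf_discovery) + 1
  v2 <- design$n_replication * (vc$var_genetic + vc$var_conf_replication) + 1
  cv <- sqrt(design$n_discovery * design$n_replication) * vc$var_genetic
  gaussian_spec(mean = c(0, 0),
                variance = matrix(c(v1, cv, cv, v2), 2, 2))
}

#' Conditional distribution of the replication z-score
#'
#' The Winner's Curse correction: given an observed discovery statistic
#' `s1 = x`, the replication statistic is normal with mean
#' `sqrt(N1 N2) sigma_g^2 / (N1 sigma_g^2 + N1 sigma_c1^2 + 1) * x`
#' (a shrinkage of `x` toward zero) and variance
#' `N2 sigma_g^2 + N2 sigma_c2^2 + 1 - N1 N2 sigma_g^4 /
#'  (N1 sigma_g^2 + N1 sigma_c1^2 + 1)`.
#' Setting both confounding components to zero recovers the
#' Winner's-Curse-only conditional.
#'
#' @param x Numeric vector of discovery z-scores to condition on.
#' @inheritParams marginal_discovery
#' @return A [gaussian_spec()] whose `mean` is vectorized over `x` and whose
#'   `variance` is the common scalar conditional variance.
#' @export
#' @examples
#' d <- study_design(2000, 1000, 1e6)
#' conditional_replication(6, d, variance_components(0.0009))
conditional_replication <- function(x, design, vc) {
  stopifnot(inherits(design, "study_design"),
            inherits(vc, "variance_components"),
            is.numeric(x), all(is.finite(x)))
  n1 <- design$n_discovery
  n2 <- design$n_replication
  v1 <- n1 * (vc$var_genetic + vc$var_conf_discovery) + 1
  v2 <- n2 * (vc$var_genetic + vc$var_conf_replication) + 1
  cv <- sqrt(n1 * n2) * vc$var_genetic
  gaussian_spec(mean = cv / v1 * x, variance = v2 - cv^2 / v1)
}

#' Confidence interval for the replication z-score
#'
#' Central normal interval from [conditional_replication()]:
#' mean +/- `qnorm((1 + level) / 2)` standard deviations.
#'
#' @param x Numeric vector of discovery z-scores.
#' @inheritParams marginal_discovery
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A two-column matrix with columns `lower` and `upper`, one row
#'   per element of `x`.
#' @export
confidence_interval <- function(x, design, vc, level = 0.95) {
  stopifnot("level must lie strictly in (0,1)" =
              is.numeric(level) && length(level) == 1L &&
              level > 0 && level < 1)
  cond <- conditional_replication(x, design, vc)
  half <- qnorm((1 + level) / 2) * sqrt(cond$variance)
  cbind(lower = cond$mean - half, upper = cond$mean + half)
}

# Log-density of the zero-mean bivariate normal with marginal variances
# v1, v2 and covariance cv, evaluated elementwise at (z1, z2).
dbvnorm_log <- function(z1, z2, v1, v2, cv) {
  det <- v1 * v2 - cv^2
  q <- (v2 * z1^2 - 2 * cv * z1 * z2 + v1 * z2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}
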