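#' Variance components for the staircase mixed model
#'
#' Bundles the intracluster correlation (ICC, \code{icc}), the cluster
#' autocorrelation (CAC, \code{cac}) and the total outcome variance into the
#' parameterisation used throughout the package. Writing \code{tau2} for the
#' cluster-period random-effect variance and \code{sigma2_eps} for the
#' residual variance, the ICC is \code{tau2 / (tau2 + sigma2_eps)} and the
#' CAC is the proportionate reduction in correlation between the two measured
#' periods of a cluster; \code{cac = 1} recovers the exchangeable structure.
#'
#' @param icc within-period intracluster correlation, in [0, 1).
#' @param cac cluster autocorrelation, in [0, 1].
#' @param sigma2_total total outcome variance \code{tau2 + sigma2_eps};
#'   defaults to 1 so that treatment effects are in outcome-SD units.
#' @return An object of class \code{"staircase_vc"} with elements \code{icc},
#'   \code{cac}, \code{sigma2_total}, \code{tau2} and \code{sigma2_eps}.
#' @export
variance_components <- function(icc, cac = 1, sigma2_total = 1) {
  if (!is.numeric(icc) || length(icc) != 1L || icc < 0 || icc >= 1)
    stop("icc must be a single value in [0, 1)")
  if (!is.numeric(cac) || length(cac) != 1L || cac < 0 || cac > 1)
    stop("cac must be a single value in [0, 1]")
  if (!is.numeric(sigma2_total) || sigma2_total <= 0)
    stop("sigma2_total must be positive")
  structure(list(
    icc = icc, cac = cac, sigma2_total = sigma2_total,
    tau2 = icc * sigma2_total,
    sigma2_eps = (1 - icc) * sigma2_total
  ), class = "staircase_vc")
}

#' Variance of a cluster-period mean (relative to total variance)
#'
#' \code{a = (1 + (m - 1) * icc) / m}: the variance of the mean of the m
#' outcomes in one cluster-period cell, in units of the total outcome
#' variance.
#'
#' @param m participants per cluster-period.
#' @param icc within-period intracluster correlation, in [0, 1).
#' @return \code{(1 + (m - 1) * icc) / m}.
#' @export
cell_mean_variance_a <- function(m, icc) {
  if (any(m < 1)) stop("m must be >= 1")
  if (any(icc < 0 | icc >= 1)) stop("icc must be in [0, 1)")
  (1 + (m - 1) * icc) / m
}

#' Correlation between the two cluster-period means of a cluster
#'
#' \code{psi = m * icc * cac / (1 + (m - 1) * icc)}: the correlation between
#' the cell means of the control and intervention periods of the same
#' cluster under the block-exchangeable structure.
#'
#' @inheritParams cell_mean_variance_a
#' @param cac cluster autocorrelation, in [0, 1].
#' @return A value in [0, 1].
#' @export
cell_mean_correlation_psi <- function(m, icc, cac) {
  if (any(cac < 0 | cac > 1)) stop("cac must be in [0, 1]")
  m * icc * cac / (1 + (m - 1) * icc)
}

#' Closed-form variance of the GLS treatment-effect estimator
#'
#' Exact expressions for \code{var(theta_hat)} of the generalised least
#' squares treatment-effect estimator in a basic staircase design, under
#' categorical (\code{var_theta_categorical}) or linear
#' (\code{var_theta_linear}) period effects. With
#' \code{a = cell_mean_variance_a(m, icc)} and
#' \code{psi = cell_mean_correlation_psi(m, icc, cac)}:
#' \deqn{var_{cat} = \frac{2a(1-\psi)^2}{K[S(1-\psi) -
#'   \sqrt{1-\psi^2}\,\frac{(1+\sqrt{1-\psi^2})^S - \psi^S}
#'   {(1+\sqrt{1-\psi^2})^S + \psi^S}]}}
#' \deqn{var_{lin} = \frac{2a[(S^2+2) - (S^2-4)\psi]}{K S (S^2-1)}}
#' The categorical expression is an indeterminate 0/0 form at \code{psi = 1};
#' for \code{psi > 1 - 1e-6} it is evaluated through the direct GLS
#' computation of \code{\link{gls_variance_oracle}} instead. The ratio in the
#' denominator is computed as \code{(1 - q^S) / (1 + q^S)} with
#' \code{q = psi / (1 + sqrt(1 - psi^2)) < 1}, which is stable for any S.
#'
#' @param S number of sequences (\code{S >= 2}).
#' @param K clusters per sequence.
#' @param m participants per cluster-period.
#' @param icc within-period intracluster correlation.
#' @param cac cluster autocorrelation.
#' @param sigma2_total total outcome variance scale (default 1).
#' @return The variance of the treatment-effect estimator.
#' @export
var_theta_categorical <- function(S, K, m, icc, cac, sigma2_total = 1) {
  if (S < 2) stop("S must be >= 2")
  a <- cell_mean_variance_a(m, icc)
  psi <- cell_mean_correlation_psi(m, icc, cac)
  if (psi > 1 - 1e-6) {
    d <- staircase_design(S, K, max(m, 1))
    return(gls_variance_oracle(d, variance_components(icc, cac, sigma2_total),
                               time = "categorical"))
  }
  # 1 - psi computed by its exact closed form to avoid cancellation as
  # psi -> 1 (large m with cac near 1)
  omp <- (1 - icc + m * icc * (1 - cac)) / (1 + (m - 1) * icc)
  c1 <- sqrt(omp * (1 + psi))
  q <- psi / (1 + c1)
  ratio <- (1 - q^S) / (1 + q^S)
  sigma2_total * 2 * a * omp^2 / (K * (S * omp - c1 * ratio))
}

#' @rdname var_theta_categorical
#' @export
var_theta_linear <- function(S, K, m, icc, cac, sigma2_total = 1) {
  if (S < 2) stop("S must be >= 2")
  a <- cell_mean_variance_a(m, icc)
  psi <- cell_mean_correlation_psi(m, icc, cac)
  sigma2_total * 2 * a * ((S^2 + 2) - (S^2 - 4) * psi) / (K * S * (S^2 - 1))
}

#' Brute-force GLS variance of the treatment-effect estimator
#'
#' Validation oracle for the closed-form variance expressions: builds the
#' block-diagonal covariance of the cluster-period means (per cluster the
#' 2x2 matrix \code{sigma2_total * a * [[1, psi], [psi, 1]]}), and returns
#' the treatment-effect entry of \code{(X' V^-1 X)^-1} for the requested
#' time parameterisation.
#'
#' @param design a \code{staircase_design}.
#' @param vc a \code{staircase_vc}.
#' @param time period-effect parameterisation.
#' @return The GLS variance of the treatment-effect estimator.
#' @export
gls_variance_oracle <- function(design, vc, time = c("categorical", "linear")) {
  stopifnot(inherits(design, "staircase_design"), inherits(vc, "staircase_vc"))
  time <- match.arg(time)
  a <- cell_mean_variance_a(design$m, vc$icc)
  psi <- cell_mean_correlation_psi(design$m, vc$icc, vc$cac)
  X <- fixed_effects_matrix(design, time)
  d <- vc$sigma2_total * a
  o <- d * psi
  det2 <- d^2 - o^2
  if (det2 <= 0) stop("singular cell-mean covariance (psi at boundary 1)")
  swap <- .pair_swap_index(design$n_cells)
  ViX <- (d * X - o * X[swap, , drop = FALSE]) / det2
  XtViX <- crossprod(X, ViX)
  Phi <- solve(XtViX)
  Phi["treatment", "treatment"]
}

# index vector that swaps the two rows of each consecutive (control,
# intervention) pair in the cell ordering
.pair_swap_index <- function(n_cells) {
  idx <- seq_len(n_cells)
  idx + rep(c(1L, -1L), times = n_cells %/% 2L)
}

#' Asymptotic power of the treatment-effect test
#'
#' Power of a two-sided size-\code{alpha} Wald test to detect an effect of
#' size \code{theta_d} (in outcome-SD units) given the variance of the
#' estimator: \code{Phi(theta_d / sqrt(var_theta) - z_{1 - alpha/2})}. When
#' \code{df} is supplied, the standard normal reference is replaced by a
#' central t distribution with that many degrees of freedom, as is
#' appropriate when small-sample corrections are used:
#' \code{P(T_df > t_{df, 1 - alpha/2} - theta_d / sqrt(var_theta))}.
#'
#' @param var_theta variance of the treatment-effect estimator (positive).
#' @param theta_d effect size to detect, in outcome-SD units.
#' @param alpha two-sided test size.
#' @param df optional degrees of freedom for t-based power.
#' @return The power, a probability.
#' @export
theoretical_power <- function(var_theta, theta_d = 0.15, alpha = 0.05, df = NULL) {
  if (any(var_theta <= 0)) stop("var_theta must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ncp <- theta_d / sqrt(var_theta)
  if (is.null(df)) {
    stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
  } else {
    if (any(df <= 0)) stop("df must be positive")
    stats::pt(stats::qt(1 - alpha / 2, df) - ncp, df, lower.tail = FALSE)
  }
}
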