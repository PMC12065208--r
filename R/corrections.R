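# ---- shared helpers for the small-sample corrections -----------------------
#
# Variance-parameter coordinates are the natural interior coordinates
# gamma = (sigma2_eps, g1[, g2]); the cell-level covariance is affine in all
# of them, so its derivatives are exact constant matrices. Components sitting
# at the zero boundary are excluded from differentiation and the information
# matrix is restricted to the remaining coordinates (the corrections must
# return finite values for singular fits, which are retained).

.gamma_of_fit <- function(fit) {
  g <- c(fit$vc_hat$sigma2_eps, fit$vc_hat$g1)
  if (!fit$exch) g <- c(g, fit$vc_hat$g2)
  g
}

# negative restricted log-likelihood as a function of natural gamma
.nll_natural <- function(fit) {
  nll <- .make_reml_nll(fit$stats, fit$X, fit$exch)
  function(gamma) {
    if (gamma[1L] <= 0 || any(gamma[-1L] < 0)) return(1e10)
    nll(c(log(gamma[1L]), gamma[-1L]))
  }
}

# GLS variance of theta_hat as a function of natural gamma
.v_theta <- function(fit) {
  st <- fit$stats; X <- fit$X
  function(gamma) {
    g2 <- if (length(gamma) > 2L) gamma[3L] else 0
    .gls_cells(st, X, gamma[1L], gamma[2L], g2)$Phi["treatment", "treatment"]
  }
}

.active_coords <- function(gamma) {
  # residual variance is always interior; variance components near zero are
  # treated as boundary-pinned for differentiation
  thr <- 1e-6 * max(1, sum(gamma))
  c(TRUE, gamma[-1L] > thr)
}

.fd_steps <- function(gamma) {
  h <- 1e-5 * (1 + abs(gamma))
  pmin(h, pmax(gamma / 2, 1e-12))
}

.fd_gradient <- function(f, gamma, active) {
  h <- .fd_steps(gamma)
  g <- numeric(length(gamma))
  for (i in which(active)) {
    up <- gamma; up[i] <- up[i] + h[i]
    dn <- gamma; dn[i] <- dn[i] - h[i]
    g[i] <- (f(up) - f(dn)) / (2 * h[i])
  }
  g
}

.fd_hessian <- function(f, gamma, active) {
  h <- .fd_steps(gamma)
  k <- length(gamma)
  H <- matrix(0, k, k)
  f0 <- f(gamma)
  idx <- which(active)
  for (i in idx) {
    up <- gamma; up[i] <- up[i] + h[i]
    dn <- gamma; dn[i] <- dn[i] - h[i]
    H[i, i] <- (f(up) + f(dn) - 2 * f0) / h[i]^2
  }
  if (length(idx) > 1L) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        pp <- gamma; pp[i] <- pp[i] + h[i]; pp[j] <- pp[j] + h[j]
        pm <- gamma; pm[i] <- pm[i] + h[i]; pm[j] <- pm[j] - h[j]
        mp <- gamma; mp[i] <- mp[i] - h[i]; mp[j] <- mp[j] + h[j]
        mm <- gamma; mm[i] <- mm[i] - h[i]; mm[j] <- mm[j] - h[j]
        H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# symmetric pseudo-inverse on the positive-eigenvalue part
.psd_inverse <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10
  if (!any(pos)) return(NULL)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Satterthwaite degrees-of-freedom correction
#'
#' Approximate degrees of freedom for the Wald test of the treatment effect,
#' by matching moments of the estimated GLS variance: with
#' \code{v(gamma)} the treatment entry of \code{(X' V(gamma)^-1 X)^-1},
#' \code{df = 2 v^2 / (g' A g)} where \code{g} is the gradient of \code{v}
#' at the REML estimate and \code{A} the inverse observed information
#' (negative Hessian of the restricted log-likelihood) of the variance
#' parameters. The standard error is unchanged; CI and p-value use the t
#' distribution with the computed df. Boundary (singular) fits restrict the
#' information to the interior coordinates; a non-positive-definite observed
#' information falls back to its positive part, flagged.
#'
#' @param fit a \code{\link{fit_staircase}} result.
#' @return A list of class \code{"staircase_correction"} with \code{method},
#'   \code{df}, \code{se_adj} (equal to the unadjusted se), \code{ci},
#'   \code{p_value} and \code{flag}.
#' @export
satterthwaite <- function(fit) {
  stopifnot(inherits(fit, "staircase_fit"))
  gamma <- .gamma_of_fit(fit)
  active <- .active_coords(gamma)
  f <- .nll_natural(fit)
  vfun <- .v_theta(fit)
  v <- vfun(gamma)
  grad <- .fd_gradient(vfun, gamma, active)[active]
  H <- .fd_hessian(f, gamma, active)[active, active, drop = FALSE]
  flag <- "ok"
  A <- tryCatch(solve(H), error = function(e) NULL)
  denom <- if (!is.null(A)) as.numeric(t(grad) %*% A %*% grad) else -1
  if (is.null(A) || denom <= 0) {
    A <- .psd_inverse(H)
    denom <- if (!is.null(A)) as.numeric(t(grad) %*% A %*% grad) else -1
    flag <- "information_adjusted"
  }
  df <- if (denom > 0) 2 * v^2 / denom else Inf
  .correction_result("satterthwaite", fit, df = df, se_adj = fit$se,
                     flag = flag)
}

#' Kenward-Roger small-sample correction
#'
#' First-order Kenward-Roger (1997) adjustment for REML-based Wald inference
#' on the treatment effect, using the expected information matrix. The
#' covariance of the fixed effects is inflated by the Kackar-Harville and
#' second-order terms built from the derivatives of the covariance matrix
#' with respect to the variance parameters (the covariance is linear in
#' them, so the second-derivative term vanishes), and the degrees of freedom
#' follow from the matched first two moments of the scaled Wald statistic.
#' The adjusted standard error is never below the unadjusted one; the df can
#' be far below 1 in weakly identified small-cluster fits, which is exactly
#' the regime where this correction turns extremely conservative.
#'
#' @inheritParams satterthwaite
#' @return As for \code{\link{satterthwaite}}, with \code{se_adj} the
#'   KR-adjusted standard error.
#' @export
kenward_roger <- function(fit) {
  stopifnot(inherits(fit, "staircase_fit"))
  st <- fit$stats; X <- fit$X
  gamma <- .gamma_of_fit(fit)
  active <- .active_coords(gamma)
  s2 <- gamma[1L]; g1 <- gamma[2L]
  g2 <- if (length(gamma) > 2L) gamma[3L] else 0
  n <- st$n_cells
  swap <- .pair_swap_index(n)
  d <- g1 + g2 + s2 / st$mcell
  o <- g1
  det <- d * d[swap] - o^2
  Vi <- matrix(0, n, n)
  Vi[cbind(seq_len(n), seq_len(n))] <- d[swap] / det
  Vi[cbind(seq_len(n), swap)] <- -o / det
  ViX <- Vi %*% X
  Phi <- solve(crossprod(X, ViX))
  tix <- which(colnames(X) == "treatment")
  # derivatives of the cell-mean covariance w.r.t. (sigma2_eps, g1[, g2])
  Ms2 <- diag(1 / st$mcell)
  Mg1 <- matrix(0, n, n)
  Mg1[cbind(seq_len(n), seq_len(n))] <- 1
  Mg1[cbind(seq_len(n), swap)] <- 1
  Mlist <- list(Ms2, Mg1)
  if (length(gamma) > 2L) Mlist <- c(Mlist, list(diag(n)))
  Pproj <- Vi - ViX %*% Phi %*% t(ViX)
  k <- length(gamma)
  EI <- matrix(0, k, k)
  Tm <- lapply(Mlist, function(M) Pproj %*% M)
  for (i in seq_len(k)) for (j in i:k)
    EI[i, j] <- EI[j, i] <- 0.5 * sum(Tm[[i]] * t(Tm[[j]]))
  EI[1L, 1L] <- EI[1L, 1L] + st$dfw / (2 * s2^2)
  Plist <- lapply(Mlist, function(M) -crossprod(ViX, M %*% ViX))
  Qfun <- function(i, j) crossprod(ViX, Mlist[[i]] %*% Vi %*% Mlist[[j]] %*% ViX)
  ia <- which(active)
  flag <- "ok"
  W <- tryCatch(solve(EI[ia, ia, drop = FALSE]), error = function(e) NULL)
  if (is.null(W)) {
    W <- .psd_inverse(EI[ia, ia, drop = FALSE])
    flag <- "information_adjusted"
    if (is.null(W)) {
      return(.correction_result("kenward_roger", fit, df = Inf,
                                se_adj = fit$se, flag = "information_singular"))
    }
  }
  p <- ncol(X)
  U <- matrix(0, p, p)
  for (a in seq_along(ia)) for (b in seq_along(ia)) {
    i <- ia[a]; j <- ia[b]
    U <- U + W[a, b] * (Qfun(i, j) - Plist[[i]] %*% Phi %*% Plist[[j]])
  }
  PhiA <- Phi + 2 * Phi %*% U %*% Phi
  v <- Phi[tix, tix]
  vA <- PhiA[tix, tix]
  if (!is.finite(vA) || vA < v) {
    vA <- v
    flag <- paste(flag, "adjustment_clamped", sep = ";")
  }
  # moment-matched df for the scalar Wald test (q = 1, where A1 = A2)
  bvec <- vapply(seq_along(ia), function(a) {
    (Phi %*% Plist[[ia[a]]] %*% Phi)[tix, tix]
  }, numeric(1))
  A1 <- as.numeric(t(bvec) %*% W %*% bvec) / v^2
  if (!is.finite(A1) || A1 <= 1e-14) {
    df <- Inf
  } else {
    q <- 1
    B <- (A1 + 6 * A1) / (2 * q)
    gg <- ((q + 1) * A1 - (q + 4) * A1) / ((q + 2) * A1)
    den <- 3 * q + 2 * (1 - gg)
    c1 <- gg / den; c2 <- (q - gg) / den; c3 <- (q + 2 - gg) / den
    Estar <- 1 / (1 - A1 / q)
    Vstar <- (2 / q) * (1 + c1 * B) / ((1 - c2 * B)^2 * (1 - c3 * B))
    rho <- Vstar / (2 * Estar^2)
    df <- 4 + (q + 2) / (q * rho - 1)
    if (!is.finite(df) || df <= 0) {
      df <- 1e-2
      flag <- paste(flag, "df_floored", sep = ";")
    }
  }
  .correction_result("kenward_roger", fit, df = df, se_adj = sqrt(vA),
                     flag = flag)
}

.correction_result <- function(method, fit, df, se_adj, flag) {
  alpha <- fit$alpha
  crit <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else
    stats::qnorm(1 - alpha / 2)
  tval <- fit$theta_hat / se_adj
  p <- if (is.finite(df)) 2 * stats::pt(-abs(tval), df) else
    2 * stats::pnorm(-abs(tval))
  structure(list(
    method = method, df = df, se_adj = se_adj,
    ci = fit$theta_hat + c(-1, 1) * crit * se_adj,
    p_value = p, flag = flag
  ), class = "staircase_correction")
}

#' Small-sample correction policy by trial size
#'
#' The simulation design applies the Satterthwaite and Kenward-Roger
#' corrections only to configurations in which the total number of clusters
#' does not exceed 50; larger trials use standard normal-based Wald
#' inference.
#'
#' @param total_clusters total number of clusters in the design (S * K).
#' @param requested requested correction.
#' @return The effective correction: \code{requested}, or \code{"none"} when
#'   \code{total_clusters > 50}.
#' @examples
#' apply_correction_policy(100, "satterthwaite")  # "none"
#' apply_correction_policy(50, "satterthwaite")   # still corrected
#' @export
apply_correction_policy <- function(total_clusters,
                                    requested = c("none", "satterthwaite",
                                                  "kenward_roger")) {
  requested <- match.arg(requested)
  if (total_clusters > 50) "none" else requested
}
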