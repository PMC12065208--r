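#' Sufficient statistics for staircase mixed-model fitting
#'
#' Collapses an individual-level staircase dataset to its cluster-period
#' cell means plus the pooled within-cell sum of squares. Because the fixed
#' effects of the analysis models are constant within a cluster-period cell
#' and the covariance structure acts at the cell level, this collapse is
#' lossless for REML inference: the individual-level restricted
#' log-likelihood equals the collapsed form up to an additive constant that
#' does not depend on the parameters. Cells of unequal size are handled
#' exactly through heterogeneous cell-mean variances.
#'
#' @param data a \code{staircase_data} frame (or any data frame with columns
#'   \code{sequence, cluster, period, treatment, y}).
#' @return An object of class \code{"staircase_stats"}: list with
#'   \code{cells} (one row per cell, ordered by sequence, cluster, period),
#'   \code{ybar} (cell means), \code{mcell} (cell sizes), \code{SSw} (pooled
#'   within-cell sum of squares), \code{dfw} (within-cell degrees of
#'   freedom, \code{sum(mcell - 1)}), \code{n_cells}, \code{n_clusters},
#'   \code{S}, \code{balanced} and \code{m} (common cell size, NA if
#'   unbalanced).
#' @export
sufficient_stats <- function(data) {
  d <- as.data.frame(data)
  need <- c("sequence", "cluster", "period", "treatment", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- d[order(d$sequence, d$cluster, d$period), , drop = FALSE]
  key <- paste(d$sequence, d$cluster, d$period, sep = "\r")
  first <- !duplicated(key)
  cell_id <- cumsum(first)
  mcell <- tabulate(cell_id)
  ybar <- as.vector(rowsum(d$y, cell_id)) / mcell
  SSw <- sum((d$y - ybar[cell_id])^2)
  cells <- d[first, c("sequence", "cluster", "period", "treatment")]
  rownames(cells) <- NULL
  # validate the staircase layout: each cluster in exactly 2 consecutive
  # periods, control then intervention
  per_cluster <- split(seq_len(nrow(cells)), cells$cluster)
  bad <- names(per_cluster)[vapply(per_cluster, function(i) {
    length(i) != 2L || diff(cells$period[i]) != 1L ||
      !identical(cells$treatment[i], c(0L, 1L)) &&
      !identical(as.numeric(cells$treatment[i]), c(0, 1))
  }, logical(1))]
  if (length(bad))
    stop("cluster(s) ", paste(bad, collapse = ", "),
         " do not form control/intervention cells in 2 consecutive periods ",
         "(empty or missing cluster-period cell?)")
  structure(list(
    cells = cells, ybar = ybar, mcell = mcell,
    SSw = SSw, dfw = sum(mcell - 1L),
    n_cells = nrow(cells), n_clusters = nrow(cells) %/% 2L,
    S = length(unique(cells$period)) - 1L,
    balanced = all(mcell == mcell[1L]),
    m = if (all(mcell == mcell[1L])) mcell[1L] else NA_integer_
  ), class = "staircase_stats")
}

# cell-level fixed-effects matrix from a cell table (handles external data
# whose periods need not start at 1)
.cell_model_matrix <- function(cells, time) {
  periods <- sort(unique(cells$period))
  n <- nrow(cells)
  if (time == "categorical") {
    X <- matrix(0, n, length(periods) + 1L)
    X[cbind(seq_len(n), match(cells$period, periods))] <- 1
    colnames(X) <- c(paste0("period", periods), "treatment")
  } else {
    X <- cbind(1, cells$period, 0)
    colnames(X) <- c("(Intercept)", "period", "treatment")
  }
  X[, ncol(X)] <- cells$treatment
  X
}

# restricted negative log-likelihood on the collapsed representation.
# par = (log sigma2_eps, g1[, g2]) with g1 = tau2*r the cluster variance and
# g2 = tau2*(1-r) the cluster-period variance; exchangeable fits pin g2 = 0.
.make_reml_nll <- function(st, X, exch) {
  swap <- .pair_swap_index(st$n_cells)
  ybar <- st$ybar; mcell <- st$mcell; SSw <- st$SSw; dfw <- st$dfw
  function(par) {
    s2 <- exp(par[1L]); g1 <- par[2L]; g2 <- if (exch) 0 else par[3L]
    if (!is.finite(s2) || g1 < 0 || g2 < 0) return(1e10)
    d <- g1 + g2 + s2 / mcell
    o <- g1
    det <- d * d[swap] - o^2
    if (any(det <= 0)) return(1e10)
    ViX <- (d[swap] * X - o * X[swap, , drop = FALSE]) / det
    XtViX <- crossprod(X, ViX)
    R <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    beta <- backsolve(R, forwardsolve(t(R), crossprod(ViX, ybar)))
    resid <- ybar - as.vector(X %*% beta)
    quad <- sum(resid * (d[swap] * resid - o * resid[swap]) / det)
    val <- dfw * log(s2) + SSw / s2 + 0.5 * sum(log(det)) + quad +
      2 * sum(log(diag(R)))
    if (!is.finite(val)) return(1e10)
    0.5 * val
  }
}

#' Restricted log-likelihood of the staircase mixed model
#'
#' Evaluates the REML criterion (up to an additive constant independent of
#' the parameters) at given variance components, using the collapsed
#' cell-mean representation. Mostly of interest for validation; model
#' fitting goes through \code{\link{fit_staircase}}.
#'
#' @param tau2 cluster-period random-effect variance (>= 0).
#' @param sigma2_eps residual variance (> 0).
#' @param cac cluster autocorrelation in [0, 1] (1 for the exchangeable
#'   structure).
#' @param stats a \code{staircase_stats} object.
#' @param time period-effect parameterisation.
#' @return The restricted log-likelihood (a scalar, up to a constant).
#' @export
reml_loglik <- function(tau2, sigma2_eps, cac, stats,
                        time = c("categorical", "linear")) {
  time <- match.arg(time)
  stopifnot(inherits(stats, "staircase_stats"),
            tau2 >= 0, sigma2_eps > 0, cac >= 0, cac <= 1)
  X <- .cell_model_matrix(stats$cells, time)
  nll <- .make_reml_nll(stats, X, exch = FALSE)
  -nll(c(log(sigma2_eps), tau2 * cac, tau2 * (1 - cac)))
}

# dense individual-level restricted negative log-likelihood (validation
# oracle for the collapsed form; small datasets only)
.make_dense_nll <- function(data, time) {
  d <- as.data.frame(data)
  d <- d[order(d$sequence, d$cluster, d$period), , drop = FALSE]
  key <- paste(d$sequence, d$cluster, d$period, sep = "\r")
  cell_id <- cumsum(!duplicated(key))
  st <- sufficient_stats(d)
  Xc <- .cell_model_matrix(st$cells, time)
  X <- Xc[cell_id, , drop = FALSE]
  y <- d$y
  n <- length(y)
  if (n > 2000L) stop("dense likelihood restricted to small datasets (n <= 2000)")
  Z1 <- outer(d$cluster, sort(unique(d$cluster)), "==") * 1
  Z2 <- outer(cell_id, seq_len(st$n_cells), "==") * 1
  B1 <- tcrossprod(Z1); B2 <- tcrossprod(Z2)
  function(par) {
    s2 <- exp(par[1L]); g1 <- par[2L]
    g2 <- if (length(par) > 2L) par[3L] else 0
    if (g1 < 0 || g2 < 0) return(1e10)
    V <- g1 * B1 + g2 * B2
    diag(V) <- diag(V) + s2
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ldV <- 2 * sum(log(diag(R)))
    Viy <- backsolve(R, forwardsolve(t(R), y))
    ViX <- backsolve(R, forwardsolve(t(R), X))
    XtViX <- crossprod(X, ViX)
    R2 <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(R2)) return(1e10)
    beta <- backsolve(R2, forwardsolve(t(R2), crossprod(X, Viy)))
    resid <- y - as.vector(X %*% beta)
    Vir <- backsolve(R, forwardsolve(t(R), resid))
    0.5 * (ldV + 2 * sum(log(diag(R2))) + sum(resid * Vir))
  }
}

# multi-start bounded REML optimisation; returns gamma = (sigma2, g1, g2)
.optimise_reml <- function(nll, st, X, exch) {
  s2w <- if (st$dfw > 0) st$SSw / st$dfw else max(stats::var(st$ybar) / 2, 1e-6)
  s2w <- max(s2w, 1e-10)
  ols <- stats::lm.fit(X, st$ybar)
  vb <- sum(ols$residuals^2) / max(1L, st$n_cells - ncol(X))
  gtot <- max(vb - s2w * mean(1 / st$mcell), 1e-3 * (s2w + vb))
  starts <- if (exch) {
    list(c(log(s2w), gtot), c(log(s2w), 1e-6 * s2w), c(log(s2w + vb), gtot / 2))
  } else {
    list(c(log(s2w), 0.75 * gtot, 0.25 * gtot),
         c(log(s2w), 1e-6 * s2w, 1e-6 * s2w),
         c(log(s2w + vb), gtot / 2, gtot / 2))
  }
  lower <- c(-30, 0, 0)[seq_len(if (exch) 2L else 3L)]
  upper <- c(30, Inf, Inf)[seq_len(if (exch) 2L else 3L)]
  best <- NULL
  conv <- FALSE
  for (p0 in starts) {
    o <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-12) best <- o
    if (o$convergence == 0L) conv <- TRUE
  }
  if (is.null(best)) stop("REML optimisation failed at all starting points")
  gamma <- c(exp(best$par[1L]), best$par[2L], if (exch) 0 else best$par[3L])
  list(gamma = gamma, value = best$value, converged = conv)
}

# GLS fixed effects and covariance at given variance components
.gls_cells <- function(st, X, s2, g1, g2) {
  swap <- .pair_swap_index(st$n_cells)
  d <- g1 + g2 + s2 / st$mcell
  o <- g1
  det <- d * d[swap] - o^2
  ViX <- (d[swap] * X - o * X[swap, , drop = FALSE]) / det
  XtViX <- crossprod(X, ViX)
  Phi <- solve(XtViX)
  beta <- as.vector(Phi %*% crossprod(ViX, st$ybar))
  names(beta) <- colnames(X)
  list(beta = beta, Phi = Phi,
       theta_hat = beta[["treatment"]],
       se = sqrt(Phi["treatment", "treatment"]))
}

#' Fit a staircase linear mixed model by REML
#'
#' Fits the repeated cross-sectional staircase mixed model with an
#' exchangeable or block-exchangeable intracluster correlation structure and
#' categorical or linear period effects. Variance components are estimated
#' by restricted maximum likelihood over the admissible region (boundary
#' solutions allowed and retained), via a bounded quasi-Newton search from
#' three starting points in the parameterisation (log residual variance,
#' cluster variance \code{g1 = tau2 * r}, cluster-period variance
#' \code{g2 = tau2 * (1 - r)}); the exchangeable structure pins
#' \code{g2 = 0}. The treatment effect is the GLS estimate at the REML
#' variance estimates. Without a correction, confidence interval and p-value
#' use standard-normal Wald quantiles; the Satterthwaite and Kenward-Roger
#' corrections replace these with t-based inference (see
#' \code{\link{satterthwaite}} and \code{\link{kenward_roger}}).
#'
#' @param data a \code{staircase_data} frame, a plain data frame with
#'   columns \code{sequence, cluster, period, treatment, y}, or a
#'   precomputed \code{staircase_stats} object.
#' @param structure intracluster correlation structure of the analysis
#'   model.
#' @param time period-effect parameterisation.
#' @param correction small-sample correction to apply to the Wald inference.
#' @param alpha two-sided level for the confidence interval (default 0.05).
#' @param method \code{"collapsed"} (default) fits on the exact cell-mean
#'   sufficient statistics; \code{"dense"} maximises the individual-level
#'   likelihood directly (validation path, small datasets only).
#' @return An object of class \code{"staircase_fit"}; a list with
#'   \code{theta_hat}, \code{se}, \code{df} (Inf for uncorrected normal
#'   inference), \code{ci}, \code{p_value}, \code{beta}, \code{vc_hat}
#'   (\code{tau2}, \code{sigma2_eps}, \code{icc}, \code{cac}, \code{g1},
#'   \code{g2}), \code{reml_loglik} (up to a constant), \code{singular}
#'   (the structure's headline flag), \code{singular_any},
#'   \code{singular_strict}, \code{converged}, and the fit specification.
#' @examples
#' d <- staircase_design(4, 5, 10)
#' dat <- simulate_staircase(d, variance_components(0.1, 0.8), theta = 0.15,
#'                           seed = 42)
#' fit_staircase(dat, "block_exchangeable", "categorical", "satterthwaite")
#' @export
fit_staircase <- function(data,
                          structure = c("exchangeable", "block_exchangeable"),
                          time = c("categorical", "linear"),
                          correction = c("none", "satterthwaite", "kenward_roger"),
                          alpha = 0.05,
                          method = c("collapsed", "dense")) {
  structure <- match.arg(structure)
  time <- match.arg(time)
  correction <- match.arg(correction)
  method <- match.arg(method)
  st <- if (inherits(data, "staircase_stats")) data else sufficient_stats(data)
  exch <- structure == "exchangeable"
  if (!exch && all(st$mcell == 1L)) {
    warning("m = 1 cells: cluster-period variance not identifiable; ",
            "collapsing it into the residual (exchangeable-form fit)")
    exch_fit <- TRUE
  } else exch_fit <- exch
  X <- .cell_model_matrix(st$cells, time)
  if (method == "dense") {
    if (inherits(data, "staircase_stats"))
      stop("dense method needs individual-level data")
    nll <- .make_dense_nll(data, time)
    opt <- .optimise_reml(nll, st, X, exch_fit)
  } else {
    nll <- .make_reml_nll(st, X, exch_fit)
    opt <- .optimise_reml(nll, st, X, exch_fit)
  }
  g <- opt$gamma
  s2 <- g[1L]; g1 <- g[2L]; g2 <- g[3L]
  tau2 <- g1 + g2
  tol <- 1e-8 * max(1, s2 + tau2)
  gls <- .gls_cells(st, X, s2, g1, g2)
  singular_any <- if (exch) g1 <= tol else (g1 <= tol || g2 <= tol)
  singular_strict <- if (exch) g1 <= tol else (g1 <= tol && g2 <= tol)
  fit <- structure(list(
    theta_hat = gls$theta_hat,
    se = gls$se,
    df = Inf,
    ci = gls$theta_hat + c(-1, 1) * stats::qnorm(1 - alpha / 2) * gls$se,
    p_value = 2 * stats::pnorm(-abs(gls$theta_hat / gls$se)),
    beta = gls$beta,
    vc_hat = list(
      tau2 = tau2, sigma2_eps = s2,
      icc = tau2 / (tau2 + s2),
      cac = if (exch) 1 else if (tau2 > tol) g1 / tau2 else NA_real_,
      g1 = g1, g2 = g2),
    reml_loglik = -opt$value,
    singular = singular_any,
    singular_any = singular_any,
    singular_strict = singular_strict,
    converged = opt$converged,
    structure = structure, time = time, correction = correction,
    alpha = alpha,
    stats = st, X = X, exch = exch_fit
  ), class = "staircase_fit")
  if (correction == "satterthwaite") {
    cr <- satterthwaite(fit)
    fit$df <- cr$df; fit$ci <- cr$ci; fit$p_value <- cr$p_value
    fit$correction_flag <- cr$flag
  } else if (correction == "kenward_roger") {
    cr <- kenward_roger(fit)
    fit$df <- cr$df; fit$se <- cr$se_adj; fit$ci <- cr$ci
    fit$p_value <- cr$p_value
    fit$correction_flag <- cr$flag
  }
  fit
}

#' @export
print.staircase_fit <- function(x, ...) {
  cat(sprintf("Staircase mixed model (%s, %s time, REML)\n",
              gsub("_", "-", x$structure), x$time))
  cat(sprintf("  theta_hat = %.4f  se = %.4f  %g%% CI (%.4f, %.4f)\n",
              x$theta_hat, x$se, 100 * (1 - x$alpha), x$ci[1], x$ci[2]))
  cat(sprintf("  p = %.4g  correction = %s  df = %s\n",
              x$p_value, x$correction,
              if (is.finite(x$df)) sprintf("%.2f", x$df) else "Inf (normal)"))
  cat(sprintf("  icc_hat = %.4f  cac_hat = %s  tau2 = %.4g  sigma2_eps = %.4g\n",
              x$vc_hat$icc,
              if (is.na(x$vc_hat$cac)) "NA" else sprintf("%.4f", x$vc_hat$cac),
              x$vc_hat$tau2, x$vc_hat$sigma2_eps))
  if (x$singular) cat("  note: singular fit (variance component at boundary)\n")
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  invisible(x)
}

#' Singularity flags for fitted variance components
#'
#' A fit is singular when a random-effect variance is estimated at the zero
#' boundary. For an exchangeable model this means a zero cluster variance.
#' For a block-exchangeable model two conventions are computed: the
#' any-boundary flag (either the cluster variance \code{g1 = tau2 * r} or
#' the cluster-period variance \code{g2 = tau2 * (1 - r)} is zero -- this is
#' the headline flag, and is the one that is high when the fitted CAC hits
#' 1) and a strict flag (both components zero).
#'
#' @param g1 estimated cluster variance.
#' @param g2 estimated cluster-period variance.
#' @param structure analysis correlation structure.
#' @param scale variance scale used for the boundary tolerance
#'   \code{1e-8 * max(1, scale)}.
#' @return A list with logical elements \code{any} and \code{strict}.
#' @export
flag_singular <- function(g1, g2 = 0,
                          structure = c("exchangeable", "block_exchangeable"),
                          scale = 1) {
  structure <- match.arg(structure)
  tol <- 1e-8 * max(1, scale)
  if (structure == "exchangeable") {
    list(any = g1 <= tol, strict = g1 <= tol)
  } else {
    list(any = g1 <= tol || g2 <= tol, strict = g1 <= tol && g2 <= tol)
  }
}
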