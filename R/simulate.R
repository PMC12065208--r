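#' Simulate a repeated cross-sectional staircase trial dataset
#'
#' Generates individual-level continuous outcomes from the linear mixed
#' model \code{Y_skti = beta_t + theta * X_st + CP_skt + eps_skti}, where the
#' two cluster-period random effects \code{(CP_sks, CP_sk,s+1)} of cluster k
#' in sequence s are bivariate normal with variance \code{tau2} and
#' correlation \code{cac}, and the residuals are iid \code{N(0, sigma2_eps)}.
#' The period effect is fixed at \code{beta_t = t}, which is consistent with
#' both the categorical and the linear time parameterisation of the analysis
#' models.
#'
#' @param design a \code{\link{staircase_design}}.
#' @param vc a \code{\link{variance_components}} object giving the generating
#'   ICC, CAC and total variance.
#' @param theta true treatment effect (in outcome-SD units when
#'   \code{sigma2_total = 1}).
#' @param seed optional integer seed; identical seeds reproduce the dataset
#'   bit for bit.
#' @return A data frame of class \code{"staircase_data"} with one row per
#'   participant observation and columns \code{sequence}, \code{cluster},
#'   \code{period}, \code{participant}, \code{treatment}, \code{y}, ordered
#'   by (sequence, cluster, period, participant). The generating design and
#'   parameters are attached as attributes \code{"design"} and
#'   \code{"truth"}.
#' @examples
#' d <- staircase_design(4, 1, 10)
#' dat <- simulate_staircase(d, variance_components(0.05, 0.8), theta = 0.15,
#'                           seed = 1)
#' nrow(dat)  # 80
#' @export
simulate_staircase <- function(design, vc, theta = 0, seed = NULL) {
  stopifnot(inherits(design, "staircase_design"), inherits(vc, "staircase_vc"))
  if (!is.null(seed)) set.seed(seed)
  S <- design$S; K <- design$K; m <- design$m
  nc <- design$n_clusters
  tau <- sqrt(vc$tau2)
  r <- vc$cac
  # bivariate cluster-period effects: cp2 = r*z1 + sqrt(1-r^2)*z2 keeps the
  # construction valid at tau2 = 0 and r = 1 without a Cholesky call
  z1 <- stats::rnorm(nc)
  z2 <- stats::rnorm(nc)
  cp1 <- tau * z1
  cp2 <- tau * (r * z1 + sqrt(1 - r^2) * z2)
  cells <- design$cells
  cp_cell <- ifelse(cells$period == cells$sequence, cp1[cells$cluster], cp2[cells$cluster])
  eps <- stats::rnorm(design$n_obs, sd = sqrt(vc$sigma2_eps))
  idx <- rep(seq_len(design$n_cells), each = m)
  out <- data.frame(
    sequence = cells$sequence[idx],
    cluster = cells$cluster[idx],
    period = cells$period[idx],
    participant = rep(seq_len(m), times = design$n_cells),
    treatment = cells$treatment[idx],
    y = cells$period[idx] + theta * cells$treatment[idx] + cp_cell[idx] + eps
  )
  attr(out, "design") <- design
  attr(out, "truth") <- list(theta = theta, icc = vc$icc, cac = vc$cac,
                             sigma2_total = vc$sigma2_total)
  class(out) <- c("staircase_data", "data.frame")
  out
}

#' Read / write staircase trial data as CSV
#'
#' The on-disk format has one row per participant observation with columns
#' \code{sequence, cluster, period, treatment, y} (a \code{participant}
#' column is accepted and otherwise regenerated). The reader validates the
#' staircase layout: each cluster observed in exactly two consecutive
#' periods with a single control-then-intervention switch. Unbalanced
#' cluster-period sizes are allowed for externally supplied trial extracts.
#'
#' @param data a data frame with the columns above.
#' @param path file path.
#' @return \code{read_staircase_csv} returns a \code{staircase_data} frame;
#'   \code{write_staircase_csv} returns \code{path} invisibly.
#' @export
write_staircase_csv <- function(data, path) {
  cols <- intersect(c("sequence", "cluster", "period", "participant", "treatment", "y"),
                    names(data))
  utils::write.csv(as.data.frame(data)[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_staircase_csv
#' @export
read_staircase_csv <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("sequence", "cluster", "period", "treatment", "y")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"participant" %in% names(dat))
    dat$participant <- stats::ave(dat$y, dat$cluster, dat$period, FUN = seq_along)
  per_cluster <- tapply(dat$period, dat$cluster, function(p) sort(unique(p)))
  ok <- vapply(per_cluster, function(p) length(p) == 2L && diff(p) == 1L, logical(1))
  if (!all(ok))
    stop("not a basic staircase layout: cluster(s) ",
         paste(names(per_cluster)[!ok], collapse = ", "),
         " not observed in exactly 2 consecutive periods")
  dat <- dat[order(dat$sequence, dat$cluster, dat$period, dat$participant), ,
             drop = FALSE]
  rownames(dat) <- NULL
  class(dat) <- c("staircase_data", "data.frame")
  dat
}

#' Enumerate a factorial scenario grid
#'
#' Builds the full Cartesian product of the design and generating factors of
#' a factorial simulation study, in a deterministic order, with a derived
#' seed per scenario. The defaults are the factor levels of the study this
#' package reproduces: S in {4, 10}, K in {1, 5, 10}, m in {10, 50, 100},
#' ICC in {0.01, 0.05, 0.1, 0.2}, CAC in {1, 0.95, 0.8, 0.5} and theta in
#' {0, 0.15} -- 576 scenario configurations.
#'
#' @param S,K,m,icc,cac,theta vectors of factor levels.
#' @param n_reps replicates planned per scenario.
#' @param master_seed integer master seed from which per-scenario seeds are
#'   derived.
#' @return A data frame with one row per scenario: columns \code{scenario}
#'   (index), the six factors, \code{n_reps} and \code{seed}.
#' @export
staircase_grid <- function(S = c(4, 10), K = c(1, 5, 10), m = c(10, 50, 100),
                           icc = c(0.01, 0.05, 0.1, 0.2),
                           cac = c(1, 0.95, 0.8, 0.5),
                           theta = c(0, 0.15),
                           n_reps = 1000, master_seed = 1) {
  g <- expand.grid(theta = theta, cac = cac, icc = icc, m = m, K = K, S = S,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("S", "K", "m", "icc", "cac", "theta")]
  g <- g[order(g$S, g$K, g$m, g$icc, -g$cac, g$theta), , drop = FALSE]
  rownames(g) <- NULL
  g$scenario <- seq_len(nrow(g))
  g$n_reps <- n_reps
  g$seed <- vapply(g$scenario, function(i) derive_seed(master_seed, i), numeric(1))
  g[, c("scenario", "S", "K", "m", "icc", "cac", "theta", "n_reps", "seed")]
}

#' Derive a reproducible substream seed
#'
#' Deterministic integer hash of (master seed, scenario index, replicate
#' index) through a few rounds of a small linear congruential map modulo
#' 2^31 - 1. Multipliers are kept small enough that all intermediate
#' products are exact in double precision, and results fit a 32-bit integer.
#'
#' @param master integer master seed.
#' @param scenario scenario index (>= 1).
#' @param rep replicate index (>= 0).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, scenario = 1, rep = 0) {
  M <- 2147483647
  step <- function(x, k) (x * 1664525 + k + 1013904223) %% M
  x <- step((abs(master) %% M) + 1, 0)
  x <- step(x, scenario %% M)
  x <- step(x, rep %% M)
  as.integer(step(x, 0))
}
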