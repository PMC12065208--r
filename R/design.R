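#' Construct a basic staircase design
#'
#' A basic staircase design is an incomplete stepped wedge layout: each of
#' the \code{S} treatment sequences is measured in exactly two consecutive
#' periods, one control period followed by one intervention period. Sequence
#' \code{s} is measured in global periods \code{s} and \code{s + 1}, so the
#' trial spans \code{S + 1} periods in total and every cluster contributes
#' exactly two cluster-period cells.
#'
#' @param S number of unique treatment sequences (\code{S >= 2}; the
#'   closed-form variance expressions are undefined at \code{S = 1}).
#' @param K number of clusters randomised to each sequence.
#' @param m number of participants measured per cluster-period cell.
#' @return An object of class \code{"staircase_design"}: a list with elements
#'   \code{S}, \code{K}, \code{m}, \code{n_periods} (\code{S + 1}),
#'   \code{n_clusters} (\code{S * K}), \code{n_cells} (\code{2 * S * K}),
#'   \code{n_obs} (\code{2 * S * K * m}) and \code{cells}, a data frame with
#'   one row per cluster-period cell ordered by (sequence, cluster, period)
#'   and columns \code{sequence}, \code{cluster} (global id), \code{period}
#'   and \code{treatment}. Cell (s, t) is under intervention iff
#'   \code{t == s + 1}.
#' @examples
#' d <- staircase_design(S = 4, K = 1, m = 10)
#' d$n_clusters  # 4
#' d$n_periods   # 5
#' @export
staircase_design <- function(S, K = 1, m = 1) {
  S <- as.integer(S); K <- as.integer(K); m <- as.integer(m)
  if (length(S) != 1L || is.na(S) || S < 2L)
    stop("S must be a single integer >= 2 (variance formulas are undefined below S = 2)")
  if (length(K) != 1L || is.na(K) || K < 1L) stop("K must be a single integer >= 1")
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be a single integer >= 1")
  seqs <- rep(seq_len(S), each = 2L * K)
  clus <- rep(seq_len(S * K), each = 2L)
  per <- seqs + rep(c(0L, 1L), times = S * K)
  cells <- data.frame(
    sequence = seqs,
    cluster = clus,
    period = per,
    treatment = as.integer(per == seqs + 1L)
  )
  structure(list(
    S = S, K = K, m = m,
    n_periods = S + 1L,
    n_clusters = S * K,
    n_cells = 2L * S * K,
    n_obs = 2L * S * K * m,
    cells = cells
  ), class = "staircase_design")
}

#' @export
print.staircase_design <- function(x, ...) {
  cat(sprintf(
    "Basic staircase design: S = %d sequences, K = %d cluster(s)/sequence, m = %d/cell\n",
    x$S, x$K, x$m))
  cat(sprintf("  %d clusters, %d periods, %d cluster-period cells, %d observations\n",
              x$n_clusters, x$n_periods, x$n_cells, x$n_obs))
  cat("\n", design_schematic(x), sep = "")
  invisible(x)
}

#' Plain-text schematic of a staircase design
#'
#' One row per sequence, one column per period; "." marks an unmeasured
#' cluster-period, "0" a control cell and "1" an intervention cell.
#'
#' @param design a \code{staircase_design}.
#' @return A single character string (rows separated by newlines).
#' @export
design_schematic <- function(design) {
  stopifnot(inherits(design, "staircase_design"))
  S <- design$S
  mat <- matrix(".", nrow = S, ncol = S + 1L)
  for (s in seq_len(S)) {
    mat[s, s] <- "0"
    mat[s, s + 1L] <- "1"
  }
  paste0(apply(mat, 1L, paste, collapse = " "), "\n", collapse = "")
}

#' Fixed-effects design matrix over cluster-period cells
#'
#' Builds the cell-level fixed-effects matrix for the mean model: period
#' effects plus a single treatment column. Under the categorical time
#' parameterisation each of the \code{S + 1} periods receives its own
#' indicator column (full-rank cell-means coding, no intercept); under the
#' linear parameterisation the period effects are an intercept plus a numeric
#' period column. Rows follow the (sequence, cluster, period) ordering of
#' \code{design$cells}.
#'
#' @param design a \code{staircase_design}.
#' @param time \code{"categorical"} or \code{"linear"} period-effect
#'   parameterisation.
#' @return A numeric matrix with \code{2 * S * K} rows; the last column is
#'   named \code{"treatment"}.
#' @export
fixed_effects_matrix <- function(design, time = c("categorical", "linear")) {
  stopifnot(inherits(design, "staircase_design"))
  time <- match.arg(time)
  cells <- design$cells
  n <- nrow(cells)
  if (time == "categorical") {
    P <- design$n_periods
    X <- matrix(0, nrow = n, ncol = P + 1L)
    X[cbind(seq_len(n), cells$period)] <- 1
    colnames(X) <- c(paste0("period", seq_len(P)), "treatment")
  } else {
    X <- matrix(0, nrow = n, ncol = 3L)
    X[, 1L] <- 1
    X[, 2L] <- cells$period
    colnames(X) <- c("(Intercept)", "period", "treatment")
  }
  X[, ncol(X)] <- cells$treatment
  X
}
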