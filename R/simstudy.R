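#' Specify an analysis model for the simulation engine
#'
#' @param structure intracluster correlation structure to fit.
#' @param time period-effect parameterisation.
#' @param correction requested small-sample correction (subject to the
#'   cluster-count policy, see \code{\link{apply_correction_policy}}).
#' @return A list of class \code{"staircase_fitspec"}.
#' @export
fit_spec <- function(structure = c("exchangeable", "block_exchangeable"),
                     time = c("categorical", "linear"),
                     correction = c("none", "satterthwaite", "kenward_roger")) {
  structure(list(structure = match.arg(structure), time = match.arg(time),
                 correction = match.arg(correction)),
            class = "staircase_fitspec")
}

.fitspec_label <- function(spec) {
  paste(c(exchangeable = "exch", block_exchangeable = "be")[spec$structure],
        c(categorical = "cat", linear = "lin")[spec$time],
        c(none = "none", satterthwaite = "sat", kenward_roger = "kr")[spec$correction],
        sep = "_")
}

#' Classify an analysis model against the generating structure
#'
#' A block-exchangeable fit to exchangeable (CAC = 1) data is
#' over-parameterised rather than misspecified; an exchangeable fit to data
#' with genuine between-period decay (CAC < 1) is misspecified.
#'
#' @param cac_true generating cluster autocorrelation.
#' @param structure fitted correlation structure.
#' @return One of \code{"correct"}, \code{"overparameterised"},
#'   \code{"misspecified"}.
#' @export
classify_fit <- function(cac_true,
                         structure = c("exchangeable", "block_exchangeable")) {
  structure <- match.arg(structure)
  if (cac_true == 1) {
    if (structure == "exchangeable") "correct" else "overparameterised"
  } else {
    if (structure == "exchangeable") "misspecified" else "correct"
  }
}

#' Performance measures with Monte Carlo standard errors
#'
#' Aggregates per-replicate fit records into the standard simulation-study
#' performance measures: bias \code{mean(theta_hat) - theta_true} with MCSE
#' \code{sd(theta_hat)/sqrt(n)}; rejection rate \code{mean(p < alpha)}
#' (Type I error under a null effect, empirical power otherwise) with MCSE
#' \code{sqrt(p_hat (1 - p_hat) / n)}; and coverage of the
#' \code{100 (1 - alpha)}\% confidence interval, with the same binomial MCSE
#' form. Singularity and non-convergence rates are reported alongside; all
#' fits (including singular ones) are retained in every measure.
#'
#' @param records data frame of per-replicate records with columns
#'   \code{theta_hat}, \code{p_value}, \code{ci_lo}, \code{ci_hi},
#'   \code{singular_any}, \code{singular_strict}, \code{converged}.
#' @param theta_true generating treatment effect.
#' @param alpha test size.
#' @return A one-row data frame of measures and their MCSEs.
#' @export
performance_measures <- function(records, theta_true, alpha = 0.05) {
  n <- nrow(records)
  if (n < 1L) stop("no retained replicates")
  bias <- mean(records$theta_hat) - theta_true
  bias_mcse <- if (n > 1L) stats::sd(records$theta_hat) / sqrt(n) else NA_real_
  rej <- mean(records$p_value < alpha)
  cov <- mean(records$ci_lo <= theta_true & theta_true <= records$ci_hi)
  data.frame(
    n_reps = n,
    bias = bias, bias_mcse = bias_mcse,
    reject_rate = rej, reject_mcse = sqrt(rej * (1 - rej) / n),
    coverage = cov, coverage_mcse = sqrt(cov * (1 - cov) / n),
    singular_rate_any = mean(records$singular_any),
    singular_rate_strict = mean(records$singular_strict),
    nonconverged_rate = mean(!records$converged)
  )
}

#' Run one simulation scenario
#'
#' Generates \code{n_reps} trial datasets under the scenario's design and
#' correlation parameters, fits each requested analysis model (applying the
#' cluster-count correction policy), and aggregates the per-replicate
#' results into performance measures. Replicate seeds are derived
#' deterministically from the scenario seed, so identical calls reproduce
#' identical summaries; a replicate whose fit fails outright is recorded as
#' non-converged rather than propagated.
#'
#' @param S,K,m,icc,cac,theta scenario parameters.
#' @param n_reps number of simulation replicates.
#' @param seed scenario seed.
#' @param fits list of \code{\link{fit_spec}} analysis models.
#' @param alpha test size.
#' @param enforce_policy apply \code{\link{apply_correction_policy}} (TRUE,
#'   as in the simulation design) or honour the requested correction always.
#' @param keep_records also return the per-replicate records.
#' @return A data frame with one row per analysis model: scenario keys, fit
#'   keys, performance measures with MCSEs, and the scenario's theoretical
#'   variance and power (normal-based, matched to the fitted time
#'   parameterisation). With \code{keep_records = TRUE}, a list with
#'   elements \code{summary} and \code{records}.
#' @export
run_scenario <- function(S, K, m, icc, cac, theta, n_reps = 1000, seed = 1,
                         fits = list(fit_spec("exchangeable", "categorical"),
                                     fit_spec("block_exchangeable", "categorical")),
                         alpha = 0.05, enforce_policy = TRUE,
                         keep_records = FALSE) {
  design <- staircase_design(S, K, m)
  vc <- variance_components(icc, cac)
  labels <- vapply(fits, .fitspec_label, character(1))
  recs <- vector("list", length(fits))
  names(recs) <- labels
  for (l in labels) recs[[l]] <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    dat <- simulate_staircase(design, vc, theta,
                              seed = derive_seed(seed, 1, rep_i))
    st <- sufficient_stats(dat)
    for (fi in seq_along(fits)) {
      spec <- fits[[fi]]
      eff_corr <- if (enforce_policy)
        apply_correction_policy(design$n_clusters, spec$correction)
      else spec$correction
      rec <- tryCatch({
        f <- fit_staircase(st, spec$structure, spec$time, eff_corr, alpha)
        data.frame(rep = rep_i, theta_hat = f$theta_hat, se = f$se,
                   df = f$df, p_value = f$p_value,
                   ci_lo = f$ci[1], ci_hi = f$ci[2],
                   icc_hat = f$vc_hat$icc,
                   cac_hat = if (is.na(f$vc_hat$cac)) NA_real_ else f$vc_hat$cac,
                   singular_any = f$singular_any,
                   singular_strict = f$singular_strict,
                   converged = f$converged)
      }, error = function(e) {
        data.frame(rep = rep_i, theta_hat = NA_real_, se = NA_real_,
                   df = NA_real_, p_value = NA_real_, ci_lo = NA_real_,
                   ci_hi = NA_real_, icc_hat = NA_real_, cac_hat = NA_real_,
                   singular_any = NA, singular_strict = NA, converged = FALSE)
      })
      recs[[labels[fi]]][[rep_i]] <- rec
    }
  }
  out <- vector("list", length(fits))
  for (fi in seq_along(fits)) {
    spec <- fits[[fi]]
    r <- do.call(rbind, recs[[labels[fi]]])
    ok <- !is.na(r$theta_hat)
    pm <- performance_measures(r[ok, , drop = FALSE], theta, alpha)
    pm$nonconverged_rate <- mean(!r$converged)
    theory_var <- if (spec$time == "categorical")
      var_theta_categorical(S, K, m, icc, cac)
    else var_theta_linear(S, K, m, icc, cac)
    out[[fi]] <- cbind(
      data.frame(S = S, K = K, m = m, icc = icc, cac = cac, theta = theta,
                 structure = spec$structure, time = spec$time,
                 correction = if (enforce_policy)
                   apply_correction_policy(S * K, spec$correction)
                 else spec$correction,
                 classification = classify_fit(cac, spec$structure)),
      pm,
      data.frame(theory_var = theory_var,
                 theory_power = theoretical_power(theory_var, theta_d = theta,
                                                  alpha = alpha))
    )
  }
  summary <- do.call(rbind, out)
  rownames(summary) <- NULL
  if (keep_records) {
    list(summary = summary,
         records = do.call(rbind, lapply(labels, function(l) {
           cbind(data.frame(fit = l), do.call(rbind, recs[[l]]))
         })))
  } else summary
}

#' Run a factorial scenario grid
#'
#' Iterates \code{\link{run_scenario}} over the rows of a scenario grid
#' (see \code{\link{staircase_grid}}), producing one summary row per
#' scenario and analysis model, in a stable column order. Per-scenario seeds
#' come from the grid, so the run is deterministic given the master seed and
#' resumable scenario by scenario.
#'
#' @param grid a data frame as returned by \code{\link{staircase_grid}}.
#' @param fits list of \code{\link{fit_spec}} analysis models.
#' @param n_reps replicates per scenario (overrides the grid's
#'   \code{n_reps} when non-NULL).
#' @param alpha test size.
#' @param out optional path; the results table is written there as CSV.
#' @param verbose print progress.
#' @return The combined results data frame (invisibly written to \code{out}
#'   when given).
#' @export
run_grid <- function(grid, fits = list(fit_spec("exchangeable", "categorical"),
                                       fit_spec("block_exchangeable", "categorical")),
                     n_reps = NULL, alpha = 0.05, out = NULL, verbose = FALSE) {
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    reps <- if (is.null(n_reps)) g$n_reps else n_reps
    if (verbose)
      message(sprintf("scenario %d/%d: S=%g K=%g m=%g icc=%g cac=%g theta=%g",
                      i, nrow(grid), g$S, g$K, g$m, g$icc, g$cac, g$theta))
    res[[i]] <- cbind(data.frame(scenario = g$scenario),
                      run_scenario(g$S, g$K, g$m, g$icc, g$cac, g$theta,
                                   n_reps = reps, seed = g$seed, fits = fits,
                                   alpha = alpha))
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
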