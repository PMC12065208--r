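test_that("sufficient statistics collapse the data losslessly", {
  dat <- small_dataset(S = 3, K = 1, m = 4)
  st <- sufficient_stats(dat)
  expect_equal(st$n_cells, 6L)
  expect_equal(st$dfw, 6L * 3L)
  expect_equal(st$m, 4L)
  # a constant cell contributes nothing to the within sum of squares
  dat2 <- as.data.frame(dat)
  dat2$y[dat2$cluster == 1 & dat2$period == 1] <- 7
  st2 <- sufficient_stats(dat2)
  dat3 <- dat2[!(dat2$cluster == 1 & dat2$period == 1), ]
  expect_equal(st2$SSw, sum(tapply(dat3$y, paste(dat3$cluster, dat3$period),
                                   function(v) sum((v - mean(v))^2))))
  # m = 1 collapses to zero within-cell information
  st1 <- sufficient_stats(small_dataset(S = 2, K = 1, m = 1))
  expect_equal(st1$SSw, 0)
  expect_equal(st1$dfw, 0L)
  # missing cells are reported
  broken <- as.data.frame(dat)[-(1:4), ]  # removes cluster 1, period 1
  expect_error(sufficient_stats(broken), "cluster")
})

test_that("restricted likelihood is translation invariant and matches the dense form", {
  dat <- small_dataset(S = 2, K = 1, m = 2, seed = 77)
  st <- sufficient_stats(dat)
  shifted <- as.data.frame(dat); shifted$y <- shifted$y + 5
  st_sh <- sufficient_stats(shifted)
  dense <- staircasesim:::.make_dense_nll(dat, "categorical")
  pars <- list(c(0.2, 0.9, 0.5), c(0.05, 0.5, 1), c(0.4, 1.3, 0))
  offs <- vapply(pars, function(p) {
    ll <- reml_loglik(p[1], p[2], p[3], st)
    expect_equal(ll, reml_loglik(p[1], p[2], p[3], st_sh), tolerance = 1e-8)
    ll + dense(c(log(p[2]), p[1] * p[3], p[1] * (1 - p[3])))
  }, numeric(1))
  # collapsed and dense restricted log-likelihoods differ by a constant
  expect_lt(diff(range(offs)), 1e-7)
})

test_that("collapsed and dense REML fits agree on random small datasets", {
  set.seed(1234)
  for (i in 1:6) {
    dat <- simulate_staircase(
      staircase_design(sample(2:3, 1), sample(1:2, 1), sample(2:4, 1)),
      variance_components(runif(1, 0.05, 0.3), runif(1, 0.3, 1)),
      theta = 0.1, seed = 5000 + i)
    for (str in c("exchangeable", "block_exchangeable")) {
      f1 <- fit_staircase(dat, str, "categorical")
      f2 <- fit_staircase(dat, str, "categorical", method = "dense")
      expect_equal(f1$theta_hat, f2$theta_hat, tolerance = 1e-6)
      expect_equal(f1$se, f2$se, tolerance = 1e-6)
      expect_equal(f1$vc_hat$tau2, f2$vc_hat$tau2, tolerance = 1e-5)
      expect_equal(f1$vc_hat$sigma2_eps, f2$vc_hat$sigma2_eps, tolerance = 1e-5)
    }
  }
})

test_that("REML fit matches lme4 on a well-conditioned dataset", {
  skip_if_not_installed("lme4")
  dat <- small_dataset(S = 4, K = 5, m = 20, icc = 0.1, cac = 0.8, seed = 7)
  f <- fit_staircase(dat, "block_exchangeable", "categorical")
  df <- as.data.frame(dat)
  df$cp <- interaction(df$cluster, df$period)
  lf <- lme4::lmer(y ~ 0 + factor(period) + treatment + (1 | cluster) + (1 | cp),
                   data = df, REML = TRUE)
  expect_equal(f$theta_hat, unname(lme4::fixef(lf)["treatment"]),
               tolerance = 1e-5)
  expect_equal(f$se, unname(coef(summary(lf))["treatment", "Std. Error"]),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$vc_hat$g1, vc$vcov[vc$grp == "cluster"], tolerance = 1e-3)
  expect_equal(f$vc_hat$g2, vc$vcov[vc$grp == "cp"], tolerance = 1e-2)
})

test_that("block-exchangeable fit nests the exchangeable fit", {
  dat <- small_dataset(S = 4, K = 2, m = 8, icc = 0.15, cac = 1, seed = 11)
  fe <- fit_staircase(dat, "exchangeable", "categorical")
  fb <- fit_staircase(dat, "block_exchangeable", "categorical")
  expect_gte(fb$reml_loglik, fe$reml_loglik - 1e-6)
  # pinning the BE likelihood at cac = 1 recovers the exchangeable value
  st <- sufficient_stats(dat)
  expect_equal(reml_loglik(fe$vc_hat$tau2, fe$vc_hat$sigma2_eps, 1, st),
               fe$reml_loglik, tolerance = 1e-8)
})

test_that("zero cluster variance reduces GLS to OLS on cell means", {
  # constructed dataset with no cluster structure at all
  dat <- simulate_staircase(staircase_design(4, 3, 6),
                            variance_components(0, 1), 0, seed = 21)
  f <- fit_staircase(dat, "exchangeable", "categorical")
  if (f$vc_hat$tau2 <= 1e-8) {
    st <- sufficient_stats(dat)
    X <- staircasesim:::.cell_model_matrix(st$cells, "categorical")
    ols <- lm.fit(X, st$ybar)
    expect_equal(f$theta_hat, unname(ols$coefficients["treatment"]),
                 tolerance = 1e-6)
    expect_true(f$singular)
  } else skip("interior optimum on this draw")
})

test_that("plug-in identity: squared se at the estimates equals the closed form", {
  dat <- small_dataset(S = 4, K = 5, m = 20, seed = 31)
  for (tm in c("categorical", "linear")) {
    f <- fit_staircase(dat, "block_exchangeable", tm)
    v <- f$vc_hat
    sig_tot <- v$tau2 + v$sigma2_eps
    vtheo <- if (tm == "categorical")
      var_theta_categorical(4, 5, 20, v$icc, v$cac, sig_tot)
    else var_theta_linear(4, 5, 20, v$icc, v$cac, sig_tot)
    expect_equal(f$se^2, vtheo, tolerance = 1e-8)
  }
})

test_that("treatment effect estimation is unbiased over replicates", {
  d <- staircase_design(4, 3, 10)
  vc <- variance_components(0.1, 0.8)
  set.seed(515)
  th <- replicate(60, {
    fit_staircase(simulate_staircase(d, vc, 0),
                  "block_exchangeable", "categorical")$theta_hat
  })
  # crude check is fine: mean within 3 MC SEs of zero
  expect_lt(abs(mean(th)), 3 * sd(th) / sqrt(length(th)))
})

test_that("singularity flags follow the structure-specific definitions", {
  expect_true(flag_singular(0, 0.2, "exchangeable")$any)
  expect_false(flag_singular(0.01, 0, "exchangeable")$any)
  be <- flag_singular(0.01, 0, "block_exchangeable")   # fitted cac = 1
  expect_true(be$any); expect_false(be$strict)
  be2 <- flag_singular(0, 0, "block_exchangeable")
  expect_true(be2$any); expect_true(be2$strict)
  expect_false(flag_singular(0.01, 0.01, "block_exchangeable")$any)
})

test_that("m = 1 block-exchangeable fits warn and stay finite", {
  dat <- small_dataset(S = 3, K = 2, m = 1, seed = 13)
  expect_warning(f <- fit_staircase(dat, "block_exchangeable", "categorical"),
                 "not identifiable")
  expect_true(is.finite(f$theta_hat) && is.finite(f$se))
})
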