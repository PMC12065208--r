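test_that("Satterthwaite df matches the lmerTest oracle", {
  skip_if_not_installed("lmerTest")
  for (seed in c(7, 19)) {
    dat <- small_dataset(S = 4, K = 5, m = 20, icc = 0.1, cac = 0.8,
                         seed = seed)
    f <- fit_staircase(dat, "block_exchangeable", "categorical")
    sw <- satterthwaite(f)
    df <- as.data.frame(dat)
    df$cp <- interaction(df$cluster, df$period)
    lt <- lmerTest::lmer(y ~ 0 + factor(period) + treatment + (1 | cluster) +
                           (1 | cp), data = df, REML = TRUE)
    co <- coef(summary(lt))["treatment", ]
    expect_equal(sw$df, unname(co["df"]), tolerance = 0.01)
    expect_equal(sw$p_value, unname(co["Pr(>|t|)"]), tolerance = 0.01)
  }
})

test_that("Satterthwaite df grows with the number of clusters", {
  dfs <- sapply(c(1, 5, 10), function(K) {
    dat <- small_dataset(S = 4, K = K, m = 10, icc = 0.1, cac = 1, seed = 40 + K)
    satterthwaite(fit_staircase(dat, "exchangeable", "categorical"))$df
  })
  expect_true(all(diff(dfs) > 0))
})

test_that("Satterthwaite interval contains the normal interval and shrinks to it", {
  dat <- small_dataset(S = 4, K = 2, m = 10, seed = 51)
  f <- fit_staircase(dat, "block_exchangeable", "categorical")
  sw <- satterthwaite(f)
  expect_lte(sw$ci[1], f$ci[1])
  expect_gte(sw$ci[2], f$ci[2])
  # many clusters: t-based and normal inference coincide
  big <- small_dataset(S = 10, K = 10, m = 10, icc = 0.1, cac = 1, seed = 52)
  fb <- fit_staircase(big, "exchangeable", "categorical")
  swb <- satterthwaite(fb)
  expect_gt(swb$df, 50)
  expect_equal(swb$ci, fb$ci, tolerance = 1e-3)
})

test_that("Kenward-Roger adjustment inflates the standard error", {
  set.seed(61)
  for (i in 1:6) {
    dat <- simulate_staircase(staircase_design(4, sample(1:3, 1), 10),
                              variance_components(runif(1, 0.02, 0.2),
                                                  runif(1, 0.5, 1)), 0)
    for (str in c("exchangeable", "block_exchangeable")) {
      f <- fit_staircase(dat, str, "categorical")
      kr <- kenward_roger(f)
      expect_gte(kr$se_adj, f$se - 1e-12)
      expect_true(is.finite(kr$df) || kr$df == Inf)
    }
  }
})

test_that("Kenward-Roger and Satterthwaite df agree asymptotically", {
  dat <- small_dataset(S = 10, K = 10, m = 20, icc = 0.1, cac = 0.8, seed = 71)
  f <- fit_staircase(dat, "block_exchangeable", "categorical")
  sw <- satterthwaite(f); kr <- kenward_roger(f)
  expect_lt(abs(kr$df - sw$df) / sw$df, 0.05)
})

test_that("KR df can collapse below 1 for overparameterised tiny designs", {
  # exchangeable truth, BE fit, 4 clusters: the between-period decay is
  # unidentified and the KR df degenerates, blowing up the interval
  set.seed(81)
  dfs <- replicate(8, {
    dat <- simulate_staircase(staircase_design(4, 1, 100),
                              variance_components(0.05, 1), 0)
    kenward_roger(fit_staircase(dat, "block_exchangeable", "categorical"))$df
  })
  expect_true(any(dfs < 1))
})

test_that("p-values are equivariant under sign flip of the treatment effect", {
  dat <- small_dataset(S = 4, K = 2, m = 10, seed = 91)
  f <- fit_staircase(dat, "block_exchangeable", "categorical")
  flipped <- as.data.frame(dat)
  # reflecting outcomes about the period means flips theta_hat
  flipped$y <- 2 * ave(flipped$y, flipped$period) - flipped$y
  ff <- fit_staircase(flipped, "block_exchangeable", "categorical")
  expect_equal(ff$theta_hat, -f$theta_hat, tolerance = 1e-6)
  expect_equal(satterthwaite(ff)$p_value, satterthwaite(f)$p_value,
               tolerance = 1e-4)
})

test_that("correction policy suppresses corrections above 50 clusters", {
  expect_equal(apply_correction_policy(100, "satterthwaite"), "none")
  expect_equal(apply_correction_policy(100, "kenward_roger"), "none")
  expect_equal(apply_correction_policy(50, "satterthwaite"), "satterthwaite")
  expect_equal(apply_correction_policy(4, "kenward_roger"), "kenward_roger")
  expect_equal(apply_correction_policy(4, "none"), "none")
})

test_that("corrections return finite results on singular fits", {
  # icc = 0 truth drives the cluster variance to the boundary often
  set.seed(95)
  found <- FALSE
  for (i in 1:10) {
    dat <- simulate_staircase(staircase_design(4, 1, 10),
                              variance_components(0.005, 0.5), 0)
    f <- fit_staircase(dat, "block_exchangeable", "categorical")
    if (f$singular_any) {
      found <- TRUE
      sw <- satterthwaite(f); kr <- kenward_roger(f)
      expect_true(is.finite(sw$p_value))
      expect_true(is.finite(kr$p_value))
      expect_true(sw$df > 0)
    }
  }
  expect_true(found)
})
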