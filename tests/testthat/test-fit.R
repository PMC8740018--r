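test_that("substitution start point uses mean and n-denominator SD", {
  d <- enum_quantitative(c(10, 1000), loq = 10)
  expect_equal(init_params(d), c(mu = 2, sigma = 1))
  # degenerate spread is floored
  d2 <- enum_quantitative(c(100, 100, 100), loq = 10)
  expect_equal(init_params(d2)[["sigma"]], 0.05)
  # censored values enter at log10(loq/2), intervals at their log midpoint
  d3 <- case_datasets()$case3
  ip <- init_params(d3)
  expect_true(all(is.finite(ip)) && ip[["sigma"]] > 0)
  v <- c(rep(log10(5), 16), rep(1.5, 19), rep(2.5, 34), rep(3.5, 22),
         rep(4.5, 8), 5.5)
  expect_equal(ip[["mu"]], mean(v), tolerance = 1e-12)
  expect_equal(ip[["sigma"]], sqrt(mean((v - mean(v))^2)),
               tolerance = 1e-12)
})

test_that("censoring-free MLE equals the closed-form mean and SD", {
  d <- enum_quantitative(c(10, 1000), loq = 10)
  f <- fit_enum(d)
  expect_equal(f$mu, 2, tolerance = 1e-6)
  expect_equal(f$sigma, 1, tolerance = 1e-6)

  d2 <- enum_quantitative(c(10, 100, 1000), loq = 10)
  s2 <- summarize_uncensored(d2)
  expect_equal(s2$mu, 2)
  expect_equal(s2$sigma, sqrt(2 / 3), tolerance = 1e-9)
  f2 <- fit_enum(d2)
  expect_equal(f2$mu, s2$mu, tolerance = 1e-6)
  expect_equal(f2$sigma, s2$sigma, tolerance = 1e-6)

  # a larger random uncensored set
  y <- with_seed_val(7, rnorm(60, 2.5, 0.8))
  d3 <- enum_quantitative(10^pmax(y, 1.01), loq = 10)
  f3 <- fit_enum(d3)
  v <- d3$observations$value
  expect_equal(f3$mu, mean(v), tolerance = 1e-6)
  expect_equal(f3$sigma, sqrt(mean((v - mean(v))^2)), tolerance = 1e-6)
})

test_that("identical observations give a degenerate-SD warning", {
  d <- enum_quantitative(c(100, 100, 100), loq = 10)
  expect_warning(s <- summarize_uncensored(d), "degenerate")
  expect_equal(s$mu, 2)
  expect_equal(s$sigma, 0)
})

test_that("Wald standard errors match the normal-theory closed forms", {
  y <- with_seed_val(21, rnorm(50, 2, 0.9))
  d <- enum_quantitative(10^pmax(y, 1.01), loq = 10)
  f <- fit_enum(d)
  n <- 50
  expect_equal(f$se_mu, f$sigma / sqrt(n), tolerance = 0.02)
  expect_equal(f$se_sigma, f$sigma / sqrt(2 * n), tolerance = 0.05)
  # intervals bracket the estimates
  expect_true(f$ci_mu[1] < f$mu && f$mu < f$ci_mu[2])
  expect_true(f$ci_sigma[1] < f$sigma && f$sigma < f$ci_sigma[2])
})

test_that("interval-only data route through the iterative fit", {
  d <- enum_intervals(c(10, 100, 1000), c(100, 1000, 10000), c(8, 11, 3),
                      loq = 10)
  expect_equal(d$mode, "QN_2")
  s <- summarize_uncensored(d)
  f <- fit_enum(d)
  expect_equal(s$mu, f$mu, tolerance = 1e-8)
  expect_equal(s$sigma, f$sigma, tolerance = 1e-8)
})

test_that("interval-censored fits agree with fitdistrplus::fitdistcens", {
  skip_if_not_installed("fitdistrplus")
  d <- case_datasets()$case3
  f <- fit_enum(d, convention = "interval")
  o <- d$observations
  cens <- data.frame(
    left = ifelse(o$kind == "left_censored", NA, o$lower),
    right = o$upper)
  cens <- cens[rep(seq_len(nrow(o)), o$weight), ]
  ref <- fitdistrplus::fitdistcens(cens, "norm")
  expect_equal(f$mu, unname(ref$estimate["mean"]), tolerance = 1e-4)
  expect_equal(f$sigma, unname(ref$estimate["sd"]), tolerance = 1e-4)
  expect_equal(f$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("the optimiser matches an exhaustive grid search", {
  for (seed in c(101, 202, 303)) {
    d <- random_small_dataset(seed)
    f <- fit_enum(d)
    g <- grid_mle(d)
    expect_lt(abs(f$mu - g[["mu"]]), 0.02)
    expect_lt(abs(f$sigma - g[["sigma"]]), 0.02)
    expect_gte(f$loglik, g[["loglik"]] - 1e-6)
  }
})

test_that("appending an ND observation never increases the fitted mean", {
  for (seed in c(5, 17)) {
    d <- random_small_dataset(seed)
    f0 <- fit_enum(d)
    o <- d$observations
    lc <- o$kind == "left_censored"
    if (any(lc)) {
      o$weight[lc] <- o$weight[lc] + 1L
    } else {
      o <- rbind(o, data.frame(kind = "left_censored", value = NA_real_,
                               lower = NA_real_, upper = log10(d$loq),
                               lin_value = NA_real_, lin_lower = NA_real_,
                               lin_upper = d$loq, weight = 1L))
    }
    d1 <- d
    d1$observations <- o
    f1 <- fit_enum(d1)
    expect_lte(f1$mu, f0$mu + 1e-8)
  }
})

test_that("fully censored data raise an identifiability error", {
  d <- simulate_enum(-4, 0.5, 10, loq = 10, seed = 2)
  expect_equal(m_censored(d), 10)
  expect_error(fit_enum(d), "100% ND")
  expect_error(init_params(d), "fully censored")
})

test_that("fit diagnostics satisfy their structural invariants", {
  f <- fit_enum(case_datasets()$case1)
  expect_true(f$converged)
  expect_gte(f$loglik, f$loglik_start)
  expect_equal(f$p05, f$mu - qnorm(0.95) * f$sigma, tolerance = 1e-9)
  expect_equal(f$p95, f$mu + qnorm(0.95) * f$sigma, tolerance = 1e-9)
  expect_equal(unname(coef(f)), c(f$mu, f$sigma))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  ci <- confint(f)
  expect_equal(unname(ci["mu", ]), f$ci_mu)
  # vcov diagonal reproduces the squared standard errors
  V <- vcov(f)
  expect_equal(sqrt(V["mu", "mu"]), f$se_mu, tolerance = 1e-6)
  # quantile predictions invert the cdf
  q <- predict(f, at = c(0.05, 0.95), type = "quantile")
  expect_equal(q, c(f$p05, f$p95), tolerance = 1e-9)
  expect_equal(predict(f, at = q[1], type = "cdf"), 0.05,
               tolerance = 1e-9)
})
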