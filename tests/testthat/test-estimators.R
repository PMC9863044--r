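test_that("Wald ratio matches direct arithmetic", {
  est <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_equal(est$pvalue, 2 * pnorm(-2.5))
  # zero outcome effect: null estimate, p = 1
  est0 <- wald_ratio(0.1, 0.01, 0, 0.02)
  expect_equal(est0$beta, 0)
  expect_equal(est0$pvalue, 1)
  # sign equivariance in the exposure
  expect_equal(wald_ratio(-0.1, 0.01, 0.05, 0.02)$beta, -0.5)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "beta_exp = 0")
})

test_that("IVW with a single SNP reduces exactly to the Wald ratio", {
  h <- harmonized_data("rs1", 0.12, 0.01, 0.03, 0.015)
  ivw <- mr_ivw(h, "fixed")
  wald <- wald_ratio(0.12, 0.01, 0.03, 0.015)
  expect_equal(ivw$beta, wald$beta, tolerance = 1e-14)
  expect_equal(ivw$se, wald$se, tolerance = 1e-14)
  expect_equal(ivw$pvalue, wald$pvalue, tolerance = 1e-12)
  expect_equal(mr_ivw(h, "random")$se, wald$se)  # K = 1: no inflation possible
})

test_that("identical ratios collapse all estimators onto the common ratio", {
  h <- make_harm(rep(0.4, 6), beta_exp = c(0.1, 0.2, 0.15, 0.3, 0.12, 0.25))
  expect_equal(mr_ivw(h, "fixed")$beta, 0.4)
  expect_equal(mr_ivw(h, "random")$beta, 0.4)
  expect_equal(mr_ivw(h, "fixed")$q, 0)
  expect_equal(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se)
  eg <- mr_egger(h)
  expect_equal(eg$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.4)
  expect_equal(mr_weighted_mode(h, n_boot = 50, seed = 1)$beta, 0.4)
})

test_that("IVW equals the zero-intercept WLS solution from lm", {
  for (seed in 1:20) {
    h <- random_harm(10, seed)
    fit <- lm(h$beta_out ~ 0 + h$beta_exp, weights = 1 / h$se_out^2)
    expect_equal(mr_ivw(h, "fixed")$beta, unname(coef(fit)[1]),
                 tolerance = 1e-10)
    # and the closed-form inverse-variance-weighted mean of Wald ratios
    r <- h$beta_out / h$beta_exp
    w <- h$beta_exp^2 / h$se_out^2
    expect_equal(mr_ivw(h, "fixed")$beta, sum(w * r) / sum(w),
                 tolerance = 1e-10)
  }
})

test_that("MR-Egger matches an independent weighted regression with intercept", {
  h <- random_harm(15, 77)
  s <- ifelse(h$beta_exp < 0, -1, 1)
  fit <- lm(I(h$beta_out * s) ~ I(abs(h$beta_exp)), weights = 1 / h$se_out^2)
  eg <- mr_egger(h)
  expect_equal(eg$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # overdispersion scale: SEs at least the unit-variance WLS values
  sm <- summary(fit)
  unit_se <- sm$coefficients[, "Std. Error"] / sm$sigma
  expect_gte(eg$se, unname(unit_se[2]) - 1e-12)
})

test_that("Egger slope tracks IVW and its intercept is null without pleiotropy", {
  st <- simulate_two_sample(sim_config(n_instruments = 80, n_null_snps = 0,
                                       theta = 0.15, palindrome_fraction = 0,
                                       seed = 55))
  h <- harm_from_study(st)
  eg <- mr_egger(h)
  ivw <- mr_ivw(h)
  expect_lt(abs(eg$beta - ivw$beta), 3 * eg$se)
  expect_lt(abs(eg$intercept), 3 * eg$intercept_se)
})

test_that("constant oriented pleiotropy shifts the Egger intercept, not the slope", {
  reps <- lapply(1:25, function(i) {
    st <- simulate_two_sample(sim_config(
      n_instruments = 80, n_null_snps = 0, theta = 0.1, invalid_fraction = 1,
      mu_alpha = 0.04, sigma_alpha = 0, palindrome_fraction = 0,
      seed = 6000 + i))
    mr_egger(harm_from_study(st))
  })
  ints <- vapply(reps, `[[`, numeric(1), "intercept")
  slopes <- vapply(reps, `[[`, numeric(1), "beta")
  expect_lt(abs(mean(ints) - 0.04), 3 * sd(ints) / sqrt(25) + 0.002)
  expect_lt(abs(mean(slopes) - 0.1), 3 * sd(slopes) / sqrt(25) + 0.01)
})

test_that("weighted median interpolates the 50% weight point", {
  h <- make_harm(c(1, 2, 9))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 2)
  # boundedness on random data
  for (seed in 1:10) {
    h <- random_harm(8, 100 + seed)
    r <- h$beta_out / h$beta_exp
    est <- mr_weighted_median(h, n_boot = 20, seed = seed)$beta
    expect_gte(est, min(r))
    expect_lte(est, max(r))
  }
})

test_that("weighted mode finds the dominant cluster of a bimodal ratio set", {
  withr::local_seed(9)
  ratios <- c(rnorm(10, 0.2, 0.01), rnorm(3, 0.8, 0.01))
  h <- make_harm(ratios)
  est <- mr_weighted_mode(h, n_boot = 50, seed = 2)$beta
  expect_lt(abs(est - 0.2), 0.05)
  expect_gte(est, min(ratios))
  expect_lte(est, max(ratios))
})

test_that("estimators are scale- and sign-equivariant in the outcome", {
  h <- random_harm(12, 31)
  c_scale <- 2.5
  h_sc <- harmonized_data(h$snp, h$beta_exp, h$se_exp,
                          c_scale * h$beta_out, c_scale * h$se_out)
  h_neg <- harmonized_data(h$snp, h$beta_exp, h$se_exp,
                           -h$beta_out, h$se_out)
  for (fn in list(function(d) mr_ivw(d, "fixed"),
                  function(d) mr_ivw(d, "random"),
                  mr_egger)) {
    e <- fn(h); e_sc <- fn(h_sc); e_neg <- fn(h_neg)
    expect_equal(e_sc$beta, c_scale * e$beta, tolerance = 1e-10)
    expect_equal(e_sc$se, c_scale * e$se, tolerance = 1e-10)
    expect_equal(e_sc$pvalue, e$pvalue, tolerance = 1e-10)
    expect_equal(e_neg$beta, -e$beta, tolerance = 1e-10)
    expect_equal(e_neg$pvalue, e$pvalue, tolerance = 1e-10)
  }
  # median/mode point estimates (bootstrap SEs are stochastic)
  wm <- mr_weighted_median(h, n_boot = 10, seed = 3)$beta
  wm_sc <- mr_weighted_median(h_sc, n_boot = 10, seed = 3)$beta
  expect_equal(wm_sc, c_scale * wm, tolerance = 1e-10)
  md <- mr_weighted_mode(h, n_boot = 10, seed = 3)$beta
  md_sc <- mr_weighted_mode(h_sc, n_boot = 10, seed = 3)$beta
  expect_equal(md_sc, c_scale * md, tolerance = 1e-6)
})

test_that("with no pleiotropy the four estimators agree within 3 SEs", {
  st <- simulate_two_sample(sim_config(n_instruments = 50, n_null_snps = 0,
                                       theta = 0.2, palindrome_fraction = 0,
                                       seed = 321))
  h <- harm_from_study(st)
  ests <- list(mr_ivw(h), mr_egger(h),
               mr_weighted_median(h, n_boot = 200, seed = 4),
               mr_weighted_mode(h, n_boot = 200, seed = 5))
  betas <- vapply(ests, `[[`, numeric(1), "beta")
  ses <- vapply(ests, `[[`, numeric(1), "se")
  for (i in 2:4) {
    expect_lt(abs(betas[i] - betas[1]), 3 * max(ses[i], ses[1]))
  }
})

test_that("binary outcomes get a consistent odds-ratio scale", {
  h <- random_harm(6, 8)
  est <- mr_ivw(h, binary = TRUE)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
  expect_equal(est$or_ci_high, exp(est$ci_high))
})

test_that("minimum instrument counts are enforced", {
  h2 <- make_harm(c(0.1, 0.2))
  expect_error(mr_egger(h2), "at least 3")
  expect_error(mr_weighted_median(h2), "at least 3")
  expect_error(mr_weighted_mode(h2), "at least 3")
  expect_error(mr_ivw(make_harm(numeric(0))), "at least one")
})
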