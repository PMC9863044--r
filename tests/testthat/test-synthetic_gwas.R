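test_that("same config and seed give identical studies", {
  cfg <- sim_config(n_instruments = 20, n_null_snps = 30, theta = 0.1, seed = 99)
  s1 <- simulate_two_sample(cfg)
  s2 <- simulate_two_sample(cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  expect_identical(s1$truth, s2$truth)
})

test_that("exposure and outcome tables share the SNP set and truth covers it", {
  st <- simulate_two_sample(sim_config(n_instruments = 15, n_null_snps = 25, seed = 3))
  expect_identical(st$exposure$snp, st$outcome$snp)
  expect_setequal(st$truth$snp, st$exposure$snp)
  expect_equal(sum(st$truth$is_instrument), 15L)
  # standard errors follow the allele-frequency/sample-size formula
  maf <- pmin(st$exposure$eaf, 1 - st$exposure$eaf)
  expect_equal(st$exposure$se, 1 / sqrt(2 * maf * (1 - maf) * 18340))
})

test_that("sigma_gamma = 0 is a null model: locus-wide hits at the nominal rate", {
  st <- simulate_two_sample(sim_config(n_instruments = 200, n_null_snps = 800,
                                       sigma_gamma = 0, seed = 17))
  expect_true(all(st$truth$gamma == 0))
  # binomial(1000, 1e-5): seeing even 1 hit has probability ~1%
  expect_lte(sum(st$exposure$p < 1e-5), 1L)
})

test_that("null-SNP p-values are uniform (KS test on 10,000 draws)", {
  st <- simulate_two_sample(sim_config(n_instruments = 0, n_null_snps = 10000,
                                       seed = 23))
  ks <- suppressWarnings(ks.test(st$exposure$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  ks_out <- suppressWarnings(ks.test(st$outcome$p, "punif"))
  expect_gt(ks_out$p.value, 0.01)
})

test_that("palindrome fraction controls A/T-C/G allele pairs", {
  st0 <- simulate_two_sample(sim_config(n_instruments = 0, n_null_snps = 500,
                                        palindrome_fraction = 0, seed = 5))
  expect_false(any(is_palindromic(st0$exposure$ea, st0$exposure$oa)))
  st1 <- simulate_two_sample(sim_config(n_instruments = 0, n_null_snps = 500,
                                        palindrome_fraction = 1, seed = 5))
  expect_true(all(is_palindromic(st1$exposure$ea, st1$exposure$oa)))
})

test_that("LD blocks enumerate within-block pairs at the configured r2", {
  st <- simulate_two_sample(sim_config(n_instruments = 0, n_null_snps = 12,
                                       ld_block_size = 4, ld_within_r2 = 0.8,
                                       seed = 2))
  snp <- st$exposure$snp
  expect_equal(ld_r2(st$ld, snp[1], snp[2]), 0.8)
  expect_equal(ld_r2(st$ld, snp[1], snp[4]), 0.8)
  expect_equal(ld_r2(st$ld, snp[1], snp[5]), 0)   # across blocks
  # within-block SNPs sit within the clumping window, distinct blocks outside
  expect_lt(abs(st$exposure$pos[1] - st$exposure$pos[4]), 1e7)
})

test_that("degenerate and invalid configs are rejected", {
  expect_error(sim_config(n_instruments = 0, n_null_snps = 0), "degenerate")
  expect_error(sim_config(invalid_fraction = 1.5), "invalid_fraction")
  expect_error(sim_config(n_exposure = 50), "sample sizes")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("inject_outlier shifts one outcome beta by the stated multiple", {
  st <- simulate_two_sample(sim_config(n_instruments = 10, n_null_snps = 0,
                                       palindrome_fraction = 0, seed = 31))
  target <- st$exposure$snp[1]
  se_y <- st$outcome$se[1]
  st10 <- inject_outlier(st, target, 10)
  expect_equal(st10$outcome$beta[1], st$outcome$beta[1] + 10 * se_y)
  expect_true(st10$truth$is_invalid[1])
  # Wald ratio departs by ~ 10 * se_y / beta_x
  r0 <- st$outcome$beta[1] / st$exposure$beta[1]
  r1 <- st10$outcome$beta[1] / st10$exposure$beta[1]
  expect_equal(r1 - r0, 10 * se_y / st$exposure$beta[1])
  # zero shift changes nothing but the flag; +5 then -5 restores the beta
  st0 <- inject_outlier(st, target, 0)
  expect_equal(st0$outcome$beta, st$outcome$beta)
  st_pm <- inject_outlier(inject_outlier(st, target, 5), target, -5)
  expect_equal(st_pm$outcome$beta, st$outcome$beta)
  expect_error(inject_outlier(st, "rs_nowhere", 1), "unknown snp_id")
})

test_that("write_study emits readable files that round-trip", {
  st <- simulate_two_sample(sim_config(n_instruments = 5, n_null_snps = 5,
                                       ld_block_size = 2, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir, prefix = "toy")
  expect_true(all(file.exists(paths)))
  exp_back <- read_sumstats(paths["exposure"])
  expect_identical(exp_back$beta, st$exposure$beta)
  ld_back <- read_ld(paths["ld"])
  snp <- st$exposure$snp
  expect_equal(ld_r2(ld_back, snp[1], snp[2]), ld_r2(st$ld, snp[1], snp[2]))
})

test_that("directional pleiotropy is recovered by the Egger intercept", {
  # invalid fraction 1, mu_alpha = 0.05: mean intercept over replicates
  # approaches 0.05
  ints <- vapply(1:40, function(i) {
    st <- simulate_two_sample(sim_config(
      n_instruments = 60, n_null_snps = 0, theta = 0.1, invalid_fraction = 1,
      mu_alpha = 0.05, sigma_alpha = 0.02, palindrome_fraction = 0,
      seed = 4000 + i))
    mr_egger(harm_from_study(st))$intercept
  }, numeric(1))
  mc_se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - 0.05), 3 * mc_se + 0.005)
})
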