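# exhaustive pairwise oracle: walk SNPs in (p, chr, pos, snp) order and keep
# each one iff it is compatible with every SNP already kept
clump_oracle <- function(rows, ld, window_kb, r2_max) {
  ord <- order(rows$p, rows$chr, rows$pos, rows$snp)
  rows <- rows[ord, ]
  kept <- integer(0)
  for (i in seq_len(nrow(rows))) {
    ok <- TRUE
    for (j in kept) {
      if (rows$chr[i] == rows$chr[j] &&
          abs(rows$pos[i] - rows$pos[j]) <= window_kb * 1000) {
        r2 <- ld_r2(ld, rows$snp[i], rows$snp[j])
        if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  rows$snp[kept]
}

test_that("clumping keeps the most significant SNP of a linked pair", {
  rows <- make_rows(2, pos = c(1e6, 1e6 + 5000), se = 0.01,
                    beta = c(0.057, 0.049))
  rows$p <- c(1e-8, 1e-6)
  ld <- ld_lookup(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  kept <- ld_clump(rows, ld, window_kb = 10000, r2_max = 0.001)
  expect_equal(kept$snp, "rs1")
})

test_that("LD across chromosomes or beyond the window is ignored", {
  rows <- make_rows(2, chr = c("1", "2"), pos = c(1e6, 1e6))
  rows$p <- c(1e-8, 1e-6)
  ld <- ld_lookup(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  expect_setequal(ld_clump(rows, ld)$snp, c("rs1", "rs2"))
  rows2 <- make_rows(2, chr = "1", pos = c(1e6, 1e6 + 2e7))  # 20,000 kb apart
  rows2$p <- c(1e-8, 1e-6)
  ld2 <- ld_lookup(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  expect_setequal(ld_clump(rows2, ld2)$snp, c("rs1", "rs2"))
})

test_that("clumping simulated LD blocks matches the exhaustive oracle", {
  for (seed in c(101, 202, 303)) {
    st <- simulate_two_sample(sim_config(
      n_instruments = 30, n_null_snps = 0, ld_block_size = 10,
      ld_within_r2 = 0.4, palindrome_fraction = 0, seed = seed))
    rows <- st$exposure
    kept <- ld_clump(rows, st$ld, 10000, 0.001)
    expect_identical(kept$snp, clump_oracle(rows, st$ld, 10000, 0.001))
    # 3 blocks of 10 -> exactly one survivor per block
    expect_equal(nrow(kept), 3L)
    # every retained same-chromosome pair within the window has r2 <= max
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i < j && kept$chr[i] == kept$chr[j] &&
          abs(kept$pos[i] - kept$pos[j]) <= 1e7) {
        expect_lte(ld_r2(st$ld, kept$snp[i], kept$snp[j]), 0.001)
      }
    }
  }
})

test_that("clumping output is invariant to input row order", {
  st <- simulate_two_sample(sim_config(n_instruments = 24, n_null_snps = 0,
                                       ld_block_size = 6, ld_within_r2 = 0.3,
                                       palindrome_fraction = 0, seed = 7))
  rows <- st$exposure
  shuffled <- rows[withr::with_seed(1, sample(nrow(rows))), ]
  expect_identical(ld_clump(rows, st$ld)$snp, ld_clump(shuffled, st$ld)$snp)
})

test_that("unknown LD (NA default) keeps both SNPs", {
  rows <- make_rows(2, pos = c(1e6, 1e6 + 5000))
  rows$p <- c(1e-8, 1e-6)
  ld <- ld_lookup(NULL, default_r2 = NA_real_)
  expect_equal(nrow(ld_clump(rows, ld)), 2L)
})

test_that("F statistic matches direct arithmetic and is monotone", {
  expect_equal(compute_f_statistic(0.01, 18340, 10),
               (0.01 / 0.99) * (18329 / 10), tolerance = 1e-12)
  expect_equal(round(compute_f_statistic(0.01, 18340, 10), 3), 18.514)
  expect_equal(compute_f_statistic(0, 1000, 5), 0)
  f <- vapply(seq(0.001, 0.9, length.out = 50), compute_f_statistic,
              numeric(1), n = 10000, k = 10)
  expect_true(all(diff(f) > 0))
  # the as-printed variant flips the sign for R2 < 1
  expect_equal(compute_f_statistic(0.01, 18340, 10, formula = "as_printed"),
               -compute_f_statistic(0.01, 18340, 10))
  expect_error(compute_f_statistic(1, 100, 1), "r2_total")
  expect_error(compute_f_statistic(0.1, 11, 10), "n must exceed")
})

test_that("a clean simulated study passes every funnel stage intact", {
  # strong unlinked instruments, null outcome, no palindromes: nothing to drop
  st <- simulate_two_sample(sim_config(
    n_instruments = 20, n_null_snps = 0, sigma_gamma = 0.5, theta = 0,
    palindrome_fraction = 0, maf_range = c(0.2, 0.5), seed = 12))
  keep <- st$exposure$p <= 1e-5 & st$outcome$p >= 0.05
  exposure <- st$exposure[keep, ]
  outcome <- st$outcome
  sel <- select_instruments(exposure, outcome, st$ld)
  expect_equal(unname(sel$funnel), rep(nrow(exposure), 6))
  expect_equal(nrow(sel$rows), nrow(exposure))
  expect_false(sel$no_instruments)
  expect_true(all(sel$f_per_snp > 10))
  # the aggregate F is undefined when the standardized-trait approximation
  # pushes total variance explained past 1 (very strong simulated effects)
  expect_true(is.na(sel$f_statistic) || sel$f_statistic > 10)
})

test_that("no candidates yields an empty flagged set with a zero funnel", {
  rows <- make_rows(5, beta = 0.001, se = 0.01)   # p ~ 0.92
  sel <- select_instruments(rows, rows, NULL)
  expect_true(sel$no_instruments)
  expect_equal(unname(sel$funnel), rep(0L, 6))
  expect_equal(nrow(sel$rows), 0L)
})

test_that("each funnel stage drops what it should, in order", {
  rows <- make_rows(7, chr = as.character(1:7), beta = 0.3, se = 0.01,
                    eaf = c(0.3, 0.005, 0.3, 0.3, 0.3, 0.3, 0.3), n_col = 18340)
  rows$beta[3] <- 0.012                      # per-SNP F ~ 1 at eaf 0.3
  rows$se[3] <- 0.002                        # ... while still locus-wide significant
  rows$p <- pmax(2 * pnorm(-abs(rows$beta / rows$se)), 1e-300)
  rows$p[1] <- 1e-4                          # fails the locus-wide threshold
  outcome <- make_rows(7, chr = as.character(1:7), beta = 0, se = 0.01, p = 0.5)
  outcome$p[5] <- 0.01                       # associated with the outcome
  outcome <- outcome[outcome$snp != "rs6", ] # rs6 missing from the outcome
  cfg <- instrument_filter_config(blocklist = "rs4")
  sel <- select_instruments(rows, outcome, NULL, cfg)
  expect_equal(unname(sel$funnel), c(6, 6, 5, 4, 3, 1))
  expect_equal(sel$rows$snp, "rs7")
  log <- sel$log
  expect_equal(log$reason[log$snp == "rs2"], "MAF below threshold")
  expect_equal(log$reason[log$snp == "rs3"], "per-SNP F below threshold")
  expect_equal(log$reason[log$snp == "rs4"], "possible confounder association")
  expect_equal(log$reason[log$snp == "rs5"], "associated with outcome")
  expect_equal(log$reason[log$snp == "rs6"], "missing in outcome")
})

test_that("funnel counts never increase and MAF/blocklist stages commute", {
  st <- simulate_two_sample(sim_config(n_instruments = 40, n_null_snps = 60,
                                       maf_range = c(0.005, 0.5), seed = 44))
  cfg_a <- instrument_filter_config(blocklist = st$exposure$snp[1:10])
  sel <- select_instruments(st$exposure, st$outcome, st$ld, cfg_a)
  expect_true(all(diff(unname(sel$funnel)) <= 0))
  # commuting check: drop blocklisted SNPs from the input instead
  pre_blocked <- st$exposure[!st$exposure$snp %in% cfg_a$blocklist, ]
  cfg_b <- instrument_filter_config()
  sel_b <- select_instruments(pre_blocked, st$outcome, st$ld, cfg_b)
  expect_setequal(sel$rows$snp, sel_b$rows$snp)
})

test_that("set-level F mode rejects a weak set wholesale", {
  rows <- make_rows(3, chr = as.character(1:3), beta = 0.012, se = 0.0025,
                    eaf = 0.3, n_col = 18340)
  rows$p <- pmax(2 * pnorm(-abs(rows$beta / rows$se)), 1e-300)
  outcome <- make_rows(3, chr = as.character(1:3), beta = 0, se = 0.01, p = 0.5)
  cfg <- instrument_filter_config(f_mode = "set")
  sel <- select_instruments(rows, outcome, NULL, cfg)
  expect_true(sel$no_instruments)
  expect_equal(unname(sel$funnel["after_f"]), 0L)
})
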