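# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# canonical summary-stat rows with sensible defaults, overridable per column
make_rows <- function(n, snp = sprintf("rs%d", seq_len(n)), chr = "1",
                      pos = seq_len(n) * 1e6, ea = "A", oa = "G",
                      eaf = 0.3, beta = 0.1, se = 0.01, p = NULL, n_col = 10000) {
  if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(snp = snp, chr = rep_len(chr, n), pos = as.integer(rep_len(pos, n)),
             ea = rep_len(ea, n), oa = rep_len(oa, n), eaf = rep_len(eaf, n),
             beta = rep_len(beta, n), se = rep_len(se, n), p = rep_len(p, n),
             n = rep_len(n_col, n), stringsAsFactors = FALSE)
}

# harmonized dataset with given Wald ratios: beta_out = ratio * beta_exp
make_harm <- function(ratios, beta_exp = NULL, se_exp = 0.01, se_out = 0.01,
                      snp = NULL) {
  k <- length(ratios)
  if (is.null(beta_exp)) beta_exp <- rep(1, k)
  if (is.null(snp)) snp <- sprintf("rs%d", seq_len(k))
  harmonized_data(snp, beta_exp, rep_len(se_exp, k),
                  ratios * beta_exp, rep_len(se_out, k))
}

# random harmonized dataset for property-style loops
random_harm <- function(k, seed) {
  withr::with_seed(seed, {
    bx <- rnorm(k, 0, 0.3) + sign(rnorm(k)) * 0.05
    harmonized_data(sprintf("rs%d", seq_len(k)), bx, runif(k, 0.005, 0.05),
                    0.2 * bx + rnorm(k, 0, 0.02), runif(k, 0.005, 0.05))
  })
}

# harmonized dataset drawn from a simulated study restricted to instruments,
# bypassing selection (no winner's-curse filtering)
harm_from_study <- function(study) {
  instr <- study$truth$snp[study$truth$is_instrument]
  e <- study$exposure[study$exposure$snp %in% instr, ]
  harmonize(e, study$outcome)
}
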