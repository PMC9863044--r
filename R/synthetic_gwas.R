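#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defines the generative model for paired exposure/outcome summary
#' statistics with known ground truth. For instrument j:
#' \deqn{maf_j ~ U(maf_range), \quad \gamma_j ~ N(0, \sigma_\gamma^2)}
#' \deqn{se_{x,j} = (2 maf_j (1-maf_j) n_{exp})^{-1/2}, \quad
#'       \hat\beta_{x,j} ~ N(\gamma_j, se_{x,j}^2)}
#' \deqn{\hat\beta_{y,j} ~ N(\theta \gamma_j + sign(\gamma_j) \alpha_j, se_{y,j}^2)}
#' where \eqn{\alpha_j = 0} for valid instruments and, for the invalid
#' fraction, \eqn{\alpha_j ~ N(\mu_\alpha, \sigma_\alpha^2)} with correlation
#' `inside_violation` to \eqn{|\gamma_j|} (an InSIDE violation). The direct
#' effect is defined relative to the exposure-increasing allele, so
#' \eqn{\mu_\alpha > 0} is *directional* pleiotropy: it biases IVW and is
#' recoverable as the MR-Egger intercept after the usual orientation. Null
#' SNPs have \eqn{\gamma = \alpha = 0}. p-values are two-sided normal.
#'
#' @param n_instruments number of true instruments.
#' @param n_null_snps number of non-instrument SNPs.
#' @param theta true causal effect of exposure on outcome.
#' @param sigma_gamma SD of true SNP-to-exposure effects (standardized-trait
#'   units). The default 0.3 puts locus-wide-significant instruments in the
#'   strong-instrument regime (per-SNP F in the hundreds) so estimator
#'   validation is not confounded by weak-instrument attenuation.
#' @param invalid_fraction fraction of instruments with a direct (pleiotropic)
#'   outcome effect, in \[0,1\].
#' @param mu_alpha,sigma_alpha mean/SD of direct effects on the
#'   exposure-increasing allele scale.
#' @param inside_violation correlation between |gamma| and alpha among invalid
#'   instruments, in \[-1,1\] (0 = InSIDE holds).
#' @param n_exposure,n_outcome GWAS sample sizes (>= 100).
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param palindrome_fraction fraction of SNPs given A/T or C/G allele pairs.
#' @param ld_block_size SNPs per LD block (1 = no LD).
#' @param ld_within_r2 pairwise r-squared within a block.
#' @param seed integer seed; identical config implies identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_instruments = 50, n_null_snps = 450, theta = 0,
                       sigma_gamma = 0.3, invalid_fraction = 0,
                       mu_alpha = 0, sigma_alpha = 0, inside_violation = 0,
                       n_exposure = 18340, n_outcome = 20000,
                       maf_range = c(0.05, 0.5), palindrome_fraction = 0.2,
                       ld_block_size = 1, ld_within_r2 = 0.3, seed = 1L) {
  cfg <- list(n_instruments = as.integer(n_instruments),
              n_null_snps = as.integer(n_null_snps), theta = theta,
              sigma_gamma = sigma_gamma, invalid_fraction = invalid_fraction,
              mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
              inside_violation = inside_violation,
              n_exposure = as.integer(n_exposure),
              n_outcome = as.integer(n_outcome),
              maf_range = as.numeric(maf_range),
              palindrome_fraction = palindrome_fraction,
              ld_block_size = as.integer(ld_block_size),
              ld_within_r2 = ld_within_r2, seed = as.integer(seed))
  with(cfg, {
    if (n_instruments < 0 || n_null_snps < 0) stop("negative SNP counts")
    if (n_instruments == 0 && n_null_snps == 0) {
      stop("degenerate config: no instruments and no null SNPs")
    }
    if (invalid_fraction < 0 || invalid_fraction > 1) stop("invalid_fraction outside [0,1]")
    if (palindrome_fraction < 0 || palindrome_fraction > 1) stop("palindrome_fraction outside [0,1]")
    if (abs(inside_violation) > 1) stop("inside_violation outside [-1,1]")
    if (sigma_gamma < 0 || sigma_alpha < 0) stop("negative sigma")
    if (n_exposure < 100 || n_outcome < 100) stop("sample sizes must be >= 100")
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) stop("maf_range must lie within (0, 0.5]")
    if (ld_block_size < 1) stop("ld_block_size must be >= 1")
    if (ld_within_r2 < 0 || ld_within_r2 > 1) stop("ld_within_r2 outside [0,1]")
  })
  structure(cfg, class = "sim_config")
}

.sign1 <- function(x) ifelse(x < 0, -1, 1)

# Allele pairs: palindromic SNPs get A/T or C/G; the rest avoid them.
.palindromic_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                             ncol = 2L, byrow = TRUE)
.nonpal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2L, byrow = TRUE)

#' Simulate a two-sample GWAS study with known ground truth
#'
#' Draws paired exposure/outcome summary-statistic tables over the same SNP
#' set under the generative model of [sim_config()], plus a block-diagonal
#' pairwise-LD lookup. LD enters only through the lookup (consumed by
#' clumping); effect-size correlation across linked SNPs is not simulated.
#'
#' @param config a [sim_config()].
#' @return object of class `simulated_study`: list with `exposure`, `outcome`
#'   (canonical summary-stat data.frames), `ld` (an `ld_lookup`), `truth`
#'   (data.frame: `snp`, `gamma`, `alpha`, `is_instrument`, `is_invalid`) and
#'   `config`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  m <- cfg$n_instruments + cfg$n_null_snps
  snp <- sprintf("rs%07d", seq_len(m))

  # block-diagonal layout: blocks cycle over 22 chromosomes, 25 Mb apart on a
  # chromosome (beyond any clumping window), 5 kb between SNPs within a block
  block <- (seq_len(m) - 1L) %/% cfg$ld_block_size
  within <- (seq_len(m) - 1L) %% cfg$ld_block_size
  chr <- as.character(block %% 22L + 1L)
  # positions wrap within the integer range for very large panels; distinct
  # blocks that land near one another are still unlinked (r2 = 0 by default)
  pos <- as.integer(1e6 + ((block %/% 22L) * 25e6) %% 2e9 + within * 5000)

  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
  pal <- stats::runif(m) < cfg$palindrome_fraction
  idx_pal <- sample.int(4L, m, replace = TRUE)
  idx_non <- sample.int(8L, m, replace = TRUE)
  ea <- ifelse(pal, .palindromic_pairs[idx_pal, 1L], .nonpal_pairs[idx_non, 1L])
  oa <- ifelse(pal, .palindromic_pairs[idx_pal, 2L], .nonpal_pairs[idx_non, 2L])

  is_instrument <- seq_len(m) <= cfg$n_instruments
  gamma <- numeric(m)
  gamma[is_instrument] <- stats::rnorm(cfg$n_instruments, 0, cfg$sigma_gamma)

  n_invalid <- round(cfg$invalid_fraction * cfg$n_instruments)
  is_invalid <- rep(FALSE, m)
  if (n_invalid > 0L) {
    inv <- sample(which(is_instrument), n_invalid)
    is_invalid[inv] <- TRUE
  }

  # direct effects on the exposure-increasing-allele scale, optionally
  # correlated with instrument strength |gamma| (InSIDE violation)
  alpha <- numeric(m)
  if (n_invalid > 0L) {
    g_abs <- abs(gamma[is_invalid])
    zg <- if (n_invalid > 1L && stats::sd(g_abs) > 0) {
      (g_abs - mean(g_abs)) / stats::sd(g_abs)
    } else rep(0, n_invalid)
    rho <- cfg$inside_violation
    z <- rho * zg + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_invalid)
    alpha_oriented <- cfg$mu_alpha + cfg$sigma_alpha * z
    alpha[is_invalid] <- .sign1(gamma[is_invalid]) * alpha_oriented
  }

  se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome)
  beta_x <- stats::rnorm(m, gamma, se_x)
  beta_y <- stats::rnorm(m, cfg$theta * gamma + alpha, se_y)
  p_x <- pmax(2 * stats::pnorm(-abs(beta_x / se_x)), 1e-300)
  p_y <- pmax(2 * stats::pnorm(-abs(beta_y / se_y)), 1e-300)

  mk <- function(beta, se, p, n) data.frame(
    snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
    beta = beta, se = se, p = p, n = n, stringsAsFactors = FALSE)

  ld_pairs <- NULL
  if (cfg$ld_block_size > 1L) {
    pairs <- do.call(rbind, lapply(split(snp, block), function(s) {
      if (length(s) < 2L) return(NULL)
      idx <- utils::combn(length(s), 2L)
      data.frame(snp_a = s[idx[1L, ]], snp_b = s[idx[2L, ]],
                 r2 = cfg$ld_within_r2, stringsAsFactors = FALSE)
    }))
    ld_pairs <- pairs
  }

  structure(list(
    exposure = mk(beta_x, se_x, p_x, cfg$n_exposure),
    outcome = mk(beta_y, se_y, p_y, cfg$n_outcome),
    ld = ld_lookup(ld_pairs, default_r2 = 0),
    truth = data.frame(snp = snp, gamma = gamma, alpha = alpha,
                       is_instrument = is_instrument, is_invalid = is_invalid,
                       stringsAsFactors = FALSE),
    config = cfg
  ), class = "simulated_study")
}

#' Shift one SNP's outcome effect to create a pleiotropic outlier
#'
#' Adds `shift_sds * se_y` to the outcome beta of `snp_id`, recomputes its
#' p-value, and marks it invalid in the truth record. Used as a fixture for
#' outlier-detection diagnostics.
#'
#' @param study a `simulated_study`.
#' @param snp_id SNP to perturb (must be present).
#' @param shift_sds shift in units of the SNP's outcome standard error.
#' @return the modified `simulated_study`.
#' @export
inject_outlier <- function(study, snp_id, shift_sds) {
  stopifnot(inherits(study, "simulated_study"))
  i <- match(snp_id, study$outcome$snp)
  if (is.na(i)) stop("unknown snp_id: ", snp_id)
  study$outcome$beta[i] <- study$outcome$beta[i] + shift_sds * study$outcome$se[i]
  study$outcome$p[i] <- pmax(
    2 * stats::pnorm(-abs(study$outcome$beta[i] / study$outcome$se[i])), 1e-300)
  study$truth$is_invalid[study$truth$snp == snp_id] <- TRUE
  study
}

#' Write a simulated study to disk
#'
#' Emits `<prefix>_exposure.tsv`, `<prefix>_outcome.tsv` (canonical
#' summary-stat dialect), `<prefix>_ld.tsv`, `<prefix>_truth.tsv` and
#' `<prefix>_config.txt` (key-value lines).
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return named character vector of paths, invisibly.
#' @export
write_study <- function(study, dir, prefix = "study") {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(x) file.path(dir, paste0(prefix, "_", x))
  write_sumstats(study$exposure, p("exposure.tsv"))
  write_sumstats(study$outcome, p("outcome.tsv"))
  ld_df <- .ld_as_df(study$ld)
  write_ld(ld_df, p("ld.tsv"))
  utils::write.table(study$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- study$config
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(v) paste(format(v, digits = 17), collapse = ","),
                           character(1L))),
             p("config.txt"))
  invisible(c(exposure = p("exposure.tsv"), outcome = p("outcome.tsv"),
              ld = p("ld.tsv"), truth = p("truth.tsv"), config = p("config.txt")))
}

.ld_as_df <- function(ld) {
  keys <- ls(ld$env)
  if (length(keys) == 0L) {
    return(data.frame(snp_a = character(), snp_b = character(), r2 = numeric()))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(snp_a = vapply(parts, `[`, character(1L), 1L),
             snp_b = vapply(parts, `[`, character(1L), 2L),
             r2 = vapply(keys, function(k) ld$env[[k]], numeric(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat("Simulated two-sample GWAS study\n")
  cat(sprintf("  SNPs: %d (%d instruments, %d null), theta = %g\n",
              nrow(x$exposure), cfg$n_instruments, cfg$n_null_snps, cfg$theta))
  cat(sprintf("  invalid instruments: %d, mu_alpha = %g\n",
              sum(x$truth$is_invalid), cfg$mu_alpha))
  cat(sprintf("  n_exposure = %d, n_outcome = %d, seed = %d\n",
              cfg$n_exposure, cfg$n_outcome, cfg$seed))
  invisible(x)
}
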