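#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j * (r_j - beta_fe)^2)` over Wald ratios `r_j` with weights
#' `w_j = beta_exp_j^2 / se_out_j^2`, centred on the fixed-effect IVW
#' estimate; upper-tail p from chi-square with `n_snp - 1` degrees of
#' freedom. Large Q indicates the instruments do not share one causal
#' ratio (heterogeneity, e.g. from pleiotropy).
#'
#' @param data a [harmonized_data()] with `n_snp >= 2`.
#' @return object of class `heterogeneity_result`: `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(data) {
  stopifnot(inherits(data, "harmonized_data"))
  k <- data$n_snp
  if (k < 2L) stop("cochran_q requires at least 2 SNPs")
  fe <- mr_ivw(data, model = "fixed")
  structure(list(q = fe$q, df = k - 1L,
                 pvalue = stats::pchisq(fe$q, k - 1L, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept triple from [mr_egger()]; the verdict is "no
#' significant horizontal pleiotropy" when the intercept p-value exceeds
#' 0.05.
#'
#' @param data a [harmonized_data()] with `n_snp >= 3`.
#' @return list with `intercept`, `se`, `pvalue`, `verdict`.
#' @export
egger_intercept_test <- function(data) {
  est <- mr_egger(data)
  list(intercept = est$intercept, se = est$intercept_se,
       pvalue = est$intercept_p,
       verdict = if (est$intercept_p > 0.05) {
         "no significant horizontal pleiotropy"
       } else "horizontal pleiotropy detected")
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' statistic is `RSS = sum_j w_j (beta_out_j - b_(-j) * beta_exp_j)^2` with
#' `w_j = 1/se_out_j^2` and `b_(-j)` the IVW estimate excluding SNP j. The
#' null distribution comes from `n_sim` parametric simulations drawing
#' `beta_out_j* ~ N(b_(-j) * beta_exp_j, se_out_j^2)` and
#' `beta_exp_j* ~ N(beta_exp_j, se_exp_j^2)` and recomputing RSS
#' identically; `global_p = (1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)` (so its
#' floor is `1/(n_sim+1)`). Each SNP's observed weighted residual is compared
#' with its own simulated distribution; SNPs with Bonferroni-corrected
#' empirical p below `outlier_alpha` are flagged as outliers. The distortion
#' is reported descriptively as the IVW estimate before and after outlier
#' removal.
#'
#' @param data a [harmonized_data()] with `n_snp >= 4`.
#' @param n_sim parametric simulations (default 1000).
#' @param seed optional integer seed (NULL = current RNG).
#' @param outlier_alpha family-wise level for the outlier test (default 0.05).
#' @return object of class `presso_result`: `rss_observed`, `global_p`,
#'   `outlier_snps`, `outlier_p` (named, per SNP), `distortion_note`
#'   (IVW beta before/after removal).
#' @export
mr_presso <- function(data, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  stopifnot(inherits(data, "harmonized_data"))
  k <- data$n_snp
  if (k < 4L) stop("mr_presso requires at least 4 SNPs")
  w <- 1 / data$se_out^2
  bx <- data$beta_exp; by <- data$beta_out

  loo_beta <- function(bx, by) {
    t_xy <- w * bx * by
    t_xx <- w * bx^2
    (sum(t_xy) - t_xy) / (sum(t_xx) - t_xx)
  }
  b_loo <- loo_beta(bx, by)
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  sim <- function() {
    bx_s <- matrix(stats::rnorm(k * n_sim, bx, data$se_exp), nrow = k)
    by_s <- matrix(stats::rnorm(k * n_sim, b_loo * bx, data$se_out), nrow = k)
    t_xy <- w * bx_s * by_s
    t_xx <- w * bx_s^2
    b_s <- sweep(-t_xy, 2L, colSums(t_xy), "+") / sweep(-t_xx, 2L, colSums(t_xx), "+")
    w * (by_s - b_s * bx_s)^2  # k x n_sim matrix of weighted residuals
  }
  res_sim <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  rss_sim <- colSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
  names(outlier_p) <- data$snp
  flagged <- data$snp[outlier_p * k < outlier_alpha]

  beta_all <- mr_ivw(data, "random")$beta
  beta_wo <- if (length(flagged) > 0L && k - length(flagged) >= 1L) {
    mr_ivw(subset_harmonized(data, !(data$snp %in% flagged)), "random")$beta
  } else NA_real_
  structure(list(rss_observed = rss_obs, global_p = global_p,
                 outlier_snps = flagged, outlier_p = outlier_p,
                 distortion_note = c(beta_all = beta_all,
                                     beta_without_outliers = beta_wo),
                 n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.3g\n", x$rss_observed, x$global_p))
  if (length(x$outlier_snps) > 0L) {
    cat("  outliers:", paste(x$outlier_snps, collapse = ", "), "\n")
    cat(sprintf("  IVW before/after removal: %.4g / %.4g\n",
                x$distortion_note["beta_all"], x$distortion_note["beta_without_outliers"]))
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out stability analysis
#'
#' Recomputes the primary (multiplicative random-effects) IVW estimate with
#' each SNP left out in turn. A SNP is flagged `dominant_snp` when the
#' full-data estimate is significant (p < `alpha`) but significance is lost
#' upon its removal — i.e. a single variant is driving the result.
#'
#' @param data a [harmonized_data()] with `n_snp >= 3`.
#' @param alpha significance level for the dominance flag (default 0.05).
#' @return data.frame with one row per left-out SNP (`snp`, `beta`, `se`,
#'   `pvalue`, `dominant_snp`); the full-data estimate is attached as
#'   attribute `"full_estimate"`.
#' @export
leave_one_out <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "harmonized_data"))
  k <- data$n_snp
  if (k < 3L) stop("leave_one_out requires at least 3 SNPs")
  full <- mr_ivw(data, "random")
  rows <- lapply(seq_len(k), function(j) {
    est <- mr_ivw(subset_harmonized(data, -j), "random")
    data.frame(snp = data$snp[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue,
               dominant_snp = full$pvalue < alpha && est$pvalue >= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_estimate") <- full
  out
}
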