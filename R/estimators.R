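#' @title Causal-effect estimators
#' @description Wald ratio, inverse-variance-weighted (fixed and
#'   multiplicative random effects), MR-Egger, weighted median and weighted
#'   mode. All return an `mr_estimate`.
#' @name estimators
NULL

.z975 <- stats::qnorm(0.975)

new_mr_estimate <- function(method, beta, se, n_snp, df = NULL, binary = FALSE,
                            ...) {
  crit <- if (is.null(df)) .z975 else stats::qt(0.975, df)
  pvalue <- if (se > 0) {
    if (is.null(df)) 2 * stats::pnorm(-abs(beta / se)) else
      2 * stats::pt(-abs(beta / se), df)
  } else if (beta == 0) 1 else 0
  pvalue <- max(pvalue, 1e-300)  # keep p in (0,1] under underflow
  est <- list(method = method, beta = beta, se = se,
              ci_low = beta - crit * se, ci_high = beta + crit * se,
              pvalue = pvalue, n_snp = n_snp, ...)
  if (binary) {
    est$or <- exp(est$beta)
    est$or_ci_low <- exp(est$ci_low)
    est$or_ci_high <- exp(est$ci_high)
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snp))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.4g, 95%% CI [%.4g, %.4g]\n", x$or, x$or_ci_low, x$or_ci_high))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_out / beta_exp` with first-order delta-method standard error
#' `|se_out / beta_exp|`; two-sided normal p-value.
#'
#' @param beta_exp,se_exp exposure effect and SE (`beta_exp` must be nonzero).
#' @param beta_out,se_out outcome effect and SE.
#' @param binary attach an odds-ratio scale (`exp(beta)` and CI).
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, binary = FALSE) {
  if (beta_exp == 0) stop("wald_ratio undefined for beta_exp = 0")
  new_mr_estimate("wald", beta_out / beta_exp, abs(se_out / beta_exp), 1L,
                  binary = binary)
}

.ratio_weights <- function(data) {
  list(r = data$beta_out / data$beta_exp,
       w = data$beta_exp^2 / data$se_out^2)
}

#' Inverse-variance-weighted estimator
#'
#' Zero-intercept weighted regression of outcome betas on exposure betas with
#' weights `1/se_out^2`:
#' `beta = sum(w * bx * by) / sum(w * bx^2)`, fixed-effect
#' `se = (sum(w * bx^2))^(-1/2)`. The multiplicative random-effects model
#' (the primary model) scales the SE by `max(1, sqrt(Q / (n_snp - 1)))`
#' where Q is Cochran's heterogeneity statistic. Normal-based CI and p.
#' With one SNP the estimate reduces exactly to the Wald ratio.
#'
#' @param data a [harmonized_data()] with `n_snp >= 1`.
#' @param model `"random"` (multiplicative random effects, primary) or
#'   `"fixed"`.
#' @param binary attach an odds-ratio scale.
#' @return an `mr_estimate` (method `"ivw_re"` or `"ivw_fe"`) with fields
#'   `q` and `q_df` attached.
#' @export
mr_ivw <- function(data, model = c("random", "fixed"), binary = FALSE) {
  stopifnot(inherits(data, "harmonized_data"))
  model <- match.arg(model)
  k <- data$n_snp
  if (k == 0L) stop("mr_ivw requires at least one SNP")
  w <- 1 / data$se_out^2
  s_xx <- sum(w * data$beta_exp^2)
  beta <- sum(w * data$beta_exp * data$beta_out) / s_xx
  se_fe <- sqrt(1 / s_xx)
  q <- sum(w * (data$beta_out - beta * data$beta_exp)^2)
  se <- se_fe
  if (model == "random" && k >= 2L) se <- se_fe * max(1, sqrt(q / (k - 1)))
  new_mr_estimate(if (model == "random") "ivw_re" else "ivw_fe",
                  beta, se, k, binary = binary, q = q, q_df = max(k - 1L, 0L))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept and weights `1/se_out^2`, after orienting every SNP so the
#' exposure beta is non-negative. The slope estimates the causal effect under
#' the InSIDE assumption; the intercept estimates average directional
#' pleiotropy. Standard errors carry a multiplicative overdispersion scale
#' `max(1, sqrt(RSS/(n-2)))`; p-values use a t reference with `n_snp - 2`
#' degrees of freedom.
#'
#' @param data a [harmonized_data()] with `n_snp >= 3`.
#' @param binary attach an odds-ratio scale.
#' @return an `mr_estimate` (method `"egger"`) with `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(data, binary = FALSE) {
  stopifnot(inherits(data, "harmonized_data"))
  k <- data$n_snp
  if (k < 3L) stop("mr_egger requires at least 3 SNPs")
  s <- .sign1(data$beta_exp)
  bx <- abs(data$beta_exp)
  by <- data$beta_out * s
  w <- 1 / data$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  # degenerate all-identical-ratio inputs fit perfectly; the warning from
  # summary.lm is expected there
  sm <- suppressWarnings(summary(fit))
  sigma <- sm$sigma
  scale <- max(1, sigma)
  co <- sm$coefficients
  se_unit <- if (sigma > 0) co[, "Std. Error"] / sigma else co[, "Std. Error"] * 0
  se <- se_unit * scale
  est <- new_mr_estimate("egger", unname(co["bx", "Estimate"]), unname(se["bx"]),
                         k, df = k - 2L, binary = binary)
  est$intercept <- unname(co["(Intercept)", "Estimate"])
  est$intercept_se <- unname(se["(Intercept)"])
  est$intercept_p <- if (est$intercept_se > 0) {
    2 * stats::pt(-abs(est$intercept / est$intercept_se), k - 2L)
  } else if (est$intercept == 0) 1 else 0
  est
}

# weighted median of ratios r with weights w (normalized internally):
# sort by r, s_j = cumsum(w) - w/2, interpolate linearly across s = 0.5
.weighted_median_est <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (all(s >= 0.5)) return(r[1L])
  below <- max(which(s < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1L] - r[below]) * (0.5 - s[below]) / (s[below + 1L] - s[below])
}

.parametric_boot <- function(data, n_boot, seed, est_fun) {
  run <- function() {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(data$n_snp, data$beta_exp, data$se_exp)
      by <- stats::rnorm(data$n_snp, data$beta_out, data$se_out)
      est_fun(bx, by)
    }, numeric(1L))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Weighted-median estimator
#'
#' Median of per-SNP Wald ratios under inverse-variance weights
#' `w = beta_exp^2 / se_out^2` (linear interpolation across the 50% weight
#' point); consistent when valid instruments carry at least half the weight.
#' The standard error comes from a parametric bootstrap: exposure and outcome
#' betas are redrawn from normal distributions centred on the observed values
#' with the reported SEs, and the SD of the replicate estimates is used with
#' a normal CI and p-value.
#'
#' @param data a [harmonized_data()] with `n_snp >= 3`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap (NULL = current RNG).
#' @param binary attach an odds-ratio scale.
#' @return an `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL, binary = FALSE) {
  stopifnot(inherits(data, "harmonized_data"))
  if (data$n_snp < 3L) stop("mr_weighted_median requires at least 3 SNPs")
  rw <- .ratio_weights(data)
  beta <- .weighted_median_est(rw$r, rw$w)
  boot <- .parametric_boot(data, n_boot, seed, function(bx, by) {
    .weighted_median_est(by / bx, bx^2 / data$se_out^2)
  })
  new_mr_estimate("weighted_median", beta, stats::sd(boot), data$n_snp,
                  binary = binary, n_boot = n_boot)
}

# weighted Gaussian kernel density argmax over ratios; grid of `grid_n`
# points spanning ratios +- 3h, optionally refined by stats::optimize
.weighted_mode_est <- function(r, w, phi, grid_n = 512L, refine = TRUE) {
  if (diff(range(r)) == 0) return(r[1L])
  w <- w / sum(w)
  spread <- min(stats::sd(r), stats::IQR(r) / 1.349)
  if (spread == 0) spread <- stats::sd(r)
  h <- phi * 0.9 * spread * length(r)^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - r) / h)), numeric(1L))
  }
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = grid_n)
  f <- colSums(w * stats::dnorm(outer(r, grid, "-") / h))
  i <- which.max(f)
  if (!refine) return(grid[i])
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  if (lo == hi) return(grid[i])
  stats::optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted-mode estimator
#'
#' Mode of the weighted Gaussian kernel density over per-SNP Wald ratios with
#' inverse-variance weights `beta_exp^2 / se_out^2` and bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.349) * n^(-1/5)`; consistent when the
#' largest group of instruments with similar ratios is valid. The point
#' estimate refines the 512-point grid argmax by golden-section search;
#' bootstrap replicates use the grid argmax. If all ratios are identical the
#' common ratio is returned (zero bandwidth), still with a bootstrap SE.
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth inflation factor (default 1).
#' @return an `mr_estimate` (method `"weighted_mode"`).
#' @export
mr_weighted_mode <- function(data, phi = 1, n_boot = 1000, seed = NULL,
                             binary = FALSE) {
  stopifnot(inherits(data, "harmonized_data"))
  if (data$n_snp < 3L) stop("mr_weighted_mode requires at least 3 SNPs")
  rw <- .ratio_weights(data)
  beta <- .weighted_mode_est(rw$r, rw$w, phi)
  boot <- .parametric_boot(data, n_boot, seed, function(bx, by) {
    .weighted_mode_est(by / bx, bx^2 / data$se_out^2, phi, refine = FALSE)
  })
  new_mr_estimate("weighted_mode", beta, stats::sd(boot), data$n_snp,
                  binary = binary, n_boot = n_boot, phi = phi)
}
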