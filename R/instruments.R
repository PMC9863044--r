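#' Instrument-selection configuration
#'
#' Thresholds for the instrument-selection funnel applied to each exposure:
#' locus-wide significance on the exposure association, greedy LD clumping,
#' minor-allele-frequency filter, instrument-strength (F) filter, confounder
#' blocklist, and exclusion of SNPs associated with the outcome.
#'
#' @param p_exposure_max locus-wide significance threshold (default 1e-5).
#' @param clump_r2_max maximum pairwise r-squared retained by clumping
#'   (default 0.001).
#' @param clump_window_kb clumping window in kilobases, inclusive
#'   (default 10,000).
#' @param maf_min minimum minor-allele frequency, `maf = min(eaf, 1 - eaf)`
#'   (default 0.01).
#' @param f_min minimum F statistic (default 10).
#' @param p_outcome_exclude SNPs with outcome p-value below this are excluded
#'   as potentially outcome-associated (default 0.05; set to 0 to disable).
#' @param blocklist character vector of SNP ids tied to known confounders.
#' @param f_mode `"per_snp"` (default) drops individual SNPs with
#'   single-variant F < `f_min` (K = 1); `"set"` rejects the whole set when
#'   the aggregate F over survivors is below `f_min`.
#' @param f_formula `"standard"` uses R^2/(1 - R^2); `"as_printed"` uses the
#'   (sign-flipped) form R^2/(R^2 - 1) sometimes seen in print.
#' @return object of class `instrument_filter_config`.
#' @export
instrument_filter_config <- function(p_exposure_max = 1e-5, clump_r2_max = 0.001,
                                     clump_window_kb = 10000, maf_min = 0.01,
                                     f_min = 10, p_outcome_exclude = 0.05,
                                     blocklist = character(),
                                     f_mode = c("per_snp", "set"),
                                     f_formula = c("standard", "as_printed")) {
  if (p_exposure_max <= 0 || clump_window_kb <= 0 || maf_min <= 0 || f_min <= 0) {
    stop("thresholds must be positive")
  }
  if (clump_r2_max <= 0 || clump_r2_max > 1) stop("clump_r2_max must be in (0,1]")
  if (p_outcome_exclude < 0 || p_outcome_exclude > 1) stop("p_outcome_exclude outside [0,1]")
  structure(list(p_exposure_max = p_exposure_max, clump_r2_max = clump_r2_max,
                 clump_window_kb = clump_window_kb, maf_min = maf_min,
                 f_min = f_min, p_outcome_exclude = p_outcome_exclude,
                 blocklist = as.character(blocklist),
                 f_mode = match.arg(f_mode), f_formula = match.arg(f_formula)),
            class = "instrument_filter_config")
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by chromosome,
#' position, then SNP id), repeatedly takes the most significant remaining
#' SNP as index, and removes every remaining SNP on the same chromosome
#' within `window_kb` (inclusive, both ends) whose r-squared with the index
#' exceeds `r2_max`. Every retained same-chromosome pair within the window
#' therefore has r-squared at or below `r2_max`. A pair whose r-squared is
#' `NA` in the lookup ("unknown") keeps both SNPs.
#'
#' @param candidates non-empty canonical summary-stat data.frame.
#' @param ld an [ld_lookup()] (NULL = all pairs unlinked).
#' @param window_kb window in kilobases.
#' @param r2_max r-squared threshold.
#' @return retained rows, sorted by (p, chr, pos, snp); independent of the
#'   input row order.
#' @export
ld_clump <- function(candidates, ld = NULL, window_kb = 10000, r2_max = 0.001) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) stop("ld_clump requires at least one candidate")
  ord <- order(candidates$p, candidates$chr, candidates$pos, candidates$snp)
  cand <- candidates[ord, , drop = FALSE]
  n <- nrow(cand)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  win_bp <- window_kb * 1000
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    later <- which(alive)
    if (length(later) == 0L) break
    near <- later[cand$chr[later] == cand$chr[i] &
                  abs(cand$pos[later] - cand$pos[i]) <= win_bp]
    if (length(near) > 0L) {
      r2 <- ld_r2(ld, cand$snp[i], cand$snp[near])
      drop <- !is.na(r2) & r2 > r2_max
      alive[near[drop]] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained
#'
#' Standardized-trait approximation: `2 * maf * (1 - maf) * beta^2` with
#' `maf = min(eaf, 1 - eaf)`.
#'
#' @param beta per-allele effect.
#' @param eaf effect-allele frequency.
#' @export
snp_variance_explained <- function(beta, eaf) {
  maf <- pmin(eaf, 1 - eaf)
  2 * maf * (1 - maf) * beta^2
}

#' Instrument-strength F statistic
#'
#' `F = (R2 / (1 - R2)) * ((N - K - 1) / K)` where `R2` is the variance in
#' the exposure explained by the `K` instruments and `N` the exposure sample
#' size. `formula = "as_printed"` computes the sign-flipped variant
#' `R2 / (R2 - 1)` occasionally seen in print (negative for R2 < 1); it is
#' provided for comparison only.
#'
#' @param r2_total variance explained, in \[0, 1).
#' @param n exposure sample size; must exceed `k + 1`.
#' @param k number of instruments (>= 1).
#' @param formula `"standard"` or `"as_printed"`.
#' @return the F statistic.
#' @export
compute_f_statistic <- function(r2_total, n, k, formula = c("standard", "as_printed")) {
  formula <- match.arg(formula)
  if (any(r2_total < 0 | r2_total >= 1)) stop("r2_total must be in [0, 1)")
  if (any(k < 1)) stop("k must be >= 1")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  denom <- if (formula == "standard") 1 - r2_total else r2_total - 1
  (r2_total / denom) * ((n - k - 1) / k)
}

#' Select instrumental variables for one exposure
#'
#' Applies the selection funnel in order: (1) exposure p-value at or below
#' `p_exposure_max`; (2) greedy LD clumping; (3) drop minor-allele frequency
#' below `maf_min`; (4) instrument-strength filter (per-SNP F with K = 1 by
#' default, or whole-set rejection with `f_mode = "set"`); (5) drop
#' blocklisted SNPs; (6) drop SNPs absent from the outcome table (reason
#' "missing in outcome") or with outcome p-value below `p_outcome_exclude`.
#' Zero survivors at any stage yields an empty set flagged `no_instruments`,
#' never an error.
#'
#' @param exposure_rows non-empty canonical summary-stat data.frame.
#' @param outcome_rows canonical summary-stat data.frame for the outcome.
#' @param ld an [ld_lookup()] or NULL.
#' @param config an [instrument_filter_config()].
#' @param exposure_id,rank labels carried into the result (rank is one of
#'   genus/family/order/class/phylum).
#' @return object of class `instrument_set`: `rows` (selected SNPs, clump
#'   order), `funnel` (named counts: candidates, after_clump, after_maf,
#'   after_f, after_blocklist, after_outcome), `f_statistic` (aggregate F
#'   over the final set, NA when undefined), `f_per_snp`, `log` (dropped
#'   SNPs with stage and reason), `no_instruments` flag.
#' @export
select_instruments <- function(exposure_rows, outcome_rows, ld = NULL,
                               config = instrument_filter_config(),
                               exposure_id = NA_character_,
                               rank = NA_character_) {
  stopifnot(is.data.frame(exposure_rows), inherits(config, "instrument_filter_config"))
  if (nrow(exposure_rows) == 0L) stop("exposure_rows must be non-empty")

  log <- data.frame(snp = character(), stage = character(), reason = character(),
                    stringsAsFactors = FALSE)
  note <- function(snps, stage, reason) {
    if (length(snps) > 0L) {
      log <<- rbind(log, data.frame(snp = snps, stage = stage, reason = reason,
                                    stringsAsFactors = FALSE))
    }
  }

  cur <- exposure_rows[exposure_rows$p <= config$p_exposure_max, , drop = FALSE]
  funnel <- c(candidates = nrow(cur))

  if (nrow(cur) > 0L) {
    kept <- ld_clump(cur, ld, config$clump_window_kb, config$clump_r2_max)
    note(setdiff(cur$snp, kept$snp), "clump", "in LD with a more significant SNP")
    cur <- kept
  }
  funnel <- c(funnel, after_clump = nrow(cur))

  if (nrow(cur) > 0L) {
    maf <- pmin(cur$eaf, 1 - cur$eaf)
    note(cur$snp[maf < config$maf_min], "maf", "MAF below threshold")
    cur <- cur[maf >= config$maf_min, , drop = FALSE]
  }
  funnel <- c(funnel, after_maf = nrow(cur))

  if (nrow(cur) > 0L) {
    r2_snp <- snp_variance_explained(cur$beta, cur$eaf)
    f_snp <- ifelse(r2_snp >= 1, Inf,
                    vapply(seq_len(nrow(cur)), function(i) {
                      compute_f_statistic(min(r2_snp[i], 1 - 1e-15), cur$n[i], 1L,
                                          config$f_formula)
                    }, numeric(1L)))
    if (config$f_mode == "per_snp") {
      weak <- f_snp < config$f_min
      note(cur$snp[weak], "f", "per-SNP F below threshold")
      cur <- cur[!weak, , drop = FALSE]
    } else {
      r2_tot <- sum(r2_snp)
      n_use <- max(cur$n)
      f_set <- if (r2_tot < 1 && n_use > nrow(cur) + 1) {
        compute_f_statistic(r2_tot, n_use, nrow(cur), config$f_formula)
      } else Inf
      if (f_set < config$f_min) {
        note(cur$snp, "f", "set-level F below threshold")
        cur <- cur[0L, , drop = FALSE]
      }
    }
  }
  funnel <- c(funnel, after_f = nrow(cur))

  if (nrow(cur) > 0L) {
    blocked <- cur$snp %in% config$blocklist
    note(cur$snp[blocked], "blocklist", "possible confounder association")
    cur <- cur[!blocked, , drop = FALSE]
  }
  funnel <- c(funnel, after_blocklist = nrow(cur))

  if (nrow(cur) > 0L) {
    idx <- match(cur$snp, outcome_rows$snp)
    missing <- is.na(idx)
    note(cur$snp[missing], "outcome", "missing in outcome")
    assoc <- !missing & outcome_rows$p[idx] < config$p_outcome_exclude
    note(cur$snp[assoc], "outcome", "associated with outcome")
    cur <- cur[!missing & !assoc, , drop = FALSE]
  }
  funnel <- c(funnel, after_outcome = nrow(cur))

  f_stat <- NA_real_
  f_per_snp <- numeric(0)
  if (nrow(cur) > 0L) {
    r2_snp <- snp_variance_explained(cur$beta, cur$eaf)
    f_per_snp <- ifelse(r2_snp >= 1, Inf,
                        (r2_snp / (1 - r2_snp)) * (cur$n - 2))
    r2_tot <- sum(r2_snp)
    n_use <- max(cur$n)
    if (r2_tot < 1 && n_use > nrow(cur) + 1) {
      f_stat <- compute_f_statistic(r2_tot, n_use, nrow(cur), config$f_formula)
    }
  }
  rownames(cur) <- NULL
  structure(list(exposure_id = exposure_id, rank = rank, rows = cur,
                 f_statistic = f_stat, f_per_snp = f_per_snp,
                 funnel = funnel, log = log,
                 no_instruments = nrow(cur) == 0L),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set", if (!is.na(x$exposure_id)) paste0("for ", x$exposure_id), "\n")
  cat("  funnel:", paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = ", "), "\n")
  cat(sprintf("  final: %d SNP(s), set-level F = %s\n", nrow(x$rows),
              format(x$f_statistic, digits = 4)))
  invisible(x)
}

#' Write a selection-funnel log
#'
#' Emits a TSV with one line per funnel stage (stage, retained, dropped) for
#' one or more instrument sets.
#'
#' @param sets a single `instrument_set` or a list of them.
#' @param path output path.
#' @export
write_funnel <- function(sets, path) {
  if (inherits(sets, "instrument_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(s) {
    f <- s$funnel
    data.frame(exposure = s$exposure_id, stage = names(f), retained = unname(f),
               dropped = c(NA_integer_, -diff(unname(f))),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
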