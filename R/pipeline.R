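#' Rank-specific multiplicity configuration
#'
#' Bonferroni correction is applied within each taxonomic rank, dividing the
#' family-wise level by the number of taxa analysed at that rank (defaults:
#' 131 genera, 35 families, 20 orders, 16 classes, 9 phyla). A p-value
#' between the corrected threshold and `nominal_alpha` is a *nominal* causal
#' signal; below the threshold it is *strong*.
#'
#' @param family_alpha family-wise level (default 0.05).
#' @param taxa_per_rank named counts of taxa per rank.
#' @param nominal_alpha nominal level (default 0.05).
#' @return object of class `multiplicity_config`.
#' @export
multiplicity_config <- function(family_alpha = 0.05,
                                taxa_per_rank = c(genus = 131, family = 35,
                                                  order = 20, class = 16,
                                                  phylum = 9),
                                nominal_alpha = 0.05) {
  if (family_alpha <= 0 || family_alpha >= 1) stop("family_alpha outside (0,1)")
  if (nominal_alpha <= 0 || nominal_alpha >= 1) stop("nominal_alpha outside (0,1)")
  if (any(taxa_per_rank <= 0)) stop("taxa counts must be positive")
  structure(list(family_alpha = family_alpha, taxa_per_rank = taxa_per_rank,
                 nominal_alpha = nominal_alpha),
            class = "multiplicity_config")
}

#' Rank-specific Bonferroni threshold
#'
#' @param rank one of the ranks in `config$taxa_per_rank`.
#' @param config a [multiplicity_config()].
#' @return `family_alpha / taxa_per_rank[rank]`.
#' @export
bonferroni_threshold <- function(rank, config = multiplicity_config()) {
  stopifnot(inherits(config, "multiplicity_config"))
  if (!rank %in% names(config$taxa_per_rank)) stop("unknown rank: ", rank)
  unname(config$family_alpha / config$taxa_per_rank[[rank]])
}

#' Classify a causal signal as strong, nominal, or none
#'
#' `strong` when p is below the rank-specific Bonferroni threshold,
#' `nominal` when between the threshold and `nominal_alpha`, `none`
#' otherwise.
#'
#' @param pvalue p-value in (0, 1].
#' @param rank taxonomic rank of the exposure.
#' @param config a [multiplicity_config()].
#' @return `"strong"`, `"nominal"`, or `"none"`.
#' @export
classify_significance <- function(pvalue, rank, config = multiplicity_config()) {
  stopifnot(pvalue > 0, pvalue <= 1)
  thr <- bonferroni_threshold(rank, config)
  if (pvalue < thr) "strong"
  else if (pvalue < config$nominal_alpha) "nominal"
  else "none"
}

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

#' Run the full analysis for one exposure-outcome pair
#'
#' Executes the whole pipeline: instrument selection, harmonization, all
#' estimators (Wald when a single SNP survives; both IVW models always;
#' MR-Egger, weighted median and weighted mode with three or more SNPs),
#' all diagnostics (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out,
#' subject to their minimum SNP counts), and significance classification on
#' the primary (multiplicative random-effects) IVW p-value. An empty
#' instrument set yields a report with tier "none" and the reason recorded;
#' statistical insufficiency is recorded in-report, never thrown.
#'
#' @param exposure_rows,outcome_rows canonical summary-stat data.frames.
#' @param ld an [ld_lookup()] or NULL.
#' @param filter_config an [instrument_filter_config()].
#' @param mult_config a [multiplicity_config()].
#' @param exposure_id,rank,outcome_id labels for the report.
#' @param binary is the outcome binary (attaches odds-ratio scales)?
#' @param n_boot bootstrap replicates for median/mode estimators.
#' @param seed integer seed governing all stochastic steps (bootstraps,
#'   MR-PRESSO); sub-seeds are derived by fixed offsets.
#' @param reverse also run the reverse-direction analysis (outcome as
#'   exposure) and attach its primary IVW estimate.
#' @param reverse_p_exposure_max instrument p-threshold for the reverse
#'   direction (default genome-wide 5e-8; disease GWAS are well powered).
#' @return object of class `mr_report`.
#' @export
run_pair <- function(exposure_rows, outcome_rows, ld = NULL,
                     filter_config = instrument_filter_config(),
                     mult_config = multiplicity_config(),
                     exposure_id = "exposure", rank = "genus",
                     outcome_id = "outcome", binary = FALSE,
                     n_boot = 1000, seed = 1L, reverse = FALSE,
                     reverse_p_exposure_max = 5e-8) {
  sel <- select_instruments(exposure_rows, outcome_rows, ld, filter_config,
                            exposure_id = exposure_id, rank = rank)
  report <- structure(list(exposure_id = exposure_id, rank = rank,
                           outcome_id = outcome_id, binary = binary,
                           instruments = sel, funnel = sel$funnel,
                           n_snp = 0L, harmonization = NULL,
                           estimates = list(), diagnostics = list(),
                           tier = "none", reason = NA_character_,
                           reverse = NULL, seed = seed),
                      class = "mr_report")
  if (sel$no_instruments) {
    report$reason <- "no instruments"
    return(report)
  }
  harm <- harmonize(sel$rows, outcome_rows)
  report$harmonization <- harm$log
  report$n_snp <- harm$n_snp
  if (harm$n_snp == 0L) {
    report$reason <- "no SNPs after harmonization"
    return(report)
  }

  est <- list()
  if (harm$n_snp == 1L) {
    est$wald <- wald_ratio(harm$beta_exp, harm$se_exp, harm$beta_out,
                           harm$se_out, binary = binary)
  }
  est$ivw_re <- mr_ivw(harm, "random", binary = binary)
  est$ivw_fe <- mr_ivw(harm, "fixed", binary = binary)
  if (harm$n_snp >= 3L) {
    est$egger <- mr_egger(harm, binary = binary)
    est$weighted_median <- mr_weighted_median(harm, n_boot = n_boot,
                                              seed = .derive_seed(seed, 1L),
                                              binary = binary)
    est$weighted_mode <- mr_weighted_mode(harm, n_boot = n_boot,
                                          seed = .derive_seed(seed, 2L),
                                          binary = binary)
  }
  report$estimates <- est

  diag <- list()
  if (harm$n_snp >= 2L) diag$q <- cochran_q(harm)
  if (harm$n_snp >= 3L) {
    diag$egger_intercept <- egger_intercept_test(harm)
    diag$loo <- leave_one_out(harm)
  }
  if (harm$n_snp >= 4L) {
    diag$presso <- mr_presso(harm, seed = .derive_seed(seed, 3L))
  }
  report$diagnostics <- diag
  report$tier <- classify_significance(est$ivw_re$pvalue, rank, mult_config)

  if (reverse) {
    report$reverse <- reverse_mr(outcome_rows, exposure_rows, ld,
                                 filter_config = filter_config,
                                 p_exposure_max = reverse_p_exposure_max,
                                 seed = .derive_seed(seed, 4L))
  }
  report
}

#' Reverse-direction Mendelian randomization
#'
#' Swaps the roles of exposure and outcome (e.g. does kidney disease shift
#' the taxon's abundance?) and runs the identical selection funnel and the
#' primary multiplicative random-effects IVW. Instruments for the reverse
#' direction default to genome-wide significance (5e-8) since disease GWAS
#' are typically well powered; pass `p_exposure_max = NULL` to keep the
#' forward threshold, in which case swapping twice reproduces the forward
#' analysis.
#'
#' @param outcome_rows_as_exposure summary stats of the original outcome,
#'   now instrumented as the exposure.
#' @param exposure_rows_as_outcome summary stats of the original exposure,
#'   now the outcome.
#' @param ld an [ld_lookup()] or NULL.
#' @param filter_config an [instrument_filter_config()]; its
#'   `p_exposure_max` is overridden by the argument below unless NULL.
#' @param p_exposure_max reverse instrument threshold (default 5e-8).
#' @param seed integer seed (unused by IVW itself; kept for interface
#'   symmetry and future stochastic additions).
#' @return list with `estimate` (primary IVW `mr_estimate`, or NULL),
#'   `n_snp`, `funnel`, and `reason` (NA on success).
#' @export
reverse_mr <- function(outcome_rows_as_exposure, exposure_rows_as_outcome,
                       ld = NULL, filter_config = instrument_filter_config(),
                       p_exposure_max = 5e-8, seed = 1L) {
  cfg <- filter_config
  if (!is.null(p_exposure_max)) cfg$p_exposure_max <- p_exposure_max
  sel <- select_instruments(outcome_rows_as_exposure, exposure_rows_as_outcome,
                            ld, cfg)
  if (sel$no_instruments) {
    return(list(estimate = NULL, n_snp = 0L, funnel = sel$funnel,
                reason = "no instruments"))
  }
  harm <- harmonize(sel$rows, exposure_rows_as_outcome)
  if (harm$n_snp == 0L) {
    return(list(estimate = NULL, n_snp = 0L, funnel = sel$funnel,
                reason = "no SNPs after harmonization"))
  }
  list(estimate = mr_ivw(harm, "random"), n_snp = harm$n_snp,
       funnel = sel$funnel, reason = NA_character_)
}

.read_dir_or_list <- function(x) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.tsv$", full.names = TRUE))
    out <- lapply(files, read_sumstats)
    names(out) <- sub("\\.tsv$", "", basename(files))
    out
  } else {
    stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
    x[sort(names(x))]
  }
}

.rank_from_id <- function(id) {
  prefix <- sub("[_.].*$", "", tolower(id))
  if (prefix %in% c("genus", "family", "order", "class", "phylum")) prefix
  else "genus"
}

#' Run the exposure-by-outcome analysis grid
#'
#' Runs [run_pair()] over the Cartesian grid of exposures and outcomes in
#' deterministic order (sorted exposure id, then outcome id). Exposures and
#' outcomes may be given as named lists of canonical summary-stat
#' data.frames or as directories of `.tsv` files. Ranks default to the
#' exposure-id prefix (`genus_...`, `phylum_...`, ...). A malformed pair is
#' skipped with a logged error; the run fails only if every pair fails.
#'
#' @param exposures,outcomes named lists of summary-stat data.frames, or
#'   directory paths.
#' @param ld an [ld_lookup()] or NULL.
#' @param filter_config an [instrument_filter_config()].
#' @param mult_config a [multiplicity_config()].
#' @param ranks optional named character vector mapping exposure id to rank.
#' @param binary_outcomes character vector of outcome ids treated as binary.
#' @param n_boot bootstrap replicates per pair.
#' @param seed integer seed; each pair gets a derived sub-seed.
#' @param reverse run the reverse direction for every pair.
#' @return list with `reports` (named `"exposure|outcome"`), `summary`
#'   (data.frame of tier counts per outcome) and `errors` (named character
#'   vector of skipped pairs).
#' @export
run_grid <- function(exposures, outcomes, ld = NULL,
                     filter_config = instrument_filter_config(),
                     mult_config = multiplicity_config(),
                     ranks = NULL, binary_outcomes = character(),
                     n_boot = 1000, seed = 1L, reverse = FALSE) {
  exp_list <- .read_dir_or_list(exposures)
  out_list <- .read_dir_or_list(outcomes)
  if (length(exp_list) == 0L || length(out_list) == 0L) {
    stop("need at least one exposure and one outcome")
  }
  reports <- list()
  errors <- character()
  i <- 0L
  for (eid in names(exp_list)) {
    rank <- if (!is.null(ranks) && eid %in% names(ranks)) ranks[[eid]]
            else .rank_from_id(eid)
    for (oid in names(out_list)) {
      i <- i + 1L
      key <- paste(eid, oid, sep = "|")
      rep_i <- tryCatch(
        run_pair(exp_list[[eid]], out_list[[oid]], ld,
                 filter_config = filter_config, mult_config = mult_config,
                 exposure_id = eid, rank = rank, outcome_id = oid,
                 binary = oid %in% binary_outcomes, n_boot = n_boot,
                 seed = .derive_seed(seed, i), reverse = reverse),
        error = function(e) conditionMessage(e))
      if (is.character(rep_i)) errors[key] <- rep_i else reports[[key]] <- rep_i
    }
  }
  if (length(reports) == 0L) {
    stop("all pairs failed; first error: ", errors[1])
  }
  tiers <- vapply(reports, `[[`, character(1L), "tier")
  oids <- vapply(reports, `[[`, character(1L), "outcome_id")
  summary <- do.call(rbind, lapply(sort(unique(oids)), function(o) {
    data.frame(outcome = o,
               strong = sum(tiers[oids == o] == "strong"),
               nominal = sum(tiers[oids == o] == "nominal"),
               none = sum(tiers[oids == o] == "none"),
               stringsAsFactors = FALSE)
  }))
  list(reports = reports, summary = summary, errors = errors)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR report: %s (%s) -> %s\n", x$exposure_id, x$rank, x$outcome_id))
  cat("  funnel:", paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = ", "), "\n")
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  for (e in x$estimates) print(e)
  if (!is.null(x$diagnostics$q)) print(x$diagnostics$q)
  cat("  tier:", x$tier, "\n")
  invisible(x)
}

.fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.estimate_rows <- function(report) {
  do.call(rbind, lapply(report$estimates, function(e) {
    data.frame(exposure = report$exposure_id, rank = report$rank,
               outcome = report$outcome_id, method = e$method,
               nsnp = e$n_snp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$pvalue,
               or = if (is.null(e$or)) NA_real_ else e$or,
               or_ci_low = if (is.null(e$or_ci_low)) NA_real_ else e$or_ci_low,
               or_ci_high = if (is.null(e$or_ci_high)) NA_real_ else e$or_ci_high,
               stringsAsFactors = FALSE)
  }))
}

.diag_row <- function(report) {
  d <- report$diagnostics
  data.frame(
    exposure = report$exposure_id, rank = report$rank,
    outcome = report$outcome_id, nsnp = report$n_snp, tier = report$tier,
    q = if (is.null(d$q)) NA_real_ else d$q$q,
    q_df = if (is.null(d$q)) NA_integer_ else d$q$df,
    q_p = if (is.null(d$q)) NA_real_ else d$q$pvalue,
    egger_intercept = if (is.null(d$egger_intercept)) NA_real_ else d$egger_intercept$intercept,
    egger_intercept_p = if (is.null(d$egger_intercept)) NA_real_ else d$egger_intercept$pvalue,
    presso_global_p = if (is.null(d$presso)) NA_real_ else d$presso$global_p,
    presso_outliers = if (is.null(d$presso)) "" else paste(d$presso$outlier_snps, collapse = ","),
    loo_dominant_snps = if (is.null(d$loo)) "" else paste(d$loo$snp[d$loo$dominant_snp], collapse = ","),
    reverse_p = if (is.null(report$reverse) || is.null(report$reverse$estimate)) {
      NA_real_
    } else report$reverse$estimate$pvalue,
    stringsAsFactors = FALSE)
}

#' Write analysis reports to disk
#'
#' Emits three files under `dir`: `estimates.tsv` (one row per pair and
#' method, with diagnostics joined per pair), `tier_summary.tsv` (tier
#' counts per outcome), and `forest.txt` (a plain-text forest table —
#' method, nsnp, estimate \[CI\], p — for every pair whose tier is not
#' "none"; header only when there are none). Numerics are written with 17
#' significant digits.
#'
#' @param reports a single `mr_report`, or a list of them (e.g.
#'   `run_grid()$reports`).
#' @param dir output directory (created if absent).
#' @return named character vector of the three paths, invisibly.
#' @export
write_report <- function(reports, dir) {
  if (inherits(reports, "mr_report")) reports <- list(reports)
  stopifnot(length(reports) > 0L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  est <- do.call(rbind, lapply(reports, .estimate_rows))
  diag <- do.call(rbind, lapply(reports, .diag_row))
  if (is.null(est)) {
    est <- data.frame(exposure = character(), rank = character(),
                      outcome = character(), method = character(),
                      nsnp = integer(), beta = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(), p = numeric(),
                      or = numeric(), or_ci_low = numeric(),
                      or_ci_high = numeric())
  } else {
    est <- merge(est, diag, by = c("exposure", "rank", "outcome"), sort = TRUE)
  }
  est_path <- file.path(dir, "estimates.tsv")
  num_cols <- vapply(est, is.numeric, logical(1L)) &
    !vapply(est, is.integer, logical(1L))
  est_out <- est
  for (cl in names(est)[num_cols]) est_out[[cl]] <- .fmt17(est[[cl]])
  utils::write.table(est_out, est_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tiers <- vapply(reports, `[[`, character(1L), "tier")
  oids <- vapply(reports, `[[`, character(1L), "outcome_id")
  summary <- do.call(rbind, lapply(sort(unique(oids)), function(o) {
    data.frame(outcome = o, strong = sum(tiers[oids == o] == "strong"),
               nominal = sum(tiers[oids == o] == "nominal"),
               none = sum(tiers[oids == o] == "none"))
  }))
  sum_path <- file.path(dir, "tier_summary.tsv")
  utils::write.table(summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  forest_path <- file.path(dir, "forest.txt")
  lines <- sprintf("%-46s %-16s %5s %24s %10s", "exposure -> outcome", "method",
                   "nsnp", "estimate [95% CI]", "p")
  for (r in reports) {
    if (r$tier == "none") next
    for (e in r$estimates) {
      lines <- c(lines, sprintf(
        "%-46s %-16s %5d %24s %10.3g",
        paste(r$exposure_id, "->", r$outcome_id), e$method, e$n_snp,
        sprintf("%.4g [%.4g, %.4g]", e$beta, e$ci_low, e$ci_high), e$pvalue))
    }
  }
  writeLines(lines, forest_path)
  invisible(c(estimates = est_path, tier_summary = sum_path,
              forest = forest_path))
}
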