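#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs cannot be strand-resolved from the alleles alone.
#'
#' @param effect_allele,other_allele character vectors of A/C/G/T alleles.
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(as.character(effect_allele))
  oa <- toupper(as.character(other_allele))
  if (any(!(ea %in% .valid_alleles)) || any(!(oa %in% .valid_alleles))) {
    stop("alleles must be one of A/C/G/T")
  }
  if (any(ea == oa)) stop("identical effect and other allele")
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a harmonized dataset directly
#'
#' Container for aligned per-SNP effect/SE vectors after harmonization to a
#' common effect allele; all estimators and diagnostics consume this type.
#'
#' @param snp SNP identifiers.
#' @param beta_exp,se_exp exposure effects and standard errors.
#' @param beta_out,se_out outcome effects and standard errors.
#' @param log optional per-SNP action log data.frame.
#' @return object of class `harmonized_data` with an `n_snp` field.
#' @export
harmonized_data <- function(snp, beta_exp, se_exp, beta_out, se_out, log = NULL) {
  k <- length(snp)
  stopifnot(length(beta_exp) == k, length(se_exp) == k,
            length(beta_out) == k, length(se_out) == k)
  if (any(se_exp <= 0) || any(se_out <= 0)) stop("standard errors must be > 0")
  if (is.null(log)) {
    log <- data.frame(snp = as.character(snp), action = rep("kept", k),
                      detail = rep("", k), stringsAsFactors = FALSE)
  }
  structure(list(snp = as.character(snp), beta_exp = as.numeric(beta_exp),
                 se_exp = as.numeric(se_exp), beta_out = as.numeric(beta_out),
                 se_out = as.numeric(se_out), n_snp = k, log = log),
            class = "harmonized_data")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each exposure SNP's outcome record to the exposure effect allele.
#' Per SNP: absent from the outcome table = `removed:missing`; palindromic
#' (A/T or C/G) = `removed:palindrome` (removed unconditionally, no
#' frequency-based strand inference); same allele pair = `kept`; swapped
#' alleles = outcome beta negated and eaf complemented, `sign-flipped`; any
#' other pair = `removed:mismatch` unless `resolve_complements = TRUE`, in
#' which case strand-complement matches (and complement-swaps) are recovered.
#' Output order follows the exposure input.
#'
#' @param exposure_rows,outcome_rows canonical summary-stat data.frames keyed
#'   by `snp` (duplicate ids are an error).
#' @param resolve_complements opt-in recovery of non-palindromic strand flips
#'   (default FALSE: treated as mismatch).
#' @return a [harmonized_data()] whose `log` records one action per exposure
#'   SNP (kept / sign-flipped / removed:palindrome / removed:mismatch /
#'   removed:missing).
#' @export
harmonize <- function(exposure_rows, outcome_rows, resolve_complements = FALSE) {
  stopifnot(is.data.frame(exposure_rows), is.data.frame(outcome_rows))
  if (anyDuplicated(exposure_rows$snp)) stop("duplicate snp id in exposure rows")
  if (anyDuplicated(outcome_rows$snp)) stop("duplicate snp id in outcome rows")

  k <- nrow(exposure_rows)
  idx <- match(exposure_rows$snp, outcome_rows$snp)
  action <- character(k)
  detail <- character(k)

  e_ea <- exposure_rows$ea; e_oa <- exposure_rows$oa
  o_ea <- outcome_rows$ea[idx]; o_oa <- outcome_rows$oa[idx]
  beta_out <- outcome_rows$beta[idx]
  se_out <- outcome_rows$se[idx]

  missing <- is.na(idx)
  # palindromic exposure alleles are removed whatever the outcome record says,
  # but a SNP absent from the outcome is logged as missing first
  pal <- !missing & is_palindromic(e_ea, e_oa)
  same <- !missing & !pal & o_ea == e_ea & o_oa == e_oa
  swap <- !missing & !pal & o_ea == e_oa & o_oa == e_ea
  comp_same <- comp_swap <- rep(FALSE, k)
  if (resolve_complements) {
    ce <- unname(.complement[e_ea]); co <- unname(.complement[e_oa])
    comp_same <- !missing & !pal & !same & !swap & o_ea == ce & o_oa == co
    comp_swap <- !missing & !pal & !same & !swap & o_ea == co & o_oa == ce
  }
  mismatch <- !missing & !pal & !same & !swap & !comp_same & !comp_swap

  action[missing] <- "removed:missing"
  action[pal] <- "removed:palindrome"
  action[same | comp_same] <- "kept"
  action[swap | comp_swap] <- "sign-flipped"
  action[mismatch] <- "removed:mismatch"
  detail[pal] <- paste0(e_ea[pal], "/", e_oa[pal])
  detail[mismatch] <- paste0("exposure ", e_ea[mismatch], "/", e_oa[mismatch],
                             " vs outcome ", o_ea[mismatch], "/", o_oa[mismatch])
  flip <- swap | comp_swap
  beta_out[flip] <- -beta_out[flip]

  keep <- action %in% c("kept", "sign-flipped")
  log <- data.frame(snp = exposure_rows$snp, action = action, detail = detail,
                    stringsAsFactors = FALSE)
  harmonized_data(exposure_rows$snp[keep],
                  exposure_rows$beta[keep], exposure_rows$se[keep],
                  beta_out[keep], se_out[keep], log = log)
}

#' Subset a harmonized dataset
#'
#' @param data a `harmonized_data`.
#' @param idx integer or logical index over SNPs.
#' @export
subset_harmonized <- function(data, idx) {
  stopifnot(inherits(data, "harmonized_data"))
  harmonized_data(data$snp[idx], data$beta_exp[idx], data$se_exp[idx],
                  data$beta_out[idx], data$se_out[idx])
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("Harmonized dataset: %d SNP(s)\n", x$n_snp))
  acts <- table(x$log$action)
  cat("  actions:", paste(sprintf("%s=%d", names(acts), acts), collapse = ", "), "\n")
  invisible(x)
}
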