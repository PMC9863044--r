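#' Canonical summary-statistic column names
#'
#' The tab-separated dialect used throughout the package: `snp` (rsID-style
#' identifier), `chr` (chromosome label), `pos` (1-based base-pair position),
#' `ea`/`oa` (effect and other allele, A/C/G/T), `eaf` (effect-allele
#' frequency), `beta` (per-allele effect; log-odds for binary traits), `se`
#' (standard error), `p` (two-sided p-value), `n` (sample size).
#'
#' @export
sumstat_columns <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

.valid_alleles <- c("A", "C", "G", "T")

#' Validate rows of a GWAS summary-statistic table
#'
#' Applies the per-row invariants (alleles in A/C/G/T and distinct, `eaf` in
#' \[0,1\], `se > 0`, `p` in (0,1\], `pos >= 1`, `n >= 1`, parseable numerics)
#' and splits the input into valid rows and a drop log. Validation is total:
#' every input row either survives or appears in the log with a reason.
#'
#' @param df data.frame with the canonical columns (character or numeric).
#' @return list with `rows` (validated data.frame, canonical types, input
#'   order preserved) and `dropped` (data.frame with `row`, `snp`, `reason`).
#' @export
validate_sumstats <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(sumstat_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, sumstat_columns, drop = FALSE]
  n_in <- nrow(df)
  reason <- rep(NA_character_, n_in)

  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  pos  <- num(df$pos);  eaf <- num(df$eaf); beta <- num(df$beta)
  se   <- num(df$se);   p   <- num(df$p);   n    <- num(df$n)
  ea <- toupper(trimws(as.character(df$ea)))
  oa <- toupper(trimws(as.character(df$oa)))
  snp <- trimws(as.character(df$snp))
  chr <- trimws(as.character(df$chr))

  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  flag(snp == "" | is.na(df$snp), "empty snp id")
  flag(chr == "" | is.na(df$chr), "empty chromosome")
  flag(is.na(pos) | pos < 1 | pos != floor(pos), "invalid position")
  flag(!(ea %in% .valid_alleles), "invalid effect allele")
  flag(!(oa %in% .valid_alleles), "invalid other allele")
  flag(ea == oa, "identical alleles")
  flag(is.na(eaf) | eaf < 0 | eaf > 1, "eaf outside [0,1]")
  flag(is.na(beta) | !is.finite(beta), "unparseable beta")
  flag(is.na(se) | !is.finite(se) | se <= 0, "se not > 0")
  flag(is.na(p) | p <= 0 | p > 1, "p outside (0,1]")
  flag(is.na(n) | n < 1, "n < 1")

  keep <- is.na(reason)
  rows <- data.frame(
    snp = snp[keep], chr = chr[keep], pos = as.integer(pos[keep]),
    ea = ea[keep], oa = oa[keep], eaf = eaf[keep], beta = beta[keep],
    se = se[keep], p = p[keep], n = n[keep],
    stringsAsFactors = FALSE
  )
  dropped <- data.frame(
    row = which(!keep), snp = snp[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(rows) + nrow(dropped) == n_in)
  list(rows = rows, dropped = dropped)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table with one header line, renames columns to the
#' canonical dialect via `column_map`, and validates every row. The drop log
#' is attached as attribute `"drop_log"` on the returned data.frame.
#'
#' @param path path to a TSV file.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(snp = "rsid", p = "pval")`. Columns
#'   not mentioned are assumed to already carry canonical names.
#' @return data.frame of validated rows in file order, canonical columns,
#'   with attribute `drop_log`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), sumstat_columns)
    if (length(bad) > 0L) stop("unknown canonical name(s) in column_map: ",
                               paste(bad, collapse = ", "))
    for (canon in names(column_map)) {
      foreign <- column_map[[canon]]
      if (!foreign %in% names(df)) {
        stop("mapped column '", foreign, "' not present in ", path)
      }
      names(df)[names(df) == foreign] <- canon
    }
  }
  missing_cols <- setdiff(sumstat_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  v <- validate_sumstats(df)
  if (nrow(v$rows) == 0L) stop("no valid rows in ", path)
  structure(v$rows, drop_log = v$dropped)
}

#' Write a GWAS summary-statistic table
#'
#' Emits the canonical tab-separated dialect. Numerics are written with 17
#' significant digits so that `read_sumstats(write_sumstats(x))` reproduces
#' every double bit-for-bit.
#'
#' @param rows non-empty data.frame with canonical columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("refusing to write an empty summary-statistic table")
  missing_cols <- setdiff(sumstat_columns, names(rows))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  out <- vapply(sumstat_columns, function(cl) fmt(rows[[cl]]), character(nrow(rows)))
  if (nrow(rows) == 1L) out <- matrix(out, nrow = 1L)
  lines <- c(paste(sumstat_columns, collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Construct a pairwise-LD lookup
#'
#' An `ld_lookup` maps unordered SNP-id pairs to squared correlation r-squared.
#' `r2(x, x)` is always 1; a pair absent from the table returns `default_r2`
#' (0 = treat as unlinked, the convention for sparse within-block LD files;
#' `NA` = unknown, which clumping treats as "keep both").
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`, or NULL for an
#'   empty lookup.
#' @param default_r2 value returned for pairs not in the table.
#' @return object of class `ld_lookup`.
#' @export
ld_lookup <- function(pairs = NULL, default_r2 = 0) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
    r2 <- as.numeric(pairs$r2)
    if (any(is.na(r2) | r2 < 0 | r2 > 1)) stop("r2 outside [0,1]")
    a <- as.character(pairs$snp_a); b <- as.character(pairs$snp_b)
    keys <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    for (i in seq_along(keys)) {
      old <- env[[keys[i]]]
      if (!is.null(old) && abs(old - r2[i]) > 1e-9) {
        stop("conflicting duplicate LD entry for pair (", a[i], ", ", b[i], "): ",
             old, " vs ", r2[i])
      }
      env[[keys[i]]] <- r2[i]
    }
  }
  structure(list(env = env, default_r2 = default_r2), class = "ld_lookup")
}

#' Query pairwise r-squared
#'
#' @param ld an `ld_lookup` (NULL is treated as an empty lookup with default 0).
#' @param a,b character vectors of SNP ids (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) ld <- ld_lookup()
  stopifnot(inherits(ld, "ld_lookup"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- rep_len(ld$default_r2, n)
  same <- a == b
  out[same] <- 1
  if (any(!same)) {
    keys <- paste(pmin(a[!same], b[!same]), pmax(a[!same], b[!same]), sep = "\r")
    hit <- mget(keys, envir = ld$env, ifnotfound = list(NULL))
    found <- !vapply(hit, is.null, logical(1L))
    out[!same][found] <- unlist(hit[found])
  }
  out
}

#' Read a pairwise-LD table
#'
#' Expects a tab-separated file with header `snp_a`, `snp_b`, `r2`. Duplicate
#' pairs must agree within 1e-9. An empty file yields a lookup that returns
#' `default_r2` for every non-identical pair.
#'
#' @inheritParams ld_lookup
#' @param path path to the TSV.
#' @export
read_ld <- function(path, default_r2 = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(ld_lookup(NULL, default_r2))
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(ld_lookup(NULL, default_r2))
  ld_lookup(df, default_r2)
}

#' Write a pairwise-LD table
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @param path output path.
#' @export
write_ld <- function(pairs, path) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  df <- data.frame(snp_a = pairs$snp_a, snp_b = pairs$snp_b,
                   r2 = sprintf("%.17g", pairs$r2))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounder SNP blocklist
#'
#' One SNP id per line; `#` starts a comment; blank lines ignored. This file
#' stands in for a manual confounder screen (e.g. a PhenoScanner review of
#' hypertension/diabetes/heart-disease associations) frozen into a static
#' list.
#'
#' @param path path to the blocklist file.
#' @return character vector of SNP ids.
#' @export
read_blocklist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}
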