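#!/usr/bin/env Rscript
# Build the synthetic study data: ten gut-microbiota taxa spanning the five
# taxonomic ranks, each with its own SNP panel, against two kidney outcomes
# (continuous "egfr", binary "ckd"). Two taxa carry true causal effects:
#   class_bacteroidia  -> egfr  (theta = -0.2)
#   genus_coprococcus  -> ckd   (theta = +0.3)
# Everything else is null. Per taxon, the two outcomes are simulated from the
# same seed, so the exposure GWAS is identical across outcomes and only the
# outcome draws differ. SNP ids are prefixed per taxon so the merged outcome
# files behave like one genome-wide GWAS subset to each taxon's instruments.

suppressMessages(library(mbmr))

out_dir <- "results/analysis"
dir.create(file.path(out_dir, "exposures"), showWarnings = FALSE, recursive = TRUE)
dir.create(file.path(out_dir, "outcomes"), showWarnings = FALSE, recursive = TRUE)

taxa <- data.frame(
  id = c("class_bacteroidia", "class_deltaproteobacteria",
         "family_lachnospiraceae", "family_pasteurellaceae",
         "genus_coprococcus", "genus_streptococcus",
         "order_bacteroidales", "order_clostridiales",
         "phylum_actinobacteria", "phylum_bacteroidetes"),
  theta_egfr = c(-0.2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  theta_ckd  = c(0, 0, 0, 0, 0.3, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

rename_snps <- function(df, j) {
  df$snp <- sub("^rs", sprintf("rs%02d", j), df$snp)
  df
}

outcome_rows <- list(egfr = list(), ckd = list())
ld_pairs <- list()
truth_all <- list()

for (j in seq_len(nrow(taxa))) {
  id <- taxa$id[j]
  base <- sim_config(n_instruments = 15, n_null_snps = 35,
                     ld_block_size = if (j <= 2) 3 else 1,
                     seed = 20230100 + j)
  for (oc in c("egfr", "ckd")) {
    cfg <- base
    cfg$theta <- if (oc == "egfr") taxa$theta_egfr[j] else taxa$theta_ckd[j]
    st <- simulate_two_sample(cfg)
    st$exposure <- rename_snps(st$exposure, j)
    st$outcome <- rename_snps(st$outcome, j)
    st$truth <- rename_snps(st$truth, j)
    if (oc == "egfr") {  # exposure identical for both outcomes: write once
      write_sumstats(st$exposure,
                     file.path(out_dir, "exposures", paste0(id, ".tsv")))
      truth_all[[id]] <- cbind(taxon = id, st$truth)
      lp <- mbmr:::.ld_as_df(st$ld)
      if (nrow(lp) > 0) {
        lp$snp_a <- sub("^rs", sprintf("rs%02d", j), lp$snp_a)
        lp$snp_b <- sub("^rs", sprintf("rs%02d", j), lp$snp_b)
        ld_pairs[[id]] <- lp
      }
    }
    outcome_rows[[oc]][[id]] <- st$outcome
  }
}

for (oc in names(outcome_rows)) {
  merged <- do.call(rbind, outcome_rows[[oc]])
  write_sumstats(merged, file.path(out_dir, "outcomes", paste0(oc, ".tsv")))
}
ld_df <- do.call(rbind, ld_pairs)
if (is.null(ld_df)) ld_df <- data.frame(snp_a = character(), snp_b = character(),
                                        r2 = numeric())
write_ld(ld_df, file.path(out_dir, "ld.tsv"))
truth <- do.call(rbind, truth_all)
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# a small confounder blocklist: pretend two instruments of a null taxon were
# flagged in a confounder screen
block <- truth$snp[truth$taxon == "genus_streptococcus" & truth$is_instrument][1:2]
writeLines(c("# synthetic confounder screen hits", block),
           file.path(out_dir, "blocklist.txt"))

cat("Simulated", nrow(taxa), "taxa x 2 outcomes;",
    sum(vapply(outcome_rows$egfr, nrow, integer(1))), "SNPs per outcome file\n")
cat("True effects: class_bacteroidia -> egfr (theta = -0.2),",
    "genus_coprococcus -> ckd (theta = 0.3)\n")
cat("Files under", out_dir, "\n")
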