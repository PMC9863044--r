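#!/usr/bin/env Rscript
# Instrument selection funnel for every taxon against each outcome: locus-wide
# p < 1e-5, LD clumping (r2 0.001 within 10,000 kb), MAF >= 0.01, per-SNP
# F >= 10, confounder blocklist, and exclusion of outcome-associated SNPs
# (outcome p < 0.05). Writes the per-stage funnel table.

suppressMessages(library(mbmr))

dir <- "results/analysis"
exposures <- lapply(
  setNames(nm = sub("\\.tsv$", "", list.files(file.path(dir, "exposures")))),
  function(id) read_sumstats(file.path(dir, "exposures", paste0(id, ".tsv"))))
outcomes <- lapply(
  setNames(nm = c("egfr", "ckd")),
  function(oc) read_sumstats(file.path(dir, "outcomes", paste0(oc, ".tsv"))))
ld <- read_ld(file.path(dir, "ld.tsv"))
blocklist <- read_blocklist(file.path(dir, "blocklist.txt"))
cfg <- instrument_filter_config(blocklist = blocklist)

sets <- list()
for (id in names(exposures)) {
  for (oc in names(outcomes)) {
    s <- select_instruments(exposures[[id]], outcomes[[oc]], ld, cfg,
                            exposure_id = paste(id, oc, sep = "|"))
    sets[[paste(id, oc, sep = "|")]] <- s
  }
}
write_funnel(sets, file.path(dir, "funnel.tsv"))

funnel_mat <- t(vapply(sets, `[[`, numeric(6), "funnel"))
cat("Selection funnel (totals over all taxon-outcome pairs):\n")
print(colSums(funnel_mat))
cat("\nPairs ending with zero instruments:",
    sum(funnel_mat[, "after_outcome"] == 0), "of", nrow(funnel_mat), "\n")
cat("Note how the outcome-association stage (outcome p < 0.05) bites hardest\n")
cat("exactly for the causal pairs - see the methods vignette.\n")
causal <- c("class_bacteroidia|egfr", "genus_coprococcus|ckd")
print(funnel_mat[causal, ])
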