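#!/usr/bin/env Rscript
# Stage 5: association testing. Runs the full suite over the statistical
# units: per-CNA Fisher 2x2 tests against ploidy (within histology strata),
# histology group and subsite (TNG vs BM) with discrete-FDR q-values per
# family, plus Mann-Whitney comparisons of the four total burden scores
# (BH families of size 4). Flags associations at q < 0.1.

source("analysis/00_config.R")

units <- read.table(file.path(OUT, "units.tsv"), sep = "\t", header = TRUE)
pres_df <- read.table(file.path(OUT, "presence.tsv"), sep = "\t",
                      header = TRUE, check.names = FALSE)
presence <- as.matrix(pres_df[, -1, drop = FALSE])
rownames(presence) <- pres_df$unit_id

res <- run_association_suite(units, presence, q_threshold = Q_SIG)
cat(sprintf("tests executed: %d (%d CNA 2x2, %d Mann-Whitney)\n",
            nrow(res), sum(!res$label %in% c("TFG", "TBG", "TFL", "TBL")),
            sum(res$label %in% c("TFG", "TBG", "TFL", "TBL"))))
sig <- res[res$significant, ]
cat(sprintf("significant at q < %.1f: %d\n", Q_SIG, nrow(sig)))
if (nrow(sig))
  print(sig[order(sig$q),
            c("analysis", "stratum", "label", "prevalence", "p", "q")],
        row.names = FALSE)

write.table(res, file.path(OUT, "associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", file.path(OUT, "associations.tsv"), "\n")
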