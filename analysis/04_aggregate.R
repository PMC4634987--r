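#!/usr/bin/env Rscript
# Stage 4: aggregate to statistical units. Collapses biopsies into
# patient x subsite units (most-severe histology, any-aneuploid ploidy),
# computes per-unit presence of the retained recurrent CNAs and the total
# burden scores TFG / TBG / TFL / TBL.

source("analysis/00_config.R")

meta <- read_metadata(file.path(DATA, "metadata.tsv"))
events <- read.table(file.path(OUT, "events.tsv"), sep = "\t", header = TRUE,
                     colClasses = c(chrom = "character",
                                    bands = "character"))
rc <- read.table(file.path(OUT, "recurrent_cnas.tsv"), sep = "\t",
                 header = TRUE, colClasses = c(chrom = "character",
                                               unit = "character"))
ret <- rc[rc$retained, ]

units <- build_units(meta, di_tol = DI_TOL)
presence <- unit_cna_presence(units, events, ret, meta)
units <- total_scores(units, events, meta)

cat(sprintf("units: %d patient-subsites from %d biopsies\n",
            nrow(units), nrow(meta)))
cat(sprintf("histology: %s; aneuploid units: %d\n",
            paste(names(table(units$histology)), table(units$histology),
                  collapse = ", ", sep = "="),
            sum(units$ploidy == "aneuploid")))
grp <- ifelse(units$histology == "ND-OPMD", "ND-OPMD", "D-OPMD/OSCC")
for (sc in c("TFG", "TBG", "TFL", "TBL"))
  cat(sprintf("%s: median %.1f (ND-OPMD) vs %.1f (D-OPMD/OSCC)\n", sc,
              median(units[[sc]][grp == "ND-OPMD"]),
              median(units[[sc]][grp == "D-OPMD/OSCC"])))

write.table(units, file.path(OUT, "units.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(unit_id = rownames(presence), presence,
                       check.names = FALSE),
            file.path(OUT, "presence.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", file.path(OUT, "units.tsv"), "and",
    file.path(OUT, "presence.tsv"), "\n")
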