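#!/usr/bin/env Rscript
# Stage 1: simulate the cohort. Generates the synthetic genome/probe grid,
# draws the patient x subsite x biopsy structure with histology, DNA-index
# and ground-truth copy-number events, renders noisy probe-level log2-ratio
# arrays, and writes everything as plain TSV under results/data/.

source("analysis/00_config.R")

gg <- demo_genome()
cat(sprintf("genome: %d chromosomes, %d cytobands, %d probes\n",
            nrow(gg$genome$chromosomes), nrow(gg$genome$cytobands),
            nrow(gg$grid)))

cohort <- generate_cohort(gg$genome, DESIGN, seed = SEED + 1)
meta <- cohort_metadata(cohort)
cat(sprintf("cohort: %d patients, %d patient-subsites, %d biopsies\n",
            length(unique(meta$patient_id)),
            nrow(unique(meta[c("patient_id", "subsite")])), nrow(meta)))
cat(sprintf("histology: %s\n",
            paste(names(table(meta$histology)), table(meta$histology),
                  collapse = ", ", sep = "=")))
cat(sprintf("aneuploid biopsies (DI != 1): %d of %d\n",
            sum(meta$di != 1), nrow(meta)))

profiles <- lapply(seq_along(cohort$samples), function(i)
  render_array(cohort$samples[[i]], gg$grid, noise_sd = NOISE_SD,
               outlier_rate = OUTLIER_RATE, outlier_sd = OUTLIER_SD,
               seed = SEED + 1000 + i))

truth <- do.call(rbind, lapply(cohort$samples, function(s)
  if (nrow(s$events)) cbind(sample = s$biopsy_id, s$events)))
cat(sprintf("planted ground truth: %d events (%d focal, %d broad)\n",
            nrow(truth), sum(truth$scope == "focal"),
            sum(truth$scope == "broad")))

write_cytobands(gg$genome, file.path(DATA, "cytobands.tsv"))
write_probe_grid(gg$grid, file.path(DATA, "probes.tsv"))
write_metadata(meta, file.path(DATA, "metadata.tsv"))
write_profiles(profiles, file.path(DATA, "profiles.tsv"))
write.table(truth, file.path(DATA, "truth_events.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", DATA, "\n")
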