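#!/usr/bin/env Rscript
# Stage 2: preprocess and segment. Reloads the probe-level arrays from TSV,
# applies dLRs quality control (cap 0.35), MAD winsorization (k = 2.5) and
# exact penalized least-squares segmentation (gamma = 40 on noise-normalized
# residuals), and writes a SEG file.

source("analysis/00_config.R")

grid <- read_probe_grid(file.path(DATA, "probes.tsv"))
profiles <- read_profiles(file.path(DATA, "profiles.tsv"), grid)
cat(sprintf("loaded %d arrays of %d probes\n", length(profiles), nrow(grid)))

qc <- qc_filter(profiles, max_dlrs = MAX_DLRS)
d <- vapply(qc$kept, function(p) p$dlrs, numeric(1))
cat(sprintf("dLRs: median %.3f, range %.3f-%.3f; discarded %d arrays\n",
            median(d), min(d), max(d), length(qc$discarded)))

segments <- do.call(rbind, lapply(qc$kept, function(p)
  segment_pcf(winsorize(p, k = WINSOR_K), gamma = GAMMA)))
cat(sprintf("segments: %d (%.1f per array)\n", nrow(segments),
            nrow(segments) / length(qc$kept)))

write_seg(segments, file.path(OUT, "segments.seg"))
cat("wrote", file.path(OUT, "segments.seg"), "\n")
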