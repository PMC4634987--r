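# Shared configuration for the analysis drivers. Source()d by each numbered
# script. A demo-scale synthetic cohort stands in for the study's raw arrays:
# 8 chromosomes x 8 cytobands (3 Mb each), 100 kb probe spacing (1920 probes),
# 80 patients with the cohort structure described in the methods vignette.

library(oralcna)

SEED <- 2026
OUT <- "results"
DATA <- file.path(OUT, "data")

GENOME_PARAMS <- list(n_chromosomes = 8, arm_bands = 4, band_len = 3e6,
                      probe_spacing = 1e5)
DESIGN <- cohort_design(n_patients = 80)
NOISE_SD <- 0.15
OUTLIER_RATE <- 0.01
OUTLIER_SD <- 1
GAMMA <- 40
GAIN_THR <- 0.3
LOSS_THR <- -0.3
MAX_DLRS <- 0.35
WINSOR_K <- 2.5
N_PERM <- 1000
FOCAL_Q <- 0.25
BROAD_Q <- 0.3
DI_TOL <- 0.05
Q_SIG <- 0.1

dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

demo_genome <- function() {
  gp <- GENOME_PARAMS
  gp$seed <- SEED
  do.call(generate_genome, gp)
}
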