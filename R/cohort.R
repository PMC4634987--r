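#' Cohort design parameters for the synthetic generator
#'
#' Defaults emulate the structure of the study cohort this package models:
#' an oral-medicine case series in which each patient presents one or more
#' oral mucosa subsites carrying a potentially malignant disorder (OPMD) or a
#' carcinoma (OSCC), each subsite is sampled by one or more biopsies, and each
#' biopsy carries a histological diagnosis, a flow-cytometric DNA index label,
#' and (in aberrant clones) somatic copy-number events diluted by the cancer
#' cell fraction. Probabilities are documented in the methods vignette; all
#' are overridable.
#'
#' @param n_patients number of patients.
#' @param subsite_probs named probability vector over subsites
#'   (BM, TNG, FOM, GUM, SP, LIP, HP).
#' @param extra_subsite_prob per-patient probability of each additional
#'   involved subsite (geometric stopping).
#' @param histology_probs matrix (subsites x 3) of histology probabilities,
#'   columns ND-OPMD, D-OPMD, OSCC; rows must sum to 1.
#' @param aneuploidy_prob named vector of per-histology aneuploidy
#'   probabilities.
#' @param tng_aneuploidy_or odds multiplier for aneuploidy at the tongue
#'   (TNG) subsite.
#' @param event_rate named vector: mean somatic events per biopsy by
#'   histology.
#' @param aneuploid_event_mult multiplier on `event_rate` for aneuploid
#'   biopsies.
#' @param focal_frac fraction of random events that are focal (<= 3 contiguous
#'   cytobands); the rest are broad (> half an arm).
#' @param gain_frac fraction of events that are gains.
#' @param qt_gain,qt_loss named probability vectors over integer total copy
#'   numbers for gains and losses (background ploidy D = 2).
#' @param alpha_range range of the per-biopsy cancer cell fraction (uniform);
#'   give two equal values for a fixed alpha.
#' @param biopsy_rate biopsies per subsite are 1 + Poisson(`biopsy_rate`).
#' @param di_range DNA-index magnitude range for aneuploid samples (uniform).
#' @param planted optional list of deterministic event specs, each a list with
#'   `chrom`, `start`, `end`, `direction` ("gain"/"loss"), `scope`
#'   ("focal"/"broad"), `prob` (per-biopsy carrier probability) and optional
#'   fixed `q_t` (otherwise drawn from the matching copy-number prior).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 60,
                          subsite_probs = c(BM = 218, TNG = 143, FOM = 35,
                                            GUM = 69, SP = 20, LIP = 2, HP = 35) / 522,
                          extra_subsite_prob = 0.13,
                          histology_probs = default_histology_probs(),
                          aneuploidy_prob = c("ND-OPMD" = 0.15, "D-OPMD" = 0.40,
                                              "OSCC" = 0.60),
                          tng_aneuploidy_or = 4,
                          event_rate = c("ND-OPMD" = 0.4, "D-OPMD" = 1.5,
                                         "OSCC" = 3),
                          aneuploid_event_mult = 3,
                          focal_frac = 0.6,
                          gain_frac = 0.5,
                          qt_gain = c("3" = 0.5, "4" = 0.35, "5" = 0.15),
                          qt_loss = c("1" = 0.85, "0" = 0.15),
                          alpha_range = c(0.4, 0.8),
                          biopsy_rate = 0.58,
                          di_range = c(1.1, 2.2),
                          planted = NULL) {
  d <- as.list(environment())
  check_probs <- function(p, what) {
    if (any(p < 0) || any(p > 1))
      stop("cohort_design: ", what, " must lie in [0, 1]")
  }
  check_simplex <- function(p, what) {
    check_probs(p, what)
    if (abs(sum(p) - 1) > 1e-8)
      stop("cohort_design: ", what, " must sum to 1")
  }
  check_simplex(d$subsite_probs, "subsite_probs")
  apply(d$histology_probs, 1, check_simplex, what = "histology_probs rows")
  check_probs(d$aneuploidy_prob, "aneuploidy_prob")
  check_probs(c(d$extra_subsite_prob, d$focal_frac, d$gain_frac),
              "fractions")
  check_simplex(d$qt_gain, "qt_gain")
  check_simplex(d$qt_loss, "qt_loss")
  if (any(as.integer(names(d$qt_gain)) <= 2))
    stop("cohort_design: gain copy numbers must exceed the background ploidy 2")
  if (any(as.integer(names(d$qt_loss)) >= 2))
    stop("cohort_design: loss copy numbers must fall below the background ploidy 2")
  if (!is.null(planted))
    for (ev in planted) check_probs(ev$prob, "planted event prob")
  structure(d, class = "cohort_design")
}

default_histology_probs <- function() {
  m <- rbind(BM  = c(183, 19, 16),
             TNG = c(67, 22, 54),
             FOM = c(21, 7, 7),
             GUM = c(49, 5, 15),
             SP  = c(10, 4, 6),
             LIP = c(2, 0, 0),
             HP  = c(23, 2, 10))
  colnames(m) <- c("ND-OPMD", "D-OPMD", "OSCC")
  sweep(m, 1, rowSums(m), "/")
}

#' Histology severity order
#' @keywords internal
histology_levels <- function() c("ND-OPMD", "D-OPMD", "OSCC")

#' Generate a synthetic biopsy cohort with ground truth
#'
#' Draws patients, their involved oral subsites, biopsies per subsite,
#' histology, DNA-index (aneuploidy) labels and ground-truth copy-number
#' events. The DNA index is 1 exactly for diploid samples and is drawn from
#' `di_range` for aneuploid ones; histology and aneuploidy probabilities are
#' conditioned on subsite per the design.
#'
#' @param genome A [genome_def()].
#' @param design A [cohort_design()].
#' @param seed integer seed; the cohort is byte-identical for a fixed seed.
#' @return list of class `synthetic_cohort` with elements `samples` (list of
#'   `biopsy_sample`), `metadata` (one row per biopsy) and `design`.
#' @export
generate_cohort <- function(genome, design = cohort_design(), seed = 1) {
  stopifnot(inherits(genome, "genome_def"), inherits(design, "cohort_design"))
  rng <- local_rng(seed)
  arms <- arm_table(genome)
  subsites <- names(design$subsite_probs)
  samples <- list()
  for (pat in seq_len(design$n_patients)) {
    pid <- sprintf("PT%03d", pat)
    n_sub <- 1
    while (rng$runif(1) < design$extra_subsite_prob) n_sub <- n_sub + 1
    n_sub <- min(n_sub, length(subsites))
    sub <- rng$sample(subsites, n_sub, prob = design$subsite_probs)
    for (ss in sub) {
      hp <- design$histology_probs[ss, ]
      hist <- rng$sample(histology_levels(), 1, prob = hp)
      p_an <- design$aneuploidy_prob[[hist]]
      if (ss == "TNG" && p_an > 0 && p_an < 1) {
        odds <- design$tng_aneuploidy_or * p_an / (1 - p_an)
        p_an <- odds / (1 + odds)
      }
      n_biop <- 1 + rng$rpois(1, design$biopsy_rate)
      for (b in seq_len(n_biop)) {
        aneu <- rng$runif(1) < p_an
        di <- if (aneu)
          design$di_range[1] + rng$runif(1) * diff(design$di_range) else 1
        alpha <- design$alpha_range[1] +
          rng$runif(1) * diff(range(design$alpha_range))
        rate <- design$event_rate[[hist]] *
          if (aneu) design$aneuploid_event_mult else 1
        n_ev <- rng$rpois(1, rate)
        evs <- draw_events(n_ev, genome, arms, design, rng)
        if (!is.null(design$planted)) {
          for (pe in design$planted) {
            if (rng$runif(1) < pe$prob) {
              qt <- if (!is.null(pe$q_t)) pe$q_t else
                draw_qt(pe$direction, design, rng)
              evs <- rbind(evs, data.frame(
                direction = pe$direction, chrom = as.character(pe$chrom),
                start = pe$start, end = pe$end, q_t = qt,
                scope = pe$scope, stringsAsFactors = FALSE))
            }
          }
        }
        samples[[length(samples) + 1L]] <- structure(
          list(patient_id = pid, subsite = ss,
               biopsy_id = sprintf("%s_%s_B%d", pid, ss, b),
               histology = hist, di = di, alpha = alpha, D = 2,
               events = evs,
               chroms = genome$chromosomes$chrom),
          class = "biopsy_sample")
      }
    }
  }
  meta <- do.call(rbind, lapply(samples, function(s)
    data.frame(patient_id = s$patient_id, subsite = s$subsite,
               biopsy_id = s$biopsy_id, histology = s$histology,
               di = s$di, alpha = s$alpha, stringsAsFactors = FALSE)))
  structure(list(samples = samples, metadata = meta, design = design),
            class = "synthetic_cohort")
}

draw_qt <- function(direction, design, rng) {
  pr <- if (direction == "gain") design$qt_gain else design$qt_loss
  as.integer(rng$sample(names(pr), 1, prob = pr))
}

# Random focal (<= 3 contiguous cytobands) or broad (> half-arm, anchored at
# an arm end) events; regions in 0-based half-open coordinates.
draw_events <- function(n, genome, arms, design, rng) {
  cols <- data.frame(direction = character(), chrom = character(),
                     start = numeric(), end = numeric(), q_t = integer(),
                     scope = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(cols)
  out <- vector("list", n)
  cb <- genome$cytobands
  for (i in seq_len(n)) {
    direction <- if (rng$runif(1) < design$gain_frac) "gain" else "loss"
    a <- arms[rng$sample(nrow(arms), 1), ]
    if (rng$runif(1) < design$focal_frac) {
      bands <- cb[cb$chrom == a$chrom & cb$arm == a$arm, ]
      bands <- bands[order(bands$start), ]
      w <- rng$sample(min(3L, nrow(bands)), 1)
      i0 <- rng$sample(nrow(bands) - w + 1L, 1)
      reg <- c(bands$start[i0], bands$end[i0 + w - 1L])
      scope <- "focal"
    } else {
      frac <- if (rng$runif(1) < 0.6) 1 else 0.55 + 0.4 * rng$runif(1)
      len <- frac * a$length
      reg <- if (rng$runif(1) < 0.5) c(a$start, a$start + len)
             else c(a$end - len, a$end)
      scope <- "broad"
    }
    out[[i]] <- data.frame(direction = direction, chrom = a$chrom,
                           start = floor(reg[1]), end = ceiling(reg[2]),
                           q_t = draw_qt(direction, design, rng),
                           scope = scope, stringsAsFactors = FALSE)
  }
  rbind(cols, do.call(rbind, out))
}

#' Cohort metadata table
#' @param cohort A `synthetic_cohort`.
#' @return data.frame, one row per biopsy.
#' @export
cohort_metadata <- function(cohort) cohort$metadata

#' Render a noisy array profile for one biopsy
#'
#' Probe means follow the clonality dilution model: inside a ground-truth
#' event with total copy number `q_t` the expected log2 ratio is
#' [expected_log2()] of the biopsy's cancer cell fraction; elsewhere it is 0.
#' Gaussian probe noise is added, and a fraction of probes receive additional
#' outlier noise. The returned profile carries a `in_event` bookkeeping flag
#' per probe.
#'
#' @param sample A `biopsy_sample`.
#' @param grid A `probe_grid` sharing the sample's genome.
#' @param noise_sd per-probe Gaussian noise SD (log2 units).
#' @param outlier_rate fraction of probes receiving extra outlier noise.
#' @param outlier_sd SD of the extra outlier noise (log2 units).
#' @param seed integer seed.
#' @return An `array_profile`: list with `sample`, `probes` (data.frame
#'   `probe_id`, `chrom`, `pos`, `log2`, `truth`, `in_event`), `dlrs`,
#'   `qc_pass`.
#' @export
render_array <- function(sample, grid, noise_sd = 0.15, outlier_rate = 0.01,
                         outlier_sd = 1, seed = 1) {
  stopifnot(inherits(sample, "biopsy_sample"))
  if (!all(unique(sample$events$chrom) %in% unique(grid$chrom)))
    stop("render_array: sample events reference chromosomes absent from the grid")
  if (!is.null(sample$chroms) && !all(grid$chrom %in% sample$chroms))
    stop("render_array: grid and sample do not share a genome")
  rng <- local_rng(seed)
  truth <- numeric(nrow(grid))
  in_event <- logical(nrow(grid))
  ev <- sample$events
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      hit <- grid$chrom == ev$chrom[i] & grid$pos >= ev$start[i] &
        grid$pos < ev$end[i]
      truth[hit] <- expected_log2(sample$alpha, ev$q_t[i], sample$D)
      in_event <- in_event | hit
    }
  }
  y <- truth + if (noise_sd > 0) rng$rnorm(nrow(grid), 0, noise_sd) else 0
  if (outlier_rate > 0 && outlier_sd > 0) {
    out <- rng$runif(nrow(grid)) < outlier_rate
    y[out] <- y[out] + rng$rnorm(sum(out), 0, outlier_sd)
  }
  probes <- data.frame(probe_id = grid$probe_id, chrom = grid$chrom,
                       pos = grid$pos, log2 = y, truth = truth,
                       in_event = in_event, stringsAsFactors = FALSE)
  array_profile(sample$biopsy_id, probes)
}

#' Construct an array profile
#'
#' @param sample_id sample identifier.
#' @param probes data.frame with at least `probe_id`, `chrom`, `pos`, `log2`,
#'   ordered by (chrom, pos).
#' @return object of class `array_profile`.
#' @export
array_profile <- function(sample_id, probes) {
  stopifnot(all(c("probe_id", "chrom", "pos", "log2") %in% names(probes)))
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$pos)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(sample = sample_id, probes = probes, dlrs = NA_real_,
                 qc_pass = NA, qc_override = FALSE),
            class = "array_profile")
}

#' @export
print.array_profile <- function(x, ...) {
  cat("array_profile", x$sample, "-", nrow(x$probes), "probes, dLRs =",
      format(x$dlrs, digits = 3), "\n")
  invisible(x)
}
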