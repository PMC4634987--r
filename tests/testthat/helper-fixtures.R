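# Shared fixtures: small genomes, hand-built profiles, and independent
# oracles used across the suite. Everything is generated in code.

tiny_genome <- function() generate_genome(2, 2, 1e6, 1e5, seed = 3)

# 6 chromosomes x 8 cytobands (3 Mb each), 200 kb probe spacing = 720 probes;
# the scaled-down genome used by the stochastic acceptance suites.
acc_genome <- function() generate_genome(6, 4, 3e6, 2e5, seed = 5)

# array_profile from a bare numeric vector (one chromosome unless given)
make_profile <- function(values, chrom = rep("1", length(values)),
                         sample_id = "S1") {
  n <- length(values)
  pos <- stats::ave(seq_len(n), chrom, FUN = seq_along) * 1000
  array_profile(sample_id,
                data.frame(probe_id = sprintf("p%04d", seq_len(n)),
                           chrom = chrom, pos = pos, log2 = values,
                           stringsAsFactors = FALSE))
}

# stack segment profiles for several hand-built samples
stack_segments <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("segment_profile", "data.frame")
  out
}

# Independent discrete-FDR oracle: same definition as carlson_fdr but scans
# every attainable p-value of every family member as a threshold (not just
# the observed ones) and uses direct double loops throughout.
carlson_oracle <- function(tables, filter = TRUE, alpha_cap = 0.05) {
  dist_of <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    supp <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- dhyper(supp, c1, n - c1, r1)
    pv <- sapply(pr, function(p0) min(1, sum(pr[pr <= p0 * (1 + 1e-7)])))
    list(supp = supp, pr = pr, pv = pv)
  }
  dists <- lapply(tables, dist_of)
  obs <- sapply(seq_along(tables), function(i)
    dists[[i]]$pv[dists[[i]]$supp == tables[[i]][1, 1]])
  minp <- sapply(dists, function(d) min(d$pv))
  filt <- if (filter) minp > alpha_cap else rep(FALSE, length(tables))
  keep <- which(!filt)
  q <- rep(NA_real_, length(tables))
  if (length(keep)) {
    thr <- sort(unique(unlist(lapply(dists[keep], `[[`, "pv"))))
    fdr <- sapply(thr, function(t) {
      e <- 0
      for (j in keep) {
        d <- dists[[j]]
        e <- e + sum(d$pr[d$pv <= t * (1 + 1e-12)])
      }
      nd <- sum(obs[keep] <= t * (1 + 1e-12))
      e / max(1, nd)
    })
    for (i in keep)
      q[i] <- min(1, min(fdr[thr >= obs[i] * (1 - 1e-12)]))
  }
  list(p = obs, q = q, filtered = filt)
}

# probe-weighted mean segment value over a region, for recovery checks
region_mean <- function(segments, sample, chrom, start, end) {
  sg <- segments[segments$sample == sample & segments$chrom == chrom, ,
                 drop = FALSE]
  w <- pmax(pmin(sg$end, end) - pmax(sg$start, start), 0)
  if (sum(w) == 0) return(NA_real_)
  sum(sg$mean * w) / sum(w)
}

# cohort design used by the stochastic acceptance criteria: 60 single-biopsy
# samples, alpha fixed at 0.5, a focal gain planted on band 3q2 in half the
# samples, random events (40% focal / 60% broad) at 1.2 per biopsy.
acc_design <- function(event_rate = 1.2, planted_prob = 0.5) {
  cohort_design(
    n_patients = 60, extra_subsite_prob = 0, biopsy_rate = 0,
    alpha_range = c(0.5, 0.5),
    event_rate = c("ND-OPMD" = event_rate, "D-OPMD" = event_rate,
                   "OSCC" = event_rate),
    aneuploid_event_mult = 1, focal_frac = 0.4,
    planted = if (planted_prob > 0)
      list(list(chrom = "3", start = 15e6, end = 18e6, direction = "gain",
                scope = "focal", prob = planted_prob)) else NULL)
}

# render + winsorize + segment one cohort on the acceptance genome
acc_segments <- function(cohort, grid, seed, noise_sd = 0.15) {
  profs <- lapply(seq_along(cohort$samples), function(i)
    render_array(cohort$samples[[i]], grid, noise_sd = noise_sd,
                 seed = seed * 1000 + i))
  do.call(rbind, lapply(profs, function(p) segment_pcf(winsorize(p))))
}
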