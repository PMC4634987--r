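#' Expected log2 ratio of a clonal copy-number event
#'
#' Clonality dilution model for a two-color aCGH ratio: a fraction `alpha` of
#' cells carries `q_t` total copies of the region on a background ploidy `D`,
#' the remainder is diploid, so
#' `log2((alpha * q_t + 2 * (1 - alpha)) / (alpha * D + 2 * (1 - alpha)))`.
#' At `alpha = 0.5, D = 2` a hemizygous deletion (`q_t = 1`) gives -0.41/-0.42
#' and a single copy gain (`q_t = 3`) gives 0.32, motivating the +/- 0.3
#' calling thresholds.
#'
#' @param alpha cancer cell fraction in `[0, 1]`.
#' @param q_t total copy number (integer >= 0).
#' @param D background ploidy of the aberrant clone (> 0).
#' @return Expected log2 ratio; `-Inf` for a fully clonal homozygous deletion
#'   (`alpha = 1, q_t = 0`).
#' @export
expected_log2 <- function(alpha, q_t, D = 2) {
  if (any(alpha < 0 | alpha > 1)) stop("expected_log2: alpha must be in [0, 1]")
  if (any(q_t < 0)) stop("expected_log2: q_t must be >= 0")
  if (any(D <= 0)) stop("expected_log2: D must be > 0")
  log2((alpha * q_t + 2 * (1 - alpha)) / (alpha * D + 2 * (1 - alpha)))
}

#' Call gains and losses on a segment profile
#'
#' Applies the symmetric log2-ratio thresholds (inclusive: `mean >= gain_thr`
#' is a gain, `mean <= loss_thr` a loss) and merges adjacent same-state
#' regions per chromosome.
#'
#' @param segments A `segment_profile` from [segment_pcf()].
#' @param gain_thr,loss_thr calling thresholds; defaults +0.3 / -0.3.
#' @return data.frame of called regions: `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `mean`, `state` in {gain, neutral, loss}.
#' @export
call_segments <- function(segments, gain_thr = 0.3, loss_thr = -0.3) {
  stopifnot(loss_thr < 0, gain_thr > 0)
  d <- as.data.frame(segments)
  d$state <- ifelse(d$mean >= gain_thr, "gain",
                    ifelse(d$mean <= loss_thr, "loss", "neutral"))
  merge_called(d)
}

# Merge adjacent same-state regions within (sample, chromosome); merged mean
# is the probe-weighted mean. Idempotent.
merge_called <- function(d) {
  out <- lapply(split(d, list(d$sample, d$chrom), drop = TRUE), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    run <- cumsum(c(TRUE, g$state[-1] != g$state[-nrow(g)] |
                            g$start[-1] != g$end[-nrow(g)]))
    do.call(rbind, lapply(split(g, run), function(r) {
      data.frame(sample = r$sample[1], chrom = r$chrom[1],
                 start = min(r$start), end = max(r$end),
                 n_probes = sum(r$n_probes),
                 mean = sum(r$mean * r$n_probes) / sum(r$n_probes),
                 state = r$state[1], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify called regions as focal or broad events
#'
#' Non-neutral regions are split at the centromere; each arm piece is broad
#' iff it covers more than half of its arm, otherwise focal. Broad events are
#' labelled at arm resolution ("8q gain"); focal events carry the list of
#' cytobands they overlap. A region is either broad or focal, never both.
#'
#' @param called data.frame from [call_segments()].
#' @param genome A [genome_def()].
#' @return data.frame of events: `sample`, `chrom`, `arm`, `start`, `end`,
#'   `direction`, `class`, `arm_frac`, `bands` (comma-joined, focal only),
#'   `label`.
#' @export
classify_events <- function(called, genome) {
  arms <- arm_table(genome)
  d <- called[called$state != "neutral", , drop = FALSE]
  if (!nrow(d)) return(empty_events())
  glen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  if (any(!d$chrom %in% names(glen)) ||
      any(d$start < 0 | d$end > glen[d$chrom]))
    stop("classify_events: region outside genome bounds")
  rows <- list()
  for (i in seq_len(nrow(d))) {
    cen <- genome$chromosomes$centromere[genome$chromosomes$chrom == d$chrom[i]]
    pieces <- list()
    if (d$start[i] < cen)
      pieces$p <- c(d$start[i], min(d$end[i], cen))
    if (d$end[i] > cen)
      pieces$q <- c(max(d$start[i], cen), d$end[i])
    for (arm in names(pieces)) {
      a <- arms[arms$chrom == d$chrom[i] & arms$arm == arm, ]
      if (!nrow(a)) next
      p <- pieces[[arm]]
      frac <- (p[2] - p[1]) / a$length
      cls <- if (frac > 0.5) "broad" else "focal"
      direction <- d$state[i]
      if (cls == "broad") {
        bands <- ""
        label <- sprintf("%s%s %s", d$chrom[i], arm, direction)
      } else {
        cb <- genome$cytobands
        hit <- cb$chrom == d$chrom[i] & cb$start < p[2] & cb$end > p[1]
        bands <- paste(cb$band[hit], collapse = ",")
        label <- sprintf("%s%s %s", d$chrom[i], cb$band[hit][1], direction)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = d$sample[i], chrom = d$chrom[i], arm = arm,
        start = p[1], end = p[2], direction = direction, class = cls,
        arm_frac = frac, bands = bands, label = label,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(sample = character(), chrom = character(), arm = character(),
             start = numeric(), end = numeric(), direction = character(),
             class = character(), arm_frac = numeric(), bands = character(),
             label = character(), stringsAsFactors = FALSE)
}

#' Expand focal events to one row per affected cytoband
#'
#' @param events data.frame from [classify_events()].
#' @return data.frame `sample`, `chrom`, `band`, `direction`, `label`.
#' @export
event_band_labels <- function(events) {
  f <- events[events$class == "focal", , drop = FALSE]
  if (!nrow(f))
    return(data.frame(sample = character(), chrom = character(),
                      band = character(), direction = character(),
                      label = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    bands <- strsplit(f$bands[i], ",", fixed = TRUE)[[1]]
    data.frame(sample = f$sample[i], chrom = f$chrom[i], band = bands,
               direction = f$direction[i],
               label = sprintf("%s%s %s", f$chrom[i], bands, f$direction[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cytoband- and arm-level amplitude matrices
#'
#' Projects per-sample segment means onto cytobands and arms: each cell is
#' the probe-weighted mean segment value over the probes falling in that band
#' (arm). This is the marker-level input of the recurrence test.
#'
#' @param segments data.frame of stacked `segment_profile`s (all samples).
#' @param grid the shared `probe_grid`.
#' @param genome A [genome_def()].
#' @return list with matrices `band` (cytobands x samples, rownames
#'   "chrom:band") and `arm` (arms x samples, rownames "chrom:arm").
#' @export
amplitude_matrices <- function(segments, grid, genome) {
  samples <- unique(segments$sample)
  cb <- genome$cytobands
  band_key <- paste(cb$chrom, cb$band, sep = ":")
  arms <- arm_table(genome)
  arm_key <- paste(arms$chrom, arms$arm, sep = ":")
  band_idx <- locate_band(genome, grid$chrom, grid$pos)
  probe_arm <- match(paste(cb$chrom, cb$arm, sep = ":")[band_idx], arm_key)
  band_m <- matrix(0, nrow(cb), length(samples),
                   dimnames = list(band_key, samples))
  arm_m <- matrix(0, nrow(arms), length(samples),
                  dimnames = list(arm_key, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    val <- rep(NA_real_, nrow(grid))
    for (cc in unique(seg$chrom)) {
      sel <- which(grid$chrom == cc)
      sc <- seg[seg$chrom == cc, , drop = FALSE]
      j <- findInterval(grid$pos[sel], sc$start)
      ok <- j >= 1L & grid$pos[sel] < sc$end[pmax(j, 1L)]
      val[sel[ok]] <- sc$mean[j[ok]]
    }
    band_m[, s] <- vapply(seq_len(nrow(cb)), function(b) {
      v <- val[which(band_idx == b)]
      if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    }, numeric(1))
    arm_m[, s] <- vapply(seq_len(nrow(arms)), function(a) {
      v <- val[which(probe_arm == a)]
      if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  list(band = band_m, arm = arm_m)
}

#' Recurrent CNAs by a simplified permutation G-score
#'
#' A declared simplification of the GISTIC approach (no ziggurat
#' deconstruction or peel-off): per marker (cytoband for the focal analysis,
#' arm for the broad analysis) and direction, the G-score sums each sample's
#' amplitude exceedance beyond the calling threshold
#' (`max(0, amp - gain_thr)` for gains, `max(0, loss_thr - amp)` for losses).
#' The null is built by random per-sample cyclic shifts of the marker
#' amplitudes (within chromosome for bands, genome-wide for arms), preserving
#' each sample's spatial autocorrelation; `perm = "shuffle"` uses independent
#' permutation instead. Empirical p-values get Benjamini-Hochberg q-values
#' per analysis; focal markers are retained at `q < focal_q`, broad at
#' `q < broad_q`.
#'
#' @param events stacked [classify_events()] output (all samples), used for
#'   carrier counts and presence vectors.
#' @param markers list from [amplitude_matrices()].
#' @param genome A [genome_def()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param gain_thr,loss_thr amplitude thresholds.
#' @param focal_q,broad_q retention q-value cutoffs (0.25 / 0.3).
#' @param perm `"cyclic"` (default) or `"shuffle"`.
#' @return data.frame with one row per tested marker x direction: `label`,
#'   `class`, `direction`, `chrom`, `unit` (band or arm name), `G`, `p`, `q`,
#'   `n_carriers`, `retained`.
#' @export
recurrent_cnas <- function(events, markers, genome, n_perm = 1000, seed = 1,
                           gain_thr = 0.3, loss_thr = -0.3,
                           focal_q = 0.25, broad_q = 0.3,
                           perm = c("cyclic", "shuffle")) {
  perm <- match.arg(perm)
  if (n_perm < 100) stop("recurrent_cnas: n_perm must be >= 100")
  if (ncol(markers$band) < 2) stop("recurrent_cnas: need >= 2 samples")
  rng <- local_rng(seed)
  marker_chrom <- function(m) sub(":.*$", "", rownames(m))
  exceed <- function(m, direction) {
    if (direction == "gain") pmax(m - gain_thr, 0) else pmax(loss_thr - m, 0)
  }
  analyses <- list(
    list(class = "focal", direction = "gain", m = markers$band),
    list(class = "focal", direction = "loss", m = markers$band),
    list(class = "broad", direction = "gain", m = markers$arm),
    list(class = "broad", direction = "loss", m = markers$arm))
  res <- list()
  for (an in analyses) {
    m <- an$m
    R <- nrow(m); S <- ncol(m)
    chrom_of <- if (an$class == "focal") marker_chrom(m)
                else rep("genome", nrow(m))
    chroms <- unique(chrom_of)
    ci <- match(chrom_of, chroms)
    blk_c <- tabulate(ci)                        # markers per chromosome
    blk <- blk_c[ci]                             # per marker row
    within <- stats::ave(seq_len(R), ci, FUN = seq_along) - 1L
    base <- match(chroms, chrom_of)[ci]          # first row of each block
    G <- rowSums(exceed(m, an$direction))
    ge <- integer(R)
    col_rep <- rep(seq_len(S), each = R)
    if (perm == "cyclic") {
      # pre-draw all per-(perm, chromosome, sample) shift offsets at once
      u <- rng$runif(n_perm * length(chroms) * S)
      dim(u) <- c(length(chroms), S, n_perm)
    }
    for (p in seq_len(n_perm)) {
      if (perm == "cyclic") {
        k <- floor(u[, , p, drop = FALSE] * blk_c)  # offsets in 0..blk-1
        K <- matrix(k, length(chroms), S)[ci, , drop = FALSE]
        idx <- base + (within + K) %% blk
        mp <- matrix(m[cbind(as.vector(idx), col_rep)], R, S)
      } else {
        mp <- apply(m, 2, function(col) col[rng$sample(R)])
      }
      ge <- ge + (rowSums(exceed(mp, an$direction)) >= G)
    }
    pval <- (1 + ge) / (n_perm + 1)
    q <- bh_qvalues(pval)
    unit <- sub("^.*:", "", rownames(m))
    chrom <- sub(":.*$", "", rownames(m))
    lab <- sprintf("%s%s %s", chrom, unit, an$direction)
    carriers <- count_carriers(events, an$class, an$direction, chrom, unit)
    cutoff <- if (an$class == "focal") focal_q else broad_q
    res[[length(res) + 1L]] <- data.frame(
      label = lab, class = an$class, direction = an$direction,
      chrom = chrom, unit = unit, G = G, p = pval, q = q,
      n_carriers = carriers,
      retained = q < cutoff & G > 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

count_carriers <- function(events, class, direction, chrom, unit) {
  vapply(seq_along(chrom), function(i) {
    length(unique(matching_samples(events, class, direction,
                                   chrom[i], unit[i])))
  }, integer(1))
}

# Samples carrying an event that matches a recurrent-CNA label's
# class/direction/location.
matching_samples <- function(events, class, direction, chrom, unit) {
  e <- events[events$class == class & events$direction == direction &
                events$chrom == chrom, , drop = FALSE]
  if (!nrow(e)) return(character())
  if (class == "broad") {
    e$sample[e$arm == unit]
  } else {
    hit <- vapply(strsplit(e$bands, ",", fixed = TRUE),
                  function(b) unit %in% b, logical(1))
    e$sample[hit]
  }
}

#' Per-sample presence matrix for retained recurrent CNAs
#'
#' @param events stacked [classify_events()] output.
#' @param recurrent data.frame from [recurrent_cnas()] (rows to use,
#'   typically the retained set).
#' @param sample_ids all sample ids (columns of the result).
#' @return binary matrix, labels x samples.
#' @export
recurrent_presence <- function(events, recurrent, sample_ids) {
  m <- matrix(0L, nrow(recurrent), length(sample_ids),
              dimnames = list(recurrent$label, sample_ids))
  for (i in seq_len(nrow(recurrent))) {
    s <- matching_samples(events, recurrent$class[i], recurrent$direction[i],
                          recurrent$chrom[i], recurrent$unit[i])
    m[i, sample_ids %in% s] <- 1L
  }
  m
}
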