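#' Penalized least-squares segmentation
#'
#' Fits, per chromosome, the piecewise-constant profile minimizing
#' `sum(residual^2) + gamma * (number of breakpoints)`, solved exactly by an
#' O(n^2) dynamic program over breakpoint positions. When `normalize` is on
#' (the default) residuals are measured on the profile divided by its dLRs
#' estimate, so the penalty is noise-scale-free; the dLRs divisor is floored
#' at `dlrs_floor` to keep noiseless synthetic profiles finite. Segment means
#' are always reported on the original (winsorized) scale.
#'
#' @param profile An [array_profile()] (typically after [winsorize()]).
#' @param gamma breakpoint penalty; default 40.
#' @param normalize divide by the dLRs noise estimate before penalization.
#' @param dlrs_floor lower bound for the dLRs divisor.
#' @return A `segment_profile`: data.frame with columns `sample`, `chrom`,
#'   `start`, `end` (0-based half-open over probe positions), `n_probes`,
#'   `mean`; attribute `gamma`.
#' @export
segment_pcf <- function(profile, gamma = 40, normalize = TRUE,
                        dlrs_floor = 1e-3) {
  stopifnot(inherits(profile, "array_profile"), gamma >= 0)
  pr <- profile$probes[!is.na(profile$probes$log2), , drop = FALSE]
  scale <- 1
  if (normalize && nrow(pr) >= 3L)
    scale <- max(dlrs(pr$log2, pr$chrom), dlrs_floor)
  segs <- list()
  for (cc in unique(pr$chrom)) {
    d <- pr[pr$chrom == cc, , drop = FALSE]
    if (nrow(d) < 1L) {
      warning("segment_pcf: chromosome ", cc, " has no probes; skipped")
      next
    }
    bk <- pcf_breakpoints(d$log2 / scale, gamma)
    starts <- c(1L, bk + 1L)
    ends <- c(bk, nrow(d))
    segs[[cc]] <- data.frame(
      sample = profile$sample, chrom = cc,
      start = d$pos[starts],
      end = c(d$pos[starts[-1]], d$pos[nrow(d)] + 1),
      n_probes = ends - starts + 1L,
      mean = vapply(seq_along(starts),
                    function(i) mean(d$log2[starts[i]:ends[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "gamma") <- gamma
  class(out) <- c("segment_profile", "data.frame")
  out
}

#' Exact changepoint dynamic program
#'
#' Returns the 0-based-exclusive breakpoint indices (a breakpoint after
#' position i means positions 1..i and i+1.. are in different segments) of
#' the least-squares piecewise-constant fit with per-breakpoint penalty
#' `gamma`. Ties are broken toward fewer/later segments by the strict `<`
#' update. Exported for validation against the exhaustive reference.
#'
#' @param y numeric vector.
#' @param gamma penalty per breakpoint.
#' @return integer vector of breakpoint indices (possibly empty).
#' @export
pcf_breakpoints <- function(y, gamma) {
  n <- length(y)
  if (n <= 1L) return(integer())
  S <- c(0, cumsum(y))
  S2 <- c(0, cumsum(y^2))
  # cost[i+1]: optimal penalized cost of y[1..i]; prev[i]: start of last segment
  cost <- c(0, rep(Inf, n))
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- seq_len(i)                      # candidate last-segment starts
    sse <- (S2[i + 1] - S2[j]) - (S[i + 1] - S[j])^2 / (i - j + 1)
    cand <- cost[j] + sse + gamma
    cand[1] <- cand[1] - gamma           # first segment carries no penalty
    best <- which.min(cand)
    cost[i + 1] <- cand[best]
    prev[i] <- best
  }
  bk <- integer()
  i <- n
  while (i > 0L) {
    j <- prev[i]
    if (j > 1L) bk <- c(j - 1L, bk)
    i <- j - 1L
  }
  bk
}

#' Exhaustive breakpoint search (brute-force reference)
#'
#' Enumerates every subset of the n-1 candidate breakpoints and returns the
#' minimum of `sum(residual^2) + gamma * (#breakpoints)`. Intended as the
#' independent correctness oracle for [pcf_breakpoints()]; quadratic-time DP
#' and this exponential search must agree for all inputs.
#'
#' @param y numeric vector (n <= 25).
#' @param gamma penalty per breakpoint.
#' @return list with `cost` (optimal penalized cost) and `breakpoints`.
#' @export
pcf_exhaustive <- function(y, gamma) {
  stopifnot(length(y) <= 25L)
  res <- exhaustive_pcf_cpp(as.numeric(y), as.numeric(gamma))
  list(cost = res$cost, breakpoints = as.integer(res$breakpoints))
}

#' Penalized cost of a given breakpoint set
#' @keywords internal
pcf_cost <- function(y, bk, gamma) {
  bounds <- c(0L, sort(bk), length(y))
  sse <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    seg <- y[(bounds[i] + 1L):bounds[i + 1L]]
    sse <- sse + sum((seg - mean(seg))^2)
  }
  sse + gamma * length(bk)
}
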