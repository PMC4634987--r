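#' Genome definition with cytobands and arms
#'
#' A `genome_def` holds chromosome sizes, centromere positions and a cytoband
#' tiling. All coordinates are 0-based half-open internally; only exported SEG
#' rows use 1-based closed coordinates. Cytobands must tile each chromosome
#' without gaps or overlaps and never cross the centromere; a band belongs to
#' the p arm iff its end is at or before the centromere.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`, `centromere`.
#' @param cytobands data.frame with columns `chrom`, `start`, `end`, `band`,
#'   `arm`.
#' @return An object of class `genome_def`.
#' @export
genome_def <- function(chromosomes, cytobands) {
  stopifnot(all(c("chrom", "length", "centromere") %in% names(chromosomes)),
            all(c("chrom", "start", "end", "band", "arm") %in% names(cytobands)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  cytobands$chrom <- as.character(cytobands$chrom)
  g <- structure(list(chromosomes = chromosomes, cytobands = cytobands),
                 class = "genome_def")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  for (cc in g$chromosomes$chrom) {
    cb <- g$cytobands[g$cytobands$chrom == cc, ]
    cb <- cb[order(cb$start), ]
    len <- g$chromosomes$length[g$chromosomes$chrom == cc]
    cen <- g$chromosomes$centromere[g$chromosomes$chrom == cc]
    if (nrow(cb) == 0L)
      stop("chromosome ", cc, " has no cytobands")
    if (cb$start[1] != 0 || cb$end[nrow(cb)] != len ||
        (nrow(cb) > 1L && any(cb$start[-1] != cb$end[-nrow(cb)])))
      stop("cytobands do not tile chromosome ", cc)
    if (any(cb$start < cen & cb$end > cen))
      stop("cytoband crosses the centromere on chromosome ", cc)
    arm_ok <- ifelse(cb$end <= cen, "p", "q")
    if (!identical(arm_ok, cb$arm))
      stop("arm labels inconsistent with centromere on chromosome ", cc)
  }
  invisible(g)
}

#' @export
print.genome_def <- function(x, ...) {
  cat("genome_def:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$cytobands), "cytobands,",
      sprintf("%.1f Mb\n", sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' Chromosome-arm table for a genome
#'
#' @param genome A [genome_def()].
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`, `length`
#'   (0-based half-open).
#' @export
arm_table <- function(genome) {
  cb <- genome$cytobands
  key <- paste(cb$chrom, cb$arm)
  out <- do.call(rbind, lapply(split(cb, key), function(d) {
    data.frame(chrom = d$chrom[1], arm = d$arm[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  out$length <- out$end - out$start
  out <- out[order(match(out$chrom, genome$chromosomes$chrom), out$arm), ]
  rownames(out) <- NULL
  out
}

#' Map positions to cytobands
#'
#' @param genome A [genome_def()].
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return Integer row indices into `genome$cytobands` (NA if unmapped).
#' @export
locate_band <- function(genome, chrom, pos) {
  cb <- genome$cytobands
  idx <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    rows <- which(cb$chrom == cc)
    if (!length(rows)) next
    j <- findInterval(pos[sel], cb$start[rows])
    ok <- j >= 1L & pos[sel] < cb$end[rows][pmax(j, 1L)]
    idx[sel[ok]] <- rows[j[ok]]
  }
  idx
}

#' Generate a synthetic genome and matched probe grid
#'
#' Builds an idealized genome of equal-sized chromosomes: each has
#' `2 * arm_bands` cytobands of `band_len` bp (named `p1..pk, q1..qk` in
#' coordinate order) with the centromere at the p/q boundary, and an
#' Agilent-like probe grid with one probe per `probe_spacing` bp window,
#' jittered uniformly within its window so spacing is irregular but the probe
#' count is exactly `floor(chromosome length / probe_spacing)` per chromosome.
#'
#' @param n_chromosomes number of chromosomes (named "1", "2", ...).
#' @param arm_bands cytobands per arm.
#' @param band_len cytoband length in bp.
#' @param probe_spacing mean probe spacing in bp (must be < `band_len`).
#' @param seed integer seed controlling probe-position jitter.
#' @return list with elements `genome` ([genome_def()]) and `grid`
#'   (data.frame `probe_id`, `chrom`, `pos`, class `probe_grid`).
#' @export
generate_genome <- function(n_chromosomes = 8, arm_bands = 4, band_len = 3e6,
                            probe_spacing = 1e5, seed = 1) {
  if (n_chromosomes < 1 || arm_bands < 1 || band_len <= 0 || probe_spacing <= 0)
    stop("generate_genome: all sizes must be positive")
  chrom_len <- 2 * arm_bands * band_len
  chroms <- as.character(seq_len(n_chromosomes))
  chromosomes <- data.frame(chrom = chroms, length = chrom_len,
                            centromere = arm_bands * band_len,
                            stringsAsFactors = FALSE)
  band_names <- c(paste0("p", seq_len(arm_bands)), paste0("q", seq_len(arm_bands)))
  cytobands <- do.call(rbind, lapply(chroms, function(cc) {
    start <- band_len * (seq_len(2 * arm_bands) - 1)
    data.frame(chrom = cc, start = start, end = start + band_len,
               band = band_names,
               arm = rep(c("p", "q"), each = arm_bands),
               stringsAsFactors = FALSE)
  }))
  genome <- genome_def(chromosomes, cytobands)

  n_per_chrom <- floor(chrom_len / probe_spacing)
  rng <- local_rng(seed)
  grid <- do.call(rbind, lapply(chroms, function(cc) {
    lo <- probe_spacing * (seq_len(n_per_chrom) - 1)
    pos <- floor(lo + rng$runif(n_per_chrom) * probe_spacing)
    data.frame(probe_id = sprintf("P_%s_%05d", cc, seq_len(n_per_chrom)),
               chrom = cc, pos = pos, stringsAsFactors = FALSE)
  }))
  class(grid) <- c("probe_grid", "data.frame")
  attr(grid, "design") <- sprintf("synthetic_%dx%d", n_chromosomes, n_per_chrom)
  list(genome = genome, grid = grid)
}

# Self-contained RNG stream so generators never disturb (or depend on) the
# caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f(...)
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       rpois = with_state(stats::rpois),
       sample = with_state(base::sample),
       rbinom = with_state(stats::rbinom))
}
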