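#' Read a UCSC-style cytoBand file into a genome definition
#'
#' Expects a tab-separated file without header and at least five columns:
#' chrom, start (0-based), end (half-open), band name (p/q prefix), stain.
#' An optional leading "chr" on chromosome names is stripped. Arms are
#' inferred from the band-name prefix and the centromere is placed at the
#' p/q boundary. Out-of-order, overlapping or gapped bands, and q bands
#' preceding p bands in coordinates, are format errors reported with line
#' numbers.
#'
#' @param path file path.
#' @return A [genome_def()].
#' @export
read_cytobands <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character"))
  if (ncol(raw) < 5)
    stop("read_cytobands: expected >= 5 tab-separated columns")
  names(raw)[1:5] <- c("chrom", "start", "end", "band", "stain")
  raw$chrom <- sub("^chr", "", raw$chrom)
  raw$line <- seq_len(nrow(raw))
  arm <- substr(raw$band, 1, 1)
  if (!all(arm %in% c("p", "q")))
    stop("read_cytobands: band names must start with p or q (lines ",
         paste(raw$line[!arm %in% c("p", "q")], collapse = ", "), ")")
  chroms <- list()
  bands <- list()
  for (cc in unique(raw$chrom)) {
    d <- raw[raw$chrom == cc, ]
    d <- d[order(d$line), ]
    if (any(diff(d$start) <= 0) || any(d$start[-1] != d$end[-nrow(d)]))
      stop("read_cytobands: bands out of order, overlapping or gapped on ",
           "chromosome ", cc, " (lines ",
           paste(d$line[c(FALSE, diff(d$start) <= 0 |
                                   d$start[-1] != d$end[-nrow(d)])],
                 collapse = ", "), ")")
    a <- substr(d$band, 1, 1)
    if (is.unsorted(match(a, c("p", "q"))))
      stop("read_cytobands: q band precedes p band on chromosome ", cc,
           " (line ", d$line[which(diff(match(a, c("p", "q"))) < 0)[1] + 1],
           ")")
    cen <- if (any(a == "p")) max(d$end[a == "p"]) else 0
    chroms[[cc]] <- data.frame(chrom = cc, length = max(d$end),
                               centromere = cen, stringsAsFactors = FALSE)
    bands[[cc]] <- data.frame(chrom = cc, start = d$start, end = d$end,
                              band = d$band, arm = a,
                              stringsAsFactors = FALSE)
  }
  chroms <- do.call(rbind, chroms)
  bands <- do.call(rbind, bands)
  rownames(chroms) <- rownames(bands) <- NULL
  genome_def(chroms, bands)
}

#' Write a genome as a UCSC cytoBand-style TSV
#' @param genome A [genome_def()].
#' @param path output path.
#' @export
write_cytobands <- function(genome, path) {
  cb <- genome$cytobands
  utils::write.table(
    data.frame(cb$chrom, cb$start, cb$end, cb$band, "gneg"),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Write / read segment tables in SEG format
#'
#' SEG rows use 1-based closed coordinates (the convention of that format
#' family); internal segment objects are 0-based half-open.
#'
#' @param segments stacked `segment_profile` rows.
#' @param path file path.
#' @name seg_io
#' @export
write_seg <- function(segments, path) {
  d <- data.frame(Sample = segments$sample, Chromosome = segments$chrom,
                  Start = segments$start + 1, End = segments$end,
                  Num_Probes = segments$n_probes,
                  Segment_Mean = segments$mean)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname seg_io
#' @export
read_seg <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "numeric", "integer", "numeric"))
  out <- data.frame(sample = d$Sample, chrom = d$Chromosome,
                    start = d$Start - 1, end = d$End,
                    n_probes = d$Num_Probes, mean = d$Segment_Mean,
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_profile", "data.frame")
  out
}

#' Write / read probe grids and long-format profile tables
#'
#' @param grid,profiles,metadata objects to serialize.
#' @param path file path.
#' @name table_io
#' @export
write_probe_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid)[c("probe_id", "chrom", "pos")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname table_io
#' @export
read_probe_grid <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  class(g) <- c("probe_grid", "data.frame")
  g
}

#' @rdname table_io
#' @export
write_profiles <- function(profiles, path) {
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample = p$sample, probe_id = p$probes$probe_id,
               log2 = p$probes$log2, stringsAsFactors = FALSE)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname table_io
#' @param grid probe grid giving each probe's position.
#' @export
read_profiles <- function(path, grid) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  lapply(split(long, long$sample), function(d) {
    i <- match(d$probe_id, grid$probe_id)
    if (any(is.na(i)))
      stop("read_profiles: probes absent from the grid")
    array_profile(d$sample[1],
                  data.frame(probe_id = d$probe_id, chrom = grid$chrom[i],
                             pos = grid$pos[i], log2 = d$log2,
                             stringsAsFactors = FALSE))
  })
}

#' @rdname table_io
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname table_io
#' @export
read_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
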