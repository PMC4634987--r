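#' Average replicate probe measurements
#'
#' Agilent designs spot some probes in replicate; downstream analysis uses one
#' log2 value per probe, the arithmetic mean of its replicates.
#'
#' @param measurements data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `log2`; probes may appear on multiple rows.
#' @param sample_id sample identifier for the resulting profile.
#' @return An [array_profile()] with one row per probe.
#' @export
average_replicates <- function(measurements, sample_id = "sample") {
  stopifnot(all(c("probe_id", "chrom", "pos", "log2") %in% names(measurements)))
  bad <- unique(measurements$probe_id[is.na(measurements$log2)])
  bad <- setdiff(bad,
                 measurements$probe_id[!is.na(measurements$log2)])
  if (length(bad))
    stop("average_replicates: probes with no usable measurement: ",
         paste(utils::head(bad, 5), collapse = ", "))
  agg <- stats::aggregate(log2 ~ probe_id + chrom + pos, data = measurements,
                          FUN = mean, na.action = stats::na.omit)
  array_profile(sample_id, agg)
}

#' Derivative log-ratio spread (dLRs)
#'
#' Robust per-array noise estimate: the interquartile range of consecutive
#' same-chromosome probe differences scaled by `1.349 * sqrt(2)`, so that for
#' iid Gaussian probes it estimates the per-probe noise SD.
#'
#' @param profile An [array_profile()] (or numeric vector with a parallel
#'   `chrom` vector).
#' @param chrom chromosome labels when `profile` is a numeric vector.
#' @return The dLRs estimate (non-negative scalar).
#' @export
dlrs <- function(profile, chrom = NULL) {
  if (inherits(profile, "array_profile")) {
    x <- profile$probes$log2
    chrom <- profile$probes$chrom
  } else {
    x <- profile
    if (is.null(chrom)) chrom <- rep("1", length(x))
  }
  if (length(x) < 3L)
    stop("dlrs: need at least 3 probes")
  d <- unlist(lapply(split(x, chrom), diff), use.names = FALSE)
  if (!length(d)) stop("dlrs: no consecutive same-chromosome probe pairs")
  unname(stats::IQR(d, na.rm = TRUE) / (1.349 * sqrt(2)))
}

#' Quality-filter arrays by dLRs
#'
#' Arrays whose dLRs exceeds the threshold are discarded, except samples on a
#' manual-override allowlist (emulating visual inspection of borderline
#' arrays), which are kept and flagged.
#'
#' @param profiles list of [array_profile()] objects.
#' @param max_dlrs discard threshold (strict `>`); default 0.35.
#' @param allowlist character vector of sample ids to keep regardless.
#' @return list with elements `kept` and `discarded`, each a list of profiles
#'   with `dlrs`, `qc_pass` and `qc_override` filled in.
#' @export
qc_filter <- function(profiles, max_dlrs = 0.35, allowlist = character()) {
  profiles <- lapply(profiles, function(p) {
    if (is.na(p$dlrs)) p$dlrs <- dlrs(p)
    p$qc_pass <- p$dlrs <= max_dlrs
    p$qc_override <- !p$qc_pass && p$sample %in% allowlist
    p
  })
  keep <- vapply(profiles, function(p) p$qc_pass || p$qc_override, logical(1))
  list(kept = profiles[keep], discarded = profiles[!keep])
}

#' MAD winsorization of probe outliers
#'
#' Per chromosome, residuals from the chromosome median are clamped to
#' `+/- k * 1.4826 * MAD` of the residuals; probes within the bounds are
#' returned bit-identical.
#'
#' @param profile An [array_profile()].
#' @param k clamp width in scaled-MAD multiples; default 2.5.
#' @return The winsorized [array_profile()].
#' @export
winsorize <- function(profile, k = 2.5) {
  stopifnot(inherits(profile, "array_profile"))
  x <- profile$probes$log2
  for (cc in unique(profile$probes$chrom)) {
    sel <- profile$probes$chrom == cc
    med <- stats::median(x[sel], na.rm = TRUE)
    s <- stats::mad(x[sel], center = med, na.rm = TRUE)  # 1.4826 * raw MAD
    if (!is.finite(s)) next
    lim <- k * s
    x[sel] <- pmin(pmax(x[sel], med - lim), med + lim)
  }
  profile$probes$log2 <- x
  profile
}
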