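#' Build patient-by-subsite statistical units
#'
#' All biopsies of one oral subsite of one patient form a statistical unit.
#' Histology collapses to the most severe diagnosis (ND-OPMD < D-OPMD < OSCC;
#' graded dysplasia values such as "D-OPMD (mild)" collapse to D-OPMD), and a
#' single aneuploid biopsy (|DI - 1| >= `di_tol`) suffices to label the unit
#' aneuploid. The exclusivity flag is TRUE iff the patient has units at
#' exactly one subsite ("limited to" that subsite).
#'
#' @param metadata data.frame with columns `patient_id`, `subsite`,
#'   `biopsy_id`, `histology`, `di`.
#' @param di_tol DNA-index tolerance around 1 for the diploid call; default
#'   0.05.
#' @return data.frame, one row per (patient, subsite): `patient_id`,
#'   `subsite`, `unit_id`, `histology`, `ploidy`, `exclusive`, `n_biopsies`.
#' @export
build_units <- function(metadata, di_tol = 0.05) {
  req <- c("patient_id", "subsite", "biopsy_id", "histology", "di")
  stopifnot(all(req %in% names(metadata)))
  metadata$histology <- normalize_histology(metadata$histology)
  bad <- is.na(metadata$histology) | is.na(metadata$di)
  if (any(bad))
    stop("build_units: missing or invalid histology/DI for biopsies: ",
         paste(metadata$biopsy_id[bad], collapse = ", "))
  lev <- histology_levels()
  units <- do.call(rbind, lapply(
    split(metadata, paste(metadata$patient_id, metadata$subsite, sep = "\r")),
    function(d) {
      data.frame(patient_id = d$patient_id[1], subsite = d$subsite[1],
                 unit_id = paste(d$patient_id[1], d$subsite[1], sep = "_"),
                 histology = lev[max(match(d$histology, lev))],
                 ploidy = if (any(abs(d$di - 1) >= di_tol)) "aneuploid"
                          else "diploid",
                 n_biopsies = nrow(d), stringsAsFactors = FALSE)
    }))
  n_sub <- table(units$patient_id)
  units$exclusive <- n_sub[units$patient_id] == 1L
  units <- units[order(units$patient_id, units$subsite),
                 c("patient_id", "subsite", "unit_id", "histology", "ploidy",
                   "exclusive", "n_biopsies")]
  rownames(units) <- NULL
  units
}

normalize_histology <- function(h) {
  h <- as.character(h)
  out <- rep(NA_character_, length(h))
  out[h == "ND-OPMD"] <- "ND-OPMD"
  out[grepl("^D-OPMD", h)] <- "D-OPMD"  # graded dysplasia collapses here
  out[h == "OSCC"] <- "OSCC"
  out
}

#' Per-unit presence of recurrent CNAs
#'
#' A unit carries a CNA label iff any of its biopsies carries an event
#' matching the label's class, direction and location (any-rule, counted
#' once).
#'
#' @param units data.frame from [build_units()].
#' @param events stacked [classify_events()] output over all biopsies.
#' @param recurrent data.frame of labels from [recurrent_cnas()] (typically
#'   the retained rows).
#' @param metadata biopsy metadata mapping `biopsy_id` to patient/subsite.
#' @return binary matrix, units (rownames `unit_id`) x labels.
#' @export
unit_cna_presence <- function(units, events, recurrent, metadata) {
  orphan <- setdiff(unique(events$sample), metadata$biopsy_id)
  if (length(orphan))
    stop("unit_cna_presence: events reference unknown biopsies: ",
         paste(orphan, collapse = ", "))
  unit_of <- stats::setNames(
    paste(metadata$patient_id, metadata$subsite, sep = "_"),
    metadata$biopsy_id)
  m <- matrix(0L, nrow(units), nrow(recurrent),
              dimnames = list(units$unit_id, recurrent$label))
  for (i in seq_len(nrow(recurrent))) {
    s <- matching_samples(events, recurrent$class[i], recurrent$direction[i],
                          recurrent$chrom[i], recurrent$unit[i])
    u <- unique(unit_of[s])
    m[rownames(m) %in% u, i] <- 1L
  }
  m
}

#' Total CNA burden scores per statistical unit
#'
#' TFG / TFL count the distinct cytobands affected by at least one focal gain
#' / loss in any biopsy of the unit; TBG / TBL count the distinct arm-level
#' broad regions (keyed by chromosome arm and direction) present in at least
#' one biopsy. Each band or arm region contributes once regardless of how
#' many biopsies or events hit it.
#'
#' @param units data.frame from [build_units()].
#' @param events stacked [classify_events()] output.
#' @param metadata biopsy metadata mapping `biopsy_id` to patient/subsite.
#' @return `units` with columns `TFG`, `TBG`, `TFL`, `TBL` appended.
#' @export
total_scores <- function(units, events, metadata) {
  unit_of <- stats::setNames(
    paste(metadata$patient_id, metadata$subsite, sep = "_"),
    metadata$biopsy_id)
  bands <- event_band_labels(events)
  bands$unit <- unit_of[bands$sample]
  broad <- events[events$class == "broad", , drop = FALSE]
  broad$unit <- if (nrow(broad)) unit_of[broad$sample] else character()
  count_distinct <- function(d, key, uid) {
    if (!nrow(d)) return(0L)
    length(unique(key[d$unit == uid]))
  }
  units$TFG <- units$TBG <- units$TFL <- units$TBL <- 0L
  fg <- bands[bands$direction == "gain", , drop = FALSE]
  fl <- bands[bands$direction == "loss", , drop = FALSE]
  bg <- broad[broad$direction == "gain", , drop = FALSE]
  bl <- broad[broad$direction == "loss", , drop = FALSE]
  for (i in seq_len(nrow(units))) {
    uid <- units$unit_id[i]
    units$TFG[i] <- count_distinct(fg, paste(fg$chrom, fg$band), uid)
    units$TFL[i] <- count_distinct(fl, paste(fl$chrom, fl$band), uid)
    units$TBG[i] <- count_distinct(bg, paste(bg$chrom, bg$arm), uid)
    units$TBL[i] <- count_distinct(bl, paste(bl$chrom, bl$arm), uid)
  }
  units
}
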