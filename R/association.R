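#' Default association-analysis plan
#'
#' Mirrors the study's analysis layout: per-CNA 2x2 Fisher tests of presence
#' vs ploidy within histology strata, vs histology group, and vs subsite
#' (TNG against BM), each with discrete-FDR q-values as a separate family;
#' and Mann-Whitney comparisons of the four total burden scores (TFG, TBG,
#' TFL, TBL) between histology groups, ploidy classes, and TNG/BM subsites,
#' each a Benjamini-Hochberg family of size 4.
#'
#' @return list of plan entries for [run_association_suite()].
#' @export
default_association_plan <- function() {
  list(
    list(name = "cna_ploidy", type = "cna2x2", group = "ploidy",
         levels = c("diploid", "aneuploid"), strata = "histology_group",
         family = "carlson"),
    list(name = "cna_histology", type = "cna2x2", group = "histology_group",
         levels = c("ND-OPMD", "D-OPMD/OSCC"), strata = NULL,
         family = "carlson"),
    list(name = "cna_subsite", type = "cna2x2", group = "subsite",
         levels = c("BM", "TNG"), strata = NULL, family = "carlson"),
    list(name = "totals_histology", type = "mw", group = "histology_group",
         levels = c("ND-OPMD", "D-OPMD/OSCC"),
         scores = c("TFG", "TBG", "TFL", "TBL"), m = 4),
    list(name = "totals_ploidy", type = "mw", group = "ploidy",
         levels = c("diploid", "aneuploid"),
         scores = c("TFG", "TBG", "TFL", "TBL"), m = 4),
    list(name = "totals_subsite", type = "mw", group = "subsite",
         levels = c("BM", "TNG"),
         scores = c("TFG", "TBG", "TFL", "TBL"), m = 4))
}

#' Run the association-testing suite
#'
#' Executes a plan of per-CNA 2x2 contingency analyses (Fisher exact test
#' with odds ratio, discrete-FDR or BH q-values per declared family) and
#' two-group Mann-Whitney comparisons of total burden scores over the
#' statistical units. Units outside an analysis' two group levels are
#' excluded from that analysis. `histology_group` (ND-OPMD vs D-OPMD/OSCC)
#' is derived automatically.
#'
#' @param units data.frame from [total_scores()] (must carry the score
#'   columns for `mw` analyses).
#' @param presence binary matrix units x CNA labels from
#'   [unit_cna_presence()].
#' @param plan list of analysis specs; see [default_association_plan()].
#' @param q_threshold significance flag cutoff on q; default 0.1.
#' @param alpha_cap Carlson filtering cap; default 0.05.
#' @return data.frame with one row per executed test: `analysis`, `stratum`,
#'   `label`, counts `n1_without`, `n1_with`, `n2_without`, `n2_with` (2x2
#'   analyses) or group sizes, `statistic`, `or`, `ci_lo`, `ci_hi`,
#'   `prevalence`, `p`, `q`, `filtered`, `significant`.
#' @export
run_association_suite <- function(units, presence, plan = NULL,
                                  q_threshold = 0.1, alpha_cap = 0.05) {
  if (is.null(plan)) plan <- default_association_plan()
  units$histology_group <- ifelse(units$histology == "ND-OPMD",
                                  "ND-OPMD", "D-OPMD/OSCC")
  res <- list()
  for (an in plan) {
    if (!an$group %in% names(units))
      stop("run_association_suite: unknown grouping column '", an$group, "'")
    if (!is.null(an$strata) && !an$strata %in% names(units))
      stop("run_association_suite: unknown strata column '", an$strata, "'")
    strata_vals <- if (is.null(an$strata)) "" else
      sort(unique(units[[an$strata]]))
    for (st in strata_vals) {
      u <- if (st == "") units else units[units[[an$strata]] == st, ,
                                          drop = FALSE]
      u <- u[u[[an$group]] %in% an$levels, , drop = FALSE]
      g <- factor(u[[an$group]], levels = an$levels)
      if (an$type == "cna2x2") {
        res[[length(res) + 1L]] <-
          suite_cna2x2(an, st, u, g, presence, q_threshold, alpha_cap)
      } else if (an$type == "mw") {
        if (!all(an$scores %in% names(u)))
          stop("run_association_suite: unknown score column(s)")
        res[[length(res) + 1L]] <-
          suite_mw(an, st, u, g, q_threshold)
      } else stop("run_association_suite: unknown analysis type '",
                  an$type, "'")
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

suite_cna2x2 <- function(an, st, u, g, presence, q_threshold, alpha_cap) {
  labs <- colnames(presence)
  if (is.null(presence) || length(labs) == 0L) return(NULL)
  pres <- presence[match(u$unit_id, rownames(presence)), , drop = FALSE]
  rows <- list()
  tables <- list()
  for (lab in labs) {
    x <- pres[, lab]
    tab <- matrix(c(sum(g == an$levels[1] & x == 0),
                    sum(g == an$levels[1] & x == 1),
                    sum(g == an$levels[2] & x == 0),
                    sum(g == an$levels[2] & x == 1)), 2, 2, byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    ft <- if (degenerate) list(p = NA_real_, or = NA_real_,
                               ci = c(NA_real_, NA_real_))
          else fisher_2x2(tab)
    f1 <- tab[1, 2] / sum(tab[1, ])
    f2 <- tab[2, 2] / sum(tab[2, ])
    prev <- if (degenerate || f1 == f2) NA_character_
            else an$levels[which.max(c(f1, f2))]
    rows[[lab]] <- data.frame(
      analysis = an$name, stratum = st, label = lab,
      n1_without = tab[1, 1], n1_with = tab[1, 2],
      n2_without = tab[2, 1], n2_with = tab[2, 2],
      statistic = ft$or, or = ft$or, ci_lo = ft$ci[1], ci_hi = ft$ci[2],
      prevalence = prev, p = ft$p, q = NA_real_, filtered = degenerate,
      stringsAsFactors = FALSE)
    if (!degenerate) tables[[lab]] <- tab
  }
  out <- do.call(rbind, rows)
  if (length(tables)) {
    fam <- if (identical(an$family, "bh")) {
      p <- vapply(names(tables), function(l) out$p[out$label == l], numeric(1))
      data.frame(filtered = rep(FALSE, length(tables)),
                 q = bh_qvalues(p, m = if (is.null(an$m)) length(p) else an$m))
    } else carlson_fdr(tables, filter = TRUE, alpha_cap = alpha_cap)
    out$q[match(names(tables), out$label)] <- fam$q
    out$filtered[match(names(tables), out$label)] <- fam$filtered
  }
  out$significant <- !is.na(out$q) & out$q < q_threshold
  rownames(out) <- NULL
  out
}

suite_mw <- function(an, st, u, g, q_threshold) {
  m <- if (is.null(an$m)) length(an$scores) else an$m
  rows <- lapply(an$scores, function(sc) {
    x <- u[[sc]][g == an$levels[1]]
    y <- u[[sc]][g == an$levels[2]]
    if (!length(x) || !length(y)) {
      return(data.frame(analysis = an$name, stratum = st, label = sc,
                        n1_without = length(x), n1_with = NA_integer_,
                        n2_without = length(y), n2_with = NA_integer_,
                        statistic = NA_real_, or = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        prevalence = NA_character_, p = NA_real_,
                        q = NA_real_, filtered = TRUE,
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(x, y)
    prev <- if (mean(x) == mean(y)) NA_character_
            else an$levels[which.max(c(mean(x), mean(y)))]
    data.frame(analysis = an$name, stratum = st, label = sc,
               n1_without = length(x), n1_with = NA_integer_,
               n2_without = length(y), n2_with = NA_integer_,
               statistic = mw$U, or = NA_real_, ci_lo = NA_real_,
               ci_hi = NA_real_, prevalence = prev, p = mw$p, q = NA_real_,
               filtered = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bh_qvalues(out$p[ok], m = max(m, sum(ok)))
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out
}
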