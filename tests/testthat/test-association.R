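test_that("Fisher 2x2 reproduces printed cohort p-values to 4 decimals", {
  # CNA-vs-ploidy and CNA-vs-histology/subsite rows with published p-values
  expect_equal(round(fisher_2x2(c(35, 0, 7, 4))$p, 4), 0.0020)
  expect_equal(round(fisher_2x2(c(10, 25, 9, 2))$p, 4), 0.0036)
  expect_equal(round(fisher_2x2(c(46, 0, 40, 8))$p, 4), 0.0057)
  expect_equal(round(fisher_2x2(c(20, 7, 15, 28))$p, 4), 0.0029)
  expect_equal(round(fisher_2x2(c(19, 8, 14, 29))$p, 4), 0.0030)
  expect_equal(round(fisher_2x2(c(26, 1, 30, 13))$p, 4), 0.0064)
  expect_equal(fisher_2x2(c(5, 5, 5, 5))$p, 1)
  expect_error(fisher_2x2(c(3, 4, 0, 0)), "empty margin")
})

test_that("Fisher p agrees with the base-R oracle and is swap-invariant", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + (i %% 3 == 0), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_2x2(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
    # simultaneous row and column swap leaves p unchanged
    expect_equal(fisher_2x2(tab[2:1, 2:1])$p, fisher_2x2(tab)$p,
                 tolerance = 1e-12)
  }
  # Haldane-corrected OR and Woolf CI with a zero cell
  ft <- fisher_2x2(c(35, 0, 7, 4))
  cc <- matrix(c(35, 0, 7, 4), 2, 2, byrow = TRUE) + 0.5
  or <- cc[1, 1] * cc[2, 2] / (cc[1, 2] * cc[2, 1])
  expect_equal(ft$or, or)
  expect_true(ft$ci[1] < ft$or && ft$or < ft$ci[2])
})

test_that("Breslow-Day detects odds-ratio heterogeneity", {
  hom <- breslow_day(list(matrix(c(10, 10, 10, 10), 2),
                          matrix(c(10, 10, 10, 10), 2)))
  expect_equal(hom$statistic, 0, tolerance = 1e-10)
  expect_equal(hom$p, 1)

  het <- breslow_day(list(matrix(c(20, 5, 5, 20), 2, byrow = TRUE),
                          matrix(c(4, 16, 16, 4), 2, byrow = TRUE)))
  expect_gt(het$statistic, 3.84)
  expect_lt(het$p, 0.05)
  expect_equal(het$df, 1)

  expect_error(breslow_day(list(matrix(c(10, 10, 10, 10), 2))), "2 usable")
  expect_warning(
    breslow_day(list(matrix(c(10, 10, 10, 10), 2),
                     matrix(c(12, 9, 11, 8), 2),
                     matrix(c(0, 0, 5, 5), 2))),
    "empty margins")
})

test_that("Mann-Whitney matches exact enumeration and the base-R oracle", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p, 1 / 3, tolerance = 1e-12)
  sep <- mann_whitney(1:10, 11:20)
  expect_equal(sep$U, 0)
  expect_lt(sep$p, 0.01)
  # identical samples: approximation path, p = 1
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1, tolerance = 0.05)

  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    ours <- mann_whitney(x, y)
    expect_true(ours$exact)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # exact and approximation agree within 0.02 at n1 = n2 = 8
    approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(ours$p - approx), 0.02)
  }
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("Cohen's kappa follows its definition", {
  u <- rep(c(1, 0), c(7, 5))
  expect_equal(cohens_kappa(u, u), 1)
  # independence table [[9,21],[21,49]]: kappa exactly 0
  u2 <- rep(c(1, 1, 0, 0), c(9, 21, 21, 49))
  v2 <- rep(c(1, 0, 1, 0), c(9, 21, 21, 49))
  expect_equal(cohens_kappa(u2, v2), 0)
  # strong agreement table [[30,3],[2,35]]
  u3 <- rep(c(1, 1, 0, 0), c(30, 3, 2, 35))
  v3 <- rep(c(1, 0, 1, 0), c(30, 3, 2, 35))
  expect_equal(round(cohens_kappa(u3, v3), 4), 0.8564)
  expect_error(cohens_kappa(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("BH q-values reproduce the aneuploidy-by-histology family", {
  # printed p-values for ND-OPMD vs D-OPMD, ND-OPMD vs OSCC, D-OPMD vs OSCC
  p <- c(2.8e-3, 1.3e-15, 1.9e-3)
  q <- bh_qvalues(p, m = 3)
  expect_equal(signif(q, 2), c(2.8e-3, 3.9e-15, 2.8e-3))
  expect_equal(bh_qvalues(0.04, m = 1), 0.04)
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  # agreement with the base-R oracle, including m > length(p)
  set.seed(3)
  pv <- runif(20)
  expect_equal(bh_qvalues(pv), p.adjust(pv, "BH"))
  expect_equal(bh_qvalues(pv, m = 40), p.adjust(pv, "BH", n = 40))
  expect_true(all(bh_qvalues(pv) >= pv))
  expect_error(bh_qvalues(c(0.2, 0)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.2, 0.3), m = 1), "family size")
})

test_that("discrete FDR handles single tables, filtering and monotonicity", {
  # margins 2/2/2/2: three attainable tables, observed p = q = 1/3
  single <- carlson_fdr(list(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
                        filter = FALSE)
  expect_equal(single$p, 1 / 3, tolerance = 1e-12)
  expect_equal(single$q, 1 / 3, tolerance = 1e-12)
  # under filtering this table is provably irrelevant (min p = 1/3 > cap)
  expect_true(carlson_fdr(list(matrix(c(2, 0, 0, 2), 2)))$filtered)

  # tiny margins cannot reach alpha_cap: whole family filtered out
  fam <- replicate(3, matrix(c(1, 1, 1, 1), 2), simplify = FALSE)
  out <- carlson_fdr(fam, filter = TRUE, alpha_cap = 0.05)
  expect_true(all(out$filtered))
  expect_true(all(is.na(out$q)))

  # q non-decreasing in p within a family
  set.seed(9)
  fam2 <- replicate(12, matrix(rpois(4, 10) + 1, 2), simplify = FALSE)
  out2 <- carlson_fdr(fam2, filter = FALSE)
  o <- order(out2$p)
  expect_true(all(diff(out2$q[o]) >= -1e-12))
})

test_that("the association suite reproduces the ND-OPMD ploidy stratum", {
  # Reconstruct the ND-OPMD stratum of the CNA-vs-ploidy analysis from its
  # printed contingency rows (35 + 0 + 7 + 4 etc. over 46 units).
  rows <- list(
    "8p gain" = c(35, 0, 7, 4), "8p11.23 gain" = c(35, 0, 7, 4),
    "14q32.33 gain" = c(10, 25, 9, 2), "8q gain" = c(34, 1, 7, 4),
    "19q loss" = c(35, 0, 8, 3), "19p loss" = c(35, 0, 8, 3),
    "11p15.5 gain" = c(15, 20, 9, 2), "15q11.1 gain" = c(32, 3, 7, 4))
  printed_p <- c(0.0020, 0.0020, 0.0036, 0.0088, 0.0109, 0.0109,
                 0.0376, 0.0458)
  units <- data.frame(
    patient_id = sprintf("P%02d", 1:46), subsite = "BM",
    unit_id = sprintf("U%02d", 1:46), histology = "ND-OPMD",
    ploidy = rep(c("diploid", "aneuploid"), c(35, 11)),
    exclusive = TRUE, n_biopsies = 1L,
    TFG = 0L, TBG = 0L, TFL = 0L, TBL = 0L, stringsAsFactors = FALSE)
  presence <- sapply(rows, function(r) {
    # r = (diploid without, diploid with, aneuploid without, aneuploid with)
    c(rep(0L, r[1]), rep(1L, r[2]), rep(0L, r[3]), rep(1L, r[4]))
  })
  rownames(presence) <- units$unit_id
  plan <- list(list(name = "cna_ploidy", type = "cna2x2", group = "ploidy",
                    levels = c("diploid", "aneuploid"), strata = NULL,
                    family = "carlson"))
  res <- run_association_suite(units, presence, plan = plan)
  expect_equal(round(res$p[match(names(rows), res$label)], 4), printed_p)
  expect_equal(res$n1_without[res$label == "8p gain"], 35)
  expect_equal(res$n2_with[res$label == "8p gain"], 4)
  expect_equal(res$prevalence[res$label == "8p gain"], "aneuploid")
  expect_equal(res$prevalence[res$label == "14q32.33 gain"], "diploid")
  # discrete-FDR q-values are valid proportions and monotone in p
  ok <- !is.na(res$q)
  expect_true(all(res$q[ok] >= 0 & res$q[ok] <= 1))
  o <- order(res$p[ok])
  expect_true(all(diff(res$q[ok][o]) >= -1e-12))

  expect_error(run_association_suite(units, presence,
                                     plan = list(list(name = "x",
                                                      type = "cna2x2",
                                                      group = "nope",
                                                      levels = c("a", "b"),
                                                      strata = NULL))),
               "unknown grouping")
})

test_that("the suite flags a planted CNA-aneuploidy association", {
  set.seed(55)
  n <- 60
  ploidy <- rep(c("diploid", "aneuploid"), c(35, 25))
  units <- data.frame(
    patient_id = sprintf("P%02d", 1:n), subsite = "TNG",
    unit_id = sprintf("U%02d", 1:n), histology = "OSCC", ploidy = ploidy,
    exclusive = TRUE, n_biopsies = 1L,
    TFG = rpois(n, 1) + 3L * (ploidy == "aneuploid"),
    TBG = 0L, TFL = 0L, TBL = 0L, stringsAsFactors = FALSE)
  presence <- cbind(
    "8q24.3 gain" = rbinom(n, 1, ifelse(ploidy == "aneuploid", 0.7, 0.12)),
    "5p1 gain" = rbinom(n, 1, 0.2))
  rownames(presence) <- units$unit_id
  plan <- list(
    list(name = "cna_ploidy", type = "cna2x2", group = "ploidy",
         levels = c("diploid", "aneuploid"), strata = NULL,
         family = "carlson"),
    list(name = "totals_ploidy", type = "mw", group = "ploidy",
         levels = c("diploid", "aneuploid"),
         scores = c("TFG", "TBG", "TFL", "TBL"), m = 4))
  res <- run_association_suite(units, presence, plan = plan)
  hit <- res[res$label == "8q24.3 gain", ]
  expect_true(hit$significant)
  expect_equal(hit$prevalence, "aneuploid")
  tfg <- res[res$label == "TFG", ]
  expect_true(tfg$significant)
  expect_equal(tfg$prevalence, "aneuploid")
  # all-zero scores are untestable, not significant
  expect_false(res$significant[res$label == "TBG"])
})
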