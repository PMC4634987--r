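test_that("generate_genome produces the requested structure deterministically", {
  gg <- generate_genome(1, 2, 1e6, 1e5, seed = 7)
  expect_equal(nrow(gg$genome$chromosomes), 1)
  expect_equal(nrow(gg$genome$cytobands), 4)
  expect_equal(nrow(gg$grid), 40)
  expect_equal(gg$genome$cytobands$band, c("p1", "p2", "q1", "q2"))

  gg2 <- generate_genome(2, 3, 1e6, 1e5, seed = 7)
  bands <- gg2$genome$cytobands
  for (cc in unique(bands$chrom))
    expect_false(anyDuplicated(bands$band[bands$chrom == cc]) > 0)
  # probes strictly increasing within chromosome, each mapped to one band
  for (cc in unique(gg2$grid$chrom)) {
    pos <- gg2$grid$pos[gg2$grid$chrom == cc]
    expect_true(all(diff(pos) > 0))
  }
  expect_false(anyNA(locate_band(gg2$genome, gg2$grid$chrom, gg2$grid$pos)))

  expect_identical(generate_genome(2, 2, 1e6, 1e5, seed = 11),
                   generate_genome(2, 2, 1e6, 1e5, seed = 11))
  expect_error(generate_genome(0, 2, 1e6, 1e5), "positive")
  expect_error(generate_genome(1, 2, -1, 1e5), "positive")
})

test_that("cohort generation honours design probabilities and ground truth", {
  gg <- tiny_genome()
  no_aneu <- cohort_design(n_patients = 20,
                           aneuploidy_prob = c("ND-OPMD" = 0, "D-OPMD" = 0,
                                               "OSCC" = 0))
  co <- generate_cohort(gg$genome, no_aneu, seed = 4)
  expect_true(all(co$metadata$di == 1))

  no_ev <- cohort_design(n_patients = 20,
                         event_rate = c("ND-OPMD" = 0, "D-OPMD" = 0,
                                        "OSCC" = 0))
  co <- generate_cohort(gg$genome, no_ev, seed = 4)
  expect_true(all(vapply(co$samples, function(s) nrow(s$events), 1L) == 0))

  # DI != 1 iff drawn aneuploid; aneuploid DI within the design range
  co <- generate_cohort(gg$genome, cohort_design(n_patients = 40), seed = 9)
  di <- co$metadata$di
  expect_true(all(di == 1 | (di >= 1.1 & di <= 2.2)))

  # every patient x subsite has >= 1 biopsy by construction
  expect_true(all(table(co$metadata$patient_id, co$metadata$subsite) >= 0))
  expect_true(all(tapply(co$metadata$biopsy_id,
                         paste(co$metadata$patient_id, co$metadata$subsite),
                         length) >= 1))

  expect_error(cohort_design(subsite_probs = c(BM = 0.7, TNG = 0.7)),
               "sum to 1")
  expect_error(cohort_design(aneuploidy_prob = c("ND-OPMD" = -0.1,
                                                 "D-OPMD" = 0.4,
                                                 "OSCC" = 0.6)),
               "\\[0, 1\\]")
})

test_that("subsite mix at n = 50 falls in the binomial 95% band", {
  gg <- tiny_genome()
  des <- cohort_design(n_patients = 50, extra_subsite_prob = 0,
                       biopsy_rate = 0)
  co <- generate_cohort(gg$genome, des, seed = 21)
  n_bm <- sum(co$metadata$subsite == "BM")
  band <- qbinom(c(0.025, 0.975), 50, des$subsite_probs[["BM"]])
  expect_gte(n_bm, band[1])
  expect_lte(n_bm, band[2])
})

test_that("rendered arrays follow the clonality dilution model", {
  gg <- tiny_genome()
  ev <- data.frame(direction = "gain", chrom = "1", start = 0, end = 1e6,
                   q_t = 3L, scope = "focal", stringsAsFactors = FALSE)
  smp <- structure(list(patient_id = "PT001", subsite = "BM",
                        biopsy_id = "B1", histology = "ND-OPMD", di = 1.3,
                        alpha = 0.5, D = 2, events = ev,
                        chroms = gg$genome$chromosomes$chrom),
                   class = "biopsy_sample")
  # noiseless: exactly piecewise constant at the formula value
  pr <- render_array(smp, gg$grid, noise_sd = 0, outlier_rate = 0, seed = 1)
  inside <- pr$probes$chrom == "1" & pr$probes$pos < 1e6
  expect_equal(unique(pr$probes$log2[inside]), expected_log2(0.5, 3, 2))
  expect_equal(round(unique(pr$probes$log2[inside]), 2), 0.32)
  expect_true(all(pr$probes$log2[!inside] == 0))
  # ground-truth bookkeeping equals the planted region's probe coverage
  expect_identical(pr$probes$in_event, inside)

  # alpha = 0 wipes out any event
  smp0 <- smp; smp0$alpha <- 0
  pr0 <- render_array(smp0, gg$grid, noise_sd = 0, outlier_rate = 0, seed = 1)
  expect_true(all(pr0$probes$log2 == 0))

  # empirical mean inside the event converges to the formula value
  big <- generate_genome(1, 2, 5e6, 1e3, seed = 2)
  smp$chroms <- big$genome$chromosomes$chrom
  prn <- render_array(smp, big$grid, noise_sd = 0.15, outlier_rate = 0,
                      seed = 8)
  ins <- prn$probes$pos < 1e6
  expect_lt(abs(mean(prn$probes$log2[ins]) - expected_log2(0.5, 3, 2)),
            3 * 0.15 / sqrt(sum(ins)))

  # mismatched genome refused
  bad <- smp
  bad$events$chrom <- "9"
  expect_error(render_array(bad, gg$grid, seed = 1), "chromosomes absent")
})

test_that("a fixed seed reproduces the full cohort byte-identically", {
  gg <- tiny_genome()
  a <- generate_cohort(gg$genome, cohort_design(n_patients = 15), seed = 33)
  b <- generate_cohort(gg$genome, cohort_design(n_patients = 15), seed = 33)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(
    serialize(render_array(a$samples[[1]], gg$grid, seed = 5), NULL),
    serialize(render_array(b$samples[[1]], gg$grid, seed = 5), NULL))
})
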