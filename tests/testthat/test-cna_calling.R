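test_that("the clonality formula reproduces its printed reference points", {
  # hemizygous deletion / single copy gain at 50% cancer cell fraction
  expect_lt(abs(expected_log2(0.5, 1, 2) - (-0.41)), 0.0051)
  expect_equal(round(expected_log2(0.5, 3, 2), 2), 0.32)
  expect_equal(expected_log2(0.3, 2, 2), 0)   # q_t = D is neutral
  expect_equal(expected_log2(1, 4, 2), 1)
  expect_identical(expected_log2(1, 0, 2), -Inf)  # homozygous deletion
  expect_error(expected_log2(1.2, 2, 2), "alpha")
  expect_error(expected_log2(0.5, -1, 2), "q_t")
  expect_error(expected_log2(0.5, 2, 0), "D")
})

test_that("segment calling applies inclusive thresholds and merges runs", {
  segs <- stack_segments(data.frame(
    sample = "S1", chrom = "1",
    start = c(0, 10, 20, 30, 40) * 1e5,
    end = c(10, 20, 30, 40, 50) * 1e5,
    n_probes = c(10L, 10L, 10L, 10L, 10L),
    mean = c(0.32, 0.30, 0.0, -0.30, -0.6)))
  called <- call_segments(segs)
  expect_equal(called$state, c("gain", "neutral", "loss"))
  expect_equal(called$n_probes, c(20L, 10L, 20L))
  # merged mean is probe-weighted
  expect_equal(called$mean[1], mean(c(0.32, 0.30)))
  # idempotent under re-merging
  expect_equal(call_segments(called), called)
  expect_error(call_segments(segs, gain_thr = -0.1))
})

test_that("events split at the centromere and classify by the half-arm rule", {
  gg <- tiny_genome()  # arms of 2 Mb, bands of 1 Mb, centromere at 2 Mb
  mk <- function(start, end, mean) {
    d <- data.frame(sample = "S1", chrom = "1", start = start, end = end,
                    n_probes = 10L, mean = mean, state = "gain",
                    stringsAsFactors = FALSE)
    d$state <- ifelse(mean >= 0.3, "gain", ifelse(mean <= -0.3, "loss",
                                                  "neutral"))
    d
  }
  # 60% of 1p -> broad gain on arm p
  ev <- classify_events(mk(0, 1.2e6, 0.5), gg$genome)
  expect_equal(ev$class, "broad")
  expect_equal(ev$arm, "p")
  expect_equal(ev$label, "1p gain")
  expect_equal(ev$arm_frac, 0.6)

  # single cytoband -> focal with that band
  ev <- classify_events(mk(2e6, 3e6, 0.5), gg$genome)
  expect_equal(ev$class, "focal")
  expect_equal(ev$bands, "q1")
  expect_equal(ev$label, "1q1 gain")

  # whole chromosome -> broad on both arms
  ev <- classify_events(mk(0, 4e6, -0.5), gg$genome)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$label, c("1p loss", "1q loss"))
  expect_equal(ev$arm_frac, c(1, 1))

  # exactly half an arm is focal (strict > 0.5), spanning both its bands
  ev <- classify_events(mk(2e6, 3e6 + 1e6, 0.5), gg$genome)
  expect_equal(ev$class, "broad")  # 2 Mb of the 2 Mb arm
  ev <- classify_events(mk(2e6, 2e6 + 1e6, 0.5), gg$genome)
  expect_equal(ev$class, "focal")  # 1 Mb of 2 Mb = exactly half

  expect_error(classify_events(mk(0, 9e6, 0.5), gg$genome), "outside")
})

test_that("recurrence testing retains planted markers and rejects noise", {
  gg <- tiny_genome()
  set.seed(31)
  n_probes <- nrow(gg$grid)
  profiles <- lapply(1:10, function(i) {
    y <- rnorm(n_probes, 0, 0.1)
    if (i <= 8) {  # gain of band 1q2 ([3e6, 4e6) on chrom 1) in 8 of 10
      sel <- gg$grid$chrom == "1" & gg$grid$pos >= 3e6
      y[sel] <- y[sel] + 0.6
    }
    if (i <= 6) {  # broad loss of all of 2q in 6 of 10
      sel <- gg$grid$chrom == "2" & gg$grid$pos >= 2e6
      y[sel] <- y[sel] - 0.6
    }
    array_profile(sprintf("S%02d", i),
                  data.frame(probe_id = gg$grid$probe_id,
                             chrom = gg$grid$chrom, pos = gg$grid$pos,
                             log2 = y, stringsAsFactors = FALSE))
  })
  segs <- do.call(rbind, lapply(profiles, segment_pcf))
  events <- classify_events(call_segments(segs), gg$genome)
  markers <- amplitude_matrices(segs, gg$grid, gg$genome)
  rc <- recurrent_cnas(events, markers, gg$genome, n_perm = 1000, seed = 1)

  focal_gain <- rc[rc$class == "focal" & rc$direction == "gain" &
                     rc$label == "1q2 gain", ]
  expect_true(focal_gain$retained)
  expect_lt(focal_gain$q, 0.25)
  expect_equal(focal_gain$n_carriers, 8L)

  broad_loss <- rc[rc$class == "broad" & rc$label == "2q loss", ]
  expect_true(broad_loss$retained)
  expect_equal(broad_loss$n_carriers, 6L)

  # presence vectors agree with the event lists that produced them
  ret <- rc[rc$retained, ]
  pres <- recurrent_presence(events, ret,
                             sprintf("S%02d", 1:10))
  for (i in seq_len(nrow(ret))) {
    carriers <- oralcna:::matching_samples(events, ret$class[i],
                                           ret$direction[i], ret$chrom[i],
                                           ret$unit[i])
    expect_equal(sum(pres[i, ]), length(unique(carriers)))
    expect_equal(unname(pres[i, ]) == 1L,
                 sprintf("S%02d", 1:10) %in% carriers)
  }

  # G-score is monotone in carriers and amplitude
  m2 <- markers
  sel <- rownames(m2$band) == "1:q2"
  m2$band[sel, "S09"] <- 0.9  # add a ninth strong carrier
  rc2 <- recurrent_cnas(events, m2, gg$genome, n_perm = 100, seed = 1)
  expect_gte(rc2$G[rc2$label == "1q2 gain" & rc2$class == "focal"],
             focal_gain$G)

  expect_error(recurrent_cnas(events, markers, gg$genome, n_perm = 10),
               "n_perm")
})

test_that("pure-noise profiles yield no retained recurrent CNAs", {
  gg <- tiny_genome()
  retained <- vapply(1:5, function(seed) {
    set.seed(seed + 100)
    profiles <- lapply(1:8, function(i)
      array_profile(sprintf("S%02d", i),
                    data.frame(probe_id = gg$grid$probe_id,
                               chrom = gg$grid$chrom, pos = gg$grid$pos,
                               log2 = rnorm(nrow(gg$grid), 0, 0.1),
                               stringsAsFactors = FALSE)))
    segs <- do.call(rbind, lapply(profiles, segment_pcf))
    events <- classify_events(call_segments(segs), gg$genome)
    markers <- amplitude_matrices(segs, gg$grid, gg$genome)
    rc <- recurrent_cnas(events, markers, gg$genome, n_perm = 200,
                         seed = seed)
    sum(rc$retained)
  }, numeric(1))
  expect_equal(median(retained), 0)
})
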