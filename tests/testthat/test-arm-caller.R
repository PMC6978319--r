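test_that("SEG files round-trip through the reader and writer", {
  seg <- toy_segments(rep("S1", 3), c("1", "1", "2"),
                      c(0, 100, 50), c(100, 200, 150),
                      c(0.5, -0.3, 0.125))
  f1 <- withr::local_tempfile(fileext = ".seg")
  f2 <- withr::local_tempfile(fileext = ".seg")
  write_segments(seg, f1)
  back <- read_segments(f1)
  expect_equal(nrow(back), 3L)
  expect_equal(back$seg_mean, seg$seg_mean)
  expect_equal(back$start_bp, seg$start_bp)
  write_segments(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("chromosome labels are normalized and errors name the problem", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tSegment_Mean",
               "S1\tchr17\t1\t100\t0.5"), f)
  seg <- read_segments(f)
  expect_identical(seg$chromosome, "17")
  expect_identical(seg$start_bp, 0)  # 1-based inclusive -> 0-based half-open

  writeLines(c("Sample\tChromosome\tStart\tEnd",
               "S1\t1\t1\t100"), f)
  expect_error(read_segments(f), "seg_mean")

  writeLines(c("Sample\tChromosome\tStart\tEnd\tSegment_Mean",
               "S1\t1\t1\t100\t0.1",
               "S1\t1\toops\t200\t0.1"), f)
  expect_error(read_segments(f), "line 3")
})

test_that("default arm model has 39 included arms and 78 signed events", {
  arms <- caa_arm_model()
  expect_equal(sum(arms$included), 39L)
  expect_equal(length(signed_events(arms)), 78L)
  # excluded arms are exactly the acrocentric short arms
  expect_setequal(arms$arm_id[!arms$included],
                  c("13p", "14p", "15p", "21p", "22p"))
  expect_silent(validate_arm_model(arms))
})

test_that("custom arm models load and invalid ones are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- as.data.frame(toy_arm_model())[, -3]  # arm_id is derived
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  arms <- load_arm_model(f)
  expect_equal(nrow(arms), 2L)
  expect_equal(signed_events(arms), c("+1p", "-1p", "+1q", "-1q"))

  bad <- tab
  bad$start_bp <- rev(bad$start_bp)  # q interval before p
  bad$end_bp <- rev(bad$end_bp)
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_arm_model(f), "precede")
})

test_that("arm fractions follow the threshold arithmetic", {
  arms <- toy_arm_model()
  # one 95-unit segment at +0.5 and one 5-unit at 0.0 on the 100-unit p arm
  seg <- toy_segments(rep("S1", 2), "1", c(0, 95), c(95, 100), c(0.5, 0))
  fr <- compute_arm_fractions(seg, arms)
  p <- fr[fr$arm_id == "1p", ]
  expect_equal(p$covered_bp, 100)
  expect_equal(p$gain_frac, 0.95)
  expect_equal(p$loss_frac, 0)
})

test_that("segment classification thresholds are strict", {
  arms <- toy_arm_model()
  seg <- toy_segments(c("S1", "S1"), "1", c(0, 120), c(100, 220),
                      c(0.2, -0.2))
  fr <- compute_arm_fractions(seg, arms)
  expect_equal(fr$covered_bp, c(100, 100))
  expect_equal(fr$gain_bp, c(0, 0))  # exactly 0.2 is not a gain
  expect_equal(fr$loss_bp, c(0, 0))  # exactly -0.2 is not a loss
})

test_that("centromere-overlapping segments are discarded entirely", {
  arms <- toy_arm_model()
  # spans the whole centromere: contributes to neither arm
  seg <- toy_segments("S1", "1", 90, 130, 1.0)
  # discarding the only segment empties the table, which warns
  expect_warning(fr <- compute_arm_fractions(seg, arms), "no segments")
  expect_equal(fr$covered_bp, c(0, 0))
  expect_equal(attr(fr, "dropped_centromere"), 1L)
  # 1 bp of overlap is enough to discard
  seg2 <- toy_segments("S1", "1", 0, 101, 1.0)
  expect_warning(fr2 <- compute_arm_fractions(seg2, arms), "no segments")
  expect_equal(fr2$covered_bp[fr2$arm_id == "1p"], 0)
})

test_that("clipping to arm boundaries is idempotent", {
  arms <- toy_arm_model()
  seg <- toy_segments(rep("S1", 2), "1", c(0, 121), c(99, 220),
                      c(0.5, -0.6))
  fr1 <- compute_arm_fractions(seg, arms)
  # segments already inside arms: recomputing changes nothing
  fr2 <- compute_arm_fractions(seg, arms)
  expect_equal(fr1, fr2)
  # conservation: gained + lost + neutral length equals covered length
  neutral <- fr1$covered_bp - fr1$gain_bp - fr1$loss_bp
  expect_true(all(neutral >= 0))
  expect_equal(fr1$gain_bp + fr1$loss_bp + neutral, fr1$covered_bp)
})

test_that("weighted-median recentring removes a constant sample shift", {
  arms <- toy_arm_model()
  seg <- toy_segments(rep("S1", 2), "1", c(0, 120), c(100, 220),
                      c(0.7, 0.7))
  fr <- compute_arm_fractions(seg, arms, recenter = "weighted_median")
  expect_equal(fr$gain_frac, c(0, 0))  # shift removed, nothing called
})

test_that("CAA calls honour the >= 0.9 rule and flag uncallable arms", {
  arms <- toy_arm_model()
  mk <- function(gain_len) {
    toy_segments(rep("S1", 2), "1", c(0, gain_len), c(gain_len, 100),
                 c(0.5, 0))
  }
  frac_call <- function(gain_len) {
    caas <- call_caas(compute_arm_fractions(mk(gain_len), arms))
    caas$calls["S1", "1p"]
  }
  expect_equal(frac_call(95), 1L)
  expect_equal(frac_call(90), 1L)   # exactly 0.90 is called
  expect_equal(frac_call(89), 0L)
  caas <- call_caas(compute_arm_fractions(mk(95), arms))
  expect_true(caas$uncallable["S1", "1q"])  # no coverage on the q arm
  expect_equal(caas$calls["S1", "1q"], 0L)
  expect_error(call_caas(compute_arm_fractions(mk(95), arms),
                         call_frac = 0.5), "0.5")
})

test_that("flat profiles produce all-zero calls and the no-CAA class", {
  arms <- toy_arm_model()
  seg <- toy_segments(rep("S1", 2), "1", c(0, 120), c(100, 220), c(0, 0))
  caas <- call_caas(compute_arm_fractions(seg, arms))
  expect_true(all(caas$calls == 0L))
  b <- summarize_burden(caas)
  expect_equal(as.character(b$gl_class), "no-CAA")
})

test_that("burden summary counts gains and losses consistently", {
  calls <- rbind(S1 = c(1L, 1L, -1L, 0L),
                 S2 = c(0L, 0L, 0L, 0L),
                 S3 = c(1L, 1L, -1L, -1L))
  colnames(calls) <- c("1p", "1q", "2p", "2q")
  b <- summarize_burden(caa_matrix(calls))
  expect_equal(b$n_gain, c(2L, 0L, 2L))
  expect_equal(b$n_loss, c(1L, 0L, 2L))
  expect_equal(b$n_caa, b$n_gain + b$n_loss)
  expect_equal(as.character(b$gl_class), c("G>L", "no-CAA", "G=L"))
})

test_that("WGD calls use the strict majority rule on autosomal length", {
  arms <- toy_arm_model()
  # 55% of covered length at major-allele CN 2 -> WGD+
  seg <- toy_segments(rep("S1", 2), "1", c(0, 120), c(100, 220),
                      c(0, 0), major_allele_cn = c(2L, 1L))
  seg$end_bp <- c(100, 120 + 81)  # p arm 100 bp at CN2, q arm 81 bp at CN1
  expect_true(call_wgd(seg, arms)[["S1"]])
  # exactly 50% -> WGD-
  seg50 <- toy_segments(rep("S1", 2), "1", c(0, 120), c(100, 220),
                        c(0, 0), major_allele_cn = c(2L, 1L))
  expect_false(call_wgd(seg50, arms)[["S1"]])
  # all major-allele CN 1 -> WGD-
  seg1 <- toy_segments("S1", "1", 0, 100, 0, major_allele_cn = 1L)
  expect_false(call_wgd(seg1, arms)[["S1"]])
  # no allele data -> NA with a warning, not an error
  seg_na <- toy_segments("S1", "1", 0, 100, 0)
  expect_warning(w <- call_wgd(seg_na, arms), "unavailable")
  expect_true(is.na(w[["S1"]]))
})

test_that("gain and loss calls are mutually exclusive for call_frac > 0.5", {
  arms <- caa_arm_model()
  for (seed in 1:5) {
    sim <- sim_segments(20, arms, event_rate = 0.3, noise_sd = 0.3,
                        seed = seed)
    fr <- compute_arm_fractions(sim$segments, arms)
    expect_true(all(fr$gain_frac + fr$loss_frac <= 1 + 1e-12,
                    na.rm = TRUE))
    caas <- call_caas(fr, call_frac = 0.51)
    expect_true(all(caas$calls %in% c(-1L, 0L, 1L)))
  }
})

test_that("the caller recovers planted truth exactly at zero noise", {
  arms <- caa_arm_model()
  sim <- sim_segments(30, arms, noise_sd = 0, focal_rate = 0, seed = 11)
  caas <- call_caas(compute_arm_fractions(sim$segments, arms))
  expect_identical(unname(caas$calls), unname(sim$truth$arm_events))
})
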