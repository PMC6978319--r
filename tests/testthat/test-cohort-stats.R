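test_that("expected gain:loss fractions equal exhaustive enumeration", {
  for (a in 1:10) {
    fr <- expected_gl_fractions(a)
    en <- enumerate_gl_fractions(a)
    expect_equal(c(fr$p_gt, fr$p_eq, fr$p_lt), unname(en),
                 tolerance = 1e-12)
    expect_equal(fr$p_gt + fr$p_eq + fr$p_lt, 1)       # fractions sum to 1
    expect_identical(fr$p_gt, fr$p_lt)                 # gain/loss symmetry
  }
  expect_equal(unlist(expected_gl_fractions(1)[, 2:4], use.names = FALSE),
               c(0.5, 0, 0.5))
  expect_equal(expected_gl_fractions(4)$p_eq, 0.375)
  expect_error(expected_gl_fractions(0), "positive")
})

test_that("expected class counts scale the fractions by the histogram", {
  out <- expected_gl_counts(data.frame(a = 1, f_a = 10))
  expect_equal(unname(out$overall), c(5, 0, 5))
  out <- expected_gl_counts(data.frame(a = 2, f_a = 8))
  expect_equal(unname(out$overall), c(2, 4, 2))
  out <- expected_gl_counts(data.frame(a = integer(), f_a = numeric()))
  expect_equal(unname(out$overall), c(0, 0, 0))
  # mixed histogram adds per-burden contributions
  out <- expected_gl_counts(c("1" = 10, "2" = 8))
  expect_equal(unname(out$overall), c(7, 4, 7))
})

test_that("chi-square bias test matches hand arithmetic and handles edge cases", {
  ht <- gl_bias_test(c(40, 20, 40), c(25, 50, 25))
  expect_equal(unname(ht$statistic), 36)
  expect_equal(unname(ht$parameter), 2)
  ht0 <- gl_bias_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  expect_warning(gl_bias_test(c(10, 5, 0), c(12, 0, 3)), "pooling")
  expect_error(
    suppressWarnings(gl_bias_test(c(10, 5), c(15, 0))), "fewer than two")
})

test_that("per-burden binomial bias test uses exact two-sided tails", {
  bur <- data.frame(
    sample_id = paste0("S", 1:10),
    n_gain = c(rep(1, 9), 0), n_loss = c(rep(0, 9), 1),
    n_caa = rep(1, 10),
    gl_class = factor(c(rep("G>L", 9), "G<L"),
                      levels = c("G>L", "G=L", "G<L", "no-CAA")))
  out <- gl_bias_by_burden(bur)
  # exact tail: 2 * P(X >= 9 | n = 10, p = 1/2) = 22/1024
  expect_equal(out$p, 22 / 1024, tolerance = 1e-12)
  expect_equal(out$frac_gt, 0.9)

  bur$n_gain <- c(rep(1, 5), rep(0, 5))
  bur$n_loss <- 1 - bur$n_gain
  bur$gl_class <- factor(ifelse(bur$n_gain == 1, "G>L", "G<L"),
                         levels = levels(bur$gl_class))
  expect_equal(gl_bias_by_burden(bur)$p, 1)

  # a stratum of pure ties is omitted
  ties <- data.frame(sample_id = "T1", n_gain = 1, n_loss = 1, n_caa = 2,
                     gl_class = factor("G=L",
                                       levels = levels(bur$gl_class)))
  expect_equal(nrow(gl_bias_by_burden(ties)), 0L)
})

test_that("binomial doubling agrees with full null enumeration", {
  for (n in c(4, 7, 10)) {
    for (x in 0:n) {
      # enumerate all 2^n equiprobable sign vectors
      counts <- dbinom(0:n, n, 0.5)
      p_ref <- min(1, 2 * min(sum(counts[(x + 1):(n + 1)]),
                              sum(counts[1:(x + 1)])))
      expect_equal(caatools:::.binom_two_sided(x, n), p_ref,
                   tolerance = 1e-12)
    }
  }
})

test_that("stage trend compares gain:loss distributions against stage I", {
  bur <- data.frame(sample_id = paste0("S", 1:40),
                    n_gain = rep(c(2, 1, 0, 2), 10),
                    n_loss = rep(c(0, 1, 2, 0), 10))
  bur$n_caa <- bur$n_gain + bur$n_loss
  bur$gl_class <- factor(ifelse(bur$n_gain > bur$n_loss, "G>L",
                                ifelse(bur$n_gain < bur$n_loss, "G<L",
                                       "G=L")),
                         levels = c("G>L", "G=L", "G<L", "no-CAA"))
  ann <- data.frame(sample_id = bur$sample_id,
                    stage = rep(c("I", "II"), each = 20))
  # stages III/IV absent: omitted with warnings
  warns <- capture_warnings(out <- stage_bias_trend(bur, ann))
  expect_match(warns, "no CAA-positive samples", all = TRUE)
  expect_length(warns, 2L)
  # stage II distribution identical to stage I -> p = 1
  expect_equal(out$p[out$stage == "II"], 1)
  expect_true(is.na(out$p[out$stage == "I"]))
  expect_error(stage_bias_trend(bur, transform(ann, stage = "II")),
               "stage I")
})

test_that("burden comparisons run MWU / signed-rank tests with BH q", {
  bur <- data.frame(sample_id = paste0("S", 1:20),
                    n_gain = rep(3, 20), n_loss = rep(3, 20),
                    n_caa = rep(6, 20))
  bur$gl_class <- factor("G=L", levels = c("G>L", "G=L", "G<L", "no-CAA"))
  ann <- data.frame(sample_id = bur$sample_id,
                    grp = rep(c("a", "b"), each = 10))
  out <- compare_burden(bur, ann, group_col = "grp")
  expect_equal(out$p, 1)  # identical groups

  ann3 <- transform(ann, grp = rep(c("a", "b", "c"), length.out = 20))
  expect_error(compare_burden(bur, ann3, group_col = "grp"), "2 groups")

  # paired: gains exceed losses by exactly 1 in all 10 samples ->
  # smallest attainable exact two-sided signed-rank p = 2/2^10
  bur10 <- data.frame(sample_id = paste0("S", 1:10),
                      n_gain = 2:11, n_loss = 1:10,
                      n_caa = 2:11 + 1:10)
  bur10$gl_class <- factor("G>L", levels = c("G>L", "G=L", "G<L", "no-CAA"))
  out <- compare_burden(bur10, paired = TRUE)
  expect_equal(out$p, 2 / 1024, tolerance = 1e-12)
  expect_match(out$method, "exact")

  # zero differences are dropped
  burz <- bur10
  burz$n_loss <- burz$n_gain
  burz$n_loss[1:3] <- burz$n_gain[1:3] - 1
  out <- compare_burden(burz, paired = TRUE)
  expect_equal(out$n_nonzero, 3L)
})

test_that("signed-rank normal approximation kicks in for larger n", {
  x <- c(1:20) + 0.5
  y <- rev(x) + rnorm(20, sd = 0.1)
  ht <- caatools:::signed_rank_test(x, y)
  expect_equal(ht$method, "normal")
  expect_true(ht$p >= 0 && ht$p <= 1)
})

test_that("per-event frequency differentials use two-sided Fisher tests", {
  calls <- matrix(0L, 20, 2, dimnames = list(paste0("S", 1:20),
                                             c("1p", "2q")))
  calls[1:10, 1] <- 1L  # +1p in all of group 1, never in group 2
  caas <- caa_matrix(calls)
  ann <- data.frame(sample_id = rownames(calls),
                    site = rep(c("metastatic", "primary"), each = 10))
  out <- caa_frequency_differential(caas, ann, "site")
  row <- out[out$event == "+1p", ]
  expect_equal(row$p, 2 / choose(20, 10), tolerance = 1e-10)
  # events absent in both groups keep p = q = 1
  absent <- out[out$event == "-2q", ]
  expect_equal(absent$p, 1)
  expect_equal(absent$q, 1)
  expect_true(all(out$q >= out$p))
})

test_that("q-value band codes follow the exponent convention", {
  expect_equal(q_band(c(0.2, 0.05, 0.049, 0.03, 0.009, 0.004, 4e-4, 0)),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 16L))
  expect_true(is.na(q_band(NA_real_)))
})

test_that("BH adjustment matches the reference step-up oracle", {
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("gain:loss bias test holds its size under the symmetric null", {
  # cohorts of independent equiprobable gains/losses: rejection rate at
  # alpha = 0.05 stays near nominal
  set.seed(2024)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- sample(1:6, 120, replace = TRUE)
    gains <- rbinom(120, a, 0.5)
    losses <- a - gains
    obs <- c(sum(gains > losses), sum(gains == losses),
             sum(gains < losses))
    exp_counts <- expected_gl_counts(as.table(table(a)))$overall
    rej[r] <- gl_bias_test(obs, exp_counts)$p.value < 0.05
  }
  expect_lte(mean(rej), 0.06)
})
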