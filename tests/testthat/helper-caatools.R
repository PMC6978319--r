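# shared fixtures built in code

# toy two-arm model on one chromosome: p = [0, 100), q = [120, 220),
# centromere = [100, 120)
toy_arm_model <- function() {
  arms <- data.frame(
    chromosome = "1", arm = c("p", "q"), arm_id = c("1p", "1q"),
    start_bp = c(0L, 120L), end_bp = c(100L, 220L),
    centromere_start_bp = 100L, centromere_end_bp = 120L,
    included = TRUE, stringsAsFactors = FALSE)
  class(arms) <- c("caa_arm_model", "data.frame")
  arms
}

toy_segments <- function(sample_id, chromosome, start, end, mean,
                         major_allele_cn = NULL) {
  seg <- data.frame(sample_id = sample_id, chromosome = chromosome,
                    start_bp = start, end_bp = end, seg_mean = mean,
                    stringsAsFactors = FALSE)
  if (!is.null(major_allele_cn)) seg$major_allele_cn <- major_allele_cn
  class(seg) <- c("caa_segments", "data.frame")
  seg
}

# reference toy cohort over two arms A and B:
# {+A}: 3 samples, {+A,+B}: 2 samples, {+A,-B}: 1 sample
toy_event_cohort <- function() {
  ev <- matrix(0L, 6, 4,
               dimnames = list(paste0("S", 1:6),
                               c("+A", "-A", "+B", "-B")))
  ev[, "+A"] <- 1L
  ev[4:5, "+B"] <- 1L
  ev[6, "-B"] <- 1L
  ev
}

# brute-force transition-matrix oracle: enumerate every parent -> child
# edge (child = observed karyotype, parent = child minus one event) and
# accumulate child frequencies for numerators and denominators
transition_oracle <- function(ev) {
  events <- colnames(ev)
  keys <- apply(ev, 1L, paste, collapse = "")
  tab <- table(keys)
  W <- matrix(0, length(events), length(events),
              dimnames = list(events, events))
  denom <- stats::setNames(numeric(length(events)), events)
  for (key in names(tab)) {
    u <- events[strsplit(key, "")[[1]] == "1"]
    f <- as.numeric(tab[[key]])
    if (length(u) < 1L) next
    for (y in u) {
      parent <- setdiff(u, y)
      for (x in parent) {
        W[x, y] <- W[x, y] + f
        denom[x] <- denom[x] + f
      }
    }
  }
  P <- W / ifelse(denom > 0, denom, 1)
  P[denom == 0, ] <- 0
  P
}

# random small cohort over a few arms for oracle-equivalence checks
random_small_cohort <- function(n_arms, n_samples) {
  arms <- LETTERS[seq_len(n_arms)]
  ev <- matrix(0L, n_samples, 2L * n_arms)
  colnames(ev) <- as.vector(rbind(paste0("+", arms), paste0("-", arms)))
  for (s in seq_len(n_samples)) {
    state <- sample(c(-1L, 0L, 1L), n_arms, replace = TRUE)
    ev[s, 2 * seq_len(n_arms) - 1] <- as.integer(state == 1L)
    ev[s, 2 * seq_len(n_arms)] <- as.integer(state == -1L)
  }
  ev
}

# reference Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# enumerate all 2^a equiprobable gain/loss assignments and count the
# G>L / G=L / G<L fractions
enumerate_gl_fractions <- function(a) {
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), a)))
  gains <- rowSums(signs == 1)
  losses <- a - gains
  c(p_gt = mean(gains > losses), p_eq = mean(gains == losses),
    p_lt = mean(gains < losses))
}
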