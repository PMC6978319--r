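#' Expected gain:loss class fractions for a given CAA burden
#'
#' Under the null that each of `a` arm-level events is independently a gain
#' or a loss with probability 1/2, the expected fraction of samples with
#' more gains than losses is `1/2 - choose(a, a/2)/2^(a+1)` for even `a` and
#' `1/2` for odd `a`; the tie fraction `G=L` is `choose(a, a/2)/2^a` for
#' even `a` and 0 for odd `a`; `G<L` equals `G>L` by symmetry. Computed with
#' log-binomial coefficients, so the three fractions sum to 1 exactly.
#'
#' @param a Vector of positive integer CAA burdens.
#' @return Data frame with columns `a`, `p_gt` (G>L), `p_eq` (G=L), `p_lt`
#'   (G<L).
#' @examples
#' expected_gl_fractions(1:4)
#' @export
expected_gl_fractions <- function(a) {
  if (length(a) == 0L || any(!is.finite(a)) || any(a < 1) ||
      any(a != round(a))) {
    stop("'a' must contain positive integers", call. = FALSE)
  }
  a <- as.integer(a)
  even <- a %% 2L == 0L
  p_eq <- numeric(length(a))
  p_eq[even] <- exp(lchoose(a[even], a[even] %/% 2L) - a[even] * log(2))
  p_gt <- (1 - p_eq) / 2
  data.frame(a = a, p_gt = p_gt, p_eq = p_eq, p_lt = p_gt)
}

#' Expected gain:loss class counts from a burden histogram
#'
#' Scales the per-burden expected fractions by the observed number of
#' samples at each burden, and totals them over the histogram, giving the
#' overall expected counts of `G>L`, `G=L` and `G<L` samples.
#'
#' @param hist Burden histogram: either a data frame with columns `a`
#'   (burden) and `f_a` (number of samples with exactly that burden), or a
#'   named numeric vector (names = burdens).
#' @return List with `by_a` (data frame of per-burden expected counts
#'   `e_gt`, `e_eq`, `e_lt`) and `overall` (named numeric totals
#'   `G>L`, `G=L`, `G<L`).
#' @examples
#' expected_gl_counts(data.frame(a = c(1, 2), f_a = c(10, 8)))
#' @export
expected_gl_counts <- function(hist) {
  if (is.data.frame(hist)) {
    stopifnot(all(c("a", "f_a") %in% names(hist)))
    a <- hist$a; f_a <- hist$f_a
  } else {
    a <- as.integer(names(hist)); f_a <- as.numeric(hist)
  }
  if (any(f_a < 0)) stop("histogram counts must be non-negative",
                         call. = FALSE)
  if (length(a) == 0L) {
    return(list(by_a = data.frame(a = integer(), f_a = numeric(),
                                  e_gt = numeric(), e_eq = numeric(),
                                  e_lt = numeric()),
                overall = c("G>L" = 0, "G=L" = 0, "G<L" = 0)))
  }
  fr <- expected_gl_fractions(a)
  by_a <- data.frame(a = a, f_a = f_a,
                     e_gt = fr$p_gt * f_a,
                     e_eq = fr$p_eq * f_a,
                     e_lt = fr$p_lt * f_a)
  list(by_a = by_a,
       overall = c("G>L" = sum(by_a$e_gt), "G=L" = sum(by_a$e_eq),
                   "G<L" = sum(by_a$e_lt)))
}

#' Chi-square goodness-of-fit test of observed vs expected gain:loss classes
#'
#' Pearson goodness-of-fit statistic without continuity correction, with
#' `df = (number of categories with positive expected count) - 1`.
#' Categories with zero expected count but non-zero observed count are
#' pooled into the category with the largest expected count (with a
#' warning); zero-expected zero-observed categories are dropped.
#'
#' @param observed Named numeric vector of observed category counts.
#' @param expected Numeric vector of expected counts on the same categories
#'   (e.g. the `overall` element of [expected_gl_counts()]).
#' @return An object of class `htest`.
#' @examples
#' gl_bias_test(c(40, 20, 40), c(25, 50, 25))  # X-squared = 36
#' @export
gl_bias_test <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("'observed' and 'expected' must have the same categories",
         call. = FALSE)
  }
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  zero <- expected == 0
  if (any(zero & observed > 0)) {
    warning("pooling ", sum(zero & observed > 0),
            " zero-expectation categor(ies) into the largest category",
            call. = FALSE)
    target <- which.max(expected)
    observed[target] <- observed[target] + sum(observed[zero])
  }
  observed <- observed[!zero]
  expected <- expected[!zero]
  if (length(observed) < 2L) {
    stop("chi-square test undefined: fewer than two categories with ",
         "positive expected counts", call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = paste("Chi-square goodness-of-fit test of",
                                "gain:loss class counts"),
                 data.name = "observed vs expected class counts"),
            class = "htest")
}

## two-sided exact binomial p for x successes in n trials at p0 = 1/2,
## doubling the smaller tail and capping at 1
.binom_two_sided <- function(x, n) {
  lower <- stats::pbinom(x, n, 0.5)
  upper <- stats::pbinom(x - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Gain-vs-loss bias stratified by CAA burden
#'
#' For each total burden `a`, tests whether samples with more gains than
#' losses outnumber samples with more losses than gains. Tied samples
#' (`G=L`, possible only at even `a`) are excluded and the remaining counts
#' are compared to a symmetric binomial null (probability 1/2) with an
#' exact two-sided p value (doubling the smaller tail, capped at 1). Odd
#' and even burdens are reported with their parity so they can be displayed
#' separately.
#'
#' @param burdens A `caa_burden` table from [summarize_burden()].
#' @param group Optional vector of sample ids restricting the analysis.
#' @return Data frame with one row per burden stratum: `a`, `parity`,
#'   `n_samples`, `n_gt`, `n_eq`, `n_lt`, `frac_gt` (fraction of all
#'   samples in the stratum with G>L) and `p`. Strata with no untied
#'   samples are omitted.
#' @export
gl_bias_by_burden <- function(burdens, group = NULL) {
  stopifnot(is.data.frame(burdens))
  b <- burdens[burdens$n_caa > 0, , drop = FALSE]
  if (!is.null(group)) b <- b[b$sample_id %in% group, , drop = FALSE]
  res <- lapply(sort(unique(b$n_caa)), function(a) {
    s <- b[b$n_caa == a, , drop = FALSE]
    n_gt <- sum(s$gl_class == "G>L")
    n_lt <- sum(s$gl_class == "G<L")
    n_eq <- sum(s$gl_class == "G=L")
    if (n_gt + n_lt < 1L) return(NULL)
    data.frame(a = a,
               parity = if (a %% 2L == 0L) "even" else "odd",
               n_samples = nrow(s), n_gt = n_gt, n_eq = n_eq, n_lt = n_lt,
               frac_gt = n_gt / nrow(s),
               p = .binom_two_sided(n_gt, n_gt + n_lt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(a = integer(), parity = character(),
                      n_samples = integer(), n_gt = integer(),
                      n_eq = integer(), n_lt = integer(),
                      frac_gt = numeric(), p = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Gain:loss class distribution across clinical stages
#'
#' Compares the `G>L` / `G=L` / `G<L` distribution of CAA-positive tumours
#' at each stage II-IV against stage I with a Pearson chi-square test on the
#' 3 x 2 contingency table (no continuity correction), and reports the
#' median CAA burden per stage.
#'
#' @param burdens A `caa_burden` table.
#' @param annotations Sample annotation data frame with `sample_id` and
#'   `stage` columns (stages `I`-`IV`).
#' @return Data frame with one row per stage: `stage`, `n`,
#'   `median_burden`, `statistic`, `df`, `p` (`NA` for the stage I
#'   reference row).
#' @export
stage_bias_trend <- function(burdens, annotations) {
  stopifnot(is.data.frame(burdens), is.data.frame(annotations))
  d <- merge(burdens, annotations[, c("sample_id", "stage")],
             by = "sample_id")
  d <- d[d$n_caa > 0 & !is.na(d$stage), , drop = FALSE]
  d$gl_class <- factor(as.character(d$gl_class),
                       levels = c("G>L", "G=L", "G<L"))
  if (!any(d$stage == "I")) {
    stop("reference level 'stage I' has no CAA-positive samples",
         call. = FALSE)
  }
  ref <- table(d$gl_class[d$stage == "I"])
  rows <- list(data.frame(stage = "I", n = sum(ref),
                          median_burden = stats::median(d$n_caa[d$stage == "I"]),
                          statistic = NA_real_, df = NA_integer_,
                          p = NA_real_, stringsAsFactors = FALSE))
  for (s in c("II", "III", "IV")) {
    cur <- table(d$gl_class[d$stage == s])
    if (sum(cur) == 0L) {
      warning("stage ", s, " has no CAA-positive samples; omitted",
              call. = FALSE)
      next
    }
    tab <- cbind(cur, ref)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <-
      data.frame(stage = s, n = sum(cur),
                 median_burden = stats::median(d$n_caa[d$stage == s]),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
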