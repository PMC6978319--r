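#' Probability that two events co-occur in exactly k samples
#'
#' Combinatorial null model for pairwise co-occurrence: given that event 1
#' occurs in `N1` of `N` samples and event 2 in `N2`, the probability that
#' they share exactly `k` samples is the ratio of binomial coefficients
#' `C(N,k) C(N-k, N2-k) C(N-N2, N1-k) / (C(N,N2) C(N,N1))`, evaluated in
#' log space. This equals the hypergeometric mass function with population
#' `N`, `N2` successes and `N1` draws. Infeasible `k` return 0.
#'
#' @param N Cohort size.
#' @param N1,N2 Number of samples carrying each event.
#' @param k Vector of co-occurrence counts.
#' @return Numeric vector of probabilities.
#' @examples
#' cooccurrence_pmf(4, 2, 2, 2)  # 1/6
#' sum(cooccurrence_pmf(20, 8, 5, 0:5))  # 1
#' @export
cooccurrence_pmf <- function(N, N1, N2, k) {
  stopifnot(length(N) == 1L, length(N1) == 1L, length(N2) == 1L)
  if (N < 0 || N1 < 0 || N2 < 0 || N1 > N || N2 > N) {
    stop("require 0 <= N1, N2 <= N", call. = FALSE)
  }
  out <- numeric(length(k))
  feas <- k >= max(0, N1 + N2 - N) & k <= min(N1, N2) & k == round(k)
  kk <- k[feas]
  lp <- lchoose(N, kk) + lchoose(N - kk, N2 - kk) +
    lchoose(N - N2, N1 - kk) - lchoose(N, N2) - lchoose(N, N1)
  out[feas] <- exp(lp)
  out
}

#' Tail probabilities for an observed co-occurrence count
#'
#' Both tails include the observed count: `p_gt` is the probability of
#' `k_obs` or more shared samples under the null, `p_lt` of `k_obs` or
#' fewer. The expected co-occurrence is `N1 * N2 / N`.
#'
#' @inheritParams cooccurrence_pmf
#' @param k_obs Observed number of samples carrying both events.
#' @return List with elements `p_gt`, `p_lt` and `expected`.
#' @export
cooccurrence_tails <- function(N, N1, N2, k_obs) {
  k_min <- max(0, N1 + N2 - N)
  k_max <- min(N1, N2)
  if (k_obs < k_min || k_obs > k_max) {
    stop("'k_obs' outside the feasible range [", k_min, ", ", k_max, "]",
         call. = FALSE)
  }
  pmf <- cooccurrence_pmf(N, N1, N2, k_min:k_max)
  ks <- k_min:k_max
  list(p_gt = sum(pmf[ks >= k_obs]),
       p_lt = sum(pmf[ks <= k_obs]),
       expected = if (N > 0) N1 * N2 / N else 0)
}

#' Pairwise co-occurrence scan over all signed-event pairs
#'
#' Evaluates every unordered pair of signed events (excluding the
#' structurally impossible gain/loss pair of one arm) against the
#' combinatorial null: observed and expected co-occurrence, upper and lower
#' tail probabilities, Benjamini-Hochberg q values, and a
#' positive/negative/random classification at level `alpha`. By default the
#' upper-tail (`p_gt`) and lower-tail (`p_lt`) families are FDR-adjusted
#' separately, mirroring the separate positive and negative co-occurrence
#' tallies; `fdr_family = "pooled"` adjusts them together.
#'
#' @param caas A `caa_matrix` or a binary samples x events matrix.
#' @param group Optional vector of sample ids (or row indices) restricting
#'   the scan.
#' @param alpha Significance level on q for classification.
#' @param fdr_family `"separate"` (default) or `"pooled"`.
#' @return Data frame of class `caa_cooccurrence` with one row per pair:
#'   `event1`, `event2`, `N`, `N1`, `N2`, `k_obs`, `expected`, `p_gt`,
#'   `p_lt`, `q_gt`, `q_lt`, `class`. Rows are in deterministic
#'   column-order of the event matrix. Attribute `N` stores the cohort
#'   size.
#' @examples
#' sim <- sim_cooccurrence_cohort(100, rep(0.3, 4), seed = 1)
#' scan <- pairwise_cooccurrence_scan(sim$events)
#' head(scan)
#' @export
pairwise_cooccurrence_scan <- function(caas, group = NULL, alpha = 0.05,
                                       fdr_family = c("separate", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  ev <- if (inherits(caas, "caa_matrix")) caa_events(caas) else as.matrix(caas)
  if (!all(ev %in% c(0L, 1L))) stop("event matrix must be binary",
                                    call. = FALSE)
  if (!is.null(group)) {
    ev <- if (is.character(group)) ev[rownames(ev) %in% group, , drop = FALSE]
    else ev[group, , drop = FALSE]
  }
  empty <- data.frame(event1 = character(), event2 = character(),
                      N = integer(), N1 = integer(), N2 = integer(),
                      k_obs = integer(), expected = numeric(),
                      p_gt = numeric(), p_lt = numeric(),
                      q_gt = numeric(), q_lt = numeric(),
                      class = character(), stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) {
    class(empty) <- c("caa_cooccurrence", "data.frame")
    return(empty)
  }
  events <- colnames(ev)
  counts <- colSums(ev)
  if (sum(counts > 0) < 2L) {
    warning("fewer than 2 events with nonzero counts", call. = FALSE)
  }
  info <- try(parse_events(events), silent = TRUE)
  arms <- if (inherits(info, "try-error")) seq_along(events) else info$arm
  K <- crossprod(ev)
  N <- nrow(ev)
  pairs <- which(upper.tri(K), arr.ind = TRUE)
  keep <- arms[pairs[, 1L]] != arms[pairs[, 2L]]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    class(empty) <- c("caa_cooccurrence", "data.frame")
    return(empty)
  }
  res <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    tl <- cooccurrence_tails(N, counts[i], counts[j], K[i, j])
    res[[r]] <- c(tl$p_gt, tl$p_lt, tl$expected)
  }
  res <- do.call(rbind, res)
  out <- data.frame(event1 = events[pairs[, 1L]],
                    event2 = events[pairs[, 2L]],
                    N = N,
                    N1 = as.integer(counts[pairs[, 1L]]),
                    N2 = as.integer(counts[pairs[, 2L]]),
                    k_obs = as.integer(K[pairs]),
                    expected = res[, 3L],
                    p_gt = res[, 1L], p_lt = res[, 2L],
                    stringsAsFactors = FALSE)
  if (fdr_family == "separate") {
    out$q_gt <- stats::p.adjust(out$p_gt, method = "BH")
    out$q_lt <- stats::p.adjust(out$p_lt, method = "BH")
  } else {
    q <- stats::p.adjust(c(out$p_gt, out$p_lt), method = "BH")
    out$q_gt <- q[seq_len(nrow(out))]
    out$q_lt <- q[nrow(out) + seq_len(nrow(out))]
  }
  out$class <- ifelse(out$q_gt < alpha, "positive",
                      ifelse(out$q_lt < alpha, "negative", "random"))
  attr(out, "N") <- N
  attr(out, "alpha") <- alpha
  class(out) <- c("caa_cooccurrence", "data.frame")
  out
}

#' Export co-occurrence scan results
#'
#' Writes the long-format record table (with volcano-plot-ready columns:
#' co-occurrence frequency, -log10 q of the classified tail, class) and a
#' square event x event class matrix, as tab-separated text.
#'
#' @param records A `caa_cooccurrence` table.
#' @param prefix Output path prefix; files `<prefix>_records.tsv` and
#'   `<prefix>_classes.tsv` are written.
#' @return Character vector of the two paths, invisibly.
#' @seealso [read_cooccurrence_records()]
#' @export
cooccurrence_matrix_export <- function(records, prefix) {
  stopifnot(is.data.frame(records))
  rec_path <- paste0(prefix, "_records.tsv")
  mat_path <- paste0(prefix, "_classes.tsv")
  rec <- as.data.frame(records)
  rec$cooc_frac <- ifelse(rec$N > 0, rec$k_obs / rec$N, NA_real_)
  qcl <- ifelse(rec$class == "negative", rec$q_lt,
                ifelse(rec$class == "positive", rec$q_gt,
                       pmin(rec$q_gt, rec$q_lt)))
  rec$neglog10_q <- -log10(qcl)
  num <- vapply(rec, is.double, logical(1L))
  rec[num] <- lapply(rec[num], fmt_full)
  utils::write.table(rec, rec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  events <- sort(unique(c(records$event1, records$event2)))
  cls <- matrix("", length(events), length(events),
                dimnames = list(events, events))
  if (nrow(records)) {
    i <- cbind(match(records$event1, events), match(records$event2, events))
    cls[i] <- records$class
    cls[i[, c(2L, 1L), drop = FALSE]] <- records$class
  }
  utils::write.table(cbind(event = events, as.data.frame(cls)), mat_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(records = rec_path, classes = mat_path))
}

#' Read back a co-occurrence record table
#'
#' @param path Path to a `<prefix>_records.tsv` file written by
#'   [cooccurrence_matrix_export()].
#' @return A `caa_cooccurrence` data frame.
#' @export
read_cooccurrence_records <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("caa_cooccurrence", "data.frame")
  out
}
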