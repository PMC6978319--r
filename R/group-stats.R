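## Wilcoxon signed-rank test with an exact sign-flip null.
## Zero differences are dropped (classical treatment); ranks of |d| may be
## tied, so for n <= max_exact the null distribution of the statistic is
## obtained by enumerating all 2^n sign assignments over the actual rank
## values; above that a normal approximation on the tied-rank variance is
## used. Two-sided p doubles the smaller tail (capped at 1); by the symmetry
## of the null this equals the usual symmetric-tail p.
signed_rank_test <- function(x, y, zero_method = c("drop", "keep"),
                             max_exact = 15L) {
  zero_method <- match.arg(zero_method)
  d <- x - y
  d <- d[is.finite(d)]
  if (zero_method == "drop") d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    return(list(statistic = NA_real_, n = 0L, p = NA_real_,
                method = "none"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= max_exact) {
    ## distribution of W over all sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p_ge <- mean(ws >= w)
    p_le <- mean(ws <= w)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, n = n, p = p, method = method)
}

#' Compare CAA burden between groups, or gains vs losses within samples
#'
#' Unpaired mode (`paired = FALSE`) runs a two-sided Mann-Whitney U test of
#' the burden column between exactly two annotation groups, optionally
#' stratified by a second factor, with Benjamini-Hochberg q values across
#' all strata tested in the call. Paired mode (`paired = TRUE`) runs a
#' two-sided Wilcoxon signed-rank test of per-sample gain counts against
#' loss counts (zero differences dropped), per group level.
#'
#' @param burdens A `caa_burden` table from [summarize_burden()].
#' @param annotations Sample annotations with a `sample_id` column; may be
#'   `NULL` in paired mode to test all samples as one group.
#' @param group_col Name of the annotation column defining the two groups
#'   (unpaired) or the strata (paired).
#' @param by Optional annotation column defining strata for the unpaired
#'   comparison (one test per stratum).
#' @param value Burden column to compare in unpaired mode (default
#'   `"n_caa"`).
#' @param paired Logical; see above.
#' @return Data frame with one row per test: stratum, group sizes, test
#'   statistic, `p` and BH-adjusted `q`.
#' @examples
#' arms <- caa_arm_model()
#' sim <- sim_segments(30, arms, seed = 7)
#' bur <- summarize_burden(call_caas(compute_arm_fractions(sim$segments, arms)))
#' ann <- sim_annotations(bur$sample_id, seed = 8)
#' compare_burden(bur, ann, group_col = "cancer_class")
#' @export
compare_burden <- function(burdens, annotations = NULL, group_col = NULL,
                           by = NULL, value = "n_caa", paired = FALSE) {
  stopifnot(is.data.frame(burdens))
  d <- burdens
  if (!is.null(annotations)) {
    d <- merge(d, annotations, by = "sample_id")
  }
  if (paired) {
    strata <- if (is.null(group_col)) list(all = d) else
      split(d, d[[group_col]])
    rows <- lapply(names(strata), function(g) {
      s <- strata[[g]]
      if (nrow(s) < 2L) {
        warning("stratum '", g, "' has fewer than 2 samples; omitted",
                call. = FALSE)
        return(NULL)
      }
      ht <- signed_rank_test(s$n_gain, s$n_loss)
      data.frame(stratum = g, n = nrow(s), n_nonzero = ht$n,
                 statistic = ht$statistic, p = ht$p,
                 method = paste0("wilcoxon-signed-rank-", ht$method),
                 stringsAsFactors = FALSE)
    })
  } else {
    if (is.null(group_col)) {
      stop("'group_col' is required for an unpaired comparison",
           call. = FALSE)
    }
    groups <- unique(as.character(d[[group_col]]))
    groups <- groups[!is.na(groups)]
    if (length(groups) != 2L) {
      stop("unpaired comparison requires exactly 2 groups, got ",
           length(groups), " (pairwise only)", call. = FALSE)
    }
    strata <- if (is.null(by)) list(all = d) else split(d, d[[by]])
    rows <- lapply(names(strata), function(g) {
      s <- strata[[g]]
      x <- s[[value]][as.character(s[[group_col]]) == groups[1L]]
      y <- s[[value]][as.character(s[[group_col]]) == groups[2L]]
      if (length(x) < 2L || length(y) < 2L) {
        warning("stratum '", g, "' has a group with fewer than 2 ",
                "observations; omitted", call. = FALSE)
        return(NULL)
      }
      ht <- suppressWarnings(stats::wilcox.test(x, y))
      ## completely tied samples carry no evidence either way
      pval <- if (is.nan(ht$p.value)) 1 else ht$p.value
      data.frame(stratum = g, group1 = groups[1L], group2 = groups[2L],
                 n1 = length(x), n2 = length(y),
                 statistic = unname(ht$statistic), p = pval,
                 method = "mann-whitney-u", stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no stratum had enough observations to test", call. = FALSE)
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-event CAA frequency differentials between two groups
#'
#' For every signed CAA event, builds the 2 x 2 table of event presence
#' against group membership and runs a two-sided Fisher's exact test, with
#' Benjamini-Hochberg q values across all events of the comparison and the
#' exponent-style significance band of [q_band()].
#'
#' @param caas A `caa_matrix`.
#' @param annotations Sample annotations with `sample_id` and the grouping
#'   column.
#' @param group_col Name of the annotation column splitting samples into
#'   exactly two groups (e.g. primary vs metastatic).
#' @param levels Optional character vector of length 2 selecting and
#'   ordering the two group levels.
#' @return Data frame of class `caa_freq_diff` with one row per signed
#'   event: counts and totals per group, sample odds ratio (group 1 odds
#'   over group 2 odds), `p`, `q` and `band`. Events absent in both groups
#'   are retained with `p = 1`.
#' @export
caa_frequency_differential <- function(caas, annotations, group_col,
                                       levels = NULL) {
  stopifnot(inherits(caas, "caa_matrix"), is.data.frame(annotations))
  ev <- caa_events(caas)
  ann <- annotations[match(rownames(ev), annotations$sample_id), ,
                     drop = FALSE]
  grp <- as.character(ann[[group_col]])
  keep <- !is.na(grp)
  ev <- ev[keep, , drop = FALSE]; grp <- grp[keep]
  if (is.null(levels)) levels <- unique(grp)
  if (length(levels) != 2L) {
    stop("'", group_col, "' must define exactly 2 groups, got ",
         length(levels), call. = FALSE)
  }
  in1 <- grp == levels[1L]; in2 <- grp == levels[2L]
  n1 <- sum(in1); n2 <- sum(in2)
  res <- lapply(colnames(ev), function(e) {
    a <- sum(ev[in1, e]); b <- sum(ev[in2, e])
    tab <- matrix(c(a, n1 - a, b, n2 - b), 2L)
    data.frame(event = e, count1 = a, total1 = n1, count2 = b, total2 = n2,
               odds_ratio = (a * (n2 - b)) / ((n1 - a) * b),
               p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$band <- q_band(out$q)
  attr(out, "groups") <- levels
  rownames(out) <- NULL
  class(out) <- c("caa_freq_diff", "data.frame")
  out
}
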