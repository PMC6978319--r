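#' Assemble a binary pharmacogenomic feature matrix
#'
#' Row-concatenates cancer-gene mutation features, focal copy-number
#' features (recurrently altered segments) and CAA signed-event features
#' into one binary features x cell-lines matrix, restricted to cell lines
#' present in every input. Copy-number features may carry a chromosome-arm
#' and direction annotation, used later to decide whether a focal event can
#' explain a CAA-drug interaction.
#'
#' @param mutations Binary features x cell-lines matrix of gene mutations
#'   (may be `NULL`).
#' @param focal_cnas Binary features x cell-lines matrix of focal
#'   copy-number features (may be `NULL`).
#' @param caas A `caa_matrix` (signed-event view is taken, transposed to
#'   events x samples) or a binary features x cell-lines matrix (may be
#'   `NULL`).
#' @param focal_annotation Optional data frame with columns `feature`,
#'   `arm`, `direction` annotating the focal features.
#' @return Object of class `caa_feature_matrix`: list with `X` (binary
#'   matrix) and `info` (feature, kind, arm, direction).
#' @examples
#' mut <- matrix(rbinom(6, 1, 0.5), 2, 3,
#'               dimnames = list(c("TP53", "KRAS"), paste0("CL", 1:3)))
#' cna <- matrix(rbinom(3, 1, 0.5), 1, 3,
#'               dimnames = list("seg17p", paste0("CL", 1:3)))
#' fm <- assemble_features(mut, cna, NULL)
#' fm$info
#' @export
assemble_features <- function(mutations = NULL, focal_cnas = NULL,
                              caas = NULL, focal_annotation = NULL) {
  blocks <- list()
  add <- function(blocks, m, kind) {
    if (is.null(m)) return(blocks)
    m <- as.matrix(m)
    if (!all(m %in% c(0L, 1L))) {
      stop(kind, " matrix must be binary (0/1)", call. = FALSE)
    }
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop(kind, " matrix needs feature rownames and cell-line colnames",
           call. = FALSE)
    }
    storage.mode(m) <- "integer"
    blocks[[kind]] <- m
    blocks
  }
  blocks <- add(blocks, mutations, "gene_mutation")
  blocks <- add(blocks, focal_cnas, "focal_cna")
  if (!is.null(caas)) {
    m <- if (inherits(caas, "caa_matrix")) t(caa_events(caas)) else
      as.matrix(caas)
    blocks <- add(blocks, m, "caa")
  }
  if (length(blocks) == 0L) stop("no feature blocks supplied", call. = FALSE)
  cells <- Reduce(intersect, lapply(blocks, colnames))
  if (length(cells) == 0L) {
    stop("empty intersection of cell lines across feature blocks",
         call. = FALSE)
  }
  X <- do.call(rbind, lapply(blocks, function(m) m[, cells, drop = FALSE]))
  feats <- unlist(lapply(blocks, rownames), use.names = FALSE)
  rownames(X) <- feats
  if (anyDuplicated(feats)) {
    stop("duplicate feature id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "),
         call. = FALSE)
  }
  info <- data.frame(feature = feats,
                     kind = rep(names(blocks), vapply(blocks, nrow,
                                                      integer(1L))),
                     arm = NA_character_, direction = NA_character_,
                     stringsAsFactors = FALSE)
  ## CAA signed events carry their own arm/direction in the label
  is_caa <- info$kind == "caa"
  if (any(is_caa)) {
    pe <- parse_events(info$feature[is_caa])
    info$arm[is_caa] <- pe$arm
    info$direction[is_caa] <- ifelse(pe$sign == 1L, "gain", "loss")
  }
  if (!is.null(focal_annotation)) {
    m <- match(info$feature, focal_annotation$feature)
    hit <- !is.na(m) & info$kind == "focal_cna"
    info$arm[hit] <- focal_annotation$arm[m[hit]]
    info$direction[hit] <- focal_annotation$direction[m[hit]]
  }
  structure(list(X = X, info = info), class = "caa_feature_matrix")
}

#' @export
print.caa_feature_matrix <- function(x, ...) {
  cat("Pharmacogenomic feature matrix: ", nrow(x$X), " features x ",
      ncol(x$X), " cell lines\n", sep = "")
  print(table(x$info$kind))
  invisible(x)
}

#' Filter drugs by their fraction of sensitive calls
#'
#' Reliable screening of drug sensitivity needs enough sensitive examples:
#' drugs are retained when the fraction of sensitive calls among
#' non-missing calls is at least `min_sensitive_frac` (default 15%).
#'
#' @param calls Drugs x cell-lines character matrix with values
#'   `"sensitive"`, `"resistant"` or `NA`.
#' @param min_sensitive_frac Minimum sensitive fraction (inclusive).
#' @return Character vector of retained drug names; the per-drug sensitive
#'   fractions are attached as attribute `sensitive_frac`.
#' @export
filter_drugs_by_sensitivity <- function(calls, min_sensitive_frac = 0.15) {
  calls <- as.matrix(calls)
  n_obs <- rowSums(!is.na(calls))
  if (any(n_obs == 0L)) {
    warning("drug(s) with no calls dropped: ",
            paste(rownames(calls)[n_obs == 0L], collapse = ", "),
            call. = FALSE)
  }
  frac <- ifelse(n_obs > 0L,
                 rowSums(calls == "sensitive", na.rm = TRUE) / n_obs,
                 NA_real_)
  keep <- !is.na(frac) & frac >= min_sensitive_frac
  structure(rownames(calls)[keep],
            sensitive_frac = stats::setNames(frac, rownames(calls)))
}

#' Impute missing IC50 values with weighted k-nearest-neighbour drugs
#'
#' Each missing log10 IC50 entry is filled with the inverse-distance
#' weighted mean of the values of the `k` nearest other drugs at that cell
#' line. Distance between two drug rows is the Euclidean distance over
#' their co-observed cell lines, scaled to a per-cell-line basis so rows
#' with different numbers of shared observations are comparable. A
#' neighbour at distance zero dominates (its value is returned). Observed
#' entries are never altered.
#'
#' @param ic50 Drugs x cell-lines numeric matrix with missing entries.
#' @param k Number of neighbouring drugs (default 4).
#' @return The completed matrix.
#' @export
impute_ic50_knn <- function(ic50, k = 4L) {
  ic50 <- as.matrix(ic50)
  out <- ic50
  D <- nrow(ic50)
  if (D < 2L) stop("need at least two drug rows to impute", call. = FALSE)
  ## pairwise distances over co-observed cell lines
  dist_fun <- function(i, j) {
    shared <- !is.na(ic50[i, ]) & !is.na(ic50[j, ])
    if (!any(shared)) return(NA_real_)
    sqrt(mean((ic50[i, shared] - ic50[j, shared])^2))
  }
  for (i in seq_len(D)) {
    miss <- which(is.na(ic50[i, ]))
    if (!length(miss)) next
    d <- vapply(seq_len(D), function(j) {
      if (j == i) NA_real_ else dist_fun(i, j)
    }, numeric(1L))
    for (cell in miss) {
      cand <- which(!is.na(ic50[, cell]) & !is.na(d))
      if (!length(cand)) {
        warning("drug ", rownames(ic50)[i] %||% i, ", cell line ",
                colnames(ic50)[cell] %||% cell,
                ": no neighbour with an observed value; left missing",
                call. = FALSE)
        next
      }
      if (length(cand) < k) {
        warning("drug ", rownames(ic50)[i] %||% i,
                ": fewer than ", k, " eligible neighbours; using ",
                length(cand), call. = FALSE)
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      if (any(d[nb] == 0)) {
        out[i, cell] <- mean(ic50[nb[d[nb] == 0], cell])
      } else {
        w <- 1 / d[nb]
        out[i, cell] <- sum(w * ic50[nb, cell]) / sum(w)
      }
    }
  }
  out
}

#' Glass' delta effect size of a binary alteration on drug response
#'
#' Standardised mean difference using the control (unaltered) group's
#' sample standard deviation: `(mean_altered - mean_unaltered) /
#' sd_unaltered`. Positive values point toward resistance (higher IC50 in
#' altered cell lines).
#'
#' @param ic50_row Numeric per-cell-line response values (log10 IC50).
#' @param feature_row Binary indicator of the alteration, same length.
#' @return Single numeric effect size; `NA` (with a warning) when fewer
#'   than two unaltered cell lines or zero unaltered spread make it
#'   undefined.
#' @examples
#' glass_delta(c(1.5, 1.5, 0.5, 0.5, 0.0, 1.0), c(1, 1, 0, 0, 0, 0))
#' @export
glass_delta <- function(ic50_row, feature_row) {
  stopifnot(length(ic50_row) == length(feature_row))
  ok <- !is.na(ic50_row) & !is.na(feature_row)
  x <- ic50_row[ok]; f <- feature_row[ok]
  if (!all(f %in% c(0, 1))) stop("'feature_row' must be binary",
                                 call. = FALSE)
  wt <- x[f == 0]; alt <- x[f == 1]
  if (length(wt) < 2L) {
    warning("fewer than 2 unaltered cell lines: Glass' delta undefined",
            call. = FALSE)
    return(NA_real_)
  }
  s <- stats::sd(wt)
  if (s == 0) {
    if (length(alt) && mean(alt) == mean(wt)) return(0)  # identical groups
    warning("zero spread in the unaltered group: Glass' delta undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(alt) - mean(wt)) / s
}

#' Enumerate all unordered feature pairs
#'
#' @param features A `caa_feature_matrix` or anything with `nrow()` /
#'   feature names.
#' @return List with `pairs` (two-column character or index matrix in
#'   deterministic order) and `count` (`F * (F - 1) / 2`).
#' @examples
#' enumerate_feature_pairs(matrix(0, 4, 2))$count  # 6
#' @export
enumerate_feature_pairs <- function(features) {
  if (inherits(features, "caa_feature_matrix")) {
    ids <- rownames(features$X)
  } else if (is.matrix(features) || is.data.frame(features)) {
    ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  } else {
    ids <- as.character(features)
  }
  F_ <- length(ids)
  if (F_ < 2L) stop("need at least 2 features", call. = FALSE)
  idx <- which(upper.tri(matrix(0L, F_, F_)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  pairs <- cbind(feature1 = ids[idx[, 1L]], feature2 = ids[idx[, 2L]])
  list(pairs = pairs, count = F_ * (F_ - 1) / 2)
}

#' Synthetic-lethality / synergistic-resistance co-occurrence screen
#'
#' For every feature pair, drug and group (each cancer type plus
#' pan-cancer), tests with a two-sided Fisher's exact test whether cell
#' lines carrying both features are more frequently sensitive or resistant
#' than the remaining cell lines. Benjamini-Hochberg q values are computed
#' within each group over all tests performed there and reported on the
#' percent scale (`fdr_pct`). Only rows with `p < p_max` are stored. A
#' stored row is classified `synthetic_lethal` when `fdr_pct <
#' fdr_pct_max` and the odds favour sensitivity among pair-positive lines,
#' `synergistic_resistance` for the opposite direction, otherwise
#' `"none"`.
#'
#' @param features A `caa_feature_matrix` (or binary features x cell-lines
#'   matrix).
#' @param calls Drugs x cell-lines character matrix (`"sensitive"`,
#'   `"resistant"`, `NA`); missing calls are excluded listwise per drug.
#' @param groups Optional named character vector mapping cell lines to
#'   cancer types; each type is screened separately in addition to the
#'   pan-cancer screen.
#' @param pairs Optional two-column matrix restricting the screened pairs
#'   (default: all pairs from [enumerate_feature_pairs()]).
#' @param p_max Fisher p threshold for storing and calling (default 0.05).
#' @param fdr_pct_max Threshold on the percent-scale FDR (default 0.001,
#'   i.e. q < 1e-5).
#' @return Data frame of class `caa_screen` with one stored row per
#'   pair x drug x group: the 2 x 2 table cells (`n_pp_sens`, `n_pp_res`,
#'   `n_pn_sens`, `n_pn_res`), odds ratio, `p`, `q`, `fdr_pct` and
#'   `class`. The number of degenerate (zero-margin) tables skipped is
#'   attached as attribute `skipped`.
#' @export
sl_sr_screen <- function(features, calls, groups = NULL, pairs = NULL,
                         p_max = 0.05, fdr_pct_max = 0.001) {
  X <- if (inherits(features, "caa_feature_matrix")) features$X else
    as.matrix(features)
  calls <- as.matrix(calls)
  cells <- intersect(colnames(X), colnames(calls))
  if (length(cells) == 0L) {
    stop("no shared cell lines between features and calls", call. = FALSE)
  }
  X <- X[, cells, drop = FALSE]
  calls <- calls[, cells, drop = FALSE]
  if (is.null(pairs)) pairs <- enumerate_feature_pairs(X)$pairs
  group_list <- list("pan-cancer" = cells)
  if (!is.null(groups)) {
    groups <- groups[cells]
    for (g in sort(unique(stats::na.omit(groups)))) {
      group_list[[g]] <- cells[!is.na(groups) & groups == g]
    }
  }
  rows <- list()
  skipped <- 0L
  for (g in names(group_list)) {
    gc <- group_list[[g]]
    g_rows <- list()
    for (drug in rownames(calls)) {
      obs <- gc[!is.na(calls[drug, gc])]
      if (length(obs) < 2L) next
      sens <- calls[drug, obs] == "sensitive"
      for (r in seq_len(nrow(pairs))) {
        f1 <- pairs[r, 1L]; f2 <- pairs[r, 2L]
        pp <- X[f1, obs] == 1L & X[f2, obs] == 1L
        a <- sum(pp & sens); b <- sum(pp & !sens)
        cc <- sum(!pp & sens); dd <- sum(!pp & !sens)
        tab <- matrix(c(a, cc, b, dd), 2L)
        if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
          skipped <- skipped + 1L
          next
        }
        p <- stats::fisher.test(tab)$p.value
        g_rows[[length(g_rows) + 1L]] <-
          data.frame(group = g, drug = drug, feature1 = f1, feature2 = f2,
                     n_pp_sens = a, n_pp_res = b, n_pn_sens = cc,
                     n_pn_res = dd,
                     odds_ratio = (a * dd) / (b * cc),
                     p = p, stringsAsFactors = FALSE)
      }
    }
    if (!length(g_rows)) next
    gr <- do.call(rbind, g_rows)
    gr$q <- stats::p.adjust(gr$p, method = "BH")
    gr$fdr_pct <- 100 * gr$q
    gr <- gr[gr$p < p_max, , drop = FALSE]
    if (nrow(gr)) rows[[g]] <- gr
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), drug = character(),
               feature1 = character(), feature2 = character(),
               n_pp_sens = integer(), n_pp_res = integer(),
               n_pn_sens = integer(), n_pn_res = integer(),
               odds_ratio = numeric(), p = numeric(), q = numeric(),
               fdr_pct = numeric(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    sens_enriched <- out$n_pp_sens / (out$n_pp_sens + out$n_pp_res) >
      out$n_pn_sens / (out$n_pn_sens + out$n_pn_res)
    called <- out$p < p_max & out$fdr_pct < fdr_pct_max
    out$class <- ifelse(called & sens_enriched, "synthetic_lethal",
                        ifelse(called, "synergistic_resistance", "none"))
  } else {
    out$class <- character()
  }
  attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  class(out) <- c("caa_screen", "data.frame")
  out
}

#' Flag CAA-drug interactions explainable by focal copy-number hits
#'
#' A CAA-drug interaction counts as "explained" by a focal copy-number
#' alteration when a focal hit matches it on all four keys: same
#' chromosome arm, same direction (co-gain or co-loss), same drug and same
#' cancer type. All other CAA hits are flagged "independent".
#'
#' @param caa_results Data frame of CAA-drug hits with columns `arm`,
#'   `direction`, `drug` and `cancer_type` (or `group`).
#' @param focal_results Data frame of focal-CNA-drug hits with the same
#'   columns.
#' @return `caa_results` with an added `explained` column
#'   (`"explained"` / `"independent"`).
#' @export
focal_explains_caa <- function(caa_results, focal_results) {
  stopifnot(is.data.frame(caa_results), is.data.frame(focal_results))
  grp_col <- function(d) if (!is.null(d$cancer_type)) d$cancer_type else
    d$group
  bad <- is.na(focal_results$arm)
  if (any(bad)) {
    warning(sum(bad), " focal hit(s) without an arm annotation cannot ",
            "explain any CAA interaction", call. = FALSE)
  }
  fk <- paste(focal_results$arm[!bad], focal_results$direction[!bad],
              focal_results$drug[!bad], grp_col(focal_results)[!bad],
              sep = "\r")
  ck <- paste(caa_results$arm, caa_results$direction, caa_results$drug,
              grp_col(caa_results), sep = "\r")
  caa_results$explained <- ifelse(ck %in% fk, "explained", "independent")
  caa_results
}

#' F1 score
#'
#' Harmonic mean of precision and recall; defined as 0 when either input
#' is 0.
#'
#' @param precision,recall Values in \[0, 1\] (vectorised).
#' @return Numeric vector of F1 scores.
#' @examples
#' f1_score(0.8, 0.5)  # 0.6154
#' @export
f1_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1,
          na.rm = TRUE)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  ifelse(precision == 0 | recall == 0, 0,
         2 / (1 / precision + 1 / recall))
}
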