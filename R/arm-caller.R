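#' Per-arm gain/loss fractions from segmented copy numbers
#'
#' The core of the arm-level caller. Segments that overlap a centromere
#' interval by at least 1 bp are discarded; the remainder are clipped to arm
#' boundaries. Per sample and arm, the total clipped length (`covered_bp`)
#' and the lengths classified as gained (`seg_mean` strictly greater than
#' `amp_thresh`) or lost (strictly less than `del_thresh`) are summed, and
#' fractions are formed over the covered length.
#'
#' @param segments A `caa_segments` data frame (internal 0-based half-open
#'   coordinates, as produced by [read_segments()] or [sim_segments()]).
#' @param arms An arm model; only arms flagged `included` are scored.
#' @param amp_thresh Log2-ratio threshold above which a segment counts as
#'   gained (strict inequality). Default 0.2.
#' @param del_thresh Log2-ratio threshold below which a segment counts as
#'   lost (strict inequality). Default -0.2.
#' @param recenter `"none"` (default; upstream pipelines usually deliver
#'   ploidy-relative ratios already) or `"weighted_median"`, which first
#'   shifts each sample's segment means by its covered-length-weighted
#'   median.
#' @param verbose Emit a message with the number of centromere-discarded
#'   segments.
#' @return A data frame of class `caa_arm_fractions` with one row per
#'   sample x included arm: `sample_id`, `arm_id`, `arm_length`,
#'   `covered_bp`, `gain_bp`, `loss_bp`, `gain_frac`, `loss_frac`
#'   (fractions are `NA` when `covered_bp` is 0). The number of segments
#'   dropped at the centromere filter is attached as attribute
#'   `dropped_centromere`.
#' @examples
#' arms <- caa_arm_model()
#' sim <- sim_segments(4, arms, noise_sd = 0, focal_rate = 0, seed = 1)
#' fr <- compute_arm_fractions(sim$segments, arms)
#' head(fr)
#' @export
compute_arm_fractions <- function(segments, arms = caa_arm_model(),
                                  amp_thresh = 0.2, del_thresh = -0.2,
                                  recenter = c("none", "weighted_median"),
                                  verbose = FALSE) {
  recenter <- match.arg(recenter)
  stopifnot(is.data.frame(segments), is.data.frame(arms))
  if (amp_thresh <= del_thresh) {
    stop("'amp_thresh' must exceed 'del_thresh'", call. = FALSE)
  }
  seg <- as.data.frame(segments)
  seg$chromosome <- sub("^chr", "", as.character(seg$chromosome))

  ## centromere filter: any overlap >= 1 bp discards the whole segment
  cen <- unique(arms[, c("chromosome", "centromere_start_bp",
                         "centromere_end_bp")])
  m <- match(seg$chromosome, cen$chromosome)
  hit <- !is.na(m) &
    seg$start_bp < cen$centromere_end_bp[m] &
    seg$end_bp > cen$centromere_start_bp[m]
  dropped <- sum(hit)
  if (verbose) {
    message("compute_arm_fractions: discarded ", dropped,
            " centromere-overlapping segment(s)")
  }
  seg <- seg[!hit, , drop = FALSE]

  if (recenter == "weighted_median" && nrow(seg)) {
    len <- seg$end_bp - seg$start_bp
    shift <- vapply(split(seq_len(nrow(seg)), seg$sample_id), function(i) {
      weighted_median(seg$seg_mean[i], len[i])
    }, numeric(1L))
    seg$seg_mean <- seg$seg_mean - shift[seg$sample_id]
  }

  use <- arms[arms$included, , drop = FALSE]
  samples <- unique(segments$sample_id)
  out <- expand.grid(sample_id = samples, arm_id = use$arm_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$arm_length <- use$end_bp[match(out$arm_id, use$arm_id)] -
    use$start_bp[match(out$arm_id, use$arm_id)]
  out$covered_bp <- 0
  out$gain_bp <- 0
  out$loss_bp <- 0

  if (nrow(seg) == 0L || nrow(use) == 0L) {
    warning("no segments intersect the arm model; returning zero coverage",
            call. = FALSE)
  } else {
    for (i in seq_len(nrow(use))) {
      on_chr <- seg$chromosome == use$chromosome[i]
      if (!any(on_chr)) next
      s <- seg[on_chr, , drop = FALSE]
      ov_start <- pmax(s$start_bp, use$start_bp[i])
      ov_end <- pmin(s$end_bp, use$end_bp[i])
      len <- ov_end - ov_start
      keep <- len > 0
      if (!any(keep)) next
      s <- s[keep, , drop = FALSE]
      len <- len[keep]
      cov <- tapply(len, s$sample_id, sum)
      gn <- tapply(len * (s$seg_mean > amp_thresh), s$sample_id, sum)
      ls <- tapply(len * (s$seg_mean < del_thresh), s$sample_id, sum)
      rows <- out$arm_id == use$arm_id[i]
      idx <- match(out$sample_id[rows], names(cov))
      out$covered_bp[rows] <- ifelse(is.na(idx), 0, cov[idx])
      out$gain_bp[rows] <- ifelse(is.na(idx), 0, gn[idx])
      out$loss_bp[rows] <- ifelse(is.na(idx), 0, ls[idx])
    }
  }
  out$gain_frac <- ifelse(out$covered_bp > 0, out$gain_bp / out$covered_bp,
                          NA_real_)
  out$loss_frac <- ifelse(out$covered_bp > 0, out$loss_bp / out$covered_bp,
                          NA_real_)
  attr(out, "dropped_centromere") <- dropped
  attr(out, "arm_ids") <- use$arm_id
  class(out) <- c("caa_arm_fractions", "data.frame")
  out
}

#' Construct a CAA call matrix
#'
#' Low-level constructor wrapping a samples x arms matrix of ternary calls
#' (-1 loss, 0 neutral, +1 gain) as a `caa_matrix`.
#'
#' @param calls Integer/numeric matrix with values in \{-1, 0, 1\}; rownames
#'   are sample ids, colnames are arm ids.
#' @param uncallable Optional logical matrix of the same shape flagging
#'   sample/arm cells without usable coverage.
#' @return An object of class `caa_matrix`.
#' @export
caa_matrix <- function(calls, uncallable = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(-1, 0, 1))) {
    stop("CAA calls must be -1, 0 or +1", call. = FALSE)
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    stop("'calls' must have arm ids as column names", call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  if (is.null(uncallable)) {
    uncallable <- matrix(FALSE, nrow(calls), ncol(calls),
                         dimnames = dimnames(calls))
  }
  structure(list(calls = calls, uncallable = uncallable,
                 samples = rownames(calls), arms = colnames(calls)),
            class = "caa_matrix")
}

#' Call chromosome arm aneuploidies from arm fractions
#'
#' An arm is called gained (+1) when its gained fraction reaches `call_frac`
#' (default 0.9, inclusive), lost (-1) when its lost fraction does, and
#' neutral (0) otherwise. Hemizygous and homozygous losses are not
#' distinguished. Arms with no covered length (or covered fraction below
#' `min_covered_frac` of the arm length) are called 0 and flagged
#' uncallable.
#'
#' @param fractions A `caa_arm_fractions` table from
#'   [compute_arm_fractions()].
#' @param call_frac Fraction of the arm that must be gained/lost for a call;
#'   must exceed 0.5 so gain and loss calls are mutually exclusive.
#' @param min_covered_frac Minimum covered fraction of the arm length below
#'   which the arm is uncallable. Default 0 (no coverage requirement beyond
#'   non-zero).
#' @return A [caa_matrix()] with samples as rows and arms as columns.
#' @examples
#' arms <- caa_arm_model()
#' sim <- sim_segments(4, arms, noise_sd = 0, focal_rate = 0, seed = 1)
#' caas <- call_caas(compute_arm_fractions(sim$segments, arms))
#' table(caas$calls)
#' @export
call_caas <- function(fractions, call_frac = 0.9, min_covered_frac = 0) {
  stopifnot(is.data.frame(fractions))
  if (call_frac <= 0.5) {
    stop("'call_frac' must exceed 0.5 (gain and loss calls would not be ",
         "mutually exclusive)", call. = FALSE)
  }
  samples <- unique(fractions$sample_id)
  arm_ids <- attr(fractions, "arm_ids") %||% unique(fractions$arm_id)
  calls <- matrix(0L, length(samples), length(arm_ids),
                  dimnames = list(samples, arm_ids))
  unc <- matrix(FALSE, length(samples), length(arm_ids),
                dimnames = list(samples, arm_ids))
  i <- cbind(match(fractions$sample_id, samples),
             match(fractions$arm_id, arm_ids))
  bad <- fractions$covered_bp <= 0 |
    fractions$covered_bp < min_covered_frac * fractions$arm_length
  unc[i] <- bad
  gain <- !bad & !is.na(fractions$gain_frac) &
    fractions$gain_frac >= call_frac
  loss <- !bad & !is.na(fractions$loss_frac) &
    fractions$loss_frac >= call_frac
  calls[i[gain, , drop = FALSE]] <- 1L
  calls[i[loss, , drop = FALSE]] <- -1L
  caa_matrix(calls, unc)
}

#' Signed-event view of a CAA matrix
#'
#' Expands the ternary calls into a binary samples x (2 x arms) indicator
#' matrix with one column per signed event (`"+arm"`, `"-arm"`); the two
#' columns of one arm are never both 1.
#'
#' @param caas A `caa_matrix`.
#' @return Binary integer matrix.
#' @export
caa_events <- function(caas) {
  stopifnot(inherits(caas, "caa_matrix"))
  calls <- caas$calls
  ev <- matrix(0L, nrow(calls), 2L * ncol(calls))
  ev[, seq(1L, ncol(ev), by = 2L)] <- (calls == 1L) + 0L
  ev[, seq(2L, ncol(ev), by = 2L)] <- (calls == -1L) + 0L
  dimnames(ev) <- list(rownames(calls),
                       as.vector(rbind(paste0("+", colnames(calls)),
                                       paste0("-", colnames(calls)))))
  ev
}

#' @export
print.caa_matrix <- function(x, ...) {
  cat("CAA call matrix: ", length(x$samples), " samples x ", length(x$arms),
      " arms\n", sep = "")
  cat("  gains: ", sum(x$calls == 1L), ", losses: ", sum(x$calls == -1L),
      ", uncallable cells: ", sum(x$uncallable), "\n", sep = "")
  invisible(x)
}

#' Per-sample CAA burden summary
#'
#' Counts arm gains and losses per sample and assigns the within-sample
#' gain:loss class: `G>L`, `G=L`, `G<L`, or `no-CAA` for samples without any
#' arm-level event.
#'
#' @param caas A `caa_matrix`.
#' @return A data frame of class `caa_burden` with columns `sample_id`,
#'   `n_gain`, `n_loss`, `n_caa` and `gl_class`.
#' @export
summarize_burden <- function(caas) {
  stopifnot(inherits(caas, "caa_matrix"))
  n_gain <- rowSums(caas$calls == 1L)
  n_loss <- rowSums(caas$calls == -1L)
  n_caa <- n_gain + n_loss
  gl <- ifelse(n_caa == 0L, "no-CAA",
               ifelse(n_gain > n_loss, "G>L",
                      ifelse(n_gain < n_loss, "G<L", "G=L")))
  out <- data.frame(sample_id = rownames(caas$calls),
                    n_gain = as.integer(n_gain),
                    n_loss = as.integer(n_loss),
                    n_caa = as.integer(n_caa),
                    gl_class = factor(gl, levels = c("G>L", "G=L", "G<L",
                                                     "no-CAA")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("caa_burden", "data.frame")
  out
}

#' Call whole-genome doubling from allele-specific copy number
#'
#' A sample is WGD-positive when strictly more than half of its autosomal
#' covered length carries two or more copies of the more frequent (major)
#' allele. Segments overlapping a centromere are discarded and the rest are
#' clipped to the arm intervals of the model before lengths are summed.
#'
#' @param segments A `caa_segments` data frame carrying a `major_allele_cn`
#'   column; without it WGD status is unavailable and `NA` is returned for
#'   every sample (with a warning), not an error.
#' @param arms Arm model defining the autosomal arm intervals (all arms are
#'   used, including any flagged not `included`).
#' @return Named logical vector, one element per sample (`NA` when
#'   allele-specific data are absent).
#' @export
call_wgd <- function(segments, arms = caa_arm_model()) {
  stopifnot(is.data.frame(segments))
  samples <- unique(segments$sample_id)
  if (is.null(segments$major_allele_cn)) {
    warning("no 'major_allele_cn' column: WGD status unavailable",
            call. = FALSE)
    return(stats::setNames(rep(NA, length(samples)), samples))
  }
  auto <- arms[arms$chromosome %in% as.character(1:22), , drop = FALSE]
  seg <- as.data.frame(segments)
  seg$chromosome <- sub("^chr", "", as.character(seg$chromosome))
  seg <- seg[seg$chromosome %in% auto$chromosome & !is.na(seg$major_allele_cn),
             , drop = FALSE]
  cen <- unique(auto[, c("chromosome", "centromere_start_bp",
                         "centromere_end_bp")])
  m <- match(seg$chromosome, cen$chromosome)
  hit <- seg$start_bp < cen$centromere_end_bp[m] &
    seg$end_bp > cen$centromere_start_bp[m]
  seg <- seg[!hit, , drop = FALSE]

  cov <- stats::setNames(numeric(length(samples)), samples)
  dup <- stats::setNames(numeric(length(samples)), samples)
  for (i in seq_len(nrow(auto))) {
    on_chr <- seg$chromosome == auto$chromosome[i]
    if (!any(on_chr)) next
    s <- seg[on_chr, , drop = FALSE]
    len <- pmin(s$end_bp, auto$end_bp[i]) - pmax(s$start_bp, auto$start_bp[i])
    keep <- len > 0
    if (!any(keep)) next
    s <- s[keep, , drop = FALSE]; len <- len[keep]
    cv <- tapply(len, s$sample_id, sum)
    dp <- tapply(len * (s$major_allele_cn >= 2L), s$sample_id, sum)
    cov[names(cv)] <- cov[names(cv)] + cv
    dup[names(dp)] <- dup[names(dp)] + dp
  }
  ifelse(cov > 0, dup > 0.5 * cov, NA)
}
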