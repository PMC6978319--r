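#' Simulate segmented copy-number profiles with planted arm events
#'
#' Generates SEG-style segment tables with the statistical structure the
#' arm caller expects: per sample, each included arm receives a whole-arm
#' log2 shift of magnitude `event_mag` (default `log2(3/2)`, one copy
#' gained or lost on a diploid background) with probability `event_rate`;
#' focal sub-arm events of 1-10% arm length occur at `focal_rate`; each
#' arm is tiled by a random number of segments whose means carry Gaussian
#' noise with standard deviation `noise_sd`. With `wgd_rate > 0` a
#' `major_allele_cn` column is added, planted so that WGD-positive samples
#' carry the major allele at copy number 2 genome-wide and WGD-negative
#' samples on roughly 30% of their genome.
#'
#' @param n_samples Number of tumour samples.
#' @param arm_model Arm model; events are planted on included arms.
#' @param event_rate Per-arm probability of a whole-arm event.
#' @param focal_rate Per-arm probability of a focal event.
#' @param noise_sd Standard deviation of per-segment log2-ratio noise.
#' @param event_mag Magnitude of whole-arm (and focal) log2 shifts.
#' @param wgd_rate Fraction of samples planted as whole-genome doubled.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with `segments` (a `caa_segments` data frame in internal
#'   0-based half-open coordinates) and `truth` (planted `arm_events`
#'   samples x arms matrix, planted `wgd` status, and the parameters).
#' @examples
#' sim <- sim_segments(3, noise_sd = 0, focal_rate = 0, seed = 1)
#' table(sim$truth$arm_events)
#' @export
sim_segments <- function(n_samples, arm_model = caa_arm_model(),
                         event_rate = 0.15, focal_rate = 0.05,
                         noise_sd = 0.05, event_mag = log2(3 / 2),
                         wgd_rate = 0, seed) {
  stopifnot(n_samples >= 1, noise_sd >= 0, event_rate >= 0, event_rate <= 1)
  arms <- arm_model[arm_model$included, , drop = FALSE]
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    truth_events <- matrix(0L, n_samples, nrow(arms),
                           dimnames = list(samples, arms$arm_id))
    wgd <- stats::setNames(stats::runif(n_samples) < wgd_rate, samples)
    rows <- vector("list", n_samples * nrow(arms))
    ri <- 0L
    for (s in seq_len(n_samples)) {
      for (a in seq_len(nrow(arms))) {
        a0 <- arms$start_bp[a]; a1 <- arms$end_bp[a]
        len <- a1 - a0
        ev <- stats::rbinom(1L, 1L, event_rate) == 1L
        sgn <- sample(c(1L, -1L), 1L)
        shift <- if (ev) sgn * event_mag else 0
        if (ev) truth_events[s, a] <- sgn
        bounds <- c(a0, a1)
        n_break <- stats::rpois(1L, 2L)
        if (n_break > 0L) {
          bounds <- c(bounds, round(stats::runif(n_break, a0 + 1, a1 - 1)))
        }
        focal <- stats::runif(1L) < focal_rate
        f0 <- f1 <- NA_real_
        fshift <- 0
        if (focal) {
          flen <- round(stats::runif(1L, 0.01, 0.10) * len)
          f0 <- round(stats::runif(1L, a0, a1 - flen))
          f1 <- f0 + flen
          fshift <- sample(c(1L, -1L), 1L) * event_mag
          bounds <- c(bounds, f0, f1)
        }
        bounds <- sort(unique(bounds))
        n_seg <- length(bounds) - 1L
        st <- bounds[-length(bounds)]
        en <- bounds[-1L]
        mean_base <- shift +
          if (focal) fshift * (st >= f0 & en <= f1) else 0
        noise <- if (noise_sd > 0) stats::rnorm(n_seg, 0, noise_sd) else 0
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          sample_id = samples[s],
          chromosome = arms$chromosome[a],
          start_bp = st, end_bp = en,
          seg_mean = mean_base + noise,
          stringsAsFactors = FALSE)
      }
    }
    seg <- do.call(rbind, rows[seq_len(ri)])
    if (wgd_rate > 0) {
      macn <- integer(nrow(seg))
      pos <- wgd[seg$sample_id]
      macn[pos] <- 2L
      macn[!pos] <- 1L + stats::rbinom(sum(!pos), 1L, 0.3)
      seg$major_allele_cn <- macn
    }
    rownames(seg) <- NULL
    class(seg) <- c("caa_segments", "data.frame")
    list(segments = seg,
         truth = list(arm_events = truth_events,
                      wgd = if (wgd_rate > 0) wgd else NULL,
                      params = list(n_samples = n_samples,
                                    event_rate = event_rate,
                                    focal_rate = focal_rate,
                                    noise_sd = noise_sd,
                                    event_mag = event_mag,
                                    wgd_rate = wgd_rate, seed = seed)))
  })
}

#' Acquisition-preference specification for evolving cohorts
#'
#' @param events Character vector of signed events (on distinct arms) that
#'   can be acquired.
#' @param prefs Optional data frame with columns `first`, `second`, `prob`:
#'   each row forces `first` to be acquired before `second` with the given
#'   probability.
#' @return A list of class `evolution_spec`.
#' @export
evolution_spec <- function(events, prefs = NULL) {
  pe <- parse_events(events)
  if (anyDuplicated(pe$arm)) {
    stop("spec events must lie on distinct arms", call. = FALSE)
  }
  if (!is.null(prefs)) {
    stopifnot(all(c("first", "second", "prob") %in% names(prefs)))
    if (!all(c(prefs$first, prefs$second) %in% events)) {
      stop("preference events must be among the spec events", call. = FALSE)
    }
    if (any(prefs$prob < 0 | prefs$prob > 1)) {
      stop("preference probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(events = events, prefs = prefs), class = "evolution_spec")
}

#' Simulate a cohort evolving by sequential CAA acquisition
#'
#' Forward model matching the karyotype-tree semantics: each tumour draws
#' a total burden `k` from `burden_dist`, lays down a random full
#' acquisition sequence over the spec's signed events, re-orients it so
#' each preference (`first` before `second`) holds with its stated
#' probability, and keeps the first `k` events. The observed karyotype is
#' therefore a truncation of a preference-biased sequence.
#'
#' @param transition_spec An [evolution_spec()]; default: gains of the
#'   first eight included arms of the arm model, no preference.
#' @param burden_dist Probability vector over burdens `0, 1, ...`;
#'   default: Poisson(3) truncated at the number of spec events. Positive
#'   mass beyond the number of available events is an error.
#' @param n_tumours Cohort size.
#' @param arm_model Arm model whose included arms define the call matrix.
#' @param seed Integer seed.
#' @return List with `caas` (a `caa_matrix`) and `truth` (per-tumour
#'   acquisition orders and burdens, plus the spec).
#' @examples
#' spec <- evolution_spec(c("+1p", "+2p", "+3p"),
#'                        prefs = data.frame(first = "+1p", second = "+2p",
#'                                           prob = 0.9))
#' sim <- sim_evolution_cohort(spec, n_tumours = 50, seed = 1)
#' sim$caas
#' @export
sim_evolution_cohort <- function(transition_spec = NULL, burden_dist = NULL,
                                 n_tumours = 500,
                                 arm_model = caa_arm_model(), seed) {
  arms <- arm_model[arm_model$included, , drop = FALSE]
  if (is.null(transition_spec)) {
    transition_spec <- evolution_spec(
      paste0("+", utils::head(arms$arm_id, 8L)))
  }
  stopifnot(inherits(transition_spec, "evolution_spec"))
  events <- transition_spec$events
  pe <- parse_events(events)
  if (!all(pe$arm %in% arms$arm_id)) {
    stop("spec events reference arms absent from the arm model: ",
         paste(setdiff(pe$arm, arms$arm_id), collapse = ", "), call. = FALSE)
  }
  n_ev <- length(events)
  if (is.null(burden_dist)) {
    burden_dist <- stats::dpois(0:n_ev, 3)
    burden_dist <- burden_dist / sum(burden_dist)
  }
  if (length(burden_dist) - 1L > n_ev &&
      any(burden_dist[(n_ev + 2L):length(burden_dist)] > 0)) {
    stop("burden distribution puts mass on more events than the spec ",
         "provides (", n_ev, ")", call. = FALSE)
  }
  burden_dist <- burden_dist / sum(burden_dist)
  prefs <- transition_spec$prefs
  with_seed(seed, {
    samples <- sprintf("T%04d", seq_len(n_tumours))
    calls <- matrix(0L, n_tumours, nrow(arms),
                    dimnames = list(samples, arms$arm_id))
    orders <- vector("list", n_tumours)
    ks <- integer(n_tumours)
    for (t in seq_len(n_tumours)) {
      ord <- sample(events)
      if (!is.null(prefs)) {
        for (r in seq_len(nrow(prefs))) {
          i <- match(prefs$first[r], ord)
          j <- match(prefs$second[r], ord)
          first_wanted <- stats::runif(1L) < prefs$prob[r]
          if ((i < j) != first_wanted) ord[c(i, j)] <- ord[c(j, i)]
        }
      }
      k <- sample.int(length(burden_dist), 1L, prob = burden_dist) - 1L
      acq <- ord[seq_len(k)]
      orders[[t]] <- acq
      ks[t] <- k
      if (k > 0L) {
        ai <- match(parse_events(acq)$arm, arms$arm_id)
        calls[t, ai] <- parse_events(acq)$sign
      }
    }
    list(caas = caa_matrix(calls),
         truth = list(orders = orders, burden = ks,
                      spec = transition_spec, seed = seed))
  })
}

## joint success probability of a Bernoulli pair with given marginals and
## odds ratio: p11 solves OR = p11 p00 / (p10 p01)
.pair_p11 <- function(p1, p2, or) {
  if (or < 0) stop("odds ratio must be non-negative", call. = FALSE)
  if (or == 1) return(p1 * p2)
  a <- or - 1
  s <- 1 + (p1 + p2) * a
  disc <- s^2 - 4 * a * or * p1 * p2
  if (disc < 0) stop("no joint distribution matches the requested ",
                     "marginals and odds ratio", call. = FALSE)
  p11 <- (s - sqrt(disc)) / (2 * a)
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop("inconsistent marginal/odds-ratio combination", call. = FALSE)
  }
  min(max(p11, lo), hi)
}

#' Simulate binary event matrices with planted pairwise dependencies
#'
#' Columns are independent Bernoulli events at the requested marginal
#' frequencies, except listed pairs, which are drawn jointly from the
#' 2 x 2 distribution matching their marginals and the requested odds
#' ratio. Each event may take part in at most one dependent pair.
#'
#' @param N Number of samples (rows).
#' @param marginals Vector of per-event marginal frequencies in \[0, 1\]
#'   (names become event labels; default `E1`, `E2`, ...).
#' @param dependent_pairs Optional data frame with columns `event1`,
#'   `event2`, `odds_ratio`.
#' @param seed Integer seed.
#' @return List with `events` (binary N x events matrix) and `truth`.
#' @export
sim_cooccurrence_cohort <- function(N, marginals, dependent_pairs = NULL,
                                    seed) {
  stopifnot(N >= 1, all(marginals >= 0 & marginals <= 1))
  labels <- names(marginals) %||% paste0("E", seq_along(marginals))
  names(marginals) <- labels
  if (!is.null(dependent_pairs)) {
    stopifnot(all(c("event1", "event2", "odds_ratio") %in%
                    names(dependent_pairs)))
    used <- c(dependent_pairs$event1, dependent_pairs$event2)
    if (!all(used %in% labels)) {
      stop("dependent pair references unknown event(s)", call. = FALSE)
    }
    if (anyDuplicated(used)) {
      stop("each event may belong to at most one dependent pair",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    ev <- matrix(0L, N, length(marginals),
                 dimnames = list(sprintf("S%04d", seq_len(N)), labels))
    paired <- character(0L)
    if (!is.null(dependent_pairs)) {
      for (r in seq_len(nrow(dependent_pairs))) {
        e1 <- dependent_pairs$event1[r]; e2 <- dependent_pairs$event2[r]
        p1 <- marginals[e1]; p2 <- marginals[e2]
        p11 <- .pair_p11(p1, p2, dependent_pairs$odds_ratio[r])
        cellp <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
        cell <- sample.int(4L, N, replace = TRUE, prob = cellp)
        ev[, e1] <- as.integer(cell %in% c(1L, 2L))
        ev[, e2] <- as.integer(cell %in% c(1L, 3L))
        paired <- c(paired, e1, e2)
      }
    }
    for (e in setdiff(labels, paired)) {
      ev[, e] <- stats::rbinom(N, 1L, marginals[e])
    }
    list(events = ev,
         truth = list(marginals = marginals,
                      dependent_pairs = dependent_pairs, seed = seed))
  })
}

#' Simulate a cell-line pharmacogenomic panel with planted effects
#'
#' Features are independent Bernoulli indicators across cell lines. Drug
#' response calls are `"sensitive"` with baseline probability tuned so the
#' overall sensitive fraction matches `sensitive_frac`; a planted pair
#' effect raises (odds ratio > 1) the sensitivity odds of cell lines
#' carrying both features of the pair to the requested odds ratio.
#' Log10 IC50 values are standard Gaussian per drug, shifted downwards
#' for sensitive calls of drugs with a planted pair effect, and shifted by
#' `delta` wild-type standard deviations in feature-positive lines for
#' planted single-feature effects.
#'
#' @param n_cell_lines,n_features,n_drugs Panel dimensions.
#' @param feature_prob Marginal feature frequency.
#' @param sensitive_frac Overall fraction of sensitive calls per drug;
#'   must lie strictly between 0 and 1.
#' @param planted_pair_effects Optional data frame with columns
#'   `feature1`, `feature2`, `drug`, `odds_ratio`.
#' @param planted_single_effects Optional data frame with columns
#'   `feature`, `drug`, `delta` (IC50 shift in wild-type SD units).
#' @param missing_rate Fraction of IC50 entries set missing.
#' @param seed Integer seed.
#' @return List with `features` (features x cell lines), `calls` (drugs x
#'   cell lines character matrix), `ic50` (drugs x cell lines) and
#'   `truth`.
#' @export
sim_pharmaco <- function(n_cell_lines = 200, n_features = 10, n_drugs = 3,
                         feature_prob = 0.4, sensitive_frac = 0.3,
                         planted_pair_effects = NULL,
                         planted_single_effects = NULL,
                         missing_rate = 0, seed) {
  if (sensitive_frac <= 0 || sensitive_frac >= 1) {
    stop("'sensitive_frac' must lie strictly between 0 and 1",
         call. = FALSE)
  }
  feats <- paste0("F", seq_len(n_features))
  cells <- paste0("CL", seq_len(n_cell_lines))
  drugs <- paste0("D", seq_len(n_drugs))
  chk <- function(d, cols) {
    if (!is.null(d)) stopifnot(all(cols %in% names(d)))
  }
  chk(planted_pair_effects, c("feature1", "feature2", "drug", "odds_ratio"))
  chk(planted_single_effects, c("feature", "drug", "delta"))
  with_seed(seed, {
    X <- matrix(stats::rbinom(n_features * n_cell_lines, 1L, feature_prob),
                n_features, n_cell_lines, dimnames = list(feats, cells))
    calls <- matrix(NA_character_, n_drugs, n_cell_lines,
                    dimnames = list(drugs, cells))
    ic50 <- matrix(stats::rnorm(n_drugs * n_cell_lines), n_drugs,
                   n_cell_lines, dimnames = list(drugs, cells))
    base_p <- stats::setNames(rep(sensitive_frac, n_drugs), drugs)
    for (d in drugs) {
      p_cell <- rep(sensitive_frac, n_cell_lines)
      if (!is.null(planted_pair_effects)) {
        hits <- planted_pair_effects[planted_pair_effects$drug == d, ,
                                     drop = FALSE]
        for (r in seq_len(nrow(hits))) {
          or <- hits$odds_ratio[r]
          pp <- X[hits$feature1[r], ] == 1L & X[hits$feature2[r], ] == 1L
          qq <- mean(pp)
          p0 <- sensitive_frac
          if (qq > 0 && qq < 1 && or != 1) {
            ## choose the baseline so the overall sensitive fraction holds
            f <- function(p0) {
              p1 <- or * p0 / (1 - p0 + or * p0)
              qq * p1 + (1 - qq) * p0 - sensitive_frac
            }
            p0 <- stats::uniroot(f, c(1e-9, 1 - 1e-9))$root
          }
          p1 <- or * p0 / (1 - p0 + or * p0)
          p_cell[pp] <- p1
          p_cell[!pp] <- p0
          base_p[d] <- p0
        }
      }
      sens <- stats::rbinom(n_cell_lines, 1L, p_cell) == 1L
      calls[d, ] <- ifelse(sens, "sensitive", "resistant")
      if (!is.null(planted_pair_effects) &&
          d %in% planted_pair_effects$drug) {
        ic50[d, sens] <- ic50[d, sens] - 2
      }
      if (!is.null(planted_single_effects)) {
        hits <- planted_single_effects[planted_single_effects$drug == d, ,
                                       drop = FALSE]
        for (r in seq_len(nrow(hits))) {
          on <- X[hits$feature[r], ] == 1L
          ic50[d, on] <- ic50[d, on] + hits$delta[r]
        }
      }
    }
    if (missing_rate > 0) {
      ic50[stats::runif(length(ic50)) < missing_rate] <- NA_real_
    }
    list(features = X, calls = calls, ic50 = ic50,
         truth = list(planted_pair_effects = planted_pair_effects,
                      planted_single_effects = planted_single_effects,
                      baseline_sensitive_p = base_p, seed = seed))
  })
}

#' Simulate per-sample clinical annotations
#'
#' Draws cancer type (with its haematological/solid class), clinical
#' stage, whole-genome-doubling status and primary/metastatic site
#' independently per sample.
#'
#' @param samples Character vector of sample ids (or a single integer, the
#'   number of samples).
#' @param type_mix Data frame with columns `cancer_type`, `cancer_class`,
#'   `prob`; the default mixes one haematological and two solid types.
#' @param stage_dist Named probability vector over stages I-IV.
#' @param wgd_rate Probability of WGD-positive status.
#' @param met_rate Probability a sample is metastatic.
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `cancer_type`,
#'   `cancer_class`, `stage`, `wgd`, `site_class`, `metastatic_site`
#'   (`NA` unless metastatic).
#' @export
sim_annotations <- function(samples,
                            type_mix = NULL,
                            stage_dist = c(I = 0.4, II = 0.3, III = 0.2,
                                           IV = 0.1),
                            wgd_rate = 0.3, met_rate = 0.3, seed) {
  if (is.numeric(samples) && length(samples) == 1L) {
    samples <- sprintf("S%03d", seq_len(samples))
  }
  if (is.null(type_mix)) {
    type_mix <- data.frame(
      cancer_type = c("LAML", "BRCA", "LUAD"),
      cancer_class = c("haematological", "solid", "solid"),
      prob = c(0.2, 0.4, 0.4), stringsAsFactors = FALSE)
  }
  stopifnot(abs(sum(type_mix$prob) - 1) < 1e-8,
            abs(sum(stage_dist) - 1) < 1e-8)
  n <- length(samples)
  with_seed(seed, {
    ti <- sample.int(nrow(type_mix), n, replace = TRUE,
                     prob = type_mix$prob)
    stage <- sample(names(stage_dist), n, replace = TRUE,
                    prob = stage_dist)
    met <- stats::runif(n) < met_rate
    site <- ifelse(met,
                   sample(c("liver", "lung", "bone", "brain"), n,
                          replace = TRUE),
                   NA_character_)
    data.frame(sample_id = samples,
               cancer_type = type_mix$cancer_type[ti],
               cancer_class = type_mix$cancer_class[ti],
               stage = stage,
               wgd = stats::runif(n) < wgd_rate,
               site_class = ifelse(met, "metastatic", "primary"),
               metastatic_site = site,
               stringsAsFactors = FALSE)
  })
}
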