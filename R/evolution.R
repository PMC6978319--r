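#' Build the karyotype tree of a cohort
#'
#' Collapses a cohort into its distinct CAA karyotypes (the set of signed
#' arm events of each sample) with observation frequencies. Nodes live on a
#' levelled tree: level `k` holds karyotypes with exactly `k` CAAs, level 0
#' is the root (no CAAs), and edges - kept implicit - connect each
#' karyotype to the karyotypes one additional compatible event away.
#'
#' @param caas A `caa_matrix`, or a binary samples x signed-events matrix.
#' @return Object of class `karyotype_tree`: a list with `events` (the
#'   signed-event universe), `karyotypes` (list of character vectors),
#'   `freq` (observed counts) and `n_samples`.
#' @examples
#' m <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0))
#' colnames(m) <- c("+1p", "-1p", "+1q", "-1q")[c(1, 3, 2, 4)]
#' # a tiny two-sample cohort
#' tree <- build_karyotype_tree(m)
#' tree$freq
#' @export
build_karyotype_tree <- function(caas) {
  ev <- if (inherits(caas, "caa_matrix")) caa_events(caas) else as.matrix(caas)
  if (!all(ev %in% c(0L, 1L))) {
    stop("event matrix must be binary", call. = FALSE)
  }
  events <- colnames(ev)
  if (is.null(events)) stop("event matrix must have column names",
                            call. = FALSE)
  info <- try(parse_events(events), silent = TRUE)
  if (!inherits(info, "try-error")) {
    paired <- intersect(info$arm[info$sign == 1L], info$arm[info$sign == -1L])
    for (a in paired) {
      if (any(ev[, paste0("+", a)] + ev[, paste0("-", a)] > 1L)) {
        stop("a sample carries both the gain and the loss of arm ", a,
             call. = FALSE)
      }
    }
  }
  keys <- apply(ev, 1L, function(r) paste(events[r == 1L], collapse = "|"))
  tab <- table(keys)
  karyotypes <- lapply(strsplit(names(tab), "|", fixed = TRUE), function(k) {
    k[nzchar(k)]
  })
  structure(list(events = events, karyotypes = karyotypes,
                 freq = as.integer(tab), n_samples = nrow(ev)),
            class = "karyotype_tree")
}

#' @export
print.karyotype_tree <- function(x, ...) {
  sizes <- lengths(x$karyotypes)
  cat("Karyotype tree: ", x$n_samples, " samples, ",
      length(x$karyotypes), " distinct karyotypes, levels 0..",
      max(c(0L, sizes)), "\n", sep = "")
  invisible(x)
}

## binary karyotype x event incidence matrix of a tree
.tree_incidence <- function(tree) {
  K <- length(tree$karyotypes)
  Bm <- matrix(0L, K, length(tree$events),
               dimnames = list(NULL, tree$events))
  for (i in seq_len(K)) Bm[i, tree$karyotypes[[i]]] <- 1L
  Bm
}

#' Unnormalised transition weight between two signed events
#'
#' Under the single-edge reading of the karyotype-tree model, the weight of
#' the transition x -> y is the summed frequency of all observed karyotypes
#' containing both events - i.e. the total weight of edges whose parent
#' (the karyotype minus y) contains x. The gain and the loss of one arm are
#' incompatible and have weight 0 by contract.
#'
#' @param x,y Signed event labels.
#' @param tree A `karyotype_tree`.
#' @return Single numeric weight.
#' @export
transition_weight <- function(x, y, tree) {
  stopifnot(inherits(tree, "karyotype_tree"))
  if (!all(c(x, y) %in% tree$events)) {
    stop("unknown event(s): ", paste(setdiff(c(x, y), tree$events),
                                     collapse = ", "), call. = FALSE)
  }
  if (x == y) return(0)
  px <- parse_events(c(x, y))
  if (px$arm[1L] == px$arm[2L]) return(0)  # +arm / -arm never co-occur
  sum(tree$freq[vapply(tree$karyotypes, function(u) {
    all(c(x, y) %in% u)
  }, logical(1L))])
}

#' Estimate the CAA transition probability matrix
#'
#' Estimates, for every ordered pair of signed events, the probability of
#' the transition x -> y (acquiring y from a karyotype already carrying x)
#' on the levelled karyotype tree.
#'
#' With the default `semantics = "edge"`, the numerator is the single-edge
#' weight of [transition_weight()] and each row is normalised by the total
#' outgoing edge weight from x-containing karyotypes,
#' `sum over u containing x of freq(u) * (|u| - 1)`, so every row sums to 1
#' (or to 0 for events never observed in a karyotype of size >= 2).
#' `semantics = "path"` is an order-sensitive variant that scores
#' multi-step paths between observed karyotypes: every observed pair
#' (v, u) with v a proper subset of u contributes `freq(v) * freq(u)` to
#' all transitions x -> y with x in v and y acquired between v and u, and
#' rows are normalised to sum to 1. Because it conditions on observed
#' starting karyotypes, the path variant retains information about which
#' event tends to appear alone; see the package vignette for when the two
#' variants disagree.
#'
#' @param tree A `karyotype_tree`.
#' @param semantics `"edge"` (default) or `"path"`.
#' @return A square numeric matrix of class `caa_transition` over the
#'   tree's signed events, zero diagonal, incompatible (same-arm) pairs
#'   identically 0.
#' @examples
#' m <- matrix(0L, 6, 4, dimnames = list(NULL, c("+A", "-A", "+B", "-B")))
#' m[1:6, 1] <- 1L; m[4:5, 3] <- 1L; m[6, 4] <- 1L
#' P <- transition_matrix(build_karyotype_tree(m))
#' P["+A", "+B"]  # 2/3
#' @export
transition_matrix <- function(tree, semantics = c("edge", "path")) {
  stopifnot(inherits(tree, "karyotype_tree"))
  semantics <- match.arg(semantics)
  events <- tree$events
  E <- length(events)
  Bm <- .tree_incidence(tree)
  f <- tree$freq
  sz <- rowSums(Bm)
  if (semantics == "edge") {
    W <- crossprod(Bm * f, Bm)   # W[x, y] = sum of freq over karyotypes with both
    diag(W) <- 0
    denom <- as.vector(crossprod(Bm, f * (sz - 1)))
    P <- W / ifelse(denom > 0, denom, 1)
    P[denom == 0, ] <- 0
  } else {
    W <- matrix(0, E, E, dimnames = list(events, events))
    K <- nrow(Bm)
    ord <- order(sz)
    for (ii in seq_len(K)) for (jj in seq_len(K)) {
      i <- ord[ii]; j <- ord[jj]
      if (sz[i] < sz[j] && all(Bm[i, ] <= Bm[j, ])) {
        xs <- Bm[i, ] == 1L
        ys <- Bm[j, ] == 1L & !xs
        W[xs, ys] <- W[xs, ys] + f[i] * f[j]
      }
    }
    rs <- rowSums(W)
    P <- W / ifelse(rs > 0, rs, 1)
  }
  ## structural zeros: the two signs of one arm can never co-occur
  info <- try(parse_events(events), silent = TRUE)
  if (!inherits(info, "try-error")) {
    same_arm <- outer(info$arm, info$arm, "==")
    P[same_arm] <- 0
    diag(P) <- 0
  }
  dimnames(P) <- list(events, events)
  structure(P, class = c("caa_transition", "matrix"),
            semantics = semantics, n_samples = tree$n_samples)
}

#' Per-event observation frequencies
#'
#' Number of samples carrying each signed event; used to size network nodes
#' and filter low-frequency events.
#'
#' @param caas A `caa_matrix` or binary event matrix.
#' @return Named integer vector.
#' @export
event_frequencies <- function(caas) {
  ev <- if (inherits(caas, "caa_matrix")) caa_events(caas) else as.matrix(caas)
  colSums(ev)
}

#' Extract the high-probability CAA acquisition network
#'
#' Filters the transition matrix to edges with probability at least
#' `min_prob` between events observed at least `min_freq` times, returning
#' a deterministic edge list (probability descending, then lexicographic).
#'
#' @param matrix A `caa_transition` matrix.
#' @param frequencies Named per-event sample counts from
#'   [event_frequencies()]; `NULL` disables the frequency filter.
#' @param min_prob Minimum transition probability for an edge.
#' @param min_freq Minimum event frequency for both endpoints.
#' @return Data frame with columns `from`, `to`, `prob`, `from_freq`,
#'   `to_freq`.
#' @export
evolution_network <- function(matrix, frequencies = NULL, min_prob = 0.5,
                              min_freq = 1L) {
  stopifnot(inherits(matrix, "caa_transition"))
  events <- rownames(matrix)
  if (is.null(frequencies)) {
    frequencies <- stats::setNames(rep(Inf, length(events)), events)
  }
  idx <- which(matrix >= min_prob & matrix > 0, arr.ind = TRUE)
  out <- data.frame(from = events[idx[, 1L]], to = events[idx[, 2L]],
                    prob = matrix[idx], stringsAsFactors = FALSE)
  out$from_freq <- as.numeric(frequencies[out$from])
  out$to_freq <- as.numeric(frequencies[out$to])
  out <- out[out$from_freq >= min_freq & out$to_freq >= min_freq, ,
             drop = FALSE]
  out <- out[order(-out$prob, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a transition matrix as a labelled TSV
#'
#' Full-precision decimal text, so [read_transition_matrix()] reproduces the
#' values bit-identically.
#'
#' @param matrix A `caa_transition` (or plain square) matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_transition_matrix <- function(matrix, path) {
  m <- unclass(matrix)
  out <- cbind(event = rownames(m),
               as.data.frame(apply(m, 2L, fmt_full), stringsAsFactors = FALSE))
  names(out) <- c("event", colnames(m))
  ok <- try(utils::write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write transition matrix to '", path, "'", call. = FALSE)
  }
  invisible(path)
}

#' Read a transition matrix written by [export_transition_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A `caa_transition` matrix.
#' @export
read_transition_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  structure(m, class = c("caa_transition", "matrix"))
}

#' Write an acquisition network in GraphML format
#'
#' Thin wrapper around the igraph GraphML writer; requires the igraph
#' package.
#'
#' @param network Edge list from [evolution_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the 'igraph' package is required for GraphML export",
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(network[, c("from", "to", "prob")],
                                     directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
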