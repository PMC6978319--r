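#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so seeded generators are pure functions
#' of their arguments and never perturb the session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Weighted median
#'
#' Lower weighted median: the smallest value whose cumulative weight reaches
#' half the total. Used to recentre per-sample segment means by covered length.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @return A single numeric value.
#' @keywords internal
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  keep <- is.finite(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

#' Significance band code for q values
#'
#' Encodes an FDR-adjusted q value as the exponent-style band used for
#' reporting: 0 for not significant (q >= 0.05), 1 for q < 0.05, 2 for
#' q < 1e-2, 3 for q < 1e-3, and so on (capped at 16).
#'
#' @param q Numeric vector of q values in \[0, 1\].
#' @return Integer vector of band codes (`NA` where `q` is `NA`).
#' @examples
#' q_band(c(0.2, 0.03, 0.004, 1e-7))
#' @export
q_band <- function(q) {
  vapply(q, function(qi) {
    if (is.na(qi)) return(NA_integer_)
    if (qi >= 0.05) return(0L)
    band <- 1L
    while (band < 16L && qi < 10^-(band + 1L)) band <- band + 1L
    band
  }, integer(1L))
}

## full-precision numeric formatting so TSV exports round-trip exactly
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  ## shorten where a shorter representation parses back identically
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out[is.na(x)] <- "NA"
  out
}

## parse signed-event labels "+17p" / "-8q" into sign and arm id
parse_events <- function(events) {
  sgn <- substr(events, 1L, 1L)
  if (!all(sgn %in% c("+", "-"))) {
    stop("signed events must start with '+' or '-': ",
         paste(utils::head(events[!sgn %in% c("+", "-")], 3L), collapse = ", "),
         call. = FALSE)
  }
  data.frame(event = events,
             sign = ifelse(sgn == "+", 1L, -1L),
             arm = substring(events, 2L),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
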