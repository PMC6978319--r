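## hg19 (GRCh37) autosome lengths and centromere intervals, from the UCSC
## cytoBand track (the centromere is the union of the two "acen" bands).
## Coordinates are 0-based half-open, the package's internal convention.
.hg19 <- data.frame(
  chromosome = as.character(1:22),
  length = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
             171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
             135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
             90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
             48129895L, 51304566L),
  cen_start = c(121500000L, 90500000L, 87900000L, 48200000L, 46100000L,
                58700000L, 58000000L, 43100000L, 47300000L, 38000000L,
                51600000L, 33300000L, 16300000L, 16100000L, 15800000L,
                34600000L, 22200000L, 15400000L, 24400000L, 25600000L,
                10900000L, 13200000L),
  cen_end = c(128900000L, 96800000L, 93900000L, 52700000L, 50700000L,
              63300000L, 61700000L, 48100000L, 50700000L, 42300000L,
              55700000L, 38200000L, 19500000L, 19100000L, 20700000L,
              38600000L, 25800000L, 19000000L, 28600000L, 29400000L,
              14300000L, 16300000L),
  stringsAsFactors = FALSE
)

## short arms of the acrocentric chromosomes carry no unique sequence worth
## calling and are excluded from the default arm set, leaving 39 arms
.acrocentric_p <- c("13p", "14p", "15p", "21p", "22p")

#' Built-in chromosome-arm model (GRCh37/hg19)
#'
#' Returns the default arm/centromere table for the 22 autosomes: one row per
#' arm with the arm interval, the centromere interval of its chromosome and an
#' `included` flag. The default marks 39 arms as included (44 autosomal arms
#' minus the five acrocentric short arms 13p, 14p, 15p, 21p and 22p), giving
#' 78 signed gain/loss events. Sex chromosomes are not part of the model.
#' Coordinates are 0-based half-open.
#'
#' @return A data frame of class `caa_arm_model` with columns `chromosome`,
#'   `arm`, `arm_id`, `start_bp`, `end_bp`, `centromere_start_bp`,
#'   `centromere_end_bp` and `included`.
#' @examples
#' arms <- caa_arm_model()
#' sum(arms$included)          # 39
#' length(signed_events(arms)) # 78
#' @export
caa_arm_model <- function() {
  p <- data.frame(chromosome = .hg19$chromosome, arm = "p",
                  start_bp = 0L, end_bp = .hg19$cen_start,
                  centromere_start_bp = .hg19$cen_start,
                  centromere_end_bp = .hg19$cen_end,
                  stringsAsFactors = FALSE)
  q <- data.frame(chromosome = .hg19$chromosome, arm = "q",
                  start_bp = .hg19$cen_end, end_bp = .hg19$length,
                  centromere_start_bp = .hg19$cen_start,
                  centromere_end_bp = .hg19$cen_end,
                  stringsAsFactors = FALSE)
  arms <- rbind(p, q)
  arms <- arms[order(as.integer(arms$chromosome), arms$arm), ]
  arms$arm_id <- paste0(arms$chromosome, arms$arm)
  arms$included <- !(arms$arm_id %in% .acrocentric_p)
  rownames(arms) <- NULL
  arms <- arms[, c("chromosome", "arm", "arm_id", "start_bp", "end_bp",
                   "centromere_start_bp", "centromere_end_bp", "included")]
  class(arms) <- c("caa_arm_model", "data.frame")
  arms
}

#' Load a chromosome-arm model
#'
#' Reads a BED-like tab-separated arm/centromere table, or returns the
#' built-in GRCh37 model when `path` is `NULL`. Required columns:
#' `chromosome`, `arm` (p/q), `start_bp`, `end_bp`, `centromere_start_bp`,
#' `centromere_end_bp`; an optional logical `included` column defaults to
#' `TRUE`. Coordinates must be 0-based half-open.
#'
#' @param path Path to a tab-separated arm table, or `NULL` for the built-in
#'   model.
#' @return A validated `caa_arm_model` data frame.
#' @seealso [caa_arm_model()], [signed_events()]
#' @export
load_arm_model <- function(path = NULL) {
  if (is.null(path)) return(caa_arm_model())
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "arm", "start_bp", "end_bp",
            "centromere_start_bp", "centromere_end_bp")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("arm model is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$chromosome <- sub("^chr", "", as.character(tab$chromosome))
  if (is.null(tab$included)) tab$included <- TRUE
  tab$arm_id <- paste0(tab$chromosome, tab$arm)
  tab <- tab[, c("chromosome", "arm", "arm_id", "start_bp", "end_bp",
                 "centromere_start_bp", "centromere_end_bp", "included")]
  class(tab) <- c("caa_arm_model", "data.frame")
  validate_arm_model(tab)
}

#' Validate an arm model
#'
#' Checks the structural invariants of an arm table: arms are non-empty
#' intervals, the p arm precedes the q arm on each chromosome, the centromere
#' lies between them, and arm intervals on one chromosome do not overlap.
#'
#' @param arms An arm model data frame.
#' @return The validated model, invisibly classed as `caa_arm_model`.
#' @export
validate_arm_model <- function(arms) {
  stopifnot(is.data.frame(arms))
  if (!all(arms$arm %in% c("p", "q"))) {
    stop("arm labels must be 'p' or 'q'", call. = FALSE)
  }
  if (any(arms$end_bp <= arms$start_bp)) {
    stop("arm intervals must have end_bp > start_bp", call. = FALSE)
  }
  if (anyDuplicated(arms$arm_id)) {
    stop("duplicate arm ids: ",
         paste(unique(arms$arm_id[duplicated(arms$arm_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (chr in unique(arms$chromosome)) {
    rows <- arms[arms$chromosome == chr, ]
    p <- rows[rows$arm == "p", ]
    q <- rows[rows$arm == "q", ]
    if (nrow(p) == 1L && nrow(q) == 1L) {
      if (p$start_bp >= q$start_bp || p$end_bp > q$start_bp) {
        stop("chromosome ", chr, ": p arm must precede the q arm",
             call. = FALSE)
      }
      if (p$end_bp > q$start_bp) {
        stop("chromosome ", chr, ": overlapping arm intervals", call. = FALSE)
      }
      cs <- unique(rows$centromere_start_bp)
      ce <- unique(rows$centromere_end_bp)
      if (length(cs) != 1L || length(ce) != 1L) {
        stop("chromosome ", chr, ": inconsistent centromere interval",
             call. = FALSE)
      }
      if (cs < p$end_bp || ce > q$start_bp || ce <= cs) {
        stop("chromosome ", chr,
             ": centromere interval must lie between the p and q arms",
             call. = FALSE)
      }
    }
  }
  if (!inherits(arms, "caa_arm_model")) {
    class(arms) <- c("caa_arm_model", "data.frame")
  }
  invisible(arms)
}

#' Signed CAA events of an arm model
#'
#' One gain and one loss event per included arm, in arm order: `"+1p"`,
#' `"-1p"`, `"+1q"`, ... The default model yields 78 events.
#'
#' @param arms An arm model (default: built-in GRCh37 model).
#' @return Character vector of signed event labels.
#' @export
signed_events <- function(arms = caa_arm_model()) {
  ids <- arms$arm_id[arms$included]
  as.vector(rbind(paste0("+", ids), paste0("-", ids)))
}

#' @export
print.caa_arm_model <- function(x, ...) {
  cat("Chromosome arm model: ", nrow(x), " arms (",
      sum(x$included), " included, ",
      2L * sum(x$included), " signed events)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more arms\n")
  invisible(x)
}
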