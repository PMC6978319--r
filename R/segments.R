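#' SEG dialect description
#'
#' Describes how a segmented copy-number file is laid out: whether its
#' coordinates are 1-based inclusive (the TCGA SEG convention, the default)
#' or already 0-based half-open, and the field separator.
#'
#' @param one_based Logical; `TRUE` for 1-based inclusive input coordinates.
#' @param sep Field separator.
#' @return A list of class `seg_dialect`.
#' @export
seg_dialect <- function(one_based = TRUE, sep = "\t") {
  structure(list(one_based = isTRUE(one_based), sep = sep),
            class = "seg_dialect")
}

## column synonyms accepted in SEG-style headers (matched case-insensitively,
## ignoring separators)
.seg_columns <- list(
  sample_id = c("sample", "sampleid", "id", "sample_id"),
  chromosome = c("chromosome", "chrom", "chr"),
  start_bp = c("start", "startbp", "start_bp", "locstart", "loc.start"),
  end_bp = c("end", "endbp", "end_bp", "locend", "loc.end"),
  seg_mean = c("segmentmean", "segment_mean", "segmean", "seg_mean",
               "seg.mean", "mean"),
  num_probes = c("numprobes", "num_probes", "nummark", "num.mark"),
  major_allele_cn = c("majorallelecn", "major_allele_cn", "majorcn",
                      "major_cn")
)

.match_seg_col <- function(header, synonyms) {
  norm <- tolower(gsub("[._ ]", "", header))
  idx <- which(norm %in% gsub("[._ ]", "", synonyms))
  if (length(idx)) idx[1L] else NA_integer_
}

#' Read a segmented copy-number (SEG) table
#'
#' Reads a delimited table of per-sample genomic segments with log2
#' copy-number ratios. Input coordinates follow `dialect` (1-based inclusive
#' by default) and are normalised to the internal 0-based half-open
#' convention; `"chr"` prefixes are stripped from chromosome labels.
#'
#' @param path Path to the file.
#' @param dialect A [seg_dialect()].
#' @return A data frame of class `caa_segments` with columns `sample_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `seg_mean` and, when present in the
#'   input, `num_probes` and `major_allele_cn`.
#' @seealso [write_segments()]
#' @export
read_segments <- function(path, dialect = seg_dialect()) {
  stopifnot(inherits(dialect, "seg_dialect"))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "")
  cols <- lapply(.seg_columns, .match_seg_col, header = names(raw))
  required <- c("sample_id", "chromosome", "start_bp", "end_bp", "seg_mean")
  for (col in required) {
    if (is.na(cols[[col]])) {
      stop("segment file '", path, "' is missing a '", col, "' column",
           call. = FALSE)
    }
  }
  out <- data.frame(
    sample_id = raw[[cols$sample_id]],
    chromosome = sub("^chr", "", raw[[cols$chromosome]]),
    start_bp = raw[[cols$start_bp]],
    end_bp = raw[[cols$end_bp]],
    seg_mean = raw[[cols$seg_mean]],
    stringsAsFactors = FALSE
  )
  for (col in c("start_bp", "end_bp", "seg_mean")) {
    num <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(num) & !is.na(out[[col]]))
    if (length(bad)) {
      stop("segment file '", path, "': non-numeric '", col, "' at line ",
           bad[1L] + 1L, " (value '", out[[col]][bad[1L]], "')",
           call. = FALSE)
    }
    out[[col]] <- num
  }
  if (!is.na(cols$num_probes)) {
    out$num_probes <- suppressWarnings(as.integer(raw[[cols$num_probes]]))
  }
  if (!is.na(cols$major_allele_cn)) {
    out$major_allele_cn <-
      suppressWarnings(as.integer(raw[[cols$major_allele_cn]]))
  }
  if (dialect$one_based) out$start_bp <- out$start_bp - 1
  if (any(!is.finite(out$seg_mean))) {
    stop("segment file '", path, "': non-finite seg_mean at line ",
         which(!is.finite(out$seg_mean))[1L] + 1L, call. = FALSE)
  }
  zero <- which(out$end_bp <= out$start_bp)
  if (length(zero)) {
    stop("segment file '", path, "': zero- or negative-length segment ",
         "at line ", zero[1L] + 1L, call. = FALSE)
  }
  class(out) <- c("caa_segments", "data.frame")
  out
}

#' Write a segmented copy-number (SEG) table
#'
#' Writes segments in the tab-separated SEG layout (`Sample`, `Chromosome`,
#' `Start`, `End`, `Segment_Mean`, plus `Num_Probes` / `Major_Allele_CN` when
#' present), converting internal 0-based half-open coordinates back to the
#' dialect's convention. Segment means are written at full precision so a
#' read/write cycle is bit-identical.
#'
#' @param segments A `caa_segments` data frame.
#' @param path Output path.
#' @param dialect A [seg_dialect()].
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, dialect = seg_dialect()) {
  stopifnot(is.data.frame(segments))
  start <- segments$start_bp + if (dialect$one_based) 1 else 0
  out <- data.frame(
    Sample = segments$sample_id,
    Chromosome = segments$chromosome,
    Start = format(start, scientific = FALSE, trim = TRUE),
    End = format(segments$end_bp, scientific = FALSE, trim = TRUE),
    Segment_Mean = fmt_full(segments$seg_mean),
    stringsAsFactors = FALSE
  )
  if (!is.null(segments$num_probes)) out$Num_Probes <- segments$num_probes
  if (!is.null(segments$major_allele_cn)) {
    out$Major_Allele_CN <- segments$major_allele_cn
  }
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
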