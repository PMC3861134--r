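#' Genomic interval sets
#'
#' A thin, BED-flavoured container for annotation intervals (CpG islands,
#' TSS, repeats, ChIP peaks, hotspot calls from other studies, ...). All
#' coordinates are 0-based half-open, as in BED. The object is a plain
#' `data.frame` with columns `chrom`, `start`, `end` and optional `strand`
#' and `name`, so it interoperates with base R; conversion to `GRanges` is
#' handled internally where interval algebra is needed.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end numeric interval bounds, 0-based half-open (`end > start`).
#' @param strand optional vector in `+`, `-`, `*`.
#' @param name optional interval names.
#' @param label optional label describing the set (kept as an attribute).
#' @return A `data.frame` of class `interval_set`.
#' @examples
#' interval_set("chr1", c(0, 100), c(50, 200), label = "islands")
#' @export
interval_set <- function(chrom, start, end, strand = NULL, name = NULL,
                         label = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start and end must have matching lengths")
  if (n > 0L && (any(!is.finite(start)) || any(!is.finite(end))))
    stop("interval bounds must be finite")
  if (any(start < 0)) stop("start must be >= 0 (coordinates are 0-based)")
  if (any(end <= start)) stop("intervals must satisfy end > start")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (length(strand) == 1L) strand <- rep(strand, n)
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand values must be one of '+', '-', '*'")
    df$strand <- strand
  }
  if (!is.null(name)) df$name <- as.character(name)
  attr(df, "label") <- label
  class(df) <- c("interval_set", "data.frame")
  df
}

# Validate/coerce anything interval-like into the canonical data.frame form.
.as_intervals <- function(x, what = "intervals") {
  if (is.null(x)) stop(what, " must not be NULL")
  df <- as.data.frame(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom, start, end")
  if (nrow(df) > 0L && any(df$end <= df$start))
    stop(what, ": all intervals must satisfy end > start")
  df$chrom <- as.character(df$chrom)
  df
}

.intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Read and write BED interval files
#'
#' Minimal BED3/BED6 support: tab-separated, no header, 0-based half-open
#' coordinates. Columns beyond the sixth are ignored on read.
#'
#' @param path file path.
#' @param label optional label attached to the returned set.
#' @return `read_bed()` returns an [interval_set()].
#' @export
read_bed <- function(path, label = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns: ", path)
  strand <- if (ncol(df) >= 6L) df[[6L]] else NULL
  name <- if (ncol(df) >= 4L) as.character(df[[4L]]) else NULL
  interval_set(df[[1L]], df[[2L]], df[[3L]], strand = strand, name = name,
               label = label)
}

#' @rdname read_bed
#' @param x an interval set (or compatible data.frame).
#' @export
write_bed <- function(x, path) {
  df <- .as_intervals(x)
  out <- df[, c("chrom", "start", "end")]
  if (!is.null(df$name) || !is.null(df$strand)) {
    out$name <- if (is.null(df$name)) "." else df$name
    out$score <- 0
    out$strand <- if (is.null(df$strand)) "*" else df$strand
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write chromosome length tables
#'
#' Two-column tab-separated files: chromosome name and length in bp.
#'
#' @param path file path.
#' @return `read_chrom_lengths()` returns a named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_chrom_lengths
#' @param lengths named numeric vector of chromosome lengths.
#' @export
write_chrom_lengths <- function(lengths, path) {
  write.table(data.frame(names(lengths), as.numeric(lengths)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Thin intervals so no two kept intervals are closer than a minimum gap
#'
#' Greedy left-to-right scan per chromosome: an interval is kept if its
#' midpoint is at least `min_gap` bp from the midpoint of the previously
#' kept interval. Used to de-cluster repeats or CpG islands before
#' profiling so clustered elements do not dominate a mean profile.
#'
#' @param x interval set.
#' @param min_gap minimum allowed midpoint separation (bp).
#' @return the thinned subset of `x`.
#' @export
thin_intervals <- function(x, min_gap) {
  df <- .as_intervals(x)
  keep <- logical(nrow(df))
  mid <- (df$start + df$end) / 2
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    i <- i[order(mid[i])]
    last <- -Inf
    for (j in i) {
      if (mid[j] - last >= min_gap) {
        keep[j] <- TRUE
        last <- mid[j]
      }
    }
  }
  df[keep, , drop = FALSE]
}
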