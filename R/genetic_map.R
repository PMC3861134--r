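#' Genetic maps as piecewise-constant rate tracks
#'
#' A genetic map stores, per chromosome, an ascending vector of boundary
#' positions (bp, 1-based as in the map TSV format) and one recombination
#' rate (cM/Mb) per interval between consecutive boundaries. The rate
#' recorded at a boundary applies from that boundary up to (not including)
#' the next one.
#'
#' @param x a data.frame with columns `chrom`, `pos`, `rate` in long format.
#'   Within each chromosome, positions must be strictly ascending and at
#'   least two rows must be present; the `rate` on the last row of a
#'   chromosome is ignored (it has no right boundary) and may be `NA`.
#' @return an object of class `genetic_map`: a named list with elements
#'   `boundaries` (numeric) and `rates` (numeric, one shorter) per
#'   chromosome.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr1",
#'                              pos = c(1, 1001, 2001),
#'                              rate = c(1, 5, NA)))
#' total_map_length(gm)  # 0.001 + 0.005 cM
#' @export
genetic_map <- function(x) {
  df <- as.data.frame(x)
  need <- c("chrom", "pos", "rate")
  if (!all(need %in% names(df)))
    stop("expected columns chrom, pos, rate")
  df$chrom <- as.character(df$chrom)
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("chromosome ", ch, " has fewer than 2 map positions")
    pos <- as.numeric(sub$pos)
    if (any(diff(pos) <= 0))
      stop("positions must be strictly ascending within chromosome ", ch)
    rates <- as.numeric(sub$rate)[-nrow(sub)]
    if (any(!is.finite(rates)))
      stop("non-finite rate within chromosome ", ch)
    if (any(rates < 0))
      stop("negative recombination rate within chromosome ", ch)
    out[[ch]] <- list(boundaries = pos, rates = rates)
  }
  if (length(out) == 0L) stop("empty genetic map")
  structure(out, class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", length(x), "chromosome(s)\n")
  for (ch in names(x)) {
    b <- x[[ch]]$boundaries
    cat(sprintf("  %s: %d intervals, %.0f bp span, %.3f cM\n",
                ch, length(x[[ch]]$rates), b[length(b)] - b[1L],
                map_length(x, ch)))
  }
  invisible(x)
}

#' Map lengths in centiMorgans
#'
#' @param map a [genetic_map()].
#' @param chrom a single chromosome name, or `NULL` for all.
#' @return `map_length()` returns a named vector of per-chromosome genetic
#'   lengths (cM); `total_map_length()` their sum.
#' @export
map_length <- function(map, chrom = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  chs <- if (is.null(chrom)) names(map) else chrom
  vapply(setNames(chs, chs), function(ch) {
    m <- map[[ch]]
    if (is.null(m)) stop("chromosome not in map: ", ch)
    sum(m$rates * diff(m$boundaries)) / 1e6
  }, numeric(1))
}

#' @rdname map_length
#' @export
total_map_length <- function(map) sum(map_length(map))

#' Read and write genetic-map TSV files
#'
#' Format: tab-separated with header columns `chrom`, `pos`, `rate`
#' (position in bp, 1-based; rate in cM/Mb applying rightwards from `pos`).
#' The last row of each chromosome carries rate 0 by convention.
#'
#' @param path file path.
#' @return `read_genetic_map()` returns a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("chrom", "pos", "rate") %in% names(df)))
    stop("map TSV must have header columns chrom, pos, rate: ", path)
  # the trailing rate of each chromosome is a placeholder; mask it so the
  # negative-rate check does not trip on e.g. -1 sentinels
  last <- !duplicated(df$chrom, fromLast = TRUE)
  df$rate[last] <- NA
  genetic_map(df)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(names(map), function(ch) {
    m <- map[[ch]]
    data.frame(chrom = ch, pos = m$boundaries, rate = c(m$rates, 0))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- rate evaluation --------------------------------------------------------

# Cumulative genetic position (cM) at an arbitrary bp coordinate, evaluated
# in BED (0-based, continuous) space. Coordinates are clamped to the mapped
# extent.
.gm_cum_at <- function(m, x) {
  b0 <- m$boundaries - 1         # continuous 0-based boundary coords
  cum <- c(0, cumsum(m$rates * diff(b0))) / 1e6
  x <- pmin(pmax(x, b0[1L]), b0[length(b0)])
  i <- findInterval(x, b0, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(m$rates))
  cum[i] + (x - b0[i]) * m$rates[i] / 1e6
}

#' Mean recombination rate over intervals
#'
#' Evaluates the length-weighted mean rate (cM/Mb) of the map over each
#' 0-based half-open interval `[start, end)`. Parts of an interval outside
#' the mapped extent are excluded from the average; an interval wholly
#' outside the map yields `NA`.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome (recycled).
#' @param start,end interval bounds (bp, 0-based half-open).
#' @return numeric vector of mean rates.
#' @export
mean_rate <- function(map, chrom, start, end) {
  stopifnot(inherits(map, "genetic_map"))
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    m <- map[[ch]]
    if (is.null(m)) next
    i <- which(chrom == ch)
    b0 <- m$boundaries - 1
    lo <- pmax(start[i], b0[1L])
    hi <- pmin(end[i], b0[length(b0)])
    ok <- hi > lo
    cm <- .gm_cum_at(m, hi[ok]) - .gm_cum_at(m, lo[ok])
    out[i][ok] <- cm / (hi[ok] - lo[ok]) * 1e6
  }
  out
}

# Maximum rate over 0-based half-open windows of one chromosome (vectorized).
.gm_max_rate <- function(m, start, end) {
  b0 <- m$boundaries - 1
  nr <- length(m$rates)
  i1 <- pmin(pmax(findInterval(start, b0, rightmost.closed = TRUE), 1L), nr)
  i2 <- pmin(pmax(findInterval(end, b0, left.open = TRUE,
                               rightmost.closed = TRUE), 1L), nr)
  vapply(seq_along(start), function(k) max(m$rates[i1[k]:i2[k]]),
         numeric(1))
}

# ---- hotspot calling --------------------------------------------------------

#' Call recombination hotspots from a genetic map
#'
#' Seeds candidate peaks where the piecewise-constant rate reaches
#' `fold` times the chromosome-wide (length-weighted) median, merges
#' candidates separated by less than `merge_gap` bp, and then retests each
#' candidate against a local background: the length-weighted median rate
#' over `flank` bp on either side, with all candidate intervals excluded
#' from the flanks so clustered peaks do not inflate the background. A
#' candidate becomes a hotspot if its peak rate is at least `fold` times
#' the local background and its width lies within `[min_width, max_width]`.
#'
#' @param map a [genetic_map()].
#' @param fold minimum peak/background rate ratio (default 5).
#' @param flank background flank length in bp (default 1e5); must exceed
#'   `max_width`, otherwise the background could be dominated by the
#'   candidate's own shoulder.
#' @param min_width,max_width admissible hotspot widths in bp.
#' @param merge_gap candidates closer than this many bp are merged.
#' @return a `data.frame` of class `hotspots` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `peak_rate`, `background_rate`
#'   and `strength_class` (unset; see [classify_strength()]).
#' @export
call_hotspots <- function(map, fold = 5, flank = 1e5,
                          min_width = 1000, max_width = 20000,
                          merge_gap = 500) {
  stopifnot(inherits(map, "genetic_map"))
  if (fold <= 1) stop("fold must exceed 1")
  if (flank <= max_width)
    stop("flank must exceed max_width, or the background is contaminated ",
         "by the candidate itself")
  res <- list()
  for (ch in names(map)) {
    m <- map[[ch]]
    b0 <- m$boundaries - 1
    w <- diff(b0)
    global_bg <- .weighted_median(m$rates, w)
    if (!is.finite(global_bg)) next
    thr <- fold * max(global_bg, .Machine$double.eps)
    pass <- m$rates >= thr
    if (!any(pass)) next
    r <- rle(pass)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    cs <- b0[starts_i[r$values]]
    ce <- b0[ends_i[r$values] + 1L]
    # merge candidates separated by < merge_gap
    if (length(cs) > 1L) {
      gap_small <- cs[-1L] - ce[-length(ce)] < merge_gap
      grp <- cumsum(c(TRUE, !gap_small))
      cs <- tapply(cs, grp, min)
      ce <- tapply(ce, grp, max)
    }
    cand <- .merge_numeric_intervals(as.numeric(cs), as.numeric(ce))
    for (k in seq_along(cand$start)) {
      s <- cand$start[k]; e <- cand$end[k]
      width <- e - s
      if (width < min_width || width > max_width) next
      bg <- .local_background(m, b0, s, e, flank, cand)
      if (!is.finite(bg)) next
      peak <- .gm_max_rate(m, s, e)
      if (peak >= fold * max(bg, .Machine$double.eps)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e,
          peak_rate = peak, background_rate = bg,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               peak_rate = numeric(0), background_rate = numeric(0))
  out$strength_class <- rep(NA_character_, nrow(out))
  class(out) <- c("hotspots", "data.frame")
  out
}

# Length-weighted median rate over the two flanks of a candidate, excluding
# every candidate interval (not just the focal one).
.local_background <- function(m, b0, s, e, flank, cand) {
  lo <- max(s - flank, b0[1L])
  hi <- min(e + flank, b0[length(b0)])
  segs_s <- c(lo, e)
  segs_e <- c(s, hi)
  # subtract candidate intervals from the flank segments
  keep_s <- numeric(0); keep_e <- numeric(0)
  for (i in seq_along(segs_s)) {
    cur_s <- segs_s[i]; cur_e <- segs_e[i]
    if (cur_e <= cur_s) next
    ov <- which(cand$start < cur_e & cand$end > cur_s)
    pts_s <- cur_s; pts_e <- cur_e
    if (length(ov)) {
      cuts <- sort(unique(c(cur_s, cur_e,
                            pmax(cand$start[ov], cur_s),
                            pmin(cand$end[ov], cur_e))))
      pts_s <- cuts[-length(cuts)]; pts_e <- cuts[-1L]
      mid <- (pts_s + pts_e) / 2
      inside <- vapply(mid, function(x)
        any(cand$start <= x & cand$end > x), logical(1))
      pts_s <- pts_s[!inside]; pts_e <- pts_e[!inside]
    }
    keep_s <- c(keep_s, pts_s); keep_e <- c(keep_e, pts_e)
  }
  if (length(keep_s) == 0L) return(NA_real_)
  # collect map pieces covered by the kept flank segments
  rates <- numeric(0); wts <- numeric(0)
  nr <- length(m$rates)
  for (i in seq_along(keep_s)) {
    i1 <- pmin(pmax(findInterval(keep_s[i], b0, rightmost.closed = TRUE), 1L), nr)
    i2 <- pmin(pmax(findInterval(keep_e[i], b0, left.open = TRUE,
                                 rightmost.closed = TRUE), 1L), nr)
    idx <- i1:i2
    piece_s <- pmax(b0[idx], keep_s[i])
    piece_e <- pmin(b0[idx + 1L], keep_e[i])
    ok <- piece_e > piece_s
    rates <- c(rates, m$rates[idx][ok])
    wts <- c(wts, (piece_e - piece_s)[ok])
  }
  .weighted_median(rates, wts)
}

#' Classify hotspots by peak-rate strength
#'
#' Partitions hotspots into weak / intermediate / strong classes at two
#' ascending peak-rate cutpoints. By default the cutpoints are the
#' empirical tertiles of the observed peak rates. A peak rate at or below
#' the lower cutpoint is weak; above the upper cutpoint, strong. When all
#' peaks are equal, the tertiles coincide and every hotspot falls in the
#' lowest ("weak") class — the documented tie-break.
#'
#' @param hotspots a hotspot data.frame from [call_hotspots()].
#' @param cutpoints numeric length-2 ascending vector, or `NULL` for
#'   empirical tertiles.
#' @return `hotspots` with the `strength_class` column filled.
#' @export
classify_strength <- function(hotspots, cutpoints = NULL) {
  hs <- as.data.frame(hotspots)
  if (nrow(hs) == 0L) return(hotspots)
  if (is.null(cutpoints))
    cutpoints <- unname(quantile(hs$peak_rate, c(1, 2) / 3))
  if (length(cutpoints) != 2L || diff(cutpoints) < 0)
    stop("cutpoints must be two ascending values")
  cls <- ifelse(hs$peak_rate <= cutpoints[1L], "weak",
                ifelse(hs$peak_rate <= cutpoints[2L], "intermediate",
                       "strong"))
  hotspots$strength_class <- cls
  hotspots
}

#' Lorenz curve and Gini coefficient of recombination concentration
#'
#' Sorts all map intervals by rate (descending) and accumulates the
#' physical fraction of the genome against the genetic (cM) fraction, so
#' the curve shows how much of the total recombination is packed into how
#' little sequence. A uniform map gives the diagonal (Gini 0); complete
#' concentration approaches Gini 1.
#'
#' @param map a [genetic_map()].
#' @return a list with `points` (data.frame `genome_frac`, `map_frac`,
#'   starting at (0,0) and ending at (1,1)) and `gini`.
#' @export
lorenz_curve <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  rates <- unlist(lapply(map, `[[`, "rates"), use.names = FALSE)
  widths <- unlist(lapply(map, function(m) diff(m$boundaries)),
                   use.names = FALSE)
  total_cm <- sum(rates * widths)
  if (total_cm <= 0) stop("Lorenz curve undefined for a zero-length map")
  o <- order(rates, decreasing = TRUE)
  x <- cumsum(widths[o]) / sum(widths)
  y <- cumsum(rates[o] * widths[o]) / total_cm
  x <- c(0, x); y <- c(0, y)
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(points = data.frame(genome_frac = x, map_frac = y),
       gini = 2 * auc - 1)
}
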