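# Internal numeric helpers shared across modules.

# Round to nearest integer, halves away from zero (reported percentages).
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Weighted median: smallest x whose cumulative weight reaches half the total.
.weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

# Merge possibly-overlapping numeric intervals (0-based half-open) on one
# chromosome; returns a list with sorted, disjoint start/end vectors.
.merge_numeric_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1L) {
    for (i in 2L:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# Count how many of the a-intervals overlap (>= 1 bp) a merged, sorted set of
# b-intervals. All coordinates 0-based half-open. b must come from
# .merge_numeric_intervals(). Used in randomization hot loops where building
# GRanges per iteration would dominate.
.count_overlapping <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L || length(b_start) == 0L) return(0L)
  idx <- findInterval(a_start, b_start)
  hit <- (idx >= 1L & b_end[pmax(idx, 1L)] > a_start) |
    (idx < length(b_start) & b_start[pmin(idx + 1L, length(b_start))] < a_end)
  sum(hit)
}

# Which a-intervals overlap any b-interval (per-chromosome wrapper).
.overlaps_any_df <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (length(bi) == 0L) next
    m <- .merge_numeric_intervals(b$start[bi], b$end[bi])
    idx <- findInterval(a$start[ai], m$start)
    n <- length(m$start)
    out[ai] <- (idx >= 1L & m$end[pmax(idx, 1L)] > a$start[ai]) |
      (idx < n & m$start[pmin(idx + 1L, n)] < a$end[ai])
  }
  out
}
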