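#' Interval-overlap randomization test
#'
#' Tests whether the number of `setA` intervals overlapping `setB` exceeds
#' what uniform placement would produce. Each randomization repositions
#' every `setA` interval uniformly within its own chromosome, preserving
#' interval widths and per-chromosome counts (intervals never move between
#' chromosomes). The empirical p-value uses the add-one convention
#' `p = (1 + #\{rand >= observed\}) / (n_rand + 1)`, which is valid (never
#' anti-conservative) for any number of randomizations.
#'
#' With `method = "exhaustive"` and a single interval in `setA`, all
#' integer placements on its chromosome are enumerated and the exact
#' placement p-value `P(overlap >= observed)` is returned (used as the
#' small-case oracle).
#'
#' @param setA,setB interval sets (0-based half-open).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_rand number of randomizations (ignored for exhaustive).
#' @param seed optional integer seed.
#' @param method `"randomize"` (default) or `"exhaustive"`.
#' @return list with `observed` (count of setA intervals overlapping any
#'   setB interval), `p`, `n_rand`, and `null_counts` (randomized counts;
#'   `NULL` for exhaustive).
#' @export
overlap_randomization_test <- function(setA, setB, chrom_lengths,
                                       n_rand = 10000, seed = NULL,
                                       method = c("randomize", "exhaustive")) {
  method <- match.arg(method)
  a <- .as_intervals(setA, "setA")
  b <- .as_intervals(setB, "setB")
  if (!is.null(seed)) set.seed(seed)
  if (n_rand < 1) stop("n_rand must be >= 1")
  for (ch in unique(a$chrom)) {
    L <- chrom_lengths[[ch]]
    if (is.null(L) || is.na(L)) stop("missing chromosome length: ", ch)
    if (any(a$end[a$chrom == ch] - a$start[a$chrom == ch] > L))
      stop("interval wider than its chromosome: ", ch)
  }
  # merged setB per chromosome, for fast overlap counting
  bm <- lapply(split(b, b$chrom),
               function(d) .merge_numeric_intervals(d$start, d$end))
  count_obs <- function(starts, ends, chroms) {
    tot <- 0L
    for (ch in unique(chroms)) {
      i <- chroms == ch
      m <- bm[[ch]]
      if (is.null(m)) next
      tot <- tot + .count_overlapping(starts[i], ends[i], m$start, m$end)
    }
    tot
  }
  observed <- count_obs(a$start, a$end, a$chrom)
  if (nrow(a) == 0L) return(list(observed = 0L, p = 1, n_rand = n_rand,
                                 null_counts = NULL))
  if (method == "exhaustive") {
    if (nrow(a) != 1L)
      stop("exhaustive enumeration requires a single interval in setA")
    w <- a$end - a$start
    L <- chrom_lengths[[a$chrom]]
    starts <- 0:(L - w)
    m <- bm[[a$chrom]]
    hits <- if (is.null(m)) rep(0L, length(starts)) else
      vapply(starts, function(s)
        .count_overlapping(s, s + w, m$start, m$end), integer(1))
    return(list(observed = observed, p = mean(hits >= observed),
                n_rand = length(starts), null_counts = NULL))
  }
  widths <- a$end - a$start
  by_ch <- split(seq_len(nrow(a)), a$chrom)
  null_counts <- integer(n_rand)
  for (r in seq_len(n_rand)) {
    tot <- 0L
    for (ch in names(by_ch)) {
      m <- bm[[ch]]
      if (is.null(m)) next
      i <- by_ch[[ch]]
      L <- chrom_lengths[[ch]]
      w <- widths[i]
      s <- floor(runif(length(i)) * (L - w + 1))
      tot <- tot + .count_overlapping(s, s + w, m$start, m$end)
    }
    null_counts[r] <- tot
  }
  p <- (1 + sum(null_counts >= observed)) / (n_rand + 1)
  list(observed = observed, p = p, n_rand = n_rand,
       null_counts = null_counts)
}

#' Compare two peak sets by overlap
#'
#' A peak is shared if it overlaps (>= 1 bp) any peak of the other set.
#' `shared` reports the symmetric count of overlapping pairs; the unique
#' counts and percentages are per set (relative to that set's size,
#' rounded to the nearest integer, halves away from zero).
#'
#' @param setP,setQ interval sets.
#' @return list with `n_p`, `n_q`, `shared_pairs`, `unique_p`, `unique_q`,
#'   `pct_unique_p`, `pct_unique_q`.
#' @export
compare_peak_sets <- function(setP, setQ) {
  p <- .as_intervals(setP, "setP")
  q <- .as_intervals(setQ, "setQ")
  p_hit <- .overlaps_any_df(p, q)
  q_hit <- .overlaps_any_df(q, p)
  shared_pairs <- if (nrow(p) == 0L || nrow(q) == 0L) 0L else
    length(GenomicRanges::findOverlaps(.intervals_to_gr(p),
                                       .intervals_to_gr(q)))
  unique_p <- sum(!p_hit)
  unique_q <- sum(!q_hit)
  list(n_p = nrow(p), n_q = nrow(q), shared_pairs = shared_pairs,
       unique_p = unique_p, unique_q = unique_q,
       pct_unique_p = if (nrow(p)) .round_half_up(100 * unique_p / nrow(p)) else NA,
       pct_unique_q = if (nrow(q)) .round_half_up(100 * unique_q / nrow(q)) else NA)
}

#' Confirm foreign hotspots against our calls
#'
#' A hotspot from another study is confirmed if it overlaps at least one
#' of our called hotspots.
#'
#' @param ours hotspot calls (interval data.frame).
#' @param theirs foreign hotspot interval set; must be non-empty.
#' @return list with `n_confirmed`, `n_total`, `fraction`, and
#'   `pct` (nearest percent, halves away from zero).
#' @export
confirm_hotspots <- function(ours, theirs) {
  o <- .as_intervals(ours, "ours")
  t_ <- .as_intervals(theirs, "theirs")
  if (nrow(t_) == 0L) stop("foreign hotspot set is empty")
  hit <- .overlaps_any_df(t_, o)
  n_conf <- sum(hit)
  list(n_confirmed = n_conf, n_total = nrow(t_),
       fraction = n_conf / nrow(t_),
       pct = .round_half_up(100 * n_conf / nrow(t_)))
}
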