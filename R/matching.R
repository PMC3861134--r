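#' Sequence composition summaries
#'
#' GC fraction, CpG dinucleotide fraction and N fraction of nucleotide
#' sequences. GC is computed over non-N bases; the CpG fraction divides
#' the number of CG dinucleotides by the number of non-N bases minus one
#' (the number of valid dinucleotide start positions in a gap-free
#' sequence).
#'
#' @param seqs a character vector, `DNAString` or `DNAStringSet`
#'   (case-insensitive, alphabet ACGTN).
#' @return a data.frame with columns `gc`, `cpg`, `n_fraction`, one row
#'   per sequence.
#' @examples
#' sequence_composition(c("CGCG", "ACGTN"))
#' @export
sequence_composition <- function(seqs) {
  s <- .as_dna(seqs)
  if (length(s) == 0L) stop("empty sequence list")
  if (any(Biostrings::width(s) == 0L)) stop("empty sequence")
  lf <- Biostrings::letterFrequency(s, c("A", "C", "G", "T", "N"))
  non_n <- rowSums(lf[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(non_n == 0L)) stop("sequence with no non-N bases")
  cg <- Biostrings::dinucleotideFrequency(s)[, "CG"]
  data.frame(
    gc = (lf[, "C"] + lf[, "G"]) / non_n,
    cpg = ifelse(non_n >= 2L, cg / (non_n - 1L), NA_real_),
    n_fraction = lf[, "N"] / Biostrings::width(s))
}

.as_dna <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Extract interval sequences from a genome
#'
#' @param genome a named `DNAStringSet` (names are chromosomes).
#' @param intervals interval set (0-based half-open).
#' @return `DNAStringSet` of interval sequences, in input order.
#' @export
interval_sequences <- function(genome, intervals) {
  df <- .as_intervals(intervals)
  if (nrow(df) == 0L) return(Biostrings::DNAStringSet())
  bad <- !(df$chrom %in% names(genome))
  if (any(bad)) stop("chromosome absent from genome: ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(df$end > lens[df$chrom] | df$start < 0))
    stop("interval outside genome bounds")
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(df)), function(i)
    as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                    start = df$start[i] + 1,
                                    end = df$end[i])),
    character(1)))
  names(out) <- sprintf("%s:%.0f-%.0f", df$chrom, df$start, df$end)
  out
}

#' Filter hotspots by missing-sequence content
#'
#' Retains hotspots whose sequence has an N fraction at most `max_missing`
#' (default 0, i.e. no missing data).
#'
#' @param hotspots hotspot data.frame.
#' @param genome named `DNAStringSet`.
#' @param max_missing maximum tolerated N fraction.
#' @return the retained subset of `hotspots`.
#' @export
select_candidates <- function(hotspots, genome, max_missing = 0) {
  hs <- .as_intervals(hotspots, "hotspots")
  if (nrow(hs) == 0L) return(hotspots)
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(!(hs$chrom %in% names(genome))) ||
      any(hs$end > lens[hs$chrom]) || any(hs$start < 0))
    stop("hotspot outside genome bounds")
  comp <- .window_composition(genome, hs)
  hotspots[comp$n_fraction <= max_missing, , drop = FALSE]
}

# Vectorized composition of many windows of a single genome, using Views to
# avoid copying sequence. Returns gc, cpg, n_fraction, snippets aligned to df.
.window_composition <- function(genome, df) {
  gc <- cpg <- nf <- rep(NA_real_, nrow(df))
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = df$start[i] + 1,
                           end = df$end[i])
    lf <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    non_n <- rowSums(lf[, 1:4, drop = FALSE])
    cg <- Biostrings::dinucleotideFrequency(v)[, "CG"]
    gc[i] <- ifelse(non_n > 0, (lf[, "C"] + lf[, "G"]) / non_n, NA)
    cpg[i] <- ifelse(non_n >= 2, cg / (non_n - 1), NA)
    nf[i] <- lf[, "N"] / (df$end[i] - df$start[i])
  }
  data.frame(gc = gc, cpg = cpg, n_fraction = nf)
}

#' Match recombination coldspots to hotspots
#'
#' For each hotspot (processed in descending peak-rate order so the
#' strongest hotspots match first), candidate coldspots are same-width,
#' non-overlapping windows tiling the hotspot's chromosome. A window is
#' eligible if it (i) overlaps no called hotspot and no previously
#' assigned coldspot, (ii) shows no local rate elevation — its maximum map
#' rate is at most `elevation_fold` times the chromosome's length-weighted
#' median, (iii) has N fraction at most `max_missing`, and (iv) matches
#' the hotspot's composition to within `gc_tol` percentage points of GC
#' and `cpg_tol` points of CpG. Among eligible windows the one minimizing
#' the absolute SNP-density difference wins; ties break to the leftmost
#' window. Hotspots with no eligible window are reported unmatched.
#'
#' @param hotspots hotspot data.frame (needs `peak_rate` for ordering; if
#'   absent, input order is used).
#' @param map a [genetic_map()].
#' @param genome named `DNAStringSet`.
#' @param snps optional data.frame with `chrom`, `pos` (1-based bp) used
#'   for SNP densities; with `NULL`, densities are zero everywhere and the
#'   tie-break degenerates to leftmost.
#' @param gc_tol,cpg_tol composition tolerances in percentage points.
#' @param elevation_fold "no rate elevation" cutoff relative to the
#'   chromosome median rate.
#' @param max_missing maximum window N fraction.
#' @return a `data.frame` of class `matched_pairs`, one row per matched
#'   hotspot, with hotspot and coldspot coordinates, `delta_gc`,
#'   `delta_cpg` (percentage points) and `delta_snp_density` (per kb).
#'   The number of unmatched hotspots is attached as attribute
#'   `n_unmatched`.
#' @export
match_coldspots <- function(hotspots, map, genome, snps = NULL,
                            gc_tol = 0.5, cpg_tol = 0.1,
                            elevation_fold = 2, max_missing = 0) {
  hs <- .as_intervals(hotspots, "hotspots")
  if (nrow(hs) == 0L) stop("no hotspots to match")
  ord <- if ("peak_rate" %in% names(hs))
    order(hs$peak_rate, decreasing = TRUE) else seq_len(nrow(hs))
  hs_comp <- .window_composition(genome, hs)
  snp_pos <- if (is.null(snps)) NULL else
    split(as.numeric(snps$pos), as.character(snps$chrom))
  chrom_median <- vapply(setNames(names(map), names(map)), function(ch)
    .weighted_median(map[[ch]]$rates, diff(map[[ch]]$boundaries)),
    numeric(1))
  lens <- setNames(Biostrings::width(genome), names(genome))
  used_s <- list()   # per-chrom assigned coldspot starts/ends
  used_e <- list()
  rows <- list()
  n_unmatched <- 0L
  for (j in ord) {
    ch <- hs$chrom[j]
    w <- hs$end[j] - hs$start[j]
    L <- lens[[ch]]
    if (is.null(map[[ch]]) || w > L) { n_unmatched <- n_unmatched + 1L; next }
    starts <- seq(0, L - w, by = w)
    wins <- data.frame(chrom = ch, start = starts, end = starts + w)
    # (i) exclude windows touching any hotspot
    ok <- !.overlaps_any_df(wins, hs)
    # ... or any already-assigned coldspot
    if (length(used_s[[ch]])) {
      prev <- data.frame(chrom = ch, start = used_s[[ch]], end = used_e[[ch]])
      ok <- ok & !.overlaps_any_df(wins, prev)
    }
    # (ii) no local rate elevation
    mx <- .gm_max_rate(map[[ch]], wins$start, wins$end)
    ok <- ok & mx <= elevation_fold * chrom_median[[ch]]
    if (!any(ok)) { n_unmatched <- n_unmatched + 1L; next }
    wins <- wins[ok, , drop = FALSE]
    comp <- .window_composition(genome, wins)
    # (iii) missing data, (iv) composition tolerances (percentage points)
    d_gc <- 100 * (comp$gc - hs_comp$gc[j])
    d_cpg <- 100 * (comp$cpg - hs_comp$cpg[j])
    ok2 <- comp$n_fraction <= max_missing &
      !is.na(d_gc) & abs(d_gc) <= gc_tol &
      !is.na(d_cpg) & abs(d_cpg) <= cpg_tol
    if (!any(ok2)) { n_unmatched <- n_unmatched + 1L; next }
    wins <- wins[ok2, , drop = FALSE]
    d_gc <- d_gc[ok2]; d_cpg <- d_cpg[ok2]
    counts <- function(s, e) {
      p <- snp_pos[[ch]]
      if (is.null(p)) return(rep(0L, length(s)))
      vapply(seq_along(s), function(k)
        sum(p > s[k] & p <= e[k]), integer(1))
    }
    # all candidates share the hotspot's width, so the density argmin is
    # decided on the integer count scale (exact ties, no float noise)
    d_count <- counts(wins$start, wins$end) -
      counts(hs$start[j], hs$end[j])
    d_dens <- d_count / (w / 1000)
    # argmin of |delta density|, ties to leftmost genomic coordinate
    best <- which(abs(d_count) == min(abs(d_count)))
    best <- best[which.min(wins$start[best])]
    used_s[[ch]] <- c(used_s[[ch]], wins$start[best])
    used_e[[ch]] <- c(used_e[[ch]], wins$end[best])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch,
      hotspot_start = hs$start[j], hotspot_end = hs$end[j],
      coldspot_start = wins$start[best], coldspot_end = wins$end[best],
      delta_gc = d_gc[best], delta_cpg = d_cpg[best],
      delta_snp_density = d_dens[best],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), hotspot_start = numeric(0),
               hotspot_end = numeric(0), coldspot_start = numeric(0),
               coldspot_end = numeric(0), delta_gc = numeric(0),
               delta_cpg = numeric(0), delta_snp_density = numeric(0))
  attr(out, "n_unmatched") <- n_unmatched
  class(out) <- c("matched_pairs", "data.frame")
  out
}
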