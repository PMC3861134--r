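#' Feature-centred recombination-rate profile
#'
#' For each anchor (a point such as a TSS, or the midpoint of an
#' interval), evaluates the mean map rate in signed distance bins spanning
#' `[-half_span, half_span)` and averages across anchors. With
#' `orient_by_strand = TRUE`, minus-strand anchors are flipped so that
#' negative distances always mean "upstream".
#'
#' Anchors whose window falls entirely outside the mapped extent are
#' skipped with a warning; partially covered bins use the covered part.
#'
#' @param map a [genetic_map()].
#' @param anchors interval set; single-bp intervals are treated as points,
#'   wider ones contribute their midpoint.
#' @param half_span profile half-width in bp.
#' @param bin_width bin width in bp.
#' @param orient_by_strand flip minus-strand anchors?
#' @return a `data.frame` of class `rate_profile` with `bin_lo`, `bin_hi`
#'   (signed bp relative to the anchor), `mean_rate` (cM/Mb) and `n`
#'   (anchors contributing).
#' @export
profile_around <- function(map, anchors, half_span = 25000,
                           bin_width = 1000, orient_by_strand = FALSE) {
  stopifnot(inherits(map, "genetic_map"))
  an <- .as_intervals(anchors, "anchors")
  if (nrow(an) == 0L) stop("no anchors")
  # width-1 intervals are point anchors (a TSS); wider ones use midpoints
  pos <- ifelse(an$end - an$start <= 1, an$start, (an$start + an$end) / 2)
  flip <- if (orient_by_strand && "strand" %in% names(an))
    an$strand == "-" else rep(FALSE, nrow(an))
  edges <- seq(-half_span, half_span, by = bin_width)
  n_bins <- length(edges) - 1L
  sums <- numeric(n_bins)
  cnts <- integer(n_bins)
  skipped <- 0L
  for (i in seq_len(nrow(an))) {
    ch <- an$chrom[i]
    if (is.null(map[[ch]])) { skipped <- skipped + 1L; next }
    lo <- pos[i] + if (flip[i]) -edges[-1L] else edges[-length(edges)]
    hi <- pos[i] + if (flip[i]) -edges[-length(edges)] else edges[-1L]
    r <- mean_rate(map, ch, lo, hi)
    if (all(is.na(r))) { skipped <- skipped + 1L; next }
    ok <- !is.na(r)
    sums[ok] <- sums[ok] + r[ok]
    cnts[ok] <- cnts[ok] + 1L
  }
  if (skipped > 0L)
    warning(skipped, " anchor(s) outside the mapped extent were skipped")
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    mean_rate = ifelse(cnts > 0L, sums / pmax(cnts, 1L), NA),
                    n = cnts)
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Partition anchors by distance to the nearest reference interval
#'
#' Labels each anchor by the distance (bp) to its nearest reference
#' interval: overlapping anchors get distance 0 and the first group;
#' otherwise the gap distance is cut at the ascending `edges`; anchors
#' beyond the last edge fall into the final "none within `max(edges)`"
#' group. An empty reference set places every anchor in that final group.
#'
#' @param anchors,references interval sets.
#' @param edges ascending distance cutoffs in bp.
#' @return factor of group labels, one per anchor, with levels
#'   `"overlap"`, `"(0,e1]"`, ..., `"none within <max>"`. Distances are
#'   attached as attribute `distance`.
#' @export
partition_by_distance <- function(anchors, references,
                                  edges = c(2000, 5000, 10000)) {
  an <- .as_intervals(anchors, "anchors")
  rf <- .as_intervals(references, "references")
  if (any(diff(edges) <= 0)) stop("edges must be strictly ascending")
  labs <- c("overlap",
            sprintf("(%s,%s]", c(0, edges[-length(edges)]), edges),
            sprintf("none within %s", edges[length(edges)]))
  if (nrow(rf) == 0L) {
    f <- factor(rep(labs[length(labs)], nrow(an)), levels = labs)
    attr(f, "distance") <- rep(Inf, nrow(an))
    return(f)
  }
  gr_a <- .intervals_to_gr(an)
  gr_r <- .intervals_to_gr(rf)
  d <- rep(Inf, nrow(an))
  nn <- GenomicRanges::distanceToNearest(gr_a, gr_r)
  d[S4Vectors::queryHits(nn)] <- S4Vectors::mcols(nn)$distance
  ov <- .overlaps_any_df(an, rf)
  grp <- ifelse(ov, 1L,
                ifelse(is.infinite(d) | d > edges[length(edges)],
                       length(labs),
                       findInterval(d, c(0, edges), left.open = TRUE) + 1L))
  f <- factor(labs[grp], levels = labs)
  attr(f, "distance") <- ifelse(ov, 0, d)
  f
}

#' Hotspot-to-TSS distance summary
#'
#' Distance is 0 when a TSS lies within the hotspot, otherwise the gap to
#' the nearest TSS.
#'
#' @param hotspots hotspot data.frame.
#' @param tss TSS interval set (single-bp intervals); must be non-empty.
#' @param far_threshold distance (bp) beyond which a hotspot counts as
#'   "far" (default 100 kb).
#' @return list with `fraction_overlapping`, `median_distance`,
#'   `fraction_beyond` (beyond `far_threshold`), and the per-hotspot
#'   `distances`.
#' @export
hotspot_tss_distances <- function(hotspots, tss, far_threshold = 1e5) {
  hs <- .as_intervals(hotspots, "hotspots")
  ts <- .as_intervals(tss, "tss")
  if (nrow(ts) == 0L) stop("empty TSS set")
  gr_h <- .intervals_to_gr(hs)
  gr_t <- .intervals_to_gr(ts)
  d <- rep(Inf, nrow(hs))
  nn <- GenomicRanges::distanceToNearest(gr_h, gr_t)
  d[S4Vectors::queryHits(nn)] <- S4Vectors::mcols(nn)$distance
  ov <- .overlaps_any_df(hs, ts)
  d[ov] <- 0
  list(fraction_overlapping = mean(ov),
       median_distance = median(d),
       fraction_beyond = mean(d > far_threshold),
       distances = d)
}

#' Windowed rate/composition tables and correlations
#'
#' Tiles each chromosome with non-overlapping windows of each requested
#' size, computes the mean recombination rate, GC fraction and CpG
#' fraction per window, and reports Pearson correlations of rate against
#' GC and against CpG at each scale. Windows without mapped rate are
#' dropped; a zero-variance column yields an `NA` correlation with a
#' warning.
#'
#' @param map a [genetic_map()].
#' @param genome named `DNAStringSet`.
#' @param window_sizes numeric vector of window sizes in bp.
#' @return named list (one element per scale) with `table` (the window
#'   data.frame) and `r_gc`, `r_cpg`.
#' @export
windowed_correlation <- function(map, genome,
                                 window_sizes = c(1e4, 1e5, 1e6)) {
  stopifnot(inherits(map, "genetic_map"))
  out <- list()
  for (w in window_sizes) {
    tabs <- list()
    for (ch in intersect(names(genome), names(map))) {
      L <- length(genome[[ch]])
      n_win <- floor(L / w)
      if (n_win < 1L) next
      starts <- (seq_len(n_win) - 1L) * w
      df <- data.frame(chrom = ch, start = starts, end = starts + w)
      comp <- .window_composition(genome, df)
      df$rate <- mean_rate(map, ch, df$start, df$end)
      df$gc <- comp$gc
      df$cpg <- comp$cpg
      tabs[[ch]] <- df
    }
    tab <- do.call(rbind, tabs)
    tab <- tab[!is.na(tab$rate), , drop = FALSE]
    if (is.null(tab) || nrow(tab) < 3L)
      stop("fewer than 3 windows at scale ", w)
    r_gc <- .safe_cor(tab$rate, tab$gc)
    r_cpg <- .safe_cor(tab$rate, tab$cpg)
    out[[format(w, scientific = FALSE)]] <-
      list(window_size = w, table = tab, r_gc = r_gc, r_cpg = r_cpg)
  }
  out
}

.safe_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  # tolerance-based: cumulative-integral rate tracks carry ~1e-16 noise
  degenerate <- function(v) stats::sd(v) <= 1e-10 * (abs(mean(v)) + 1)
  if (degenerate(x[ok]) || degenerate(y[ok])) {
    warning("zero-variance column; correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])
}

#' Multiple regression of rate on composition
#'
#' Ordinary least squares of the window rate on standardized GC and CpG
#' fractions (optionally gene density), to check the sign pattern of the
#' two predictors once both enter jointly.
#'
#' @param table a window data.frame with columns `rate`, `gc`, `cpg` and
#'   optionally `gene_density`.
#' @param include_gene_density add the gene-density predictor?
#' @return data.frame with one row per predictor: `estimate`, `sign`,
#'   `ci_lo`, `ci_hi` (95%).
#' @export
composition_regression <- function(table, include_gene_density = FALSE) {
  tab <- as.data.frame(table)
  preds <- c("gc", "cpg", if (include_gene_density) "gene_density")
  if (!all(c("rate", preds) %in% names(tab)))
    stop("table must have columns rate, ", paste(preds, collapse = ", "))
  tab <- tab[complete.cases(tab[, c("rate", preds)]), , drop = FALSE]
  if (nrow(tab) < length(preds) + 2L)
    stop("need at least ", length(preds) + 2L, " windows")
  X <- scale(as.matrix(tab[, preds, drop = FALSE]))
  cc <- cor(X)
  if (any(abs(cc[upper.tri(cc)]) > 0.999))
    stop("collinear predictors (|r| > 0.999)")
  fit <- lm(tab$rate ~ X)
  est <- coef(fit)[-1L]
  ci <- suppressMessages(confint(fit))[-1L, , drop = FALSE]
  data.frame(predictor = preds, estimate = unname(est),
             sign = ifelse(est > 0, "+", "-"),
             ci_lo = unname(ci[, 1L]), ci_hi = unname(ci[, 2L]),
             stringsAsFactors = FALSE)
}

#' Compare flanking sequence composition between two interval sets
#'
#' For every interval, computes the CpG (or GC) fraction of its two
#' flanks of `flank` bp (clipped to the chromosome, with a warning), then
#' compares the two sets of per-interval flanking fractions with a
#' two-sample Wilcoxon rank-sum test.
#'
#' @param setA,setB interval sets.
#' @param genome named `DNAStringSet`.
#' @param flank flank length in bp (default 50 kb).
#' @param measure `"cpg"` or `"gc"`.
#' @return list with `mean_a`, `mean_b`, `p`, and the per-interval
#'   vectors `values_a`, `values_b`.
#' @export
flanking_composition_compare <- function(setA, setB, genome, flank = 5e4,
                                         measure = c("cpg", "gc")) {
  measure <- match.arg(measure)
  val <- function(set) {
    df <- .as_intervals(set)
    lens <- setNames(Biostrings::width(genome), names(genome))
    truncated <- FALSE
    v <- vapply(seq_len(nrow(df)), function(i) {
      L <- lens[[df$chrom[i]]]
      ls <- max(df$start[i] - flank, 0); le <- df$start[i]
      rs <- df$end[i]; re <- min(df$end[i] + flank, L)
      if (ls > df$start[i] - flank + 1e-9 || re < df$end[i] + flank - 1e-9)
        truncated <<- TRUE
      segs <- data.frame(chrom = df$chrom[i],
                         start = c(ls, rs), end = c(le, re))
      segs <- segs[segs$end > segs$start, , drop = FALSE]
      if (nrow(segs) == 0L) return(NA_real_)
      comp <- .window_composition(genome, segs)
      wts <- segs$end - segs$start
      sum(comp[[measure]] * wts, na.rm = TRUE) / sum(wts)
    }, numeric(1))
    if (truncated) warning("flank truncated at chromosome end")
    v
  }
  va <- suppressWarnings(val(setA))
  vb <- suppressWarnings(val(setB))
  p <- suppressWarnings(wilcox.test(va, vb)$p.value)
  list(mean_a = mean(va, na.rm = TRUE), mean_b = mean(vb, na.rm = TRUE),
       p = p, values_a = va, values_b = vb)
}

#' Gene-body recombination profile on proportional bins
#'
#' Rescales every gene to `n_bins` equally spaced proportional bins
#' (orientation-aware: bin 1 is the 5' end) and averages the map rate per
#' bin across genes, so genes of different lengths are comparable.
#'
#' @param map a [genetic_map()].
#' @param genes interval set with optional `strand`.
#' @param n_bins number of proportional bins (default 50).
#' @return data.frame with `bin` (1..n_bins), `mean_rate`, `n`.
#' @export
gene_body_profile <- function(map, genes, n_bins = 50) {
  gn <- .as_intervals(genes, "genes")
  if (nrow(gn) == 0L) stop("no genes")
  sums <- numeric(n_bins); cnts <- integer(n_bins)
  for (i in seq_len(nrow(gn))) {
    ch <- gn$chrom[i]
    if (is.null(map[[ch]])) next
    edges <- seq(gn$start[i], gn$end[i], length.out = n_bins + 1L)
    r <- mean_rate(map, ch, edges[-length(edges)], edges[-1L])
    if ("strand" %in% names(gn) && identical(gn$strand[i], "-"))
      r <- rev(r)
    ok <- !is.na(r)
    sums[ok] <- sums[ok] + r[ok]
    cnts[ok] <- cnts[ok] + 1L
  }
  data.frame(bin = seq_len(n_bins),
             mean_rate = ifelse(cnts > 0, sums / pmax(cnts, 1L), NA),
             n = cnts)
}
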