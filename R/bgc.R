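#' Polarize biallelic polymorphisms against an outgroup
#'
#' Applies the parsimony rule: if the outgroup allele equals exactly one
#' of the two ingroup alleles, that allele is called ancestral and the
#' other derived; otherwise the site is rejected (no high-confidence
#' polarity). Mutation classes follow the weak/strong dichotomy
#' (W = A/T, S = C/G): `AT_GC` for W ancestral, S derived; `GC_AT` for the
#' reverse; `neutral` for W-to-W or S-to-S changes.
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based bp), `a1`,
#'   `a2` (the two ingroup alleles), `outgroup` (outgroup allele), and
#'   optionally `left`, `right` (immediate flanking reference bases, used
#'   by [flag_cpg_creating()]).
#' @return the input data.frame with added columns `ancestral`,
#'   `derived`, `mutation_class`, `creates_cpg` (NA when flanks are
#'   missing or uninformative) and `reject_reason` (`NA` for accepted
#'   sites). Use `subset(x, is.na(reject_reason))` for the accepted set.
#' @examples
#' polarize(data.frame(chrom = "chr1", pos = 100,
#'                     a1 = "A", a2 = "G", outgroup = "A"))
#' @export
polarize <- function(snps) {
  df <- as.data.frame(snps)
  need <- c("chrom", "pos", "a1", "a2", "outgroup")
  if (!all(need %in% names(df)))
    stop("snps must have columns chrom, pos, a1, a2, outgroup")
  a1 <- toupper(as.character(df$a1))
  a2 <- toupper(as.character(df$a2))
  og <- toupper(as.character(df$outgroup))
  reason <- rep(NA_character_, nrow(df))
  bad_allele <- !(a1 %in% c("A", "C", "G", "T")) |
    !(a2 %in% c("A", "C", "G", "T")) | a1 == a2
  reason[bad_allele] <- "invalid ingroup alleles"
  no_og <- is.na(reason) & !(og %in% c("A", "C", "G", "T"))
  reason[no_og] <- "outgroup allele missing"
  m1 <- og == a1
  m2 <- og == a2
  none <- is.na(reason) & !m1 & !m2
  reason[none] <- "no shared allele"
  anc <- ifelse(m1, a1, ifelse(m2, a2, NA))
  der <- ifelse(m1, a2, ifelse(m2, a1, NA))
  anc[!is.na(reason)] <- NA
  der[!is.na(reason)] <- NA
  W <- c("A", "T")
  cls <- rep(NA_character_, nrow(df))
  ok <- is.na(reason)
  cls[ok] <- ifelse(anc[ok] %in% W & !(der[ok] %in% W), "AT_GC",
                    ifelse(!(anc[ok] %in% W) & der[ok] %in% W, "GC_AT",
                           "neutral"))
  df$ancestral <- anc
  df$derived <- der
  df$mutation_class <- cls
  df$creates_cpg <- if (all(c("left", "right") %in% names(df)))
    flag_cpg_creating(a1, a2, df$left, df$right) else NA
  df$reject_reason <- reason
  df
}

#' Flag polymorphisms where either allele would create a CpG
#'
#' A site is CpG-creating if the left flanking base is C and either allele
#' is G (forming CpG), or the right flanking base is G and either allele
#' is C. Sites with N (or missing) flanks are flagged `NA` so they can be
#' excluded conservatively.
#'
#' @param a1,a2 allele vectors.
#' @param left,right immediate flanking bases.
#' @return logical vector (with `NA` for undeterminable sites).
#' @examples
#' flag_cpg_creating("A", "G", left = "C", right = "T")  # TRUE
#' @export
flag_cpg_creating <- function(a1, a2, left, right) {
  a1 <- toupper(as.character(a1)); a2 <- toupper(as.character(a2))
  left <- toupper(as.character(left)); right <- toupper(as.character(right))
  ok <- left %in% c("A", "C", "G", "T") & right %in% c("A", "C", "G", "T")
  flag <- (left == "C" & (a1 == "G" | a2 == "G")) |
    (right == "G" & (a1 == "C" | a2 == "C"))
  flag[!ok] <- NA
  flag
}

# Assign each SNP to the nearest hotspot center on its chromosome.
# Returns data.frame(snp_row, hotspot, distance).
.nearest_center <- function(snp_chrom, snp_pos, hs) {
  centers <- (hs$start + hs$end) / 2
  out_h <- rep(NA_integer_, length(snp_pos))
  out_d <- rep(NA_real_, length(snp_pos))
  for (ch in unique(snp_chrom)) {
    hi <- which(hs$chrom == ch)
    if (length(hi) == 0L) next
    o <- hi[order(centers[hi])]
    cs <- centers[o]
    si <- which(snp_chrom == ch)
    p <- snp_pos[si] - 1  # continuous 0-based, to match interval coords
    idx <- findInterval(p, cs)
    lo <- pmax(idx, 1L)
    hi2 <- pmin(idx + 1L, length(cs))
    d_lo <- abs(p - cs[lo])
    d_hi <- abs(p - cs[hi2])
    pick <- ifelse(idx < 1L, hi2, ifelse(idx >= length(cs), lo,
                                         ifelse(d_lo <= d_hi, lo, hi2)))
    out_h[si] <- o[pick]
    out_d[si] <- abs(p - cs[pick])
  }
  data.frame(hotspot = out_h, distance = out_d)
}

#' BGC skew profile around hotspots
#'
#' Bins polarized polymorphisms by distance from the nearest hotspot
#' center and computes, per bin, the ratio of AT->GC to GC->AT derived
#' counts — the biased-gene-conversion skew statistic. Confidence bands
#' come from a bootstrap whose resampling unit is the hotspot: each
#' resample redraws hotspots with replacement together with their
#' attached SNPs, preserving within-hotspot correlation.
#'
#' Only hotspots no wider than `max_hotspot_width` are used (the skew
#' signal is only interpretable for well-localized peaks); set it to
#' `Inf` to disable the filter.
#'
#' @param snps polarized SNP data.frame (from [polarize()]); rows with a
#'   non-`NA` `reject_reason` or a `neutral` class are ignored.
#' @param hotspots hotspot data.frame.
#' @param bin_width bin width in bp (default 1000).
#' @param max_dist maximum distance from a hotspot center (default
#'   25000); more distant SNPs are dropped.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed optional integer seed for the bootstrap.
#' @param exclude_cpg drop SNPs whose `creates_cpg` flag is `TRUE` or
#'   `NA` (conservative CpG exclusion)?
#' @param max_hotspot_width localization filter in bp (default 5000).
#' @param boot `"hotspot"` (random resampling) or `"exhaustive"`
#'   (enumerate all resamples; only feasible for a handful of hotspots,
#'   used as a small-case oracle).
#' @return a `data.frame` of class `skew_profile` with columns `bin_lo`,
#'   `bin_hi` (bp), `n_WS`, `n_SW`, `ratio` (`NA`-flagged when
#'   `n_SW` is 0), `ci_lo`, `ci_hi`. Attributes: `n_hotspots`, `n_boot`.
#' @export
skew_profile <- function(snps, hotspots, bin_width = 1000,
                         max_dist = 25000, n_boot = 200, seed = NULL,
                         exclude_cpg = FALSE, max_hotspot_width = 5000,
                         boot = c("hotspot", "exhaustive")) {
  boot <- match.arg(boot)
  hs <- .as_intervals(hotspots, "hotspots")
  hs <- hs[hs$end - hs$start <= max_hotspot_width, , drop = FALSE]
  if (nrow(hs) == 0L) stop("no hotspots pass the localization filter")
  df <- as.data.frame(snps)
  if (!"mutation_class" %in% names(df))
    stop("snps must be polarized first (missing mutation_class)")
  if ("reject_reason" %in% names(df))
    df <- df[is.na(df$reject_reason), , drop = FALSE]
  df <- df[df$mutation_class %in% c("AT_GC", "GC_AT"), , drop = FALSE]
  if (exclude_cpg) {
    if (!"creates_cpg" %in% names(df))
      stop("exclude_cpg requires a creates_cpg column")
    df <- df[!is.na(df$creates_cpg) & !df$creates_cpg, , drop = FALSE]
  }
  nn <- .nearest_center(as.character(df$chrom), as.numeric(df$pos), hs)
  keep <- !is.na(nn$hotspot) & nn$distance < max_dist
  df <- df[keep, , drop = FALSE]
  nn <- nn[keep, , drop = FALSE]
  n_bins <- ceiling(max_dist / bin_width)
  bin <- pmin(floor(nn$distance / bin_width), n_bins - 1L) + 1L
  n_hot <- nrow(hs)
  is_ws <- df$mutation_class == "AT_GC"
  # hotspot x bin count matrices, the bootstrap currency
  tab_ws <- matrix(0, nrow = n_hot, ncol = n_bins)
  tab_sw <- matrix(0, nrow = n_hot, ncol = n_bins)
  if (nrow(df)) {
    iws <- cbind(nn$hotspot[is_ws], bin[is_ws])
    isw <- cbind(nn$hotspot[!is_ws], bin[!is_ws])
    for (r in seq_len(nrow(iws)))
      tab_ws[iws[r, 1L], iws[r, 2L]] <- tab_ws[iws[r, 1L], iws[r, 2L]] + 1
    for (r in seq_len(nrow(isw)))
      tab_sw[isw[r, 1L], isw[r, 2L]] <- tab_sw[isw[r, 1L], isw[r, 2L]] + 1
  }
  n_ws <- colSums(tab_ws)
  n_sw <- colSums(tab_sw)
  ratio <- ifelse(n_sw > 0, n_ws / n_sw, NA_real_)
  if (!is.null(seed)) set.seed(seed)
  boot_ratios <- if (boot == "exhaustive") {
    if (n_hot^n_hot > 2e4)
      stop("exhaustive bootstrap infeasible for ", n_hot, " hotspots")
    combos <- as.matrix(expand.grid(rep(list(seq_len(n_hot)), n_hot)))
    br <- vapply(seq_len(nrow(combos)), function(r) {
      ix <- combos[r, ]
      ws <- colSums(tab_ws[ix, , drop = FALSE])
      sw <- colSums(tab_sw[ix, , drop = FALSE])
      ifelse(sw > 0, ws / sw, NA_real_)
    }, numeric(n_bins))
    matrix(br, ncol = n_bins, byrow = TRUE)
  } else {
    br <- vapply(seq_len(n_boot), function(b) {
      w <- tabulate(sample.int(n_hot, n_hot, replace = TRUE), n_hot)
      ws <- as.numeric(crossprod(tab_ws, w))
      sw <- as.numeric(crossprod(tab_sw, w))
      ifelse(sw > 0, ws / sw, NA_real_)
    }, numeric(n_bins))
    matrix(br, ncol = n_bins, byrow = TRUE)
  }
  ci <- apply(boot_ratios, 2L, function(x)
    if (all(is.na(x))) c(NA_real_, NA_real_) else
      quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  ci[, is.na(ratio)] <- NA_real_
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
                    bin_hi = seq_len(n_bins) * bin_width,
                    n_WS = n_ws, n_SW = n_sw, ratio = ratio,
                    ci_lo = ci[1L, ], ci_hi = ci[2L, ])
  attr(out, "n_hotspots") <- n_hot
  attr(out, "n_boot") <- nrow(boot_ratios)
  class(out) <- c("skew_profile", "data.frame")
  out
}

#' Skew profiles stratified by hotspot strength class
#'
#' Runs [skew_profile()] separately for each `strength_class` of the
#' hotspots (see [classify_strength()]), with identical binning. Empty
#' classes are omitted with a warning.
#'
#' @inheritParams skew_profile
#' @param ... further arguments passed to [skew_profile()].
#' @return named list of `skew_profile` objects, one per class present.
#' @export
stratified_skew <- function(snps, hotspots, ...) {
  hs <- as.data.frame(hotspots)
  if (!"strength_class" %in% names(hs) || all(is.na(hs$strength_class)))
    stop("hotspots must carry strength_class (see classify_strength)")
  classes <- c("weak", "intermediate", "strong")
  classes <- classes[classes %in% hs$strength_class]
  out <- list()
  for (cl in classes) {
    sub <- hs[hs$strength_class %in% cl, , drop = FALSE]
    res <- tryCatch(skew_profile(snps, sub, ...), error = function(e) e)
    if (inherits(res, "error")) {
      warning("class ", cl, " omitted: ", conditionMessage(res))
    } else {
      out[[cl]] <- res
    }
  }
  if (length(out) == 0L) warning("no class produced a profile")
  out
}

#' Read and write polarized-SNP (VCF-lite) tables
#'
#' Tab-separated with header: `chrom`, `pos` (1-based), `a1`, `a2`,
#' `outgroup`, `left`, `right`. This is the minimal information the BGC
#' statistics need; full VCF parsing is out of scope.
#'
#' @param path file path.
#' @return `read_snps()` returns a data.frame.
#' @export
read_snps <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "a1", "a2", "outgroup")
  if (!all(need %in% names(df)))
    stop("SNP TSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_snps
#' @param snps SNP data.frame.
#' @export
write_snps <- function(snps, path) {
  keep <- intersect(c("chrom", "pos", "a1", "a2", "outgroup",
                      "left", "right"), names(snps))
  write.table(as.data.frame(snps)[, keep], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
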