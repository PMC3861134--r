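#' Fraction of sequences containing a motif
#'
#' Presence/absence scan: the fraction of sequences carrying at least one
#' exact occurrence of the motif. By default the scan is single-strand on
#' the given sequences; with `double_strand = TRUE` a sequence also counts
#' if its reverse complement carries the motif.
#'
#' @param seqs character vector or `DNAStringSet`; must be non-empty.
#' @param motif a k-mer over ACGT.
#' @param double_strand scan both strands?
#' @return presence fraction in `[0, 1]`.
#' @examples
#' motif_presence(c("ACGCGCGT", "AAAA"), "CGCGCG")  # 0.5
#' @export
motif_presence <- function(seqs, motif, double_strand = FALSE) {
  s <- .as_dna(seqs)
  if (length(s) == 0L) stop("empty sequence list")
  motif <- toupper(as.character(motif))
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over A, C, G, T")
  hit <- Biostrings::vcountPattern(motif, s) > 0L
  if (double_strand) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    hit <- hit | Biostrings::vcountPattern(rc, s) > 0L
  }
  mean(hit)
}

# Two-sided Fisher exact p for the 2x2 presence table
# (a present / n1 - a absent | b present / n2 - b absent), memoized across a
# scan via an environment keyed on the counts.
.fisher_p <- function(a, b, n1, n2, memo = NULL) {
  key <- paste(a, b, n1, n2, sep = "_")
  if (!is.null(memo) && !is.null(memo[[key]])) return(memo[[key]])
  p <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), nrow = 2))$p.value
  p <- min(p, 1)
  if (!is.null(memo)) memo[[key]] <- p
  p
}

#' Fisher exact enrichment test for presence fractions
#'
#' Converts presence fractions into counts (`round(f * n)`), runs a
#' two-sided Fisher exact test on the 2x2 presence table, and applies a
#' Bonferroni correction over `m_tests` motifs.
#'
#' @param f_hot,f_cold presence fractions in hotspots and coldspots.
#' @param n_hot,n_cold numbers of hotspot and coldspot sequences.
#' @param m_tests Bonferroni denominator (number of motifs tested).
#' @param motif optional motif label carried through to the result.
#' @return one-row data.frame with `motif`, `f_hot`, `f_cold`,
#'   `enrichment` (`f_hot / f_cold`; `Inf` when `f_cold` is 0 and `f_hot`
#'   positive), `p_raw`, `p_bonferroni`.
#' @examples
#' enrichment_test(0.213, 0.132, 4759, 4759)  # enrichment 1.61
#' @export
enrichment_test <- function(f_hot, f_cold, n_hot, n_cold, m_tests = 1,
                            motif = NA_character_) {
  if (n_hot <= 0 || n_cold <= 0) stop("n_hot and n_cold must be positive")
  a <- round(f_hot * n_hot)
  b <- round(f_cold * n_cold)
  p <- .fisher_p(a, b, n_hot, n_cold)
  enr <- if (f_cold > 0) f_hot / f_cold else if (f_hot > 0) Inf else NA_real_
  data.frame(motif = motif, f_hot = f_hot, f_cold = f_cold,
             enrichment = enr, p_raw = p,
             p_bonferroni = min(1, m_tests * p),
             stringsAsFactors = FALSE)
}

# Per-sequence presence matrix for all 4^k motifs (logical, n x 4^k),
# computed in chunks to bound memory. Columns named by motif.
.presence_matrix <- function(seqs, k, double_strand = TRUE,
                             chunk = 256L) {
  n <- length(seqs)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  rcs <- if (double_strand) Biostrings::reverseComplement(seqs) else NULL
  out <- NULL
  for (i in idx) {
    m <- Biostrings::oligonucleotideFrequency(seqs[i], width = k) > 0L
    if (double_strand)
      m <- m | (Biostrings::oligonucleotideFrequency(rcs[i], width = k) > 0L)
    out <- rbind(out, m)
  }
  out
}

#' Exhaustive k-mer enrichment scan between matched sequence sets
#'
#' Tests every k-mer for k in `k_range` for presence enrichment in the
#' hotspot sequences relative to the coldspot sequences, using two-sided
#' Fisher exact tests and a Bonferroni correction whose denominator is the
#' total number of distinct motifs actually scanned. In double-strand
#' mode (the default) a sequence contains a motif if either strand
#' matches, and reverse-complement duplicates are collapsed onto the
#' lexicographically smaller k-mer before testing.
#'
#' Sequence masking (for the repeat / non-repeat partition) is the
#' caller's responsibility: hard-mask with [mask_intervals()] before
#' passing the sequences in. Masked (N) stretches never match a motif.
#'
#' @param hot_seqs,cold_seqs `DNAStringSet`s (or character vectors) of
#'   matched hotspot and coldspot sequences.
#' @param k_range integer vector of k-mer sizes (default `6:9`).
#' @param double_strand scan both strands and collapse reverse
#'   complements?
#' @param alpha Bonferroni-corrected significance threshold for
#'   reporting.
#' @param report_all return all motifs instead of the significant set?
#' @param partition label stored in the result (`"all"`, `"non-repeat"`,
#'   `"repeat"`).
#' @return data.frame of [enrichment_test()] rows (plus `k`, `partition`),
#'   sorted by raw p-value. The Bonferroni denominator is attached as
#'   attribute `m_tests`.
#' @export
scan_all_motifs <- function(hot_seqs, cold_seqs, k_range = 6:9,
                            double_strand = TRUE, alpha = 0.05,
                            report_all = FALSE, partition = "all") {
  hot <- .as_dna(hot_seqs)
  cold <- .as_dna(cold_seqs)
  if (length(hot) == 0L || length(cold) == 0L)
    stop("empty sequence set")
  n_hot <- length(hot); n_cold <- length(cold)
  per_k <- lapply(k_range, function(k) {
    ph <- colSums(.presence_matrix(hot, k, double_strand))
    pc <- colSums(.presence_matrix(cold, k, double_strand))
    motifs <- names(ph)
    if (double_strand) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(motifs)))
      keep <- motifs <= rc
      motifs <- motifs[keep]; ph <- ph[keep]; pc <- pc[keep]
    }
    data.frame(motif = motifs, k = k, count_hot = as.integer(ph),
               count_cold = as.integer(pc), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_k)
  m_tests <- nrow(tab)
  memo <- new.env(parent = emptyenv())
  tab$p_raw <- vapply(seq_len(m_tests), function(i)
    .fisher_p(tab$count_hot[i], tab$count_cold[i], n_hot, n_cold, memo),
    numeric(1))
  tab$f_hot <- tab$count_hot / n_hot
  tab$f_cold <- tab$count_cold / n_cold
  tab$enrichment <- ifelse(tab$f_cold > 0, tab$f_hot / tab$f_cold,
                           ifelse(tab$f_hot > 0, Inf, NA))
  tab$p_bonferroni <- pmin(1, m_tests * tab$p_raw)
  tab$partition <- partition
  if (!report_all) tab <- tab[tab$p_bonferroni < alpha, , drop = FALSE]
  tab <- tab[order(tab$p_raw, tab$motif), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "m_tests") <- m_tests
  tab
}

#' Hard-mask sub-intervals of extracted sequences
#'
#' Replaces the parts of each extracted interval sequence that fall inside
#' (or, with `mode = "keep"`, outside) a mask set with N. Coordinates of
#' both sets are genomic (0-based half-open); the sequences must have
#' been extracted from `intervals` in order.
#'
#' @param seqs `DNAStringSet` extracted from `intervals` (same order).
#' @param intervals the source intervals of `seqs`.
#' @param mask intervals to mask (e.g. repeats).
#' @param mode `"drop"` masks bases inside `mask` (non-repeat partition);
#'   `"keep"` masks bases outside `mask` (repeat partition).
#' @return masked `DNAStringSet`.
#' @export
mask_intervals <- function(seqs, intervals, mask, mode = c("drop", "keep")) {
  mode <- match.arg(mode)
  iv <- .as_intervals(intervals)
  mk <- .as_intervals(mask, "mask")
  stopifnot(length(seqs) == nrow(iv))
  gr_iv <- .intervals_to_gr(iv)
  gr_mk <- .intervals_to_gr(mk)
  hits <- GenomicRanges::findOverlaps(gr_iv, gr_mk)
  out <- seqs
  for (i in seq_along(seqs)) {
    w <- length(seqs[[i]])
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    loc <- IRanges::IRanges()
    if (length(j)) {
      s <- pmax(mk$start[j] - iv$start[i], 0) + 1
      e <- pmin(mk$end[j] - iv$start[i], w)
      loc <- IRanges::reduce(IRanges::IRanges(start = s, end = e))
    }
    at <- if (mode == "drop") loc else
      IRanges::setdiff(IRanges::IRanges(1, w), loc)
    if (length(at) == 0L) next
    out[[i]] <- Biostrings::replaceAt(
      seqs[[i]], at,
      Biostrings::DNAStringSet(strrep("N", IRanges::width(at))))
  }
  out
}
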