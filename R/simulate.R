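#' Simulation configuration
#'
#' Collects and validates all parameters of the synthetic world: a genome
#' with CpG-island-dense promoters, a recombination map whose hotspots
#' colocate with islands, and two diverged lineages of polymorphisms with
#' an optional W->S transmission bias (biased gene conversion) near
#' hotspot centers.
#'
#' The transmission-bias parameter `bias_b` is the probability that a
#' W/S (A,T vs C,G) heteroduplex inside the bias kernel resolves towards
#' the strong (C/G) allele; `bias_b = 0.5` is exact neutrality. The
#' simulator applies it as a retention probability on segregating
#' variants: every mutation is retained with baseline probability 1/2,
#' while W->S (respectively S->W) mutations inside the kernel are
#' retained with probability `b` (respectively `1 - b`), which reproduces
#' neutrality exactly at `b = 0.5` and gives a central skew-ratio
#' elevation of `b / (1 - b)` under a rectangular kernel.
#'
#' @param seed integer seed; each generator consumes a documented offset
#'   from it (genome +0, map +1, polymorphisms +2, peaks +3) so stages
#'   are independently reproducible.
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param base_comp named background base probabilities (A, C, G, T).
#' @param n_islands,island_width,island_gc,island_cpg_mult CpG islands:
#'   count, width (bp), island GC fraction, and the target CpG fraction
#'   as a multiple of the background `P(C) * P(G)`.
#' @param n_genes,gene_width,tss_island_frac genes: count, width, and
#'   fraction whose TSS sits on a CpG island center.
#' @param n_repeats,repeat_width planted repeat elements.
#' @param background_rate map background (cM/Mb).
#' @param n_hotspots,hotspot_fold,fold_cv,hotspot_width,width_cv planted
#'   hotspots: count, peak fold over background (lognormal spread
#'   `fold_cv`), width in bp (lognormal spread `width_cv`).
#' @param island_coloc_frac fraction of hotspots centered on islands.
#' @param hotspot_shape `"rect"` or `"gaussian"` rate bump.
#' @param mutation_rate,outgroup_mutation_rate pre-retention mutation
#'   densities per bp on the ingroup and outgroup lineages (observed SNP
#'   density is about half, from the baseline 1/2 retention).
#' @param divergence probability that the outgroup base differs from the
#'   common ancestor at a site (creates polarization failures).
#' @param bias_b,bias_halfwidth,bias_kernel,bias_by_strength BGC model:
#'   bias in `[0.5, 1)`, kernel half-width (bp), kernel shape (`"rect"`
#'   or `"triangular"`), and whether the per-hotspot bias scales with its
#'   peak fold (strongest hotspot gets `bias_b`).
#' @param n_peaks,peak_width,peak_island_frac,peak_sharing ChIP-like peak
#'   sets for two cell stages: per-stage count, width, island overlap
#'   fraction, and the fraction of each stage's peaks shared between the
#'   stages.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 1, chrom_length = 2e7,
                       base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_islands = 400, island_width = 1000,
                       island_gc = 0.6, island_cpg_mult = 3,
                       n_genes = 300, gene_width = 10000,
                       tss_island_frac = 0.7,
                       n_repeats = 300, repeat_width = 500,
                       background_rate = 0.5,
                       n_hotspots = 500, hotspot_fold = 10, fold_cv = 0,
                       hotspot_width = 4300, width_cv = 0,
                       island_coloc_frac = 0.8,
                       hotspot_shape = c("rect", "gaussian"),
                       mutation_rate = 0.004,
                       outgroup_mutation_rate = 0.0015,
                       divergence = 0.01,
                       bias_b = 0.5, bias_halfwidth = 5000,
                       bias_kernel = c("rect", "triangular"),
                       bias_by_strength = FALSE,
                       n_peaks = 500, peak_width = 1000,
                       peak_island_frac = 0.6, peak_sharing = 0.6) {
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_length = chrom_length, base_comp = base_comp,
              n_islands = n_islands, island_width = island_width,
              island_gc = island_gc, island_cpg_mult = island_cpg_mult,
              n_genes = n_genes, gene_width = gene_width,
              tss_island_frac = tss_island_frac, n_repeats = n_repeats,
              repeat_width = repeat_width,
              background_rate = background_rate, n_hotspots = n_hotspots,
              hotspot_fold = hotspot_fold, fold_cv = fold_cv,
              hotspot_width = hotspot_width, width_cv = width_cv,
              island_coloc_frac = island_coloc_frac,
              hotspot_shape = match.arg(hotspot_shape),
              mutation_rate = mutation_rate,
              outgroup_mutation_rate = outgroup_mutation_rate,
              divergence = divergence, bias_b = bias_b,
              bias_halfwidth = bias_halfwidth,
              bias_kernel = match.arg(bias_kernel),
              bias_by_strength = bias_by_strength, n_peaks = n_peaks,
              peak_width = peak_width,
              peak_island_frac = peak_island_frac,
              peak_sharing = peak_sharing)
  if (cfg$chrom_length <= 0 || cfg$n_chrom < 1)
    stop("genome dimensions must be positive")
  if (abs(sum(cfg$base_comp) - 1) > 1e-8 || any(cfg$base_comp < 0) ||
      !all(c("A", "C", "G", "T") %in% names(cfg$base_comp)))
    stop("base_comp must be named A,C,G,T probabilities summing to 1")
  if (cfg$bias_b < 0.5 || cfg$bias_b >= 1)
    stop("bias_b must lie in [0.5, 1)")
  if (any(c(cfg$mutation_rate, cfg$outgroup_mutation_rate,
            cfg$background_rate, cfg$divergence) < 0))
    stop("rates must be non-negative")
  # island feasibility: placement needs room for the islands plus gaps
  if (cfg$n_islands * (cfg$island_width + 2000) >
      0.8 * cfg$n_chrom * cfg$chrom_length)
    stop("island density infeasible for genome length")
  bg_cpg <- cfg$base_comp[["C"]] * cfg$base_comp[["G"]]
  if (cfg$island_cpg_mult * bg_cpg > 0.9 * cfg$island_gc / 2)
    stop("island CpG target infeasible for the chosen island GC content")
  class(cfg) <- "sim_config"
  cfg
}

.sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chrom))

# First-order Markov sampler used for island sequence; trans is a 4x4
# row-stochastic matrix over A,C,G,T.
.markov_seq <- function(n, init, trans) {
  out <- integer(n)
  u <- runif(n)
  cum <- t(apply(trans, 1L, cumsum))
  out[1L] <- findInterval(u[1L], cumsum(init), left.open = TRUE) + 1L
  for (i in seq_len(n - 1L) + 1L)
    out[i] <- findInterval(u[i], cum[out[i - 1L], ], left.open = TRUE) + 1L
  paste(c("A", "C", "G", "T")[out], collapse = "")
}

# Non-overlapping placements: sample starts, keep a greedily spaced subset.
.place_nonoverlapping <- function(n, width, L, min_gap = 2000,
                                  avoid = NULL, label = "elements") {
  lo <- width; hi <- L - 2 * width
  for (try in 1:60) {
    cand <- sort(floor(runif(4 * n + 40) * (hi - lo)) + lo)
    keep <- numeric(0)
    last <- -Inf
    for (s in cand) {
      if (s - last >= width + min_gap) {
        if (!is.null(avoid) &&
            any(avoid$start < s + width + min_gap &
                avoid$end > s - min_gap)) next
        keep <- c(keep, s)
        last <- s
        if (length(keep) == n) break
      }
    }
    if (length(keep) == n) return(keep)
  }
  stop("could not place ", n, " non-overlapping ", label)
}

#' Simulate a genome with CpG islands, genes, and repeats
#'
#' Background sequence is i.i.d. at the configured base composition.
#' Islands are first-order Markov segments with elevated GC and a CpG
#' dinucleotide fraction targeting `island_cpg_mult` times the background
#' `P(C) * P(G)`. A configurable fraction of gene TSS sit on island
#' centers; repeats are planted AT-rich or GC-rich low-complexity
#' segments (labelled `ATrich_sim` / `GCrich_sim`).
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override (default `cfg$seed`).
#' @return list with `genome` (named `DNAStringSet`), `islands`, `genes`,
#'   `tss`, `repeats` (interval sets, BED coordinates) and
#'   `chrom_lengths`.
#' @export
simulate_genome <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  comp <- cfg$base_comp[bases]
  # island transition matrix: marginal rows, except C -> G boosted to hit
  # the CpG target
  m <- c(A = (1 - cfg$island_gc) / 2, C = cfg$island_gc / 2,
         G = cfg$island_gc / 2, T = (1 - cfg$island_gc) / 2)
  target_cpg <- cfg$island_cpg_mult * comp[["C"]] * comp[["G"]]
  rest <- m[c("A", "C", "T")] / sum(m[c("A", "C", "T")])
  # boosting C->G shifts the stationary C frequency below the marginal;
  # fixed-point-solve P(G|C) so that pi_C * P(G|C) hits the CpG target
  pgc <- target_cpg / m[["C"]]
  for (it in 1:50) {
    pi_c <- m[["C"]] / (1 + m[["C"]] - rest[["C"]] * (1 - pgc))
    pgc_new <- min(target_cpg / pi_c, 0.95)
    if (abs(pgc_new - pgc) < 1e-12) break
    pgc <- pgc_new
  }
  trans <- matrix(rep(m, 4), nrow = 4, byrow = TRUE,
                  dimnames = list(bases, bases))
  trans["C", ] <- c(rest[["A"]] * (1 - pgc), rest[["C"]] * (1 - pgc),
                    pgc, rest[["T"]] * (1 - pgc))
  chroms <- .sim_chrom_names(cfg)
  L <- cfg$chrom_length
  genome <- list()
  islands <- genes <- tss <- repeats <- list()
  n_isl_ch <- .split_count(cfg$n_islands, cfg$n_chrom)
  n_gene_ch <- .split_count(cfg$n_genes, cfg$n_chrom)
  n_rep_ch <- .split_count(cfg$n_repeats, cfg$n_chrom)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    seq_ch <- Biostrings::DNAString(
      paste(sample(bases, L, replace = TRUE, prob = comp), collapse = ""))
    # islands
    isl_start <- if (n_isl_ch[ci] > 0)
      .place_nonoverlapping(n_isl_ch[ci], cfg$island_width, L,
                            label = "islands") else numeric(0)
    isl <- data.frame(chrom = rep(ch, length(isl_start)),
                      start = isl_start,
                      end = isl_start + cfg$island_width)
    if (nrow(isl)) {
      isl_seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(isl)),
        function(i) .markov_seq(cfg$island_width, m, trans), character(1)))
      seq_ch <- Biostrings::replaceAt(
        seq_ch, IRanges::IRanges(isl$start + 1, isl$end), isl_seqs)
    }
    # repeats (placed away from islands)
    rep_start <- if (n_rep_ch[ci] > 0)
      .place_nonoverlapping(n_rep_ch[ci], cfg$repeat_width, L,
                            min_gap = 500, avoid = isl,
                            label = "repeats") else numeric(0)
    reps <- data.frame(chrom = rep(ch, length(rep_start)),
                       start = rep_start,
                       end = rep_start + cfg$repeat_width)
    if (nrow(reps)) {
      fam <- rep(c("ATrich_sim", "GCrich_sim"), length.out = nrow(reps))
      rep_seqs <- Biostrings::DNAStringSet(vapply(fam, function(f) {
        p <- if (f == "ATrich_sim") c(0.4, 0.1, 0.1, 0.4) else
          c(0.1, 0.4, 0.4, 0.1)
        paste(sample(bases, cfg$repeat_width, TRUE, p), collapse = "")
      }, character(1)))
      seq_ch <- Biostrings::replaceAt(
        seq_ch, IRanges::IRanges(reps$start + 1, reps$end), rep_seqs)
      reps$name <- fam
    }
    # genes: a fraction of TSS on island centers, the rest uniform
    ng <- n_gene_ch[ci]
    if (ng > 0) {
      k <- round(cfg$tss_island_frac * ng)
      if (k > nrow(isl)) stop("not enough islands for tss_island_frac")
      isl_pick <- sample.int(nrow(isl), k)
      tss_pos <- c(floor((isl$start[isl_pick] + isl$end[isl_pick]) / 2),
                   floor(runif(ng - k) * (L - 2 * cfg$gene_width)) +
                     cfg$gene_width)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      g_start <- ifelse(strand == "+", tss_pos,
                        pmax(tss_pos - cfg$gene_width, 0))
      g_end <- ifelse(strand == "+",
                      pmin(tss_pos + cfg$gene_width, L), tss_pos)
      genes[[ch]] <- data.frame(chrom = ch, start = g_start, end = g_end,
                                strand = strand,
                                name = sprintf("%s_gene%d", ch, seq_len(ng)))
      tss[[ch]] <- data.frame(chrom = ch, start = tss_pos,
                              end = tss_pos + 1, strand = strand,
                              name = genes[[ch]]$name)
    }
    genome[[ch]] <- seq_ch
    islands[[ch]] <- isl
    repeats[[ch]] <- reps
  }
  g <- Biostrings::DNAStringSet(genome)
  names(g) <- chroms
  list(genome = g,
       islands = do.call(rbind, islands),
       genes = if (length(genes)) do.call(rbind, genes) else NULL,
       tss = if (length(tss)) do.call(rbind, tss) else NULL,
       repeats = do.call(rbind, repeats),
       chrom_lengths = setNames(rep(L, length(chroms)), chroms))
}

.split_count <- function(n, k) {
  out <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

#' Simulate a recombination map with island-colocated hotspots
#'
#' Plants `n_hotspots` rate elevations on a constant background:
#' `island_coloc_frac` of them centered on (distinct) CpG islands, the
#' rest at uniform positions. Overlapping planted bumps are merged in the
#' returned truth set (keeping the maximum fold).
#'
#' @param cfg a [sim_config()].
#' @param islands island intervals from [simulate_genome()].
#' @param seed optional seed override (default `cfg$seed + 1`).
#' @return list with `map` (a [genetic_map()]) and `hotspots` (truth
#'   data.frame with `chrom`, `start`, `end`, `center`, `fold`).
#' @export
simulate_map <- function(cfg, islands, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  isl <- .as_intervals(islands, "islands")
  chroms <- .sim_chrom_names(cfg)
  L <- cfg$chrom_length
  bg <- cfg$background_rate
  n_hs_ch <- .split_count(cfg$n_hotspots, cfg$n_chrom)
  map_rows <- list()
  truth <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n <- n_hs_ch[ci]
    isl_ch <- isl[isl$chrom == ch, , drop = FALSE]
    k <- round(cfg$island_coloc_frac * n)
    if (k > nrow(isl_ch)) stop("not enough islands for island_coloc_frac")
    centers <- c(
      (isl_ch$start + isl_ch$end)[sample.int(nrow(isl_ch), k)] / 2,
      floor(runif(n - k) * (L - 2 * cfg$hotspot_width)) + cfg$hotspot_width)
    widths <- cfg$hotspot_width * exp(stats::rnorm(n, 0, cfg$width_cv))
    folds <- cfg$hotspot_fold * exp(stats::rnorm(n, 0, cfg$fold_cv))
    hs_s <- pmax(round(centers - widths / 2), 0)
    hs_e <- pmin(round(centers + widths / 2), L)
    # build breakpoints and per-segment rates
    if (cfg$hotspot_shape == "rect") {
      brk <- sort(unique(c(0, L, hs_s, hs_e)))
      seg_rate <- rep(bg, length(brk) - 1L)
      for (i in seq_len(n)) {
        j <- which(brk >= hs_s[i] & brk < hs_e[i])
        seg_rate[j] <- pmax(seg_rate[j], bg * folds[i])
      }
    } else {  # gaussian bumps discretized at 250 bp
      step <- 250
      pts <- unlist(lapply(seq_len(n), function(i)
        seq(max(hs_s[i] - widths[i], 0), min(hs_e[i] + widths[i], L),
            by = step)))
      brk <- sort(unique(c(0, L, round(pts))))
      mid <- (brk[-length(brk)] + brk[-1L]) / 2
      seg_rate <- rep(bg, length(mid))
      for (i in seq_len(n)) {
        sigma <- (hs_e[i] - hs_s[i]) / 4
        ctr <- (hs_s[i] + hs_e[i]) / 2
        j <- which(mid > ctr - 4 * sigma & mid < ctr + 4 * sigma)
        seg_rate[j] <- seg_rate[j] +
          bg * (folds[i] - 1) * exp(-(mid[j] - ctr)^2 / (2 * sigma^2))
      }
    }
    map_rows[[ch]] <- data.frame(chrom = ch, pos = brk + 1,
                                 rate = c(seg_rate, NA))
    # merged truth: the strongest constituent provides fold and center (a
    # planted center, so island colocalization survives merging)
    mg <- .merge_numeric_intervals(hs_s, hs_e)
    fold_m <- center_m <- numeric(length(mg$start))
    for (i in seq_along(mg$start)) {
      ov <- which(hs_s < mg$end[i] & hs_e > mg$start[i])
      best <- ov[which.max(folds[ov])]
      fold_m[i] <- folds[best]
      center_m[i] <- (hs_s[best] + hs_e[best]) / 2
    }
    truth[[ch]] <- data.frame(chrom = ch, start = mg$start, end = mg$end,
                              center = center_m, fold = fold_m)
  }
  list(map = genetic_map(do.call(rbind, map_rows)),
       hotspots = do.call(rbind, truth))
}

#' Simulate two-lineage polymorphisms with transmission bias
#'
#' Ingroup and outgroup lineages diverge from the simulated genome as a
#' common ancestor. Mutations arise at the configured per-bp densities
#' with a symmetric single-base model (the derived base is uniform over
#' the three alternatives). Every mutation is retained as a segregating
#' polymorphism with baseline probability 1/2; on the ingroup lineage,
#' W/S mutations inside the bias kernel around hotspot centers are
#' retained with probability `bias_b` (W->S) or `1 - bias_b` (S->W)
#' instead, so `bias_b = 0.5` reproduces neutrality exactly. The
#' outgroup lineage evolves without bias. The outgroup allele reported
#' for each ingroup SNP is the ancestral base, flipped with probability
#' `divergence` to model fixed differences (these sites fail
#' polarization downstream, as in real data).
#'
#' @param cfg a [sim_config()].
#' @param genome named `DNAStringSet` from [simulate_genome()].
#' @param hotspots truth hotspots from [simulate_map()] (used for the
#'   bias kernel). May have zero rows, in which case no bias is applied.
#' @param seed optional seed override (default `cfg$seed + 2`).
#' @return list with `ingroup` and `outgroup` SNP data.frames (columns
#'   `chrom`, `pos`, `a1`, `a2`, `outgroup`, `left`, `right`; allele
#'   order randomized) and `truth` (per-SNP `lineage`, true `ancestral`,
#'   `derived`, `mutation_class`, and `bias_applied`).
#' @export
simulate_polymorphisms <- function(cfg, genome, hotspots = NULL,
                                   seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  hs <- if (is.null(hotspots) || nrow(hotspots) == 0L) NULL else
    .as_intervals(hotspots, "hotspots")
  bases_at <- function(s, pos) {
    if (length(pos) == 0L) return(character(0))
    strsplit(as.character(unlist(
      Biostrings::extractAt(s, IRanges::IRanges(pos, pos)))), "")[[1L]]
  }
  sim_lineage <- function(rate, biased) {
    rows <- list(); truths <- list()
    for (ch in names(genome)) {
      s <- genome[[ch]]
      L <- length(s)
      n <- rpois(1L, rate * L)
      if (n == 0L) next
      pos <- sort(sample.int(L, min(n, L)))
      anc <- bases_at(s, pos)
      ok <- anc %in% c("A", "C", "G", "T")
      pos <- pos[ok]; anc <- anc[ok]
      bases <- c("A", "C", "G", "T")
      ai <- match(anc, bases)
      der <- bases[((ai - 1L + sample.int(3L, length(pos), TRUE)) %% 4L) + 1L]
      W <- c("A", "T")
      cls <- ifelse(anc %in% W & !(der %in% W), "AT_GC",
                    ifelse(!(anc %in% W) & der %in% W, "GC_AT", "neutral"))
      # kernel factor in [0, 1]
      kfac <- rep(0, length(pos))
      b_eff <- rep(cfg$bias_b, length(pos))
      if (biased && !is.null(hs)) {
        nn <- .nearest_center(rep(ch, length(pos)), pos, hs)
        hit <- !is.na(nn$distance) & nn$distance <= cfg$bias_halfwidth
        kfac[hit] <- if (cfg$bias_kernel == "rect") 1 else
          pmax(0, 1 - nn$distance[hit] / cfg$bias_halfwidth)
        if (cfg$bias_by_strength && "fold" %in% names(hs)) {
          fmax <- max(hs$fold)
          b_eff <- 0.5 + (cfg$bias_b - 0.5) * hs$fold[nn$hotspot] / fmax
          b_eff[is.na(b_eff)] <- cfg$bias_b
        }
      }
      p_keep <- rep(0.5, length(pos))
      ws <- cls == "AT_GC"; sw <- cls == "GC_AT"
      p_keep[ws] <- 0.5 + (b_eff[ws] - 0.5) * kfac[ws]
      p_keep[sw] <- 0.5 - (b_eff[sw] - 0.5) * kfac[sw]
      keep <- runif(length(pos)) < p_keep
      if (!any(keep)) next
      pos <- pos[keep]; anc <- anc[keep]; der <- der[keep]
      cls <- cls[keep]; kfac <- kfac[keep]
      # outgroup allele = ancestral, flipped at diverged sites
      og <- anc
      flip <- runif(length(pos)) < cfg$divergence
      if (any(flip)) {
        oi <- match(og[flip], bases)
        og[flip] <- bases[((oi - 1L + sample.int(3L, sum(flip), TRUE))
                           %% 4L) + 1L]
      }
      left <- ifelse(pos > 1L, bases_at(s, pmax(pos - 1L, 1L)), "N")
      right <- ifelse(pos < L, bases_at(s, pmin(pos + 1L, L)), "N")
      swap <- runif(length(pos)) < 0.5
      a1 <- ifelse(swap, der, anc)
      a2 <- ifelse(swap, anc, der)
      rows[[ch]] <- data.frame(chrom = ch, pos = pos, a1 = a1, a2 = a2,
                               outgroup = og, left = left, right = right,
                               stringsAsFactors = FALSE)
      truths[[ch]] <- data.frame(chrom = ch, pos = pos, ancestral = anc,
                                 derived = der, mutation_class = cls,
                                 bias_applied = biased & kfac > 0 &
                                   cfg$bias_b > 0.5,
                                 stringsAsFactors = FALSE)
    }
    empty <- data.frame(chrom = character(0), pos = numeric(0),
                        a1 = character(0), a2 = character(0),
                        outgroup = character(0), left = character(0),
                        right = character(0))
    list(snps = if (length(rows)) do.call(rbind, rows) else empty,
         truth = if (length(truths)) do.call(rbind, truths) else NULL)
  }
  ing <- sim_lineage(cfg$mutation_rate, biased = TRUE)
  outg <- sim_lineage(cfg$outgroup_mutation_rate, biased = FALSE)
  if (!is.null(ing$truth)) ing$truth$lineage <- "ingroup"
  if (!is.null(outg$truth)) outg$truth$lineage <- "outgroup"
  list(ingroup = ing$snps, outgroup = outg$snps,
       truth = list(ingroup = ing$truth, outgroup = outg$truth))
}

#' Simulate two stages of ChIP-like peak sets
#'
#' Generates `n_peaks` peaks for each of two cell stages with a
#' configurable fraction shared between them (shared peaks are identical
#' intervals) and a configurable fraction centered on CpG islands. All
#' distinct peaks are placed disjointly, so the realized unique fractions
#' match `1 - peak_sharing` exactly up to rounding.
#'
#' @param cfg a [sim_config()].
#' @param islands island intervals from [simulate_genome()].
#' @param seed optional seed override (default `cfg$seed + 3`).
#' @return list with `stage1` and `stage2` interval sets.
#' @export
simulate_peaks <- function(cfg, islands, seed = cfg$seed + 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  isl <- .as_intervals(islands, "islands")
  n <- cfg$n_peaks
  n_shared <- round(cfg$peak_sharing * n)
  n_unique <- n - n_shared
  n_total <- n_shared + 2L * n_unique
  chroms <- .sim_chrom_names(cfg)
  n_ch <- .split_count(n_total, cfg$n_chrom)
  pools <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    nt <- n_ch[ci]
    isl_ch <- isl[isl$chrom == ch, , drop = FALSE]
    k_isl <- min(round(cfg$peak_island_frac * nt), nrow(isl_ch))
    ctr_isl <- if (k_isl > 0)
      (isl_ch$start + isl_ch$end)[sample.int(nrow(isl_ch), k_isl)] / 2 else
        numeric(0)
    rest <- nt - k_isl
    s_rest <- if (rest > 0)
      .place_nonoverlapping(rest, cfg$peak_width, cfg$chrom_length,
                            min_gap = cfg$peak_width, avoid = isl_ch,
                            label = "peaks") else numeric(0)
    starts <- round(c(ctr_isl - cfg$peak_width / 2, s_rest))
    pools[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = starts + cfg$peak_width)
  }
  pool <- do.call(rbind, pools)
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  shared <- pool[seq_len(n_shared), , drop = FALSE]
  u1 <- pool[n_shared + seq_len(n_unique), , drop = FALSE]
  u2 <- pool[n_shared + n_unique + seq_len(n_unique), , drop = FALSE]
  s1 <- rbind(shared, u1)
  s2 <- rbind(shared, u2)
  list(stage1 = interval_set(s1$chrom, s1$start, s1$end, label = "stage1"),
       stage2 = interval_set(s2$chrom, s2$start, s2$end, label = "stage2"))
}

#' Run the whole simulator
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_map()],
#' [simulate_polymorphisms()] and [simulate_peaks()].
#'
#' @param cfg a [sim_config()].
#' @return list combining all generator outputs (`genome`, `islands`,
#'   `genes`, `tss`, `repeats`, `chrom_lengths`, `map`, `hotspots`,
#'   `snps`, `peaks`).
#' @export
simulate_all <- function(cfg) {
  g <- simulate_genome(cfg)
  m <- simulate_map(cfg, g$islands)
  p <- simulate_polymorphisms(cfg, g$genome, m$hotspots)
  pk <- simulate_peaks(cfg, g$islands)
  c(g, list(map = m$map, hotspots = m$hotspots, snps = p, peaks = pk))
}

#' Write a simulation to plain-text files
#'
#' Emits FASTA (genome), BED (islands, genes, repeats, true hotspots,
#' peaks), the genetic-map TSV, chromosome lengths, and the SNP TSVs,
#' using the package's own readers' formats so everything round-trips.
#'
#' @param sim output of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  Biostrings::writeXStringSet(sim$genome, f("genome.fa"))
  write_bed(sim$islands, f("islands.bed"))
  if (!is.null(sim$genes)) write_bed(sim$genes, f("genes.bed"))
  if (!is.null(sim$tss)) write_bed(sim$tss, f("tss.bed"))
  write_bed(sim$repeats, f("repeats.bed"))
  write_bed(sim$hotspots, f("true_hotspots.bed"))
  write_bed(sim$peaks$stage1, f("peaks_stage1.bed"))
  write_bed(sim$peaks$stage2, f("peaks_stage2.bed"))
  write_genetic_map(sim$map, f("map.tsv"))
  write_chrom_lengths(sim$chrom_lengths, f("chrom_lengths.tsv"))
  write_snps(sim$snps$ingroup, f("snps_ingroup.tsv"))
  write_snps(sim$snps$outgroup, f("snps_outgroup.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
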