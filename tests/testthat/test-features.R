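test_that("profile_around reproduces flat maps and step changes", {
  gm <- flat_map(L = 1e6, rate = 2.5, n_seg = 5)
  anchors <- data.frame(chrom = "chr1", start = c(2e5, 5e5, 8e5),
                        end = c(2e5, 5e5, 8e5) + 1)
  pr <- profile_around(gm, anchors, half_span = 10000, bin_width = 1000)
  expect_true(all(abs(pr$mean_rate - 2.5) < 1e-12))
  expect_true(all(pr$n == 3L))

  # single anchor at a rate step: left bins at 1, right bins at 5
  step <- genetic_map(data.frame(chrom = "chr1", pos = c(1, 5e5 + 1, 1e6 + 1),
                                 rate = c(1, 5, NA)))
  a1 <- data.frame(chrom = "chr1", start = 5e5, end = 5e5 + 1)
  pr2 <- profile_around(step, a1, half_span = 5000, bin_width = 1000)
  expect_true(all(abs(pr2$mean_rate[pr2$bin_hi <= 0] - 1) < 1e-9))
  expect_true(all(abs(pr2$mean_rate[pr2$bin_lo >= 1] - 5) < 1e-9))

  # anchors beyond the mapped extent are skipped with a warning
  a2 <- data.frame(chrom = "chr1", start = c(5e5, 5e6), end = c(5e5, 5e6) + 1)
  expect_warning(profile_around(step, a2, half_span = 5000), "skipped")

  # strand orientation flips the profile
  a3 <- data.frame(chrom = "chr1", start = 5e5, end = 5e5 + 1, strand = "-")
  pr3 <- profile_around(step, a3, half_span = 5000, bin_width = 1000,
                        orient_by_strand = TRUE)
  expect_true(all(abs(pr3$mean_rate[pr3$bin_lo >= 1] - 1) < 1e-9))
})

test_that("gaussian hotspots on islands put the profile peak at the center", {
  cfg <- sim_config(seed = 17, chrom_length = 2e6, n_islands = 60,
                    n_hotspots = 30, island_coloc_frac = 1,
                    n_genes = 20, n_repeats = 20,
                    hotspot_shape = "gaussian", hotspot_fold = 15)
  g <- simulate_genome(cfg)
  m <- simulate_map(cfg, g$islands)
  used <- recland:::.overlaps_any_df(g$islands, m$hotspots)
  pr <- profile_around(m$map, g$islands[used, ], half_span = 20000,
                       bin_width = 1000)
  peak_bin <- which.max(pr$mean_rate)
  center_bin <- which(pr$bin_lo == 0)
  expect_lte(abs(peak_bin - center_bin), 1)
})

test_that("distance partitions match a brute-force nearest-neighbor scan", {
  ref <- data.frame(chrom = "chr1", start = c(1e4, 5e4), end = c(1.2e4, 5.2e4))
  # TSS inside an island
  a_in <- data.frame(chrom = "chr1", start = 1.1e4, end = 1.1e4 + 1)
  expect_equal(as.character(partition_by_distance(a_in, ref)), "overlap")
  # nearest island 12 kb away with max edge 10 kb
  a_far <- data.frame(chrom = "chr1", start = 6.4e4, end = 6.4e4 + 1)
  expect_equal(as.character(partition_by_distance(a_far, ref)),
               "none within 10000")
  # empty reference set
  expect_equal(as.character(partition_by_distance(a_in, ref[0, ])),
               "none within 10000")

  set.seed(18)
  anchors <- random_intervals(80, 1e5, 1)
  refs <- random_intervals(10, 1e5, 2000)
  edges <- c(2000, 5000, 10000)
  grp <- partition_by_distance(anchors, refs, edges)
  # partition property: every anchor in exactly one group
  expect_equal(sum(table(grp)), nrow(anchors))
  # brute-force oracle
  for (i in seq_len(nrow(anchors))) {
    d <- Inf
    for (j in seq_len(nrow(refs))) {
      if (anchors$start[i] < refs$end[j] && anchors$end[i] > refs$start[j]) {
        d <- 0
      } else {
        d <- min(d, max(refs$start[j] - anchors$end[i],
                        anchors$start[i] - refs$end[j]))
      }
    }
    want <- if (d == 0) "overlap" else if (d > 10000) "none within 10000"
    else if (d <= 2000) "(0,2000]" else if (d <= 5000) "(2000,5000]"
    else "(5000,10000]"
    expect_equal(as.character(grp[i]), want)
  }
})

test_that("hotspot-TSS distance summaries match a sort-based oracle", {
  hs_all <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 200))
  tss_in <- data.frame(chrom = "chr1", start = c(10, 150), end = c(11, 151))
  r <- hotspot_tss_distances(hs_all, tss_in)
  expect_equal(r$fraction_overlapping, 1)
  expect_equal(r$median_distance, 0)
  expect_equal(r$fraction_beyond, 0)

  far <- hotspot_tss_distances(
    data.frame(chrom = "chr1", start = 2e5, end = 2.1e5),
    data.frame(chrom = "chr1", start = 36e4, end = 36e4 + 1))
  expect_equal(far$fraction_beyond, 1)
  expect_error(hotspot_tss_distances(hs_all, tss_in[0, ]), "empty")

  set.seed(19)
  hs <- random_intervals(20, 1e6, 2000)
  tss <- random_intervals(15, 1e6, 1)
  r2 <- hotspot_tss_distances(hs, tss)
  oracle <- vapply(seq_len(nrow(hs)), function(i) {
    d <- vapply(seq_len(nrow(tss)), function(j) {
      if (tss$start[j] < hs$end[i] && tss$end[j] > hs$start[i]) 0
      else max(tss$start[j] - hs$end[i], hs$start[i] - tss$end[j])
    }, numeric(1))
    min(d)
  }, numeric(1))
  expect_equal(sort(r2$distances), sort(oracle))
  expect_equal(r2$median_distance, median(oracle))
})

test_that("windowed correlations: exact linear signal and hand-computed r", {
  set.seed(20)
  base <- paste(sample(c("A", "C", "G", "T"), 2e5, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(base)
  names(genome) <- "chr1"
  w <- 1e4
  wins <- data.frame(chrom = "chr1", start = (0:19) * w, end = (1:20) * w)
  comp <- sequence_composition(interval_sequences(genome, wins))
  # rate constructed as an exact linear function of window CpG
  gm <- genetic_map(data.frame(chrom = "chr1", pos = c(wins$start + 1, 2e5 + 1),
                               rate = c(1 + 50 * comp$cpg, NA)))
  wc <- windowed_correlation(gm, genome, window_sizes = w)[[1]]
  expect_equal(wc$r_cpg, 1, tolerance = 1e-9)

  # 5-window table: r matches the explicit Pearson formula
  wc5 <- windowed_correlation(gm, genome, window_sizes = 4e4)[[1]]
  t5 <- wc5$table
  hand_r <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  expect_equal(wc5$r_gc, hand_r(t5$rate, t5$gc), tolerance = 1e-9)
  expect_equal(wc5$r_cpg, hand_r(t5$rate, t5$cpg), tolerance = 1e-9)

  # affine rescaling of the rate track leaves r unchanged
  gm2 <- gm
  gm2$chr1$rates <- 3 * gm2$chr1$rates + 2
  wc2 <- windowed_correlation(gm2, genome, window_sizes = w)[[1]]
  expect_equal(wc2$r_cpg, wc$r_cpg, tolerance = 1e-9)

  # zero-variance flag
  expect_warning(
    windowed_correlation(flat_map(L = 2e5, n_seg = 4), genome,
                         window_sizes = w),
    "zero-variance")
})

test_that("composition regression recovers planted signs", {
  set.seed(21)
  n <- 200
  tab <- data.frame(gc = runif(n, 0.3, 0.6), cpg = runif(n, 0.01, 0.1))
  tab$rate <- 2 * tab$cpg - 1 * tab$gc + rnorm(n, 0, 0.005)
  fit <- composition_regression(tab)
  expect_equal(fit$sign[fit$predictor == "cpg"], "+")
  expect_equal(fit$sign[fit$predictor == "gc"], "-")

  # exact fit without noise: standardized coefficients are b * sd(x)
  tab2 <- tab
  tab2$rate <- 2 * tab2$cpg - 1 * tab2$gc
  fit2 <- composition_regression(tab2)
  expect_equal(fit2$estimate[fit2$predictor == "cpg"],
               2 * stats::sd(tab2$cpg), tolerance = 1e-9)
  expect_equal(fit2$estimate[fit2$predictor == "gc"],
               -1 * stats::sd(tab2$gc), tolerance = 1e-9)

  # independence: both CIs cover zero
  tab3 <- tab
  tab3$rate <- rnorm(n)
  fit3 <- composition_regression(tab3)
  expect_true(all(fit3$ci_lo < 0 & fit3$ci_hi > 0))

  # collinearity guard
  tab4 <- tab
  tab4$cpg <- tab4$gc * 2 + 1e-9
  expect_error(composition_regression(tab4), "collinear")
})

test_that("flanking composition comparison: arithmetic oracle and planted signal", {
  # hand-checkable toy: flanks of known composition
  blocks <- c(strrep("CG", 50), strrep("AT", 50),   # around interval 1
              strrep("AT", 100),
              strrep("CG", 25), strrep("AT", 75))
  base <- paste0(strrep("AT", 50), "AAAA", strrep("CG", 50),
                 strrep("AT", 450))
  genome <- Biostrings::DNAStringSet(base)
  names(genome) <- "chr1"
  iv <- data.frame(chrom = "chr1", start = 100, end = 104)
  # left flank [0,100): (AT)50, right flank [104,204): (CG)50
  r <- flanking_composition_compare(iv, iv, genome, flank = 100)
  # left: 0 CpG in 99 dinucs; right: 50 CG in 99 -> mean over 200 bp
  expect_equal(r$mean_a, (0 + 50) / (99 + 99), tolerance = 1e-12)
  expect_equal(r$mean_a, r$mean_b)

  # identical sets: p ~ 1
  set.seed(22)
  g2 <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = ""))
  names(g2) <- "chr1"
  sa <- random_intervals(10, 9e4, 1000)
  sa$start <- sa$start + 5000; sa$end <- sa$end + 5000
  r2 <- flanking_composition_compare(sa, sa, g2, flank = 2000)
  expect_gt(r2$p, 0.9)

  # planted difference: CpG-rich flanks around set A only
  g3 <- Biostrings::DNAStringSet(strrep("AT", 1e5))
  names(g3) <- "chr1"
  a3 <- data.frame(chrom = "chr1", start = (1:8) * 2e4,
                   end = (1:8) * 2e4 + 500)
  b3 <- data.frame(chrom = "chr1", start = (1:8) * 2e4 + 1e4,
                   end = (1:8) * 2e4 + 1e4 + 500)
  for (s in a3$start)
    g3[[1]] <- Biostrings::replaceAt(
      g3[[1]], IRanges::IRanges(s - 999, s - 500),
      Biostrings::DNAStringSet(strrep("CG", 250)))
  r3 <- flanking_composition_compare(a3, b3, g3, flank = 1000)
  expect_gt(r3$mean_a, r3$mean_b)
  expect_lt(r3$p, 0.01)
})

test_that("shuffled anchors converge to the genome-mean rate", {
  cfg <- sim_config(seed = 23, chrom_length = 3e6, n_islands = 60,
                    n_hotspots = 30, n_genes = 20, n_repeats = 20)
  m <- simulate_map(cfg, simulate_genome(cfg)$islands)
  genome_mean <- total_map_length(m$map) / 3e6 * 1e6
  set.seed(24)
  anchors <- random_intervals(400, 3e6 - 1e5, 1)
  anchors$start <- anchors$start + 5e4; anchors$end <- anchors$end + 5e4
  pr <- profile_around(m$map, anchors, half_span = 10000, bin_width = 2000)
  expect_true(all(abs(pr$mean_rate - genome_mean) < 0.35 * genome_mean))
})

test_that("gene-body profile rescales genes onto proportional bins", {
  step <- genetic_map(data.frame(chrom = "chr1", pos = c(1, 5e4 + 1, 1e5 + 1),
                                 rate = c(1, 9, NA)))
  genes <- data.frame(chrom = "chr1", start = c(0, 0), end = c(1e5, 1e5),
                      strand = c("+", "-"))
  pr_f <- gene_body_profile(step, genes[1, ], n_bins = 10)
  expect_equal(pr_f$mean_rate, c(rep(1, 5), rep(9, 5)))
  pr_r <- gene_body_profile(step, genes[2, ], n_bins = 10)
  expect_equal(pr_r$mean_rate, c(rep(9, 5), rep(1, 5)))
})
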