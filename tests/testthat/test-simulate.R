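test_that("config validation enforces the stated world", {
  expect_error(sim_config(bias_b = 0.4), "bias_b")
  expect_error(sim_config(bias_b = 1), "bias_b")
  expect_error(sim_config(base_comp = c(A = 0.5, C = 0.5, G = 0, T = 0.1)),
               "base_comp")
  expect_error(sim_config(chrom_length = 1e5, n_islands = 1000),
               "infeasible")
  expect_error(sim_config(island_cpg_mult = 30), "CpG target infeasible")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 25, chrom_length = 3e5, n_islands = 12,
                    n_hotspots = 6, n_genes = 10, n_repeats = 10,
                    n_peaks = 15)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$map, s2$map)
  expect_identical(s1$snps$ingroup, s2$snps$ingroup)
  expect_identical(s1$peaks, s2$peaks)
  # a different seed gives different output
  s3 <- simulate_all(sim_config(seed = 26, chrom_length = 3e5,
                                n_islands = 12, n_hotspots = 6,
                                n_genes = 10, n_repeats = 10,
                                n_peaks = 15))
  expect_false(identical(as.character(s1$genome),
                         as.character(s3$genome)))
})

test_that("island-free genome matches the i.i.d. closed form for CpG", {
  cfg <- sim_config(seed = 27, chrom_length = 1e6, n_islands = 0,
                    n_genes = 0, n_repeats = 0)
  g <- simulate_genome(cfg)
  comp <- sequence_composition(g$genome)
  # i.i.d.: P(CpG) = P(C) * P(G) = 0.0625; sd ~ sqrt(p(1-p)/L)
  expect_lt(abs(comp$cpg - 0.0625), 5 * sqrt(0.0625 * 0.9375 / 1e6))
  expect_lt(abs(comp$gc - 0.5), 5 * sqrt(0.25 / 1e6) * 2)
})

test_that("island CpG enrichment hits the configured multiplier", {
  cfg <- sim_config(seed = 28, chrom_length = 2e6, n_islands = 150,
                    island_cpg_mult = 10, island_gc = 0.7,
                    base_comp = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35),
                    n_genes = 0, n_repeats = 0)
  g <- simulate_genome(cfg)
  isl_comp <- sequence_composition(interval_sequences(g$genome, g$islands))
  bg_cpg <- 0.15 * 0.15
  expect_lt(abs(mean(isl_comp$cpg) / bg_cpg - 10), 2)  # within 20%
  expect_gt(mean(isl_comp$gc), 0.6)
})

test_that("planted map integrates to background plus bump mass", {
  cfg <- sim_config(seed = 29, chrom_length = 5e6, n_islands = 0,
                    n_genes = 0, n_repeats = 0, n_hotspots = 20,
                    hotspot_fold = 10, island_coloc_frac = 0)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  m <- simulate_map(cfg, empty)
  # all folds are equal, so even merged clusters sit at bg * fold and the
  # integral follows from the merged truth widths alone
  expect_gte(nrow(m$hotspots), 19L)
  w <- sum(m$hotspots$end - m$hotspots$start)
  expected_cm <- (0.5 * (5e6 - w) + 0.5 * 10 * w) / 1e6
  expect_equal(total_map_length(m$map), expected_cm, tolerance = 1e-9)
})

test_that("hotspot-island colocalization follows the configured fraction", {
  cfg <- sim_config(seed = 30, chrom_length = 4e6, n_islands = 120,
                    n_hotspots = 60, island_coloc_frac = 1,
                    n_genes = 0, n_repeats = 0)
  g <- simulate_genome(cfg)
  m <- simulate_map(cfg, g$islands)
  centers <- data.frame(chrom = m$hotspots$chrom,
                        start = m$hotspots$center,
                        end = m$hotspots$center + 1)
  expect_true(all(recland:::.overlaps_any_df(centers, g$islands)))

  # fraction 0: nearest-island distances look uniform (KS against a
  # directly drawn uniform-position null)
  cfg0 <- sim_config(seed = 31, chrom_length = 4e6, n_islands = 120,
                     n_hotspots = 60, island_coloc_frac = 0,
                     n_genes = 0, n_repeats = 0)
  m0 <- simulate_map(cfg0, g$islands)
  nearest <- function(pos) {
    ic <- (g$islands$start + g$islands$end) / 2
    vapply(pos, function(p) min(abs(p - ic)), numeric(1))
  }
  d_obs <- nearest(m0$hotspots$center)
  set.seed(32)
  d_null <- nearest(runif(5000, cfg0$hotspot_width,
                          4e6 - cfg0$hotspot_width))
  ks <- suppressWarnings(stats::ks.test(d_obs, d_null))
  expect_gt(ks$p.value, 0.001)
})

test_that("polymorphism generator honors rates, divergence, and truth", {
  cfg <- sim_config(seed = 33, chrom_length = 3e5, n_islands = 10,
                    n_genes = 0, n_repeats = 0, n_hotspots = 5,
                    mutation_rate = 0)
  g <- simulate_genome(cfg)
  m <- simulate_map(cfg, g$islands)
  p <- simulate_polymorphisms(cfg, g$genome, m$hotspots)
  expect_equal(nrow(p$ingroup), 0L)   # zero mutation rate
  expect_gt(nrow(p$outgroup), 0L)

  cfg2 <- sim_config(seed = 34, chrom_length = 3e5, n_islands = 10,
                     n_genes = 0, n_repeats = 0, n_hotspots = 5,
                     mutation_rate = 0.01, divergence = 0)
  p2 <- simulate_polymorphisms(cfg2, g$genome, m$hotspots)
  # observed density ~ rate/2 from the baseline retention
  expect_lt(abs(nrow(p2$ingroup) / 3e5 - 0.005), 0.001)
  # with zero divergence every site polarizes to the true ancestral state
  pol <- polarize(p2$ingroup)
  expect_true(all(is.na(pol$reject_reason)))
  expect_identical(pol$ancestral, p2$truth$ingroup$ancestral)
  expect_identical(pol$mutation_class, p2$truth$ingroup$mutation_class)
  # alleles are genuinely polymorphic and positions stay in bounds
  expect_true(all(pol$a1 != pol$a2))
  expect_true(all(p2$ingroup$pos >= 1 & p2$ingroup$pos <= 3e5))
})

test_that("peak sharing fractions are reproduced", {
  cfg <- sim_config(seed = 35, chrom_length = 4e6, n_islands = 150,
                    n_genes = 50, n_repeats = 50,
                    n_peaks = 300, peak_sharing = 1)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, g$islands)
  r <- compare_peak_sets(pk$stage1, pk$stage2)
  expect_equal(r$pct_unique_p, 0)
  expect_equal(r$pct_unique_q, 0)

  cfg2 <- sim_config(seed = 36, chrom_length = 4e6, n_islands = 150,
                     n_genes = 50, n_repeats = 50,
                     n_peaks = 300, peak_sharing = 0.6)
  pk2 <- simulate_peaks(cfg2, g$islands)
  r2 <- compare_peak_sets(pk2$stage1, pk2$stage2)
  expect_lt(abs(r2$pct_unique_p - 40), 3)
  expect_lt(abs(r2$pct_unique_q - 40), 3)
})

test_that("emitted files round-trip through the I/O layer", {
  cfg <- sim_config(seed = 37, chrom_length = 2e5, n_islands = 8,
                    n_hotspots = 4, n_genes = 6, n_repeats = 6,
                    n_peaks = 8)
  sim <- simulate_all(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)

  g2 <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(g2[[1]]), as.character(sim$genome[[1]]))
  m2 <- read_genetic_map(file.path(dir, "map.tsv"))
  expect_equal(m2$chr1$boundaries, sim$map$chr1$boundaries)
  expect_equal(m2$chr1$rates, sim$map$chr1$rates)
  isl2 <- read_bed(file.path(dir, "islands.bed"))
  expect_equal(isl2$start, sim$islands$start)
  expect_equal(isl2$end, sim$islands$end)
  snp2 <- read_snps(file.path(dir, "snps_ingroup.tsv"))
  expect_equal(snp2$pos, sim$snps$ingroup$pos)
  expect_equal(snp2$a1, sim$snps$ingroup$a1)
  cl2 <- read_chrom_lengths(file.path(dir, "chrom_lengths.tsv"))
  expect_equal(cl2, sim$chrom_lengths)
})

test_that("the CLI dispatches subcommands", {
  cfg <- sim_config(seed = 38, chrom_length = 3e5, n_islands = 10,
                    n_hotspots = 5, n_genes = 5, n_repeats = 5,
                    n_peaks = 10)
  sim <- simulate_all(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  out <- file.path(dir, "called.bed")
  suppressMessages(recland_cli(c("callhotspots", "--map",
                                 file.path(dir, "map.tsv"),
                                 "--out", out)))
  expect_true(file.exists(out))
  called <- read_bed(out)
  expect_gt(nrow(called), 0)
  r <- suppressMessages(recland_cli(c(
    "overlap-test",
    "--seta", out,
    "--setb", file.path(dir, "true_hotspots.bed"),
    "--lengths", file.path(dir, "chrom_lengths.tsv"),
    "--n-rand", "99", "--seed", "1")))
  expect_lt(r$p, 0.05)
  expect_error(recland_cli("nosuch"), "unknown subcommand")
})
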