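# Shared fixture builders. Everything is generated in code (no binary
# fixtures); heavier simulated fixtures are cached per test file run.

flat_map <- function(L = 1e6, rate = 1, chrom = "chr1", n_seg = 1) {
  pos <- round(seq(1, L + 1, length.out = n_seg + 1))
  genetic_map(data.frame(chrom = chrom, pos = pos,
                         rate = c(rep(rate, n_seg), NA)))
}

# Flat background with one elevated segment.
map_with_peak <- function(L = 1e6, bg = 1, peak = 20,
                          p_start = 5e5, p_width = 4000, chrom = "chr1") {
  genetic_map(data.frame(
    chrom = chrom,
    pos = c(1, p_start + 1, p_start + p_width + 1, L + 1),
    rate = c(bg, peak, bg, NA)))
}

random_intervals <- function(n, L, w, chrom = "chr1") {
  s <- floor(runif(n) * (L - w))
  interval_set(chrom, s, s + w)
}

random_seqs <- function(n, len, probs = rep(0.25, 4)) {
  Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, probs), collapse = ""),
    character(1)))
}

# Brute-force overlap count between two interval data.frames (quadratic
# oracle, deliberately naive).
brute_overlap_count <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && a$end[i] > b$start[j]) hit <- TRUE
    }
    if (hit) n <- n + 1L
  }
  n
}

# Small simulated world reused by the bgc/matching module tests.
.fixture_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(seed = 42, chrom_length = 3e6, n_islands = 80,
                      n_hotspots = 30, n_genes = 40, n_repeats = 60,
                      bias_b = 0.7, mutation_rate = 0.005)
    g <- simulate_genome(cfg)
    m <- simulate_map(cfg, g$islands)
    p <- simulate_polymorphisms(cfg, g$genome, m$hotspots)
    .fixture_cache$sim <- c(g, list(cfg = cfg, map = m$map,
                                    truth = m$hotspots, snps = p))
  }
  .fixture_cache$sim
}
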