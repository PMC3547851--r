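test_that("window tiling assigns every SNP to one tile and drops sparse tiles", {
  m <- data.frame(chrom = "1",
                  snp_id = sprintf("s%d", 1:4),
                  pos_bp = c(100e3, 200e3, 300e3, 400e3),
                  ref = "A", alt = "C")
  w <- build_windows(m, scan_config())
  expect_equal(nrow(w), 1)
  expect_equal(w$n_snps, 4L)
  expect_equal(w$start_bp, 1)
  expect_equal(w$end_bp, 500001)
  expect_equal(w$center_bp, 250001)

  # 3 SNPs in a tile: dropped
  w3 <- build_windows(m[1:3, ], scan_config())
  expect_equal(nrow(w3), 0)

  # 1.2 Mb map: tiles [1,500001), [500001,1000001), [1000001,1500001)
  set.seed(8)
  pos <- sort(c(sample(1:499000, 6), sample(500001:999000, 5),
                sample(1000001:1200000, 4)))
  m2 <- data.frame(chrom = "5", snp_id = sprintf("t%02d", 1:15),
                   pos_bp = pos, ref = "A", alt = "C")
  w2 <- build_windows(m2, scan_config())
  expect_equal(nrow(w2), 3)
  expect_equal(w2$n_snps, c(6L, 5L, 4L))
  expect_equal(sort(unlist(w2$snp_idx)), 1:15)

  expect_equal(nrow(build_windows(m[0, ], scan_config())), 0)
})

test_that("window F_ST hits the fixation and no-divergence limits", {
  m <- data.frame(chrom = "1", snp_id = sprintf("s%d", 1:4),
                  pos_bp = (1:4) * 1e4, ref = "A", alt = "C")
  s <- data.frame(sample_id = sprintf("i%02d", 1:20),
                  breed = rep(c("P", "Q"), each = 10))
  # opposite fixation, no heterozygotes
  g <- rbind(matrix(0L, 10, 4), matrix(2L, 10, 4))
  w <- build_windows(m, scan_config())
  fst <- window_fst(genotype_dataset(g, m, s), w)
  expect_equal(fst$fst, 1)

  # identical genotype counts in both breeds -> fst <= 0
  gg <- rbind(matrix(rep(c(0L, 1L, 2L, 1L), each = 10), 10, 4),
              matrix(rep(c(0L, 1L, 2L, 1L), each = 10), 10, 4))
  fst2 <- window_fst(genotype_dataset(gg, m, s), w)
  expect_lte(fst2$fst, 0)
})

test_that("window F_ST equals the brute-force Weir-Cockerham oracle", {
  # fixed 2 x 20 x 6 instance
  set.seed(12)
  m <- data.frame(chrom = "1", snp_id = sprintf("s%d", 1:6),
                  pos_bp = (1:6) * 1e4, ref = "A", alt = "C")
  s <- data.frame(sample_id = sprintf("i%02d", 1:40),
                  breed = rep(c("P", "Q"), each = 20))
  g <- rbind(matrix(rbinom(120, 2, 0.3), 20, 6),
             matrix(rbinom(120, 2, 0.6), 20, 6))
  ds <- genotype_dataset(g, m, s)
  w <- build_windows(m, scan_config(min_snps_per_window = 4))
  fst <- window_fst(ds, w)
  expect_equal(fst$fst, wc_window_oracle(g[1:20, ], g[21:40, ]),
               tolerance = 1e-12)

  # property: random small instances, unequal sizes, missing calls
  for (rep in 1:20) {
    set.seed(1000 + rep)
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    S <- sample(4:10, 1)
    mm <- data.frame(chrom = "1", snp_id = sprintf("r%d", seq_len(S)),
                     pos_bp = seq_len(S) * 1e4, ref = "A", alt = "C")
    ss <- data.frame(sample_id = sprintf("x%02d", seq_len(n1 + n2)),
                     breed = rep(c("A1", "B1"), c(n1, n2)))
    gg <- matrix(rbinom((n1 + n2) * S, 2, runif(1, 0.1, 0.9)),
                 n1 + n2, S)
    gg[matrix(runif((n1 + n2) * S) < 0.1, n1 + n2, S)] <- NA_integer_
    dss <- genotype_dataset(gg, mm, ss)
    ww <- build_windows(mm, scan_config(min_snps_per_window = 1))
    got <- window_fst(dss, ww)$fst
    want <- wc_window_oracle(gg[seq_len(n1), , drop = FALSE],
                             gg[n1 + seq_len(n2), , drop = FALSE])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("genome stats summarize exactly the defined windows of each pair", {
  fst <- data.frame(window_id = rep(1:3, 2),
                    breed_a = rep(c("A", "A"), each = 3),
                    breed_b = rep(c("B", "C"), each = 3),
                    n_snps_used = 4L,
                    fst = c(0.0, 0.1, 0.2, 0.15, NA, 0.05))
  gs <- genome_stats(fst)
  ab <- gs[gs$breed_b == "B", ]
  expect_equal(ab$mean_fst, 0.1)
  expect_equal(ab$sd_fst, 0.1)
  expect_equal(ab$n_windows_used, 3L)
  ac <- gs[gs$breed_b == "C", ]
  expect_equal(ac$mean_fst, 0.1)
  expect_equal(ac$n_windows_used, 2L)

  # constant fst: sd 0 (degenerate, flagged downstream)
  const <- data.frame(window_id = 1:3, breed_a = "A", breed_b = "B",
                      n_snps_used = 4L, fst = 0.1)
  gsc <- genome_stats(const)
  expect_equal(gsc$mean_fst, 0.1)
  expect_equal(gsc$sd_fst, 0)
  di <- compute_di(const, gsc)
  expect_true(all(is.na(di$di)))
  expect_true(all(!di$complete))

  # < 2 defined windows: warning, sd NA
  single <- data.frame(window_id = 1:2, breed_a = "A", breed_b = "B",
                       n_snps_used = 4L, fst = c(0.1, NA))
  expect_warning(gs1 <- genome_stats(single), "< 2 defined windows")
  expect_true(is.na(gs1$sd_fst))
})

test_that("d_i matches hand arithmetic and collapses to symmetry for 2 breeds", {
  # 3 breeds, window 1 with fst {AB:0.30, AC:0.10, BC:0.05},
  # genome means all 0.10, sds all 0.05 -> d_A=4, d_B=3, d_C=-1
  fst <- data.frame(window_id = 1L,
                    breed_a = c("A", "A", "B"),
                    breed_b = c("B", "C", "C"),
                    n_snps_used = 4L,
                    fst = c(0.30, 0.10, 0.05))
  stats <- data.frame(breed_a = c("A", "A", "B"),
                      breed_b = c("B", "C", "C"),
                      mean_fst = 0.10, sd_fst = 0.05,
                      n_windows_used = 100L)
  di <- compute_di(fst, stats)
  expect_equal(di$di[di$breed == "A"], 4.0)
  expect_equal(di$di[di$breed == "B"], 3.0)
  expect_equal(di$di[di$breed == "C"], -1.0)
  expect_true(all(di$complete))

  # fst equal to the genome mean everywhere -> d_i = 0
  fst0 <- fst; fst0$fst <- 0.10
  expect_true(all(compute_di(fst0, stats)$di == 0))

  # exactly two breeds: d_1 = d_2 per window
  sim <- simulate_breeds(sim_config(n_breeds = 2, samples_per_breed = 12,
                                    n_chromosomes = 2,
                                    chromosome_length_bp = 8e6,
                                    n_snps = 600, breed_f = 0.1,
                                    missing_rate = 0, seed = 13))
  w <- build_windows(sim$genotypes$markers, scan_config())
  f2 <- window_fst(sim$genotypes, w)
  d2 <- compute_di(f2, genome_stats(f2))
  expect_equal(d2$di[d2$breed == "breed01"], d2$di[d2$breed == "breed02"])
})

test_that("per-breed mean d_i over fully defined windows is zero", {
  sim <- simulate_breeds(sim_config(n_breeds = 4, samples_per_breed = 12,
                                    n_chromosomes = 3,
                                    chromosome_length_bp = 10e6,
                                    n_snps = 1200, breed_f = 0.15,
                                    missing_rate = 0.01, seed = 19))
  w <- build_windows(sim$genotypes$markers, scan_config())
  fst <- window_fst(sim$genotypes, w)
  di <- compute_di(fst, genome_stats(fst))
  full <- di[di$complete, ]
  means <- tapply(full$di, full$breed, mean)
  expect_true(all(abs(means) < 1e-8))
})

test_that("the empirical-percentile rule flags ceil(0.01 W) windows with positional ties", {
  mk_di <- function(vals) {
    data.frame(window_id = seq_along(vals), breed = "X", di = vals,
               n_pairs_used = 1L, n_pairs_total = 1L, complete = TRUE)
  }
  set.seed(3)
  cs <- call_significant(mk_di(runif(100)), scan_config())
  expect_equal(sum(cs$di_table$significant), 1)
  expect_equal(cs$di_table$window_id[cs$di_table$significant],
               which.max(cs$di_table$di))

  cs250 <- call_significant(mk_di(runif(250)), scan_config())
  expect_equal(cs250$thresholds$k, 3L)

  # ties at the cut broken by window order
  tied <- mk_di(c(5, 5, 5, rep(0, 197)))
  cst <- call_significant(tied, scan_config())
  expect_equal(cst$thresholds$k, 2L)
  expect_equal(which(cst$di_table$significant), c(1L, 2L))
})

test_that("an injected sweep makes its window the breed d_i maximum (small-scale)", {
  hits <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    sim <- simulate_breeds(sim_config(n_breeds = 5, samples_per_breed = 20,
                                      n_chromosomes = 4,
                                      chromosome_length_bp = 15e6,
                                      n_snps = 2400, breed_f = 0.1,
                                      missing_rate = 0, seed = 500 + r))
    set.seed(600 + r)
    sw <- inject_sweep(sim$phased,
                       sweep_spec("breed01", "2", 5e6, 7e6, q = 0.95))
    ds <- collapse_phased(sw$phased)
    w <- build_windows(ds$markers, scan_config())
    fst <- window_fst(ds, w)
    di <- compute_di(fst, genome_stats(fst))
    d1 <- di[di$breed == "breed01" & !is.na(di$di), ]
    top <- w[w$window_id == d1$window_id[which.max(d1$di)], ]
    if (top$chrom == "2" && top$start_bp < 7e6 && top$end_bp > 5e6)
      hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.75 * n_rep))
})
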