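toy_window <- function(snp_idx) list(snp_idx = list(snp_idx))

test_that("window haplotype frequencies are exact rational counts summing to 1", {
  # 4 chromosomes (2 samples), two distinct haplotypes 3:1
  h <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  ph <- phased_from_matrix(h, "P")
  hf <- window_haplotype_frequencies(ph, toy_window(1:3), "P")
  expect_equal(hf$frequency, c(0.75, 0.25))
  expect_equal(hf$haplotype, c("101", "011"))
  expect_equal(sum(hf$frequency), 1)

  # all chromosomes identical -> single haplotype at 1.0
  mono <- phased_from_matrix(matrix(1L, 4, 3), "P")
  hfm <- window_haplotype_frequencies(mono, toy_window(1:3), "P")
  expect_equal(nrow(hfm), 1)
  expect_equal(hfm$frequency, 1.0)

  # absent breed -> empty table
  expect_equal(nrow(window_haplotype_frequencies(ph, toy_window(1:3), "Q")),
               0)

  # random panels always sum to exactly 1
  for (r in 1:10) {
    set.seed(700 + r)
    hr <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6)
    phr <- phased_from_matrix(hr, c("P", "Q"))
    s <- window_haplotype_frequencies(phr, toy_window(2:5), "P")
    expect_identical(sum(s$frequency), 1)
  }
})

test_that("core haplotype extension stops where carriers diverge and is maximal", {
  # 10 chromosomes; seed window SNPs 5:6; carriers (8 chrs) share alleles
  # out to SNPs 3..8; at SNP 2 carriers split 4/4 so extension past 3
  # drops frequency to 0.4 < 0.5; right side closes at 9 (split 4/4)
  n_chr <- 10; S <- 10
  h <- matrix(0L, n_chr, S)
  h[9:10, 5:6] <- 1L            # non-carriers differ inside the seed
  h[1:4, 2] <- 1L               # carriers split at SNP 2
  h[5:8, 9] <- 1L               # carriers split at SNP 9
  ph <- phased_from_matrix(h, c("P", "P", "P", "P", "P"))
  rec <- extend_core_haplotype(ph, toy_window(5:6), "P", f_min = 0.5)
  expect_equal(rec$snp_from, 3L)
  expect_equal(rec$snp_to, 8L)
  expect_equal(rec$frequency, 0.8)
  expect_equal(rec$n_snps, 6L)
  expect_equal(rec$length_bp, 5000L)

  # exhaustive one-SNP maximality: either allele on either open side
  # keeps fewer than f_min * 2N carriers
  target <- paste(rec$alleles, collapse = "")
  all_h <- apply(ph$haplotypes, 1, function(x)
    paste(x[rec$snp_from:rec$snp_to], collapse = ""))
  carriers <- sum(all_h == target)
  for (side in c(rec$snp_from - 1L, rec$snp_to + 1L)) {
    for (allele in 0:1) {
      ext <- sum(all_h == target &
                   ph$haplotypes[, side] == allele)
      expect_lt(ext, 0.5 * n_chr)
    }
  }
})

test_that("extension spans the whole chromosome for a monomorphic breed", {
  h <- rbind(matrix(1L, 6, 8),                 # breed P: monomorphic
             matrix(rep(c(0L, 1L), 8), 2, 8))  # breed Q: noise
  ph <- phased_from_matrix(h, c(rep("P", 3), "Q"))
  rec <- extend_core_haplotype(ph, toy_window(4:5), "P", f_min = 0.5)
  expect_equal(rec$snp_from, 1L)
  expect_equal(rec$snp_to, 8L)
  expect_equal(rec$frequency, 1.0)
})

test_that("f_min = 1 with a discordant adjacent chromosome keeps the seed extent", {
  h <- matrix(1L, 4, 5)
  h[4, 2] <- 0L  # one chromosome breaks perfect sharing left of the seed
  h[4, 5] <- 0L  # and right of it
  ph <- phased_from_matrix(h, "P")
  rec <- extend_core_haplotype(ph, toy_window(3:4), "P", f_min = 1.0)
  expect_equal(rec$snp_from, 3L)
  expect_equal(rec$snp_to, 4L)

  # seed modal frequency below f_min -> no record
  h2 <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L), c(0L, 1L))
  ph2 <- phased_from_matrix(h2, "P")
  expect_null(extend_core_haplotype(ph2, toy_window(1:2), "P", f_min = 0.6))
})

test_that("cross-breed frequencies count exact matches, pooled over non-excluded breeds", {
  # 3 breeds x 2 samples = 4 chromosomes each; haplotype 11 planted in
  # 4/4 of P, 1/4 of Q, 0/4 of R
  h <- rbind(matrix(1L, 4, 2),
             rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L), c(1L, 0L)),
             matrix(0L, 4, 2))
  ph <- phased_from_matrix(h, c("P", "P", "Q", "Q", "R", "R"))
  rec <- extend_core_haplotype(ph, toy_window(1:2), "P", f_min = 0.5)
  fr <- haplotype_frequency_across_breeds(ph, rec)
  expect_equal(fr$by_breed$frequency[fr$by_breed$breed == "P"], 1.0)
  expect_equal(fr$by_breed$frequency[fr$by_breed$breed == "Q"], 0.25)
  expect_equal(fr$by_breed$frequency[fr$by_breed$breed == "R"], 0.0)
  expect_equal(fr$other_breeds$count, 1)
  expect_equal(fr$other_breeds$n_chromosomes, 8)
  expect_equal(fr$other_breeds$frequency, 1 / 8)
})

test_that("planted sweep haplotypes are recovered at the target frequency", {
  sim <- simulate_breeds(sim_config(n_breeds = 3, samples_per_breed = 20,
                                    n_chromosomes = 2,
                                    chromosome_length_bp = 10e6,
                                    n_snps = 800, breed_f = 0.1,
                                    missing_rate = 0, seed = 23))
  set.seed(24)
  sw <- inject_sweep(sim$phased, sweep_spec("breed02", "1", 2e6, 4e6,
                                            q = 0.9))
  rec <- list(snp_from = min(sw$snp_cols), snp_to = max(sw$snp_cols),
              alleles = sw$founder, breed = "breed02")
  fr <- haplotype_frequency_across_breeds(sw$phased, rec)
  got <- fr$by_breed$frequency[fr$by_breed$breed == "breed02"]
  expect_equal(got, 36 / 40)  # round(0.9 * 40) carriers, exactly
  # non-target breeds essentially never share a 2 Mb exact haplotype
  expect_lt(fr$other_breeds$frequency, 0.05)
})

test_that("variant-haplotype concordance reproduces count arithmetic", {
  # 264 chromosomes, haplotype on 240, variant on 230 of those
  carrier <- rep(c(TRUE, FALSE), c(240, 24))
  variant <- rep(c(TRUE, FALSE, TRUE, FALSE), c(230, 10, 2, 22))
  conc <- variant_haplotype_concordance(carrier, variant)
  expect_equal(round(conc$percent_on_haplotype, 1), 95.8)
  expect_equal(conc$n_haplotype, 240)
  expect_equal(conc$n_concordant, 230)
  expect_lt(conc$p_value, 0.001)

  # invariant to chromosome ordering
  set.seed(42)
  perm <- sample(length(carrier))
  conc_p <- variant_haplotype_concordance(carrier[perm], variant[perm])
  expect_equal(conc_p$percent_on_haplotype, conc$percent_on_haplotype)
  expect_equal(conc_p$p_value, conc$p_value)

  # perfect concordance
  v <- rep(c(TRUE, FALSE), each = 30)
  pc <- variant_haplotype_concordance(v, v)
  expect_equal(pc$percent_on_haplotype, 100)
  expect_lt(pc$p_value, 1e-10)

  # no haplotype-positive chromosomes
  expect_warning(
    und <- variant_haplotype_concordance(rep(FALSE, 10),
                                         rep(TRUE, 10)),
    "undefined")
  expect_true(is.na(und$percent_on_haplotype))
})

test_that("independent vectors give null-like Fisher p-values", {
  set.seed(31)
  reject <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    a <- runif(200) < 0.5
    b <- runif(200) < 0.5
    p <- variant_haplotype_concordance(a, b)$p_value
    if (p < 0.05) reject <- reject + 1L
  }
  expect_lte(reject / n_rep, 0.08)
})

test_that("allele frequency from genotype counts follows the 2n arithmetic", {
  expect_equal(round(allele_frequency_from_counts(309, 51, 29), 2), 0.86)
  expect_equal(allele_frequency_from_counts(0, 0, 25), 0)
  expect_equal(round(allele_frequency_from_counts(61, 40, 11), 3), 0.723)
  expect_error(allele_frequency_from_counts(0, 0, 0), "zero")
})

test_that("phased TSV round trip preserves haplotypes and breed labels", {
  set.seed(9)
  h <- matrix(rbinom(12 * 6, 1, 0.4), 12, 6)
  ph <- phased_from_matrix(h, c("P", "Q", "R"))
  td <- withr::local_tempdir()
  write_phased(ph, file.path(td, "hap.tsv"))
  back <- read_phased(file.path(td, "hap.tsv"), "tsv")
  expect_equal(unname(back$haplotypes), unname(ph$haplotypes))
  expect_equal(back$samples$breed, ph$samples$breed)
  expect_equal(back$markers, ph$markers)
})
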