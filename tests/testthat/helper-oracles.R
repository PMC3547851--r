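# Independent scalar oracle for the two-population Weir-Cockerham (1984)
# theta, written directly from the variance-component equations in their
# general r-population form, from raw genotype vectors. Window estimate
# is the ratio of averages over SNPs. Deliberately loop-based and kept
# separate from the package's vectorized implementation.
wc_window_oracle <- function(g1, g2) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  r <- 2
  sum_a <- 0; sum_abc <- 0
  for (j in seq_len(ncol(g1))) {
    x1 <- g1[, j]; x1 <- x1[!is.na(x1)]
    x2 <- g2[, j]; x2 <- x2[!is.na(x2)]
    n <- c(length(x1), length(x2))
    if (any(n < 2)) next
    p <- c(sum(x1) / (2 * n[1]), sum(x2) / (2 * n[2]))
    h <- c(mean(x1 == 1), mean(x2 == 1))
    n_bar <- mean(n)
    n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n * p) / (r * n_bar)
    if (p_bar <= 0 || p_bar >= 1) next
    s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n * h) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
         (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  if (sum_abc == 0) return(NA_real_)
  sum_a / sum_abc
}

# Panel sizes of a 33-breed, 744-horse reference cohort
study_breed_sizes <- c(
  `Akhal Teke` = 19, Andalusian = 18, Arabian = 24, Belgian = 30,
  `Caspian Pony` = 18, Clydesdale = 24, Exmoor = 24, `Fell Pony` = 21,
  Finnhorse = 27, `Franches-Montagnes` = 19, `French Trotter` = 17,
  Hanoverian = 15, Icelandic = 25, `Mangalarga Paulista` = 15,
  Miniature = 21, Mongolian = 19, Morgan = 40, `New Forest Pony` = 15,
  `North Swedish Horse` = 19, `Norwegian Fjord` = 21, Paint = 25,
  Percheron = 23, `Peruvian Paso` = 21, `Puerto Rican Paso Fino` = 20,
  `Quarter Horse` = 40, Saddlebred = 25, Shetland = 27, Shire = 23,
  Standardbred = 25, `Swiss Warmblood` = 14,
  `Tennessee Walking Horse` = 19, Thoroughbred = 36, Tuva = 15)

# Tiny dataset with given breed sizes and trivial genotypes
dataset_with_breed_sizes <- function(sizes) {
  n <- sum(sizes)
  markers <- data.frame(chrom = "1", snp_id = c("s1", "s2"),
                        pos_bp = c(1000L, 2000L), ref = "A", alt = "C")
  samples <- data.frame(
    sample_id = sprintf("h%04d", seq_len(n)),
    breed = rep(names(sizes), sizes))
  g <- matrix(rep(c(0L, 1L), length.out = 2L * n), n, 2)
  genotype_dataset(g, markers, samples)
}

# Small random dataset for IO round trips
random_dataset <- function(n_samples = 5, n_snps = 10, seed = 99,
                           missing_rate = 0.1) {
  set.seed(seed)
  markers <- data.frame(chrom = rep("2", n_snps),
                        snp_id = sprintf("rs%03d", seq_len(n_snps)),
                        pos_bp = sort(sample.int(1e6, n_snps)),
                        ref = "G", alt = "T")
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n_samples)),
                        breed = rep(c("alpha", "beta"),
                                    length.out = n_samples),
                        sex = sample(c("F", "M", NA), n_samples,
                                     replace = TRUE),
                        age = NA_real_)
  g <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
              n_samples, n_snps)
  g[matrix(runif(n_samples * n_snps) < missing_rate,
           n_samples, n_snps)] <- NA_integer_
  genotype_dataset(g, markers, samples)
}

# Phased panel from an explicit chromosome x SNP 0/1 matrix
phased_from_matrix <- function(h, breeds, chrom = "1",
                               pos = NULL) {
  n <- nrow(h) / 2
  S <- ncol(h)
  if (is.null(pos)) pos <- seq_len(S) * 1000L
  markers <- data.frame(chrom = chrom, snp_id = sprintf("p%03d", seq_len(S)),
                        pos_bp = pos, ref = "A", alt = "C")
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        breed = rep(breeds, length.out = n))
  phased_dataset(h, markers, samples)
}
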