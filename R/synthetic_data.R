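#' Configuration for the multi-breed genotype simulator
#'
#' Defaults emulate a multi-breed SNP-array panel of the kind the scan is
#' designed for: 33 breeds of ~22 diploids each, ~23,400 informative
#' SNPs placed uniformly over 31 autosomes of 75 Mb (about 5 SNPs per
#' 500-kb tile), ancestral allele frequencies uniform on (0.05, 0.95),
#' per-breed drift parameters uniform on (0.05, 0.25) — the range of
#' breed differentiation typical of domestic horse breeds — and a 1%
#' missing-call rate typical of array data. Tests and examples pass
#' smaller values explicitly.
#'
#' @param n_breeds number of breed populations (default 33).
#' @param samples_per_breed diploids per breed; scalar or length
#'   `n_breeds` vector (default 22).
#' @param n_chromosomes autosome count (default 31).
#' @param chromosome_length_bp length of every autosome (default 75 Mb).
#' @param n_snps total SNPs, placed uniformly at random over the genome
#'   (default 23,400).
#' @param ancestral_maf_range range of the uniform ancestral allele
#'   frequency (default `c(0.05, 0.95)`).
#' @param breed_f per-breed drift parameter F; scalar, length-`n_breeds`
#'   vector, or range `c(lo, hi)` to draw each breed's F uniformly
#'   (default `c(0.05, 0.25)`).
#' @param missing_rate fraction of genotype calls masked as missing in
#'   the unphased dataset (default 0.01).
#' @param seed integer seed fixing all downstream randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 33, samples_per_breed = 22,
                       n_chromosomes = 31, chromosome_length_bp = 75e6,
                       n_snps = 23400,
                       ancestral_maf_range = c(0.05, 0.95),
                       breed_f = c(0.05, 0.25),
                       missing_rate = 0.01, seed = 1L) {
  stopifnot(n_breeds >= 1, all(samples_per_breed >= 1), n_chromosomes >= 1,
            chromosome_length_bp > 0, n_snps >= 1,
            length(ancestral_maf_range) == 2,
            all(breed_f > 0), all(breed_f < 1),
            missing_rate >= 0, missing_rate < 1)
  if (!length(samples_per_breed) %in% c(1L, n_breeds))
    stop("samples_per_breed must be scalar or one value per breed")
  structure(list(n_breeds = as.integer(n_breeds),
                 samples_per_breed = rep(as.integer(samples_per_breed),
                                         length.out = n_breeds),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 n_snps = as.integer(n_snps),
                 ancestral_maf_range = ancestral_maf_range,
                 breed_f = breed_f,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate differentiated breed populations (Balding-Nichols model)
#'
#' Per SNP, an ancestral allele frequency `p` is drawn uniformly from the
#' configured range; each breed's frequency is then drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, whose mean is `p` and
#' whose spread around it grows with the breed's drift parameter `F`
#' (the expected per-breed F_ST against the ancestral pool). Chromosomes
#' are drawn as independent Bernoulli strings — truth phase is known by
#' construction — and genotypes are the per-sample chromosome sums, with
#' missing calls masked only in the unphased copy. SNPs are independent:
#' there is no background LD; sweep-like LD is added explicitly by
#' [inject_sweep()].
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_dataset()]), `phased` (the
#'   [phased_dataset()] truth, no missingness), and `breed_f` (the
#'   realized per-breed F values).
#' @examples
#' sim <- simulate_breeds(sim_config(n_breeds = 2, samples_per_breed = 10,
#'                                   n_chromosomes = 2, n_snps = 100,
#'                                   seed = 42))
#' summarize_genotypes(sim$genotypes)
#' @export
simulate_breeds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_snps
  B <- config$n_breeds
  # uniform marker placement, distinct positions within chromosome
  chrom <- sort(sample.int(config$n_chromosomes, S, replace = TRUE))
  pos <- integer(S)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(config$chromosome_length_bp, length(idx)))
  }
  markers <- data.frame(chrom = as.character(chrom),
                        snp_id = sprintf("snp%06d", seq_len(S)),
                        pos_bp = pos, ref = "A", alt = "C",
                        stringsAsFactors = FALSE)

  f <- config$breed_f
  breed_f <- if (length(f) == B) f else if (length(f) == 1) rep(f, B) else
    stats::runif(B, f[1], f[2])
  p_anc <- stats::runif(S, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])

  n_per <- config$samples_per_breed
  breeds <- sprintf("breed%02d", seq_len(B))
  hap_rows <- vector("list", B)
  for (b in seq_len(B)) {
    Fb <- breed_f[b]
    shape_scale <- (1 - Fb) / Fb
    p_b <- stats::rbeta(S, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    n_chr <- 2L * n_per[b]
    hap_rows[[b]] <- matrix(
      stats::rbinom(n_chr * S, 1L, rep(p_b, each = n_chr)), n_chr, S)
  }
  h <- do.call(rbind, hap_rows)
  samples <- data.frame(
    sample_id = sprintf("%s_h%03d", rep(breeds, n_per),
                        unlist(lapply(n_per, seq_len))),
    breed = rep(breeds, n_per),
    sex = sample(c("F", "M"), sum(n_per), replace = TRUE),
    age = round(stats::runif(sum(n_per), 2, 20), 1),
    stringsAsFactors = FALSE)
  phased <- phased_dataset(h, markers, samples)
  genotypes <- collapse_phased(phased, missing_rate = config$missing_rate)
  list(genotypes = genotypes, phased = phased, breed_f = breed_f)
}

#' Specify a selective sweep to inject
#'
#' @param breeds target breed label(s).
#' @param chrom chromosome label.
#' @param start_bp,end_bp interval (inclusive of SNPs at these positions).
#' @param q target carrier frequency in the target breed(s), in (0, 1].
#' @param founder optional 0/1 founder haplotype over the interval's
#'   SNPs; default: the majority-allele haplotype of the first target
#'   breed.
#' @return list of class `sweep_spec`.
#' @export
sweep_spec <- function(breeds, chrom, start_bp, end_bp, q, founder = NULL) {
  stopifnot(q > 0, q <= 1, end_bp >= start_bp)
  structure(list(breeds = breeds, chrom = as.character(chrom),
                 start_bp = start_bp, end_bp = end_bp, q = q,
                 founder = founder),
            class = "sweep_spec")
}

#' Inject a breed-restricted swept haplotype
#'
#' In each target breed, exactly `round(q * 2N)` chromosomes — chosen at
#' random from the current RNG stream — have the interval overwritten
#' with the founder haplotype. The deterministic carrier count makes
#' haplotype-frequency assertions exact. Other breeds are untouched.
#'
#' @param phased a [phased_dataset()].
#' @param spec a [sweep_spec()].
#' @return list with `phased` (modified), `snp_cols` (interval marker
#'   indices), `founder` (the haplotype used), and `carriers` (data.frame
#'   `breed`, `n_chromosomes`, `n_carriers`).
#' @export
inject_sweep <- function(phased, spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  m <- phased$markers
  cols <- which(m$chrom == spec$chrom & m$pos_bp >= spec$start_bp &
                  m$pos_bp <= spec$end_bp)
  if (length(cols) == 0)
    stop("sweep interval chr", spec$chrom, ":", spec$start_bp, "-",
         spec$end_bp, " contains no SNPs")
  rb <- .row_breed(phased)
  founder <- spec$founder
  if (is.null(founder)) {
    rows0 <- which(rb == spec$breeds[1])
    founder <- as.integer(colMeans(
      phased$haplotypes[rows0, cols, drop = FALSE]) >= 0.5)
  }
  if (length(founder) != length(cols))
    stop("founder haplotype length ", length(founder),
         " != interval SNP count ", length(cols))
  carriers <- list()
  for (b in spec$breeds) {
    rows <- which(rb == b)
    if (length(rows) == 0) stop("breed not present: ", b)
    n_car <- round(spec$q * length(rows))
    chosen <- sample(rows, n_car)
    phased$haplotypes[chosen, cols] <-
      matrix(founder, n_car, length(cols), byrow = TRUE)
    carriers[[b]] <- data.frame(breed = b, n_chromosomes = length(rows),
                                n_carriers = n_car, stringsAsFactors = FALSE)
  }
  list(phased = phased, snp_cols = cols, founder = founder,
       carriers = do.call(rbind, carriers))
}

#' Append related samples to a genotype dataset
#'
#' Builds fixtures for relatedness pruning: duplicates copy an existing
#' sample's genotypes; parent-offspring and full-sib samples are created
#' by Mendelian gamete sampling — at each SNP a parent transmits one of
#' its two alleles at random (a missing parental genotype transmits an
#' allele drawn from the breed frequency). New samples join the parents'
#' breed; truth relationships are recorded.
#'
#' @param dataset a [genotype_dataset()].
#' @param n_pairs number of related pairs to create.
#' @param relationship `"parent_offspring"`, `"full_sib"`, or
#'   `"duplicate"`.
#' @return list with `dataset` (augmented) and `truth` (data.frame
#'   `sample_a`, `sample_b`, `relationship`; for parent-offspring the
#'   pair is parent and child, for full sibs the two children).
#' @export
add_relatives <- function(dataset, n_pairs,
                          relationship = c("parent_offspring", "full_sib",
                                           "duplicate")) {
  relationship <- match.arg(relationship)
  validate_genotype_dataset(dataset)
  s <- dataset$samples
  g <- dataset$genotypes
  S <- ncol(g)

  gamete <- function(parent_g, p_breed) {
    a <- ifelse(is.na(parent_g),
                stats::rbinom(S, 1L, p_breed),
                stats::rbinom(S, 1L, parent_g / 2))
    as.integer(a)
  }

  new_rows <- list(); new_samples <- list(); truth <- list()
  breeds <- unique(s$breed)
  for (k in seq_len(n_pairs)) {
    b <- breeds[1 + (k - 1) %% length(breeds)]
    idx <- which(s$breed == b)
    if (length(idx) < 2) stop("breed ", b, " has < 2 samples to parent from")
    p_breed <- .alt_freq(g[idx, , drop = FALSE])
    p_breed[is.na(p_breed)] <- 0.5
    pick <- sample(idx, 2)
    if (relationship == "duplicate") {
      id_new <- sprintf("dup%03d", k)
      new_rows[[length(new_rows) + 1L]] <- g[pick[1], ]
      new_samples[[length(new_samples) + 1L]] <-
        data.frame(sample_id = id_new, breed = b, sex = s$sex[pick[1]],
                   age = s$age[pick[1]], stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(sample_a = s$sample_id[pick[1]],
                               sample_b = id_new,
                               relationship = relationship,
                               stringsAsFactors = FALSE)
    } else if (relationship == "parent_offspring") {
      child <- gamete(g[pick[1], ], p_breed) + gamete(g[pick[2], ], p_breed)
      id_new <- sprintf("child%03d", k)
      new_rows[[length(new_rows) + 1L]] <- child
      new_samples[[length(new_samples) + 1L]] <-
        data.frame(sample_id = id_new, breed = b,
                   sex = sample(c("F", "M"), 1), age = NA_real_,
                   stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(sample_a = s$sample_id[pick[1]],
                               sample_b = id_new,
                               relationship = relationship,
                               stringsAsFactors = FALSE)
    } else { # full_sib: two new children of the same two parents
      sib1 <- gamete(g[pick[1], ], p_breed) + gamete(g[pick[2], ], p_breed)
      sib2 <- gamete(g[pick[1], ], p_breed) + gamete(g[pick[2], ], p_breed)
      id1 <- sprintf("sibA%03d", k); id2 <- sprintf("sibB%03d", k)
      new_rows[[length(new_rows) + 1L]] <- sib1
      new_rows[[length(new_rows) + 1L]] <- sib2
      new_samples[[length(new_samples) + 1L]] <-
        data.frame(sample_id = c(id1, id2), breed = b,
                   sex = sample(c("F", "M"), 2, replace = TRUE),
                   age = NA_real_, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(sample_a = id1, sample_b = id2,
                               relationship = relationship,
                               stringsAsFactors = FALSE)
    }
  }
  g_new <- rbind(g, do.call(rbind, new_rows))
  s_new <- rbind(s, do.call(rbind, new_samples))
  list(dataset = genotype_dataset(g_new, dataset$markers, s_new),
       truth = do.call(rbind, truth))
}

#' Configuration for the fiber-type phenotype simulator
#'
#' Defaults reproduce the design of a 79-horse biopsy cohort genotyped
#' for a candidate variant at genotype counts 18/31/30 (alt-allele count
#' 0/1/2), with genotype-0 baseline fiber proportions
#' (Type 1, 2A, 2B) = (20.4, 27.1, 52.5)%, additive effects per allele
#' copy of (-2.10, -1.69, +3.79) percentage points — the Type 2B gain
#' balancing the Type 1 and 2A losses so effects sum to zero — residual
#' standard deviation 6 percentage points per type, ages uniform on 2-20
#' years and a balanced sex ratio.
#'
#' @param genotype_counts horses per genotype level 0/1/2
#'   (default `c(18, 31, 30)`).
#' @param effects additive effect (percentage points per allele copy) on
#'   each fiber type, named or ordered (type1, type2a, type2b); must sum
#'   to 0 (default `c(-2.10, -1.69, 3.79)`).
#' @param baseline genotype-0 mean proportions, summing to 100
#'   (default `c(20.4, 27.1, 52.5)`).
#' @param residual_sd Gaussian residual sd in percentage points
#'   (default 6).
#' @param age_range uniform age range in years (default `c(2, 20)`).
#' @param prop_female fraction of females (default 0.5).
#' @param seed integer seed.
#' @return list of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(genotype_counts = c(18L, 31L, 30L),
                             effects = c(type1 = -2.10, type2a = -1.69,
                                         type2b = 3.79),
                             baseline = c(type1 = 20.4, type2a = 27.1,
                                          type2b = 52.5),
                             residual_sd = 6,
                             age_range = c(2, 20), prop_female = 0.5,
                             seed = 1L) {
  stopifnot(length(genotype_counts) == 3, all(genotype_counts >= 0),
            length(effects) == 3, length(baseline) == 3,
            residual_sd >= 0)
  if (abs(sum(effects)) > 1e-8)
    stop("additive effects must sum to 0 across the three fiber types")
  if (abs(sum(baseline) - 100) > 1e-6)
    stop("baseline proportions must sum to 100")
  structure(list(genotype_counts = as.integer(genotype_counts),
                 effects = effects, baseline = baseline,
                 residual_sd = residual_sd, age_range = age_range,
                 prop_female = prop_female, seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Simulate fiber-type phenotypes with additive genotype effects
#'
#' Per horse: proportions = baseline + effect * allele count + Gaussian
#' noise per type, clipped to `[0, 100]` and renormalized to sum 100;
#' age and sex are drawn per the config. Genotype counts are taken
#' literally (not resampled), so the design is identical across
#' replicates that share a config.
#'
#' @param config a [pheno_sim_config()].
#' @return a phenotype data.frame (see [validate_phenotypes()]) with
#'   genotype column `geno`.
#' @export
simulate_fiber_phenotypes <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  set.seed(config$seed)
  n <- sum(config$genotype_counts)
  geno <- rep(0:2, config$genotype_counts)
  raw <- matrix(rep(config$baseline, each = n), n, 3) +
    outer(geno, config$effects) +
    matrix(stats::rnorm(n * 3, 0, config$residual_sd), n, 3)
  raw <- pmin(pmax(raw, 0), 100)
  raw <- raw / rowSums(raw) * 100
  data.frame(id = sprintf("qh%03d", seq_len(n)),
             type1_pct = raw[, 1], type2a_pct = raw[, 2],
             type2b_pct = raw[, 3],
             age = round(stats::runif(n, config$age_range[1],
                                      config$age_range[2]), 1),
             sex = sample(c("F", "M"), n, replace = TRUE,
                          prob = c(config$prop_female,
                                   1 - config$prop_female)),
             geno = geno, stringsAsFactors = FALSE)
}
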