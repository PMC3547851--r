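#' Construct a genotype dataset
#'
#' Bundles a diploid alt-allele-count matrix with its marker map and
#' breed-labelled sample table. This is the substrate of every downstream
#' analysis: QC, relatedness pruning, the windowed F_ST / d_i scan.
#'
#' @param genotypes integer matrix, samples x SNPs, entries in \{0, 1, 2\}
#'   counting copies of the alt allele; `NA` marks a missing call.
#' @param markers data.frame with columns `chrom` (character, "1".."31"),
#'   `snp_id` (unique), `pos_bp` (integer, 1-based), `ref`, `alt`
#'   (single distinct characters). Positions must be strictly increasing
#'   within each chromosome.
#' @param samples data.frame with columns `sample_id` (unique), `breed`,
#'   and optionally `sex` (levels "F", "M", "G" for gelding) and `age`
#'   (years, non-negative).
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `markers`, `samples`.
#' @examples
#' m <- data.frame(chrom = "1", snp_id = c("s1", "s2"), pos_bp = c(100L, 200L),
#'                 ref = "A", alt = "C")
#' s <- data.frame(sample_id = c("h1", "h2"), breed = "Arabian")
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(s$sample_id, m$snp_id))
#' gd <- genotype_dataset(g, m, s)
#' @export
genotype_dataset <- function(genotypes, markers, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  markers <- as.data.frame(markers)
  samples <- as.data.frame(samples)
  if (is.null(samples$sex)) samples$sex <- rep(NA_character_, nrow(samples))
  if (is.null(samples$age)) samples$age <- rep(NA_real_, nrow(samples))
  markers$chrom <- as.character(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  obj <- structure(list(genotypes = genotypes, markers = markers,
                        samples = samples),
                   class = "genotype_dataset")
  validate_genotype_dataset(obj)
  dimnames(obj$genotypes) <- list(samples$sample_id, markers$snp_id)
  obj
}

validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  m <- x$markers; s <- x$samples; g <- x$genotypes
  req_m <- c("chrom", "snp_id", "pos_bp", "ref", "alt")
  if (!all(req_m %in% names(m)))
    stop("marker map must have columns: ", paste(req_m, collapse = ", "))
  if (!all(c("sample_id", "breed") %in% names(s)))
    stop("sample table must have columns: sample_id, breed")
  if (nrow(g) != nrow(s) || ncol(g) != nrow(m))
    stop("genotype matrix is ", nrow(g), " x ", ncol(g),
         " but there are ", nrow(s), " samples and ", nrow(m), " markers")
  bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  if (anyDuplicated(m$snp_id)) stop("snp_ids are not unique")
  if (anyDuplicated(s$sample_id)) stop("sample_ids are not unique")
  if (any(is.na(s$breed)) || any(s$breed == ""))
    stop("every sample needs a breed label")
  if (any(m$ref == m$alt)) stop("ref and alt alleles must differ")
  for (ch in unique(m$chrom)) {
    p <- m$pos_bp[m$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples,",
      length(unique(x$samples$breed)), "breeds,",
      nrow(x$markers), "SNPs on",
      length(unique(x$markers$chrom)), "chromosomes\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset by sample and/or SNP index
#'
#' @param x a `genotype_dataset`.
#' @param samples,snps integer or logical index vectors (default: keep all).
#' @return a `genotype_dataset` with the selected rows/columns; relative
#'   order is preserved.
#' @export
subset_dataset <- function(x, samples = seq_len(nrow(x$samples)),
                           snps = seq_len(nrow(x$markers))) {
  genotype_dataset(x$genotypes[samples, snps, drop = FALSE],
                   x$markers[snps, , drop = FALSE],
                   x$samples[samples, , drop = FALSE])
}

# PED sex code -> letter and back
.sex_to_ped <- function(sex) {
  out <- rep("0", length(sex))
  out[!is.na(sex) & sex == "M"] <- "1"
  out[!is.na(sex) & sex == "F"] <- "2"
  out
}
.sex_from_ped <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == "1"] <- "M"
  out[code == "2"] <- "F"
  out
}

#' Read diploid SNP genotypes from PLINK text or VCF files
#'
#' For `format = "ped_map"`, `path` is the file prefix: `<path>.ped` and
#' `<path>.map` are read. The breed label is taken from the family-ID
#' column. The MAP file may carry the usual four columns
#' (chrom, snp_id, cM, bp) or six (plus ref and alt alleles). With four
#' columns, ref/alt are inferred from the PED alleles: the pooled major
#' allele becomes ref (ties broken alphabetically). Genotypes are recoded
#' to alt-allele counts; the missing code `0 0` maps to `NA`.
#'
#' For `format = "vcf"`, `path` is a VCF 4.x file with GT fields
#' (parsed with \pkg{vcfR}); `./.` maps to `NA`. Breed labels come from
#' `sample_info` if given, otherwise from sample names of the form
#' `breed__sample` (the convention [write_genotypes()] uses).
#'
#' @param path file prefix (ped_map) or file name (vcf).
#' @param format `"ped_map"` or `"vcf"`.
#' @param sample_info optional data.frame (or TSV path) with columns
#'   `sample_id`, `breed` and optionally `sex`, `age`, used to label VCF
#'   samples.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "vcf"),
                           sample_info = NULL) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(path) else read_vcf(path, sample_info)
}

read_ped_map <- function(prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  for (f in c(ped_file, map_file)) if (!file.exists(f)) stop("no such file: ", f)

  map <- tryCatch(
    data.table::fread(map_file, header = FALSE, data.table = FALSE,
                      colClasses = "character"),
    error = function(e) stop("malformed MAP file ", map_file, ": ",
                             conditionMessage(e)))
  if (!ncol(map) %in% c(4L, 6L))
    stop("MAP file must have 4 or 6 columns, found ", ncol(map))
  markers <- data.frame(chrom = map[[1]], snp_id = map[[2]],
                        pos_bp = as.integer(map[[4]]),
                        ref = if (ncol(map) == 6) map[[5]] else NA_character_,
                        alt = if (ncol(map) == 6) map[[6]] else NA_character_,
                        stringsAsFactors = FALSE)
  n_snps <- nrow(markers)

  ped <- tryCatch(
    data.table::fread(ped_file, header = FALSE, data.table = FALSE,
                      colClasses = "character"),
    error = function(e) stop("malformed PED file ", ped_file, ": ",
                             conditionMessage(e)))
  if (ncol(ped) != 6L + 2L * n_snps)
    stop("PED/MAP mismatch: PED has ", ncol(ped), " columns but ",
         n_snps, " MAP SNPs imply ", 6L + 2L * n_snps)

  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_snps) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_snps), drop = FALSE])
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing)) {
    idx <- which(half_missing, arr.ind = TRUE)[1, ]
    stop("half-missing genotype in PED line ", idx[1], ", SNP ", idx[2])
  }

  if (anyNA(markers$ref)) {
    # infer ref = pooled major allele, alphabetical on ties
    for (j in seq_len(n_snps)) {
      al <- c(a1[, j], a2[, j])
      al <- al[al != "0"]
      tab <- sort(table(al), decreasing = TRUE)
      alleles <- names(tab)[order(-tab, names(tab))]
      if (length(alleles) == 0) alleles <- c("A", "C")
      if (length(alleles) == 1)
        alleles <- c(alleles, setdiff(c("A", "C"), alleles)[1])
      if (length(alleles) > 2)
        stop("SNP ", markers$snp_id[j], " has >2 alleles in PED")
      markers$ref[j] <- alleles[1]
      markers$alt[j] <- alleles[2]
    }
  }

  ref_mat <- matrix(markers$ref, nrow(ped), n_snps, byrow = TRUE)
  alt_mat <- matrix(markers$alt, nrow(ped), n_snps, byrow = TRUE)
  known <- a1 == ref_mat | a1 == alt_mat
  bad <- a1 != "0" & !known
  bad2 <- a2 != "0" & !(a2 == ref_mat | a2 == alt_mat)
  if (any(bad | bad2)) {
    idx <- which(bad | bad2, arr.ind = TRUE)[1, ]
    stop("PED line ", idx[1], ", SNP ", markers$snp_id[idx[2]],
         ": allele not in {ref, alt}")
  }
  geno <- (a1 == alt_mat) + (a2 == alt_mat)
  geno[a1 == "0"] <- NA
  storage.mode(geno) <- "integer"

  samples <- data.frame(sample_id = ped[[2]], breed = ped[[1]],
                        sex = .sex_from_ped(ped[[5]]),
                        age = NA_real_, stringsAsFactors = FALSE)
  genotype_dataset(geno, markers, samples)
}

read_vcf <- function(path, sample_info = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  markers <- data.frame(chrom = fix[, "CHROM"], snp_id = fix[, "ID"],
                        pos_bp = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  sample_ids <- colnames(gt)
  # strip phase separator, count alt alleles
  count_alt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  geno <- t(apply(gt, 2, count_alt))
  if (nrow(markers) == 1L) geno <- matrix(geno, ncol = 1L)

  if (!is.null(sample_info)) {
    if (is.character(sample_info))
      sample_info <- utils::read.delim(sample_info, stringsAsFactors = FALSE)
    samples <- sample_info[match(sample_ids, sample_info$sample_id), ,
                           drop = FALSE]
    if (anyNA(samples$sample_id))
      stop("sample_info does not cover all VCF samples")
  } else if (all(grepl("__", sample_ids, fixed = TRUE))) {
    pos <- regexpr("__", sample_ids, fixed = TRUE)
    samples <- data.frame(
      sample_id = substring(sample_ids, pos + 2L),
      breed = substring(sample_ids, 1L, pos - 1L), stringsAsFactors = FALSE)
  } else {
    stop("VCF carries no breed labels: pass sample_info or use ",
         "'breed__sample' column names")
  }
  genotype_dataset(geno, markers, samples)
}

#' Write a genotype dataset to PLINK text or VCF files
#'
#' `ped_map` emits `<path>.ped` (breed in the family-ID column, sex coded
#' 1/2/0, phenotype column `-9`) and a 6-column `<path>.map`
#' (chrom, id, 0, bp, ref, alt). `vcf` emits a GT-only VCF 4.2 file with
#' sample columns named `breed__sample_id` so the breed survives the
#' round trip. Missing calls are written as `0 0` / `./.`.
#'
#' @param dataset a [genotype_dataset()].
#' @param path file prefix (ped_map) or file name (vcf).
#' @param format `"ped_map"` or `"vcf"`.
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(dataset, path, format = c("ped_map", "vcf")) {
  validate_genotype_dataset(dataset)
  format <- match.arg(format)
  if (format == "ped_map") write_ped_map(dataset, path) else
    write_vcf(dataset, path)
}

write_ped_map <- function(dataset, prefix) {
  m <- dataset$markers; s <- dataset$samples; g <- dataset$genotypes
  map <- data.frame(m$chrom, m$snp_id, 0L, m$pos_bp, m$ref, m$alt)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  n_snps <- nrow(m)
  alle <- matrix("0", nrow(s), 2L * n_snps)
  for (j in seq_len(n_snps)) {
    gj <- g[, j]
    a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, m$alt[j], m$ref[j]))
    a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, m$alt[j], m$ref[j]))
    alle[, 2L * j - 1L] <- a1
    alle[, 2L * j] <- a2
  }
  ped <- cbind(s$breed, s$sample_id, "0", "0", .sex_to_ped(s$sex), "-9", alle)
  data.table::fwrite(as.data.frame(ped), paste0(prefix, ".ped"), sep = " ",
                     col.names = FALSE, quote = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}

write_vcf <- function(dataset, path) {
  m <- dataset$markers; s <- dataset$samples; g <- dataset$genotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=breedscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  header <- if (nrow(s) > 0) {
    paste(c(fixed, "FORMAT", paste0(s$breed, "__", s$sample_id)),
          collapse = "\t")
  } else paste(fixed, collapse = "\t")
  writeLines(header, con)
  if (nrow(m) > 0) {
    if (nrow(s) > 0) {
      gt <- matrix("./.", nrow(m), nrow(s))
      tg <- t(g)
      gt[!is.na(tg) & tg == 0L] <- "0/0"
      gt[!is.na(tg) & tg == 1L] <- "0/1"
      gt[!is.na(tg) & tg == 2L] <- "1/1"
      body <- paste(m$chrom, m$pos_bp, m$snp_id, m$ref, m$alt, ".", "PASS",
                    ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                    sep = "\t")
    } else {
      body <- paste(m$chrom, m$pos_bp, m$snp_id, m$ref, m$alt, ".", "PASS",
                    ".", sep = "\t")
    }
    writeLines(body, con)
  }
  invisible(path)
}

#' Quality-control filter on minor allele frequency and missingness
#'
#' SNP filters (MAF and per-SNP missingness) are computed over the called
#' genotypes of all samples pooled, then applied; per-sample missingness
#' is then computed over the retained SNPs and the sample filter applied.
#' Relative order of retained SNPs and samples is preserved.
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_min minimum pooled minor allele frequency (default 0.01).
#' @param max_variant_missing maximum fraction of missing calls per SNP
#'   (default 0.05).
#' @param max_sample_missing maximum fraction of missing calls per sample
#'   (default 0.02, i.e. a genotyping rate above 0.98).
#' @return the filtered `genotype_dataset`. A warning is raised if every
#'   SNP is removed.
#' @export
apply_qc <- function(dataset, maf_min = 0.01, max_variant_missing = 0.05,
                     max_sample_missing = 0.02) {
  validate_genotype_dataset(dataset)
  stopifnot(maf_min >= 0, maf_min <= 1,
            max_variant_missing >= 0, max_variant_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  g <- dataset$genotypes
  n_called <- colSums(!is.na(g))
  p_alt <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_called == 0] <- 0
  snp_miss <- 1 - n_called / nrow(g)
  keep_snp <- maf >= maf_min & snp_miss <= max_variant_missing
  if (!any(keep_snp))
    warning("QC removed every SNP (maf_min = ", maf_min, ")")
  g2 <- g[, keep_snp, drop = FALSE]
  samp_miss <- rowMeans(is.na(g2))
  if (ncol(g2) == 0) samp_miss <- rep(0, nrow(g2))
  keep_samp <- samp_miss <= max_sample_missing
  subset_dataset(dataset, samples = which(keep_samp), snps = which(keep_snp))
}

#' Summarize a genotype dataset
#'
#' @param dataset a [genotype_dataset()].
#' @return a list of class `genotype_summary`: `n_samples`, `n_breeds`,
#'   `n_snps`, `breed_counts` (named integer vector), `mean_call_rate`,
#'   `mean_samples_per_breed` (= n_samples / n_breeds).
#' @examples
#' sim <- simulate_breeds(sim_config(n_breeds = 3, samples_per_breed = 4,
#'                                   n_chromosomes = 1, n_snps = 20,
#'                                   seed = 1))
#' summarize_genotypes(sim$genotypes)
#' @export
summarize_genotypes <- function(dataset) {
  validate_genotype_dataset(dataset)
  breeds <- table(dataset$samples$breed)
  structure(list(
    n_samples = nrow(dataset$samples),
    n_breeds = length(breeds),
    n_snps = nrow(dataset$markers),
    breed_counts = c(breeds),
    mean_call_rate = if (length(dataset$genotypes)) {
      mean(!is.na(dataset$genotypes))
    } else NA_real_,
    mean_samples_per_breed = nrow(dataset$samples) / length(breeds)
  ), class = "genotype_summary")
}

#' @export
summary.genotype_dataset <- function(object, ...) summarize_genotypes(object)

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf("%d samples in %d breeds (mean %.1f/breed), %d SNPs, %s call rate\n",
              x$n_samples, x$n_breeds, x$mean_samples_per_breed, x$n_snps,
              ifelse(is.na(x$mean_call_rate), "NA",
                     sprintf("%.1f%%", 100 * x$mean_call_rate))))
  invisible(x)
}
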