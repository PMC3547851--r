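#' Construct a phased dataset
#'
#' Holds phased chromosomes: a `(2 * n_samples) x n_snps` 0/1 matrix in
#' which each sample owns two adjacent rows (maternal/paternal order is
#' arbitrary but fixed). Phasing is assumed done upstream (or known from
#' simulation truth); there are no missing entries.
#'
#' @param haplotypes 0/1 integer matrix, `2 * nrow(samples)` rows.
#' @param markers marker map as in [genotype_dataset()].
#' @param samples sample table as in [genotype_dataset()].
#' @return object of class `phased_dataset` with elements `haplotypes`,
#'   `markers`, `samples`, and `row_sample` (sample index of each row).
#' @export
phased_dataset <- function(haplotypes, markers, samples) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  markers <- as.data.frame(markers)
  samples <- as.data.frame(samples)
  if (nrow(haplotypes) != 2L * nrow(samples))
    stop("haplotype matrix must have two rows per sample")
  if (ncol(haplotypes) != nrow(markers))
    stop("haplotype matrix has ", ncol(haplotypes), " columns but ",
         nrow(markers), " markers")
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L)))
    stop("phased entries must be 0 or 1 with no missing values")
  rownames(haplotypes) <- paste0(rep(samples$sample_id, each = 2), "_",
                                 rep(1:2, nrow(samples)))
  structure(list(haplotypes = haplotypes, markers = markers,
                 samples = samples,
                 row_sample = rep(seq_len(nrow(samples)), each = 2)),
            class = "phased_dataset")
}

#' @export
print.phased_dataset <- function(x, ...) {
  cat("phased_dataset:", nrow(x$samples), "samples (",
      nrow(x$haplotypes), "chromosomes ),", nrow(x$markers), "SNPs\n")
  invisible(x)
}

# breed label of every chromosome row
.row_breed <- function(phased) phased$samples$breed[phased$row_sample]

#' Collapse a phased dataset to unphased genotypes
#'
#' Sums each sample's two chromosome rows into alt-allele counts and
#' optionally masks a fraction of calls at random (useful when deriving
#' an array-like dataset from simulation truth).
#'
#' @param phased a [phased_dataset()].
#' @param missing_rate fraction of genotype calls set to missing
#'   (default 0; uses the current RNG stream).
#' @return a [genotype_dataset()].
#' @export
collapse_phased <- function(phased, missing_rate = 0) {
  h <- phased$haplotypes
  g <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
    h[seq(2, nrow(h), by = 2), , drop = FALSE]
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(g)) < missing_rate, nrow(g))
    g[mask] <- NA_integer_
  }
  genotype_dataset(g, phased$markers, phased$samples)
}

.hap_strings <- function(phased, snp_cols, rows) {
  m <- phased$haplotypes[rows, snp_cols, drop = FALSE]
  apply(m, 1, paste, collapse = "")
}

#' Haplotype frequencies within a window for one breed
#'
#' Counts the distinct allele strings over the window's SNPs among the
#' `2N` chromosomes of a breed.
#'
#' @param phased a [phased_dataset()].
#' @param window one row of a [build_windows()] table (or any list with
#'   `snp_idx`).
#' @param breed breed label.
#' @return data.frame `haplotype` (allele string), `count`, `frequency`,
#'   sorted by decreasing frequency; frequencies sum to 1 exactly.
#'   Empty if the breed is absent.
#' @export
window_haplotype_frequencies <- function(phased, window, breed) {
  snp_cols <- if (is.list(window$snp_idx)) window$snp_idx[[1]] else
    window$snp_idx
  rows <- which(.row_breed(phased) == breed)
  if (length(rows) == 0)
    return(data.frame(haplotype = character(), count = integer(),
                      frequency = numeric()))
  hs <- .hap_strings(phased, snp_cols, rows)
  tab <- sort(table(hs), decreasing = TRUE)
  data.frame(haplotype = names(tab), count = as.integer(tab),
             frequency = as.integer(tab) / length(hs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extend a core haplotype outward from a seed window
#'
#' Takes the modal haplotype of `seed_window` in `breed` and its carrier
#' chromosomes, then greedily grows the haplotype one flanking SNP at a
#' time, alternating left and right. At each step the appended allele is
#' the majority allele among the current carriers at that SNP (ties to
#' allele 0); carriers not matching it are dropped. A side closes when
#' extending it would push the carrier frequency (carriers over the
#' breed's `2N` chromosomes) below `f_min`, or at the chromosome end. The
#' result is the maximal contiguous record whose carrier frequency stays
#' at or above `f_min` — the deterministic reconstruction of the
#' "minimal / shared / extended" haplotype nesting seen around swept
#' loci.
#'
#' @param phased a [phased_dataset()].
#' @param seed_window one row of a [build_windows()] table.
#' @param breed breed label.
#' @param f_min minimum carrier frequency (default 0.5).
#' @return object of class `haplotype_record`: list with `chrom`,
#'   `snp_from`, `snp_to` (inclusive marker-row indices), `alleles`
#'   (integer vector), `start_bp`, `end_bp` (positions of the first/last
#'   SNP), `length_bp`, `n_snps`, `breed`, `frequency`, `carrier_rows`.
#'   `NULL` if the seed's modal frequency is below `f_min`.
#' @export
extend_core_haplotype <- function(phased, seed_window, breed, f_min = 0.5) {
  snp_cols <- if (is.list(seed_window$snp_idx)) seed_window$snp_idx[[1]] else
    seed_window$snp_idx
  chrom <- phased$markers$chrom[snp_cols[1]]
  rows <- which(.row_breed(phased) == breed)
  n_chr <- length(rows)
  if (n_chr == 0) stop("breed not present: ", breed)
  hs <- .hap_strings(phased, snp_cols, rows)
  tab <- sort(table(hs), decreasing = TRUE)
  modal <- names(tab)[1]
  carriers <- rows[hs == modal]
  if (length(carriers) / n_chr < f_min) return(NULL)

  chrom_cols <- which(phased$markers$chrom == chrom)
  lo <- min(snp_cols); hi <- max(snp_cols)
  open_left <- TRUE; open_right <- TRUE
  side <- "left"
  while (open_left || open_right) {
    if (side == "left" && !open_left) side <- "right"
    if (side == "right" && !open_right) side <- "left"
    nxt <- if (side == "left") lo - 1L else hi + 1L
    if (!(nxt %in% chrom_cols)) {
      if (side == "left") open_left <- FALSE else open_right <- FALSE
    } else {
      al <- phased$haplotypes[carriers, nxt]
      maj <- if (sum(al == 1L) > length(al) / 2) 1L else 0L
      new_carriers <- carriers[al == maj]
      if (length(new_carriers) / n_chr >= f_min) {
        carriers <- new_carriers
        if (side == "left") lo <- nxt else hi <- nxt
      } else {
        if (side == "left") open_left <- FALSE else open_right <- FALSE
      }
    }
    side <- if (side == "left") "right" else "left"
  }
  alleles <- as.integer(phased$haplotypes[carriers[1], lo:hi])
  structure(list(
    chrom = chrom, snp_from = lo, snp_to = hi, alleles = alleles,
    start_bp = phased$markers$pos_bp[lo], end_bp = phased$markers$pos_bp[hi],
    length_bp = phased$markers$pos_bp[hi] - phased$markers$pos_bp[lo],
    n_snps = hi - lo + 1L, breed = breed,
    frequency = length(carriers) / n_chr,
    carrier_rows = carriers), class = "haplotype_record")
}

#' @export
print.haplotype_record <- function(x, ...) {
  cat(sprintf(
    "haplotype_record: chr%s:%d-%d (%.1f kb, %d SNPs), %s frequency %.3f\n",
    x$chrom, x$start_bp, x$end_bp, x$length_bp / 1000, x$n_snps,
    x$breed, x$frequency))
  invisible(x)
}

#' Carrier frequency of a haplotype record in every breed
#'
#' Exact-match carrier frequency of `record`'s allele string per breed,
#' plus the pooled frequency across all breeds not in `exclude` — the
#' "all other samples in the study" figure used when asking whether a
#' swept haplotype is breed-restricted.
#'
#' @param phased a [phased_dataset()].
#' @param record a `haplotype_record` (or list with `snp_from`, `snp_to`,
#'   `alleles`).
#' @param exclude breeds excluded from the pooled "all other breeds"
#'   frequency (default: the record's own breed).
#' @return list with `by_breed` (data.frame `breed`, `n_chromosomes`,
#'   `count`, `frequency`) and `other_breeds` (list `breeds`, `count`,
#'   `n_chromosomes`, `frequency`).
#' @export
haplotype_frequency_across_breeds <- function(phased, record,
                                              exclude = record$breed) {
  cols <- record$snp_from:record$snp_to
  target <- paste(record$alleles, collapse = "")
  hs <- .hap_strings(phased, cols, seq_len(nrow(phased$haplotypes)))
  hit <- hs == target
  rb <- .row_breed(phased)
  breeds <- sort(unique(rb))
  by_breed <- data.frame(
    breed = breeds,
    n_chromosomes = as.integer(table(rb)[breeds]),
    count = as.integer(tapply(hit, rb, sum)[breeds]),
    stringsAsFactors = FALSE, row.names = NULL)
  by_breed$frequency <- by_breed$count / by_breed$n_chromosomes
  other <- !(rb %in% exclude)
  list(by_breed = by_breed,
       other_breeds = list(breeds = setdiff(breeds, exclude),
                           count = sum(hit[other]),
                           n_chromosomes = sum(other),
                           frequency = if (any(other))
                             sum(hit[other]) / sum(other) else NA_real_))
}

#' Concordance between a candidate variant and an extended haplotype
#'
#' Given per-chromosome presence of the extended haplotype and the
#' candidate allele, reports the percent of haplotype-bearing chromosomes
#' that also carry the variant, the 2x2 table, and a two-sided Fisher
#' exact test of association.
#'
#' @param carrier_status logical (or 0/1) vector: haplotype present.
#' @param variant_status logical (or 0/1) vector: variant allele present,
#'   same chromosomes in the same order.
#' @return list `percent_on_haplotype`, `n_haplotype` (carrier count),
#'   `n_concordant`, `table` (2x2), `p_value`. Percent is `NA` with a
#'   warning when no chromosome carries the haplotype.
#' @export
variant_haplotype_concordance <- function(carrier_status, variant_status) {
  if (length(carrier_status) != length(variant_status))
    stop("carrier and variant vectors differ in length")
  h <- as.logical(carrier_status)
  v <- as.logical(variant_status)
  tab <- table(factor(h, c(FALSE, TRUE)), factor(v, c(FALSE, TRUE)),
               dnn = c("haplotype", "variant"))
  n_h <- sum(h)
  if (n_h == 0) {
    warning("no haplotype-positive chromosomes; percent undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * sum(h & v) / n_h
  }
  p <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) NA_real_)
  list(percent_on_haplotype = pct, n_haplotype = n_h,
       n_concordant = sum(h & v), table = tab, p_value = p)
}

#' Allele frequency from genotype counts
#'
#' `(2 * n_hom_alt + n_het) / (2 * (n_hom_alt + n_het + n_hom_ref))` —
#' the allele frequency implied by a printed genotype-count breakdown.
#'
#' @param n_hom_alt,n_het,n_hom_ref non-negative genotype counts.
#' @return the alt allele frequency.
#' @examples
#' allele_frequency_from_counts(309, 51, 29) # 0.86
#' @export
allele_frequency_from_counts <- function(n_hom_alt, n_het, n_hom_ref) {
  stopifnot(n_hom_alt >= 0, n_het >= 0, n_hom_ref >= 0)
  total <- n_hom_alt + n_het + n_hom_ref
  if (total == 0) stop("all genotype counts are zero")
  (2 * n_hom_alt + n_het) / (2 * total)
}

#' Read phased haplotypes from TSV or phased VCF
#'
#' The TSV layout (the transposed form [write_phased()] emits) has one
#' row per chromosome copy with columns `sample_id`, `breed`, `hap`
#' (1 or 2), then one 0/1 column per SNP named by snp_id; the marker map
#' is read from a sibling `<path>.map` 6-column file. Phased VCF input
#' requires `|`-separated GT fields and uses the same breed conventions
#' as [read_genotypes()].
#'
#' @param path TSV path (with `<path>.map` alongside) or VCF path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample_info optional sample table for VCF input.
#' @return a [phased_dataset()].
#' @export
read_phased <- function(path, format = c("tsv", "vcf"), sample_info = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.table::fread(path, data.table = FALSE)
    map <- data.table::fread(paste0(path, ".map"), header = FALSE,
                             data.table = FALSE, colClasses = "character")
    markers <- data.frame(chrom = map[[1]], snp_id = map[[2]],
                          pos_bp = as.integer(map[[4]]),
                          ref = map[[5]], alt = map[[6]],
                          stringsAsFactors = FALSE)
    ord <- order(match(tab$sample_id, unique(tab$sample_id)), tab$hap)
    tab <- tab[ord, ]
    h <- as.matrix(tab[, -(1:3), drop = FALSE])
    samples <- unique(tab[, c("sample_id", "breed")])
    phased_dataset(h, markers, samples)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
    markers <- data.frame(chrom = fix[, "CHROM"], snp_id = fix[, "ID"],
                          pos_bp = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (!all(grepl("|", gt, fixed = TRUE)))
      stop("VCF is not phased (expected '|' GT separators)")
    sample_ids <- colnames(gt)
    n <- length(sample_ids); S <- nrow(gt)
    h <- matrix(0L, 2L * n, S)
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
    h[seq(1, 2 * n, 2), ] <- t(matrix(as.integer(a1), S, n))
    h[seq(2, 2 * n, 2), ] <- t(matrix(as.integer(a2), S, n))
    if (!is.null(sample_info)) {
      if (is.character(sample_info))
        sample_info <- utils::read.delim(sample_info, stringsAsFactors = FALSE)
      samples <- sample_info[match(sample_ids, sample_info$sample_id), ,
                             drop = FALSE]
    } else if (all(grepl("__", sample_ids, fixed = TRUE))) {
      pos <- regexpr("__", sample_ids, fixed = TRUE)
      samples <- data.frame(
        sample_id = substring(sample_ids, pos + 2L),
        breed = substring(sample_ids, 1L, pos - 1L), stringsAsFactors = FALSE)
    } else stop("VCF carries no breed labels: pass sample_info")
    phased_dataset(h, markers, samples)
  }
}

#' Write phased haplotypes as transposed TSV
#'
#' One row per chromosome copy (`sample_id`, `breed`, `hap`, then one
#' column per SNP); the marker map goes to `<path>.map`.
#'
#' @param phased a [phased_dataset()].
#' @param path output TSV path.
#' @return invisibly, the paths written.
#' @export
write_phased <- function(phased, path) {
  m <- phased$markers
  tab <- data.frame(sample_id = phased$samples$sample_id[phased$row_sample],
                    breed = .row_breed(phased),
                    hap = rep(1:2, nrow(phased$samples)),
                    stringsAsFactors = FALSE)
  h <- as.data.frame(phased$haplotypes)
  names(h) <- m$snp_id
  data.table::fwrite(cbind(tab, h), path, sep = "\t")
  map <- data.frame(m$chrom, m$snp_id, 0L, m$pos_bp, m$ref, m$alt)
  data.table::fwrite(map, paste0(path, ".map"), sep = "\t",
                     col.names = FALSE)
  invisible(c(path, paste0(path, ".map")))
}
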