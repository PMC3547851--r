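#' Method-of-moments IBD estimation (pi-hat) for sample pairs
#'
#' Estimates, for each sample pair in scope, the probabilities
#' `k0`, `k1`, `k2` of sharing 0/1/2 alleles identical-by-descent from
#' observed identity-by-state counts, and the genome-sharing coefficient
#' `pi_hat = k2 + k1/2`. This is the moment estimator behind the familiar
#' PLINK `--genome` report: per SNP, the probabilities of each IBS state
#' conditional on IBD state are computed from allele frequencies, and the
#' IBD fractions solved sequentially from the IBS-0, IBS-1, IBS-2 counts,
#' then clipped to `[0, 1]` and renormalized onto the simplex.
#'
#' Allele frequencies are estimated per breed when `scope = "within_breed"`
#' (pooled frequencies would inflate apparent relatedness inside
#' differentiated breeds); for `scope = "all_pairs"`, cross-breed pairs use
#' pooled frequencies. SNPs monomorphic in the frequency reference are
#' uninformative and are skipped. The dataset should already be
#' QC-filtered (MAF >= 0.01, SNP missingness <= 0.05) and carry at least
#' a few hundred SNPs for stable estimates.
#'
#' @param dataset a [genotype_dataset()].
#' @param scope `"within_breed"` (default; pairs within each breed only)
#'   or `"all_pairs"`.
#' @return data.frame of class `relatedness_table` with columns
#'   `sample_a`, `sample_b`, `breed` (NA for cross-breed pairs),
#'   `n_snps_used`, `k0`, `k1`, `k2`, `pi_hat`. Pairs with zero
#'   informative SNPs have `NA` estimates. Fewer than two samples in
#'   scope yields an empty table.
#' @export
estimate_ibd <- function(dataset, scope = c("within_breed", "all_pairs")) {
  validate_genotype_dataset(dataset)
  scope <- match.arg(scope)
  s <- dataset$samples
  g <- dataset$genotypes
  rows <- list()

  breeds <- unique(s$breed)
  for (b in breeds) {
    idx <- which(s$breed == b)
    if (length(idx) < 2) next
    p <- .alt_freq(g[idx, , drop = FALSE])
    rows[[length(rows) + 1L]] <-
      .ibd_pairs(g, idx, p, s$sample_id, breed = b)
  }
  if (scope == "all_pairs" && length(breeds) > 1) {
    p_pool <- .alt_freq(g)
    for (i in seq_along(breeds)[-length(breeds)]) {
      for (j in (i + 1):length(breeds)) {
        ia <- which(s$breed == breeds[i])
        ib <- which(s$breed == breeds[j])
        rows[[length(rows) + 1L]] <-
          .ibd_cross_pairs(g, ia, ib, p_pool, s$sample_id)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_a = character(), sample_b = character(),
               breed = character(), n_snps_used = integer(),
               k0 = numeric(), k1 = numeric(), k2 = numeric(),
               pi_hat = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("relatedness_table", "data.frame")
  out
}

.alt_freq <- function(g) {
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p[n_called == 0] <- NA_real_
  p
}

# IBS-state probabilities given IBD state, per SNP (plug-in frequencies)
.ibs_given_ibd <- function(p) {
  q <- 1 - p
  list(
    p00 = 2 * p^2 * q^2,
    p10 = 4 * p^3 * q + 4 * p * q^3,
    p20 = p^4 + q^4 + 4 * p^2 * q^2,
    p11 = 2 * p * q,              # het x (ibd-shared) -> IBS1 paths
    p21 = 1 - 2 * p * q
  )
}

.ibd_one_pair <- function(g1, g2, p) {
  use <- !is.na(g1) & !is.na(g2) & !is.na(p) & p > 0 & p < 1
  if (!any(use))
    return(c(n = 0L, k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
             pi_hat = NA_real_))
  g1 <- g1[use]; g2 <- g2[use]; pp <- p[use]
  d <- abs(g1 - g2)
  n0 <- sum(d == 2)
  n1 <- sum(d == 1)
  n2 <- sum(d == 0)
  pr <- .ibs_given_ibd(pp)
  k0 <- n0 / sum(pr$p00)
  k1 <- (n1 - k0 * sum(pr$p10)) / sum(pr$p11)
  k2 <- (n2 - k0 * sum(pr$p20) - k1 * sum(pr$p21)) / length(pp)
  k <- pmax(c(k0, k1, k2), 0)
  k <- k / sum(k)
  c(n = length(pp), k0 = k[1], k1 = k[2], k2 = k[3],
    pi_hat = k[3] + k[2] / 2)
}

.ibd_pairs <- function(g, idx, p, ids, breed) {
  n <- length(idx)
  pairs <- utils::combn(n, 2)
  res <- matrix(NA_real_, ncol(pairs), 5)
  for (k in seq_len(ncol(pairs))) {
    res[k, ] <- .ibd_one_pair(g[idx[pairs[1, k]], ], g[idx[pairs[2, k]], ], p)
  }
  data.frame(sample_a = ids[idx[pairs[1, ]]], sample_b = ids[idx[pairs[2, ]]],
             breed = breed, n_snps_used = as.integer(res[, 1]),
             k0 = res[, 2], k1 = res[, 3], k2 = res[, 4], pi_hat = res[, 5],
             stringsAsFactors = FALSE)
}

.ibd_cross_pairs <- function(g, ia, ib, p, ids) {
  grid <- expand.grid(a = ia, b = ib)
  res <- matrix(NA_real_, nrow(grid), 5)
  for (k in seq_len(nrow(grid))) {
    res[k, ] <- .ibd_one_pair(g[grid$a[k], ], g[grid$b[k], ], p)
  }
  data.frame(sample_a = ids[grid$a], sample_b = ids[grid$b],
             breed = NA_character_, n_snps_used = as.integer(res[, 1]),
             k0 = res[, 2], k1 = res[, 3], k2 = res[, 4], pi_hat = res[, 5],
             stringsAsFactors = FALSE)
}

#' Greedily prune related samples
#'
#' Removes samples until no within-breed pair has `pi_hat >= threshold`.
#' Removal is greedy: at each step the sample involved in the most
#' over-threshold pairs is dropped, ties broken by lower genotype call
#' rate, then lexicographically by sample id. Removing one member of each
#' flagged pair mirrors the study design for building breed panels of
#' nominally unrelated animals.
#'
#' @param dataset a [genotype_dataset()].
#' @param table a `relatedness_table` from [estimate_ibd()] computed on
#'   this dataset.
#' @param threshold prune pairs with `pi_hat >= threshold`
#'   (default 0.25, the first-degree half-way point; 0.3 is the common
#'   looser alternative).
#' @return list with `dataset` (pruned, original order preserved) and
#'   `removed_ids` (character, in removal order).
#' @export
prune_related <- function(dataset, table, threshold = 0.25) {
  validate_genotype_dataset(dataset)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single value in (0, 1]")
  bad <- table[!is.na(table$pi_hat) & table$pi_hat >= threshold &
                 !is.na(table$breed), c("sample_a", "sample_b")]
  call_rate <- rowMeans(!is.na(dataset$genotypes))
  names(call_rate) <- dataset$samples$sample_id
  removed <- character()
  while (nrow(bad) > 0) {
    counts <- table(c(bad$sample_a, bad$sample_b))
    top <- max(counts)
    cand <- names(counts)[counts == top]
    if (length(cand) > 1) {
      cr <- call_rate[cand]
      cand <- cand[cr == min(cr)]
      cand <- sort(cand)
    }
    victim <- cand[1]
    removed <- c(removed, victim)
    bad <- bad[bad$sample_a != victim & bad$sample_b != victim, ,
               drop = FALSE]
  }
  keep <- !(dataset$samples$sample_id %in% removed)
  list(dataset = subset_dataset(dataset, samples = which(keep)),
       removed_ids = removed)
}
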