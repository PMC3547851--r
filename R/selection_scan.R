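#' Scan configuration
#'
#' @param window_size_bp window length in bp (default 500 kb).
#' @param min_snps_per_window minimum SNPs for a window to be analyzed
#'   (default 4).
#' @param significance_percentile empirical percentile defining the
#'   outlier cut (default 0.99, i.e. the top 1% of windows per breed).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(window_size_bp = 500000L, min_snps_per_window = 4L,
                        significance_percentile = 0.99) {
  stopifnot(window_size_bp > 0, min_snps_per_window >= 1,
            significance_percentile > 0, significance_percentile < 1)
  structure(list(window_size_bp = as.integer(window_size_bp),
                 min_snps_per_window = as.integer(min_snps_per_window),
                 significance_percentile = significance_percentile),
            class = "scan_config")
}

.chrom_order <- function(chrom) {
  suppressWarnings(num <- as.numeric(chrom))
  order(is.na(num), num, chrom)
}

#' Tile chromosomes into fixed windows
#'
#' Windows are half-open intervals `[1 + k*L, 1 + (k+1)*L)` anchored at
#' bp 1 on every chromosome, so each SNP belongs to exactly one tile.
#' Tiles holding fewer than `min_snps_per_window` SNPs are dropped;
#' the rest are returned in (chromosome, start) order. The reported
#' `center_bp` is `start + L/2`.
#'
#' @param markers a marker map data.frame (see [genotype_dataset()]).
#' @param config a [scan_config()].
#' @return data.frame of class `scan_windows` with columns `window_id`,
#'   `chrom`, `start_bp`, `end_bp`, `center_bp`, `n_snps`, and a
#'   list-column `snp_idx` of row indices into `markers`.
#' @export
build_windows <- function(markers, config = scan_config()) {
  if (nrow(markers) == 0) {
    out <- data.frame(window_id = integer(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      center_bp = numeric(), n_snps = integer())
    out$snp_idx <- list()
    class(out) <- c("scan_windows", "data.frame")
    return(out)
  }
  L <- config$window_size_bp
  k <- (markers$pos_bp - 1) %/% L
  key <- paste(markers$chrom, k, sep = "\r")
  idx_by_window <- split(seq_len(nrow(markers)), key)
  n_snps <- lengths(idx_by_window)
  keep <- n_snps >= config$min_snps_per_window
  idx_by_window <- idx_by_window[keep]
  first <- vapply(idx_by_window, `[`, integer(1), 1L)
  chrom <- markers$chrom[first]
  start <- 1 + (markers$pos_bp[first] - 1) %/% L * L
  chrom_levels <- unique(chrom)[.chrom_order(unique(chrom))]
  ord <- order(match(chrom, chrom_levels), start)
  out <- data.frame(window_id = seq_along(ord),
                    chrom = chrom[ord],
                    start_bp = start[ord],
                    end_bp = start[ord] + L,
                    center_bp = start[ord] + L / 2,
                    n_snps = as.integer(n_snps[keep][ord]),
                    stringsAsFactors = FALSE)
  out$snp_idx <- unname(idx_by_window[ord])
  class(out) <- c("scan_windows", "data.frame")
  out
}

# Per-breed, per-SNP called sample size, alt frequency, het proportion
.breed_snp_stats <- function(dataset) {
  g <- dataset$genotypes
  breeds <- sort(unique(dataset$samples$breed))
  n <- p <- h <- matrix(NA_real_, length(breeds), ncol(g),
                        dimnames = list(breeds, NULL))
  for (i in seq_along(breeds)) {
    gb <- g[dataset$samples$breed == breeds[i], , drop = FALSE]
    nb <- colSums(!is.na(gb))
    n[i, ] <- nb
    p[i, ] <- colSums(gb, na.rm = TRUE) / (2 * pmax(nb, 1L))
    h[i, ] <- colSums(gb == 1L, na.rm = TRUE) / pmax(nb, 1L)
  }
  list(breeds = breeds, n = n, p = p, h = h)
}

# Weir-Cockerham (1984) two-population variance components, vectorized
# over SNPs. Returns a (between) and d = a + b + c (total) per SNP; NA
# where the SNP is unusable for the pair.
.wc_components <- function(n1, n2, p1, p2, h1, h2) {
  ok <- n1 >= 2 & n2 >= 2
  n_bar <- (n1 + n2) / 2
  n_c <- (2 * n1 * n2) / (n1 + n2)
  p_bar <- (n1 * p1 + n2 * p2) / (2 * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / n_bar
  h_bar <- (n1 * h1 + n2 * h2) / (2 * n_bar)
  inner <- p_bar * (1 - p_bar) - s2 / 2 - h_bar / 4
  a <- (n_bar / n_c) * (s2 - inner / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 / 2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  poly <- p_bar > 0 & p_bar < 1
  use <- ok & poly
  a[!use] <- NA_real_
  d <- a + b + cc
  d[!use] <- NA_real_
  list(a = a, d = d, usable = use)
}

#' Windowed pairwise Weir-Cockerham F_ST
#'
#' For every retained window and every unordered breed pair, computes the
#' two-population Weir-Cockerham theta as a ratio of averages: per-SNP
#' between-population (`a`) and total (`a + b + c`) variance components
#' are summed over the window's SNPs and the window estimate is
#' `sum(a) / sum(a + b + c)`. Per-SNP sample sizes count called genotypes
#' only; a SNP enters a pair's sum only when both breeds have at least
#' two called genotypes and the SNP is polymorphic in the pooled pair
#' (monomorphic SNPs carry no variance components). Negative estimates
#' are retained so the genome-wide standardization stays unbiased.
#'
#' @param dataset a [genotype_dataset()] with at least two breeds.
#' @param windows output of [build_windows()].
#' @return data.frame of class `fst_table`, long format: `window_id`,
#'   `breed_a`, `breed_b` (alphabetical within pair), `n_snps_used`,
#'   `fst` (`NA` when no usable SNP).
#' @export
window_fst <- function(dataset, windows) {
  validate_genotype_dataset(dataset)
  st <- .breed_snp_stats(dataset)
  B <- length(st$breeds)
  if (B < 2) stop("window_fst needs at least two breeds")
  W <- nrow(windows)
  w_of_snp <- rep(NA_integer_, nrow(dataset$markers))
  for (w in seq_len(W)) w_of_snp[windows$snp_idx[[w]]] <- w

  pairs <- utils::combn(B, 2)
  res <- vector("list", ncol(pairs))
  in_window <- !is.na(w_of_snp)
  grp <- w_of_snp[in_window]
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    comp <- .wc_components(st$n[i, ], st$n[j, ], st$p[i, ], st$p[j, ],
                           st$h[i, ], st$h[j, ])
    a <- comp$a[in_window]; d <- comp$d[in_window]
    use <- comp$usable[in_window]
    a[!use] <- 0; d[!use] <- 0
    sums <- rowsum(cbind(a, d, n = as.numeric(use)), grp)
    w_ids <- as.integer(rownames(sums))
    fst <- rep(NA_real_, W)
    nuse <- integer(W)
    nuse[w_ids] <- as.integer(sums[, "n"])
    ok <- sums[, "n"] > 0 & sums[, "d"] != 0
    fst[w_ids[ok]] <- sums[ok, "a"] / sums[ok, "d"]
    res[[k]] <- data.frame(window_id = windows$window_id,
                           breed_a = st$breeds[i], breed_b = st$breeds[j],
                           n_snps_used = nuse, fst = fst,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("fst_table", "data.frame")
  out
}

#' Genome-wide F_ST background per breed pair
#'
#' Mean and sample standard deviation (n - 1 denominator) of the defined
#' window F_ST values of each breed pair — the genome-wide expectation
#' against which window divergence is standardized.
#'
#' @param fst_table output of [window_fst()].
#' @return data.frame of class `genome_stats`: `breed_a`, `breed_b`,
#'   `mean_fst`, `sd_fst`, `n_windows_used`. Pairs with fewer than two
#'   defined windows get `NA` sd and a warning; pairs with zero window
#'   spread (sd 0) are flagged degenerate downstream.
#' @export
genome_stats <- function(fst_table) {
  key <- paste(fst_table$breed_a, fst_table$breed_b, sep = "\r")
  splits <- split(fst_table$fst, key)
  stats <- lapply(splits, function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
      n = length(v))
  })
  keys <- do.call(rbind, strsplit(names(stats), "\r", fixed = TRUE))
  mat <- do.call(rbind, stats)
  out <- data.frame(breed_a = keys[, 1], breed_b = keys[, 2],
                    mean_fst = mat[, "mean"], sd_fst = mat[, "sd"],
                    n_windows_used = as.integer(mat[, "n"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(out$n_windows_used < 2))
    warning("breed pair(s) with < 2 defined windows: sd undefined, ",
            "excluded from d_i")
  class(out) <- c("genome_stats", "data.frame")
  out
}

#' The d_i locus-specific divergence statistic
#'
#' For window `w` and breed `i`,
#' `d_i(w) = sum over j != i of (fst_ij(w) - mean_fst_ij) / sd_fst_ij`:
#' each pairwise window F_ST is standardized by that pair's genome-wide
#' mean and standard deviation, and the standardized scores of all pairs
#' involving breed `i` are summed. Large values flag windows where breed
#' `i` is more diverged from the other breeds than is typical for it
#' genome-wide. Pair terms that are undefined for a window (no usable
#' SNP, or a degenerate sd of 0) are skipped; the sum over the remaining
#' pairs is reported with `complete = FALSE`.
#'
#' @param fst_table output of [window_fst()].
#' @param stats output of [genome_stats()].
#' @return data.frame of class `di_table`: `window_id`, `breed`, `di`,
#'   `n_pairs_used`, `n_pairs_total`, `complete`. `di` is `NA` where no
#'   pair term was defined.
#' @export
compute_di <- function(fst_table, stats) {
  key_f <- paste(fst_table$breed_a, fst_table$breed_b, sep = "\r")
  key_s <- paste(stats$breed_a, stats$breed_b, sep = "\r")
  mi <- match(key_f, key_s)
  if (anyNA(mi)) stop("stats missing for some breed pairs")
  mu <- stats$mean_fst[mi]
  sd <- stats$sd_fst[mi]
  z <- (fst_table$fst - mu) / sd
  z[!is.na(sd) & sd == 0] <- NA_real_
  zt <- data.frame(window_id = rep(fst_table$window_id, 2),
                   breed = c(fst_table$breed_a, fst_table$breed_b),
                   z = rep(z, 2), stringsAsFactors = FALSE)
  grp <- paste(zt$window_id, zt$breed, sep = "\r")
  ok <- !is.na(zt$z)
  di_sum <- rowsum(ifelse(ok, zt$z, 0), grp)
  n_used <- rowsum(as.numeric(ok), grp)
  n_tot <- rowsum(rep(1, nrow(zt)), grp)
  keys <- do.call(rbind, strsplit(rownames(di_sum), "\r", fixed = TRUE))
  out <- data.frame(window_id = as.integer(keys[, 1]), breed = keys[, 2],
                    di = ifelse(n_used[, 1] > 0, di_sum[, 1], NA_real_),
                    n_pairs_used = as.integer(n_used[, 1]),
                    n_pairs_total = as.integer(n_tot[, 1]),
                    complete = n_used[, 1] == n_tot[, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(out$breed, out$window_id), ]
  rownames(out) <- NULL
  class(out) <- c("di_table", "data.frame")
  out
}

#' Call significant windows by the empirical-percentile rule
#'
#' Per breed, the top `k = ceiling((1 - percentile) * W)` windows by
#' `d_i` are flagged, where `W` is that breed's number of analyzed
#' (defined-`d_i`) windows — the count form of "windows falling into the
#' upper percentile of the empirical distribution". Ties at the cut are
#' broken by window order (chromosome, start). The reported per-breed
#' `threshold` is the smallest flagged `d_i`.
#'
#' @param di_table output of [compute_di()].
#' @param config a [scan_config()].
#' @return list with `di_table` (input plus logical column `significant`)
#'   and `thresholds` (data.frame `breed`, `n_windows`, `k`, `threshold`).
#' @export
call_significant <- function(di_table, config = scan_config()) {
  pct <- config$significance_percentile
  di_table$significant <- FALSE
  thr <- list()
  for (b in unique(di_table$breed)) {
    rows <- which(di_table$breed == b & !is.na(di_table$di))
    W <- length(rows)
    if (W == 0) {
      thr[[b]] <- data.frame(breed = b, n_windows = 0L, k = 0L,
                             threshold = NA_real_)
      next
    }
    # epsilon guards the count rule against floating-point in (1 - pct)
    k <- as.integer(ceiling((1 - pct) * W - 1e-9))
    k <- max(k, 1L)
    ord <- rows[order(-di_table$di[rows], di_table$window_id[rows])]
    top <- ord[seq_len(k)]
    di_table$significant[top] <- TRUE
    thr[[b]] <- data.frame(breed = b, n_windows = W, k = k,
                           threshold = min(di_table$di[top]),
                           stringsAsFactors = FALSE)
  }
  thresholds <- do.call(rbind, thr)
  rownames(thresholds) <- NULL
  list(di_table = di_table, thresholds = thresholds)
}
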