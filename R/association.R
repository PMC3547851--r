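#' Validate a fiber-type phenotype table
#'
#' @param pheno data.frame with columns `id`, `type1_pct`, `type2a_pct`,
#'   `type2b_pct` (proportions in percent, summing to 100 per horse),
#'   `age` (years), `sex` (factor-like), plus one 0/1/2 (or NA) column
#'   per candidate variant, and optionally per-type mean maximum fiber
#'   diameters (micrometers).
#' @return the table, invisibly, after checks.
#' @export
validate_phenotypes <- function(pheno) {
  req <- c("id", "type1_pct", "type2a_pct", "type2b_pct", "age", "sex")
  if (!all(req %in% names(pheno)))
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  tot <- pheno$type1_pct + pheno$type2a_pct + pheno$type2b_pct
  if (any(abs(tot - 100) > 1e-6))
    stop("fiber-type proportions must sum to 100 per horse")
  if (any(pheno$age < 0, na.rm = TRUE)) stop("age must be non-negative")
  invisible(pheno)
}

.assoc_frame <- function(pheno, variant, covariates, responses) {
  validate_phenotypes(pheno)
  if (!variant %in% names(pheno)) stop("no genotype column: ", variant)
  cols <- c(responses, variant, covariates)
  d <- pheno[, cols, drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  d$geno <- as.numeric(d[[variant]])
  if (!all(d$geno %in% 0:2)) stop("genotypes must be coded 0/1/2")
  if ("sex" %in% names(d)) d$sex <- factor(d$sex)
  attr(d, "n_dropped") <- sum(!keep)
  d
}

.covariate_formula <- function(covariates) {
  if (length(covariates) == 0) "" else
    paste("+", paste(covariates, collapse = " + "))
}

#' MANOVA for additive genotype effects on fiber-type composition
#'
#' Tests whether the candidate genotype, coded additively as the numeric
#' allele count 0/1/2, shifts the joint fiber-type composition, adjusting
#' for covariates. Because the three fiber-type proportions sum to 100,
#' the response is the bivariate `(type1_pct, type2b_pct)` — the slow and
#' fast extremes — dropping the collinear middle category. The test
#' statistic is Pillai's trace with its approximate F.
#'
#' @param pheno a phenotype table (see [validate_phenotypes()]).
#' @param variant name of the genotype column.
#' @param covariates covariate column names (default `c("age", "sex")`).
#' @param responses the two response columns (default
#'   `c("type1_pct", "type2b_pct")`).
#' @return list `pillai`, `approx_f`, `df` (num, den), `p_value`, `n`,
#'   `n_dropped` (rows lost to missing data).
#' @export
manova_additive <- function(pheno, variant, covariates = c("age", "sex"),
                            responses = c("type1_pct", "type2b_pct")) {
  d <- .assoc_frame(pheno, variant, covariates, responses)
  if (length(unique(d$geno)) < 2)
    stop("need at least two genotype levels, found ",
         length(unique(d$geno)))
  Y <- as.matrix(d[, responses, drop = FALSE])
  if (qr(stats::cov(Y))$rank < ncol(Y))
    stop("singular response covariance: responses are collinear")
  # genotype last: sequential SS then test it adjusted for the covariates
  rhs <- paste(c(covariates, "geno"), collapse = " + ")
  f <- stats::as.formula(paste("Y ~", rhs))
  fit <- stats::manova(f, data = d)
  sm <- summary(fit, test = "Pillai")$stats
  row <- match("geno", trimws(rownames(sm)))
  list(pillai = sm[row, "Pillai"],
       approx_f = sm[row, "approx F"],
       df = c(num = sm[row, "num Df"], den = sm[row, "den Df"]),
       p_value = sm[row, "Pr(>F)"],
       n = nrow(d), n_dropped = attr(d, "n_dropped"))
}

#' Additive effect sizes by multiple linear regression
#'
#' Per response, fits `response ~ allele_count + covariates` and reports
#' the additive slope (percentage points, or micrometers for diameters,
#' per allele copy) with its t-based 95% confidence interval and
#' two-sided p-value.
#'
#' @param pheno a phenotype table.
#' @param variant name of the genotype column.
#' @param responses response column names (default the three fiber-type
#'   proportions).
#' @param covariates covariate column names (default `c("age", "sex")`).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame `response`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `p_value`, `n`.
#' @export
regression_effects <- function(pheno, variant,
                               responses = c("type1_pct", "type2a_pct",
                                             "type2b_pct"),
                               covariates = c("age", "sex"),
                               conf_level = 0.95) {
  d <- .assoc_frame(pheno, variant, covariates, responses)
  out <- lapply(responses, function(resp) {
    f <- stats::as.formula(paste(resp, "~ geno",
                                 .covariate_formula(covariates)))
    fit <- stats::lm(f, data = d)
    if (fit$rank < ncol(stats::model.matrix(fit))) {
      mm <- stats::model.matrix(fit)
      dropped <- colnames(mm)[is.na(stats::coef(fit))]
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    co <- summary(fit)$coefficients["geno", ]
    ci <- stats::confint(fit, "geno", level = conf_level)
    data.frame(response = resp, estimate = co["Estimate"],
               se = co["Std. Error"], ci_lo = ci[1], ci_hi = ci[2],
               p_value = co["Pr(>|t|)"], n = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# letter grouping from a logical "significantly different" matrix:
# split every group containing a significant pair, absorb subsets,
# letter groups in order of their best (largest) mean
.lsd_letters <- function(means, sig) {
  k <- length(means)
  groups <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_groups <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
        } else new_groups <- c(new_groups, list(g))
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_groups[[a]] %in% new_groups[[b]]) &&
              (length(new_groups[[a]]) < length(new_groups[[b]]) || a > b))
            keep[a] <- FALSE
        }
      }
      groups <- new_groups[keep]
    }
  }
  best <- vapply(groups, function(g) max(means[g]), numeric(1))
  groups <- groups[order(-best)]
  letters_out <- rep("", k)
  for (g in seq_along(groups)) {
    for (i in groups[[g]]) {
      letters_out[i] <- paste0(letters_out[i], letters[g])
    }
  }
  # letters within a level in alphabetical order
  vapply(strsplit(letters_out, ""), function(x)
    paste(sort(x), collapse = ""), character(1))
}

#' Genotypic LS-means with Fisher's LSD letter groups
#'
#' Fits a genotypic (3-level factor) model with covariates, computes
#' least-squares means — model predictions for each genotype level at the
#' covariate means, categorical covariates weighted by their observed
#' proportions — and performs unadjusted pairwise t-tests (Fisher's LSD)
#' on the model's residual variance. Levels sharing a letter are not
#' significantly different at `alpha`. The pairwise tests are flagged
#' `protected` when the overall genotypic F-test is itself significant.
#'
#' @param pheno a phenotype table.
#' @param variant name of the genotype column (levels 0/1/2).
#' @param response a single response column name.
#' @param covariates covariate column names (default `c("age", "sex")`).
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `ls_means` (data.frame `genotype`, `n`, `ls_mean`,
#'   `se`, `letters`), `pairwise` (data.frame `a`, `b`, `diff`, `se`,
#'   `t`, `p_value`), `overall_f_p`, `protected`. Empty genotype levels
#'   are omitted with a warning.
#' @export
ls_means_lsd <- function(pheno, variant, response = "type2b_pct",
                         covariates = c("age", "sex"), alpha = 0.05) {
  d <- .assoc_frame(pheno, variant, covariates, response)
  present <- sort(unique(d$geno))
  if (length(present) < 3)
    warning("genotype level(s) ", paste(setdiff(0:2, present),
                                        collapse = ", "),
            " absent; omitted")
  d$gf <- factor(d$geno, levels = present)
  f <- stats::as.formula(paste(response, "~ gf",
                               .covariate_formula(covariates)))
  fit <- stats::lm(f, data = d)
  mm <- stats::model.matrix(fit)
  # design rows at covariate means: genotype dummies set per level,
  # every other column at its observed column mean
  xbar <- colMeans(mm)
  lev_cols <- paste0("gf", present)
  L <- matrix(rep(xbar, length(present)), nrow = length(present),
              byrow = TRUE, dimnames = list(present, names(xbar)))
  for (i in seq_along(present)) {
    hit <- intersect(lev_cols, colnames(L))
    L[i, hit] <- 0
    this <- paste0("gf", present[i])
    if (this %in% colnames(L)) L[i, this] <- 1
  }
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  lsm <- drop(L %*% beta)
  lsm_se <- sqrt(diag(L %*% V %*% t(L)))
  df_res <- stats::df.residual(fit)

  np <- length(present)
  pair_idx <- utils::combn(np, 2)
  pw <- data.frame(a = present[pair_idx[1, ]], b = present[pair_idx[2, ]],
                   diff = NA_real_, se = NA_real_, t = NA_real_,
                   p_value = NA_real_)
  sig <- matrix(FALSE, np, np)
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    cvec <- L[i, ] - L[j, ]
    diff <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- diff / se
    p <- 2 * stats::pt(-abs(tval), df_res)
    pw[k, c("diff", "se", "t", "p_value")] <- c(diff, se, tval, p)
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  overall <- stats::anova(fit)
  overall_p <- overall["gf", "Pr(>F)"]
  list(ls_means = data.frame(genotype = present,
                             n = as.integer(table(d$gf)),
                             ls_mean = lsm, se = lsm_se,
                             letters = .lsd_letters(lsm, sig),
                             stringsAsFactors = FALSE, row.names = NULL),
       pairwise = pw, overall_f_p = overall_p,
       protected = !is.na(overall_p) && overall_p < alpha)
}
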