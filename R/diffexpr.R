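# Library-size normalisation (median-of-ratios), a variance-stabilising log
# transform for downstream QTL/eQTM use, and a deliberately simple
# negative-binomial Wald test for differential expression: per-gene
# method-of-moments dispersion, NB log-link GLM with a log size-factor
# offset, two-sided normal reference on the disease coefficient. No
# dispersion shrinkage, outlier refitting or independent filtering.

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of count / geometric-mean(count), using
#' only genes with all-positive counts; factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Count matrix (gene x sample).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) rlang::abort("No gene with positive counts in every sample.")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  f <- exp(apply(lg - ref, 2, median))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Variance-stabilising log transform
#'
#' `log2(count / size_factor + 1)`, elementwise. Puts counts on the log scale
#' used by the cis-eQTL and eQTM scans.
#'
#' @param counts Count matrix (gene x sample).
#' @param factors Size factors from [size_factors()] (computed if omitted).
#' @return Log-scale matrix of the same shape.
#' @export
vst_transform <- function(counts, factors = size_factors(counts)) {
  if (any(factors <= 0)) rlang::abort("Size factors must be positive.")
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Method-of-moments dispersion for one gene
#'
#' On size-factor-normalised counts: `alpha = max((s^2 - mu) / mu^2, floor)`.
#'
#' @param counts_row Counts for one gene across samples.
#' @param factors Size factors.
#' @param floor Lower bound on alpha (default 1e-8).
#' @return List with `alpha` and a `flagged` marker for degenerate rows.
#' @export
estimate_dispersion <- function(counts_row, factors, floor = 1e-8) {
  if (length(counts_row) < 3) rlang::abort("Need at least 3 samples.")
  x <- counts_row / factors
  mu <- mean(x)
  if (mu == 0) return(list(alpha = floor, flagged = TRUE))
  s2 <- stats::var(x)
  list(alpha = max((s2 - mu) / mu^2, floor), flagged = FALSE)
}

#' Negative-binomial Wald scan for differential expression
#'
#' Per gene: gene-wise dispersion by method of moments, then an NB log-link
#' regression of counts on disease status plus covariates with
#' `offset = log(size factor)` and fixed dispersion, fitted by iteratively
#' reweighted least squares. Wald test (two-sided normal) on the disease
#' coefficient; `log2fc` is the coefficient divided by ln 2. Genes with
#' all-zero counts are dropped before testing and excluded from the
#' Bonferroni denominator.
#'
#' @param counts Count matrix (gene x sample).
#' @param sheet Sample sheet.
#' @param model_spec Covariate specification; the RNA-seq default adjusts
#'   for age, sex, PC1, cell proportions, sequencing pool and RIN.
#' @return A tibble of class `de_scan`: gene_id, log2fc, se, wald_z, p,
#'   p_bonferroni, p_fdr, base_mean, dispersion, converged.
#' @export
run_de_scan <- function(counts, sheet,
                        model_spec = epicohort::model_spec(
                          c("age", "sex", "pc1", "cells", "pool", "rin"))) {
  spec <- as_model_spec(model_spec)
  al <- align_samples(sheet, counts = counts)
  counts <- al$counts; sheet <- al$sheet
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  X <- build_design(sheet, spec$covariates,
                    extra = list(disease = disease_indicator(sheet)))
  off <- log(sf)
  k <- ncol(X)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    disp <- estimate_dispersion(y, sf)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, offset = off,
        family = MASS::negative.binomial(theta = 1 / disp$alpha),
        control = list(epsilon = 1e-10, maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble::tibble(gene_id = rownames(counts)[i], log2fc = NA_real_,
                            se = NA_real_, wald_z = NA_real_, p = NA_real_,
                            base_mean = mean(y / sf),
                            dispersion = disp$alpha, converged = FALSE))
    }
    # Wald covariance at the IRLS solution, dispersion fixed at 1
    W <- fit$weights
    cov_u <- chol2inv(chol(crossprod(X * sqrt(W))))
    est <- unname(fit$coefficients[k])
    se <- sqrt(cov_u[k, k])
    z <- est / se
    tibble::tibble(gene_id = rownames(counts)[i], log2fc = est / log(2),
                   se = se / log(2), wald_z = z,
                   p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                   base_mean = mean(y / sf), dispersion = disp$alpha,
                   converged = TRUE)
  })
  res <- dplyr::bind_rows(rows)
  m <- sum(!is.na(res$p))
  res$p_bonferroni <- pmin(1, res$p * m)
  res$p_fdr <- stats::p.adjust(res$p, "BH")
  res <- dplyr::arrange(res, .data$p)
  structure(res, class = c("de_scan", class(res)), m_tests = m)
}
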