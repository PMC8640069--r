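# Epigenome-wide association scans: covariate-adjusted OLS per CpG for mean
# differences (DMPs), Brown-Forsythe tests on covariate residuals for
# variance differences (VMPs), sensitivity refits with extra covariates and
# autoantibody-stratified/conditional contrasts.

#' Ordinary least squares fit with a focal binary term
#'
#' Fits `y ~ covariates + group` and returns the group coefficient with its
#' standard error and two-sided t test. The workhorse behind every
#' methylation and QTL scan.
#'
#' @param y Numeric response vector.
#' @param group Binary (0/1) indicator of interest.
#' @param covariates Optional numeric matrix/data frame of design columns
#'   (no intercept; one is added).
#' @return A list: `estimate`, `se`, `statistic`, `p`, `df`, `degenerate`.
#' @export
#' @examples
#' fit_linear_model(c(1, 2, 3, 4), c(0, 0, 1, 1))
fit_linear_model <- function(y, group, covariates = NULL) {
  if (length(unique(group)) < 2) rlang::abort("`group` is constant.")
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(covariates)) as.matrix(covariates),
             group = group)
  if (nrow(X) <= ncol(X)) rlang::abort("More design columns than observations.")
  check_full_rank(X)
  if (stats::var(y) == 0) {
    return(list(estimate = 0, se = NA_real_, statistic = NA_real_, p = 1,
                df = nrow(X) - ncol(X), degenerate = TRUE))
  }
  fit <- stats::lm.fit(X, y)
  df <- nrow(X) - ncol(X)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  k <- ncol(X)
  se <- sqrt(rss / df * xtx_inv[k, k])
  est <- unname(fit$coefficients[k])
  tval <- est / se
  list(estimate = est, se = se, statistic = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

# Vectorised OLS across all features sharing one design matrix.
# Returns estimate/se/t/p for the LAST design column.
ols_scan <- function(Y, X) {
  check_full_rank(X)
  k <- ncol(X)
  df <- nrow(X) - k
  xtx_inv <- chol2inv(chol(crossprod(X)))
  H <- X %*% xtx_inv                       # n x p
  B <- Y %*% H                             # features x p
  rss <- rowSums((Y - B %*% t(X))^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv[k, k])
  est <- B[, k]
  tval <- est / se
  zero_var <- matrixStats::rowVars(Y) == 0
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  est[zero_var] <- 0; p[zero_var] <- 1; tval[zero_var] <- NA_real_
  tibble::tibble(feature_id = rownames(Y), estimate = est, se = se,
                 statistic = tval, p = p, n_used = nrow(X),
                 degenerate = zero_var)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 776284)
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) rlang::abort("`m` must be at least 1.")
  alpha / m
}

#' Scan for differentially methylated positions (DMPs)
#'
#' Per CpG, ordinary least squares of methylation beta on disease status plus
#' the covariates named in `model_spec` (sex, age, genetic PC1, measured cell
#' proportions as k-1 columns, batch dummies by default). Two-sided t test on
#' the disease coefficient; Bonferroni and Benjamini-Hochberg adjustment over
#' the CpGs tested.
#'
#' @param methylation Beta-value matrix (CpG x sample).
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param model_spec A [model_spec()] or character vector of covariates.
#' @return A tibble of class `ewas_scan`, one row per CpG sorted by p:
#'   feature_id, estimate, se, statistic, p, p_bonferroni, p_fdr, mean_case,
#'   mean_control, delta_beta, n_used.
#' @export
run_dmp_scan <- function(methylation, sheet,
                         model_spec = epicohort::model_spec()) {
  spec <- as_model_spec(model_spec)
  al <- align_samples(sheet, methylation = methylation)
  Y <- al$methylation; sheet <- al$sheet
  X <- build_design(sheet, spec$covariates,
                    extra = list(disease = disease_indicator(sheet)))
  res <- ols_scan(Y, X)
  case <- disease_indicator(sheet) == 1
  res$mean_case <- rowMeans(Y[, case, drop = FALSE])
  res$mean_control <- rowMeans(Y[, !case, drop = FALSE])
  res$delta_beta <- res$mean_case - res$mean_control
  m <- nrow(res)
  res$p_bonferroni <- pmin(1, res$p * m)
  res$p_fdr <- stats::p.adjust(res$p, "BH")
  res <- dplyr::arrange(res, .data$p)
  res <- dplyr::select(res, "feature_id", "estimate", "se", "statistic", "p",
                       "p_bonferroni", "p_fdr", "mean_case", "mean_control",
                       "delta_beta", "n_used", "degenerate")
  structure(res, class = c("ewas_scan", class(res)), m_tests = m,
            covariates = spec$covariates)
}

# Residualize rows of Y on design X (least squares projection).
residualize <- function(Y, X) {
  H <- X %*% chol2inv(chol(crossprod(X)))
  Y - (Y %*% H) %*% t(X)
}

brown_forsythe_row <- function(r, case) {
  z <- abs(r - ifelse(case, median(r[case]), median(r[!case])))
  n <- length(z)
  m1 <- mean(z[case]); m0 <- mean(z[!case]); mg <- mean(z)
  ssb <- sum(case) * (m1 - mg)^2 + sum(!case) * (m0 - mg)^2
  ssw <- sum((z[case] - m1)^2) + sum((z[!case] - m0)^2)
  if (ssw <= .Machine$double.eps * n) {
    if (ssb <= .Machine$double.eps * n) {
      return(c(stat = 0, p = 1, flag = 1))
    }
    return(c(stat = Inf, p = 0, flag = 1))
  }
  f <- (ssb / 1) / (ssw / (n - 2))
  c(stat = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE), flag = 0)
}

#' Scan for variably methylated positions (VMPs)
#'
#' Per CpG, residualizes methylation on all covariates except disease, then
#' applies a Brown-Forsythe test (one-way F on absolute deviations from the
#' group medians) comparing residual spread between cases and controls. The
#' median centring makes the test robust to residual mean differences.
#'
#' @inheritParams run_dmp_scan
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"` (classic
#'   Levene).
#' @return A tibble of class `vmp_scan`: feature_id, levene_statistic, p,
#'   p_bonferroni, p_fdr, var_case, var_control, variance_ratio.
#' @export
run_vmp_scan <- function(methylation, sheet,
                         model_spec = epicohort::model_spec(),
                         center = c("median", "mean")) {
  center <- match.arg(center)
  spec <- as_model_spec(model_spec)
  al <- align_samples(sheet, methylation = methylation)
  Y <- al$methylation; sheet <- al$sheet
  case <- disease_indicator(sheet) == 1
  if (sum(case) < 3 || sum(!case) < 3) {
    rlang::abort("Both groups need at least 3 samples for the variance scan.")
  }
  X <- build_design(sheet, spec$covariates)
  R <- residualize(Y, X)
  stat <- if (center == "median") {
    t(apply(R, 1, brown_forsythe_row, case = case))
  } else {
    t(apply(R, 1, function(r) {
      z <- abs(r - ifelse(case, mean(r[case]), mean(r[!case])))
      rr <- brown_forsythe_row_from_z(z, case)
      rr
    }))
  }
  res <- tibble::tibble(
    feature_id = rownames(Y),
    levene_statistic = stat[, "stat"],
    p = stat[, "p"],
    var_case = matrixStats::rowVars(R[, case, drop = FALSE]),
    var_control = matrixStats::rowVars(R[, !case, drop = FALSE]),
    degenerate = stat[, "flag"] == 1)
  res$variance_ratio <- res$var_case / res$var_control
  m <- nrow(res)
  res$p_bonferroni <- pmin(1, res$p * m)
  res$p_fdr <- stats::p.adjust(res$p, "BH")
  res <- dplyr::arrange(res, .data$p)
  structure(res, class = c("vmp_scan", class(res)), m_tests = m)
}

brown_forsythe_row_from_z <- function(z, case) {
  n <- length(z)
  m1 <- mean(z[case]); m0 <- mean(z[!case]); mg <- mean(z)
  ssb <- sum(case) * (m1 - mg)^2 + sum(!case) * (m0 - mg)^2
  ssw <- sum((z[case] - m1)^2) + sum((z[!case] - m0)^2)
  if (ssw <= .Machine$double.eps * n) {
    return(c(stat = if (ssb <= .Machine$double.eps * n) 0 else Inf,
             p = if (ssb <= .Machine$double.eps * n) 1 else 0, flag = 1))
  }
  f <- ssb / (ssw / (n - 2))
  c(stat = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE), flag = 0)
}

#' Sensitivity refit with additional covariates
#'
#' Re-fits the DMP model on a feature subset with extra sample-sheet columns
#' (treatments, autoantibody serology) added to the covariates, and compares
#' effect sizes between the base and adjusted fits.
#'
#' @inheritParams run_dmp_scan
#' @param base_spec Base [model_spec()].
#' @param extra_covariates Sheet columns to add.
#' @param features CpG ids to refit (e.g. the significant DMPs).
#' @param threshold Significance threshold used for the retained fraction
#'   (default: Bonferroni at 0.05 over the full scan size, taken from the
#'   refit if not supplied).
#' @return A list: `refit` (ewas_scan on the subset with added covariates),
#'   `base` (base-model fit on the subset), `effect_correlation` (Pearson r
#'   between the two estimate vectors), `fraction_retained`.
#' @export
sensitivity_refit <- function(methylation, sheet, base_spec, extra_covariates,
                              features, threshold = NULL) {
  if (length(features) == 0) rlang::abort("Empty feature subset.")
  base_spec <- as_model_spec(base_spec)
  missing <- setdiff(extra_covariates, names(sheet))
  if (length(missing) > 0) {
    rlang::abort(paste0("Extra covariate(s) not in sheet: ",
                        paste(missing, collapse = ", ")))
  }
  sub <- methylation[features, , drop = FALSE]
  base_fit <- run_dmp_scan(sub, sheet, base_spec)
  refit <- run_dmp_scan(sub, sheet,
                        model_spec(c(base_spec$covariates, extra_covariates)))
  ord <- match(base_fit$feature_id, refit$feature_id)
  r <- stats::cor(base_fit$estimate, refit$estimate[ord])
  thr <- threshold %||% bonferroni_threshold(0.05, nrow(refit))
  list(refit = refit, base = base_fit, effect_correlation = r,
       fraction_retained = mean(refit$p < thr))
}

#' Stratified or conditional DMP scan
#'
#' Runs the DMP model on a subgroup (e.g. SSA-positive cases versus all
#' controls) or, in conditional mode, on the full cohort with an extra
#' covariate such as SSA status.
#'
#' @inheritParams run_dmp_scan
#' @param stratum Logical vector over sheet rows selecting the samples to
#'   keep (default: all). Cases and controls must both survive.
#' @param condition_on Optional sheet column added as covariate (conditional
#'   mode).
#' @return An `ewas_scan` tibble.
#' @export
stratified_scan <- function(methylation, sheet,
                            model_spec = epicohort::model_spec(),
                            stratum = NULL, condition_on = NULL) {
  spec <- as_model_spec(model_spec)
  if (!is.null(condition_on)) {
    spec <- model_spec(c(spec$covariates, condition_on))
  }
  if (!is.null(stratum)) {
    if (length(stratum) != nrow(sheet)) {
      rlang::abort("`stratum` must be a logical over sheet rows.")
    }
    sheet <- sheet[stratum, , drop = FALSE]
    if (!all(c("case", "control") %in% sheet$disease)) {
      rlang::abort("Stratum must retain both cases and controls.")
    }
    methylation <- methylation[, colnames(methylation) %in% sheet$sample_id,
                               drop = FALSE]
  }
  run_dmp_scan(methylation, sheet, spec)
}
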