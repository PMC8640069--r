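# cis-QTL mapping (methylation and expression layers) and
# genotype-by-disease interaction scans with stratified fits and the
# three-condition disease-dependent filter. The per-pair OLS is the same
# engine as the EWAS scans; full-cohort cis fits use Frisch-Waugh
# residualization on the shared covariate design for speed, which is exactly
# equivalent to the full regression.

#' Minor allele frequency from dosages
#'
#' `f = mean(dosage) / 2` over non-missing entries; `maf = min(f, 1 - f)`.
#'
#' @param dosages Numeric dosage vector in \[0, 2\] (fractional allowed).
#' @return MAF in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0) rlang::abort("All dosages missing.")
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Enumerate cis SNP-feature pairs
#'
#' Same-chromosome pairs with `|snp_pos - anchor| <= window`, boundary
#' inclusive. The anchor is the CpG coordinate or the strand-aware gene TSS
#' (`pos` in the annotation).
#'
#' @param feature_annot Tibble feature_id/chrom/pos.
#' @param snp_annot Tibble feature_id/chrom/pos for SNPs.
#' @param window Window in bp (default 1e6).
#' @return Tibble: snp_id, feature_id, distance_bp.
#' @export
cis_pairs <- function(feature_annot, snp_annot, window = 1000000) {
  fa <- dplyr::select(feature_annot, feature_id = "feature_id",
                      chrom = "chrom", anchor = "pos")
  sa <- dplyr::select(snp_annot, snp_id = "feature_id", chrom = "chrom",
                      snp_pos = "pos")
  pairs <- dplyr::inner_join(sa, fa, by = "chrom",
                             relationship = "many-to-many")
  pairs$distance_bp <- abs(pairs$snp_pos - pairs$anchor)
  pairs <- pairs[pairs$distance_bp <= window, ]
  dplyr::select(pairs, "snp_id", "feature_id", "distance_bp")
}

#' Full-cohort cis-QTL scan
#'
#' Per SNP-feature pair, OLS of the molecular level (methylation beta or
#' log-scale expression) on allele dosage plus covariates including disease
#' status. SNPs below the MAF filter or monomorphic after missing-dosage
#' dropping are skipped. Benjamini-Hochberg FDR over all tested pairs within
#' the layer. Samples with a missing dosage are dropped for that SNP only.
#'
#' @param feature_matrix Methylation (beta) or expression (log-scale) matrix.
#' @param genotypes Dosage matrix (SNP x sample), NAs allowed.
#' @param sheet Sample sheet.
#' @param model_spec Covariates; disease status is always added.
#' @param pairs Pairs tibble from [cis_pairs()] (rows restricted as wanted).
#' @param layer `"methylation"` or `"expression"`.
#' @param maf_min Full-cohort MAF filter (default 0.05).
#' @return Tibble of class `qtl_scan`: snp_id, feature_id, layer,
#'   distance_bp, maf_all, beta_qtl, se, statistic, p, p_fdr, n_used.
#' @export
run_cis_scan <- function(feature_matrix, genotypes, sheet, pairs,
                         model_spec = epicohort::model_spec(),
                         layer = c("methylation", "expression"),
                         maf_min = 0.05) {
  layer <- match.arg(layer)
  spec <- as_model_spec(model_spec)
  al <- align_samples(sheet, features = feature_matrix, genotypes = genotypes,
                      allow_subset = TRUE)
  Y <- al$features; G <- al$genotypes; sheet <- al$sheet
  pairs <- pairs[pairs$snp_id %in% rownames(G) &
                   pairs$feature_id %in% rownames(Y), , drop = FALSE]
  if (nrow(pairs) == 0) rlang::abort("No testable cis pairs.")
  X <- build_design(sheet, spec$covariates,
                    extra = list(disease = disease_indicator(sheet)))
  p_cov <- ncol(X)
  n <- nrow(X)
  maf_all <- apply(G, 1, minor_allele_frequency)
  keep_snp <- maf_all >= maf_min & apply(G, 1, function(g) {
    g <- g[!is.na(g)]; length(unique(g)) > 1
  })
  skipped <- unique(pairs$snp_id[!keep_snp[pairs$snp_id]])
  if (length(skipped) > 0) {
    rlang::inform(paste0(length(skipped),
                         " SNP(s) skipped (MAF filter or monomorphic)."))
  }
  pairs <- pairs[keep_snp[pairs$snp_id], , drop = FALSE]
  complete_g <- !anyNA(G)
  RY <- residualize(Y, X)
  RG <- if (complete_g) residualize(G, X) else NULL
  rows <- purrr::pmap(pairs, function(snp_id, feature_id, distance_bp, ...) {
    g <- G[snp_id, ]
    if (anyNA(g)) {
      ok <- !is.na(g)
      fit <- fit_linear_model(Y[feature_id, ok], g[ok],
                              X[ok, -1, drop = FALSE])
      return(tibble::tibble(snp_id = snp_id, feature_id = feature_id,
                            distance_bp = distance_bp,
                            maf_all = maf_all[snp_id],
                            beta_qtl = fit$estimate, se = fit$se,
                            statistic = fit$statistic, p = fit$p,
                            n_used = sum(ok)))
    }
    ry <- RY[feature_id, ]
    rg <- RG[snp_id, ]
    sxx <- sum(rg^2)
    slope <- sum(rg * ry) / sxx
    rss <- sum(ry^2) - slope^2 * sxx
    df <- n - p_cov - 1
    se <- sqrt(rss / df / sxx)
    tval <- slope / se
    tibble::tibble(snp_id = snp_id, feature_id = feature_id,
                   distance_bp = distance_bp, maf_all = maf_all[snp_id],
                   beta_qtl = slope, se = se, statistic = tval,
                   p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                   n_used = n)
  })
  res <- dplyr::bind_rows(rows)
  res$layer <- layer
  res$p_fdr <- stats::p.adjust(res$p, "BH")
  res <- dplyr::arrange(res, .data$p)
  res <- dplyr::select(res, "snp_id", "feature_id", "layer", "distance_bp",
                       "maf_all", "beta_qtl", "se", "statistic", "p", "p_fdr",
                       "n_used")
  structure(res, class = c("qtl_scan", class(res)))
}

#' Genotype-by-disease interaction QTL scan
#'
#' Per pair, the full-cohort model adds a dosage-by-disease interaction term
#' to the cis model (dosage + disease + covariates), recording the
#' interaction effect `beta_int` and its p-value. Case-only and control-only
#' stratified fits (dosage + covariates) give the per-group QTL effects. The
#' case-group MAF is recorded for the disease-dependent filter.
#'
#' @inheritParams run_cis_scan
#' @return Tibble of class `interaction_scan`: snp_id, feature_id, layer,
#'   maf_case, beta_int, se_int, p_int, beta_case, p_case, beta_ctrl,
#'   p_ctrl, n_used.
#' @export
run_interaction_scan <- function(feature_matrix, genotypes, sheet, pairs,
                                 model_spec = epicohort::model_spec(),
                                 layer = c("methylation", "expression")) {
  layer <- match.arg(layer)
  spec <- as_model_spec(model_spec)
  al <- align_samples(sheet, features = feature_matrix, genotypes = genotypes,
                      allow_subset = TRUE)
  Y <- al$features; G <- al$genotypes; sheet <- al$sheet
  pairs <- pairs[pairs$snp_id %in% rownames(G) &
                   pairs$feature_id %in% rownames(Y), , drop = FALSE]
  if (nrow(pairs) == 0) rlang::abort("No testable pairs.")
  case <- disease_indicator(sheet) == 1
  Xc <- build_design(sheet, spec$covariates)[, -1, drop = FALSE]  # no intercept
  dis <- as.numeric(case)
  strat_fit <- function(y, g, keep) {
    g <- g[keep]; y <- y[keep]
    ok <- !is.na(g)
    if (length(unique(g[ok])) < 2) {
      return(list(estimate = NA_real_, p = NA_real_, flagged = TRUE))
    }
    cv <- Xc[keep, , drop = FALSE][ok, , drop = FALSE]
    cv <- cv[, matrixStats::colVars(cv) > 0, drop = FALSE]
    tryCatch({
      f <- fit_linear_model(y[ok], g[ok], cv)
      list(estimate = f$estimate, p = f$p, flagged = FALSE)
    }, error = function(e) list(estimate = NA_real_, p = NA_real_,
                                flagged = TRUE))
  }
  rows <- purrr::pmap(pairs, function(snp_id, feature_id, ...) {
    g <- G[snp_id, ]
    y <- Y[feature_id, ]
    ok <- !is.na(g)
    maf_case <- minor_allele_frequency(g[case])
    res <- tryCatch({
      Xfull <- cbind(`(Intercept)` = 1, Xc, dosage = g, disease = dis,
                     interaction = g * dis)[ok, , drop = FALSE]
      check_full_rank(Xfull)
      fit <- stats::lm.fit(Xfull, y[ok])
      dfres <- sum(ok) - ncol(Xfull)
      xtx_inv <- chol2inv(chol(crossprod(Xfull)))
      kk <- ncol(Xfull)
      se <- sqrt(sum(fit$residuals^2) / dfres * xtx_inv[kk, kk])
      tv <- fit$coefficients[kk] / se
      list(b = unname(fit$coefficients[kk]), se = se,
           p = 2 * stats::pt(abs(tv), dfres, lower.tail = FALSE))
    }, error = function(e) list(b = NA_real_, se = NA_real_, p = NA_real_))
    fc <- strat_fit(y, g, case)
    f0 <- strat_fit(y, g, !case)
    tibble::tibble(snp_id = snp_id, feature_id = feature_id, layer = layer,
                   maf_case = maf_case, beta_int = res$b, se_int = res$se,
                   p_int = res$p, beta_case = fc$estimate, p_case = fc$p,
                   beta_ctrl = f0$estimate, p_ctrl = f0$p,
                   stratum_flagged = fc$flagged | f0$flagged,
                   n_used = sum(ok))
  })
  res <- dplyr::bind_rows(rows)
  res <- dplyr::arrange(res, .data$p_int)
  structure(res, class = c("interaction_scan", class(res)))
}

#' Disease-dependent QTL filter
#'
#' Joins discovery and replication interaction scans on (SNP, feature) and
#' keeps pairs satisfying all of: (i) interaction p below `p_int` in
#' discovery and below `p_int_repl` in replication with consistent
#' interaction sign; (ii) a within-case QTL (`p_case < p_case_max`, or case
#' FDR when `ss_evidence = "fdr"`) with no control-group evidence
#' (`p_ctrl > p_ctrl_min`); (iii) case-group MAF above `maf_case_min`.
#' Per-condition audit columns and failure reasons are returned for every
#' pair.
#'
#' @param discovery,replication `interaction_scan` tibbles.
#' @param p_int,p_int_repl Interaction significance thresholds (0.005, 0.05).
#' @param p_case_max,p_ctrl_min Case/control stratified thresholds (0.05).
#' @param maf_case_min Case MAF floor (0.10).
#' @param ss_evidence `"p"` (nominal case p, default) or `"fdr"`
#'   (Benjamini-Hochberg over the case p-values).
#' @return Tibble of class `dd_qtl`: all discovery columns plus
#'   replication_beta_int, replication_p_int, per-condition booleans,
#'   passes_filter and filter_reasons (list-column).
#' @export
select_disease_dependent <- function(discovery, replication,
                                     p_int = 0.005, p_int_repl = 0.05,
                                     p_case_max = 0.05, p_ctrl_min = 0.05,
                                     maf_case_min = 0.10,
                                     ss_evidence = c("p", "fdr")) {
  ss_evidence <- match.arg(ss_evidence)
  repl <- dplyr::select(tibble::as_tibble(replication), "snp_id", "feature_id",
                        replication_beta_int = "beta_int",
                        replication_p_int = "p_int")
  out <- dplyr::left_join(tibble::as_tibble(discovery), repl,
                          by = c("snp_id", "feature_id"))
  case_p <- if (ss_evidence == "fdr") stats::p.adjust(out$p_case, "BH") else out$p_case
  out$cond_interaction <- !is.na(out$p_int) & out$p_int < p_int &
    !is.na(out$replication_p_int) & out$replication_p_int < p_int_repl &
    sign(out$beta_int) == sign(out$replication_beta_int)
  out$cond_case_only <- !is.na(case_p) & case_p < p_case_max &
    (is.na(out$p_ctrl) | out$p_ctrl > p_ctrl_min)
  out$cond_maf <- !is.na(out$maf_case) & out$maf_case > maf_case_min
  out$passes_filter <- out$cond_interaction & out$cond_case_only & out$cond_maf
  out$filter_reasons <- purrr::pmap(
    list(out$cond_interaction, out$cond_case_only, out$cond_maf,
         is.na(out$replication_p_int), !is.na(out$p_ctrl) & out$p_ctrl <= p_ctrl_min),
    function(ci, cc, cm, norep, ctrlsig) {
      r <- character(0)
      if (norep) r <- c(r, "no_replication")
      if (!ci) r <- c(r, "interaction_not_supported")
      if (ctrlsig) r <- c(r, "ctrl_significant")
      if (!cc) r <- c(r, "no_case_only_qtl")
      if (!cm) r <- c(r, "maf_case_low")
      r
    })
  out <- dplyr::arrange(out, dplyr::desc(.data$passes_filter), .data$p_int)
  structure(out, class = c("dd_qtl", class(out)))
}
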