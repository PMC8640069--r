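# Case-control genetic association under the additive logistic model,
# mediation-direction consistency classification for QTL SNPs, the
# epigenetic IFN-signature classifier, and the six-model HLA
# stratified/conditional suite.

#' Additive logistic association of a variant with case status
#'
#' Maximum-likelihood logistic regression of disease status on allele dosage
#' plus covariates (IRLS via `glm`, deviance tolerance 1e-12, up to 100
#' iterations);
#' Wald test on the dosage term. Complete separation and non-convergence are
#' flagged rather than fatal.
#'
#' @param dosage Allele dosage vector in \[0, 2\] (fractional allowed).
#' @param status Binary outcome (1 = case) or case/control strings.
#' @param covariates Optional numeric design columns (data frame or matrix).
#' @param snp_id Label carried into the record.
#' @param model_tag Free-text tag describing the model.
#' @return One-row tibble: snp_id, beta_logit, or_, se, p, n_used,
#'   model_tag, flagged.
#' @export
fit_logistic_additive <- function(dosage, status, covariates = NULL,
                                  snp_id = "snp", model_tag = "additive") {
  y <- if (is.numeric(status)) status else as.numeric(status == "case")
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  d <- dosage[ok]; yy <- y[ok]
  if (length(unique(yy)) < 2) rlang::abort("Both outcome classes required.")
  if (length(unique(d)) < 2) rlang::abort("Dosage is constant.")
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(covariates)) covariates[ok, , drop = FALSE],
             dosage = d)
  check_full_rank(X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, yy, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  k <- ncol(X)
  flagged <- sep || !fit$converged || abs(fit$coefficients[k]) > 15
  if (flagged) {
    return(tibble::tibble(snp_id = snp_id, beta_logit = NA_real_,
                          or_ = NA_real_, se = NA_real_, p = NA_real_,
                          n_used = sum(ok), model_tag = model_tag,
                          flagged = TRUE))
  }
  cov_u <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  b <- unname(fit$coefficients[k])
  se <- sqrt(cov_u[k, k])
  z <- b / se
  tibble::tibble(snp_id = snp_id, beta_logit = b, or_ = exp(b), se = se,
                 p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                 n_used = sum(ok), model_tag = model_tag, flagged = FALSE)
}

#' Case-control association scan over a dosage matrix
#'
#' Applies [fit_logistic_additive()] to every row of a dosage matrix with the
#' given sheet covariates. Default covariates follow the additive SNP model:
#' genetic PC1, sex and age.
#'
#' @param genotypes Dosage matrix (variant x sample).
#' @param sheet Sample sheet.
#' @param covariates Sheet columns used as covariates.
#' @param alpha Optional significance level; a Bonferroni column over tested
#'   variants is always added.
#' @return Tibble of class `assoc_scan`.
#' @export
run_assoc_scan <- function(genotypes, sheet,
                           covariates = c("pc1", "sex", "age"),
                           alpha = 0.05) {
  al <- align_samples(sheet, genotypes = genotypes)
  G <- al$genotypes; sheet <- al$sheet
  X <- build_design(sheet, covariates)[, -1, drop = FALSE]
  y <- disease_indicator(sheet)
  rows <- lapply(rownames(G), function(s) {
    g <- G[s, ]
    tryCatch(fit_logistic_additive(g, y, X, snp_id = s),
             error = function(e) tibble::tibble(
               snp_id = s, beta_logit = NA_real_, or_ = NA_real_,
               se = NA_real_, p = NA_real_, n_used = sum(!is.na(g)),
               model_tag = "additive", flagged = TRUE))
  })
  res <- dplyr::bind_rows(rows)
  m <- sum(!is.na(res$p))
  res$p_bonferroni <- pmin(1, res$p * m)
  res <- dplyr::arrange(res, .data$p)
  structure(res, class = c("assoc_scan", class(res)), m_tests = m,
            alpha = alpha)
}

#' Mediation-direction consistency of QTL, disease effect and risk
#'
#' For SNPs whose case-control association passes `alpha_snp`, classifies
#' whether the per-allele molecular effect, the case-control molecular
#' difference and the allelic disease risk point the same way:
#' `consistent` iff `sign(beta_qtl) * sign(log OR) == sign(beta_disease)`.
#' An odds ratio of exactly 1 has no direction and is flagged `null_assoc`.
#'
#' @param qtl_table QTL records (snp_id, feature_id, layer, beta_qtl).
#' @param disease_effect_table Per-feature disease effects: feature_id plus
#'   `estimate` (methylation beta difference) or `log2fc`.
#' @param assoc_table [run_assoc_scan()] output (snp_id, beta_logit, or_, p).
#' @param alpha_snp Association significance required before a verdict.
#' @return Tibble of class `mediation_verdicts`: snp_id, feature_id, layer,
#'   beta_qtl, beta_disease_feature, or_, consistent, narrative, flag.
#' @export
mediation_consistency <- function(qtl_table, disease_effect_table,
                                  assoc_table, alpha_snp) {
  eff <- tibble::as_tibble(disease_effect_table)
  if (!"feature_id" %in% names(eff) && "gene_id" %in% names(eff)) {
    eff <- dplyr::rename(eff, feature_id = "gene_id")
  }
  eff_col <- if ("log2fc" %in% names(eff)) "log2fc" else "estimate"
  eff <- dplyr::select(eff, "feature_id",
                       beta_disease_feature = dplyr::all_of(eff_col))
  a <- dplyr::select(tibble::as_tibble(assoc_table), "snp_id", "beta_logit",
                     "or_", assoc_p = "p")
  out <- dplyr::inner_join(tibble::as_tibble(qtl_table), a, by = "snp_id")
  n_miss <- nrow(qtl_table) - nrow(out)
  if (n_miss > 0) {
    rlang::inform(paste0(n_miss, " QTL row(s) had no association record."))
  }
  out <- dplyr::inner_join(out, eff, by = "feature_id")
  out <- out[!is.na(out$assoc_p) & out$assoc_p < alpha_snp, , drop = FALSE]
  lo <- log(out$or_)
  out$flag <- rep(NA_character_, nrow(out))
  out$flag[!is.na(lo) & lo == 0] <- "null_assoc"
  out$consistent <- lo != 0 &
    sign(out$beta_qtl) * sign(lo) == sign(out$beta_disease_feature)
  out$narrative <- purrr::pmap_chr(
    list(out$beta_qtl, lo, out$beta_disease_feature,
         out$layer %||% rep("methylation", nrow(out))),
    function(bq, lor, bd, layer) {
      word <- if (layer == "expression") "expression" else "methylation"
      paste0("risk allele ", if (lor > 0) "" else "(protective) ",
             if (bq < 0) "lowers " else if (bq > 0) "raises " else "leaves ",
             word, "; feature ",
             if (bd < 0) "down" else "up", " in cases")
    })
  keep <- c("snp_id", "feature_id", "layer", "beta_qtl",
            "beta_disease_feature", "or_", "consistent", "narrative", "flag")
  out <- dplyr::select(out, dplyr::any_of(keep))
  structure(out, class = c("mediation_verdicts", class(out)))
}

#' Classify samples by the epigenetic IFN signature
#'
#' Methylation at a proxy interferon-regulated CpG below the cutoff marks a
#' sample as signature-positive (hypomethylated); at or above the cutoff,
#' negative.
#'
#' @param proxy_betas Named numeric vector of beta values at the proxy CpG
#'   (names are sample ids).
#' @param cutoff Beta cutoff (default 0.8).
#' @return Tibble: sample_id, proxy_beta, label (`positive`/`negative`, NA
#'   for missing betas).
#' @export
classify_epig_ifn <- function(proxy_betas, cutoff = 0.8) {
  tibble::tibble(
    sample_id = names(proxy_betas),
    proxy_beta = unname(proxy_betas),
    label = dplyr::case_when(
      is.na(proxy_betas) ~ NA_character_,
      proxy_betas < cutoff ~ "positive",
      TRUE ~ "negative"))
}

#' Six-model HLA association suite
#'
#' Per HLA allele dosage: (1) logistic disease ~ dosage + sex + age;
#' (2) logistic SSA ~ dosage + sex + age among cases; (3) linear proxy-CpG
#' beta ~ dosage + sex + age + cells + batch among cases; (4) model 3 with
#' SSA added; (5)/(6) model 1 restricted to IFN-signature-positive
#' (respectively negative) cases versus all controls. Bonferroni adjustment
#' over alleles tested, within each model.
#'
#' @param hla HLA dosage matrix (allele x sample).
#' @param sheet Sample sheet (needs ssa).
#' @param proxy_betas Named beta vector at the proxy CpG (cases at least).
#' @param cutoff IFN-signature beta cutoff (default 0.8).
#' @param alpha Per-model significance level before Bonferroni (default
#'   0.05).
#' @return Tibble of class `hla_suite`: allele, model (ss_hla, ssa_hla,
#'   ifn_hla, ifn_hla_ssa, ss_hla_ifn_pos, ss_hla_ifn_neg), estimate, se, p,
#'   p_bonferroni, n_used, flagged.
#' @export
hla_suite <- function(hla, sheet, proxy_betas, cutoff = 0.8, alpha = 0.05) {
  al <- align_samples(sheet, hla = hla)
  H <- al$hla; sheet <- al$sheet
  case <- disease_indicator(sheet) == 1
  pb <- proxy_betas[sheet$sample_id]
  labels <- classify_epig_ifn(stats::setNames(pb, sheet$sample_id), cutoff)
  ifn_pos <- labels$label == "positive" & !is.na(labels$label)
  ifn_neg <- labels$label == "negative" & !is.na(labels$label)
  X_sa <- build_design(sheet, c("sex", "age"))[, -1, drop = FALSE]
  X_full <- build_design(sheet, c("sex", "age", "cells", "batch"))[, -1, drop = FALSE]
  ssa_pos <- as.numeric(sheet$ssa == "positive")
  logistic_row <- function(allele, d, y, keep, cv, tag) {
    tryCatch({
      cv2 <- cv[keep, , drop = FALSE]
      cv2 <- cv2[, matrixStats::colVars(cv2) > 0, drop = FALSE]
      r <- fit_logistic_additive(d[keep], y[keep], cv2, snp_id = allele,
                                 model_tag = tag)
      tibble::tibble(allele = allele, model = tag, estimate = r$beta_logit,
                     or_ = r$or_, se = r$se, p = r$p, n_used = r$n_used,
                     flagged = r$flagged)
    }, error = function(e) tibble::tibble(
      allele = allele, model = tag, estimate = NA_real_, or_ = NA_real_,
      se = NA_real_, p = NA_real_, n_used = sum(keep), flagged = TRUE))
  }
  linear_row <- function(allele, d, y, keep, cv, tag) {
    tryCatch({
      keep2 <- keep & !is.na(y)
      cv2 <- cv[keep2, , drop = FALSE]
      cv2 <- cv2[, matrixStats::colVars(cv2) > 0, drop = FALSE]
      f <- fit_linear_model(y[keep2], d[keep2], cv2)
      tibble::tibble(allele = allele, model = tag, estimate = f$estimate,
                     or_ = NA_real_, se = f$se, p = f$p, n_used = sum(keep2),
                     flagged = isTRUE(f$degenerate))
    }, error = function(e) tibble::tibble(
      allele = allele, model = tag, estimate = NA_real_, or_ = NA_real_,
      se = NA_real_, p = NA_real_, n_used = sum(keep), flagged = TRUE))
  }
  all_rows <- lapply(rownames(H), function(allele) {
    d <- H[allele, ]
    dplyr::bind_rows(
      logistic_row(allele, d, as.numeric(case), rep(TRUE, length(d)), X_sa, "ss_hla"),
      logistic_row(allele, d, ssa_pos, case, X_sa, "ssa_hla"),
      linear_row(allele, d, pb, case, X_full, "ifn_hla"),
      linear_row(allele, d, pb, case, cbind(X_full, ssa = ssa_pos), "ifn_hla_ssa"),
      logistic_row(allele, d, as.numeric(case), ifn_pos | !case, X_sa, "ss_hla_ifn_pos"),
      logistic_row(allele, d, as.numeric(case), ifn_neg | !case, X_sa, "ss_hla_ifn_neg"))
  })
  res <- dplyr::bind_rows(all_rows)
  n_alleles <- length(unique(res$allele))
  res$p_bonferroni <- pmin(1, res$p * n_alleles)
  structure(res, class = c("hla_suite", class(res)), n_alleles = n_alleles,
            alpha = alpha)
}
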