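test_that("the OLS engine reproduces the closed-form two-group fit", {
  f <- fit_linear_model(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(f$estimate, 2)
  expect_equal(f$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(f$statistic, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(f$df, 2)
  expect_equal(f$p, 2 * pt(2 * sqrt(2), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(f$p, 4), 0.1056)
})

test_that("the OLS engine matches the normal-equations oracle on random designs", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(12:40, 1)
    k <- sample(0:3, 1)
    covs <- if (k > 0) matrix(rnorm(n * k), n) else NULL
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    y <- rnorm(n)
    f <- fit_linear_model(y, g, covs)
    X <- cbind(1, covs, g)
    o <- ols_oracle(y, X)
    expect_equal(f$estimate, unname(o$coef[ncol(X)]), tolerance = 1e-8)
    expect_equal(f$se, unname(o$se[ncol(X)]), tolerance = 1e-8)
    expect_equal(f$p, unname(o$p[ncol(X)]), tolerance = 1e-8)
  }
})

test_that("degenerate designs are refused or flagged", {
  expect_error(fit_linear_model(1:4, rep(1, 4)), "constant")
  f <- fit_linear_model(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(f$estimate, 0)
  expect_equal(f$p, 1)
  expect_true(f$degenerate)
  x <- rnorm(8)
  expect_error(fit_linear_model(rnorm(8), rep(c(0, 1), 4),
                                cbind(a = x, b = 2 * x)),
               "collinear")
})

test_that("a response equal to a covariate yields a zero group estimate", {
  set.seed(5)
  x <- rnorm(8)
  g <- rep(c(0, 1), each = 4)
  f <- fit_linear_model(x, g, cbind(x = x))
  expect_equal(f$estimate, 0, tolerance = 1e-10)
})

test_that("bonferroni_threshold is alpha over m and rejects m = 0", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 20), 5e-4)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("DMP scan records, ordering and adjustments are coherent", {
  sim <- small_cohort
  dmp <- run_dmp_scan(sim$methylation, sim$sheet)
  expect_equal(nrow(dmp), nrow(sim$methylation))
  expect_false(is.unsorted(dmp$p))
  expect_equal(dmp$p_bonferroni, pmin(1, dmp$p * nrow(dmp)))
  expect_equal(dmp$delta_beta, dmp$mean_case - dmp$mean_control)
  expect_true(all(dmp$p >= 0 & dmp$p <= 1))
  # planted DMPs dominate the top of the table
  thr <- bonferroni_threshold(0.05, nrow(dmp))
  planted <- names(sim$truth$dmp_effects)
  expect_gte(mean(dmp$p[match(planted, dmp$feature_id)] < thr), 0.9)
})

test_that("effect estimate and observed delta beta agree in sign without covariates", {
  sim <- small_cohort
  dmp <- run_dmp_scan(sim$methylation, sim$sheet, model_spec(character(0)))
  nz <- abs(dmp$delta_beta) > 1e-8
  expect_true(all(sign(dmp$estimate[nz]) == sign(dmp$delta_beta[nz])))
  expect_equal(dmp$estimate, dmp$delta_beta, tolerance = 1e-8)
})

test_that("Brown-Forsythe evaluates the hand-computed example and symmetry", {
  case <- c(TRUE, TRUE, FALSE, FALSE)
  r <- epicohort:::brown_forsythe_row(c(0, 2, 1, 3), case)
  expect_equal(unname(r["stat"]), 0)
  expect_equal(unname(r["p"]), 1)
  # identical residual distributions in both groups
  z <- c(1.3, -0.2, 0.8, 1.3, -0.2, 0.8)
  r2 <- epicohort:::brown_forsythe_row(z, rep(c(TRUE, FALSE), each = 3))
  expect_equal(unname(r2["stat"]), 0)
})

test_that("the variance test is exactly invariant to group-wise mean shifts", {
  set.seed(9)
  r <- rnorm(40)
  case <- rep(c(TRUE, FALSE), each = 20)
  a <- epicohort:::brown_forsythe_row(r, case)
  shifted <- r + ifelse(case, 5.3, 0)
  b <- epicohort:::brown_forsythe_row(shifted, case)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("VMP scan detects planted variance inflation and reports ratios", {
  sim <- small_cohort
  vmp <- run_vmp_scan(sim$methylation, sim$sheet)
  planted <- names(sim$truth$vmp_features)
  hit <- vmp$p[match(planted, vmp$feature_id)] < 0.05
  expect_gte(mean(hit), 0.9)
  expect_true(all(vmp$var_case >= 0 & vmp$var_control >= 0))
  # classic mean-centred Levene is available and broadly agrees
  vmp_mean <- run_vmp_scan(sim$methylation, sim$sheet, center = "mean")
  expect_gt(cor(-log10(vmp$p), -log10(vmp_mean$p[match(vmp$feature_id,
                                                       vmp_mean$feature_id)])),
            0.9)
})

test_that("sensitivity refit with an uninformative covariate is a no-op", {
  sim <- small_cohort
  sheet <- sim$sheet
  # covariate orthogonal to everything: residualize noise on design and data
  feats <- names(sim$truth$dmp_effects)
  Y <- sim$methylation[feats, ]
  X <- epicohort:::build_design(sheet, model_spec()$covariates,
                                extra = list(d = as.numeric(sheet$disease == "case")))
  set.seed(2)
  z <- rnorm(nrow(sheet))
  z <- residuals(lm(z ~ X + t(Y)))
  sheet$inert <- z
  out <- sensitivity_refit(sim$methylation, sheet, model_spec(), "inert", feats)
  expect_equal(out$effect_correlation, 1, tolerance = 1e-6)
  expect_error(sensitivity_refit(sim$methylation, sheet, model_spec(), "inert",
                                 character(0)), "Empty")
  expect_error(sensitivity_refit(sim$methylation, sheet, model_spec(),
                                 "absent_col", feats), "not in sheet")
})

test_that("a treatment that mediates part of the signal lowers the correlation", {
  sim <- small_cohort
  sheet <- sim$sheet
  case <- sheet$disease == "case"
  set.seed(31)
  treated <- case & runif(nrow(sheet)) < 0.6
  sheet$planted_treatment <- treated
  meth <- sim$methylation
  feats <- names(sim$truth$dmp_effects)
  mediated <- feats[1:3]
  # make the case effect at mediated sites flow through the treatment
  meth[mediated, ] <- meth[mediated, ] -
    outer(unlist(sim$truth$dmp_effects[mediated]), as.numeric(case)) +
    outer(unlist(sim$truth$dmp_effects[mediated]), as.numeric(treated))
  meth <- pmin(pmax(meth, 0), 1)
  out <- sensitivity_refit(meth, sheet, model_spec(), "planted_treatment", feats)
  expect_lt(out$effect_correlation, 0.999)
  expect_lt(out$fraction_retained, 1)
})

test_that("stratified scan: whole-cohort stratum equals the plain scan", {
  sim <- small_cohort
  a <- run_dmp_scan(sim$methylation, sim$sheet)
  b <- stratified_scan(sim$methylation, sim$sheet,
                       stratum = rep(TRUE, nrow(sim$sheet)))
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_error(stratified_scan(sim$methylation, sim$sheet,
                               stratum = sim$sheet$disease == "case"),
               "both cases and controls")
})

test_that("autoantibody stratification isolates the IFN-block signal", {
  sim <- small_cohort
  blk <- sim$truth$ifn_block
  keep_pos <- sim$sheet$disease == "control" | sim$sheet$ssa == "positive"
  pos <- stratified_scan(sim$methylation, sim$sheet, stratum = keep_pos)
  d_pos <- pos$delta_beta[match(blk, pos$feature_id)]
  expect_lt(abs(mean(d_pos) + sim$config$ifn_delta_beta), 0.06)
  thr <- bonferroni_threshold(0.05, nrow(pos))
  expect_gte(mean(pos$p[match(blk, pos$feature_id)] < thr), 0.9)

  keep_neg <- sim$sheet$disease == "control" |
    (sim$sheet$disease == "case" & sim$sheet$ssa == "negative")
  neg <- stratified_scan(sim$methylation, sim$sheet, stratum = keep_neg)
  expect_gte(min(neg$p_bonferroni[match(blk, neg$feature_id)]), 0.05)

  cond <- stratified_scan(sim$methylation, sim$sheet, condition_on = "ssa")
  expect_gte(min(cond$p_bonferroni[match(blk, cond$feature_id)]), 0.05)
})
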