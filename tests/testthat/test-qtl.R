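test_that("minor allele frequency folds correctly and handles fractions", {
  expect_equal(minor_allele_frequency(c(0, 1, 2, 1)), 0.5)
  expect_equal(minor_allele_frequency(c(0, 0, 0, 1)), 0.125)
  expect_equal(minor_allele_frequency(c(0.5, 1.5)), 0.5)
  expect_equal(minor_allele_frequency(c(2, 2, 2, 1)), 0.125)
  expect_equal(minor_allele_frequency(c(1, NA, 0)), 0.25)
  expect_error(minor_allele_frequency(c(NA_real_, NA_real_)), "missing")
})

test_that("cis pairing is boundary-inclusive and chromosome-aware", {
  feats <- tibble::tibble(feature_id = "cg1", chrom = "chr1", pos = 5000000L)
  snps <- tibble::tibble(feature_id = c("in", "out", "offchrom"),
                         chrom = c("chr1", "chr1", "chr2"),
                         pos = c(4000000L, 3999999L, 5000000L))
  pairs <- cis_pairs(feats, snps, window = 1000000)
  expect_equal(pairs$snp_id, "in")
  expect_equal(pairs$distance_bp, 1000000)
})

test_that("the fast cis scan equals per-pair full OLS exactly", {
  sim <- small_cohort
  pairs <- cis_pairs(sim$cpg_annotation[1:20, ], sim$snp_annotation)
  pairs <- pairs[1:15, ]
  scan <- run_cis_scan(sim$methylation, sim$genotypes, sim$sheet, pairs,
                       layer = "methylation", maf_min = 0)
  X <- epicohort:::build_design(
    sim$sheet, model_spec()$covariates,
    extra = list(disease = as.numeric(sim$sheet$disease == "case")))
  for (i in seq_len(nrow(scan))) {
    y <- sim$methylation[scan$feature_id[i], ]
    g <- sim$genotypes[scan$snp_id[i], ]
    o <- ols_oracle(y, cbind(X, g = g))
    expect_equal(scan$beta_qtl[i], unname(o$coef["g"]), tolerance = 1e-10)
    expect_equal(scan$se[i], unname(o$se["g"]), tolerance = 1e-10)
    expect_equal(scan$p[i], unname(o$p[length(o$p)]), tolerance = 1e-10)
  }
})

test_that("missing dosages fall back to complete-case OLS for that SNP only", {
  sim <- small_cohort
  G <- sim$genotypes
  G["snp00005", 1:7] <- NA
  pairs <- tibble::tibble(snp_id = c("snp00005", "snp00010"),
                          feature_id = c("cpg00001", "cpg00002"),
                          distance_bp = c(0, 0))
  scan <- run_cis_scan(sim$methylation, G, sim$sheet, pairs,
                       layer = "methylation", maf_min = 0)
  expect_equal(sort(scan$n_used), c(ncol(G) - 7, ncol(G)))
  ok <- !is.na(G["snp00005", ])
  X <- epicohort:::build_design(
    sim$sheet[ok, ], model_spec()$covariates,
    extra = list(disease = as.numeric(sim$sheet$disease[ok] == "case")))
  o <- ols_oracle(sim$methylation["cpg00001", ok],
                  cbind(X, g = G["snp00005", ok]))
  i <- which(scan$snp_id == "snp00005")
  expect_equal(scan$beta_qtl[i], unname(o$coef["g"]), tolerance = 1e-10)
})

test_that("monomorphic or low-MAF SNPs are skipped with a message", {
  sim <- small_cohort
  G <- sim$genotypes
  G["snp00003", ] <- 1
  pairs <- tibble::tibble(snp_id = c("snp00003", "snp00010"),
                          feature_id = c("cpg00001", "cpg00002"),
                          distance_bp = c(0, 0))
  expect_message(scan <- run_cis_scan(sim$methylation, G, sim$sheet, pairs,
                                      layer = "methylation", maf_min = 0),
                 "skipped")
  expect_false("snp00003" %in% scan$snp_id)
})

test_that("planted cis effects are recovered with correct magnitude", {
  sim <- small_cohort
  tr <- sim$truth$meqtl
  pairs <- tibble::tibble(snp_id = tr$snp_id, feature_id = tr$feature_id,
                          distance_bp = 0)
  scan <- run_cis_scan(sim$methylation, sim$genotypes, sim$sheet, pairs,
                       layer = "methylation")
  j <- dplyr::inner_join(tibble::as_tibble(scan), tr,
                         by = c("snp_id", "feature_id"))
  expect_gt(cor(j$beta_qtl, j$effect), 0.95)
  expect_true(all(j$p_fdr < 0.05))
})

test_that("interaction model recovers the stratified-fit algebra", {
  set.seed(77)
  n <- 300
  sheet <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                          disease = rep(c("case", "control"), each = n / 2),
                          sex = "F", age = 50)
  case <- as.numeric(sheet$disease == "case")
  g <- matrix(rbinom(n, 2, 0.4), 1, dimnames = list("snpA", sheet$sample_id))
  beta_main <- 0.03; beta_int <- 0.05
  y <- 0.5 + beta_main * g[1, ] + beta_int * g[1, ] * case + rnorm(n, 0, 0.05)
  Y <- matrix(pmin(pmax(y, 0), 1), 1, dimnames = list("cgA", sheet$sample_id))
  pairs <- tibble::tibble(snp_id = "snpA", feature_id = "cgA")
  res <- run_interaction_scan(Y, g, sheet, pairs, model_spec(character(0)),
                              layer = "methylation")
  expect_lt(abs((res$beta_case - res$beta_ctrl) - res$beta_int), 0.02)
  expect_lt(abs(res$beta_int - beta_int), 0.02)
  expect_lt(res$p_case, 0.05)
})

test_that("case-only effects pass the disease-dependent filter; shared effects fail", {
  sim <- small_cohort
  tr <- sim$truth$interaction_qtl
  tr_m <- tr[tr$layer == "methylation", ]
  pairs <- tibble::tibble(snp_id = c(tr_m$snp_id, sim$truth$meqtl$snp_id),
                          feature_id = c(tr_m$feature_id,
                                         sim$truth$meqtl$feature_id))
  scan <- run_interaction_scan(sim$methylation, sim$genotypes, sim$sheet,
                               pairs, layer = "methylation")
  dd <- select_disease_dependent(scan, scan, p_int = 0.05, p_int_repl = 0.05)
  got <- dd[match(tr_m$feature_id, dd$feature_id), ]
  # planted case-only pairs show case-stratum signal without control signal
  expect_gte(mean(got$p_case < 0.05, na.rm = TRUE), 0.6)
  shared <- dd[dd$feature_id %in% sim$truth$meqtl$feature_id, ]
  # equal planted effect in both groups leaves no interaction
  expect_lt(mean(shared$passes_filter), 0.3)
})

test_that("the three-condition filter audits every failure mode", {
  base <- tibble::tibble(snp_id = "rs1", feature_id = "f1",
                         layer = "methylation", maf_case = 0.15,
                         beta_int = -0.018, se_int = 0.005, p_int = 1.6e-4,
                         beta_case = -0.016, p_case = 6e-4,
                         beta_ctrl = NA_real_, p_ctrl = NA_real_,
                         stratum_flagged = TRUE, n_used = 400)
  repl <- tibble::tibble(snp_id = "rs1", feature_id = "f1",
                         beta_int = -0.020, p_int = 0.0061)
  pass <- select_disease_dependent(base, dplyr::bind_cols(
    repl[, c("snp_id", "feature_id")], layer = "methylation", maf_case = 0.15,
    beta_int = repl$beta_int, se_int = 0.006, p_int = repl$p_int,
    beta_case = -0.02, p_case = 0.01, beta_ctrl = NA_real_, p_ctrl = NA_real_,
    stratum_flagged = TRUE, n_used = 150))
  expect_true(pass$passes_filter)

  flip <- base; flip$p_ctrl <- 0.03; flip$beta_ctrl <- -0.01
  fail_ctrl <- select_disease_dependent(flip, base)
  expect_false(fail_ctrl$passes_filter)
  expect_true("ctrl_significant" %in% unlist(fail_ctrl$filter_reasons))

  opp <- base; opp$beta_int <- 0.018
  fail_sign <- select_disease_dependent(opp, base)
  expect_false(fail_sign$passes_filter)

  lowmaf <- base; lowmaf$maf_case <- 0.08
  fail_maf <- select_disease_dependent(lowmaf, base)
  expect_false(fail_maf$passes_filter)
  expect_true("maf_case_low" %in% unlist(fail_maf$filter_reasons))

  norep <- select_disease_dependent(base, base[0, ])
  expect_false(norep$passes_filter)
  expect_true("no_replication" %in% unlist(norep$filter_reasons))
})

test_that("the filter is idempotent and order-independent", {
  sim <- small_cohort
  tr <- sim$truth$interaction_qtl
  pairs <- tibble::tibble(snp_id = tr$snp_id, feature_id = tr$feature_id)
  scan <- run_interaction_scan(sim$methylation, sim$genotypes, sim$sheet,
                               pairs[tr$layer == "methylation", ],
                               layer = "methylation")
  a <- select_disease_dependent(scan, scan)
  b <- select_disease_dependent(a[, names(scan)], scan)
  expect_equal(a$passes_filter, b$passes_filter)
  shuffled <- scan[rev(seq_len(nrow(scan))), ]
  c2 <- select_disease_dependent(shuffled, scan)
  j <- dplyr::inner_join(tibble::as_tibble(a),
                         tibble::as_tibble(c2)[, c("snp_id", "feature_id",
                                                   "passes_filter")],
                         by = c("snp_id", "feature_id"))
  expect_equal(j$passes_filter.x, j$passes_filter.y)
})

test_that("fully null interaction scans almost never pass the filter", {
  set.seed(5150)
  n <- 200
  sheet <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                          disease = rep(c("case", "control"), each = n / 2),
                          sex = "F", age = 50)
  n_pairs <- 2500
  G <- matrix(rbinom(40 * n, 2, 0.3), 40,
              dimnames = list(sprintf("s%02d", 1:40), sheet$sample_id))
  Y <- matrix(runif(80 * n, 0.3, 0.7), 80,
              dimnames = list(sprintf("f%02d", 1:80), sheet$sample_id))
  pairs <- tibble::tibble(snp_id = sample(rownames(G), n_pairs, TRUE),
                          feature_id = sample(rownames(Y), n_pairs, TRUE))
  pairs <- dplyr::distinct(pairs)
  disc <- run_interaction_scan(Y, G, sheet, pairs, model_spec(character(0)),
                               layer = "methylation")
  Y2 <- matrix(runif(80 * n, 0.3, 0.7), 80, dimnames = dimnames(Y))
  repl <- run_interaction_scan(Y2, G, sheet, pairs,
                               model_spec(character(0)), layer = "methylation")
  dd <- select_disease_dependent(disc, repl)
  expect_lte(sum(dd$passes_filter), 5)
})
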