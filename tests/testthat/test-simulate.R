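test_that("identical seeds give bit-identical cohorts and truth", {
  cf <- simulation_config(n_cases = 20, n_controls = 20, n_cpgs = 80,
                          n_genes = 40, n_snps = 30, n_dmp = 5, n_vmp = 5,
                          n_deg = 5, n_meqtl = 3, n_eqtl = 3, n_int_meqtl = 2,
                          n_int_eqtl = 2, ifn_block_size = 4, seed = 7)
  a <- simulate_cohort(cf)
  b <- simulate_cohort(cf)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$expression, b$expression)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$hla, b$hla)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth, b$truth)
})

test_that("null configuration produces empty truth registries", {
  cf <- simulation_config(n_cases = 10, n_controls = 10, n_cpgs = 50,
                          n_genes = 20, n_snps = 10, n_dmp = 0, n_vmp = 0,
                          n_deg = 0, n_meqtl = 0, n_eqtl = 0, n_int_meqtl = 0,
                          n_int_eqtl = 0, ifn_block_size = 0, seed = 1)
  sim <- simulate_cohort(cf)
  expect_length(sim$truth$dmp_effects, 0)
  expect_length(sim$truth$vmp_features, 0)
  expect_length(sim$truth$deg_effects, 0)
  expect_equal(nrow(sim$truth$meqtl), 0)
  expect_equal(nrow(sim$truth$interaction_qtl), 0)
  expect_length(sim$truth$ifn_block, 0)
})

test_that("matrix value contracts hold: betas, counts, dosages", {
  sim <- small_cohort
  expect_true(all(sim$methylation >= 0 & sim$methylation <= 1))
  expect_true(all(sim$expression >= 0))
  expect_true(all(sim$expression == round(sim$expression)))
  expect_true(all(sim$genotypes %in% 0:2))
  expect_true(all(sim$hla %in% 0:2))
  cells <- as.matrix(sim$sheet[, grep("^cell_", names(sim$sheet))])
  expect_true(all(cells >= 0 & cells <= 1))
  expect_true(all(abs(rowSums(cells) - 1) < 1e-6))
  expect_true(all(sim$sheet$ssa[sim$sheet$disease == "control"] == "negative"))
})

test_that("empirical MAF matches the binomial sampling oracle", {
  cf <- simulation_config(n_cases = 500, n_controls = 500, n_cpgs = 40,
                          n_genes = 20, n_snps = 200, maf_range = c(0.3, 0.3),
                          n_dmp = 0, n_vmp = 0, n_deg = 0, n_meqtl = 0,
                          n_eqtl = 0, n_int_meqtl = 0, n_int_eqtl = 0,
                          ifn_block_size = 0, seed = 3)
  sim <- simulate_cohort(cf)
  emp <- rowMeans(sim$genotypes) / 2
  # binomial CI: sd of the frequency estimate is sqrt(.3*.7/2000) = 0.0102,
  # so +-0.05 is ~4.9 sd; nearly every SNP must fall inside
  expect_gte(mean(abs(emp - 0.3) <= 0.05), 0.95)
})

test_that("planted case-control methylation differences hit their targets", {
  cf <- simulation_config(n_cases = 200, n_controls = 200, n_cpgs = 600,
                          n_genes = 50, n_snps = 30, n_dmp = 40,
                          delta_beta_range = c(0.1, 0.36), n_vmp = 0,
                          n_deg = 0, n_meqtl = 0, n_eqtl = 0, n_int_meqtl = 0,
                          n_int_eqtl = 0, ifn_block_size = 0, seed = 11)
  sim <- simulate_cohort(cf)
  case <- sim$sheet$disease == "case"
  emp <- vapply(names(sim$truth$dmp_effects), function(cg) {
    mean(sim$methylation[cg, case]) - mean(sim$methylation[cg, !case])
  }, numeric(1))
  expect_lt(abs(mean(emp - unlist(sim$truth$dmp_effects))), 0.03)
})

test_that("case variance inflation at VMP sites matches the configured factor", {
  cf <- simulation_config(n_cases = 250, n_controls = 250, n_cpgs = 500,
                          n_genes = 50, n_snps = 30, n_dmp = 0, n_vmp = 40,
                          variance_inflation = 4, n_deg = 0, n_meqtl = 0,
                          n_eqtl = 0, n_int_meqtl = 0, n_int_eqtl = 0,
                          ifn_block_size = 0, seed = 13)
  sim <- simulate_cohort(cf)
  vmp <- run_vmp_scan(sim$methylation, sim$sheet)
  vr <- vmp$variance_ratio[vmp$feature_id %in% names(sim$truth$vmp_features)]
  expect_gt(mean(vr), 4 * 0.8)
  expect_lt(mean(vr), 4 * 1.2)
})

test_that("IFN-block hypomethylation is confined to SSA-positive cases", {
  sim <- small_cohort
  case <- sim$sheet$disease == "case"
  ssa_pos <- sim$sheet$ssa == "positive" & case
  ssa_neg <- sim$sheet$ssa == "negative" & case
  blk <- sim$truth$ifn_block
  d_pos <- mean(rowMeans(sim$methylation[blk, ssa_pos, drop = FALSE]) -
                  rowMeans(sim$methylation[blk, !case, drop = FALSE]))
  d_neg <- mean(rowMeans(sim$methylation[blk, ssa_neg, drop = FALSE]) -
                  rowMeans(sim$methylation[blk, !case, drop = FALSE]))
  expect_lt(abs(d_pos + sim$config$ifn_delta_beta), 0.06)
  expect_lt(abs(d_neg), 0.06)
})

test_that("planted interaction pairs have no control-group effect", {
  sim <- small_cohort
  tr <- sim$truth$interaction_qtl
  ctrl <- sim$sheet$disease == "control"
  # control-only regression slopes should be null-distributed
  slopes <- vapply(seq_len(nrow(tr)), function(i) {
    if (tr$layer[i] != "methylation") return(NA_real_)
    g <- sim$genotypes[tr$snp_id[i], ctrl]
    y <- sim$methylation[tr$feature_id[i], ctrl]
    unname(coef(lm(y ~ g))[2])
  }, numeric(1))
  expect_lt(mean(abs(slopes), na.rm = TRUE), 0.05)
})

test_that("config validation rejects impossible plantings", {
  expect_error(simulate_cohort(simulation_config(n_cpgs = 10, n_dmp = 20)),
               "exceed")
  expect_error(simulate_cohort(simulation_config(n_cases = 1)), "at least 2")
  expect_error(simulate_cohort(simulation_config(maf_range = c(0, 0.5))),
               "maf_range")
  expect_error(simulate_cohort(simulation_config(variance_inflation = 0.5)),
               "variance_inflation")
})

test_that("truth registry round-trips through JSON", {
  sim <- small_cohort
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(unlist(back$dmp_effects), unlist(sim$truth$dmp_effects))
  expect_equal(as.data.frame(back$meqtl), as.data.frame(sim$truth$meqtl))
  expect_equal(back$ifn_block, sim$truth$ifn_block)
  expect_equal(back$hla_risk_allele, sim$truth$hla_risk_allele)

  # hand-built two-entry registry
  tiny <- list(dmp_effects = list(cgA = -0.2, cgB = 0.1),
               vmp_features = list(), deg_effects = list(),
               meqtl = tibble::tibble(snp_id = "rs1", feature_id = "cgA",
                                      layer = "methylation", effect = 0.05),
               eqtl = tibble::tibble(snp_id = character(0),
                                     feature_id = character(0),
                                     layer = character(0), effect = numeric(0)),
               interaction_qtl = tibble::tibble(snp_id = character(0),
                                                feature_id = character(0),
                                                layer = character(0),
                                                effect = numeric(0)),
               dmr_blocks = tibble::tibble(region_id = character(0),
                                           delta_beta = numeric(0),
                                           members = list()),
               ifn_block = character(0), ifn_proxy = character(0),
               hla_risk_allele = "hla_allele_01", hla_ssa_log_odds = 1.1,
               ifn_delta_beta = 0.3)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_truth(tiny, p2)
  t2 <- read_truth(p2)
  expect_equal(unlist(t2$dmp_effects), c(cgA = -0.2, cgB = 0.1))
  expect_equal(nrow(t2$eqtl), 0)
  expect_equal(t2$meqtl$effect, 0.05)
})

test_that("cohort files written to disk reload consistently", {
  sim <- small_cohort
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  m <- read_matrix(file.path(dir, "methylation.tsv"), "methylation")
  expect_equal(unname(m), unname(sim$methylation), tolerance = 1e-10)
  vcf <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(vcf$dosages), unname(sim$genotypes))
  sheet <- read_sample_sheet(file.path(dir, "sheet.tsv"))
  expect_equal(sheet$sample_id, sim$sheet$sample_id)
  sets <- read_gmt(file.path(dir, "regions.gmt"))
  expect_equal(sets$region_id, sim$region_sets$region_id)
  expect_equal(sets$members, sim$region_sets$members)
})
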