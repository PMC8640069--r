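# Synthetic multi-omics case-control cohort generator with planted ground
# truth. Methylation is simulated on the logit scale (covariate loadings,
# disease shifts, cis genetic effects, case-only interaction effects,
# SSA-driven IFN-block hypomethylation) and inverse-logit transformed to
# betas; planted beta-scale effect sizes are calibrated numerically so the
# expected case-control (or per-allele) difference on the beta scale equals
# the configured target despite the nonlinearity. Expression is negative
# binomial with planted log2 fold changes and log-scale cis effects.
# Genotypes are independent Binomial(2, MAF) dosages.

#' Configuration for the synthetic cohort simulator
#'
#' Defaults emulate a whole-blood primary Sjogren's syndrome discovery cohort
#' (189 cases, 220 controls) at desk scale: 2000 CpGs organised into 10-CpG
#' promoter regions, 1000 genes, 500 SNPs. Planted effect sizes span the
#' ranges reported for such cohorts: case-control methylation differences up
#' to |delta beta| = 0.36, top expression log2 fold changes near 3, per-allele
#' cis effects of 0.01-0.3.
#'
#' @param n_cases,n_controls Group sizes (each >= 2).
#' @param n_cpgs,n_genes,n_snps Feature counts.
#' @param cpgs_per_region CpGs per promoter region block.
#' @param maf_range Minor-allele-frequency interval in (0, 0.5].
#' @param n_dmp Number of CpGs with a planted case-control mean shift.
#' @param delta_beta_range Magnitude interval for planted delta beta.
#' @param prop_hypo Fraction of planted DMPs that are hypomethylated in cases.
#' @param n_vmp Number of CpGs with case-only variance inflation.
#' @param variance_inflation Case/control residual-variance ratio (> 1).
#' @param n_deg Genes with planted log2 fold change.
#' @param log2fc_range Magnitude interval for planted log2 fold changes.
#' @param prop_up Fraction of planted DEGs overexpressed in cases.
#' @param nb_dispersion Negative-binomial dispersion (alpha; variance =
#'   mu + alpha mu^2).
#' @param n_meqtl,n_eqtl Planted cis QTL pair counts (both-group effects).
#' @param n_int_meqtl,n_int_eqtl Planted case-only (interaction) QTL pairs.
#' @param qtl_effect_range Per-allele effect magnitude interval (beta scale
#'   for methylation, natural-log scale for expression).
#' @param qtl_effect_range_expr Optional separate interval for the
#'   expression layer (log scale); defaults to `qtl_effect_range`.
#' @param n_dmr_blocks Promoter regions given a small coherent shift at every
#'   member CpG (the region-level signal a single-CpG scan misses).
#' @param dmr_block_delta Signed per-CpG delta beta inside planted blocks.
#' @param n_hla_alleles Number of classical HLA allele dosage columns.
#' @param hla_ssa_log_odds Log-odds of SSA positivity per risk-allele dose.
#' @param ifn_block_size CpGs in the interferon-regulated block.
#' @param ifn_delta_beta Hypomethylation depth of the IFN block in
#'   SSA-positive cases (beta scale, in (0, 1)).
#' @param confounded_batch Assign batch preferentially to cases.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_cases = 189, n_controls = 220,
                              n_cpgs = 2000, n_genes = 1000, n_snps = 500,
                              cpgs_per_region = 10,
                              maf_range = c(0.05, 0.5),
                              n_dmp = 50, delta_beta_range = c(0.1, 0.36),
                              prop_hypo = 0.915,
                              n_vmp = 50, variance_inflation = 4,
                              n_deg = 50, log2fc_range = c(0.5, 3.12),
                              prop_up = 0.7,
                              nb_dispersion = 0.1,
                              n_meqtl = 50, n_eqtl = 50,
                              n_int_meqtl = 20, n_int_eqtl = 20,
                              qtl_effect_range = c(0.02, 0.3),
                              qtl_effect_range_expr = NULL,
                              n_dmr_blocks = 0, dmr_block_delta = 0.05,
                              n_hla_alleles = 12, hla_ssa_log_odds = 1.1,
                              ifn_block_size = 20, ifn_delta_beta = 0.3,
                              confounded_batch = FALSE,
                              seed = 1L) {
  cf <- as.list(environment())
  cf$seed <- as.integer(seed)
  structure(cf, class = "sim_config")
}

validate_config <- function(cf) {
  stopifnot(inherits(cf, "sim_config"))
  if (cf$n_cases < 2 || cf$n_controls < 2) {
    rlang::abort("Need at least 2 cases and 2 controls.")
  }
  for (rg in list(cf$maf_range, cf$delta_beta_range, cf$log2fc_range,
                  cf$qtl_effect_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) rlang::abort("Malformed range in config.")
  }
  if (cf$maf_range[1] <= 0 || cf$maf_range[2] > 0.5) {
    rlang::abort("maf_range must lie in (0, 0.5].")
  }
  if (cf$variance_inflation <= 1) rlang::abort("variance_inflation must exceed 1.")
  if (cf$ifn_delta_beta <= 0 || cf$ifn_delta_beta >= 1) {
    rlang::abort("ifn_delta_beta must lie in (0, 1).")
  }
  cpg_used <- cf$n_dmp + cf$n_vmp + cf$n_meqtl + cf$n_int_meqtl +
    cf$ifn_block_size + cf$n_dmr_blocks * cf$cpgs_per_region
  if (cpg_used > cf$n_cpgs) {
    rlang::abort("Planted CpG effect counts exceed n_cpgs.")
  }
  if (cf$n_deg + cf$n_eqtl + cf$n_int_eqtl > cf$n_genes) {
    rlang::abort("Planted gene effect counts exceed n_genes.")
  }
  if (cf$n_meqtl + cf$n_eqtl + cf$n_int_meqtl + cf$n_int_eqtl > cf$n_snps) {
    rlang::abort("Planted QTL pair counts exceed n_snps.")
  }
  if (cf$n_dmr_blocks > floor(cf$n_cpgs / cf$cpgs_per_region)) {
    rlang::abort("n_dmr_blocks exceeds the number of promoter regions.")
  }
  invisible(cf)
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# Genomic layout: CpGs grouped into promoter regions (fixed spacing), genes
# anchored just downstream of their region, extra genes and SNPs spread along
# the same chromosome so each feature sees a handful of cis SNPs.
build_layout <- function(cf) {
  k <- cf$cpgs_per_region
  cpg_id <- sprintf("cpg%05d", seq_len(cf$n_cpgs))
  region_of <- ceiling(seq_len(cf$n_cpgs) / k)
  n_regions <- floor(cf$n_cpgs / k)
  cpg_pos <- (region_of - 1L) * 200000L + 10000L + ((seq_len(cf$n_cpgs) - 1L) %% k) * 100L
  gene_id <- sprintf("gene%04d", seq_len(cf$n_genes))
  g_idx <- seq_len(cf$n_genes)
  anchored <- g_idx <= n_regions
  gene_pos <- integer(cf$n_genes)
  gene_pos[anchored] <- (g_idx[anchored] - 1L) * 200000L + 10000L + k * 100L + 200L
  if (any(!anchored)) {
    gene_pos[!anchored] <- n_regions * 200000L + 10000L +
      (g_idx[!anchored] - n_regions) * 150000L
  }
  strand <- rep(c("+", "-"), length.out = cf$n_genes)
  strand[anchored] <- "+"
  n_linked <- min(n_regions, cf$n_genes)
  region_sets <- tibble::tibble(
    region_id = paste0("prom_", gene_id[seq_len(n_linked)]),
    region_kind = "promoter",
    members = lapply(seq_len(n_linked), function(r) cpg_id[region_of == r]))
  list(
    cpg = tibble::tibble(feature_id = cpg_id, chrom = "chr1", pos = cpg_pos,
                         gene_label = ifelse(region_of <= n_linked,
                                             gene_id[pmin(region_of, n_linked)],
                                             "intergenic"),
                         region_class = ifelse(region_of <= n_linked,
                                               "promoter", "open_sea")),
    gene = tibble::tibble(feature_id = gene_id, chrom = "chr1",
                          pos = gene_pos, strand = strand),
    region_sets = region_sets,
    region_of = region_of,
    n_regions = n_linked)
}

#' Simulate a multi-omics case-control cohort with planted ground truth
#'
#' Generates aligned genotype, methylation, expression and HLA dosage
#' matrices, a sample sheet (disease, sex, age, autoantibody serology, cell
#' proportions, batch factors, genetic PC1, treatment flags) and a truth
#' registry of every planted effect, under a single seed. See
#' [simulation_config()] for the generative parameters.
#'
#' @param config A [simulation_config()].
#' @return An object of class `epicohort_sim`: a list with elements
#'   `genotypes`, `methylation`, `expression`, `hla` (molecular matrices),
#'   `sheet`, `cpg_annotation`, `gene_annotation`, `snp_annotation`,
#'   `region_sets`, `truth` and `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(n_cases = 20, n_controls = 20,
#'   n_cpgs = 100, n_genes = 50, n_snps = 40, n_dmp = 5, n_vmp = 5,
#'   n_deg = 5, n_meqtl = 5, n_eqtl = 5, n_int_meqtl = 2, n_int_eqtl = 2,
#'   ifn_block_size = 5, seed = 7))
#' dim(sim$methylation)
simulate_cohort <- function(config) {
  cf <- validate_config(config)
  set.seed(cf$seed)
  n <- cf$n_cases + cf$n_controls
  sample_id <- sprintf("S%04d", seq_len(n))
  disease <- rep(c("case", "control"), c(cf$n_cases, cf$n_controls))
  case <- as.numeric(disease == "case")

  # --- sample sheet ----------------------------------------------------------
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.9, 0.1))
  age <- pmin(pmax(round(rnorm(n, 55, 12)), 18), 85)
  pc1 <- rnorm(n)
  if (cf$confounded_batch) {
    batch <- ifelse(runif(n) < ifelse(case == 1, 0.7, 0.3), "B2", "B1")
  } else {
    batch <- sample(c("B1", "B2"), n, replace = TRUE)
  }
  pool <- sample(c("P1", "P2"), n, replace = TRUE)
  rin <- pmin(pmax(rnorm(n, 8, 0.8), 6), 10)
  cell_names <- c("cell_gran", "cell_mono", "cell_bcell", "cell_tcell", "cell_nk")
  conc_control <- c(28, 4, 2, 13, 2)
  conc_case <- c(32, 4, 1.6, 10, 1.6)
  cells <- matrix(NA_real_, n, 5, dimnames = list(NULL, cell_names))
  cells[case == 1, ] <- rdirichlet_rows(sum(case), conc_case)
  cells[case == 0, ] <- rdirichlet_rows(sum(case == 0), conc_control)

  # --- HLA and the HLA -> SSA -> IFN-block causal chain ----------------------
  hla_id <- sprintf("hla_allele_%02d", seq_len(cf$n_hla_alleles))
  hla_freq <- runif(cf$n_hla_alleles, 0.05, 0.3)
  risk_idx <- 1L
  hla_freq[risk_idx] <- runif(1, 0.15, 0.35)
  hla <- matrix(rbinom(cf$n_hla_alleles * n, 2, rep(hla_freq, n)),
                nrow = cf$n_hla_alleles,
                dimnames = list(hla_id, sample_id))
  # the HLA risk allele acts through the autoantibody-positive disease
  # subtype: SSA-positive cases carry the risk allele at elevated frequency
  # (log-odds tilt per allele dose), SSA-negative cases and controls at the
  # population frequency
  ssa <- rep("negative", n)
  ssa[case == 1] <- ifelse(runif(sum(case)) < 0.55, "positive", "negative")
  tilt <- stats::dbinom(0:2, 2, hla_freq[risk_idx]) *
    exp(cf$hla_ssa_log_odds * (0:2))
  idx_pos <- which(ssa == "positive")
  hla[risk_idx, idx_pos] <- sample(0:2, length(idx_pos), replace = TRUE,
                                   prob = tilt / sum(tilt))
  ssb <- rep("negative", n)
  ssb[ssa == "positive"] <- ifelse(runif(sum(ssa == "positive")) < 0.55,
                                   "positive", "negative")
  treat <- function(p) case == 1 & runif(n) < p
  sheet <- tibble::tibble(
    sample_id = sample_id, disease = disease, sex = sex, age = age,
    ssa = ssa, ssb = ssb, pc1 = pc1, batch = batch, pool = pool, rin = rin,
    antimalarial = treat(0.4), steroids = treat(0.35),
    immunosuppressant = treat(0.2))
  sheet <- dplyr::bind_cols(sheet, tibble::as_tibble(cells))

  # --- layout and planted-feature assignment ---------------------------------
  lay <- build_layout(cf)
  cpg_id <- lay$cpg$feature_id
  gene_id <- lay$gene$feature_id
  snp_id <- sprintf("snp%05d", seq_len(cf$n_snps))

  dmr_regions <- if (cf$n_dmr_blocks > 0) {
    sort(sample(lay$n_regions, cf$n_dmr_blocks))
  } else integer(0)
  blocked <- which(lay$region_of %in% dmr_regions)
  pool_cpg <- setdiff(seq_len(cf$n_cpgs), blocked)
  take <- function(pool, k) {
    idx <- if (k > 0) sort(sample(pool, k)) else integer(0)
    list(idx = idx, pool = setdiff(pool, idx))
  }
  s <- take(pool_cpg, cf$n_dmp);       dmp_idx <- s$idx
  s <- take(s$pool, cf$n_vmp);         vmp_idx <- s$idx
  # cis and interaction QTLs are planted preferentially at disease-associated
  # features: the scans (like the study design) map QTLs at significant
  # DMPs/DEGs, so genetic control must overlap the disease signature
  alloc_from <- function(primary, pool, k) {
    t1 <- min(k, length(primary))
    idx <- primary[seq_len(t1)]
    if (k > t1) {
      extra <- sort(sample(pool, k - t1))
      idx <- c(idx, extra)
      pool <- setdiff(pool, extra)
    }
    list(idx = idx, primary = primary[-seq_len(t1)], pool = pool)
  }
  a <- alloc_from(dmp_idx, s$pool, cf$n_meqtl)
  meqtl_cpg <- a$idx
  a <- alloc_from(a$primary, a$pool, cf$n_int_meqtl)
  int_meqtl_cpg <- a$idx
  s <- take(a$pool, cf$ifn_block_size); ifn_idx <- s$idx
  pool_gene <- seq_len(cf$n_genes)
  s <- take(pool_gene, cf$n_deg);      deg_idx <- s$idx
  a <- alloc_from(deg_idx, s$pool, cf$n_eqtl)
  eqtl_gene <- a$idx
  a <- alloc_from(a$primary, a$pool, cf$n_int_eqtl)
  int_eqtl_gene <- a$idx

  # --- genotypes: planted QTL SNPs are placed cis to their partner -----------
  maf <- runif(cf$n_snps, cf$maf_range[1], cf$maf_range[2])
  n_qtl_snps <- cf$n_meqtl + cf$n_int_meqtl + cf$n_eqtl + cf$n_int_eqtl
  qtl_snp_idx <- if (n_qtl_snps > 0) sample(cf$n_snps, n_qtl_snps) else integer(0)
  # planted regulatory variants are common (the disease-dependent QTL filter
  # requires MAF > 0.10 in cases; reported QTL SNPs are common variants)
  maf[qtl_snp_idx] <- runif(n_qtl_snps, max(0.2, cf$maf_range[1]),
                            cf$maf_range[2])
  partner_pos <- c(lay$cpg$pos[meqtl_cpg], lay$cpg$pos[int_meqtl_cpg],
                   lay$gene$pos[eqtl_gene], lay$gene$pos[int_eqtl_gene])
  span_max <- max(lay$cpg$pos, lay$gene$pos, 1000000L)
  snp_pos <- sample.int(span_max, cf$n_snps, replace = TRUE)
  snp_pos[qtl_snp_idx] <- pmax(1L, partner_pos +
                                 sample(-100000:100000, n_qtl_snps, replace = TRUE))
  genotypes <- matrix(rbinom(cf$n_snps * n, 2, rep(maf, n)),
                      nrow = cf$n_snps, dimnames = list(snp_id, sample_id))
  meqtl_snp <- qtl_snp_idx[seq_len(cf$n_meqtl)]
  int_meqtl_snp <- qtl_snp_idx[cf$n_meqtl + seq_len(cf$n_int_meqtl)]
  eqtl_snp <- qtl_snp_idx[cf$n_meqtl + cf$n_int_meqtl + seq_len(cf$n_eqtl)]
  int_eqtl_snp <- qtl_snp_idx[cf$n_meqtl + cf$n_int_meqtl + cf$n_eqtl +
                                seq_len(cf$n_int_eqtl)]

  # --- methylation on the logit scale ----------------------------------------
  base_beta <- sample_baseline_beta(cf$n_cpgs)
  sigma <- runif(cf$n_cpgs, 0.25, 0.45)
  planted_mid <- unique(c(dmp_idx, vmp_idx, meqtl_cpg, int_meqtl_cpg, blocked))
  base_beta[planted_mid] <- runif(length(planted_mid), 0.35, 0.65)
  base_beta[ifn_idx] <- runif(length(ifn_idx), 0.75, 0.9)
  sigma[vmp_idx] <- 0.25
  # coherent-block CpGs sit at intermediate methylation with typical array
  # noise: the per-CpG signal is deliberately weak relative to the region
  base_beta[blocked] <- 0.5
  sigma[blocked] <- 0.35

  signed_delta <- function(idx, magnitude, sign_prob_neg) {
    d <- magnitude * ifelse(runif(length(idx)) < sign_prob_neg, -1, 1)
    out_of_range <- base_beta[idx] + d < 0.05 | base_beta[idx] + d > 0.95
    d[out_of_range] <- -d[out_of_range]
    d
  }
  dmp_delta <- signed_delta(dmp_idx,
                            runif(cf$n_dmp, cf$delta_beta_range[1],
                                  cf$delta_beta_range[2]), cf$prop_hypo)
  # the case-group baseline at a CpG includes any planted disease shift;
  # case-only effects are calibrated against it so the registered per-allele
  # effect is what cases actually exhibit
  dmp_delta_of <- stats::setNames(rep(0, cf$n_cpgs), cpg_id)
  dmp_delta_of[dmp_idx] <- dmp_delta
  case_base <- function(j) {
    pmin(pmax(base_beta[j] + dmp_delta_of[j], 0.05), 0.95)
  }
  meqtl_eff <- signed_delta(meqtl_cpg,
                            runif(cf$n_meqtl, cf$qtl_effect_range[1],
                                  cf$qtl_effect_range[2]) / 2, 0.5) * 2
  int_base <- case_base(int_meqtl_cpg)
  int_mag <- runif(cf$n_int_meqtl, cf$qtl_effect_range[1],
                   cf$qtl_effect_range[2])
  int_meqtl_eff <- int_mag * ifelse(runif(cf$n_int_meqtl) < 0.5, -1, 1)
  out_rng <- int_base + 2 * int_meqtl_eff < 0.05 |
    int_base + 2 * int_meqtl_eff > 0.95
  int_meqtl_eff[out_rng] <- -int_meqtl_eff[out_rng]

  L <- matrix(stats::qlogis(base_beta), cf$n_cpgs, n)
  # cell-composition effects are applied on the beta scale further down
  # (bulk beta is a proportion-weighted mixture of cell-type betas);
  # batch/sex/age/pc1 array effects load on the logit scale
  cellc <- scale(cells[, 1:2], scale = FALSE)
  load_idx <- sample(cf$n_cpgs, round(0.3 * cf$n_cpgs))
  cell_coef <- matrix(rnorm(length(load_idx) * 2, 0, 0.5), ncol = 2)
  b_idx <- sample(cf$n_cpgs, round(0.2 * cf$n_cpgs))
  L[b_idx, ] <- L[b_idx, ] + rnorm(length(b_idx), 0, 0.15) %o% (batch == "B2")
  s_idx <- sample(cf$n_cpgs, round(0.1 * cf$n_cpgs))
  L[s_idx, ] <- L[s_idx, ] + rnorm(length(s_idx), 0, 0.2) %o% (sex == "M")
  L <- L + rnorm(cf$n_cpgs, 0, 0.003) %o% (age - mean(age))
  p_idx <- sample(cf$n_cpgs, round(0.1 * cf$n_cpgs))
  L[p_idx, ] <- L[p_idx, ] + rnorm(length(p_idx), 0, 0.1) %o% pc1

  # disease mean shifts at DMPs
  for (i in seq_along(dmp_idx)) {
    j <- dmp_idx[i]
    L[j, ] <- L[j, ] + calibrate_logit_shift(base_beta[j], dmp_delta[i], sigma[j]) * case
  }
  # coherent small shifts across planted DMR blocks
  for (j in blocked) {
    L[j, ] <- L[j, ] + calibrate_logit_shift(base_beta[j], cf$dmr_block_delta, sigma[j]) * case
  }
  # SSA-driven IFN-block hypomethylation (cases positive for SSA only)
  ssa_pos <- as.numeric(ssa == "positive")
  for (j in ifn_idx) {
    L[j, ] <- L[j, ] + calibrate_logit_shift(base_beta[j], -cf$ifn_delta_beta, sigma[j]) * ssa_pos
  }
  # cis per-allele effects (both groups) and case-only interaction effects
  for (i in seq_along(meqtl_cpg)) {
    j <- meqtl_cpg[i]
    d <- calibrate_logit_shift(base_beta[j], meqtl_eff[i], sigma[j])
    L[j, ] <- L[j, ] + d * genotypes[meqtl_snp[i], ]
  }
  for (i in seq_along(int_meqtl_cpg)) {
    j <- int_meqtl_cpg[i]
    d <- calibrate_logit_shift(unname(case_base(j)), int_meqtl_eff[i], sigma[j])
    L[j, ] <- L[j, ] + d * genotypes[int_meqtl_snp[i], ] * case
  }
  noise <- matrix(rnorm(cf$n_cpgs * n), cf$n_cpgs, n) * sigma
  if (length(vmp_idx) > 0) {
    noise[vmp_idx, case == 1] <- noise[vmp_idx, case == 1] *
      sqrt(cf$variance_inflation)
  }
  methylation <- stats::plogis(L + noise)
  methylation[load_idx, ] <- methylation[load_idx, ] + cell_coef %*% t(cellc)
  methylation <- pmin(pmax(methylation, 0.001), 0.999)
  dimnames(methylation) <- list(cpg_id, sample_id)

  # --- expression: negative binomial with log-scale effects ------------------
  base_expr <- exp(rnorm(cf$n_genes, log(200), 1.2))
  size_factor <- exp(rnorm(n, 0, 0.25))
  lfc <- runif(cf$n_deg, cf$log2fc_range[1], cf$log2fc_range[2]) *
    ifelse(runif(cf$n_deg) < cf$prop_up, 1, -1)
  er <- cf$qtl_effect_range_expr %||% cf$qtl_effect_range
  eqtl_eff <- runif(cf$n_eqtl, er[1], er[2]) *
    sample(c(-1, 1), cf$n_eqtl, replace = TRUE)
  int_eqtl_eff <- runif(cf$n_int_eqtl, er[1], er[2]) *
    sample(c(-1, 1), cf$n_int_eqtl, replace = TRUE)
  logmu <- matrix(log(base_expr), cf$n_genes, n)
  logmu <- sweep(logmu, 2, log(size_factor), "+")
  gl_idx <- sample(cf$n_genes, round(0.3 * cf$n_genes))
  logmu[gl_idx, ] <- logmu[gl_idx, ] + rnorm(length(gl_idx), 0, 1) %o% cellc[, 1]
  pl_idx <- sample(cf$n_genes, round(0.2 * cf$n_genes))
  logmu[pl_idx, ] <- logmu[pl_idx, ] + rnorm(length(pl_idx), 0, 0.1) %o% (pool == "P2")
  logmu <- logmu + 0.05 * rep(1, cf$n_genes) %o% (rin - mean(rin))
  logmu[deg_idx, ] <- logmu[deg_idx, ] + (lfc * log(2)) %o% case
  for (i in seq_along(eqtl_gene)) {
    logmu[eqtl_gene[i], ] <- logmu[eqtl_gene[i], ] +
      eqtl_eff[i] * genotypes[eqtl_snp[i], ]
  }
  for (i in seq_along(int_eqtl_gene)) {
    logmu[int_eqtl_gene[i], ] <- logmu[int_eqtl_gene[i], ] +
      int_eqtl_eff[i] * genotypes[int_eqtl_snp[i], ] * case
  }
  counts <- matrix(rnbinom(cf$n_genes * n, mu = exp(logmu),
                           size = 1 / cf$nb_dispersion),
                   cf$n_genes, n, dimnames = list(gene_id, sample_id))

  # --- truth registry --------------------------------------------------------
  pair_tbl <- function(snps, feats, layer, eff) {
    tibble::tibble(snp_id = snp_id[snps], feature_id = feats,
                   layer = layer, effect = eff)
  }
  truth <- list(
    dmp_effects = stats::setNames(as.list(dmp_delta), cpg_id[dmp_idx]),
    vmp_features = stats::setNames(as.list(rep(cf$variance_inflation,
                                               length(vmp_idx))), cpg_id[vmp_idx]),
    deg_effects = stats::setNames(as.list(lfc), gene_id[deg_idx]),
    meqtl = pair_tbl(meqtl_snp, cpg_id[meqtl_cpg], "methylation", meqtl_eff),
    eqtl = pair_tbl(eqtl_snp, gene_id[eqtl_gene], "expression", eqtl_eff),
    interaction_qtl = dplyr::bind_rows(
      pair_tbl(int_meqtl_snp, cpg_id[int_meqtl_cpg], "methylation", int_meqtl_eff),
      pair_tbl(int_eqtl_snp, gene_id[int_eqtl_gene], "expression", int_eqtl_eff)),
    dmr_blocks = tibble::tibble(
      region_id = lay$region_sets$region_id[dmr_regions],
      delta_beta = rep(cf$dmr_block_delta, length(dmr_regions)),
      members = lay$region_sets$members[dmr_regions]),
    ifn_block = cpg_id[ifn_idx],
    ifn_proxy = if (length(ifn_idx) > 0) cpg_id[ifn_idx[1]] else character(0),
    hla_risk_allele = hla_id[risk_idx],
    hla_ssa_log_odds = cf$hla_ssa_log_odds,
    ifn_delta_beta = cf$ifn_delta_beta)

  structure(list(
    genotypes = molecular_matrix(genotypes, "dosage"),
    methylation = molecular_matrix(methylation, "methylation"),
    expression = molecular_matrix(counts, "expression"),
    hla = molecular_matrix(hla, "hla"),
    sheet = validate_sample_sheet(sheet),
    cpg_annotation = lay$cpg,
    gene_annotation = lay$gene,
    snp_annotation = tibble::tibble(feature_id = snp_id, chrom = "chr1",
                                    pos = snp_pos, maf = maf),
    region_sets = lay$region_sets,
    truth = truth,
    config = cf), class = "epicohort_sim")
}

# Whole-blood array betas are bimodal: most CpGs sit near 0.1 or 0.9 with a
# minority at intermediate levels.
sample_baseline_beta <- function(n_cpgs) {
  grp <- sample(3, n_cpgs, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  b <- numeric(n_cpgs)
  b[grp == 1] <- stats::rbeta(sum(grp == 1), 5, 45)
  b[grp == 2] <- stats::rbeta(sum(grp == 2), 45, 5)
  b[grp == 3] <- stats::rbeta(sum(grp == 3), 5, 5)
  pmin(pmax(b, 0.02), 0.98)
}

#' Serialize or restore the planted-effect truth registry
#'
#' JSON round trip preserving full numeric precision; used by recovery tests
#' and the pipeline manifest.
#'
#' @param truth Truth registry from [simulate_cohort()].
#' @param path JSON path.
#' @return `read_truth()` returns the registry.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (nm in c("meqtl", "eqtl", "interaction_qtl", "dmr_blocks")) {
    out[[nm]] <- as.data.frame(truth[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_pairs <- function(x, cols) {
    if (is.null(x) || length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) {
      return(tibble::as_tibble(stats::setNames(
        rep(list(character(0)), length(cols)), cols)))
    }
    tibble::as_tibble(x)
  }
  scalar_map <- function(x) {
    if (is.null(x) || length(x) == 0) return(stats::setNames(list(), character(0)))
    lapply(as.list(x), as.numeric)
  }
  list(
    dmp_effects = scalar_map(raw$dmp_effects),
    vmp_features = scalar_map(raw$vmp_features),
    deg_effects = scalar_map(raw$deg_effects),
    meqtl = as_pairs(raw$meqtl, c("snp_id", "feature_id", "layer", "effect")),
    eqtl = as_pairs(raw$eqtl, c("snp_id", "feature_id", "layer", "effect")),
    interaction_qtl = as_pairs(raw$interaction_qtl,
                               c("snp_id", "feature_id", "layer", "effect")),
    dmr_blocks = as_pairs(raw$dmr_blocks, c("region_id", "delta_beta", "members")),
    ifn_block = as.character(raw$ifn_block %||% character(0)),
    ifn_proxy = as.character(raw$ifn_proxy %||% character(0)),
    hla_risk_allele = as.character(raw$hla_risk_allele %||% character(0)),
    hla_ssa_log_odds = as.numeric(raw$hla_ssa_log_odds %||% numeric(0)),
    ifn_delta_beta = as.numeric(raw$ifn_delta_beta %||% numeric(0)))
}

#' Write a simulated cohort to a directory of standard-format files
#'
#' TSV matrices for methylation, expression and HLA dosages, a VCF for
#' genotypes, TSV sample sheet and annotations, a GMT region-set file and the
#' JSON truth registry.
#'
#' @param sim An `epicohort_sim` object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(sim$methylation, file.path(dir, "methylation.tsv"))
  write_matrix(sim$expression, file.path(dir, "expression.tsv"))
  write_matrix(sim$hla, file.path(dir, "hla.tsv"))
  write_vcf_dosages(sim$genotypes, sim$snp_annotation,
                    file.path(dir, "genotypes.vcf"))
  write_sample_sheet(sim$sheet, file.path(dir, "sheet.tsv"))
  write_annotation(sim$cpg_annotation, file.path(dir, "cpg_annotation.tsv"))
  write_annotation(sim$gene_annotation, file.path(dir, "gene_annotation.tsv"))
  write_annotation(sim$snp_annotation, file.path(dir, "snp_annotation.tsv"))
  write_gmt(sim$region_sets, file.path(dir, "regions.gmt"))
  write_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
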