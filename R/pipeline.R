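# End-to-end orchestration: simulate (or load) a cohort, split it into
# discovery and replication sets, run every scan in dependency order, write
# each stage's TSV with a JSON parameter sidecar, and return a run manifest.

#' Stratified discovery/replication split
#'
#' Splits sample ids into disjoint discovery and replication sets, stratified
#' by disease status, under a seed.
#'
#' @param sheet Sample sheet.
#' @param fraction Discovery fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `discovery` and `replication` id vectors.
#' @export
split_cohort <- function(sheet, fraction = 0.5, seed = 1) {
  if (fraction <= 0 || fraction >= 1) rlang::abort("fraction must be in (0, 1).")
  set.seed(as.integer(seed))
  disc <- unlist(lapply(split(sheet$sample_id, sheet$disease), function(ids) {
    k <- round(length(ids) * fraction)
    if (k < 2 || length(ids) - k < 2) {
      rlang::abort("A stratum is too small to split.")
    }
    sample(ids, k)
  }), use.names = FALSE)
  list(discovery = sheet$sample_id[sheet$sample_id %in% disc],
       replication = setdiff(sheet$sample_id, disc))
}

#' Default pipeline configuration
#'
#' @param simulation A [simulation_config()] (or NULL to load inputs from
#'   `input_dir`).
#' @param input_dir Directory of cohort files as written by [write_cohort()].
#' @param out_dir Output directory.
#' @param seed Seed controlling the split and permutation nulls.
#' @param split_fraction Discovery fraction.
#' @param alpha Family-wise error rate for Bonferroni thresholds.
#' @param dmr_n_perm Permutations for the region scan.
#' @param qtl_window cis window in bp.
#' @param maf_min,maf_case_min MAF filters (cohort-wide cis filter; case
#'   floor for the interaction filter).
#' @param p_int,p_int_repl Interaction thresholds (discovery/replication).
#' @param eqtm_window Region-to-TSS pairing window in bp.
#' @param alpha_snp Association threshold feeding mediation verdicts.
#' @param ifn_cutoff Proxy-CpG beta cutoff for the IFN signature.
#' @param meth_covariates,expr_covariates,assoc_covariates Covariate sets.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       input_dir = NULL,
                       out_dir = tempfile("epicohort_run_"),
                       seed = 1,
                       split_fraction = 0.5,
                       alpha = 0.05,
                       dmr_n_perm = 499,
                       qtl_window = 1000000,
                       maf_min = 0.05,
                       maf_case_min = 0.10,
                       p_int = 0.005,
                       p_int_repl = 0.05,
                       eqtm_window = 1500,
                       alpha_snp = 0.05,
                       ifn_cutoff = 0.8,
                       meth_covariates = c("sex", "age", "pc1", "cells", "batch"),
                       expr_covariates = c("age", "sex", "pc1", "cells", "pool", "rin"),
                       assoc_covariates = c("pc1", "sex", "age")) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields override [run_config()] defaults; a `simulation` block
#' overrides [simulation_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) {
    do.call(simulation_config, y$simulation)
  } else if (!is.null(y$input_dir)) NULL else simulation_config()
  y$simulation <- NULL
  do.call(run_config, c(list(simulation = sim), y))
}

stage_write <- function(dir, stage, table, params) {
  write_results(tibble::as_tibble(table), file.path(dir, paste0(stage, ".tsv")))
  jsonlite::write_json(params, file.path(dir, paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "list")
}

drop_list_cols <- function(tb) {
  tb[, !vapply(tb, is.list, logical(1)), drop = FALSE]
}

#' Run the full integrative analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), discovery/replication
#' split, DMP and VMP scans, region (DMR) scan, differential expression, VST,
#' eQTM, cis-meQTL and cis-eQTL scans, interaction scans on both cohort
#' halves, the disease-dependent filter, SNP case-control association,
#' mediation verdicts, IFN-signature classification and the HLA suite. Every
#' stage writes `<stage>.tsv` plus a JSON sidecar of the parameters applied.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list: per-stage row counts, file paths, the
#'   thresholds applied, seed, and the simulated truth (when simulating).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    log_line("simulate", "generating synthetic cohort")
    sim <- simulate_cohort(config$simulation)
    write_cohort(sim, file.path(config$out_dir, "cohort"))
  } else {
    log_line("load", paste("reading cohort from", config$input_dir))
    d <- config$input_dir
    vcf <- read_vcf_dosages(file.path(d, "genotypes.vcf"))
    sim <- list(
      methylation = read_matrix(file.path(d, "methylation.tsv"), "methylation"),
      expression = read_matrix(file.path(d, "expression.tsv"), "expression"),
      hla = read_matrix(file.path(d, "hla.tsv"), "hla"),
      genotypes = vcf$dosages,
      sheet = read_sample_sheet(file.path(d, "sheet.tsv")),
      cpg_annotation = read_annotation(file.path(d, "cpg_annotation.tsv")),
      gene_annotation = read_annotation(file.path(d, "gene_annotation.tsv")),
      snp_annotation = vcf$annotation,
      region_sets = read_gmt(file.path(d, "regions.gmt")),
      truth = if (file.exists(file.path(d, "truth.json"))) {
        read_truth(file.path(d, "truth.json"))
      })
  }
  sheet <- sim$sheet
  manifest <- list(seed = config$seed, out_dir = config$out_dir,
                   stages = list(), thresholds = list(
                     alpha = config$alpha, maf_min = config$maf_min,
                     maf_case_min = config$maf_case_min, p_int = config$p_int,
                     p_int_repl = config$p_int_repl,
                     qtl_window = config$qtl_window,
                     eqtm_window = config$eqtm_window,
                     alpha_snp = config$alpha_snp,
                     ifn_cutoff = config$ifn_cutoff,
                     dmr_n_perm = config$dmr_n_perm,
                     split_fraction = config$split_fraction))
  record <- function(stage, table) {
    manifest$stages[[stage]] <<- list(rows = nrow(table),
                                      file = paste0(stage, ".tsv"))
    invisible(NULL)
  }

  sp <- split_cohort(sheet, config$split_fraction, config$seed)
  sheet_d <- sheet[sheet$sample_id %in% sp$discovery, ]
  sheet_r <- sheet[sheet$sample_id %in% sp$replication, ]
  sub <- function(m, ids) m[, colnames(m) %in% ids, drop = FALSE]
  mspec <- model_spec(config$meth_covariates)
  espec <- model_spec(config$expr_covariates)

  # --- methylation ----------------------------------------------------------
  log_line("dmp", "differential methylation scan (discovery)")
  dmp <- run_dmp_scan(sub(sim$methylation, sp$discovery), sheet_d, mspec)
  m_thr <- bonferroni_threshold(config$alpha, nrow(dmp))
  stage_write(config$out_dir, "dmp", dmp,
              list(covariates = config$meth_covariates, threshold = m_thr))
  record("dmp", dmp)

  log_line("vmp", "variance scan (discovery)")
  vmp <- run_vmp_scan(sub(sim$methylation, sp$discovery), sheet_d, mspec)
  stage_write(config$out_dir, "vmp", vmp,
              list(covariates = config$meth_covariates, threshold = m_thr))
  record("vmp", vmp)

  log_line("dmp_replication", "replicating significant DMPs")
  sig_dmp <- dmp$feature_id[dmp$p < m_thr]
  dmp_rep <- if (length(sig_dmp) > 0) {
    run_dmp_scan(sub(sim$methylation, sp$replication)[sig_dmp, , drop = FALSE],
                 sheet_r, mspec)
  } else dmp[0, ]
  stage_write(config$out_dir, "dmp_replication", dmp_rep,
              list(threshold = 0.05, n_candidates = length(sig_dmp)))
  record("dmp_replication", dmp_rep)

  log_line("dmr", "region enrichment scan")
  dmr <- dmr_scan(dmp, sim$region_sets, n_perm = config$dmr_n_perm,
                  seed = config$seed)
  stage_write(config$out_dir, "dmr", drop_list_cols(dmr),
              list(n_perm = config$dmr_n_perm, fdr = 0.05, min_cpgs = 5))
  record("dmr", dmr)

  # --- expression -----------------------------------------------------------
  log_line("de", "differential expression scan (discovery)")
  de <- run_de_scan(sub(sim$expression, sp$discovery), sheet_d, espec)
  e_thr <- bonferroni_threshold(config$alpha, attr(de, "m_tests"))
  stage_write(config$out_dir, "de", de,
              list(covariates = config$expr_covariates, threshold = e_thr))
  record("de", de)

  expr_log <- vst_transform(sim$expression)

  log_line("eqtm", "region methylation vs expression")
  sig_dmr <- dmr[!is.na(dmr$p_fdr) & dmr$p_fdr < 0.05, , drop = FALSE]
  eqtm <- eqtm_scan(if (nrow(sig_dmr) > 0) sig_dmr else dmr,
                    sim$methylation, expr_log, sim$gene_annotation,
                    sim$cpg_annotation, window = config$eqtm_window,
                    sheet = sheet)
  stage_write(config$out_dir, "eqtm", eqtm,
              list(window = config$eqtm_window, r_call = 0.6))
  record("eqtm", eqtm)

  # --- QTLs -----------------------------------------------------------------
  log_line("meqtl", "cis-meQTL scan at significant DMPs")
  dmp_feats <- if (length(sig_dmp) > 0) sig_dmp else
    head(dmp$feature_id, 50)
  cis_m <- cis_pairs(sim$cpg_annotation[sim$cpg_annotation$feature_id %in%
                                          dmp_feats, ],
                     sim$snp_annotation, config$qtl_window)
  meqtl <- run_cis_scan(sim$methylation, sim$genotypes, sheet, cis_m,
                        mspec, layer = "methylation", maf_min = config$maf_min)
  stage_write(config$out_dir, "meqtl",
              meqtl, list(window = config$qtl_window, maf_min = config$maf_min,
                          fdr = 0.05))
  record("meqtl", meqtl)

  log_line("eqtl", "cis-eQTL scan at significant DEGs")
  sig_deg <- de$gene_id[!is.na(de$p) & de$p < e_thr]
  deg_feats <- if (length(sig_deg) > 0) sig_deg else head(de$gene_id, 50)
  cis_e <- cis_pairs(sim$gene_annotation[sim$gene_annotation$feature_id %in%
                                           deg_feats, ],
                     sim$snp_annotation, config$qtl_window)
  eqtl <- run_cis_scan(expr_log, sim$genotypes, sheet, cis_e, espec,
                       layer = "expression", maf_min = config$maf_min)
  stage_write(config$out_dir, "eqtl",
              eqtl, list(window = config$qtl_window, maf_min = config$maf_min,
                         fdr = 0.05))
  record("eqtl", eqtl)

  # --- interaction QTLs on both halves --------------------------------------
  log_line("interaction", "genotype-by-disease scans, discovery + replication")
  int_pairs_m <- dplyr::select(meqtl, "snp_id", "feature_id")
  int_pairs_e <- dplyr::select(eqtl, "snp_id", "feature_id")
  run_int <- function(ids, sh) {
    dplyr::bind_rows(
      run_interaction_scan(sub(sim$methylation, ids), sub(sim$genotypes, ids),
                           sh, int_pairs_m, mspec, layer = "methylation"),
      run_interaction_scan(sub(expr_log, ids), sub(sim$genotypes, ids),
                           sh, int_pairs_e, espec, layer = "expression"))
  }
  int_disc <- run_int(sp$discovery, sheet_d)
  int_repl <- run_int(sp$replication, sheet_r)
  dd <- select_disease_dependent(int_disc, int_repl,
                                 p_int = config$p_int,
                                 p_int_repl = config$p_int_repl,
                                 maf_case_min = config$maf_case_min)
  stage_write(config$out_dir, "interaction_discovery", int_disc,
              list(p_int = config$p_int))
  stage_write(config$out_dir, "interaction_replication", int_repl,
              list(p_int_repl = config$p_int_repl))
  stage_write(config$out_dir, "disease_dependent_qtl", drop_list_cols(dd),
              list(p_int = config$p_int, p_int_repl = config$p_int_repl,
                   maf_case_min = config$maf_case_min))
  record("interaction_discovery", int_disc)
  record("interaction_replication", int_repl)
  record("disease_dependent_qtl", dd)

  # --- genetic association, mediation, IFN, HLA -----------------------------
  log_line("assoc", "case-control association of QTL SNPs")
  qtl_snps <- unique(c(meqtl$snp_id[meqtl$p_fdr < 0.05],
                       eqtl$snp_id[eqtl$p_fdr < 0.05]))
  assoc <- if (length(qtl_snps) > 0) {
    run_assoc_scan(sim$genotypes[qtl_snps, , drop = FALSE], sheet,
                   config$assoc_covariates)
  } else tibble::tibble()
  stage_write(config$out_dir, "assoc", assoc,
              list(covariates = config$assoc_covariates,
                   alpha_snp = config$alpha_snp))
  record("assoc", assoc)

  log_line("mediation", "direction-consistency verdicts")
  mediation <- if (nrow(assoc) > 0) {
    dplyr::bind_rows(
      mediation_consistency(meqtl[meqtl$p_fdr < 0.05, ], dmp, assoc,
                            config$alpha_snp),
      mediation_consistency(eqtl[eqtl$p_fdr < 0.05, ], de, assoc,
                            config$alpha_snp))
  } else tibble::tibble()
  stage_write(config$out_dir, "mediation", mediation,
              list(alpha_snp = config$alpha_snp))
  record("mediation", mediation)

  log_line("hla", "IFN classification and HLA suite")
  proxy <- sim$truth$ifn_proxy %||% character(0)
  if (length(proxy) == 1 && proxy %in% rownames(sim$methylation)) {
    proxy_betas <- sim$methylation[proxy, ]
    ifn <- classify_epig_ifn(proxy_betas, config$ifn_cutoff)
    hla <- hla_suite(sim$hla, sheet, proxy_betas, config$ifn_cutoff)
    stage_write(config$out_dir, "ifn_labels", ifn,
                list(cutoff = config$ifn_cutoff, proxy = proxy))
    stage_write(config$out_dir, "hla_suite", hla,
                list(alpha = bonferroni_threshold(config$alpha, nrow(sim$hla))))
    record("ifn_labels", ifn)
    record("hla_suite", hla)
  }

  manifest$truth <- sim$truth
  manifest$split <- sp
  class(manifest) <- "run_manifest"
  jsonlite::write_json(
    list(seed = manifest$seed,
         stages = manifest$stages, thresholds = manifest$thresholds),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}
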