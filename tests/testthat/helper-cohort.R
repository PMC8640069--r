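# One modest cohort shared by several test files; built once per test run.

small_cohort <- simulate_cohort(simulation_config(
  n_cases = 60, n_controls = 60, n_cpgs = 300, n_genes = 120, n_snps = 80,
  n_dmp = 12, delta_beta_range = c(0.2, 0.3), n_vmp = 10, n_deg = 10,
  n_meqtl = 6, n_eqtl = 5, n_int_meqtl = 3, n_int_eqtl = 3,
  qtl_effect_range = c(0.05, 0.1), qtl_effect_range_expr = c(0.3, 0.5),
  ifn_block_size = 8, n_dmr_blocks = 1, seed = 42))
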