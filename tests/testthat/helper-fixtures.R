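# a small, fast simulation configuration for pipeline and IO tests;
# any sim_config() argument can be overridden
small_cfg <- function(seed = 1, ...) {
  defaults <- list(
    n_samples = c(outgroup = 10, wild_A = 20, wild_B = 20,
                  cultivar_A = 16, cultivar_B = 16),
    chrom_length = 60000,
    focal_cds_start = 29251,
    n_bg_genes = 4,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
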