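## Simulated worlds are expensive; build each named configuration once per
## test run and share it across test files.

.world_cache <- new.env(parent = emptyenv())

world_config <- function(key) {
  switch(key,
    small = sim_config(genome_length = 120000, n_contigs = 2, n_genes = 16,
                       n_hap_specific_genes = 2, sv_len_range = c(60, 400),
                       seed = 101),
    megabase = sim_config(genome_length = 1e6, n_contigs = 2, n_genes = 40,
                          snp_rate = 1e-3, indel_rate = 1e-4, sv_rate = 5e-6,
                          n_hap_specific_genes = 3, seed = 101),
    stop("unknown world key: ", key))
}

test_world <- function(key = "small") {
  if (!exists(key, envir = .world_cache)) {
    cfg <- world_config(key)
    assign(key, list(cfg = cfg, world = simulate_diploid(cfg)),
           envir = .world_cache)
  }
  get(key, envir = .world_cache)
}
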