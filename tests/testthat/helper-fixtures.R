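# shared fixtures: generated once per test run, cached across files

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, make(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 5-strain panel with every planted feature, used by most modules
small_panel <- function() {
  fixture("small_panel", function() {
    simulate_pangenome(sim_config(
      n_strains = 5, n_core_families = 25, n_accessory_families = 20,
      n_islands = 1, island_size = 6, n_phage_families = 5,
      accessory_presence_prob = 0.4, n_plasmids_per_strain = 1,
      fragmentation = 6, label_noise_rate = 0, seed = 42))
  })
}

# same panel plus predictor error, for consensus-calling stress tests
noisy_panel <- function() {
  fixture("noisy_panel", function() {
    simulate_pangenome(sim_config(
      n_strains = 3, n_core_families = 25, n_accessory_families = 15,
      n_islands = 1, island_size = 5, n_phage_families = 4,
      n_plasmids_per_strain = 1, fragmentation = 6,
      predictor_error = list(miss_rate = 0.1, spurious_rate = 0.1,
                             boundary_jitter_bp = 12),
      label_noise_rate = 0, seed = 77))
  })
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste0(sample(panforge:::AA20, len, replace = TRUE), collapse = ""), "")
}

random_dna_chr <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
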