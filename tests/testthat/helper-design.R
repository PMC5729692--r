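## small default design for fast unit tests
tiny_design <- function(...) {
  args <- list(...)
  defaults <- list(n_species_pairs = 2, tissues = c("heart", "liver"),
                   n_individuals = 1, n_genes = 10, n_cassette_exons = 5,
                   read_length = 50, depth = 40, error_rate = 0,
                   divergence = 0.02, seed = 11)
  do.call(simulation_design, utils::modifyList(defaults, args))
}
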