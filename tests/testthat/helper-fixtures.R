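# shared fixtures: all built in code, nothing on disk

# reduced-size study configuration for fast unit tests; the full-size
# defaults are exercised in the acceptance suite
small_config <- function(...) {
  user <- list(...)
  defaults <- list(n_genes_a = 600L, n_genes_b = 600L,
                   n_shared_homologs = 400L, program_size = 60L,
                   n_decoys = 6L)
  do.call(synthetic_config,
          c(user, defaults[!names(defaults) %in% names(user)]))
}

# random expression profile with ids, optionally structured
rand_profile <- function(s, g, seed = 1, species = "toy") {
  set.seed(seed)
  mat <- matrix(rnorm(s * g, mean = 8), s, g,
                dimnames = list(paste0("s", seq_len(s)),
                                paste0("g", seq_len(g))))
  expression_profile(mat, species = species)
}

# named score vector from a polarized component
gene_scores <- function(pc) {
  pc$gene_loadings
}
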