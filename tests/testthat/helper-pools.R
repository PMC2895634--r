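# Shared small fixtures, generated once per session and cached on disk in
# tempdir so multiple test files can reuse them.

cached_pool <- function(name, ...) {
  path <- file.path(tempdir(), paste0("plumotif-pool-", name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  pool <- simulate_pool(...)
  saveRDS(pool, path)
  pool
}

# small annotated pool used by training / evaluation unit tests
small_pool <- function() {
  cached_pool("small",
              design = pool_design(n_stemloop = 80L, n_weak = 80L,
                                   plant_fraction = 0.2),
              n_samples = 200L, seed = 42L)
}

# tiny records with random profiles (no folding) for pure model math
synthetic_records <- function(n, len = 35L, seed = 1L,
                              alphabet = plum_alphabet()) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("r%03d", seq_len(n)),
      seq = replicate(n, random_rna_str(len)),
      profile = replicate(n, random_profile(len, alphabet),
                          simplify = FALSE),
      affinity = stats::rnorm(n)
    )
  })
}
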