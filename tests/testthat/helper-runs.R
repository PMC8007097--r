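# Shared small simulation runs, computed lazily and cached for the session
# so several test files can reuse them.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# A small glycine solution (3 solutes + 90 waters) sampled long enough for
# stable first-shell statistics; used by scattering/hydration tests.
mini_glycine <- function() {
  cached("mini_glycine", {
    sys <- load_builtin_system("glycine", scale = 1 / 10)
    run_simulation(sys, mc_settings(n_equilibration = 400,
                                    n_production = 2000,
                                    sample_every = 10, seed = 101))
  })
}

# The reduced glycine and betaine runs of the acceptance conditions
# (5 solutes + 150 waters, >= 2e4 production sweeps).
reduced_run <- function(name, seed) {
  cached(paste0("reduced_", name), {
    sys <- load_builtin_system(name, scale = 1 / 6)
    run_simulation(sys, mc_settings(n_equilibration = 2000,
                                    n_production = 20000,
                                    sample_every = 20, seed = seed))
  })
}
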