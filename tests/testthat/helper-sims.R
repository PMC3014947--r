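# Small simulated fixtures, built once per test run and memoized.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .sim_cache)) assign(key, builder(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small equilibrated SAW ensemble
saw_ensemble <- function(N, n_conf = 80, seed = 1000 + N) {
  cached(paste0("saw", N, "_", n_conf, "_", seed), function() {
    suppressWarnings(dl_simulate(N, p = 0, n_conformations = n_conf,
                                 max_sweeps = 4e6, record_every = 2L,
                                 seed = seed))
  })
}

# a valid random conformation (equilibrated a little)
random_conf <- function(N, seed = 1) dl_init_chain(N, seed = seed,
                                                   relax_sweeps = 40L * N)
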