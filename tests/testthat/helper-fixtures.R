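# shared fixtures and a cache for expensive simulation results reused across
# test files (computed once per test run)

rand_state <- function(n, seed = 1, box = tissue_box(n)) {
  set.seed(seed)
  make_fixture("random", n, box)
}

solid_resident <- function() reference_resident(p0 = 3.3)
liquid_resident <- function() reference_resident(p0 = 4.0)

# heterogeneous parameter pair exercising every per-type field
hetero_pair <- function() {
  spv_params(resident = type_params(a0 = 1, p0 = 3.3, gamma = 1, k = 1),
             mutant = type_params(a0 = 0.85, p0 = 3.8, gamma = 0.7, k = 1.3))
}

.acc_cache <- new.env(parent = emptyenv())

acc_memo <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) assign(key, force(expr), envir = .acc_cache)
  get(key, envir = .acc_cache)
}

# the reference invasion experiment: preferred-area mutant (a_m0 = 0.9) in the
# solid phase, droplet f0 = 0.1, N0 = 400, 10 replicates
acc_invasion_a0 <- function() acc_memo("invasion_a0", {
  des <- invasion_design(resident = solid_resident(),
                         mutant = list(a0 = 0.9),
                         n0 = 400, initial_fraction = 0.1,
                         n_replicates = 10, horizon = 25,
                         record_every = 50L, relax_steps = 300L)
  run_invasion(des, seed = 20260901L)
})
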