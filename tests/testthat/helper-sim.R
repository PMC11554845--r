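# Shared fixtures, computed lazily once per test run.
.fixture_env <- new.env(parent = emptyenv())

# default-parameter simulation on the coarse study grid
shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- pulmsim(config = solver_config(dx = 0.25, n_per = 4096))
  .fixture_env$sim
}

# reduced prior ensemble for the stochastic acceptance checks
shared_ensemble <- function() {
  if (is.null(.fixture_env$ens))
    .fixture_env$ens <- run_ensemble(N = 32, seed = 101,
                                     config = solver_config(dx = 0.25,
                                                            n_per = 4096))
  .fixture_env$ens
}

# minimal hand-built object exposing the pulmsim surface needed by the
# proximal QoI functions (single vessel, prescribed midpoint traces)
fake_sim <- function(p, q, A, r0 = 1, K_A = 8e5, name = "V1",
                     period = 0.85) {
  n <- length(p)
  seg <- data.frame(name = name, length_cm = 1, radius_cm = r0,
                    side = "arterial", parent = "", daughter1 = "",
                    daughter2 = "", terminal_partner = "")
  net <- list(segments = seg, inlet = name,
              materials = material_parameters(K_A = K_A))
  structure(list(p = setNames(list(matrix(p, n, 1)), name),
                 q = setNames(list(matrix(q, n, 1)), name),
                 A = setNames(list(matrix(A, n, 1)), name),
                 times = period * seq_len(n) / n, network = net),
            class = "pulmsim")
}
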