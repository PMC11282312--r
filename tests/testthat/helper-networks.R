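# Small network specs used across tests (fast to build and simulate).

small_spec <- function(N = 200, Q = 4, J_Eplus = 2, ...) {
  network_spec(N = N, Q = Q, J_Eplus = J_Eplus, ...)
}

# connectivity with all weights zeroed: isolated neurons driven by I_x only
isolated_conn <- function(N = 10) {
  conn <- build_random_balanced(network_spec(N = N, Q = 1, J_Eplus = 1),
                                seed = 1)
  conn$W@x[] <- 0
  conn
}

# extract a population-pair block of the weight matrix (target a, source b)
weight_block <- function(conn, a, b) {
  u <- conn$units
  conn$W[u$unit[u$population == a], u$unit[u$population == b], drop = FALSE]
}
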