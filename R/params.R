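#' Define a network parameter set
#'
#' Collects all neuron, synapse and topology parameters of a balanced
#' E/I network in a single validated structure. Defaults correspond to the
#' 5000-neuron parameterization used for the metastability analyses
#' (4000 excitatory, 1000 inhibitory neurons).
#'
#' @param N total number of neurons.
#' @param n_E,n_I excitatory/inhibitory population fractions (must sum to 1).
#' @param E_L resting potential (mV).
#' @param V_th spike threshold (mV).
#' @param V_R reset potential (mV).
#' @param C_m membrane capacitance (pF).
#' @param tau_m membrane time constants (ms), named vector \code{c(E=, I=)}.
#' @param tau_syn synaptic current decay constants (ms) by source population,
#'   named vector \code{c(E=, I=)}.
#' @param tau_r absolute refractory period (ms).
#' @param p connection probabilities, named vector
#'   \code{c(p_EE=, p_EI=, p_IE=, p_II=)}; the first index is the postsynaptic
#'   (target) population, the second the presynaptic (source) population.
#' @param g relative strength of inhibition (dimensionless).
#' @param I_x_mult external current expressed as multiples of the rheobase
#'   current of each population, named vector \code{c(E=, I=)}.
#' @param Q number of clusters.
#' @param J_Eplus excitatory within-cluster potentiation factor.
#' @param R_J ratio of inhibitory to excitatory clustering strength in [0, 1].
#'
#' @return An object of class \code{network_spec}.
#' @seealso [task_network_spec()] for the 1500-neuron task configuration.
#' @export
network_spec <- function(N = 5000, n_E = 0.8, n_I = 0.2,
                         E_L = 0, V_th = 15, V_R = 0, C_m = 1,
                         tau_m = c(E = 20, I = 10),
                         tau_syn = c(E = 3, I = 2),
                         tau_r = 5,
                         p = c(p_EE = 0.2, p_EI = 0.5, p_IE = 0.5, p_II = 0.5),
                         g = 1.2,
                         I_x_mult = c(E = 2.13, I = 1.24),
                         Q = 50, J_Eplus = 1, R_J = 3/4) {
  spec <- list(N = N, n_E = n_E, n_I = n_I, E_L = E_L, V_th = V_th,
               V_R = V_R, C_m = C_m,
               tau_m = tau_m[c("E", "I")], tau_syn = tau_syn[c("E", "I")],
               tau_r = tau_r, p = p[c("p_EE", "p_EI", "p_IE", "p_II")],
               g = g, I_x_mult = I_x_mult[c("E", "I")],
               Q = Q, J_Eplus = J_Eplus, R_J = R_J)
  class(spec) <- "network_spec"
  validate_network_spec(spec)
  spec
}

#' Task-network parameter set
#'
#' The 1500-neuron attractor model of motor cortex used for the delayed
#' center-out task: six E/I clusters of 200 excitatory and 50 inhibitory
#' neurons each, cluster strength 3.2, inhibitory/excitatory clustering
#' ratio 3/4, and external currents of 1.25 and 0.78 rheobase units for the
#' E and I populations.
#'
#' @inheritParams network_spec
#' @return An object of class \code{network_spec}.
#' @export
task_network_spec <- function(N = 1500, Q = 6, J_Eplus = 3.2, R_J = 3/4,
                              I_x_mult = c(E = 1.25, I = 0.78), ...) {
  network_spec(N = N, Q = Q, J_Eplus = J_Eplus, R_J = R_J,
               I_x_mult = I_x_mult, ...)
}

validate_network_spec <- function(spec) {
  stopifnot(
    spec$N >= 2, spec$V_R < spec$V_th, spec$C_m > 0,
    all(spec$tau_m > 0), all(spec$tau_syn > 0), spec$tau_r >= 0,
    all(spec$p > 0), all(spec$p <= 1), spec$g >= 0,
    abs(spec$n_E + spec$n_I - 1) < 1e-12,
    spec$Q >= 1, spec$J_Eplus >= 1, spec$R_J >= 0, spec$R_J <= 1
  )
  if (spec$J_Eplus > spec$Q)
    stop("J_Eplus must not exceed Q (across-cluster weight would be negative)")
  # PSP amplitude (and hence the calibration) has a pole at tau_syn == tau_m
  for (a in c("E", "I")) for (b in c("E", "I")) {
    if (isTRUE(all.equal(spec$tau_m[[a]], spec$tau_syn[[b]])))
      stop("tau_syn of source ", b, " equals tau_m of target ", a,
           ": PSP amplitude is degenerate")
  }
  invisible(spec)
}

#' Population sizes of a network spec
#'
#' @param spec a \code{network_spec}.
#' @return Named integer vector with elements \code{E} and \code{I}.
#' @export
population_sizes <- function(spec) {
  N_E <- round(spec$N * spec$n_E)
  c(E = N_E, I = spec$N - N_E)
}

#' @export
print.network_spec <- function(x, ...) {
  ns <- population_sizes(x)
  cat("<network_spec>", x$N, "neurons (", ns["E"], "E /", ns["I"], "I )\n")
  cat("  V_th - E_L =", x$V_th - x$E_L, "mV; tau_m =", x$tau_m["E"], "/",
      x$tau_m["I"], "ms; tau_syn =", x$tau_syn["E"], "/", x$tau_syn["I"],
      "ms; tau_r =", x$tau_r, "ms\n")
  cat("  p =", paste(names(x$p), x$p, sep = "=", collapse = ", "),
      "; g =", x$g, "\n")
  cat("  clusters: Q =", x$Q, ", J_E+ =", x$J_Eplus, ", R_J =", x$R_J, "\n")
  invisible(x)
}

#' Read or write a network configuration file
#'
#' Configurations are YAML key-value documents whose keys mirror the
#' parameter names of [network_spec()] (\code{N}, \code{E_L}, \code{V_th},
#' \code{V_R}, \code{C_m}, \code{tau_m}, \code{tau_syn}, \code{tau_r},
#' \code{p_EE} ... \code{p_II}, \code{g}, \code{I_x_mult}, \code{Q},
#' \code{J_Eplus}, \code{R_J}).
#'
#' @param path file path.
#' @return \code{read_network_config} returns a \code{network_spec}.
#' @export
read_network_config <- function(path) {
  y <- yaml::read_yaml(path)
  two <- function(v) {
    v <- unlist(v)
    if (is.null(names(v)) || !all(c("E", "I") %in% names(v)))
      names(v) <- c("E", "I")
    v
  }
  network_spec(
    N = y$N, n_E = y$n_E %||% 0.8, n_I = y$n_I %||% 0.2,
    E_L = y$E_L, V_th = y$V_th, V_R = y$V_R, C_m = y$C_m,
    tau_m = two(y$tau_m), tau_syn = two(y$tau_syn), tau_r = y$tau_r,
    p = c(p_EE = y$p_EE, p_EI = y$p_EI, p_IE = y$p_IE, p_II = y$p_II),
    g = y$g, I_x_mult = two(y$I_x_mult),
    Q = y$Q %||% 1, J_Eplus = y$J_Eplus %||% 1, R_J = y$R_J %||% 0
  )
}

#' @param spec a \code{network_spec} to serialize.
#' @rdname read_network_config
#' @export
write_network_config <- function(spec, path) {
  y <- list(N = spec$N, n_E = spec$n_E, n_I = spec$n_I, E_L = spec$E_L,
            V_th = spec$V_th, V_R = spec$V_R, C_m = spec$C_m,
            tau_m = as.list(spec$tau_m), tau_syn = as.list(spec$tau_syn),
            tau_r = spec$tau_r,
            p_EE = unname(spec$p["p_EE"]), p_EI = unname(spec$p["p_EI"]),
            p_IE = unname(spec$p["p_IE"]), p_II = unname(spec$p["p_II"]),
            g = spec$g, I_x_mult = as.list(spec$I_x_mult),
            Q = spec$Q, J_Eplus = spec$J_Eplus, R_J = spec$R_J)
  yaml::write_yaml(y, path)
  invisible(path)
}
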