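#' Postsynaptic potential kernel
#'
#' Membrane-potential deflection of a leaky integrate-and-fire neuron in
#' response to a single presynaptic spike arriving at \code{t = 0}, assuming
#' an exponential synaptic current that jumps by the efficacy \code{J} (pA)
#' and decays with \code{tau_syn}:
#' \deqn{PSP(t) = \frac{J}{C_m}\frac{\tau_m \tau_{syn}}{\tau_m - \tau_{syn}}
#'   \left(e^{-t/\tau_m} - e^{-t/\tau_{syn}}\right), \quad t \ge 0.}
#'
#' @param J synaptic efficacy (pA).
#' @param tau_m membrane time constant of the target neuron (ms).
#' @param tau_syn synaptic decay constant of the source population (ms);
#'   must differ from \code{tau_m}.
#' @param C_m membrane capacitance (pF).
#' @param t time since spike arrival (ms), vectorized, non-negative.
#' @return Membrane deflection in mV (same length as \code{t}).
#' @examples
#' psp_kernel(1, 20, 3, 1, t = seq(0, 50, by = 0.5))
#' @export
psp_kernel <- function(J, tau_m, tau_syn, C_m, t) {
  stopifnot(tau_m > 0, tau_syn > 0, C_m > 0, all(t >= 0))
  if (isTRUE(all.equal(tau_m, tau_syn)))
    stop("tau_m == tau_syn: PSP kernel is degenerate")
  (J / C_m) * tau_m * tau_syn / (tau_m - tau_syn) *
    (exp(-t / tau_m) - exp(-t / tau_syn))
}

#' Peak of the postsynaptic potential
#'
#' Time and amplitude of the maximal deflection of [psp_kernel()] for a unit
#' efficacy. The maximum occurs at
#' \eqn{t^* = \log(\tau_{syn}/\tau_m) / (1/\tau_m - 1/\tau_{syn})}.
#'
#' @inheritParams psp_kernel
#' @return Named numeric vector \code{c(t_star = , peak = )} with the peak
#'   time (ms) and peak amplitude per unit efficacy (mV/pA).
#' @export
psp_max <- function(tau_m, tau_syn, C_m = 1) {
  stopifnot(tau_m > 0, tau_syn > 0)
  if (isTRUE(all.equal(tau_m, tau_syn)))
    stop("tau_m == tau_syn: PSP amplitude is degenerate")
  t_star <- log(tau_syn / tau_m) / (1 / tau_m - 1 / tau_syn)
  c(t_star = t_star, peak = psp_kernel(1, tau_m, tau_syn, C_m, t_star))
}

# PSP peak amplitudes for all four synapse types (target alpha, source beta);
# tau_m of the target and tau_syn of the source set the kernel shape.
psp_max_matrix <- function(spec) {
  pops <- c("E", "I")
  m <- matrix(NA_real_, 2, 2, dimnames = list(target = pops, source = pops))
  for (a in pops) for (b in pops)
    m[a, b] <- psp_max(spec$tau_m[[a]], spec$tau_syn[[b]], spec$C_m)["peak"]
  m
}

#' Balanced-state synaptic weight calibration
#'
#' Derives the four base synaptic efficacies from first principles: scale-free
#' weights are constructed so that of the order of \eqn{\sqrt{K}} (with
#' \eqn{K} the excitatory in-degree) near-simultaneous excitatory spikes drive
#' the membrane from rest to threshold, each weight divided by the PSP peak
#' amplitude of the corresponding synapse type, with inhibition scaled by the
#' relative strength \code{g}; the final weights are obtained by dividing by
#' \eqn{\sqrt{N}}.
#'
#' @param spec a [network_spec()].
#' @return Named numeric vector \code{c(J_EE, J_EI, J_IE, J_II)} in pA
#'   (inhibitory weights negative). Attribute \code{"psp_max"} carries the
#'   2x2 matrix of PSP peak amplitudes.
#' @examples
#' compute_weights(network_spec())        # 5000-neuron parameterization
#' compute_weights(task_network_spec())   # 1500-neuron task network
#' @export
compute_weights <- function(spec) {
  validate_network_spec(spec)
  pm <- psp_max_matrix(spec)
  dV <- spec$V_th - spec$E_L
  p <- spec$p
  rad_EE <- p[["p_EE"]] * spec$n_E
  rad_IE <- p[["p_IE"]] * spec$n_E
  if (rad_EE <= 0 || rad_IE <= 0) stop("non-positive radicand in weight scale")
  j_EE <- dV / sqrt(rad_EE) / pm["E", "E"]
  j_EI <- -spec$g * j_EE * (p[["p_EE"]] * spec$n_E) / (p[["p_EI"]] * spec$n_I) *
    pm["E", "E"] / pm["E", "I"]
  j_IE <- dV / sqrt(rad_IE) / pm["I", "E"]
  j_II <- -j_IE * (p[["p_IE"]] * spec$n_E) / (p[["p_II"]] * spec$n_I) *
    pm["I", "E"] / pm["I", "I"]
  w <- c(J_EE = j_EE, J_EI = j_EI, J_IE = j_IE, J_II = j_II) / sqrt(spec$N)
  attr(w, "psp_max") <- pm
  w
}

#' Rheobase (threshold) current
#'
#' Constant current that brings the membrane potential exactly to threshold
#' in the absence of synaptic input: \eqn{I_{th} = (V_{th} - E_L) C_m / \tau_m}.
#'
#' @param spec a [network_spec()].
#' @return Named numeric vector \code{c(E = , I = )} in pA.
#' @export
threshold_current <- function(spec) {
  c(E = (spec$V_th - spec$E_L) * spec$C_m / spec$tau_m[["E"]],
    I = (spec$V_th - spec$E_L) * spec$C_m / spec$tau_m[["I"]])
}

#' External input currents
#'
#' Constant external drive per population, expressed as multiples of the
#' rheobase current ([threshold_current()]).
#'
#' @param spec a [network_spec()]; multipliers are taken from
#'   \code{spec$I_x_mult}.
#' @return Named numeric vector \code{c(E = , I = )} in pA.
#' @export
external_currents <- function(spec) {
  ith <- threshold_current(spec)
  c(E = spec$I_x_mult[["E"]] * ith[["E"]],
    I = spec$I_x_mult[["I"]] * ith[["I"]])
}

#' Cluster weight-scaling factors
#'
#' Within-cluster weights are potentiated by \code{J_Eplus} (excitatory) and
#' \code{J_Iplus} (inhibitory-related), and across-cluster weights depressed
#' by \eqn{J_{\alpha-} = (Q - J_{\alpha+})/(Q - 1)} so that the mean synaptic
#' strength of each weight class is preserved. The inhibitory clustering
#' strength is tied to the excitatory one by the proportionality factor
#' \code{R_J}: \eqn{J_{I+} = 1 + R_J (J_{E+} - 1)}. \code{R_J = 0} leaves the
#' inhibitory population unclustered (E-clustered network); \code{R_J = 1}
#' clusters it as strongly as the excitatory one.
#'
#' @param Q number of clusters (>= 2).
#' @param J_Eplus excitatory cluster strength, in \code{[1, Q]}.
#' @param R_J inhibitory/excitatory clustering ratio, in \code{[0, 1]}.
#' @return Object of class \code{cluster_scaling}: list with fields \code{Q},
#'   \code{J_Eplus}, \code{J_Eminus}, \code{J_Iplus}, \code{J_Iminus},
#'   \code{R_J}.
#' @examples
#' cluster_scaling(Q = 6, J_Eplus = 3.2, R_J = 3/4)
#' @export
cluster_scaling <- function(Q, J_Eplus, R_J = 3/4) {
  stopifnot(Q >= 2, J_Eplus >= 1, R_J >= 0, R_J <= 1)
  if (J_Eplus > Q)
    stop("J_Eplus > Q gives a negative across-cluster weight")
  J_Iplus <- 1 + R_J * (J_Eplus - 1)
  out <- list(Q = Q, J_Eplus = J_Eplus,
              J_Eminus = (Q - J_Eplus) / (Q - 1),
              J_Iplus = J_Iplus,
              J_Iminus = (Q - J_Iplus) / (Q - 1),
              R_J = R_J)
  class(out) <- "cluster_scaling"
  out
}

#' @export
print.cluster_scaling <- function(x, ...) {
  cat(sprintf("<cluster_scaling> Q=%d  J_E+=%.4g J_E-=%.4g  J_I+=%.4g J_I-=%.4g (R_J=%.3g)\n",
              x$Q, x$J_Eplus, x$J_Eminus, x$J_Iplus, x$J_Iminus, x$R_J))
  invisible(x)
}

#' Derived-parameter report
#'
#' All calibrated quantities of a network specification in one data frame:
#' base weights, rheobase and external currents, and cluster scaling factors.
#'
#' @param spec a [network_spec()].
#' @return A data frame with columns \code{parameter}, \code{unit},
#'   \code{value}.
#' @export
derived_parameters <- function(spec) {
  w <- compute_weights(spec)
  ith <- threshold_current(spec)
  ix <- external_currents(spec)
  sc <- if (spec$Q >= 2) cluster_scaling(spec$Q, spec$J_Eplus, spec$R_J)
        else list(J_Eminus = 1, J_Iplus = 1, J_Iminus = 1)
  data.frame(
    parameter = c("J_EE", "J_EI", "J_IE", "J_II",
                  "I_th_E", "I_th_I", "I_x_E", "I_x_I",
                  "J_Eplus", "J_Eminus", "J_Iplus", "J_Iminus"),
    unit = c(rep("pA", 8), rep("", 4)),
    value = unname(c(w, ith, ix, spec$J_Eplus, sc$J_Eminus, sc$J_Iplus,
                     sc$J_Iminus))
  )
}
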