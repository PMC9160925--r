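# Neuron, device and synapse model definitions.
#
# Dynamic neurons follow the exact-integration scheme for linear membrane
# equations: current-based cells use the full matrix propagator of the
# (y1, y2, V) system obtained with Matrix::expm, conductance-based cells
# advance their alpha conductances exactly and the membrane semi-analytically
# (exponential Euler with the exact within-step conductance average).

#' Default parameters of the current-based leaky integrate-and-fire neuron
#'
#' Membrane time constant `tau_m` (ms), capacitance `C_m` (pF), resting
#' potential `E_L` (mV), threshold `V_th` (mV), reset `V_reset` (mV),
#' refractory period `t_ref` (ms), alpha-PSC time constant `tau_syn` (ms)
#' and bias current `I_e` (pA).
#'
#' @return named list of defaults.
#' @export
lif_current_defaults <- function() {
  list(tau_m = 10, C_m = 250, E_L = -70, V_th = -55, V_reset = -70,
       t_ref = 2, tau_syn = 2, I_e = 0)
}

#' Default parameters of the conductance-based leaky integrate-and-fire neuron
#'
#' Four alpha-shaped receptor channels (AMPA, NMDA, GABA_A, GABA_B), each with
#' a reversal potential `E_rev` (mV) and time constant `tau` (ms). NMDA is a
#' slow alpha conductance without a voltage-dependent magnesium block. The
#' leak conductance is `C_m / tau_m`.
#'
#' @return named list of defaults.
#' @export
lif_conductance_defaults <- function() {
  list(tau_m = 10, C_m = 250, E_L = -70, V_th = -55, V_reset = -70,
       t_ref = 2, I_bias = 0,
       receptors = list(
         AMPA   = list(E_rev = 0,   tau = 2),
         NMDA   = list(E_rev = 0,   tau = 20),
         GABA_A = list(E_rev = -80, tau = 4),
         GABA_B = list(E_rev = -90, tau = 30)
       ))
}

RECEPTORS <- c("AMPA", "NMDA", "GABA_A", "GABA_B")

.model_kinds <- c("lif_current", "lif_conductance", "parrot",
                  "poisson_generator", "readout_neuron", "spike_recorder")

validate_model_params <- function(model, params) {
  if (!model %in% .model_kinds) {
    stop("unknown model kind: ", model, call. = FALSE)
  }
  if (model %in% c("lif_current", "readout_neuron")) {
    p <- utils::modifyList(lif_current_defaults(), params)
    if (model == "readout_neuron") p$V_th <- Inf
    with(p, {
      stopifnot(tau_m > 0, C_m > 0, t_ref >= 0, tau_syn > 0)
      if (is.finite(V_th) && !(V_reset < V_th)) {
        stop("V_reset must be below V_th", call. = FALSE)
      }
    })
    unknown <- setdiff(names(params), names(lif_current_defaults()))
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    return(p)
  }
  if (model == "lif_conductance") {
    defs <- lif_conductance_defaults()
    p <- utils::modifyList(defs, params)
    stopifnot(p$tau_m > 0, p$C_m > 0, p$t_ref >= 0, p$V_reset < p$V_th)
    if (!all(names(p$receptors) %in% RECEPTORS)) {
      stop("receptor labels must be among ", paste(RECEPTORS, collapse = ", "),
           call. = FALSE)
    }
    for (r in p$receptors) stopifnot(r$tau > 0)
    ex <- vapply(p$receptors[intersect(names(p$receptors), c("AMPA", "NMDA"))],
                 function(r) r$E_rev, 0)
    inh <- vapply(p$receptors[intersect(names(p$receptors),
                                        c("GABA_A", "GABA_B"))],
                  function(r) r$E_rev, 0)
    if (length(ex) && length(inh) && !(min(ex) > max(inh))) {
      stop("excitatory reversal must exceed inhibitory reversal",
           call. = FALSE)
    }
    return(p)
  }
  if (model == "poisson_generator") {
    p <- utils::modifyList(list(rate = 0), params)
    if (p$rate < 0) stop("rate must be >= 0", call. = FALSE)
    return(p)
  }
  # parrot, spike_recorder: no parameters
  if (length(params)) stop(model, " takes no parameters", call. = FALSE)
  list()
}

# Exact propagator of the current-based neuron over one step h.
# State z = (y1, y2, u, I_e) with u = V - E_L:
#   y1' = -y1/tau_s;  y2' = y1 - y2/tau_s;  u' = -u/tau_m + (y2 + I_e)/C_m
# Returns the 4x4 matrix exp(A h); the I_e column makes heterogeneous
# per-neuron bias currents exact.
current_propagator <- function(tau_m, C_m, tau_syn, h) {
  A <- matrix(0, 4, 4)
  A[1, 1] <- -1 / tau_syn
  A[2, 1] <- 1
  A[2, 2] <- -1 / tau_syn
  A[3, 2] <- 1 / C_m
  A[3, 3] <- -1 / tau_m
  A[3, 4] <- 1 / C_m
  as.matrix(Matrix::expm(A * h))
}

#' One exact-integration step of the current-based LIF neuron
#'
#' Pure function advancing membrane potential and the two-state alpha PSC by
#' one step of width `dt`. Arriving spike weights (`input_w`, pA at PSC peak)
#' are added to the first synaptic state after propagation, so they act from
#' the end of the step onward. A spike is emitted iff `V >= V_th` at the end
#' of the step; the potential is then reset and the refractory counter armed.
#'
#' @param state list with numeric vectors `V`, `y1`, `y2`, `refr`.
#' @param input_w summed arriving weights per neuron (pA), scalar or vector.
#' @param params parameter record as from [lif_current_defaults()].
#' @param dt step width, ms.
#' @param prop optional precomputed propagator from the same parameters.
#' @return list with updated `state` and logical vector `spiked`.
#' @export
lif_current_step <- function(state, input_w, params, dt, prop = NULL) {
  p <- validate_model_params("lif_current", params)
  if (is.null(prop)) prop <- current_propagator(p$tau_m, p$C_m, p$tau_syn, dt)
  u <- state$V - p$E_L
  u2 <- prop[3, 1] * state$y1 + prop[3, 2] * state$y2 + prop[3, 3] * u +
    prop[3, 4] * p$I_e
  y2 <- prop[2, 1] * state$y1 + prop[2, 2] * state$y2
  y1 <- prop[1, 1] * state$y1
  V <- p$E_L + u2
  refr <- state$refr
  inref <- refr > 0
  V[inref] <- p$V_reset
  refr[inref] <- refr[inref] - 1L
  y1 <- y1 + input_w * exp(1) / p$tau_syn
  spiked <- !inref & V >= p$V_th
  if (any(spiked)) {
    V[spiked] <- p$V_reset
    refr[spiked] <- as.integer(round(p$t_ref / dt))
  }
  list(state = list(V = V, y1 = y1, y2 = y2, refr = refr), spiked = spiked)
}

# Per-receptor exact alpha-conductance propagation constants for step h:
# decay d = exp(-h/tau); y1' = d y1; y2' = d (y2 + h y1); and the exact step
# integral of y2, int_0^h y2 dt = A y2 + B y1 with
#   A = tau (1 - d),  B = tau^2 (1 - d) - tau h d.
alpha_step_constants <- function(tau, h) {
  d <- exp(-h / tau)
  list(d = d, h = h, A = tau * (1 - d), B = tau^2 * (1 - d) - tau * h * d)
}

#' One step of the conductance-based LIF neuron
#'
#' Alpha conductances are advanced exactly; the membrane uses exponential
#' Euler with the exact time-averaged conductance of each receptor over the
#' step, which keeps the update second-order accurate in `dt`. The membrane
#' potential can never leave the interval spanned by the reversal potentials
#' and the leak equilibrium.
#'
#' @param state list with `V`, `refr`, and per-receptor matrices `g1`, `g2`
#'   (columns = receptors present in `params$receptors`).
#' @param input_w matrix of arriving weights (nS at conductance peak), one
#'   column per receptor, or NULL.
#' @param params record as from [lif_conductance_defaults()].
#' @param dt step width, ms.
#' @return list with updated `state` and logical `spiked`.
#' @export
lif_conductance_step <- function(state, input_w, params, dt) {
  p <- validate_model_params("lif_conductance", params)
  rec <- p$receptors
  g_L <- p$C_m / p$tau_m
  n <- length(state$V)
  gbar_sum <- numeric(n)
  gE_sum <- numeric(n)
  g1 <- state$g1
  g2 <- state$g2
  for (k in seq_along(rec)) {
    cst <- alpha_step_constants(rec[[k]]$tau, dt)
    gbar <- (cst$A * g2[, k] + cst$B * g1[, k]) / dt # exact step average
    gbar_sum <- gbar_sum + gbar
    gE_sum <- gE_sum + gbar * rec[[k]]$E_rev
    g2[, k] <- cst$d * (g2[, k] + dt * g1[, k])
    g1[, k] <- cst$d * g1[, k]
  }
  gtot <- g_L + gbar_sum
  Vinf <- (g_L * p$E_L + gE_sum + p$I_bias) / gtot
  V <- Vinf + (state$V - Vinf) * exp(-dt * gtot / p$C_m)
  refr <- state$refr
  inref <- refr > 0
  V[inref] <- p$V_reset
  refr[inref] <- refr[inref] - 1L
  if (!is.null(input_w)) {
    for (k in seq_along(rec)) {
      g1[, k] <- g1[, k] + input_w[, k] * exp(1) / rec[[k]]$tau
    }
  }
  spiked <- !inref & V >= p$V_th
  if (any(spiked)) {
    V[spiked] <- p$V_reset
    refr[spiked] <- as.integer(round(p$t_ref / dt))
  }
  list(state = list(V = V, g1 = g1, g2 = g2, refr = refr), spiked = spiked)
}

#' Single pair update of the power-law STDP synapse
#'
#' Multiplicative depression, power-law potentiation. For a pre-before-post
#' interval `dt_pre_post > 0` (potentiation):
#' `w' = w + lambda * w0^(1-mu) * w^mu * exp(-dt/tau_plus)`;
#' for post-before-pre (`dt_pre_post < 0`, depression):
#' `w' = w - lambda * alpha * w * exp(-|dt|/tau_minus)`.
#' The weight is floored at `1e-12 * w0` so depression can never cross zero.
#'
#' @param syn list with `weight`, `lambda_`, `mu`, `alpha_`, `tau_plus`,
#'   `tau_minus`, `w0`.
#' @param dt_pre_post sign-carrying pre/post interval in ms.
#' @return the updated weight.
#' @export
stdp_update <- function(syn, dt_pre_post) {
  s <- utils::modifyList(stdp_defaults(), syn)
  stopifnot(s$mu >= 0, s$mu <= 1, s$weight > 0)
  w <- s$weight
  if (dt_pre_post > 0) {
    w <- w + s$lambda_ * s$w0^(1 - s$mu) * w^s$mu *
      exp(-dt_pre_post / s$tau_plus)
  } else if (dt_pre_post < 0) {
    w <- w - s$lambda_ * s$alpha_ * w * exp(dt_pre_post / s$tau_minus)
  }
  max(w, 1e-12 * s$w0)
}

#' Default constants of the power-law STDP synapse
#'
#' The learning-rule constants are configurable throughout; these defaults
#' follow the common benchmark lineage for this rule.
#'
#' @return named list: `lambda_`, `mu`, `alpha_`, `tau_plus` (ms),
#'   `tau_minus` (ms), `w0`, `weight`, `delay` (ms).
#' @export
stdp_defaults <- function() {
  list(lambda_ = 0.1, mu = 0.4, alpha_ = 0.05, tau_plus = 15, tau_minus = 30,
       w0 = 1, weight = 1, delay = 1.5)
}
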