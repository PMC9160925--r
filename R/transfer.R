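# Transfer functions between the spike domain and the plant domain:
# spike sinks (population -> muscle activation) and spike sources
# (rate -> population drive).

#' Create a spike sink
#'
#' A readout pathway: one leaky integrator neuron with disabled (infinite)
#' threshold receives static synapses from every neuron of the source
#' population; its membrane displacement above rest, normalized by `v_span`
#' and clipped to [0, 1], is the muscle activation signal.
#'
#' @param kernel kernel object.
#' @param population source population handle (must be non-empty).
#' @param muscles integer indices of the muscles this sink drives.
#' @param weight synaptic weight onto the readout neuron, pA.
#' @param delay synaptic delay, ms.
#' @param v_span normalization span in mV: a readout sitting `v_span` above
#'   rest maps to activation 1. Chosen so that a population firing at the
#'   reference resting rate drives the sink near 0.8; configurable.
#' @param tau_m readout integrator time constant, ms; sets the smoothing
#'   window of the activation signal.
#' @return sink of class `embsnn_sink`.
#' @export
make_spike_sink <- function(kernel, population, muscles = integer(0),
                            weight = 20, delay = 1.5, v_span = 10,
                            tau_m = 10) {
  if (population$count < 1) stop("empty population", call. = FALSE)
  readout <- create(kernel, "readout_neuron", 1,
                    list(tau_m = tau_m, I_e = 0))
  n <- connect(kernel, population, readout, conn_all_to_all(),
               syn_static(weight = weight, delay = delay))
  structure(list(readout = readout, source = population, muscles = muscles,
                 v_span = v_span, n_synapses = n,
                 E_L = get_status(kernel, readout)$E_L),
            class = "embsnn_sink")
}

#' Read the activation of a spike sink
#'
#' `clip((V_readout - E_L) / v_span, 0, 1)` — always in [0, 1].
#'
#' @param kernel kernel object.
#' @param sink sink from [make_spike_sink()].
#' @return activation value in [0, 1].
#' @export
read_activation <- function(kernel, sink) {
  v <- get_v(kernel, sink$readout)
  min(max((v - sink$E_L) / sink$v_span, 0), 1)
}

#' Create a spike source
#'
#' A Poisson generator connected to every neuron of the target population;
#' each connection carries an independent Poisson realization at the
#' device rate.
#'
#' @param kernel kernel object.
#' @param population target population handle.
#' @param rate initial rate, Hz (>= 0).
#' @param weight synaptic weight per delivered spike.
#' @param delay delay, ms.
#' @param receptor receptor label for conductance-based targets.
#' @return source of class `embsnn_source`.
#' @export
make_spike_source <- function(kernel, population, rate = 0, weight = 1,
                              delay = 1.5, receptor = "AMPA") {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  gen <- create(kernel, "poisson_generator", 1, list(rate = rate))
  n <- connect(kernel, gen, population, conn_all_to_all(),
               syn_static(weight = weight, delay = delay,
                          receptor = receptor))
  structure(list(generator = gen, target = population, n_connections = n),
            class = "embsnn_source")
}

#' Set the rate of a spike source
#'
#' Takes effect from the next kernel step; rate 0 emits nothing.
#'
#' @param kernel kernel object.
#' @param source source from [make_spike_source()].
#' @param rate_hz new rate, Hz (>= 0).
#' @export
set_rate <- function(kernel, source, rate_hz) {
  if (rate_hz < 0) stop("rate must be >= 0", call. = FALSE)
  set_status(kernel, source$generator, list(rate = rate_hz))
  invisible(NULL)
}
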