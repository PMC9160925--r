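# Balanced random benchmark network: 11,250 neurons per unit scale, fixed
# recurrent indegree of 11,250 per neuron regardless of scale, power-law
# STDP on excitatory-excitatory synapses, all other synapses static, one
# external Poisson drive device connected once to every neuron.

BRUNEL_BASE_N <- 11250L
BRUNEL_INDEGREE <- 11250L

#' Dry-run census of the balanced network
#'
#' Exact integer counts without instantiating anything. Neurons =
#' `round(11250 * scale)`; nodes add the single external drive device;
#' connections = fixed recurrent indegree per neuron plus one drive
#' connection per neuron.
#'
#' @param scale positive scale parameter (scale 20 is the benchmark
#'   configuration with 225,000 neurons).
#' @return list with `neurons`, `nodes`, `connections`.
#' @export
count_brunel <- function(scale) {
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  neurons <- round(BRUNEL_BASE_N * scale)
  list(neurons = neurons,
       nodes = neurons + 1,
       connections = neurons * BRUNEL_INDEGREE + neurons)
}

#' Default dynamics parameters of the balanced network
#'
#' Weights, delays and the external drive rate are not part of the
#' benchmark's printed configuration; these are documented package
#' defaults. `g` is the inhibition-excitation weight ratio, `J_pA` the
#' excitatory PSC peak.
#'
#' @return named list of defaults.
#' @export
brunel_defaults <- function() {
  list(J_pA = 20, g = 5, delay = 1.5, ext_rate_hz = 8000,
       epsilon_E = 0.8, stdp = stdp_defaults())
}

#' Build the balanced network
#'
#' Instantiates the network whose census equals [count_brunel()]:
#' excitatory and inhibitory current-based LIF populations (4:1), fixed
#' indegree of 11,250 per neuron split proportionally between the E and I
#' pools, plastic (power-law STDP) E-to-E synapses, static synapses
#' everywhere else, one Poisson drive device with one connection per
#' neuron, and a spike recorder on all neurons (an instrument, excluded
#' from the node census).
#'
#' @param scale scale parameter; guarded by `max_synapses`.
#' @param kernel kernel object (created with resolution 0.1 ms by default).
#' @param params dynamics defaults, see [brunel_defaults()].
#' @param max_synapses refusal guard for desk-scale use; the error names
#'   the dry-run census.
#' @param record attach a spike recorder (default TRUE).
#' @return list of handles: `E`, `I`, `drive`, `recorder`, `kernel`,
#'   and the realized `census`.
#' @export
build_brunel <- function(scale, kernel = new_kernel(resolution = 0.1),
                         params = brunel_defaults(),
                         max_synapses = 5e7, record = TRUE) {
  cb <- count_brunel(scale)
  if (cb$connections > max_synapses) {
    stop("refusing to instantiate ", cb$connections, " connections (",
         cb$neurons, " neurons, ", cb$nodes, " nodes); raise max_synapses ",
         "to override", call. = FALSE)
  }
  N <- as.integer(cb$neurons)
  NE <- as.integer(round(N * params$epsilon_E))
  NI <- N - NE
  KE <- as.integer(round(BRUNEL_INDEGREE * params$epsilon_E))
  KI <- BRUNEL_INDEGREE - KE
  E <- create(kernel, "lif_current", NE)
  I <- create(kernel, "lif_current", NI)
  JE <- params$J_pA
  JI <- -params$g * params$J_pA
  sp <- params$stdp
  n_ee <- connect(kernel, E, E, conn_fixed_indegree(KE),
                  syn_stdp(weight = JE, delay = params$delay,
                           lambda_ = sp$lambda_, mu = sp$mu,
                           alpha_ = sp$alpha_, tau_plus = sp$tau_plus,
                           tau_minus = sp$tau_minus, w0 = JE))
  n_ei <- connect(kernel, E, I, conn_fixed_indegree(KE),
                  syn_static(weight = JE, delay = params$delay))
  n_ie <- connect(kernel, I, E, conn_fixed_indegree(KI),
                  syn_static(weight = JI, delay = params$delay))
  n_ii <- connect(kernel, I, I, conn_fixed_indegree(KI),
                  syn_static(weight = JI, delay = params$delay))
  drive <- create(kernel, "poisson_generator", 1,
                  list(rate = params$ext_rate_hz))
  n_dr <- connect(kernel, drive, E, conn_all_to_all(),
                  syn_static(weight = JE, delay = params$delay)) +
    connect(kernel, drive, I, conn_all_to_all(),
            syn_static(weight = JE, delay = params$delay))
  recorder <- NULL
  if (record) {
    recorder <- create(kernel, "spike_recorder", 1)
    connect(kernel, E, recorder)
    connect(kernel, I, recorder)
  }
  census <- list(neurons = as.numeric(N), nodes = N + 1,
                 connections = as.numeric(n_ee + n_ei + n_ie + n_ii + n_dr))
  list(E = E, I = I, drive = drive, recorder = recorder, kernel = kernel,
       census = census)
}
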