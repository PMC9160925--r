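# Clock-driven spiking network kernel.
#
# A kernel is a mutable environment holding populations, projections and
# recorders. Time advances on a fixed grid (default 0.1 ms); spikes are
# detected at step ends, travel through per-population ring buffers indexed
# by arrival step, and all randomness is drawn from gid-keyed streams so the
# spike output is bitwise independent of the number of logical workers.

#' Create a simulation kernel
#'
#' @param resolution integration step in ms (default 0.1).
#' @param seed master seed; every stochastic draw derives from it.
#' @param n_workers number of logical workers; neurons are assigned
#'   round-robin by `gid %% n_workers` and synapses live with the owner of
#'   the post-synaptic neuron. The value never influences simulation results.
#' @param min_delay lower bound on synaptic delays, ms; must be at least one
#'   resolution step.
#' @param init_v_random if TRUE, initial membrane potentials are drawn
#'   uniformly in `[V_reset, V_th]` from each population's private stream;
#'   otherwise neurons start at their resting potential.
#' @return a kernel object (environment) of class `embsnn_kernel`.
#' @export
new_kernel <- function(resolution = 0.1, seed = 1, n_workers = 1L,
                       min_delay = resolution, init_v_random = FALSE) {
  stopifnot(resolution > 0, n_workers >= 1, seed >= 0)
  if (min_delay < resolution - 1e-12) {
    stop("min_delay must be at least one resolution step", call. = FALSE)
  }
  k <- new.env(parent = emptyenv())
  k$res <- resolution
  k$seed <- as.numeric(seed)
  k$n_workers <- as.integer(n_workers)
  k$min_delay <- min_delay
  k$init_v_random <- isTRUE(init_v_random)
  k$step <- 0L
  k$next_gid <- 1L
  k$pops <- list()
  k$projections <- list()
  k$n_connect_calls <- 0L
  k$dirty <- TRUE
  class(k) <- "embsnn_kernel"
  k
}

#' @export
print.embsnn_kernel <- function(x, ...) {
  cat("<embsnn kernel> t =", kernel_time(x), "ms,",
      length(x$pops), "populations,",
      sum(vapply(x$projections, function(p) p$n_syn, 0)), "synapses,",
      x$n_workers, "worker(s)\n")
  invisible(x)
}

#' Current kernel time in ms
#' @param kernel a kernel object.
#' @return simulated time, always an integer multiple of the resolution.
#' @export
kernel_time <- function(kernel) kernel$step * kernel$res

#' Owning worker of a neuron
#'
#' Neurons are distributed over logical workers round-robin; synapses and
#' per-neuron bookkeeping follow the owner of the post-synaptic neuron.
#'
#' @param gid global neuron id (or vector).
#' @param n_workers number of workers.
#' @return 0-based worker index, `gid %% n_workers`.
#' @export
owner_worker <- function(gid, n_workers) {
  stopifnot(n_workers >= 1)
  gid %% n_workers
}

#' Kernel status record
#' @param kernel a kernel object.
#' @return list with resolution, time, seed, worker count, node and
#'   connection counts.
#' @export
get_kernel_status <- function(kernel) {
  list(resolution = kernel$res,
       time_ms = kernel_time(kernel),
       seed = kernel$seed,
       n_workers = kernel$n_workers,
       network_size = if (length(kernel$pops)) {
         sum(vapply(kernel$pops, function(p) p$count, 0))
       } else 0,
       num_connections = if (length(kernel$projections)) {
         sum(vapply(kernel$projections, function(p) p$n_syn, 0))
       } else 0)
}

n_channels_for <- function(model, params) {
  switch(model,
         lif_current = 1L, readout_neuron = 1L,
         lif_conductance = length(params$receptors),
         parrot = 1L,
         0L)
}

#' Create a population of neurons or devices
#'
#' Allocates `n` fresh contiguous global ids and initializes state. Dynamic
#' neurons start at the resting potential `E_L` unless the kernel was
#' configured with randomized initial potentials.
#'
#' @param kernel a kernel object.
#' @param model one of `"lif_current"`, `"lif_conductance"`, `"parrot"`,
#'   `"poisson_generator"`, `"readout_neuron"`, `"spike_recorder"`.
#' @param n number of elements (>= 1).
#' @param params model parameter record; missing entries take defaults.
#' @param positions optional n x 2 matrix of (x, y) sheet positions in mm.
#' @return a population handle of class `embsnn_population`.
#' @export
create <- function(kernel, model, n, params = list(), positions = NULL) {
  stopifnot(inherits(kernel, "embsnn_kernel"), n >= 1)
  n <- as.integer(n)
  par <- validate_model_params(model, params)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n || ncol(positions) != 2) {
      stop("positions must be an n x 2 matrix", call. = FALSE)
    }
  }
  p <- new.env(parent = emptyenv())
  p$id <- length(kernel$pops) + 1L
  p$first_id <- kernel$next_gid
  p$count <- n
  p$model <- model
  p$par <- par
  p$positions <- positions
  p$out_projs <- integer(0)
  p$rec_ids <- integer(0)
  p$slots <- 0L
  p$buffer <- NULL
  p$has_traces <- FALSE
  kernel$next_gid <- kernel$next_gid + n
  init_pop_state(kernel, p)
  kernel$pops[[p$id]] <- p
  kernel$dirty <- TRUE
  structure(list(pop = p$id, first_id = p$first_id, count = n, model = model),
            class = "embsnn_population")
}

#' @export
print.embsnn_population <- function(x, ...) {
  cat("<embsnn population>", x$model, "gids", x$first_id, "..",
      x$first_id + x$count - 1L, "\n")
  invisible(x)
}

#' Global ids of a population
#' @param pop a population handle.
#' @return integer vector of gids.
#' @export
pop_gids <- function(pop) seq.int(pop$first_id, length.out = pop$count)

init_pop_state <- function(kernel, p) {
  n <- p$count
  model <- p$model
  if (model %in% c("lif_current", "readout_neuron")) {
    V0 <- initial_v(kernel, p)
    p$state <- list(V = V0, y1 = numeric(n), y2 = numeric(n),
                    refr = integer(n))
    pr <- current_propagator(p$par$tau_m, p$par$C_m, p$par$tau_syn,
                             kernel$res)
    p$fast <- list(P11 = pr[1, 1], P21 = pr[2, 1], P22 = pr[2, 2],
                   P31 = pr[3, 1], P32 = pr[3, 2], P33 = pr[3, 3],
                   P34 = pr[3, 4],
                   psc = exp(1) / p$par$tau_syn,
                   refr_steps = as.integer(round(p$par$t_ref / kernel$res)))
  } else if (model == "lif_conductance") {
    V0 <- initial_v(kernel, p)
    nr <- length(p$par$receptors)
    p$state <- list(V = V0,
                    g1 = lapply(seq_len(nr), function(k) numeric(n)),
                    g2 = lapply(seq_len(nr), function(k) numeric(n)),
                    refr = integer(n))
    taus <- vapply(p$par$receptors, function(r) r$tau, 0)
    cst <- lapply(taus, alpha_step_constants, h = kernel$res)
    p$fast <- list(
      d = vapply(cst, `[[`, 0, "d"),
      A = vapply(cst, `[[`, 0, "A"),
      B = vapply(cst, `[[`, 0, "B"),
      gin = exp(1) / taus,
      E_rev = vapply(p$par$receptors, function(r) r$E_rev, 0),
      g_L = p$par$C_m / p$par$tau_m,
      dt = kernel$res,
      inv_dt = 1 / kernel$res,
      refr_steps = as.integer(round(p$par$t_ref / kernel$res)))
  } else if (model == "spike_recorder") {
    p$ev <- new.env(parent = emptyenv())
    p$n_chunks <- 0L
  }
  invisible(p)
}

initial_v <- function(kernel, p) {
  if (kernel$init_v_random && is.finite(p$par$V_th)) {
    with_stream(kernel$seed, "init_v", p$first_id, 0,
                stats::runif(p$count, p$par$V_reset, p$par$V_th))
  } else {
    rep(p$par$E_L, p$count)
  }
}

is_dynamic <- function(model) {
  model %in% c("lif_current", "lif_conductance", "readout_neuron", "parrot")
}

#' Read membrane potentials of a population
#' @param kernel kernel object.
#' @param pop population handle of a dynamic neuron model.
#' @return numeric vector of membrane potentials, mV.
#' @export
get_v <- function(kernel, pop) {
  p <- kernel$pops[[pop$pop]]
  if (is.null(p$state$V)) stop("population has no membrane potential")
  p$state$V
}

#' Update parameters of a population or device
#'
#' Device parameter changes (e.g. a Poisson generator's `rate`) take effect
#' from the next kernel step. For neurons, `I_e`/`I_bias` may be a vector of
#' per-neuron values.
#'
#' @param kernel kernel object.
#' @param pop population handle.
#' @param params named list of parameters to update.
#' @export
set_status <- function(kernel, pop, params) {
  p <- kernel$pops[[pop$pop]]
  vec_ok <- intersect(names(params), c("I_e", "I_bias"))
  scalars <- params[setdiff(names(params), vec_ok)]
  merged <- utils::modifyList(p$par, scalars)
  merged[vec_ok] <- params[vec_ok]
  for (nm in vec_ok) {
    if (!length(merged[[nm]]) %in% c(1L, p$count)) {
      stop(nm, " must be scalar or one value per neuron", call. = FALSE)
    }
  }
  # revalidate via the model contract (vector currents checked above)
  chk <- merged
  for (nm in vec_ok) chk[[nm]] <- merged[[nm]][1]
  validate_model_params(p$model, chk)
  p$par <- merged
  if (p$model %in% c("lif_current", "readout_neuron",
                     "lif_conductance")) {
    init_refresh_fast(kernel, p)
  }
  invisible(NULL)
}

init_refresh_fast <- function(kernel, p) {
  st <- p$state
  init_pop_state(kernel, p)
  p$state <- st # keep dynamic state, refresh only propagator constants
  invisible(p)
}

#' Read parameters of a population
#' @param kernel kernel object.
#' @param pop population handle.
#' @return the parameter record.
#' @export
get_status <- function(kernel, pop) kernel$pops[[pop$pop]]$par
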