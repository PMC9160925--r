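# Connectivity rules and synapse instantiation.
#
# Instantiation iterates post-synaptic neurons in ascending gid and draws
# from each post neuron's private stream, so the realized wiring is a pure
# function of (master seed, connect-call counter, post gid) — independent of
# worker count and iteration order.

#' Connectivity rules
#'
#' Declarative connection rules: `conn_all_to_all()` connects every ordered
#' pair; `conn_one_to_one()` requires equal population sizes;
#' `conn_fixed_indegree(k)` gives every post neuron exactly `k` incoming
#' synapses drawn uniformly (with multapses when allowed);
#' `conn_pairwise_gaussian(p0, sigma_mm)` connects each ordered pair
#' independently with probability `p0 * exp(-d^2 / (2 sigma^2))` based on
#' sheet positions, excluding autapses when pre and post are the same
#' population.
#'
#' @param k fixed indegree per post neuron.
#' @param allow_multapses permit repeated pre partners (default TRUE).
#' @param p0 peak connection probability at distance zero, in (0, 1].
#' @param sigma_mm Gaussian width in mm.
#' @return a rule object for [connect()].
#' @export
conn_all_to_all <- function() structure(list(rule = "all_to_all"),
                                        class = "embsnn_rule")

#' @rdname conn_all_to_all
#' @export
conn_one_to_one <- function() structure(list(rule = "one_to_one"),
                                        class = "embsnn_rule")

#' @rdname conn_all_to_all
#' @export
conn_fixed_indegree <- function(k, allow_multapses = TRUE) {
  stopifnot(k >= 1)
  structure(list(rule = "fixed_indegree", k = as.integer(k),
                 allow_multapses = isTRUE(allow_multapses)),
            class = "embsnn_rule")
}

#' @rdname conn_all_to_all
#' @export
conn_pairwise_gaussian <- function(p0, sigma_mm) {
  stopifnot(p0 > 0, p0 <= 1, sigma_mm > 0)
  structure(list(rule = "pairwise_gaussian", p0 = p0, sigma = sigma_mm),
            class = "embsnn_rule")
}

#' Synapse specifications
#'
#' `syn_static()` is a fixed-weight synapse; `syn_stdp()` carries the
#' power-law STDP rule (multiplicative depression, power-law potentiation).
#' Weights are in pA (current-based targets) or nS (conductance-based
#' targets); delays in ms must be positive multiples of the kernel
#' resolution and at least `min_delay`.
#'
#' @param weight synaptic weight at PSC/conductance peak.
#' @param delay transmission delay, ms.
#' @param receptor receptor label for conductance-based targets.
#' @param lambda_,mu,alpha_,tau_plus,tau_minus,w0 STDP constants, see
#'   [stdp_defaults()].
#' @return a synapse spec for [connect()].
#' @export
syn_static <- function(weight = 1, delay = 1.5, receptor = "AMPA") {
  structure(list(type = "static", weight = weight, delay = delay,
                 receptor = receptor), class = "embsnn_syn")
}

#' @rdname syn_static
#' @export
syn_stdp <- function(weight = 1, delay = 1.5, receptor = "AMPA",
                     lambda_ = 0.1, mu = 0.4, alpha_ = 0.05,
                     tau_plus = 15, tau_minus = 30, w0 = weight) {
  stopifnot(weight > 0, mu >= 0, mu <= 1)
  structure(list(type = "stdp", weight = weight, delay = delay,
                 receptor = receptor, lambda_ = lambda_, mu = mu,
                 alpha_ = alpha_, tau_plus = tau_plus, tau_minus = tau_minus,
                 w0 = w0), class = "embsnn_syn")
}

#' Connect two populations
#'
#' Creates synapses according to a connectivity rule. Connections onto a
#' `spike_recorder` register the source population with the recorder;
#' connections from a `poisson_generator` are realized as independent Poisson
#' processes per connection at delivery time.
#'
#' @param kernel kernel object.
#' @param pre,post population handles.
#' @param rule a rule from [conn_all_to_all()] and friends.
#' @param syn a synapse spec from [syn_static()] or [syn_stdp()].
#' @return the exact number of connections created (invisibly a scalar).
#' @export
connect <- function(kernel, pre, post, rule = conn_all_to_all(),
                    syn = syn_static()) {
  stopifnot(inherits(kernel, "embsnn_kernel"),
            inherits(rule, "embsnn_rule"), inherits(syn, "embsnn_syn"))
  pre_p <- kernel$pops[[pre$pop]]
  post_p <- kernel$pops[[post$pop]]
  if (post_p$model == "spike_recorder") {
    post_p$sources <- union(post_p$sources, pre_p$id)
    pre_p$rec_ids <- union(pre_p$rec_ids, post_p$id)
    return(pre_p$count)
  }
  if (!is_dynamic(post_p$model)) {
    stop("cannot connect onto a ", post_p$model, call. = FALSE)
  }
  if (syn$delay < kernel$min_delay - 1e-12) {
    stop("delay ", syn$delay, " below min_delay ", kernel$min_delay,
         call. = FALSE)
  }
  dsteps <- syn$delay / kernel$res
  if (abs(dsteps - round(dsteps)) > 1e-9) {
    stop("delay must be a multiple of the resolution", call. = FALSE)
  }
  dsteps <- as.integer(round(dsteps))
  kernel$n_connect_calls <- kernel$n_connect_calls + 1L
  edges <- instantiate_rule(kernel, pre_p, post_p, rule)
  n_syn <- length(edges$pre_idx)
  proj <- new.env(parent = emptyenv())
  proj$id <- length(kernel$projections) + 1L
  proj$pre <- pre_p$id
  proj$post <- post_p$id
  proj$rule <- rule
  proj$syn <- syn
  proj$delay_steps <- dsteps
  proj$pre_idx <- edges$pre_idx
  proj$post_idx <- edges$post_idx
  proj$n_syn <- n_syn
  proj$weight <- rep(syn$weight, length.out = n_syn)
  proj$uniform_w <- if (syn$type == "static") syn$weight else NA_real_
  proj$plastic <- syn$type == "stdp"
  proj$is_poisson <- pre_p$model == "poisson_generator"
  proj$receptor_col <- if (post_p$model == "lif_conductance") {
    m <- match(syn$receptor, names(post_p$par$receptors))
    if (is.na(m)) stop("target has no receptor ", syn$receptor,
                       call. = FALSE)
    m
  } else 1L
  kernel$projections[[proj$id]] <- proj
  pre_p$out_projs <- c(pre_p$out_projs, proj$id)
  if (proj$plastic) enable_traces(kernel, pre_p, post_p)
  kernel$dirty <- TRUE
  n_syn
}

enable_traces <- function(kernel, pre_p, post_p) {
  for (p in list(pre_p, post_p)) {
    if (!p$has_traces) {
      p$has_traces <- TRUE
      p$Kplus <- numeric(p$count)
      p$Kminus <- numeric(p$count)
    }
  }
}

instantiate_rule <- function(kernel, pre_p, post_p, rule) {
  n_pre <- pre_p$count
  n_post <- post_p$count
  switch(rule$rule,
    all_to_all = list(pre_idx = rep(seq_len(n_pre), times = n_post),
                      post_idx = rep(seq_len(n_post), each = n_pre)),
    one_to_one = {
      if (n_pre != n_post) {
        stop("one_to_one requires equal population sizes (",
             n_pre, " vs ", n_post, ")", call. = FALSE)
      }
      list(pre_idx = seq_len(n_pre), post_idx = seq_len(n_post))
    },
    fixed_indegree = {
      k <- rule$k
      if (!rule$allow_multapses && k > n_pre) {
        stop("indegree exceeds pre size without multapses", call. = FALSE)
      }
      pre_idx <- integer(n_post * k)
      cc <- kernel$n_connect_calls
      for (j in seq_len(n_post)) {
        gid <- post_p$first_id + j - 1L
        draws <- with_stream(kernel$seed, "connect", gid, cc, {
          if (rule$allow_multapses) {
            sample.int(n_pre, k, replace = TRUE)
          } else {
            sample.int(n_pre, k, replace = FALSE)
          }
        })
        pre_idx[((j - 1L) * k + 1L):(j * k)] <- draws
      }
      list(pre_idx = pre_idx, post_idx = rep(seq_len(n_post), each = k))
    },
    pairwise_gaussian = {
      if (is.null(pre_p$positions) || is.null(post_p$positions)) {
        stop("pairwise_gaussian requires positions on both populations",
             call. = FALSE)
      }
      px <- pre_p$positions[, 1]; py <- pre_p$positions[, 2]
      cc <- kernel$n_connect_calls
      pre_l <- vector("list", n_post)
      post_l <- vector("list", n_post)
      for (j in seq_len(n_post)) {
        gid <- post_p$first_id + j - 1L
        d2 <- (px - post_p$positions[j, 1])^2 +
          (py - post_p$positions[j, 2])^2
        pconn <- rule$p0 * exp(-d2 / (2 * rule$sigma^2))
        hit <- with_stream(kernel$seed, "connect", gid, cc,
                           stats::runif(n_pre) < pconn)
        if (identical(pre_p$id, post_p$id)) hit[j] <- FALSE # no autapses
        sel <- which(hit)
        pre_l[[j]] <- sel
        post_l[[j]] <- rep.int(j, length(sel))
      }
      list(pre_idx = unlist(pre_l, use.names = FALSE),
           post_idx = unlist(post_l, use.names = FALSE))
    },
    stop("unknown rule: ", rule$rule, call. = FALSE)
  )
}

#' Incoming synapse counts per neuron
#'
#' Counts instantiated synapses (excluding device drives if
#' `recurrent_only`) per post neuron of a population.
#'
#' @param kernel kernel object.
#' @param pop population handle.
#' @param recurrent_only exclude projections whose source is a device.
#' @return integer vector of indegrees, one per neuron.
#' @export
indegree <- function(kernel, pop, recurrent_only = TRUE) {
  p <- kernel$pops[[pop$pop]]
  deg <- integer(p$count)
  for (proj in kernel$projections) {
    if (proj$post != p$id) next
    if (recurrent_only && proj$is_poisson) next
    deg <- deg + tabulate(proj$post_idx, nbins = p$count)
  }
  deg
}
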