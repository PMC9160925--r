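# Multi-region CBCT rodent brain builder: packaged region composition,
# exact dry-run census, uniform 2D placement, distance-dependent Gaussian
# wiring, ten topographic inter-regional pathways over parrot interfaces,
# per-population bias currents and the calibrated Pons (mossy fiber) drive.

#' Load the packaged CBCT configuration
#'
#' Reads the packaged region-composition table, the pathway/bias parameter
#' set and the calibrated drive. The per-population breakdown below region
#' level and all pathway parameters are synthetic packaged defaults (the
#' reference breakdown is unpublished); regional totals, layer and type
#' counts are exact.
#'
#' @param composition,connectivity,calibration optional paths overriding
#'   the packaged files.
#' @return configuration list with `rows` (one population per sheet),
#'   `connectivity` and `calibration`.
#' @export
cbct_default_config <- function(
    composition = system.file("extdata", "cbct_composition.yaml",
                              package = "embsnn"),
    connectivity = system.file("extdata", "cbct_connectivity.yaml",
                               package = "embsnn"),
    calibration = system.file("extdata", "cbct_calibration.yaml",
                              package = "embsnn")) {
  comp <- yaml::read_yaml(composition)
  rows <- list()
  for (rg in names(comp$regions)) {
    reg <- comp$regions[[rg]]
    for (pp in reg$populations) {
      sheets <- pp$sheets %||% 1L
      for (s in seq_len(sheets)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, kind = reg$kind, layer = pp$layer, type = pp$type,
          sheet = s, count = pp$count, ei = pp$ei,
          model = pp$model %||% "lif_conductance",
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  list(extent_mm = comp$meta$extent_mm,
       rows = rows,
       connectivity = yaml::read_yaml(connectivity),
       calibration = yaml::read_yaml(calibration))
}

scaled_counts <- function(rows, scale) {
  # round-half-even per sheet-level population; totals are sums of parts
  round(rows$count * scale)
}

#' Dry-run census of the CBCT model
#'
#' Pure arithmetic on the configuration: per-region neuron totals, layer
#' and neuron-type counts, and the grand total. At scale 1 the regional
#' totals reproduce the reference summary table exactly; scaled counts are
#' per-population round-half-even, so the total is the sum of rounded
#' parts.
#'
#' @param config from [cbct_default_config()].
#' @param scale shrink factor in (0, 1].
#' @param regions optional character vector restricting to a region subset.
#' @return list with `per_region` data.frame (neurons, layers, types) and
#'   totals `neurons`, `layers`, `types`.
#' @export
census_cbct <- function(config = cbct_default_config(), scale = 1,
                        regions = NULL) {
  stopifnot(scale > 0, scale <= 1)
  rows <- config$rows
  if (!is.null(regions)) rows <- rows[rows$region %in% regions, ]
  n <- scaled_counts(rows, scale)
  per <- do.call(rbind, lapply(split(seq_len(nrow(rows)), rows$region),
    function(ix) {
      data.frame(region = rows$region[ix[1]],
                 neurons = sum(n[ix]),
                 layers = length(unique(rows$layer[ix])),
                 types = length(unique(rows$type[ix])))
    }))
  per <- per[order(match(per$region, unique(rows$region))), ]
  rownames(per) <- NULL
  list(per_region = per,
       neurons = sum(per$neurons),
       layers = sum(per$layers),
       types = sum(per$types))
}

#' Uniform 2D placement on a sheet
#'
#' Draws `n` i.i.d. uniform positions on `[0, extent]^2` from the
#' population's private stream, so placement is independent of worker
#' count and build order.
#'
#' @param n number of neurons.
#' @param extent_mm sheet edge length, mm.
#' @param seed master seed.
#' @param stream_id population stream identifier (e.g. first gid).
#' @return n x 2 matrix of (x, y) in mm.
#' @export
place_neurons_2d <- function(n, extent_mm, seed = 1, stream_id = 0) {
  stopifnot(n >= 0, extent_mm > 0)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  xy <- with_stream(seed, "positions", stream_id, 0,
                    stats::runif(2 * n, 0, extent_mm))
  matrix(xy, n, 2)
}

#' Distance-dependent Gaussian connection
#'
#' Connects each ordered (pre, post) pair independently with probability
#' `p0 * exp(-d^2 / (2 sigma^2))`, `d` being the in-plane distance between
#' sheet positions; autapses are excluded when pre and post are the same
#' population. Sampling is keyed to each post neuron's private stream.
#'
#' @param kernel kernel object.
#' @param pre,post population handles with positions.
#' @param p0 peak probability in (0, 1].
#' @param sigma_mm Gaussian width, mm.
#' @param syn synapse spec.
#' @return number of connections created.
#' @export
gaussian_connect <- function(kernel, pre, post, p0, sigma_mm,
                             syn = syn_static()) {
  connect(kernel, pre, post, conn_pairwise_gaussian(p0, sigma_mm), syn)
}

match_sel <- function(rows, sel) {
  keep <- rep(TRUE, nrow(rows))
  for (f in intersect(names(sel), c("region", "layer", "type", "ei"))) {
    alts <- strsplit(sel[[f]], "|", fixed = TRUE)[[1]]
    keep <- keep & rows[[f]] %in% alts
  }
  which(keep)
}

#' Build the CBCT network (or a region subset)
#'
#' Creates every population of the scaled composition with uniform sheet
#' positions, draws per-neuron bias currents, wires all intra-regional
#' Gaussian pathways and the ten inter-regional topographic pathways
#' (through parrot interface sheets where configured), attaches the
#' calibrated Poisson drive to the Pons mossy fibers, and connects one
#' spike recorder to every population. Parrot interfaces and devices are
#' counted separately from the neuron census.
#'
#' @param config from [cbct_default_config()].
#' @param scale shrink factor in (0, 1].
#' @param kernel kernel object.
#' @param regions optional region subset, e.g. `c("M1")` or
#'   `c("CB_M1")`; inter-regional pathways are wired only when both ends
#'   are present.
#' @return list with `kernel`, `rows` (composition with realized counts and
#'   handles), `pathways` (named inter-regional connection counts),
#'   `recorder`, `drives`, `census` (realized, matching [census_cbct()])
#'   and `device_census`.
#' @export
build_cbct <- function(config = cbct_default_config(), scale = 0.01,
                       kernel = new_kernel(resolution = 0.1),
                       regions = NULL) {
  stopifnot(scale > 0, scale <= 1)
  rows <- config$rows
  if (!is.null(regions)) rows <- rows[rows$region %in% regions, ]
  rows$n <- scaled_counts(rows, scale)
  rows <- rows[rows$n > 0, ]
  rownames(rows) <- NULL
  extent <- config$extent_mm %||% 1.0
  handles <- vector("list", nrow(rows))
  bias_cfg <- config$connectivity$bias_currents
  for (i in seq_len(nrow(rows))) {
    n <- rows$n[i]
    model <- rows$model[i]
    pos <- place_neurons_2d(n, extent, kernel$seed, kernel$next_gid)
    params <- list()
    if (model == "lif_conductance") {
      for (b in bias_cfg) {
        if (i %in% match_sel(rows, b$selector)) {
          params$I_bias <- with_stream(kernel$seed, "bias", kernel$next_gid,
                                       0, stats::rnorm(n, b$mean, b$sd))
          break
        }
      }
    }
    handles[[i]] <- create(kernel, model, n, params, positions = pos)
  }
  rows$handle <- I(handles)
  syn_for <- function(rec, w = rec$weight) {
    syn_static(weight = w, delay = rec$delay, receptor = rec$receptor)
  }
  # intra-regional Gaussian wiring
  for (rec in config$connectivity$intra) {
    regs <- strsplit(rec$region, "|", fixed = TRUE)[[1]]
    for (rg in intersect(regs, unique(rows$region))) {
      sub <- which(rows$region == rg)
      pre_ix <- intersect(sub, match_sel(rows, rec$pre %||% list()))
      post_ix <- intersect(sub, match_sel(rows, rec$post %||% list()))
      for (i in pre_ix) for (j in post_ix) {
        if (isTRUE(rec$same_layer) && rows$layer[i] != rows$layer[j]) next
        if (rows$model[j] == "parrot") next
        gaussian_connect(kernel, handles[[i]], handles[[j]],
                         rec$p0, rec$sigma, syn_for(rec))
      }
    }
  }
  # inter-regional topographic pathways (parrot interfaces where flagged)
  pathways <- list()
  relays <- list()
  for (rec in config$connectivity$inter) {
    pre_ix <- match_sel(rows, rec$pre)
    post_ix <- match_sel(rows, rec$post)
    if (!length(pre_ix) || !length(post_ix)) next
    total <- 0
    for (i in pre_ix) {
      src <- handles[[i]]
      if (isTRUE(rec$relay)) {
        relay <- create(kernel, "parrot", rows$n[i],
                        positions = kernel$pops[[src$pop]]$positions)
        connect(kernel, src, relay, conn_one_to_one(),
                syn_static(weight = 1, delay = 1.0))
        relays[[length(relays) + 1L]] <- relay
        src <- relay
      }
      for (j in post_ix) {
        cnt <- if (rows$model[j] == "parrot") {
          gaussian_connect(kernel, src, handles[[j]], rec$p0, rec$sigma,
                           syn_static(weight = 1, delay = rec$delay))
        } else {
          gaussian_connect(kernel, src, handles[[j]], rec$p0, rec$sigma,
                           syn_for(rec))
        }
        total <- total + cnt
      }
    }
    pathways[[rec$pathway]] <- (pathways[[rec$pathway]] %||% 0) + total
  }
  # calibrated Pons drive: one generator per cerebellar module, one
  # independent Poisson realization per mossy fiber
  drives <- list()
  cal <- config$calibration$pons_drive
  mf_ix <- which(rows$type == "MF")
  for (i in mf_ix) {
    gen <- create(kernel, "poisson_generator", 1,
                  list(rate = cal$drive_rate_hz))
    connect(kernel, gen, handles[[i]], conn_all_to_all(),
            syn_static(weight = 1, delay = cal$delay_ms))
    drives[[rows$region[i]]] <- gen
  }
  recorder <- create(kernel, "spike_recorder", 1)
  for (h in handles) connect(kernel, h, recorder)
  per <- do.call(rbind, lapply(split(seq_len(nrow(rows)), rows$region),
    function(ix) data.frame(region = rows$region[ix[1]],
                            neurons = sum(rows$n[ix]))))
  list(kernel = kernel, rows = rows, pathways = pathways,
       recorder = recorder, drives = drives,
       census = list(per_region = per, neurons = sum(rows$n)),
       device_census = list(parrot_relays = length(relays),
                            relay_neurons = sum(vapply(relays,
                                                       function(r) r$count,
                                                       0)),
                            generators = length(drives),
                            recorders = 1L))
}

#' Mean population firing rate from a recorder
#'
#' @param kernel kernel object.
#' @param recorder spike recorder handle.
#' @param pop population handle.
#' @param t_from,t_to measurement window, ms.
#' @return mean rate in Hz (spikes per neuron per second).
#' @export
pop_rate <- function(kernel, recorder, pop, t_from = 0,
                     t_to = kernel_time(kernel)) {
  ev <- get_spikes(kernel, recorder, t_from, t_to)
  gids <- pop_gids(pop)
  nev <- sum(ev$gid >= gids[1] & ev$gid <= gids[length(gids)])
  nev / pop$count / ((t_to - t_from) / 1000)
}

#' Calibrate a drive rate against a simulated firing-rate target
#'
#' Secant search with bisection fallback over a monotone rate-versus-drive
#' response. `rate_fn(drive_rate)` must run the probe simulation and return
#' the measured population rate in Hz.
#'
#' @param rate_fn function mapping drive rate (Hz) to measured rate (Hz).
#' @param target_rate_hz target rate (> 0).
#' @param tol_hz convergence tolerance (> 0; a zero tolerance cannot
#'   terminate against a stochastic probe and raises a convergence error).
#' @param initial_rate starting drive rate.
#' @param max_iter iteration budget.
#' @return list with `rate` (calibrated drive), `measured`, `iterations`,
#'   and the evaluation `history`.
#' @export
calibrate_resting_input <- function(rate_fn, target_rate_hz, tol_hz = 0.5,
                                    initial_rate = target_rate_hz,
                                    max_iter = 20) {
  stopifnot(target_rate_hz > 0, max_iter >= 1)
  if (tol_hz <= 0) {
    stop("tolerance must be > 0: a zero tolerance cannot converge against ",
         "a stochastic probe", call. = FALSE)
  }
  history <- data.frame(drive = numeric(0), rate = numeric(0))
  evals <- function(r) {
    m <- rate_fn(r)
    history[nrow(history) + 1L, ] <<- c(r, m)
    m
  }
  r0 <- initial_rate
  f0 <- evals(r0) - target_rate_hz
  if (abs(f0) <= tol_hz) {
    return(list(rate = r0, measured = f0 + target_rate_hz, iterations = 0L,
                history = history))
  }
  r1 <- if (f0 > 0) r0 / 2 else r0 * 2
  for (it in seq_len(max_iter)) {
    f1 <- evals(r1) - target_rate_hz
    if (abs(f1) <= tol_hz) {
      return(list(rate = r1, measured = f1 + target_rate_hz,
                  iterations = it, history = history))
    }
    if (f1 == f0) { # flat response: expand the bracket
      r2 <- r1 * 2
    } else {
      r2 <- r1 - f1 * (r1 - r0) / (f1 - f0)
      if (!is.finite(r2) || r2 <= 0) r2 <- (r0 + r1) / 2
    }
    r0 <- r1; f0 <- f1; r1 <- r2
  }
  stop("drive calibration did not converge after ", max_iter,
       " iterations; last evaluations:\n",
       paste(utils::capture.output(print(utils::tail(history, 5))),
             collapse = "\n"), call. = FALSE)
}
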