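# Benchmark harness: the scaling procedure over worker counts (network
# build, closed-loop run, profiling, metrics) and the embodied stepwise
# protocol coupling the motor-cortex readout to the joystick rig.

#' Define a benchmark plan
#'
#' @param kind one of `"brunel"`, `"cbct"`, `"cbct_m1_only"`.
#' @param scale network scale (desk defaults: brunel 0.01-0.1, cbct
#'   0.005-0.02).
#' @param workers strictly increasing worker counts (default powers of 2).
#' @param repetitions number of repetitions (>= 1).
#' @param duration_ms simulated time per cell (default 1000 = 50 exchange
#'   windows of 20 ms).
#' @param exchange_ms CLE exchange interval, ms.
#' @param seed master seed, identical across worker counts so spike output
#'   is comparable cell to cell.
#' @return plan of class `embsnn_plan`.
#' @export
benchmark_plan <- function(kind = "brunel", scale = 0.01, workers = c(1, 2, 4),
                           repetitions = 1, duration_ms = 1000,
                           exchange_ms = 20, seed = 1) {
  stopifnot(kind %in% c("brunel", "cbct", "cbct_m1_only"),
            all(diff(workers) > 0), repetitions >= 1, duration_ms > 0)
  structure(list(kind = kind, scale = scale, workers = as.integer(workers),
                 repetitions = as.integer(repetitions),
                 duration_ms = duration_ms, exchange_ms = exchange_ms,
                 seed = seed),
            class = "embsnn_plan")
}

build_for_plan <- function(plan, srv) {
  k <- srv$kernel
  switch(plan$kind,
    brunel = {
      net <- build_brunel(plan$scale, kernel = k)
      list(recorder = net$recorder, net = net)
    },
    cbct = {
      net <- build_cbct(scale = plan$scale, kernel = k)
      list(recorder = net$recorder, net = net)
    },
    cbct_m1_only = {
      net <- build_cbct(scale = plan$scale, kernel = k, regions = "M1")
      list(recorder = net$recorder, net = net)
    })
}

#' Run a benchmark plan
#'
#' For every (repetition, worker count) cell: start a server with that many
#' logical workers, build the network (timed), run the closed-loop engine
#' for the plan duration against the default plant, collect the step
#' profile and derived metrics, and tear the server down. Seeds are
#' identical across worker counts, so recorded spikes must match cell to
#' cell. A failing cell is recorded and the grid continues.
#'
#' @param plan from [benchmark_plan()].
#' @return list with `results` (one row per cell: build_s,
#'   last_sim_step_s, runtime_s, rtf, step_ratio, node_hours, error) and
#'   `spikes` (per-cell recorded spike frames).
#' @export
run_benchmark <- function(plan) {
  grid <- expand.grid(rep = seq_len(plan$repetitions),
                      n_workers = plan$workers)
  results <- vector("list", nrow(grid))
  spikes <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    nw <- grid$n_workers[ci]
    cell <- tryCatch({
      srv <- start_server(n_workers = nw, seed = plan$seed)
      tb0 <- wall_now()
      built <- build_for_plan(plan, srv)
      build_s <- wall_now() - tb0
      plant_cfg <- build_default_forelimb()
      plant_state <- plant_init(plant_cfg)
      eng <- cle_engine(
        brain = list(step = function(ms) {
          server_call(srv, "Simulate", list(duration = ms))
        }, clock = function() kernel_time(srv$kernel)),
        plant = list(step = function(ms) {
          plant_state <<- plant_advance(plant_cfg, plant_state,
                                        numeric(8), ms)
        }, clock = function() NA),
        transfers = list(),
        exchange_interval = plan$exchange_ms,
        total_duration = plan$duration_ms)
      t0 <- wall_now()
      prof <- cle_run(eng)
      runtime_s <- wall_now() - t0
      n_nodes <- ceiling(nw / 2) + 1 # worker pairs per node, plus control
      spikes[[ci]] <- server_call(srv, "GetSpikes",
                                  list(recorder = built$recorder))
      stop_server(srv)
      data.frame(rep = grid$rep[ci], n_workers = nw, build_s = build_s,
                 last_sim_step_s = prof$brain_s[nrow(prof)],
                 runtime_s = runtime_s,
                 rtf = real_time_factor(prof, plan$exchange_ms),
                 step_ratio = step_ratio(prof),
                 node_hours = node_hours(runtime_s, n_nodes),
                 error = NA_character_)
    }, error = function(e) {
      # never leave an orphan control plane behind a failed cell
      if (!is.null(.srv_state$active) && isTRUE(.srv_state$active$running)) {
        stop_server(.srv_state$active)
      }
      data.frame(rep = grid$rep[ci], n_workers = nw, build_s = NA,
                 last_sim_step_s = NA, runtime_s = NA, rtf = NA,
                 step_ratio = NA, node_hours = NA,
                 error = conditionMessage(e))
    })
    results[[ci]] <- cell
  }
  list(results = do.call(rbind, results), spikes = spikes)
}

#' Run the embodied stepwise protocol
#'
#' The benchmark's brain-to-body experiment: a base activation is sent to
#' all 8 muscles for the first 5 exchange steps; every step sets all spike
#' sources to rate 0; from step 25 the source feeding the motor-cortex
#' elongated neurogliaform cells (ENGC) is fed 5000.0 Hz; from step 6
#' onward the clipped ENGC readout continuously drives its three bound
#' muscles, and a status line reports the input state.
#'
#' @param net a [build_cbct()] result containing M1.
#' @param n_steps number of exchange steps (default 50).
#' @param exchange_ms exchange interval, ms (default 20).
#' @param base_activation excitation sent to all muscles during the first
#'   5 steps (default 0.2).
#' @param sink_muscles the three muscle indices driven by the ENGC readout.
#' @param verbose print the status line per step.
#' @return list with `log` (per-step trajectory and activation),
#'   `profile` (CLE step profile), the `sink` and `sources`.
#' @export
run_embodied_protocol <- function(net, n_steps = 50, exchange_ms = 20,
                                  base_activation = 0.2,
                                  sink_muscles = c(1, 3, 5),
                                  verbose = FALSE) {
  kernel <- net$kernel
  rows <- net$rows
  engc_i <- which(rows$region == "M1" & rows$type == "L1_ENGC")
  if (!length(engc_i)) stop("network lacks the M1 ENGC population",
                            call. = FALSE)
  engc <- rows$handle[[engc_i]]
  sink <- make_spike_sink(kernel, engc, muscles = sink_muscles)
  src_rows <- c(engc_i,
                which(rows$region == "M1" & rows$type == "L23_IT"),
                which(rows$region == "M1" & rows$type == "L5A_IT"))
  src_rows <- src_rows[!is.na(src_rows)]
  sources <- lapply(src_rows, function(i) {
    make_spike_source(kernel, rows$handle[[i]], rate = 0, weight = 1,
                      receptor = "AMPA")
  })
  names(sources) <- rows$type[src_rows]
  plant_cfg <- build_default_forelimb()
  plant_state <- plant_init(plant_cfg)
  u <- rep(base_activation, 8)
  engc_rate <- 0
  log <- vector("list", n_steps)
  eng <- cle_engine(
    brain = list(step = function(ms) simulate(kernel, ms),
                 clock = function() kernel_time(kernel)),
    plant = list(step = function(ms) {
      plant_state <<- plant_advance(plant_cfg, plant_state, u, ms)
    }, clock = function() NA),
    transfers = list(function(e) {
      k <- e$step_no + 1L # step just completed
      act <- read_activation(kernel, sink)
      # every iteration all sources are (re)set; the ENGC source switches
      # to 5000.0 Hz once step 25 is reached
      next_rate <- if (k + 1 >= 25) 5000.0 else 0
      for (s in sources) set_rate(kernel, s, 0)
      set_rate(kernel, sources[[1]], next_rate)
      u <<- if (k + 1 <= 5) {
        rep(base_activation, 8)
      } else {
        uu <- numeric(8)
        uu[sink_muscles] <- act
        uu
      }
      ja <- joystick_angles(plant_state)
      status <- if (k >= 6) {
        sprintf("step %d: ENGC input rate %.1f Hz, readout activation %.3f",
                k, engc_rate, act)
      } else {
        sprintf("step %d: base activation %.2f", k, base_activation)
      }
      if (verbose) message(status)
      log[[k]] <<- data.frame(step = k, t_ms = k * exchange_ms,
                              activation = act, joy_fb = ja[["fb"]],
                              joy_lm = ja[["lm"]], engc_rate = engc_rate,
                              status = status)
      engc_rate <<- next_rate
    }),
    exchange_interval = exchange_ms,
    total_duration = n_steps * exchange_ms)
  prof <- cle_run(eng)
  list(log = do.call(rbind, log), profile = prof, sink = sink,
       sources = sources, plant_state = plant_state)
}
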