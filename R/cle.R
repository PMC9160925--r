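# Closed-Loop Engine: advances brain and plant in lockstep exchange windows,
# runs transfer functions after both complete, and profiles each component.

#' Create a closed-loop engine
#'
#' Per step, the brain and the plant each advance one exchange interval —
#' both must complete before any transfer function runs (the orchestration
#' contract; execution here is sequential with per-component wall-time
#' measurement). The profile keeps every step including the first; derived
#' metrics exclude the first step, which carries initialization cost.
#'
#' @param brain list with `step = function(ms)` and `clock = function()`
#'   returning the brain time in ms.
#' @param plant list with `step = function(ms)` and `clock = function()`.
#' @param transfers list of functions `function(engine)` run after each
#'   step, in order.
#' @param exchange_interval data-exchange window, ms (default 20).
#' @param total_duration total simulated time, ms.
#' @return engine of class `embsnn_cle`.
#' @export
cle_engine <- function(brain, plant, transfers = list(),
                       exchange_interval = 20, total_duration = 1000) {
  stopifnot(exchange_interval > 0, total_duration >= exchange_interval)
  e <- new.env(parent = emptyenv())
  e$brain <- brain
  e$plant <- plant
  e$transfers <- transfers
  e$interval <- exchange_interval
  e$total <- total_duration
  e$n_steps_max <- as.integer(round(total_duration / exchange_interval))
  e$profile <- data.frame(step = integer(0), brain_s = numeric(0),
                          robot_s = numeric(0), tf_s = numeric(0),
                          wall_s = numeric(0))
  e$step_no <- 0L
  class(e) <- "embsnn_cle"
  e
}

wall_now <- function() proc.time()[["elapsed"]]

#' Advance the engine by one exchange window
#'
#' @param e engine from [cle_engine()].
#' @return invisibly, the appended profile row (brain, robot, transfer and
#'   total wall seconds).
#' @export
cle_step <- function(e) {
  if (e$step_no >= e$n_steps_max) {
    stop("total_duration reached after ", e$step_no, " steps",
         call. = FALSE)
  }
  t0 <- wall_now()
  e$brain$step(e$interval)
  t1 <- wall_now()
  e$plant$step(e$interval)
  t2 <- wall_now()
  for (tf in e$transfers) tf(e)
  t3 <- wall_now()
  e$step_no <- e$step_no + 1L
  row <- data.frame(step = e$step_no, brain_s = t1 - t0,
                    robot_s = t2 - t1, tf_s = t3 - t2, wall_s = t3 - t0)
  e$profile <- rbind(e$profile, row)
  invisible(row)
}

#' Run the engine to completion
#' @param e engine.
#' @return the full step profile data.frame.
#' @export
cle_run <- function(e) {
  while (e$step_no < e$n_steps_max) cle_step(e)
  e$profile
}

#' Real-time factor of a profile
#'
#' Quotient of simulated step time to mean real step time, excluding the
#' first step (which carries initialization procedures).
#'
#' @param profile data.frame with a `wall_s` column (or numeric vector of
#'   wall times in s).
#' @param exchange_interval window length, ms.
#' @param first_step_excluded drop the first step from the mean
#'   (default TRUE).
#' @return dimensionless real-time factor.
#' @export
real_time_factor <- function(profile, exchange_interval,
                             first_step_excluded = TRUE) {
  wall <- if (is.data.frame(profile)) profile$wall_s else profile
  if (length(wall) < 2) stop("need at least 2 recorded steps", call. = FALSE)
  if (first_step_excluded) wall <- wall[-1]
  (exchange_interval / 1000) / mean(wall)
}

#' Node-hours of a run
#'
#' Product of the experiment runtime and the number of utilized compute
#' nodes.
#'
#' @param runtime_s wall runtime in seconds.
#' @param n_nodes number of nodes (>= 1).
#' @return node-hours.
#' @export
node_hours <- function(runtime_s, n_nodes) {
  stopifnot(runtime_s >= 0, n_nodes >= 1)
  runtime_s / 3600 * n_nodes
}

#' Brain-to-body step-time ratio
#'
#' Ratio of mean brain step time to mean robot (plant) step time, first step
#' excluded. Equal means — the most efficient configuration, as both run in
#' parallel — give 1. Zero robot time yields NA (undefined), reported as
#' such rather than an error.
#'
#' @param profile data.frame with `brain_s` and `robot_s` columns.
#' @param first_step_excluded drop the first step (default TRUE).
#' @return dimensionless ratio, or NA if undefined.
#' @export
step_ratio <- function(profile, first_step_excluded = TRUE) {
  if (nrow(profile) < 2) stop("need at least 2 recorded steps",
                              call. = FALSE)
  p <- if (first_step_excluded) profile[-1, ] else profile
  mr <- mean(p$robot_s)
  if (mr == 0) return(NA_real_)
  mean(p$brain_s) / mr
}

#' Write / read a CLE metrics file
#'
#' CSV with columns step, brain_s, robot_s, tf_s, wall_s; round-trips
#' losslessly (full double precision).
#'
#' @param profile step profile data.frame.
#' @param path CSV path.
#' @export
write_metrics <- function(profile, path) {
  prof <- profile
  for (cn in c("brain_s", "robot_s", "tf_s", "wall_s")) {
    prof[[cn]] <- sprintf("%.17g", prof[[cn]])
  }
  utils::write.csv(prof, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  d <- utils::read.csv(path)
  d$step <- as.integer(d$step)
  for (cn in c("brain_s", "robot_s", "tf_s", "wall_s")) {
    d[[cn]] <- as.numeric(d[[cn]])
  }
  d
}

#' Summarize a profile into the benchmark metrics
#'
#' @param profile step profile.
#' @param exchange_interval window length, ms.
#' @param runtime_s total experiment runtime, s.
#' @param n_nodes nodes used.
#' @return list with rtf, step_ratio, runtime_s, node_hours.
#' @export
summarize_profile <- function(profile, exchange_interval,
                              runtime_s = sum(profile$wall_s),
                              n_nodes = 1) {
  list(rtf = real_time_factor(profile, exchange_interval),
       step_ratio = step_ratio(profile),
       runtime_s = runtime_s,
       node_hours = node_hours(runtime_s, n_nodes))
}
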