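# Readers and writers: GDF-like spike files, network descriptions,
# CLE metrics.

#' Write spikes in GDF-like format
#'
#' Two whitespace-separated columns (gid, time in ms), one event per line,
#' sorted by (time, gid).
#'
#' @param spikes data.frame with columns `gid`, `t` (as from [get_spikes()]).
#' @param path output file.
#' @export
write_gdf <- function(spikes, path) {
  o <- order(spikes$t, spikes$gid)
  lines <- sprintf("%d\t%.3f", as.integer(spikes$gid[o]), spikes$t[o])
  writeLines(lines, path)
  invisible(path)
}

#' Read a GDF-like spike file
#' @param path input file.
#' @return data.frame with columns `gid`, `t`, sorted by (t, gid).
#' @export
read_gdf <- function(path) {
  if (file.size(path) == 0) return(data.frame(gid = integer(0),
                                              t = numeric(0)))
  d <- utils::read.table(path, col.names = c("gid", "t"))
  o <- order(d$t, d$gid)
  data.frame(gid = as.integer(d$gid[o]), t = d$t[o])
}

#' Dump a network description
#'
#' Serializes kernel configuration, populations (model, size, parameters,
#' positions) and connectivity as declarative rules — not instantiated
#' synapse lists — to a YAML file. [load_network()] rebuilds an equivalent
#' kernel; with the same master seed the rebuilt network is identical.
#'
#' @param kernel kernel object.
#' @param path output YAML file.
#' @export
dump_network <- function(kernel, path) {
  pops <- lapply(kernel$pops, function(p) {
    x <- list(model = p$model, n = p$count, params = strip_defaults(p))
    if (!is.null(p$positions)) {
      x$positions <- list(x = as.numeric(p$positions[, 1]),
                          y = as.numeric(p$positions[, 2]))
    }
    x
  })
  projs <- lapply(kernel$projections, function(pr) {
    list(pre = pr$pre, post = pr$post,
         rule = unclass(pr$rule), syn = unclass(pr$syn))
  })
  recordings <- list()
  for (p in kernel$pops) {
    if (p$model == "spike_recorder" && length(p$sources)) {
      recordings[[length(recordings) + 1L]] <-
        list(recorder = p$id, sources = as.integer(p$sources))
    }
  }
  doc <- list(kernel = list(resolution = kernel$res, seed = kernel$seed,
                            n_workers = kernel$n_workers,
                            min_delay = kernel$min_delay),
              populations = pops, projections = projs,
              recordings = recordings)
  yaml::write_yaml(doc, path)
  invisible(path)
}

strip_defaults <- function(p) {
  par <- p$par
  # keep records YAML-friendly: drop vector currents down to lists
  rapply(par, as.vector, how = "replace")
}

#' Load a network description
#'
#' @param path YAML file written by [dump_network()].
#' @return a list with the rebuilt `kernel` and the population handles.
#' @export
load_network <- function(path) {
  doc <- yaml::read_yaml(path)
  kc <- doc$kernel
  kernel <- new_kernel(resolution = kc$resolution, seed = kc$seed,
                       n_workers = kc$n_workers, min_delay = kc$min_delay)
  handles <- vector("list", length(doc$populations))
  for (i in seq_along(doc$populations)) {
    pd <- doc$populations[[i]]
    pos <- if (!is.null(pd$positions)) {
      cbind(pd$positions$x, pd$positions$y)
    } else NULL
    params <- pd$params
    if (!is.null(params$receptors)) {
      params$receptors <- lapply(params$receptors, function(r) {
        list(E_rev = r$E_rev, tau = r$tau)
      })
    }
    handles[[i]] <- create(kernel, pd$model, pd$n, params %||% list(),
                           positions = pos)
  }
  for (pr in doc$projections) {
    rule <- do.call(switch(pr$rule$rule,
                           all_to_all = conn_all_to_all,
                           one_to_one = conn_one_to_one,
                           fixed_indegree = conn_fixed_indegree,
                           pairwise_gaussian = function(p0, sigma, ...) {
                             conn_pairwise_gaussian(p0, sigma)
                           }),
                    pr$rule[setdiff(names(pr$rule), "rule")])
    sd <- pr$syn
    syn <- if (identical(sd$type, "stdp")) {
      do.call(syn_stdp, sd[setdiff(names(sd), "type")])
    } else {
      do.call(syn_static, sd[setdiff(names(sd), "type")])
    }
    connect(kernel, handles[[pr$pre]], handles[[pr$post]], rule, syn)
  }
  for (rc in doc$recordings) {
    for (s in rc$sources) connect(kernel, handles[[s]], handles[[rc$recorder]])
  }
  list(kernel = kernel, populations = handles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
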