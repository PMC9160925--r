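# Master-worker simulation-control plane.
#
# The master (worker 0) owns the API surface; every call is broadcast to all
# logical workers, each of which answers from its shard view (neurons it
# owns under round-robin assignment), and the per-worker responses are
# combined into a single consistent view. The combination heuristics are an
# explicit per-endpoint registry: identical scalars collapse, additive
# fields (locally created / recorded entities) sum, event lists merge-sort
# by (t, gid), records combine field-wise.

.endpoints <- c("Create", "Connect", "Simulate", "GetKernelStatus",
                "SetStatus", "GetStatus", "GetSpikes")

# field -> combination mode, per endpoint
.combine_registry <- list(
  Create          = list(first_id = "identical", count = "identical",
                         model = "identical", local_count = "sum"),
  Connect         = list(local_count = "sum"),
  Simulate        = list(time_ms = "identical"),
  GetKernelStatus = list(resolution = "identical", time_ms = "identical",
                         seed = "identical", n_workers = "identical",
                         network_size = "identical",
                         num_connections = "identical"),
  SetStatus       = list(ok = "identical"),
  GetStatus       = list(.record = "identical"),
  GetSpikes       = list(.events = "merge")
)

#' Start a simulation-control server
#'
#' Creates one kernel shared by `n_workers` logical workers. The master
#' participates in the simulation as worker 0. Serving the API never
#' advances the clock; only the `Simulate` endpoint does.
#'
#' @param n_workers number of logical workers (>= 1).
#' @param resolution,seed,min_delay kernel configuration, see
#'   [new_kernel()].
#' @return a server handle of class `embsnn_server`.
#' @export
start_server <- function(n_workers = 1L, resolution = 0.1, seed = 1,
                         min_delay = resolution) {
  if (!is.null(.srv_state$active) && isTRUE(.srv_state$active$running)) {
    stop("a server is already running; stop it first", call. = FALSE)
  }
  srv <- new.env(parent = emptyenv())
  srv$kernel <- new_kernel(resolution = resolution, seed = seed,
                           n_workers = n_workers, min_delay = min_delay)
  srv$n_workers <- as.integer(n_workers)
  srv$running <- TRUE
  srv$handles <- list() # population handles by pop id, for payload lookup
  class(srv) <- "embsnn_server"
  .srv_state$active <- srv
  srv
}

# one control plane per process, like one simulation kernel per process
.srv_state <- new.env(parent = emptyenv())

#' Stop a server
#' @param srv server handle.
#' @export
stop_server <- function(srv) {
  srv$running <- FALSE
  invisible(NULL)
}

assert_running <- function(srv) {
  if (!isTRUE(srv$running)) stop("server not running", call. = FALSE)
}

# Shard view: how worker w answers `endpoint` after the shared deterministic
# kernel executed the operation. Ownership is owner_worker(gid, n_workers).
worker_response <- function(srv, w, endpoint, result) {
  k <- srv$kernel
  switch(endpoint,
    Create = {
      pop <- result
      gids <- pop_gids(pop)
      list(first_id = pop$first_id, count = pop$count, model = pop$model,
           local_count = sum(owner_worker(gids, srv$n_workers) == w))
    },
    Connect = {
      post_gids <- result$post_gids
      list(local_count = sum(owner_worker(post_gids, srv$n_workers) == w))
    },
    Simulate = list(time_ms = kernel_time(k)),
    GetKernelStatus = get_kernel_status(k),
    SetStatus = list(ok = TRUE),
    GetStatus = list(.record = result),
    GetSpikes = {
      ev <- result
      keep <- owner_worker(ev$gid, srv$n_workers) == w
      list(.events = ev[keep, , drop = FALSE])
    })
}

#' Combine per-worker responses
#'
#' Identical scalars collapse to the scalar; additive fields sum; event
#' lists merge-sort by (t, gid); records recurse field-wise. Contradictory
#' non-additive values raise a divergence error — never silently masked.
#' Combination is associative over worker order.
#'
#' @param responses list with one response record per worker.
#' @param endpoint endpoint name, selects the field registry.
#' @return combined response; per-worker raw responses are attached as the
#'   `provenance` attribute for audit.
#' @export
combine <- function(responses, endpoint) {
  if (!endpoint %in% .endpoints) {
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  }
  reg <- .combine_registry[[endpoint]]
  fields <- names(responses[[1]])
  out <- list()
  for (f in fields) {
    vals <- lapply(responses, `[[`, f)
    mode <- reg[[f]] %||% "identical"
    out[[f]] <- switch(mode,
      sum = Reduce(`+`, vals),
      merge = {
        ev <- do.call(rbind, vals)
        o <- order(ev$t, ev$gid)
        ev[o, , drop = FALSE]
      },
      identical = {
        first <- vals[[1]]
        same <- vapply(vals, identical, TRUE, y = first)
        if (!all(same)) {
          stop("worker divergence on field '", f, "' of ", endpoint, ": ",
               paste(vapply(vals, function(v) paste(format(v),
                                                    collapse = ","), ""),
                     collapse = " | "), call. = FALSE)
        }
        first
      })
  }
  attr(out, "provenance") <- responses
  out
}

#' Call a server endpoint
#'
#' Broadcasts the command, executes it against the kernel, collects one
#' response per worker and combines them. The combined observable state for
#' any worker count equals the single-worker one.
#'
#' @param srv server handle.
#' @param endpoint one of Create, Connect, Simulate, GetKernelStatus,
#'   SetStatus, GetStatus, GetSpikes.
#' @param payload named list of endpoint arguments. Population references
#'   are handles previously returned by `Create`.
#' @return combined response record.
#' @export
server_call <- function(srv, endpoint, payload = list()) {
  assert_running(srv)
  if (!endpoint %in% .endpoints) {
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  }
  k <- srv$kernel
  result <- switch(endpoint,
    Create = {
      pop <- create(k, payload$model, payload$n, payload$params %||% list(),
                    positions = payload$positions)
      srv$handles[[pop$pop]] <- pop
      pop
    },
    Connect = {
      n <- connect(k, payload$pre, payload$post,
                   payload$rule %||% conn_all_to_all(),
                   payload$syn %||% syn_static())
      post_p <- k$pops[[payload$post$pop]]
      proj <- k$projections[[length(k$projections)]]
      gids <- if (post_p$model == "spike_recorder") {
        pop_gids(payload$pre) # recording happens on the neuron's owner
      } else {
        post_p$first_id + proj$post_idx - 1L
      }
      list(n = n, post_gids = gids)
    },
    Simulate = {
      simulate(k, payload$duration)
      NULL
    },
    GetKernelStatus = NULL,
    SetStatus = {
      set_status(k, payload$pop, payload$params)
      NULL
    },
    GetStatus = get_status(k, payload$pop),
    GetSpikes = get_spikes(k, payload$recorder,
                           payload$t_from %||% 0, payload$t_to %||% Inf))
  responses <- lapply(seq_len(srv$n_workers) - 1L, function(w) {
    worker_response(srv, w, endpoint, result)
  })
  out <- combine(responses, endpoint)
  if (endpoint == "GetSpikes") {
    out <- out$.events
  } else if (endpoint == "GetStatus") {
    out <- out$.record
  }
  out
}

# ---------------------------------------------------------------------------
# HTTP binding. The wire shape mirrors POST /api/<Endpoint> with a JSON
# body. No web-server package is assumed: a minimal HTTP/1.1 handler over
# base sockets is provided for interactive use; the parser and dispatcher
# are plain functions so they are testable without opening sockets.

#' Parse a raw HTTP request
#' @param text the full request (headers + body) as a single string.
#' @return list with `method`, `path` and parsed JSON `body`.
#' @export
parse_http_request <- function(text) {
  parts <- strsplit(text, "\r\n\r\n", fixed = TRUE)[[1]]
  head_lines <- strsplit(parts[1], "\r\n", fixed = TRUE)[[1]]
  req <- strsplit(head_lines[1], " ", fixed = TRUE)[[1]]
  body <- if (length(parts) > 1 && nzchar(parts[2])) {
    jsonlite::fromJSON(parts[2], simplifyVector = TRUE)
  } else {
    list()
  }
  list(method = req[1], path = req[2], body = body)
}

#' Dispatch a parsed HTTP request against a server
#'
#' Maps `POST /api/<Endpoint>` onto [server_call()]. Population references
#' in the JSON body are given as `{"first_id":..,"count":..}` records or as
#' the 1-based population index under `pop`.
#'
#' @param srv server handle.
#' @param req parsed request from [parse_http_request()].
#' @return list with `status` and JSON `body` string.
#' @export
dispatch_http <- function(srv, req) {
  if (!identical(req$method, "POST") || !grepl("^/api/", req$path)) {
    return(list(status = 404L,
                body = jsonlite::toJSON(list(error = "not found"),
                                        auto_unbox = TRUE)))
  }
  endpoint <- sub("^/api/", "", req$path)
  payload <- as.list(req$body)
  for (f in c("pre", "post", "pop", "recorder")) {
    if (!is.null(payload[[f]]) && is.numeric(payload[[f]])) {
      payload[[f]] <- srv$handles[[payload[[f]]]]
    }
  }
  if (!is.null(payload$rule) && is.list(payload$rule)) {
    payload$rule <- structure(payload$rule, class = "embsnn_rule")
  }
  if (!is.null(payload$syn) && is.list(payload$syn)) {
    payload$syn <- structure(payload$syn, class = "embsnn_syn")
  }
  out <- tryCatch({
    r <- server_call(srv, endpoint, payload)
    list(status = 200L,
         body = jsonlite::toJSON(unclass(r), auto_unbox = TRUE,
                                 dataframe = "columns", null = "null"))
  }, error = function(e) {
    list(status = 400L,
         body = jsonlite::toJSON(list(error = conditionMessage(e)),
                                 auto_unbox = TRUE))
  })
  out
}

#' Serve the HTTP API (blocking)
#'
#' Minimal single-connection HTTP loop over base sockets, mirroring the
#' `http://host:5000/api/<Endpoint>` shape. Intended for interactive use;
#' programmatic work should prefer [server_call()].
#'
#' @param srv server handle.
#' @param port TCP port (default 5000).
#' @param max_requests stop after this many requests (Inf to run forever).
#' @export
serve_http <- function(srv, port = 5000, max_requests = Inf) {
  n <- 0
  while (n < max_requests && isTRUE(srv$running)) {
    con <- suppressWarnings(socketConnection(host = "127.0.0.1",
                                             port = port, server = TRUE,
                                             blocking = TRUE,
                                             open = "r+b", timeout = 30))
    req_text <- read_http_connection(con)
    if (nzchar(req_text)) {
      resp <- dispatch_http(srv, parse_http_request(req_text))
      writeLines(c(sprintf("HTTP/1.1 %d OK", resp$status),
                   "Content-Type: application/json",
                   sprintf("Content-Length: %d", nchar(resp$body, "bytes")),
                   "", resp$body), con, sep = "\r\n")
    }
    close(con)
    n <- n + 1
  }
  invisible(n)
}

read_http_connection <- function(con) {
  lines <- character(0)
  repeat {
    l <- readLines(con, n = 1)
    if (!length(l)) break
    if (!nzchar(l)) break
    lines <- c(lines, l)
  }
  clen <- grep("^Content-Length:", lines, ignore.case = TRUE, value = TRUE)
  body <- ""
  if (length(clen)) {
    nb <- as.integer(sub("^[^:]+: *", "", clen[1]))
    if (nb > 0) body <- rawToChar(readBin(con, "raw", nb))
  }
  paste0(paste(lines, collapse = "\r\n"), "\r\n\r\n", body)
}
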