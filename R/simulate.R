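# The simulation loop: ring-buffered spike delivery, neuron updates,
# threshold detection, STDP, device handling and spike recording.

ensure_built <- function(kernel) {
  if (!kernel$dirty) return(invisible(kernel))
  # adjacency by pre neuron, and by post neuron for plastic projections
  for (proj in kernel$projections) {
    if (proj$is_poisson) next
    n_pre <- kernel$pops[[proj$pre]]$count
    f <- factor(proj$pre_idx, levels = seq_len(n_pre))
    proj$by_pre <- split(seq_len(proj$n_syn), f)
    if (proj$plastic) {
      n_post <- kernel$pops[[proj$post]]$count
      fp <- factor(proj$post_idx, levels = seq_len(n_post))
      proj$by_post <- split(seq_len(proj$n_syn), fp)
    }
  }
  # ring buffers sized by the longest incoming delay; remember which
  # receptor channels a population actually receives
  need <- integer(length(kernel$pops))
  used <- vector("list", length(kernel$pops))
  for (proj in kernel$projections) {
    pp <- kernel$pops[[proj$post]]
    if (pp$model == "spike_recorder") next
    need[proj$post] <- max(need[proj$post], proj$delay_steps + 1L)
    used[[proj$post]] <- union(used[[proj$post]], proj$receptor_col)
  }
  for (p in kernel$pops) {
    if (p$model == "lif_conductance") {
      p$used_rec <- sort(used[[p$id]] %||% integer(0))
    }
  }
  # buffers are per-slot lists of per-channel accumulator vectors (NULL =
  # all-zero); small pieces keep copy-on-write assignments cheap
  for (p in kernel$pops) {
    ch <- n_channels_for(p$model, p$par)
    if (ch == 0L || need[p$id] == 0L) next
    p$n_ch <- ch
    if (is.null(p$buf)) {
      p$slots <- need[p$id]
      p$buf <- lapply(seq_len(p$slots), function(s) vector("list", ch))
      p$slot_has <- rep(FALSE, p$slots)
    } else if (p$slots < need[p$id]) {
      old <- p$buf
      old_slots <- p$slots
      old_has <- p$slot_has
      p$slots <- need[p$id]
      p$buf <- lapply(seq_len(p$slots), function(s) vector("list", ch))
      p$slot_has <- rep(FALSE, p$slots)
      for (a in (kernel$step + 1L):(kernel$step + old_slots)) {
        p$buf[[(a %% p$slots) + 1L]] <- old[[(a %% old_slots) + 1L]]
        p$slot_has[(a %% p$slots) + 1L] <- old_has[(a %% old_slots) + 1L]
      }
    }
  }
  kernel$dirty <- FALSE
  invisible(kernel)
}

# Accumulate weighted events into a population's ring buffer. When all
# weights are identical (`uw` given), a tabulate pass replaces the rowsum.
buffer_add <- function(post_p, slot, ch, posts, w, uw = NULL) {
  if (length(posts) == 0L) return(invisible(NULL))
  if (!is.null(uw)) {
    counts <- tabulate(posts, nbins = post_p$count)
    idx <- which(counts > 0L)
    agg <- uw * counts[idx]
  } else {
    agg <- rowsum(w, posts)
    idx <- as.integer(rownames(agg))
    agg <- as.numeric(agg)
  }
  cur <- post_p$buf[[slot]][[ch]]
  if (is.null(cur)) cur <- numeric(post_p$count)
  cur[idx] <- cur[idx] + agg
  post_p$buf[[slot]][[ch]] <- cur
  post_p$slot_has[slot] <- TRUE
  invisible(NULL)
}

# Event chunks live in a hashed environment keyed by chunk index, so an
# append is O(1) regardless of how many chunks exist already.
record_spikes <- function(kernel, p, local_idx, mult, t) {
  for (rid in p$rec_ids) {
    rec <- kernel$pops[[rid]]
    gids <- p$first_id + local_idx - 1L
    if (any(mult > 1L)) gids <- rep(gids, times = mult)
    k <- rec$n_chunks + 1L
    assign(as.character(k), list(gids, t), envir = rec$ev)
    rec$n_chunks <- k
  }
}

# Deliver the spikes of `local_idx` (with multiplicities `mult`) of
# population `p`, emitted at step m, into all outgoing projections;
# apply STDP depression on plastic ones.
deliver <- function(kernel, p, local_idx, mult, m) {
  for (pid in p$out_projs) {
    proj <- kernel$projections[[pid]]
    sidx <- proj$by_pre[local_idx]
    lens <- lengths(sidx)
    sidx <- unlist(sidx, use.names = FALSE)
    if (length(sidx) == 0L) next
    post_p <- kernel$pops[[proj$post]]
    posts <- proj$post_idx[sidx]
    mm <- if (any(mult > 1L)) rep(mult, times = lens) else 1
    if (proj$plastic) {
      # depression at pre-spike time using the post trace
      s <- proj$syn
      wold <- proj$weight[sidx]
      wnew <- pmax(1e-12 * s$w0,
                   wold - s$lambda_ * s$alpha_ * wold * post_p$Kminus[posts])
      proj$weight[sidx] <- wnew
      w <- wnew * mm
    } else {
      w <- proj$weight[sidx] * mm
    }
    slot <- ((m + proj$delay_steps) %% post_p$slots) + 1L
    unit_mult <- length(mm) == 1L && mm == 1
    if (post_p$model == "parrot") {
      if (unit_mult) {
        buffer_add(post_p, slot, 1L, posts, NULL, uw = 1)
      } else {
        buffer_add(post_p, slot, 1L, posts, rep(mm, length.out = length(posts)))
      }
    } else if (!proj$plastic && unit_mult && !is.na(proj$uniform_w)) {
      buffer_add(post_p, slot, proj$receptor_col, posts, NULL,
                 uw = proj$uniform_w)
    } else {
      buffer_add(post_p, slot, proj$receptor_col, posts, w)
    }
  }
}

# STDP potentiation for spiking post neurons, using pre traces.
potentiate <- function(kernel, p, local_idx) {
  for (proj in kernel$projections) {
    if (!proj$plastic || proj$post != p$id) next
    sidx <- unlist(proj$by_post[local_idx], use.names = FALSE)
    if (length(sidx) == 0L) next
    pre_p <- kernel$pops[[proj$pre]]
    s <- proj$syn
    w <- proj$weight[sidx]
    proj$weight[sidx] <- w + s$lambda_ * s$w0^(1 - s$mu) * w^s$mu *
      pre_p$Kplus[proj$pre_idx[sidx]]
  }
}

#' Advance the simulation
#'
#' Runs the kernel for `duration` ms (a positive multiple of the
#' resolution). Per step: due spikes are read from the ring buffers, all
#' neurons are updated, threshold crossings are detected at step end,
#' deliveries are enqueued and STDP is applied on spike events.
#'
#' @param kernel kernel object.
#' @param duration simulated time to advance, ms.
#' @export
simulate <- function(kernel, duration) {
  stopifnot(inherits(kernel, "embsnn_kernel"), duration > 0)
  n_steps <- duration / kernel$res
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("duration must be a positive multiple of the resolution",
         call. = FALSE)
  }
  n_steps <- as.integer(round(n_steps))
  ensure_built(kernel)
  pois <- Filter(function(pr) pr$is_poisson, kernel$projections)
  dyn <- Filter(function(p) is_dynamic(p$model), kernel$pops)
  trace_decay <- list()
  for (p in dyn) {
    if (p$has_traces) {
      # tau_plus/tau_minus of the (single) plastic rule touching this pop
      tp <- tm <- NULL
      for (proj in kernel$projections) {
        if (proj$plastic && (proj$pre == p$id || proj$post == p$id)) {
          tp <- proj$syn$tau_plus; tm <- proj$syn$tau_minus
        }
      }
      trace_decay[[as.character(p$id)]] <-
        c(exp(-kernel$res / tp), exp(-kernel$res / tm))
    }
  }
  res <- kernel$res
  for (m in (kernel$step + 1L):(kernel$step + n_steps)) {
    t <- m * res
    # Poisson drives: one independent realization per connection,
    # drawn from the device's stream keyed by the absolute step.
    for (proj in pois) {
      dev <- kernel$pops[[proj$pre]]
      rate <- dev$par$rate
      if (rate <= 0) next
      lam <- rate * res / 1000
      counts <- with_stream(kernel$seed, "poisson", dev$first_id,
                            m * 131L + proj$id,
                            stats::rpois(proj$n_syn, lam))
      nz <- which(counts > 0L)
      if (!length(nz)) next
      post_p <- kernel$pops[[proj$post]]
      slot <- ((m + proj$delay_steps) %% post_p$slots) + 1L
      if (post_p$model == "parrot") {
        buffer_add(post_p, slot, 1L, proj$post_idx[nz],
                   as.numeric(counts[nz]))
      } else {
        buffer_add(post_p, slot, proj$receptor_col, proj$post_idx[nz],
                   counts[nz] * proj$weight[nz])
      }
    }
    # neuron updates
    for (p in dyn) {
      inp <- NULL
      if (!is.null(p$buf)) {
        slot <- (m %% p$slots) + 1L
        if (p$slot_has[slot]) {
          inp <- p$buf[[slot]]
          p$buf[[slot]] <- vector("list", p$n_ch)
          p$slot_has[slot] <- FALSE
        }
      }
      if (p$model == "parrot") {
        if (!is.null(inp) && !is.null(inp[[1]])) {
          counts <- as.integer(inp[[1]])
          sp <- which(counts > 0L)
          if (length(sp)) {
            record_spikes(kernel, p, sp, counts[sp], t)
            deliver(kernel, p, sp, counts[sp], m)
          }
        }
        next
      }
      sp <- if (p$model == "lif_conductance") {
        step_conductance_pop(p, inp)
      } else {
        w1 <- if (is.null(inp)) NULL else inp[[1]]
        step_current_pop(p, if (is.null(w1)) 0 else w1)
      }
      if (length(sp)) {
        mult <- rep.int(1L, length(sp))
        record_spikes(kernel, p, sp, mult, t)
        deliver(kernel, p, sp, mult, m)
        if (p$has_traces) potentiate(kernel, p, sp)
      }
      if (p$has_traces) {
        dk <- trace_decay[[as.character(p$id)]]
        p$Kplus <- p$Kplus * dk[1]
        p$Kminus <- p$Kminus * dk[2]
        if (length(sp)) {
          p$Kplus[sp] <- p$Kplus[sp] + 1
          p$Kminus[sp] <- p$Kminus[sp] + 1
        }
      }
    }
    kernel$step <- m
  }
  invisible(kernel)
}

step_current_pop <- function(p, input_w) {
  f <- p$fast
  st <- p$state
  par <- p$par
  u <- st$V - par$E_L
  u2 <- f$P31 * st$y1 + f$P32 * st$y2 + f$P33 * u + f$P34 * par$I_e
  y2 <- f$P21 * st$y1 + f$P22 * st$y2
  y1 <- f$P11 * st$y1
  V <- par$E_L + u2
  refr <- st$refr
  inref <- refr > 0L
  if (any(inref)) {
    V[inref] <- par$V_reset
    refr[inref] <- refr[inref] - 1L
  }
  y1 <- y1 + input_w * f$psc
  sp <- which(!inref & V >= par$V_th)
  if (length(sp)) {
    V[sp] <- par$V_reset
    refr[sp] <- f$refr_steps
  }
  p$state <- list(V = V, y1 = y1, y2 = y2, refr = refr)
  sp
}

step_conductance_pop <- function(p, input_w) {
  f <- p$fast
  st <- p$state
  par <- p$par
  g1 <- st$g1
  g2 <- st$g2
  gbar_sum <- 0
  gE_sum <- 0
  cols <- p$used_rec %||% seq_along(f$d)
  for (k in cols) {
    y1 <- g1[[k]]
    y2 <- g2[[k]]
    gbar <- (f$A[k] * y2 + f$B[k] * y1) * f$inv_dt # exact step average
    gbar_sum <- gbar_sum + gbar
    gE_sum <- gE_sum + gbar * f$E_rev[k]
    y2 <- f$d[k] * (y2 + f$dt * y1)
    y1 <- f$d[k] * y1
    if (!is.null(input_w) && !is.null(input_w[[k]])) {
      y1 <- y1 + input_w[[k]] * f$gin[k]
    }
    g1[[k]] <- y1
    g2[[k]] <- y2
  }
  gtot <- f$g_L + gbar_sum
  Vinf <- (f$g_L * par$E_L + gE_sum + par$I_bias) / gtot
  V <- Vinf + (st$V - Vinf) * exp(-f$dt * gtot / par$C_m)
  refr <- st$refr
  inref <- refr > 0L
  if (any(inref)) {
    V[inref] <- par$V_reset
    refr[inref] <- refr[inref] - 1L
  }
  sp <- which(!inref & V >= par$V_th)
  if (length(sp)) {
    V[sp] <- par$V_reset
    refr[sp] <- f$refr_steps
  }
  p$state <- list(V = V, g1 = g1, g2 = g2, refr = refr)
  sp
}

#' Retrieve recorded spikes
#'
#' Events are merged across all owning workers and sorted by (time, gid);
#' the result is identical for any worker count.
#'
#' @param kernel kernel object.
#' @param recorder a `spike_recorder` population handle.
#' @param t_from,t_to inclusive time window in ms.
#' @return data.frame with columns `gid` and `t`.
#' @export
get_spikes <- function(kernel, recorder, t_from = 0, t_to = Inf) {
  if (t_to < t_from) stop("inverted time window", call. = FALSE)
  rec <- kernel$pops[[recorder$pop]]
  if (rec$model != "spike_recorder") stop("not a spike recorder")
  chunks <- lapply(seq_len(rec$n_chunks),
                   function(i) get(as.character(i), envir = rec$ev))
  gids_l <- lapply(chunks, `[[`, 1L)
  gid <- unlist(gids_l, use.names = FALSE)
  t <- rep(vapply(chunks, `[[`, 0, 2L), times = lengths(gids_l))
  if (is.null(gid)) gid <- integer(0)
  keep <- t >= t_from & t <= t_to
  gid <- gid[keep]; t <- t[keep]
  o <- order(t, gid)
  data.frame(gid = gid[o], t = t[o])
}
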