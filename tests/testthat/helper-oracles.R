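# Shared fixtures and independent oracles, built in code at test time.

lif_defaults <- embsnn::lif_current_defaults()

# Small balanced network with Poisson drive, built through the server API;
# used for worker-invariance and determinism checks.
build_tiny_net <- function(n_workers, seed = 42, duration = 200) {
  srv <- start_server(n_workers = n_workers, seed = seed)
  on.exit(stop_server(srv))
  E <- server_call(srv, "Create", list(model = "lif_current", n = 80))
  I <- server_call(srv, "Create", list(model = "lif_current", n = 20))
  hE <- srv$handles[[1]]; hI <- srv$handles[[2]]
  server_call(srv, "Connect", list(pre = hE, post = hE,
    rule = conn_fixed_indegree(20), syn = syn_stdp(weight = 20, w0 = 20)))
  server_call(srv, "Connect", list(pre = hE, post = hI,
    rule = conn_fixed_indegree(20), syn = syn_static(weight = 20)))
  server_call(srv, "Connect", list(pre = hI, post = hE,
    rule = conn_fixed_indegree(5), syn = syn_static(weight = -100)))
  server_call(srv, "Connect", list(pre = hI, post = hI,
    rule = conn_fixed_indegree(5), syn = syn_static(weight = -100)))
  server_call(srv, "Create", list(model = "poisson_generator", n = 1,
                                  params = list(rate = 15000)))
  hd <- srv$handles[[3]]
  server_call(srv, "Connect", list(pre = hd, post = hE,
                                   syn = syn_static(weight = 20)))
  server_call(srv, "Connect", list(pre = hd, post = hI,
                                   syn = syn_static(weight = 20)))
  server_call(srv, "Create", list(model = "spike_recorder", n = 1))
  hr <- srv$handles[[4]]
  server_call(srv, "Connect", list(pre = hE, post = hr))
  server_call(srv, "Connect", list(pre = hI, post = hr))
  server_call(srv, "Simulate", list(duration = duration))
  server_call(srv, "GetSpikes", list(recorder = hr))
}

# Independent fine-step RK4 oracle for the conductance neuron: membrane ODE
# with the analytic alpha-conductance waveform of the given arrival times
# (weight w nS on the AMPA channel), sampled at the kernel grid.
rk4_conductance_oracle <- function(arrivals, n_grid, grid_dt = 0.1,
                                   w = 1, substeps = 400) {
  d <- lif_conductance_defaults()
  gL <- d$C_m / d$tau_m
  tauA <- d$receptors$AMPA$tau
  g_of <- function(t) {
    dt0 <- t - arrivals
    sum(ifelse(dt0 > 0, w * exp(1) / tauA * dt0 * exp(-dt0 / tauA), 0))
  }
  f <- function(t, V) (-gL * (V - d$E_L) - g_of(t) * V) / d$C_m # E_ex = 0
  dt <- grid_dt / substeps
  V <- d$E_L
  out <- numeric(n_grid)
  for (j in seq_len(n_grid)) {
    for (i in seq_len(substeps)) {
      tt <- (j - 1) * grid_dt + (i - 1) * dt
      k1 <- f(tt, V)
      k2 <- f(tt + dt / 2, V + dt / 2 * k1)
      k3 <- f(tt + dt / 2, V + dt / 2 * k2)
      k4 <- f(tt + dt, V + dt * k3)
      V <- V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[j] <- V
  }
  out
}
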