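test_that("single-step current LIF is a pure function with an E_L fixed
           point", {
  d <- lif_defaults
  st <- list(V = d$E_L, y1 = 0, y2 = 0, refr = 0L)
  out <- lif_current_step(st, 0, d, 0.1)
  expect_equal(out$state$V, d$E_L)
  expect_false(out$spiked)
  out2 <- lif_current_step(st, 0, d, 0.1)
  expect_identical(out, out2)
})

test_that("conductance neuron tracks a 1000x-oversampled reference within
           1e-4 mV after a single alpha event", {
  k <- new_kernel(resolution = 0.1, seed = 1)
  src <- create(k, "lif_current", 1, list(I_e = 500))
  tgt <- create(k, "lif_conductance", 1, list(V_th = 0))
  connect(k, src, tgt, conn_one_to_one(),
          syn_static(weight = 1, delay = 1.0, receptor = "AMPA"))
  rec <- create(k, "spike_recorder", 1)
  connect(k, src, rec)
  n_grid <- 200
  Vtrace <- numeric(n_grid)
  for (i in seq_len(n_grid)) {
    simulate(k, 0.1)
    Vtrace[i] <- get_v(k, tgt)
  }
  arrivals <- get_spikes(k, rec)$t + 1.0
  expect_gte(length(arrivals), 1)
  Voracle <- rk4_conductance_oracle(arrivals, n_grid)
  expect_lt(max(abs(Vtrace - Voracle)), 1e-4)
})

test_that("conductance membrane decays to rest and respects the excitatory
           reversal bound under saturating drive", {
  k <- new_kernel()
  p <- create(k, "lif_conductance", 1, list(V_th = 1e9))
  # kick V above rest via a strong transient, then watch the decay
  gen <- create(k, "poisson_generator", 1, list(rate = 50000))
  connect(k, gen, p, conn_all_to_all(),
          syn_static(weight = 100, delay = 0.1, receptor = "AMPA"))
  vmax <- -Inf
  for (i in 1:2000) {
    simulate(k, 0.1)
    vmax <- max(vmax, get_v(k, p))
  }
  E_ex <- lif_conductance_defaults()$receptors$AMPA$E_rev
  expect_lte(vmax, E_ex)
  # now remove the drive: monotone decay toward E_L
  set_status(k, gen, list(rate = 0))
  simulate(k, 50) # flush residual conductance
  vs <- numeric(60)
  for (i in seq_along(vs)) {
    simulate(k, 1)
    vs[i] <- get_v(k, p)
  }
  expect_true(all(diff(vs) <= 1e-12))
  expect_lt(abs(vs[60] - lif_conductance_defaults()$E_L), 0.5)
})

test_that("STDP pair update equals the scalar closed form to machine
           precision", {
  syn <- list(weight = 1, w0 = 1, lambda_ = 0.1, mu = 0.4, tau_plus = 15)
  expect_equal(stdp_update(syn, 10), 1 + 0.1 * exp(-10 / 15),
               tolerance = 1e-15)
  # depression closed form
  syn2 <- list(weight = 2, w0 = 1, lambda_ = 0.1, alpha_ = 0.5,
               tau_minus = 30)
  expect_equal(stdp_update(syn2, -12), 2 - 0.1 * 0.5 * 2 * exp(-12 / 30),
               tolerance = 1e-15)
  # zero learning rate leaves the weight untouched
  expect_equal(stdp_update(list(weight = 3, lambda_ = 0), 5), 3)
  expect_equal(stdp_update(list(weight = 3, lambda_ = 0), -5), 3)
})

test_that("repeated depression never drives a weight to zero or below", {
  w <- 1
  for (i in 1:500) {
    w <- stdp_update(list(weight = w, w0 = 1, lambda_ = 0.9, alpha_ = 1,
                          tau_minus = 30), -0.1)
  }
  expect_gt(w, 0)
})

test_that("plastic synapses potentiate under causal pre-post pairing in the
           kernel", {
  k <- new_kernel()
  pre <- create(k, "lif_current", 1, list(I_e = 500))
  post <- create(k, "lif_current", 1, list(I_e = 470))
  w0 <- 10
  connect(k, pre, post, conn_one_to_one(), syn_stdp(weight = w0, w0 = w0))
  simulate(k, 500)
  w <- k$projections[[1]]$weight
  expect_true(is.finite(w) && w > 0)
  expect_false(identical(w, w0)) # pairing must have moved the weight
})
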