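test_that("population creation allocates fresh contiguous disjoint ids", {
  k <- new_kernel()
  p1 <- create(k, "lif_current", 5)
  expect_equal(p1$first_id, 1L)
  expect_equal(p1$count, 5L)
  p2 <- create(k, "parrot", 1)
  expect_equal(pop_gids(p2), 6L)
  a <- create(k, "lif_current", 10)
  b <- create(k, "lif_current", 20)
  ids <- c(pop_gids(a), pop_gids(b))
  expect_length(unique(ids), 30)
  expect_equal(range(ids), c(7L, 36L))
  expect_error(create(k, "no_such_model", 1), "unknown model")
  expect_error(create(k, "lif_current", 1, list(V_reset = 0, V_th = -60)),
               "V_reset")
  expect_error(create(k, "lif_current", 1, list(banana = 1)), "unknown")
})

test_that("round-robin ownership partitions gids evenly", {
  expect_equal(owner_worker(5, 4), 1)
  expect_true(all(owner_worker(0:999, 1) == 0))
  own <- owner_worker(0:99, 4)
  expect_equal(as.numeric(table(own)), rep(25, 4))
})

test_that("the clock advances only by exact multiples of the resolution", {
  k <- new_kernel(resolution = 0.1)
  create(k, "lif_current", 1)
  simulate(k, 20.0)
  expect_identical(k$step, 200L)
  expect_equal(kernel_time(k), 20.0)
  expect_error(simulate(k, 0.25), "multiple")
  expect_error(simulate(k, -1), "duration > 0")
})

test_that("constant-current membrane matches the closed form on the grid", {
  k <- new_kernel(resolution = 0.1)
  I_e <- 300
  p <- create(k, "lif_current", 1, list(I_e = I_e, V_th = 1e9))
  d <- lif_defaults
  R <- d$tau_m / d$C_m
  for (t in c(0.5, 5, 20, 50)) {
    simulate(k, t - kernel_time(k))
    expect_lt(abs(get_v(k, p) -
                    (d$E_L + R * I_e * (1 - exp(-t / d$tau_m)))), 1e-9)
  }
})

test_that("suprathreshold drive spikes at the closed-form time, snapped up
           to the grid", {
  k <- new_kernel(resolution = 0.1)
  I_e <- 500
  n <- create(k, "lif_current", 1, list(I_e = I_e))
  rec <- create(k, "spike_recorder", 1)
  connect(k, n, rec)
  simulate(k, 100)
  sp <- get_spikes(k, rec)
  d <- lif_defaults
  RI <- d$tau_m / d$C_m * I_e
  tstar <- d$tau_m * log(RI / (RI - (d$V_th - d$E_L)))
  expect_equal(sp$t[1], 0.1 * ceiling(tstar / 0.1))
  # subsequent interspike intervals: refractory period + fresh charge-up
  expect_true(all(abs(diff(sp$t) -
                        (d$t_ref + 0.1 * ceiling(tstar / 0.1))) < 1e-9))
})

test_that("zero input is a fixed point and parrots relay with pure delay", {
  k <- new_kernel()
  q <- create(k, "lif_current", 1)
  simulate(k, 10)
  expect_equal(get_v(k, q), lif_defaults$E_L)

  k2 <- new_kernel()
  src <- create(k2, "lif_current", 1, list(I_e = 500))
  pa <- create(k2, "parrot", 1)
  connect(k2, src, pa, conn_one_to_one(), syn_static(delay = 1.0))
  rec <- create(k2, "spike_recorder", 1)
  connect(k2, src, rec)
  connect(k2, pa, rec)
  simulate(k2, 60)
  sp <- get_spikes(k2, rec)
  expect_gt(nrow(sp), 0)
  expect_equal(sp$t[sp$gid == pa$first_id], sp$t[sp$gid == src$first_id] + 1.0)
})

test_that("empty recorders and window handling", {
  k <- new_kernel()
  create(k, "lif_current", 3) # silent
  rec <- create(k, "spike_recorder", 1)
  simulate(k, 10)
  ev <- get_spikes(k, rec)
  expect_identical(nrow(ev), 0L)
  expect_error(get_spikes(k, rec, 10, 5), "inverted")
})

test_that("Poisson generator counts follow the rate over long windows", {
  k <- new_kernel(seed = 7)
  gen <- create(k, "poisson_generator", 1, list(rate = 1000))
  pa <- create(k, "parrot", 1)
  connect(k, gen, pa, conn_all_to_all(), syn_static(delay = 1.0))
  rec <- create(k, "spike_recorder", 1)
  connect(k, pa, rec)
  simulate(k, 10000)
  n <- nrow(get_spikes(k, rec))
  expect_lt(abs(n - 10000), 4 * sqrt(10000))
})

test_that("set_status updates device and neuron parameters with validation", {
  k <- new_kernel()
  gen <- create(k, "poisson_generator", 1)
  set_status(k, gen, list(rate = 100))
  expect_equal(get_status(k, gen)$rate, 100)
  expect_error(set_status(k, gen, list(rate = -1)), ">= 0")
  p <- create(k, "lif_current", 3)
  set_status(k, p, list(I_e = c(1, 2, 3)))
  expect_equal(get_status(k, p)$I_e, c(1, 2, 3))
  expect_error(set_status(k, p, list(I_e = c(1, 2))), "per neuron")
})
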