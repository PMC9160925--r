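test_that("balanced-network dry-run census follows the fixed-indegree
           arithmetic at any scale", {
  cb <- count_brunel(1)
  expect_equal(cb$neurons, 11250)
  expect_equal(cb$nodes, 11251)
  expect_equal(cb$connections, 11250 * 11250 + 11250)
  expect_equal(count_brunel(0.02)$neurons, 225)
  expect_error(count_brunel(0), "> 0")
  expect_error(count_brunel(-3), "> 0")
})

test_that("instantiated balanced network matches its dry-run census and the
           synapse budget guard refuses oversized builds", {
  net <- build_brunel(0.02, kernel = new_kernel(seed = 3))
  expect_equal(net$census, count_brunel(0.02))
  deg <- c(indegree(net$kernel, net$E), indegree(net$kernel, net$I))
  expect_true(all(deg == 11250))
  expect_error(build_brunel(20), "refusing")
  # the guard's message names the dry-run census
  expect_error(build_brunel(20), "2531475000")
})

test_that("a desk-scale balanced network simulates without error and its
           E-E synapses are the plastic ones", {
  net <- build_brunel(0.005, kernel = new_kernel(seed = 31))
  plastic <- vapply(net$kernel$projections, function(p) p$plastic, TRUE)
  expect_equal(sum(plastic), 1)
  ee <- which(plastic)
  expect_equal(net$kernel$projections[[ee]]$pre, net$E$pop)
  expect_equal(net$kernel$projections[[ee]]$post, net$E$pop)
  simulate(net$kernel, 200)
  ev <- get_spikes(net$kernel, net$recorder)
  expect_gte(nrow(ev), 0)
  expect_equal(kernel_time(net$kernel), 200)
})

test_that("the packaged CBCT composition reproduces the reference regional
           summary exactly", {
  cz <- census_cbct(cbct_default_config(), scale = 1)
  per <- cz$per_region
  expected <- c(M1 = 58805, S1 = 94396, VL = 6144, VM = 6144, BG = 10976,
                CB_M1 = 414720, CB_S1 = 414720)
  for (rg in names(expected)) {
    expect_equal(per$neurons[per$region == rg], unname(expected[rg]),
                 label = rg)
  }
  expect_equal(cz$neurons, 1005905)
  expect_equal(cz$layers, 33)
  layers <- c(M1 = 5, S1 = 7, VL = 2, VM = 2, BG = 5, CB_M1 = 6, CB_S1 = 6)
  types <- c(M1 = 19, S1 = 22, VL = 3, VM = 3, BG = 5, CB_M1 = 6, CB_S1 = 6)
  for (rg in names(layers)) {
    expect_equal(per$layers[per$region == rg], unname(layers[rg]))
    expect_equal(per$types[per$region == rg], unname(types[rg]))
  }
  # thalamic zone structure: 2 zones x (1024 + 1024 + 1024)
  cfg <- cbct_default_config()
  vl <- cfg$rows[cfg$rows$region == "VL", ]
  expect_equal(nrow(vl), 6)
  expect_true(all(vl$count == 1024))
})

test_that("cortical non-L1 layers keep a 4:1 E:I ratio", {
  cfg <- cbct_default_config()
  ctx <- cfg$rows[cfg$rows$kind == "cortex" & cfg$rows$layer != "L1", ]
  by_layer <- split(ctx, paste(ctx$region, ctx$layer))
  expect_gt(length(by_layer), 0)
  for (lay in by_layer) {
    e <- sum(lay$count[lay$ei == "E"])
    i <- sum(lay$count[lay$ei == "I"])
    expect_equal(e / i, 4, label = paste(lay$region[1], lay$layer[1]))
  }
  # L1 itself is purely inhibitory
  l1 <- cfg$rows[cfg$rows$kind == "cortex" & cfg$rows$layer == "L1", ]
  expect_true(all(l1$ei == "I"))
})

test_that("scaled censuses are sums of per-population rounded parts", {
  cfg <- cbct_default_config()
  cz <- census_cbct(cfg, scale = 0.5)
  expect_equal(cz$neurons, sum(round(cfg$rows$count * 0.5)))
  expect_equal(census_cbct(cfg, scale = 1)$neurons,
               sum(round(cfg$rows$count)))
})

test_that("a reduced-scale full build carries all ten inter-regional
           pathways and matches its dry-run census", {
  net <- build_cbct(scale = 0.01, kernel = new_kernel(seed = 17))
  expected_paths <- c("M1_L5A_to_BG_striatum", "S1_L5A_to_BG_striatum",
                      "BG_GPiSNr_to_TH", "M1_L5B_to_CB_pons",
                      "S1_L5B_to_CB_pons", "CB_DCN_to_TH", "M1_L6_to_TH",
                      "S1_L6_to_TH", "TH_to_M1_L23", "TH_to_S1_L4")
  expect_setequal(names(net$pathways), expected_paths)
  expect_true(all(unlist(net$pathways) >= 1))
  expect_equal(net$census$neurons,
               census_cbct(cbct_default_config(), 0.01)$neurons)
  # devices (parrot interfaces, generators, recorder) counted separately
  expect_gt(net$device_census$parrot_relays, 0)
  expect_equal(net$device_census$generators, 2)
})

test_that("drive calibration converges on a monotone toy response and
           reports its contracts", {
  # toy f-I curve: rate = drive^2 / 50 (monotone); target 8 -> drive 20
  toy <- function(drive) drive^2 / 50
  out <- calibrate_resting_input(toy, 8, tol_hz = 0.01, initial_rate = 5)
  expect_lt(abs(out$rate - 20), 0.5)
  expect_lt(abs(out$measured - 8), 0.01)
  # target already achieved: zero iterations
  out0 <- calibrate_resting_input(function(r) 8, 8, tol_hz = 0.5,
                                  initial_rate = 123)
  expect_equal(out0$iterations, 0L)
  expect_equal(out0$rate, 123)
  expect_error(calibrate_resting_input(toy, 8, tol_hz = 0),
               "tolerance")
  expect_error(calibrate_resting_input(function(r) 0, 8, tol_hz = 0.1,
                                       max_iter = 3), "did not converge")
})

test_that("the packaged Pons drive reproduces the 8 Hz mossy-fiber resting
           rate through the parrot interface", {
  cfg <- cbct_default_config()
  k <- new_kernel(seed = 23)
  mf_n <- round(28736 * 0.02)
  mf <- create(k, "parrot", mf_n,
               positions = place_neurons_2d(mf_n, 1, 23, 1))
  cal <- cfg$calibration$pons_drive
  gen <- create(k, "poisson_generator", 1, list(rate = cal$drive_rate_hz))
  connect(k, gen, mf, conn_all_to_all(),
          syn_static(weight = 1, delay = cal$delay_ms))
  rec <- create(k, "spike_recorder", 1)
  connect(k, mf, rec)
  simulate(k, 2000)
  r <- pop_rate(k, rec, mf, 0, 2000)
  expect_lt(abs(r - cal$target_rate_hz), cal$tolerance_hz)
})
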