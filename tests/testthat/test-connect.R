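test_that("deterministic rules create the exact pair sets", {
  k <- new_kernel()
  E <- create(k, "lif_current", 4)
  I <- create(k, "lif_current", 4)
  expect_equal(connect(k, E, I, conn_one_to_one(), syn_static()), 4)
  J <- create(k, "lif_current", 10)
  P <- create(k, "lif_current", 10)
  expect_equal(connect(k, J, P, conn_all_to_all(), syn_static()), 100)
  bad <- create(k, "lif_current", 3)
  expect_error(connect(k, E, bad, conn_one_to_one(), syn_static()),
               "equal population sizes")
})

test_that("delays are validated against min_delay and the grid", {
  k <- new_kernel(resolution = 0.1, min_delay = 0.5)
  a <- create(k, "lif_current", 2)
  b <- create(k, "lif_current", 2)
  expect_error(connect(k, a, b, conn_one_to_one(),
                       syn_static(delay = 0.2)), "min_delay")
  expect_error(connect(k, a, b, conn_one_to_one(),
                       syn_static(delay = 0.55)), "multiple")
  expect_equal(connect(k, a, b, conn_one_to_one(),
                       syn_static(delay = 0.5)), 2)
})

test_that("fixed indegree gives every post neuron exactly k inputs for any
           population sizes", {
  for (sizes in list(c(10, 7), c(3, 40), c(25, 25))) {
    k <- new_kernel(seed = 13)
    pre <- create(k, "lif_current", sizes[1])
    post <- create(k, "lif_current", sizes[2])
    kdeg <- 12 # > n_pre in the first case: multapses must fill in
    n <- connect(k, pre, post, conn_fixed_indegree(kdeg), syn_static())
    expect_equal(n, kdeg * sizes[2])
    expect_true(all(indegree(k, post) == kdeg))
  }
})

test_that("gaussian rule degenerates to all-to-all (minus autapses) and to
           nothing at the kernel limits", {
  k <- new_kernel(seed = 3)
  pos1 <- place_neurons_2d(10, 1, seed = 3, stream_id = 1)
  pos2 <- place_neurons_2d(10, 1, seed = 3, stream_id = 2)
  a <- create(k, "lif_current", 10, positions = pos1)
  b <- create(k, "lif_current", 10, positions = pos2)
  expect_equal(connect(k, a, b, conn_pairwise_gaussian(1, 1e6),
                       syn_static()), 100)
  # recurrent: autapses excluded
  expect_equal(connect(k, a, a, conn_pairwise_gaussian(1, 1e6),
                       syn_static()), 90)
  nopos <- create(k, "lif_current", 5)
  expect_error(connect(k, a, nopos, conn_pairwise_gaussian(0.5, 0.1),
                       syn_static()), "positions")
  expect_error(conn_pairwise_gaussian(0, 0.1))
})

test_that("empirical connection probability follows the gaussian kernel
           within 4-sigma binomial bands", {
  k <- new_kernel(seed = 21)
  n_pre <- 1000; n_post <- 2000
  p0 <- 0.8; sigma <- 0.15
  pre <- create(k, "lif_current", n_pre,
                positions = place_neurons_2d(n_pre, 1, 21, 1))
  post <- create(k, "lif_current", n_post,
                 positions = place_neurons_2d(n_post, 1, 21, 2))
  connect(k, pre, post, conn_pairwise_gaussian(p0, sigma), syn_static())
  proj <- k$projections[[1]]
  prep <- k$pops[[pre$pop]]$positions
  postp <- k$pops[[post$pop]]$positions
  # distances of all ordered pairs, and of the realized connections
  d_all <- sqrt(outer(postp[, 1], prep[, 1], "-")^2 +
                  outer(postp[, 2], prep[, 2], "-")^2)
  d_conn <- d_all[cbind(proj$post_idx, proj$pre_idx)]
  breaks <- seq(0, 0.6, by = 0.1)
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    n_pairs <- sum(d_all >= lo & d_all < hi)
    n_hit <- sum(d_conn >= lo & d_conn < hi)
    mid_p <- p0 * exp(-((lo + hi) / 2)^2 / (2 * sigma^2))
    # compare against the pair-averaged kernel probability in the bin
    p_bin <- mean(p0 * exp(-d_all[d_all >= lo & d_all < hi]^2 /
                             (2 * sigma^2)))
    se <- sqrt(n_pairs * p_bin * (1 - p_bin))
    expect_lt(abs(n_hit - n_pairs * p_bin), 4 * se + 1e-9,
              label = sprintf("bin [%.1f,%.1f): hits %d, expected %.1f",
                              lo, hi, n_hit, n_pairs * p_bin))
    expect_gt(mid_p, 0) # bins stay inside the kernel's support
  }
})

test_that("uniform placement stays in bounds with the right mean", {
  pos <- place_neurons_2d(1e5, 2, seed = 5, stream_id = 9)
  expect_true(all(pos >= 0 & pos <= 2))
  se <- 2 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(pos[, 1]) - 1), 4 * se)
  expect_lt(abs(mean(pos[, 2]) - 1), 4 * se)
  expect_identical(nrow(place_neurons_2d(0, 1)), 0L)
})
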