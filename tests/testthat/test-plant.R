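test_that("the default rig matches its documented interface constants", {
  cfg <- build_default_forelimb()
  expect_equal(nrow(cfg$muscles), 8)
  expect_equal(cfg$bias_torque_nm, -0.001)
  expect_length(cfg$joystick_dof, 2)
  expect_equal(nrow(cfg$segments), 3)
  expect_setequal(cfg$segments$name, c("humerus", "ulna_radius", "foot"))
  # two muscles per actuated axis, with opposite-signed moment arms
  for (ax in unique(cfg$muscles$axis)) {
    arms <- cfg$muscles$arm_m[cfg$muscles$axis == ax]
    expect_length(arms, 2)
    expect_equal(sum(sign(arms)), 0)
  }
  expect_true(all(cfg$segments$mass_kg > 0))
  expect_true(all(cfg$inertia > 0))
})

test_that("activation dynamics follow the first-order closed form", {
  cfg <- build_default_forelimb()
  st <- plant_init(cfg)
  u <- c(1, rep(0, 7))
  for (i in 1:30) st <- plant_step(cfg, st, u)
  expect_equal(st$a[1], 1 - exp(-0.030 / cfg$muscles$tau_act_s[1]),
               tolerance = 1e-12)
  # deactivation branch
  for (i in 1:40) st <- plant_step(cfg, st, numeric(8))
  a30 <- 1 - exp(-0.030 / cfg$muscles$tau_act_s[1])
  expect_equal(st$a[1], a30 * exp(-0.040 / cfg$muscles$tau_deact_s[1]),
               tolerance = 1e-12)
  expect_true(all(st$a >= 0 & st$a <= 1))
})

test_that("equal co-activation of an antagonist pair is torque-neutral", {
  cfg <- build_default_forelimb()
  a <- plant_init(cfg)
  b <- plant_init(cfg)
  for (i in 1:200) {
    a <- plant_step(cfg, a, c(1, 1, rep(0, 6)))
    b <- plant_step(cfg, b)
  }
  expect_equal(a$q, b$q, tolerance = 1e-12)
  expect_equal(a$qdot, b$qdot, tolerance = 1e-12)
})

test_that("with zero excitation the energy never increases and the rig
           settles at the bias equilibrium", {
  cfg <- build_default_forelimb()
  st <- plant_init(cfg)
  E <- plant_energy(cfg, st)
  for (i in 1:3000) {
    st <- plant_step(cfg, st)
    E2 <- plant_energy(cfg, st)
    expect_lte(E2, E + 1e-15)
    E <- E2
  }
  for (i in 1:5000) st <- plant_step(cfg, st)
  expect_lt(max(abs(st$qdot)), 1e-6)
  # both joystick DOF deflect toward the (negative) bias torque
  expect_true(all(joystick_angles(st) < 0))
})

test_that("an equilibrium state with zero activation is a fixed point", {
  cfg <- build_default_forelimb()
  st <- plant_init(cfg)
  for (i in 1:20000) st <- plant_step(cfg, st)
  st2 <- plant_step(cfg, st)
  expect_equal(st2$q, st$q, tolerance = 1e-9)
  expect_equal(st2$a, st$a, tolerance = 1e-12)
})

test_that("sustained elbow flexion from equilibrium pushes the joystick
           strictly forward", {
  cfg <- build_default_forelimb()
  st <- plant_init(cfg)
  for (i in 1:5000) st <- plant_step(cfg, st)
  fwd <- numeric(150)
  u <- numeric(8); u[5] <- 1 # elbow flexor
  for (i in seq_along(fwd)) {
    st <- plant_step(cfg, st, u)
    fwd[i] <- joystick_angles(st)[["fb"]]
  }
  expect_true(all(diff(fwd) > 0))
})

test_that("the state stays bounded and deterministic over long runs", {
  cfg <- build_default_forelimb()
  st <- plant_init(cfg)
  u <- rep(0.7, 8)
  for (i in 1:20000) st <- plant_step(cfg, st, u)
  expect_true(all(is.finite(c(st$q, st$qdot, st$a))))
  expect_lt(max(abs(st$q)), 10)
  # bitwise determinism
  run <- function() {
    s <- plant_init(cfg)
    for (i in 1:500) s <- plant_step(cfg, s, c(0.3, 0, 0.8, 0, 1, 0, 0, 0.2))
    s
  }
  expect_identical(run(), run())
  st_bad <- plant_init(cfg); st_bad$q[1] <- NaN
  expect_error(plant_step(cfg, st_bad), "non-finite")
})
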