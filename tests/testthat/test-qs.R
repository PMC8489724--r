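test_that("qs_params validates rates and thresholds", {
  q <- qs_params()
  expect_s3_class(q, "qs_params")
  expect_error(qs_params(H_T = 0))
  expect_error(qs_params(alpha = c(-1, 1)))
  expect_error(qs_params(K_L = 0))
  expect_error(qs_external(H_trap = c(-1, 0)))
})

test_that("production-free exchange equilibrium leaves concentrations unchanged", {
  q <- qs_params(alpha = c(0, 0), beta = 0, delta_L = 0)
  ext <- qs_external(H_trap = c(0.7, 0.3))
  d <- new_cells(x = 1:2, y = 1, phi = 0, l = 2,
                 strain = c("blue", "orange"))
  d$H1 <- 0.7; d$H2 <- 0.3
  out <- update_intracellular(d, ext, dt = 0.1, q)
  expect_equal(out$H1, d$H1)
  expect_equal(out$H2, d$H2)
  expect_equal(out$lacI, d$lacI)
})

test_that("LacI represses own-signal production via the Hill term", {
  q <- qs_params(alpha = c(6, 6), d = c(0, 0), K_L = 0.5, m_L = 2)
  ext <- qs_external()
  d <- new_cells(x = 1, y = 1, phi = 0, l = 2, strain = "blue")
  d$lacI <- 1e6
  out <- update_intracellular(d, ext, dt = 1, q)
  expect_lt(out$H1, 1e-6) # production fully repressed
  d$lacI <- 0.5
  out2 <- update_intracellular(d, ext, dt = 1, q)
  expect_equal(out2$H1, 6 / 2) # alpha / (1 + (K_L/K_L)^2)
})

test_that("a producing cell in a closed pool accumulates signal monotonically", {
  q <- qs_params(alpha = c(6, 6), gamma = 0, delta_L = 0, beta = 0)
  ext <- qs_external()
  d <- new_cells(x = 1, y = 1, phi = 0, l = 2, strain = "orange")
  prev <- 0
  for (k in 1:50) {
    d <- update_intracellular(d, ext, dt = 0.01, q)
    expect_gte(d$H2, prev)
    prev <- d$H2
  }
  expect_gt(d$H2, 0)
  expect_equal(d$H1, 0) # only its own molecule is produced
})

test_that("too large a step clips negatives with a warning", {
  q <- qs_params(d = c(5, 5))
  ext <- qs_external()
  d <- new_cells(x = 1, y = 1, phi = 0, l = 2, strain = "blue")
  d$H2 <- 1 # exchange term -5 * 1 over dt = 1 overshoots zero
  expect_warning(out <- update_intracellular(d, ext, dt = 1, q), "clipped")
  expect_gte(out$H2, 0)
})

test_that("external pools decay without cells and conserve mass when closed", {
  q <- qs_params(gamma = 1)
  empty <- new_cells(x = 1, y = 1, phi = 0, l = 2)[0, ]
  ext <- qs_external(H_trap = c(1, 1), H_channel = c(0, 0))
  for (k in 1:200) ext <- update_external(empty, ext, dt = 0.05, q)
  expect_lt(max(ext$H_trap), 0.05)
  expect_lt(max(ext$H_channel), 0.05)

  # gamma = 0 and symmetric exchange: trap + channel total is conserved
  q0 <- qs_params(gamma = 0, k_ex = 0.5, k_ex_channel = 0.5)
  ext <- qs_external(H_trap = c(1, 0.4), H_channel = c(0, 0))
  tot0 <- ext$H_trap + ext$H_channel
  for (k in 1:400) ext <- update_external(empty, ext, dt = 0.05, q0)
  expect_equal(ext$H_trap + ext$H_channel, tot0)
  # and the two compartments equilibrate
  expect_equal(ext$H_trap, ext$H_channel, tolerance = 1e-3)
})

test_that("a steadily producing population drives the trap pool to a positive steady state", {
  q <- qs_params()
  d <- new_cells(x = seq(2, 38, by = 4), y = 10, phi = 0, l = 3,
                 strain = "blue")
  d$H1 <- 5 # fixed intracellular level (membrane flux source)
  ext <- qs_external()
  trap_area <- 800
  for (k in 1:4000) ext <- update_external(d, ext, dt = 0.05, q, trap_area)
  h1 <- ext$H_trap[1]
  expect_gt(h1, 0)
  ext2 <- update_external(d, ext, dt = 0.05, q, trap_area)
  expect_equal(ext2$H_trap[1], h1, tolerance = 1e-4) # at steady state
})

test_that("kinetics are step-size robust (step-doubling check)", {
  q <- qs_params()
  ext <- qs_external(H_trap = c(0.5, 0.2))
  d <- new_cells(x = 1:2, y = 1, phi = 0, l = 2,
                 strain = c("blue", "orange"))
  fine <- d
  for (k in 1:40) fine <- update_intracellular(fine, ext, dt = 0.025, q)
  coarse <- d
  for (k in 1:20) coarse <- update_intracellular(coarse, ext, dt = 0.05, q)
  expect_equal(fine$H1, coarse$H1, tolerance = 0.02)
  expect_equal(fine$H2, coarse$H2, tolerance = 0.02)
  expect_equal(fine$lacI, coarse$lacI, tolerance = 0.02)
})
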