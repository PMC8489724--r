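test_that("directional division rates match the closed forms", {
  p <- lm_params(M = 5, N = 5, lambda = 1, kappa = 0.5)
  r <- lm_growth_rates(2, 1, p)
  expect_equal(unname(r["v_plus"]), exp(-1.5))
  expect_equal(unname(r["v_minus"]), exp(-0.5))
  expect_equal(unname(r["h_plus"]), exp(-2))
  expect_equal(unname(r["h_minus"]), 1)
  # lambda scales all rates
  p2 <- lm_params(M = 5, N = 5, lambda = 3, kappa = 0.5)
  expect_equal(lm_growth_rates(2, 1, p2), 3 * r)
  expect_error(lm_growth_rates(0, 1, p), "outside")
  expect_error(lm_growth_rates(1, 6, p), "outside")
})

test_that("kappa = 0 makes every directional rate equal to lambda", {
  p <- lm_params(M = 3, N = 4, lambda = 2, kappa = 0)
  for (i in 1:3) for (j in 1:4)
    expect_equal(unname(lm_growth_rates(i, j, p)), rep(2, 4))
  # total exposed rate of a full lattice is then 2 * lambda * M * N
  st <- lm_seed(p, mode = "single", orientation = "vertical")
  rates <- consortsim:::lm_rate_matrix(st, p)
  expect_equal(sum(rates), 2 * 2 * 3 * 4)
})

test_that("a cell exposes only the rate pair of its orientation", {
  p <- lm_params(M = 5, N = 5, kappa = 0.5)
  v <- lm_exposed_rates("V", 2, 3, p)
  expect_named(v, c("up", "down"))
  expect_equal(unname(v), c(exp(-1.5), exp(-0.5)))
  h <- lm_exposed_rates("H", 2, 3, p)
  expect_named(h, c("right", "left"))
  expect_equal(unname(h), c(exp(-1), exp(-1)))
  expect_error(lm_exposed_rates("X", 2, 3, p), "orientation")
})

test_that("rotation probability is the Moore-neighborhood average", {
  p <- lm_params(M = 3, N = 3, p_rot = c(blue = 0.5, orange = 0.1))
  strains <- matrix("orange", 3, 3)
  strains[2, 2] <- "blue"
  st <- new_lattice_state(strains, matrix("V", 3, 3))
  expect_equal(lm_rotation_prob(st, c(2, 2), p), (0.5 + 8 * 0.1) / 9)
  # corner site averages over the 4 existing cells
  expect_equal(lm_rotation_prob(st, c(1, 1), p), (0.5 + 3 * 0.1) / 4)
  # uniform neighborhood reduces to the strain's own probability
  st1 <- new_lattice_state(matrix("blue", 3, 3), matrix("V", 3, 3))
  expect_equal(lm_rotation_prob(st1, c(2, 2), p), 0.5)
})

test_that("rotation probability switches at the induction time", {
  p <- lm_params(M = 2, N = 2, p_rot = c(blue = 0.1, orange = 0.1),
                 induction_time = 5,
                 p_rot_post = c(blue = 0.1, orange = 0.9))
  st <- new_lattice_state(matrix("orange", 2, 2), matrix("V", 2, 2))
  expect_equal(lm_rotation_prob(st, c(1, 1), p, time = 4.99), 0.1)
  expect_equal(lm_rotation_prob(st, c(1, 1), p, time = 5), 0.9)
})

test_that("division shifts the displaced half-line and keeps the lattice full", {
  p <- lm_params(M = 1, N = 3)
  st <- new_lattice_state(matrix(c("blue", "blue", "orange"), 1, 3),
                          matrix(c("H", "H", "V"), 1, 3))
  ev <- list(site = c(1, 2), direction = "right", daughter_orientation = "H")
  out <- lm_apply_division(st, ev)
  # daughter lands at column 3; former occupant pushed out
  expect_identical(out$strain[1, ], c("blue", "blue", "blue"))
  expect_identical(out$orientation[1, ], c("H", "H", "H"))

  # division toward the near boundary discards the daughter: no change
  ev2 <- list(site = c(1, 1), direction = "left", daughter_orientation = "H")
  out2 <- lm_apply_division(st, ev2)
  expect_identical(out2$strain, st$strain)
  expect_identical(out2$orientation, st$orientation)
})

test_that("vertical division shifts a column segment upward", {
  p <- lm_params(M = 4, N = 1)
  st <- new_lattice_state(matrix(c("blue", "orange", "orange", "blue"), 4, 1),
                          matrix(c("V", "V", "H", "V"), 4, 1))
  ev <- list(site = c(2, 1), direction = "up", daughter_orientation = "V")
  out <- lm_apply_division(st, ev)
  # mother at row 2; daughter at row 3; rows 3..4 shift up, old row 4 removed
  expect_identical(as.vector(out$strain), c("blue", "orange", "orange", "orange"))
  expect_identical(as.vector(out$orientation), c("V", "V", "V", "H"))
})

test_that("division direction must match the mother's orientation", {
  st <- new_lattice_state(matrix("blue", 2, 2), matrix("V", 2, 2))
  ev <- list(site = c(1, 1), direction = "right", daughter_orientation = "H")
  expect_error(lm_apply_division(st, ev), "inconsistent")
})

test_that("the lattice stays full under many random events", {
  set.seed(7)
  p <- lm_params(M = 5, N = 8, kappa = 0.3,
                 p_rot = c(blue = 0.3, orange = 0.3))
  st <- lm_seed(p, mode = "random", seed = 7)
  for (k in 1:200) st <- lm_gillespie_step(st, p)$state
  expect_identical(dim(st$strain), c(5L, 8L))
  expect_true(all(st$strain %in% c("blue", "orange")))
  expect_true(all(st$orientation %in% c("V", "H")))
  expect_gt(st$time, 0)
})

test_that("horizontal growth propensity matches a hand computation", {
  p <- lm_params(M = 2, N = 3, kappa = 0.5)
  strains <- matrix("blue", 2, 3)
  orient <- matrix("V", 2, 3)
  orient[1, 2] <- "H" # one horizontal blue cell in column 2
  st <- new_lattice_state(strains, orient)
  hsum_col2 <- exp(-0.5 * (3 - 2)) + exp(-0.5 * (2 - 1))
  expect_equal(lm_horizontal_propensity(st, "blue", p), hsum_col2 / 6)
  expect_error(lm_horizontal_propensity(st, "orange", p), "absent")
  # no horizontal cells -> 0
  st_v <- new_lattice_state(strains, matrix("V", 2, 3))
  expect_equal(lm_horizontal_propensity(st_v, "blue", p), 0)
})
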