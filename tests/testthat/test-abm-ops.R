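test_that("new_cells builds a well-formed cell table", {
  d <- new_cells(x = c(2, 6), y = 10, phi = pi / 2, l = 3, strain = "blue")
  expect_identical(nrow(d), 2L)
  expect_identical(names(d), c("x", "y", "phi", "l", "l0", "ld", "strain",
                               "F_axial", "H1", "H2", "lacI"))
  # default division target: sqrt(2 * l0 * l_d_bar)
  expect_equal(d$ld, rep(sqrt(2 * 1.5 * 4.2), 2))
  # angles are reduced to [0, pi)
  d2 <- new_cells(x = 1, y = 1, phi = pi + 0.3, l = 2)
  expect_equal(d2$phi, 0.3)
  expect_error(new_cells(x = 1, y = 1, phi = 0, l = -1))
})

test_that("growth is exponential with the configured doubling time", {
  d <- new_cells(x = 1:2, y = 1, phi = 0, l = 2,
                 strain = c("blue", "orange"))
  g <- abm_grow(d, dt = 20, doubling_time = 20)
  expect_equal(g$l, c(4, 4))
  g2 <- abm_grow(d, dt = 10, doubling_time = c(blue = 10, orange = 20))
  expect_equal(g2$l, c(4, 2 * sqrt(2)))
  expect_error(abm_grow(d, dt = -1), "dt")
})

test_that("division splits the mother along her axis and conserves length", {
  set.seed(1)
  cell <- new_cells(x = 10, y = 5, phi = 0.7, l = 5, strain = "orange",
                    ld = 4.5)
  out <- abm_divide_cell(cell, l_d_bar_eff = 4.2, noise_sd = 0)
  expect_identical(nrow(out), 2L)
  expect_equal(sum(out$l), 5)
  expect_true(all(out$l / 5 >= 0.45 & out$l / 5 <= 0.55))
  # daughters are born at their full length and inherit fresh targets
  expect_equal(out$l0, out$l)
  expect_equal(out$ld, sqrt(2 * out$l0 * 4.2))
  # centers sit end-to-end on the mother's axis within her footprint
  u <- c(cos(0.7), sin(0.7))
  off <- cbind(out$x - 10, out$y - 5)
  expect_equal(abs(off[1, ] / u) , rep((5 - out$l[1]) / 2, 2))
  expect_equal(off[1, ] + off[2, ], u * (out$l[1] - out$l[2]) / 2)
  # below the target: no division
  same <- abm_divide_cell(new_cells(x = 0, y = 0, phi = 0, l = 2), 4.2)
  expect_identical(nrow(same), 1L)
  expect_error(abm_divide_cell(cell, l_d_bar_eff = 0), "l_d_bar_eff")
})

test_that("the division-target map is a contraction to the mean division length", {
  # with symmetric splitting, a lineage's division length follows
  # l' = sqrt(l * l_d_bar): iterating from any start converges to l_d_bar
  l <- 2
  for (k in 1:60) l <- sqrt(l * 4.2)
  expect_equal(l, 4.2, tolerance = 1e-8)
})

test_that("mechanical relaxation separates overlapping cells", {
  g <- trap_geometry(width = 20, height = 20)
  d <- new_cells(x = c(9.8, 10.2), y = 10.5, phi = 0, l = 3)
  d$y <- c(10.2, 10.8) # deep side-by-side overlap of the 1 um wide rods
  res <- relax_mechanics(d, g)
  expect_true(res$max_overlap < 0.05 || !res$converged)
  dist0 <- sqrt(diff(d$x)^2 + diff(d$y)^2)
  dist1 <- sqrt(diff(res$cells$x)^2 + diff(res$cells$y)^2)
  expect_gt(dist1, dist0)
  # a lone pair far apart is untouched
  d2 <- new_cells(x = c(5, 15), y = 10, phi = pi / 2, l = 3)
  res2 <- relax_mechanics(d2, g)
  expect_equal(res2$cells$x, d2$x, tolerance = 1e-9)
  expect_equal(res2$iterations, 0)
})

test_that("cells whose centers leave the trap are removed", {
  g <- trap_geometry(width = 10, height = 10)
  d <- new_cells(x = c(5, -0.1, 10.1, 5), y = c(5, 5, 5, 10.4), phi = 0, l = 2)
  kept <- remove_exited(d, g)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$x, 5)
})

test_that("effective division length honors external induction and QS threshold", {
  p <- abm_params(blue = strain_params(l_d_bar = 4.2, a = 0.6),
                  orange = strain_params(l_d_bar = 4.2, a = 0.6),
                  induce_time = c(blue = Inf, orange = 100),
                  qs = qs_params(H_T = 0.4))
  d <- new_cells(x = 1:3, y = 1, phi = 0, l = 2,
                 strain = c("blue", "blue", "orange"))
  d$H2 <- c(0.41, 0.4, 9) # blue senses molecule 2; orange ignores it
  expect_equal(unname(effective_l_d_bar(d, p, time = 0)),
               c(0.6 * 4.2, 4.2, 4.2))      # strict threshold
  expect_equal(unname(effective_l_d_bar(d, p, time = 100)),
               c(0.6 * 4.2, 4.2, 0.6 * 4.2)) # orange externally induced
})

test_that("threshold controller reduces 4.2 to 2.52 (2.5 at reporting precision)", {
  q <- qs_params(H_T = 0.4)
  cell <- new_cells(x = 0, y = 0, phi = 0, l = 2, strain = "blue")
  expect_equal(threshold_controller(cell, q, 4.2, 0.6), 4.2) # H_opp = 0
  cell$H2 <- 0.4
  expect_equal(threshold_controller(cell, q, 4.2, 0.6), 4.2) # equality: unreduced
  cell$H2 <- 0.5
  expect_equal(threshold_controller(cell, q, 4.2, 0.6), 2.52)
  expect_equal(round(threshold_controller(cell, q, 4.2, 0.6), 1), 2.5)
})

test_that("induce_length_reduction rescales only the chosen strain's targets", {
  p <- abm_params(orange = strain_params(l_d_bar = 4.2, a = 0.6))
  d <- new_cells(x = 1:2, y = 1, phi = 0, l = 2,
                 strain = c("blue", "orange"))
  out <- induce_length_reduction(d, p, "orange")
  expect_equal(out$ld[1], d$ld[1])
  expect_equal(out$ld[2], sqrt(2 * d$l0[2] * 0.6 * 4.2))
})

test_that("step_abm advances time and grows the population", {
  set.seed(3)
  g <- trap_geometry(width = 20, height = 10)
  p <- abm_params(geometry = g, dt = 0.1)
  cells <- new_cells(x = c(6, 10, 14), y = 5, phi = pi / 2, l = 4.5)
  state <- list(cells = cells, time = 0)
  for (k in 1:30) state <- step_abm(state, p)
  expect_equal(state$time, 3, tolerance = 1e-9)
  expect_gte(nrow(state$cells), 3L)
  expect_true(all(state$cells$x >= 0 & state$cells$x <= 20))
  # the hard cap aborts a runaway population
  p_cap <- abm_params(geometry = g, dt = 0.1, cap = 2L)
  expect_error(step_abm(list(cells = cells, time = 0), p_cap), "cap")
})
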