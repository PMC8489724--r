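test_that("order parameter matches hand-computed values", {
  expect_equal(order_parameter(rep(pi / 2, 10)), 1)
  expect_equal(order_parameter(c(0, pi / 2)), 0)
  # nematic identification: phi and phi + pi are the same orientation
  expect_equal(order_parameter(c(0.3, 0.3 + pi)), 1)
  # three angles 0, 0, pi/2: mean cos(2 phi) = 1/3, mean sin = 0
  expect_equal(order_parameter(c(0, 0, pi / 2)), 1 / 3)
  expect_error(order_parameter(numeric(0)), "at least one")
})

test_that("weighted order parameter follows the weights", {
  phi <- c(0, pi / 2)
  expect_equal(order_parameter(phi, weights = c(3, 1)), 0.5)
  expect_equal(order_parameter(phi, weights = c(1, 0)), 1)
  expect_error(order_parameter(phi, weights = c(-1, 1)))
  expect_error(order_parameter(phi, weights = c(1, 1, 1)))
})

test_that("region_q restricts to the analysis strips", {
  g <- trap_geometry(width = 100, height = 20)
  # aligned cells in the bulk, perpendicular pair at the left edge
  cells <- new_cells(x = c(40, 50, 60, 5, 5), y = 10,
                     phi = c(pi / 2, pi / 2, pi / 2, 0, pi / 2), l = 3)
  expect_equal(region_q(cells, g, "bulk"), 1)
  expect_equal(region_q(cells, g, "edge_left"), 0)
  expect_true(is.na(region_q(cells, g, "edge_right")))
})

test_that("kymograph bins cells into columns at each sample", {
  tr <- list(cells = data.frame(t = rep(c(0, 10), each = 3),
                                x = rep(c(1.5, 5.5, 5.7), 2),
                                phi = c(rep(pi / 2, 3), pi / 2, 0, pi / 2),
                                F_axial = 2),
             params = list(geometry = trap_geometry(width = 10, height = 10)))
  ky <- kymograph(tr, "q", bin_width = 2)
  expect_equal(ky$t, c(0, 10))
  expect_equal(ky$x, seq(1, 9, by = 2))
  expect_identical(dim(ky$z), c(2L, 5L))
  expect_equal(ky$z[1, 1], 1)       # single-orientation column
  expect_equal(ky$z[2, 3], 0)       # mixed perpendicular pair
  expect_true(all(is.na(ky$z[, 5]))) # empty column
  kf <- kymograph(tr, "F_x", bin_width = 2)
  expect_equal(kf$z[1, 1], 2 * abs(cos(pi / 2)))
  expect_equal(kf$z[2, 3], mean(2 * abs(cos(c(0, pi / 2)))))
  expect_error(kymograph(list(cells = NULL), "q"), "record_cells")
})

test_that("fit_alpha recovers an exact invasion exponential", {
  fx <- fixture_suite("exp-series")
  fit <- fit_alpha(fx$t, fx$f, mode = "invasion", t0 = fx$t0)
  expect_equal(fit$alpha, fx$alpha, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_identical(fit$mode, "invasion")
  # the window stops at the first crossing of f_max (t = 2.2 on this grid)
  expect_equal(max(fit$fitted$t), 2.2)
  expect_lt(nrow(fit$fitted), length(fx$t))
})

test_that("fit_alpha recovers an exact early-growth exponential", {
  t <- seq(0, 1, by = 0.05)
  f <- 0.5 * exp(1.3 * t)
  fit <- fit_alpha(t, f, mode = "growth", t0 = 0, window = 1)
  expect_equal(fit$alpha, 1.3, tolerance = 1e-6)
  expect_error(fit_alpha(t[1:3], f[1:3], mode = "growth"), "fewer than 5")
})

test_that("fit_alpha recovers alpha within 10% under noise", {
  set.seed(123)
  t <- seq(1, 4, by = 0.02)
  alpha_true <- 1.5
  f <- 1 - 0.5 * exp(-alpha_true * (t - 1)) + rnorm(length(t), 0, 0.02)
  fit <- fit_alpha(t, pmin(pmax(f, 0), 1), mode = "invasion", t0 = 1)
  expect_lt(abs(fit$alpha - alpha_true) / alpha_true, 0.1)
})

test_that("alpha_vs_parameter classifies monotone trends and fits them", {
  p <- c(0.1, 0.3, 0.5)
  out <- alpha_vs_parameter(p, 2 * p + 0.05, relation = "linear")
  expect_identical(out$monotone, "increasing")
  expect_equal(out$coef[2], 2, tolerance = 1e-9)
  expect_equal(out$r_squared, 1)
  out2 <- alpha_vs_parameter(p, exp(-3 * p), relation = "exponential")
  expect_identical(out2$monotone, "decreasing")
  expect_equal(out2$coef[2], -3, tolerance = 1e-9)
  out3 <- alpha_vs_parameter(p, c(1, 2, 1.5))
  expect_identical(out3$monotone, "no")
  expect_error(alpha_vs_parameter(p, c(-1, 1, 2), relation = "exponential"),
               "> 0")
  expect_error(alpha_vs_parameter(p[1:2], c(1, 2)), "length")
})

test_that("strain_fraction_series extracts the fraction columns", {
  tr <- list(summary = data.frame(t = 0:2, frac_orange = c(0.5, 0.6, 0.7),
                                  other = 1))
  s <- strain_fraction_series(tr)
  expect_identical(names(s), c("t", "frac_orange"))
  expect_equal(s$frac_orange, c(0.5, 0.6, 0.7))
})
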