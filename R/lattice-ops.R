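#' Location-dependent division rates of the lattice model
#'
#' Growth in the lattice model is modulated by the amount of population that
#' lies between a cell and the trap boundary it grows toward:
#' `v+(i) = lambda * exp(-kappa * (M - i))`,
#' `v-(i) = lambda * exp(-kappa * (i - 1))`,
#' `h+(j) = lambda * exp(-kappa * (N - j))`,
#' `h-(j) = lambda * exp(-kappa * (j - 1))`,
#' with 1-based indices, row 1 at the bottom and column 1 at the left.
#' A vertical cell exposes only the `v` pair, a horizontal cell only the `h`
#' pair; see [lm_exposed_rates()].
#'
#' @param i,j Row and column index (1-based).
#' @param params An [lm_params()] object.
#' @return Named numeric vector `c(v_plus, v_minus, h_plus, h_minus)`.
#' @examples
#' p <- lm_params(M = 5, N = 5, lambda = 1, kappa = 0.5)
#' lm_growth_rates(2, 1, p)["v_plus"] # exp(-1.5)
#' @export
lm_growth_rates <- function(i, j, params) {
  M <- params$M; N <- params$N
  if (i < 1 || i > M || j < 1 || j > N) stop("site (", i, ",", j,
                                             ") outside the lattice")
  lam <- params$lambda; kap <- params$kappa
  c(v_plus = lam * exp(-kap * (M - i)),
    v_minus = lam * exp(-kap * (i - 1)),
    h_plus = lam * exp(-kap * (N - j)),
    h_minus = lam * exp(-kap * (j - 1)))
}

#' Directional rates exposed by a cell given its orientation
#'
#' @param orientation `"V"` or `"H"`.
#' @inheritParams lm_growth_rates
#' @return Named numeric vector of the two exposed rates (`up`/`down` for a
#'   vertical cell, `right`/`left` for a horizontal one).
#' @export
lm_exposed_rates <- function(orientation, i, j, params) {
  r <- lm_growth_rates(i, j, params)
  if (orientation == "V") c(up = unname(r["v_plus"]), down = unname(r["v_minus"]))
  else if (orientation == "H") c(right = unname(r["h_plus"]), left = unname(r["h_minus"]))
  else stop("orientation must be 'V' or 'H'")
}

#' Neighborhood-averaged rotation probability
#'
#' The displacing daughter of a dividing mother rotates with a probability
#' equal to the arithmetic mean of the mother's intrinsic rotation
#' probability and those of her existing Moore (8-)neighbors; at the lattice
#' boundary the average runs over the neighbors that exist. When all
#' neighbors share the mother's strain this reduces to the strain's own
#' `p_rot`.
#'
#' @param state A `"lattice_state"`.
#' @param site Integer vector `c(i, j)`.
#' @param params An [lm_params()] object.
#' @param time Model time used to select pre- vs post-induction
#'   probabilities; defaults to `state$time`.
#' @return The effective rotation probability.
#' @export
lm_rotation_prob <- function(state, site, params, time = state$time) {
  M <- params$M; N <- params$N
  i <- site[1]; j <- site[2]
  if (i < 1 || i > M || j < 1 || j > N) stop("site outside the lattice")
  p <- if (time >= params$induction_time) params$p_rot_post else params$p_rot
  ii <- max(1, i - 1):min(M, i + 1)
  jj <- max(1, j - 1):min(N, j + 1)
  mean(p[state$strain[ii, jj, drop = FALSE]])
}

dir_delta <- function(direction) {
  switch(direction, up = c(1L, 0L), down = c(-1L, 0L),
         right = c(0L, 1L), left = c(0L, -1L),
         stop("unknown direction: ", direction))
}

#' Apply a division event to a lattice state
#'
#' The in-place daughter keeps the mother's site and orientation. The
#' displacing daughter occupies the adjacent site in the division direction
#' with `daughter_orientation`; every cell from that site to the boundary
#' shifts one site in the same direction, and the cell shifted past the
#' boundary is removed, so the lattice stays full. If the displacing
#' daughter would land outside the lattice it is discarded and no shift
#' occurs.
#'
#' @param state A `"lattice_state"`.
#' @param event List with `site = c(i, j)`, `direction` (`"up"`, `"down"`,
#'   `"left"`, `"right"`), `daughter_orientation` (`"V"`/`"H"`) and
#'   optionally `waiting_time` (advances `state$time`).
#' @return The updated `"lattice_state"`.
#' @examples
#' p <- lm_params(M = 1, N = 3)
#' st <- new_lattice_state(matrix("blue", 1, 3),
#'                         matrix(c("H", "H", "V"), 1, 3))
#' ev <- list(site = c(1, 2), direction = "right", daughter_orientation = "H")
#' lm_apply_division(st, ev)$orientation  # [H, H, H]; the V cell is removed
#' @export
lm_apply_division <- function(state, event) {
  i <- event$site[1]; j <- event$site[2]
  M <- nrow(state$strain); N <- ncol(state$strain)
  orient_m <- state$orientation[i, j]
  vertical <- event$direction %in% c("up", "down")
  if (vertical != (orient_m == "V"))
    stop("division direction inconsistent with mother orientation")
  d <- dir_delta(event$direction)
  ti <- i + d[1]; tj <- j + d[2]
  if (!is.null(event$waiting_time)) state$time <- state$time + event$waiting_time
  if (ti < 1 || ti > M || tj < 1 || tj > N) return(state)  # daughter discarded
  if (d[1] != 0) { # vertical shift in column j
    rng <- if (d[1] > 0) {
      if (ti < M) seq(M, ti + 1L) else integer(0)
    } else {
      if (ti > 1L) seq(1L, ti - 1L) else integer(0)
    }
    for (ii in rng) {
      state$strain[ii, j] <- state$strain[ii - d[1], j]
      state$orientation[ii, j] <- state$orientation[ii - d[1], j]
    }
    state$strain[ti, j] <- state$strain[i, j]
    state$orientation[ti, j] <- event$daughter_orientation
  } else {
    rng <- if (d[2] > 0) {
      if (tj < N) seq(N, tj + 1L) else integer(0)
    } else {
      if (tj > 1L) seq(1L, tj - 1L) else integer(0)
    }
    for (jj in rng) {
      state$strain[i, jj] <- state$strain[i, jj - d[2]]
      state$orientation[i, jj] <- state$orientation[i, jj - d[2]]
    }
    state$strain[i, tj] <- state$strain[i, j]
    state$orientation[i, tj] <- event$daughter_orientation
  }
  state
}

lm_rate_matrix <- function(state, params) {
  M <- params$M; N <- params$N
  iv <- seq_len(M); jv <- seq_len(N)
  vsum <- params$lambda * (exp(-params$kappa * (M - iv)) +
                           exp(-params$kappa * (iv - 1)))
  hsum <- params$lambda * (exp(-params$kappa * (N - jv)) +
                           exp(-params$kappa * (jv - 1)))
  ifelse(state$orientation == "V",
         matrix(vsum, M, N), matrix(hsum, M, N, byrow = TRUE))
}

#' Draw and apply one Gillespie event
#'
#' Draws the exponential waiting time from the sum of all exposed directional
#' rates, picks a division event proportionally to its rate, flips the
#' displacing daughter's orientation with the neighborhood-averaged rotation
#' probability, and applies the division. Uses R's RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param state A full `"lattice_state"`.
#' @param params An [lm_params()] object.
#' @return List with the updated `state`, the `event` (site, direction,
#'   daughter_orientation, rotated, waiting_time), and `dt`.
#' @export
lm_gillespie_step <- function(state, params) {
  rates <- lm_rate_matrix(state, params)
  R <- sum(rates)
  if (R <= 0) stop("total event rate is not positive")
  dt <- stats::rexp(1, R)
  idx <- sample.int(length(rates), 1L, prob = as.vector(rates))
  M <- params$M
  i <- ((idx - 1L) %% M) + 1L
  j <- ((idx - 1L) %/% M) + 1L
  orient_m <- state$orientation[i, j]
  ex <- lm_exposed_rates(orient_m, i, j, params)
  direction <- names(ex)[sample.int(2L, 1L, prob = ex)]
  t_event <- state$time + dt
  p_eff <- lm_rotation_prob(state, c(i, j), params, time = t_event)
  rotated <- stats::runif(1) < p_eff
  d_orient <- if (rotated) setdiff(c("V", "H"), orient_m) else orient_m
  event <- list(site = c(i, j), direction = direction,
                daughter_orientation = d_orient, rotated = rotated,
                waiting_time = dt)
  state <- lm_apply_division(state, event)
  state$time <- state$time + dt
  list(state = state, event = event, dt = dt)
}

#' Mean horizontal growth propensity of a strain
#'
#' The propensity of strain `k` to displace cells horizontally:
#' `(1 / sigma_k) * sum(h+(j) + h-(j))` over the horizontally oriented cells
#' of strain `k`, where `sigma_k` counts all cells of strain `k`. This is the
#' lattice-model counterpart of the cooperative lateral bulk force in the
#' agent-based model.
#'
#' @param state A `"lattice_state"`.
#' @param strain `"blue"` or `"orange"`.
#' @param params An [lm_params()] object.
#' @return The mean horizontal growth propensity (0 if the strain has no
#'   horizontal cells).
#' @export
lm_horizontal_propensity <- function(state, strain, params) {
  strain <- match.arg(strain, c("blue", "orange"))
  sigma <- sum(state$strain == strain)
  if (sigma == 0) stop("strain '", strain, "' absent from the lattice")
  sel <- state$strain == strain & state$orientation == "H"
  if (!any(sel)) return(0)
  jv <- seq_len(params$N)
  hsum <- params$lambda * (exp(-params$kappa * (params$N - jv)) +
                           exp(-params$kappa * (jv - 1)))
  hmat <- matrix(hsum, params$M, params$N, byrow = TRUE)
  sum(hmat[sel]) / sigma
}
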