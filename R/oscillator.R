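#' Parameters of the reduced strain-fraction oscillator
#'
#' Two-variable fast-slow caricature of the consortial relay: `x` is the
#' fraction of one strain and `Q` a fast switch tracking which strain
#' currently grows faster. The strain fraction obeys
#' `dx/dt = Q * x - (1 - Q) * (1 - x)` and the switch relaxes on the fast
#' time scale `eps` toward Hill switching functions of `x`:
#' `dQ/dt = (1/eps) * (-Q * L1(x) + (1 - Q) * L2(x))` with
#' `L1(x) = 1 / (1 + ((1 - x) / (1 - K2))^n)` (switch off as `x` nears `K2`)
#' and `L2(x) = 1 / (1 + (x / K1)^n)` (switch on as `x` falls to `K1`).
#' For `K1 < K2` and large `n` the fraction relaxes between the two
#' thresholds, giving a limit cycle; for `K1 > K2` both switching regions
#' overlap and no oscillation occurs.
#'
#' @param K1,K2 Lower and upper switching thresholds in `(0, 1)`.
#' @param n Hill exponent (sharpness of the switch).
#' @param eps Fast-variable time-scale separation (> 0).
#' @param x0,Q0 Initial conditions.
#' @return An object of class `"osc_params"`.
#' @examples
#' osc_params(K1 = 0.2, K2 = 0.8)
#' @export
osc_params <- function(K1 = 0.2, K2 = 0.8, n = 8, eps = 1e-3,
                       x0 = 0.5, Q0 = 0) {
  stopifnot(is.numeric(K1), is.numeric(K2), n >= 1, eps > 0,
            x0 >= 0, x0 <= 1, Q0 >= 0, Q0 <= 1)
  if (K1 <= 0 || K1 >= 1 || K2 <= 0 || K2 >= 1)
    stop("`K1` and `K2` must lie strictly inside (0, 1)")
  structure(list(K1 = K1, K2 = K2, n = n, eps = eps, x0 = x0, Q0 = Q0),
            class = "osc_params")
}

#' Hill switching functions of the reduced oscillator
#'
#' @param x Strain fraction(s) in `[0, 1]`.
#' @param params An [osc_params()] object.
#' @return A list with vectors `L1` (off-switch) and `L2` (on-switch).
#' @examples
#' hill_switches(c(0.2, 0.5, 0.8), osc_params())
#' @export
hill_switches <- function(x, params) {
  stopifnot(all(x >= 0), all(x <= 1))
  list(L1 = 1 / (1 + ((1 - x) / (1 - params$K2))^params$n),
       L2 = 1 / (1 + (x / params$K1)^params$n))
}

#' Right-hand side of the reduced oscillator
#'
#' In the signature expected by [deSolve::ode()].
#'
#' @param t Time (unused; autonomous system).
#' @param state Named numeric `c(x=, Q=)`.
#' @param params An [osc_params()] object.
#' @return A list whose first element is `c(dx, dQ)`.
#' @export
osc_rhs <- function(t, state, params) {
  x <- state[["x"]]; Q <- state[["Q"]]
  L <- hill_switches(min(max(x, 0), 1), params)
  dx <- Q * x - (1 - Q) * (1 - x)
  dQ <- (-Q * L$L1 + (1 - Q) * L$L2) / params$eps
  list(c(dx, dQ))
}

#' Integrate the reduced oscillator
#'
#' Stiff integration (the switch relaxes on the `eps` time scale) with
#' `deSolve`'s `lsoda`.
#'
#' @param params An [osc_params()] object.
#' @param t_end Integration horizon (model time units).
#' @param dt Output interval.
#' @return A data frame with columns `t`, `x`, `Q`.
#' @examples
#' head(osc_integrate(osc_params(), t_end = 1))
#' @export
osc_integrate <- function(params, t_end = 20, dt = 0.001) {
  stopifnot(inherits(params, "osc_params"), t_end > 0, dt > 0)
  sol <- deSolve::ode(y = c(x = params$x0, Q = params$Q0),
                      times = seq(0, t_end, by = dt),
                      func = osc_rhs, parms = params,
                      rtol = 1e-8, atol = 1e-10)
  data.frame(t = sol[, "time"], x = sol[, "x"], Q = sol[, "Q"])
}

#' Measure the oscillation period from a trajectory
#'
#' Detects upward crossings of the switch variable `Q` through 1/2 (with
#' linear interpolation) and returns the mean spacing of consecutive
#' crossings, discarding the first crossing as transient.
#'
#' @param traj A data frame from [osc_integrate()].
#' @return The period.
#' @export
measure_period <- function(traj) {
  q <- traj$Q; t <- traj$t
  up <- which(q[-length(q)] < 0.5 & q[-1] >= 0.5)
  if (length(up) < 3)
    stop("fewer than two full cycles detected; increase `t_end`")
  tc <- t[up] + (0.5 - q[up]) / (q[up + 1] - q[up]) * (t[up + 1] - t[up])
  tc <- tc[-1]
  mean(diff(tc))
}

#' Closed-form period in the sharp-switch limit
#'
#' In the limit `n -> Inf`, `eps -> 0`, the fraction relaxes exponentially
#' between the thresholds and the period is
#' `ln(K2 / K1) + ln((1 - K1) / (1 - K2))`.
#'
#' @param params An [osc_params()] object.
#' @return The limiting period.
#' @examples
#' osc_period_limit(osc_params(K1 = 0.2, K2 = 0.8)) # 2 * log(4)
#' @export
osc_period_limit <- function(params) {
  if (params$K1 >= params$K2)
    stop("no limit cycle: requires K1 < K2")
  log(params$K2 / params$K1) + log((1 - params$K1) / (1 - params$K2))
}
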