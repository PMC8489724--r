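#' Nematic order parameter
#'
#' For axis angles `phi` (radians, nematic: `phi` and `phi + pi` are the same
#' orientation), `q = sqrt(mean(cos 2 phi)^2 + mean(sin 2 phi)^2)`: 1 for
#' perfect common alignment, near 0 for isotropic angles.
#'
#' @param phi Numeric vector of angles, radians.
#' @param weights Optional non-negative weights (e.g. cell lengths).
#' @return The order parameter in `[0, 1]`.
#' @examples
#' order_parameter(rep(pi / 2, 10))          # 1
#' order_parameter(c(0, pi / 2))             # 0
#' @export
order_parameter <- function(phi, weights = NULL) {
  if (length(phi) == 0) stop("`phi` must contain at least one angle")
  if (is.null(weights)) weights <- rep(1, length(phi))
  stopifnot(length(weights) == length(phi), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  sqrt(sum(w * cos(2 * phi))^2 + sum(w * sin(2 * phi))^2)
}

#' Order parameter within a trap region
#'
#' @param cells A cell table (see [new_cells()]).
#' @param geometry A [trap_geometry()].
#' @param region `"bulk"`, `"edge_left"` or `"edge_right"` (see
#'   [region_boxes()]).
#' @param weighted Weight each cell by its length.
#' @return The order parameter, or `NA` if the region is empty.
#' @export
region_q <- function(cells, geometry, region = "bulk", weighted = FALSE) {
  region <- match.arg(region, c("bulk", "edge_left", "edge_right"))
  b <- region_boxes(geometry)[[region]]
  sel <- cells$x >= b$xmin & cells$x <= b$xmax &
         cells$y >= b$ymin & cells$y <= b$ymax
  if (!any(sel)) return(NA_real_)
  order_parameter(cells$phi[sel],
                  weights = if (weighted) cells$l[sel] else NULL)
}

#' Space-time kymograph of order or axial force
#'
#' Bins the recorded per-cell snapshots of an agent-based trajectory into
#' vertical columns of width `bin_width` um and computes, per time sample and
#' column, either the local nematic order parameter or the mean horizontal
#' component of the axial contact force,
#' `F_x = mean(F_axial * |cos phi|)` (the growth-expansion force projected on
#' the trap's long axis; the absolute value respects nematic symmetry).
#'
#' @param trajectory An [abm_simulate()] result run with
#'   `record_cells = TRUE`.
#' @param statistic `"q"` or `"F_x"`.
#' @param bin_width Column width, um (default 1).
#' @return A list: `t` (sample times), `x` (column centers), `z` (matrix
#'   time x column; `NA` where a column is empty).
#' @export
kymograph <- function(trajectory, statistic = "q", bin_width = 1) {
  statistic <- match.arg(statistic, c("q", "F_x"))
  cells <- trajectory$cells
  if (is.null(cells)) stop("run `abm_simulate()` with `record_cells = TRUE`")
  W <- trajectory$params$geometry$width
  edges <- seq(0, W, by = bin_width)
  if (edges[length(edges)] < W) edges <- c(edges, W)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  tt <- sort(unique(cells$t))
  z <- matrix(NA_real_, length(tt), length(centers))
  for (k in seq_along(tt)) {
    d <- cells[cells$t == tt[k], , drop = FALSE]
    bin <- findInterval(d$x, edges, rightmost.closed = TRUE)
    for (j in unique(bin[bin >= 1 & bin <= length(centers)])) {
      sel <- bin == j
      z[k, j] <- if (statistic == "q") order_parameter(d$phi[sel]) else
        mean(d$F_axial[sel] * abs(cos(d$phi[sel])))
    }
  }
  list(t = tt, x = centers, z = z)
}

#' Strain-fraction time series of a trajectory
#'
#' @param trajectory An `"lm_trajectory"` or `"abm_trajectory"`.
#' @return A data frame with columns `t` and `frac_orange`.
#' @export
strain_fraction_series <- function(trajectory) {
  s <- trajectory$summary
  data.frame(t = s$t, frac_orange = s$frac_orange)
}

#' Fit the exponential takeover rate of a strain-fraction trajectory
#'
#' Two regimes are supported for the fraction `f(t)` of the advantaged
#' (shorter) strain starting from `f(t0) = 1/2`:
#' \describe{
#'   \item{`"invasion"`}{saturating takeover `f = 1 - 0.5 * exp(-alpha *
#'     (t - t0))`, fitted from `t0` to the first time `f >= f_max`
#'     (default 0.95) to avoid the flat saturated tail.}
#'   \item{`"growth"`}{early exponential departure `f = 0.5 * exp(alpha *
#'     (t - t0))`, fitted on the window `[t0, t0 + window]`.}
#' }
#' Nonlinear least squares via [minpack.lm::nlsLM()].
#'
#' @param t,f Time and fraction vectors.
#' @param mode `"invasion"` or `"growth"`.
#' @param t0 Start of the fitting window (induction time).
#' @param f_max Saturation cutoff for `"invasion"`.
#' @param window Window length for `"growth"`.
#' @return A list: `alpha`, `r_squared`, `n` (points used), `fitted`
#'   (data frame `t`, `f`, `fit`), `mode`.
#' @export
fit_alpha <- function(t, f, mode = "invasion", t0 = 0, f_max = 0.95,
                      window = 1) {
  mode <- match.arg(mode, c("invasion", "growth"))
  stopifnot(length(t) == length(f))
  if (mode == "invasion") {
    hit <- which(t >= t0 & f >= f_max)
    t_hi <- if (length(hit)) t[hit[1]] else max(t)
    sel <- t >= t0 & t <= t_hi
    form <- f ~ 1 - 0.5 * exp(-alpha * (t - t0))
  } else {
    sel <- t >= t0 & t <= t0 + window
    form <- f ~ 0.5 * exp(alpha * (t - t0))
  }
  ts <- t[sel]; fs <- f[sel]
  if (length(ts) < 5) stop("fewer than 5 points in the fitting window")
  fit <- minpack.lm::nlsLM(form, data = data.frame(t = ts, f = fs),
                           start = list(alpha = 1),
                           lower = 0, control = list(maxiter = 200))
  pred <- stats::predict(fit)
  ss_res <- sum((fs - pred)^2)
  ss_tot <- sum((fs - mean(fs))^2)
  list(alpha = unname(stats::coef(fit)["alpha"]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(ts),
       fitted = data.frame(t = ts, f = fs, fit = pred),
       mode = mode)
}

#' Relation between the takeover rate and a control parameter
#'
#' Given takeover rates `alpha` measured at several values of a control
#' parameter, reports whether the relation is monotone and fits either a
#' straight line or an exponential trend `alpha = A * exp(B * param)` on the
#' log scale.
#'
#' @param param Numeric vector of parameter values (sorted or not).
#' @param alpha Matching takeover rates (> 0 for `"exponential"`).
#' @param relation `"linear"` or `"exponential"`.
#' @return A list: `monotone` (`"increasing"`, `"decreasing"` or `"no"`),
#'   `coef` (intercept and slope of the fit; on the log scale for
#'   `"exponential"`), `r_squared`.
#' @export
alpha_vs_parameter <- function(param, alpha, relation = "linear") {
  relation <- match.arg(relation, c("linear", "exponential"))
  stopifnot(length(param) == length(alpha), length(param) >= 3)
  o <- order(param)
  p <- param[o]; a <- alpha[o]
  monotone <- if (all(diff(a) > 0)) "increasing" else
    if (all(diff(a) < 0)) "decreasing" else "no"
  y <- if (relation == "exponential") {
    if (any(a <= 0)) stop("`alpha` must be > 0 for an exponential fit")
    log(a)
  } else a
  fit <- stats::lm(y ~ p)
  list(monotone = monotone,
       coef = unname(stats::coef(fit)),
       r_squared = summary(fit)$r.squared)
}
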