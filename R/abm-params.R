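#' Strain-level parameters for the agent-based model
#'
#' @param l_d_bar Mean division length, um. The target division length of a
#'   daughter born at length `l0` is `sqrt(2 * l0 * l_d_bar)`, so a strain's
#'   average length at division fluctuates around `l_d_bar`.
#' @param a Division-length reduction factor in `(0, 1]` applied while the
#'   strain is induced (externally or by quorum sensing); `a = 1` disables
#'   reduction. The biologically motivated range is 0.6-0.85.
#' @param doubling_time Exponential length doubling time, minutes.
#' @return An object of class `"strain_params"`.
#' @examples
#' strain_params(l_d_bar = 4.2, a = 0.6)
#' @export
strain_params <- function(l_d_bar = 4.2, a = 1, doubling_time = 20) {
  if (!is.numeric(l_d_bar) || l_d_bar <= 1)
    stop("`l_d_bar` must exceed the 1 um cell width")
  if (!is.numeric(a) || a <= 0 || a > 1) stop("`a` must lie in (0, 1]")
  if (doubling_time <= 0) stop("`doubling_time` must be > 0")
  structure(list(l_d_bar = l_d_bar, a = a, doubling_time = doubling_time),
            class = "strain_params")
}

#' Open microfluidic trap geometry
#'
#' A monolayer rectangular trapping region, open on all four sides: cells
#' whose center crosses the boundary are washed away by the flow channels.
#' Bulk and edge analysis sub-regions are full-height strips defined as
#' fractions of the trap width: the edges are the leftmost and rightmost
#' `edge_frac` strips and the bulk is the central `bulk_frac` strip
#' (defaults mirror 15 um edges and a 40 um bulk in the 100 um trap).
#'
#' @param width,height Trap dimensions in um (default 100 x 20).
#' @param edge_frac,bulk_frac Fractions of the width used for the edge and
#'   bulk analysis strips.
#' @return An object of class `"trap_geometry"`.
#' @examples
#' region_boxes(trap_geometry(width = 50, height = 20))
#' @export
trap_geometry <- function(width = 100, height = 20, edge_frac = 0.15,
                          bulk_frac = 0.40) {
  stopifnot(width > 0, height > 0, edge_frac > 0, bulk_frac > 0,
            2 * edge_frac + bulk_frac <= 1)
  structure(list(width = width, height = height, edge_frac = edge_frac,
                 bulk_frac = bulk_frac),
            class = "trap_geometry")
}

#' Analysis regions of a trap
#'
#' @param geometry A [trap_geometry()] object.
#' @return A list of rectangles (`xmin`, `xmax`, `ymin`, `ymax`) named
#'   `bulk`, `edge_left`, `edge_right`.
#' @export
region_boxes <- function(geometry) {
  W <- geometry$width; H <- geometry$height
  e <- geometry$edge_frac * W
  b <- geometry$bulk_frac * W
  list(bulk = list(xmin = (W - b) / 2, xmax = (W + b) / 2, ymin = 0, ymax = H),
       edge_left = list(xmin = 0, xmax = e, ymin = 0, ymax = H),
       edge_right = list(xmin = W - e, xmax = W, ymin = 0, ymax = H))
}

#' Parameters for the agent-based simulation
#'
#' Bundles the trap geometry, the two strain parameter sets, the simplified
#' Hookean contact-mechanics constants, the induction schedule and the
#' optional quorum-sensing circuit.
#'
#' The contact scheme applies a linear repulsive force proportional to the
#' overlap depth between the closest points of two cells' axis segments, with
#' torque, and relaxes positions and angles by overdamped first-order updates
#' until the maximum pairwise overlap falls below `tol` or `max_iter`
#' relaxation sweeps have run.
#'
#' @param geometry A [trap_geometry()].
#' @param blue,orange [strain_params()] for the two strains (single-strain
#'   runs use `blue` only).
#' @param dt Update-cycle time step, minutes.
#' @param k_n Contact stiffness (force units per um of overlap).
#' @param zeta Translational drag coefficient per unit cell length.
#' @param tol Relaxation tolerance: maximum residual overlap, um.
#' @param max_iter Relaxation sweep cap per time step.
#' @param noise_sd Standard deviation of the angular jitter (radians) given
#'   to daughters at division, breaking perfect-alignment symmetry.
#' @param induce_time Named numeric `c(blue=, orange=)`: times (minutes) at
#'   which each strain's division-length reduction is switched on externally
#'   (`Inf` = never).
#' @param qs Optional [qs_params()] circuit; `NULL` disables signaling.
#' @param cap Hard population cap; exceeding it aborts with status
#'   `"runaway"`.
#' @param sample_dt Sampling interval, minutes (default 10 = twice per
#'   20-minute generation).
#' @return An object of class `"abm_params"`.
#' @export
abm_params <- function(geometry = trap_geometry(),
                       blue = strain_params(),
                       orange = strain_params(),
                       dt = 0.02, k_n = 100, zeta = 100, tol = 0.05,
                       max_iter = 50, noise_sd = 0.02,
                       induce_time = c(blue = Inf, orange = Inf),
                       qs = NULL, cap = 20000L, sample_dt = 10) {
  stopifnot(inherits(geometry, "trap_geometry"),
            inherits(blue, "strain_params"), inherits(orange, "strain_params"),
            dt > 0, k_n > 0, zeta > 0, tol > 0, max_iter >= 1, noise_sd >= 0,
            sample_dt > 0)
  induce_time <- check_induce(induce_time)
  if (!is.null(qs)) stopifnot(inherits(qs, "qs_params"))
  structure(list(geometry = geometry, blue = blue, orange = orange, dt = dt,
                 k_n = k_n, zeta = zeta, tol = tol, max_iter = max_iter,
                 noise_sd = noise_sd, induce_time = induce_time, qs = qs,
                 cap = as.integer(cap), sample_dt = sample_dt),
            class = "abm_params")
}

check_induce <- function(x) {
  if (length(x) == 1L) x <- c(blue = unname(x), orange = unname(x))
  if (is.null(names(x))) names(x) <- c("blue", "orange")
  x <- x[c("blue", "orange")]
  if (anyNA(x)) stop("`induce_time` must be named blue/orange")
  x
}

#' @export
print.abm_params <- function(x, ...) {
  cat("Agent-based model parameters\n")
  cat(sprintf("  trap: %g x %g um; dt = %g min; sample every %g min\n",
              x$geometry$width, x$geometry$height, x$dt, x$sample_dt))
  cat(sprintf("  blue:   l_d_bar = %g um, a = %g\n", x$blue$l_d_bar, x$blue$a))
  cat(sprintf("  orange: l_d_bar = %g um, a = %g\n",
              x$orange$l_d_bar, x$orange$a))
  cat(sprintf("  mechanics: k_n = %g, zeta = %g, tol = %g um, max_iter = %d\n",
              x$k_n, x$zeta, x$tol, x$max_iter))
  cat(sprintf("  induction: blue at %g, orange at %g min; QS %s\n",
              x$induce_time["blue"], x$induce_time["orange"],
              if (is.null(x$qs)) "off" else "on"))
  invisible(x)
}
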