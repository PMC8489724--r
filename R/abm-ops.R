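#' Construct a table of spherocylinder cells
#'
#' Cells are 2D spherocylinders of constant 1 um width; `l` is the total
#' pole-to-pole length, `phi` the axis angle from horizontal in `[0, pi)`
#' (nematic identification), `l0` the birth length and `ld` the target
#' division length.
#'
#' @param x,y Center coordinates, um.
#' @param phi Angles from horizontal, radians.
#' @param l Lengths, um (> width of 1 um for a well-formed rod).
#' @param strain `"blue"` or `"orange"` (recycled).
#' @param l0 Birth lengths (default `l / 2`).
#' @param ld Target division lengths (default computed for `l_d_bar`).
#' @param l_d_bar Mean division length used for default targets.
#' @return A `data.frame` with one row per cell.
#' @examples
#' new_cells(x = c(2, 6), y = 10, phi = pi / 2, l = 3, strain = "blue")
#' @export
new_cells <- function(x, y, phi, l, strain = "blue", l0 = l / 2, ld = NULL,
                      l_d_bar = 4.2) {
  n <- max(length(x), length(y), length(phi), length(l))
  d <- data.frame(x = rep_len(x, n), y = rep_len(y, n),
                  phi = rep_len(phi, n) %% pi, l = rep_len(l, n),
                  l0 = rep_len(l0, n),
                  strain = rep_len(strain, n),
                  F_axial = 0, H1 = 0, H2 = 0, lacI = 0)
  d$ld <- if (is.null(ld)) sqrt(2 * d$l0 * l_d_bar) else rep_len(ld, n)
  stopifnot(all(d$l > 0), all(d$strain %in% c("blue", "orange")))
  d[, c("x", "y", "phi", "l", "l0", "ld", "strain",
        "F_axial", "H1", "H2", "lacI")]
}

strain_idx <- function(strain) match(strain, c("blue", "orange")) - 1L

#' Exponential cell growth
#'
#' Each cell's length grows exponentially, `l <- l * 2^(dt / doubling_time)`;
#' the width stays fixed at 1 um, so population area grows at a rate
#' independent of the mean cell length.
#'
#' @param cells A cell table (see [new_cells()]).
#' @param dt Time increment, minutes (>= 0).
#' @param doubling_time Doubling time(s) in minutes: a single value or a
#'   named vector `c(blue=, orange=)`.
#' @return The grown cell table.
#' @export
abm_grow <- function(cells, dt, doubling_time = 20) {
  if (dt < 0) stop("`dt` must be >= 0")
  if (length(doubling_time) == 1L)
    doubling_time <- c(blue = unname(doubling_time),
                       orange = unname(doubling_time))
  cells$l <- cells$l * 2^(dt / doubling_time[cells$strain])
  cells
}

#' Divide a cell if it has reached its target division length
#'
#' A mother of length `l` splits into daughters of birth lengths `eps0 * l`
#' and `(1 - eps0) * l`, `eps0 ~ U[0.45, 0.55]`, placed end-to-end along the
#' mother's axis inside her footprint. Each daughter's division target is
#' `sqrt(2 * l0 * l_d_bar_eff)`; intracellular species amounts split in
#' proportion to the birth lengths (equal concentrations). Uses R's RNG.
#'
#' @param cell A single-row cell table.
#' @param l_d_bar_eff The strain's current effective mean division length
#'   (reduced by the factor `a` while induced).
#' @param noise_sd Angular jitter given to each daughter (radians).
#' @return A one-row table (no division) or a two-row table of daughters.
#' @export
abm_divide_cell <- function(cell, l_d_bar_eff, noise_sd = 0.02) {
  stopifnot(nrow(cell) == 1)
  if (l_d_bar_eff <= 0) stop("`l_d_bar_eff` must be > 0")
  if (cell$l < cell$ld) return(cell)
  eps0 <- stats::runif(1, 0.45, 0.55)
  L <- cell$l
  lA <- eps0 * L; lB <- (1 - eps0) * L
  u <- c(cos(cell$phi), sin(cell$phi))
  mk <- function(len, sgn) {
    d <- cell
    d$x <- cell$x + sgn * u[1] * (L - len) / 2
    d$y <- cell$y + sgn * u[2] * (L - len) / 2
    d$phi <- (cell$phi + stats::rnorm(1, 0, noise_sd)) %% pi
    d$l <- len; d$l0 <- len
    d$ld <- sqrt(2 * len * l_d_bar_eff)
    d
  }
  out <- rbind(mk(lA, -1), mk(lB, 1))
  rownames(out) <- NULL
  out
}

#' Relax mechanical contacts between cells
#'
#' Pairwise spherocylinder contacts generate linear repulsive forces normal
#' to the contact (proportional to overlap depth), applied at the contact
#' point with torque. Positions and angles follow overdamped first-order
#' updates until the maximum overlap is below `tol` or `max_iter` sweeps ran.
#' The net inward axial contact load (growth-expansion force proxy) is
#' recorded in `F_axial`.
#'
#' @param cells A cell table.
#' @param geometry A [trap_geometry()].
#' @param k_n,zeta,tol,max_iter Mechanics constants, see [abm_params()].
#' @param seed Seed for the degenerate-contact tie-break RNG.
#' @return A list: `cells` (updated), `iterations`, `max_overlap`,
#'   `converged` (`FALSE` is flagged, the state is still returned).
#' @export
relax_mechanics <- function(cells, geometry, k_n = 100, zeta = 100,
                            tol = 0.05, max_iter = 50, seed = 1L) {
  df <- cells
  df$strain <- strain_idx(df$strain)
  res <- cpp_relax_cells(df, geometry$width, geometry$height, k_n, zeta, tol,
                         max_iter, as.integer(seed))
  out <- res$cells
  out$strain <- c("blue", "orange")[out$strain + 1L]
  out$induced <- NULL
  out <- out[, c("x", "y", "phi", "l", "l0", "ld", "strain",
                 "F_axial", "H1", "H2", "lacI")]
  list(cells = out, iterations = res$iterations,
       max_overlap = res$max_overlap, converged = res$converged)
}

#' Remove cells whose centers have left the trap
#'
#' The trap is open on all sides: a cell whose center coordinate leaves the
#' trap rectangle is carried away by the flow channels, keeping the
#' population approximately constant after filling.
#'
#' @param cells A cell table.
#' @param geometry A [trap_geometry()].
#' @return The retained cells.
#' @export
remove_exited <- function(cells, geometry) {
  keep <- cells$x >= 0 & cells$x <= geometry$width &
          cells$y >= 0 & cells$y <= geometry$height
  cells[keep, , drop = FALSE]
}

#' Effective mean division length under the threshold controller
#'
#' While a cell's intracellular concentration of the opposite strain's
#' quorum-sensing signal strictly exceeds the threshold `H_T` (or the strain
#' is under external induction), the strain's mean division length is reduced
#' by the factor `a`.
#'
#' @param cells A cell table.
#' @param params An [abm_params()] object.
#' @param time Current model time, minutes.
#' @return Numeric vector of per-cell effective mean division lengths.
#' @export
effective_l_d_bar <- function(cells, params, time = 0) {
  sp <- list(blue = params$blue, orange = params$orange)
  ldbar <- vapply(sp, `[[`, numeric(1), "l_d_bar")[cells$strain]
  afac <- vapply(sp, `[[`, numeric(1), "a")[cells$strain]
  exo <- time >= params$induce_time[cells$strain]
  qs_on <- FALSE
  if (!is.null(params$qs)) {
    h_opp <- ifelse(cells$strain == "blue", cells$H2, cells$H1)
    qs_on <- h_opp > params$qs$H_T
  }
  ifelse(exo | qs_on, afac * ldbar, ldbar)
}

#' Induce division-length reduction in a strain
#'
#' Applies a strain's reduction factor from a given time onward and
#' recomputes the division targets of live cells from their stored birth
#' lengths; cells already beyond the new target divide at the next division
#' check.
#'
#' @param cells A cell table.
#' @param params An [abm_params()] object (supplies `a` and `l_d_bar`).
#' @param strain `"blue"` or `"orange"`.
#' @return The cell table with updated `ld` targets.
#' @export
induce_length_reduction <- function(cells, params, strain = "orange") {
  strain <- match.arg(strain, c("blue", "orange"))
  sp <- params[[strain]]
  sel <- cells$strain == strain
  cells$ld[sel] <- sqrt(2 * cells$l0[sel] * sp$a * sp$l_d_bar)
  cells
}

#' One agent-based update cycle
#'
#' Applies, in order: exponential growth, division-target refresh and
#' divisions (random processing order), mechanical relaxation, removal of
#' exited cells and (when configured) the quorum-sensing update. This is the
#' reference composition of the individual operations; long simulations use
#' the compiled loop in [abm_simulate()].
#'
#' @param state List with elements `cells`, `time` and (if QS is active)
#'   `external` (see [qs_external()]).
#' @param params An [abm_params()] object.
#' @param dt Time step (defaults to `params$dt`).
#' @return The updated state.
#' @export
step_abm <- function(state, params, dt = params$dt) {
  if (dt > params$dt + 1e-12) stop("`dt` exceeds the configured maximum step")
  cells <- state$cells
  if (nrow(cells) == 0) { state$time <- state$time + dt; return(state) }
  doubling <- c(blue = params$blue$doubling_time,
                orange = params$orange$doubling_time)
  cells <- abm_grow(cells, dt, doubling)
  lde <- effective_l_d_bar(cells, params, state$time)
  cells$ld <- sqrt(2 * cells$l0 * lde)
  ready <- which(cells$l >= cells$ld)
  if (length(ready)) {
    ready <- sample(ready)
    pieces <- vector("list", length(ready))
    for (k in seq_along(ready))
      pieces[[k]] <- abm_divide_cell(cells[ready[k], , drop = FALSE],
                                     lde[ready[k]], params$noise_sd)
    cells <- rbind(cells[-ready, , drop = FALSE], do.call(rbind, pieces))
  }
  if (nrow(cells) > params$cap) stop("population exceeded the hard cap")
  rel <- relax_mechanics(cells, params$geometry, params$k_n, params$zeta,
                         params$tol, params$max_iter,
                         seed = sample.int(.Machine$integer.max, 1))
  cells <- remove_exited(rel$cells, params$geometry)
  if (!is.null(params$qs)) {
    ext <- state$external %||% qs_external()
    # external flux uses the pre-update intracellular concentrations
    new_ext <- update_external(cells, ext, dt, params$qs,
                               trap_area = params$geometry$width *
                                 params$geometry$height)
    cells <- update_intracellular(cells, ext, dt, params$qs)
    state$external <- new_ext
  }
  state$cells <- cells
  state$time <- state$time + dt
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
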