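#' Quorum-sensing circuit parameters
#'
#' Two orthogonal acyl-homoserine-lactone signals are used: molecule 1
#' (C4HSL, produced by the blue strain) and molecule 2 (C14HSL, produced by
#' the orange strain). Each cell produces its own molecule at rate `alpha`
#' under Hill repression by its LacI level; signals cross the membrane with
#' first-order kinetics at per-molecule rate `d` (the smaller C4HSL exchanges
#' faster by default, the source of oscillation asymmetry); the trap-averaged
#' external pool exchanges with a well-mixed flow-channel compartment which
#' is diluted at rate `gamma`. The received (opposite-strain) signal
#' activates LacI via a Hill function, and while it strictly exceeds the
#' threshold `H_T` the receiving strain's mean division length is reduced by
#' its factor `a`, closing the co-repressive negative-feedback loop.
#'
#' All rates are per minute; concentrations are in arbitrary units. The
#' defaults are calibrated to give sustained strain-fraction oscillations in
#' a reduced trap (see the methods vignette): the LacI turnover `delta_L` is
#' fast enough that a strain's signal output tracks its population, and the
#' threshold `H_T` sits just above the 50/50 operating level of the external
#' signals, so only a majority strain's signal induces the (minority)
#' receiving strain to shorten and counter-invade.
#'
#' @param alpha Production rates `c(blue, orange)` of each strain's own
#'   molecule.
#' @param d Membrane exchange rates `c(C4HSL, C14HSL)`.
#' @param k_ex Trap-to-channel exchange rate.
#' @param k_ex_channel Channel-side exchange rate.
#' @param gamma Channel dilution rate due to media flow.
#' @param K_L,m_L LacI repression constant and Hill exponent on own-signal
#'   production.
#' @param K_H,m_H Activation constant and Hill exponent of the received
#'   signal on LacI.
#' @param beta,delta_L LacI maximal production and decay rates.
#' @param H_T Threshold concentration of the received signal that triggers
#'   division-length reduction (strict inequality).
#' @return An object of class `"qs_params"`.
#' @export
qs_params <- function(alpha = c(blue = 6, orange = 6),
                      d = c(C4HSL = 2, C14HSL = 1),
                      k_ex = 0.5, k_ex_channel = 0.5, gamma = 1,
                      K_L = 2, m_L = 2, K_H = 1, m_H = 2,
                      beta = 1, delta_L = 1, H_T = 9) {
  stopifnot(all(alpha >= 0), all(d >= 0), k_ex >= 0, k_ex_channel >= 0,
            gamma >= 0, K_L > 0, m_L >= 1, K_H > 0, m_H >= 1, beta >= 0,
            delta_L >= 0, H_T > 0)
  structure(list(alpha = unname(alpha), d = unname(d), k_ex = k_ex,
                 k_ex_channel = k_ex_channel, gamma = gamma, K_L = K_L,
                 m_L = m_L, K_H = K_H, m_H = m_H, beta = beta,
                 delta_L = delta_L, H_T = H_T),
            class = "qs_params")
}

#' External signal compartments
#'
#' @param H_trap Trap-averaged external concentrations `c(C4HSL, C14HSL)`.
#' @param H_channel Flow-channel concentrations `c(C4HSL, C14HSL)`.
#' @return An object of class `"qs_external"`.
#' @export
qs_external <- function(H_trap = c(0, 0), H_channel = c(0, 0)) {
  stopifnot(all(H_trap >= 0), all(H_channel >= 0))
  structure(list(H_trap = unname(H_trap), H_channel = unname(H_channel)),
            class = "qs_external")
}

#' Update intracellular signal and LacI concentrations
#'
#' Forward-Euler update of the per-cell ODEs over one step: production of the
#' own molecule at rate `alpha / (1 + (LacI/K_L)^m_L)`, first-order membrane
#' exchange `d * (H_e - H)` for both molecules, and LacI dynamics
#' `beta * H_opp^m_H / (K_H^m_H + H_opp^m_H) - delta_L * LacI` driven by the
#' received opposite-strain signal. Negative values arising from too large a
#' step are clipped to zero with a warning.
#'
#' @param cells A cell table with columns `H1`, `H2`, `lacI`, `strain`.
#' @param external A [qs_external()] object.
#' @param dt Time step, minutes (> 0).
#' @param params A [qs_params()] object.
#' @return The updated cell table.
#' @export
update_intracellular <- function(cells, external, dt, params) {
  if (dt <= 0) stop("`dt` must be > 0")
  s <- strain_idx(cells$strain) # 0 blue produces H1, 1 orange produces H2
  rep_own <- 1 / (1 + (cells$lacI / params$K_L)^params$m_L)
  alpha <- params$alpha[s + 1L]
  He <- external$H_trap
  prod1 <- ifelse(s == 0L, alpha * rep_own, 0)
  prod2 <- ifelse(s == 1L, alpha * rep_own, 0)
  dH1 <- prod1 + params$d[1] * (He[1] - cells$H1)
  dH2 <- prod2 + params$d[2] * (He[2] - cells$H2)
  h_opp <- ifelse(s == 0L, cells$H2, cells$H1)
  hill <- h_opp^params$m_H / (params$K_H^params$m_H + h_opp^params$m_H)
  dL <- params$beta * hill - params$delta_L * cells$lacI
  cells$H1 <- cells$H1 + dt * dH1
  cells$H2 <- cells$H2 + dt * dH2
  cells$lacI <- cells$lacI + dt * dL
  if (any(cells$H1 < 0 | cells$H2 < 0 | cells$lacI < 0)) {
    warning("negative concentrations clipped to 0; reduce the step size")
    cells$H1 <- pmax(cells$H1, 0)
    cells$H2 <- pmax(cells$H2, 0)
    cells$lacI <- pmax(cells$lacI, 0)
  }
  cells
}

#' Update the external signal compartments
#'
#' The trap pool receives the area-weighted membrane flux from all cells and
#' exchanges with the flow channel, which is diluted at rate `gamma`:
#' `dH_trap/dt = sum(area_k * d * (H_k - H_trap)) / A_trap -
#'  k_ex * (H_trap - H_channel)` and
#' `dH_channel/dt = k_ex_channel * (H_trap - H_channel) - gamma * H_channel`.
#'
#' @inheritParams update_intracellular
#' @param trap_area Trap area in um^2 used to convert total membrane flux to
#'   a concentration rate.
#' @return The updated [qs_external()] object.
#' @export
update_external <- function(cells, external, dt, params, trap_area = 2000) {
  if (dt <= 0) stop("`dt` must be > 0")
  He <- external$H_trap; Hc <- external$H_channel
  area <- cells$l * 1 # width 1 um
  for (m in 1:2) {
    Hm <- if (m == 1) cells$H1 else cells$H2
    flux <- sum(area * params$d[m] * (Hm - He[m])) / trap_area
    dHe <- flux - params$k_ex * (He[m] - Hc[m])
    dHc <- params$k_ex_channel * (He[m] - Hc[m]) - params$gamma * Hc[m]
    external$H_trap[m] <- max(0, He[m] + dt * dHe)
    external$H_channel[m] <- max(0, Hc[m] + dt * dHc)
  }
  external
}

#' Threshold controller for division length
#'
#' Returns the effective mean division length of a single cell: `a * l_d_bar`
#' while the intracellular concentration of the opposite strain's signal
#' strictly exceeds `H_T`, else `l_d_bar` (evaluated every step; equality at
#' the threshold leaves the length unreduced).
#'
#' @param cell A single-row cell table.
#' @param params A [qs_params()] object.
#' @param l_d_bar,a The strain's baseline mean division length and reduction
#'   factor.
#' @return The effective mean division length.
#' @export
threshold_controller <- function(cell, params, l_d_bar = 4.2, a = 0.6) {
  stopifnot(nrow(cell) == 1)
  h_opp <- if (cell$strain == "blue") cell$H2 else cell$H1
  if (h_opp > params$H_T) a * l_d_bar else l_d_bar
}
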