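#' Simulate the lattice model
#'
#' Runs the event-driven (Gillespie) lattice simulation in compiled code from
#' an initial fully occupied state to `t_end`, switching the per-strain
#' rotation probabilities at `params$induction_time` and recording strain
#' fraction, horizontal fraction, nematic order `q = |2 f_H - 1|` and the
#' per-strain mean horizontal growth propensities at every sampling time.
#'
#' @param params An [lm_params()] object.
#' @param init Initial `"lattice_state"`; if `NULL`, seeded with
#'   [lm_seed()] using `mode`/`orientation`.
#' @param t_end End time (model time units); must be at least
#'   `params$induction_time` when the induced probabilities differ.
#' @param sample_dt Sampling interval.
#' @param seed Integer seed for the simulation RNG (also used for seeding
#'   when `init` is `NULL`).
#' @param mode,orientation Passed to [lm_seed()] when `init` is `NULL`.
#' @param record_grids If `TRUE`, keep the full strain/orientation grids at
#'   every sampling time.
#' @return An object of class `"lm_trajectory"`: a list with `summary` (data
#'   frame of per-sample statistics), `final` lattice state, `params`, `seed`,
#'   `n_events` and optionally `grids`.
#' @examples
#' p <- lm_params(M = 8, N = 20, p_rot = 0.3)
#' tr <- lm_simulate(p, t_end = 2, sample_dt = 0.5, seed = 1, mode = "single")
#' tr$summary
#' @export
lm_simulate <- function(params, init = NULL, t_end = 6, sample_dt = 0.05,
                        seed = 1L, mode = "random", orientation = "random",
                        record_grids = FALSE) {
  stopifnot(inherits(params, "lm_params"))
  if (t_end < params$induction_time &&
      !identical(params$p_rot, params$p_rot_post))
    stop("`t_end` must not precede the induction time")
  if (is.null(init))
    init <- lm_seed(params, mode = mode, orientation = orientation,
                    seed = seed)
  stopifnot(inherits(init, "lattice_state"),
            nrow(init$strain) == params$M, ncol(init$strain) == params$N)
  res <- cpp_lm_run(state_to_int(init$strain, c("blue", "orange")),
                    state_to_int(init$orientation, c("V", "H")),
                    params$lambda, params$kappa,
                    unname(params$p_rot), unname(params$p_rot_post),
                    params$induction_time, t_end, sample_dt,
                    as.integer(seed), record_grids)
  final <- new_lattice_state(int_to_state(res$strain, c("blue", "orange")),
                             int_to_state(res$orientation, c("V", "H")),
                             time = res$t_final)
  out <- list(summary = res$summary, final = final, params = params,
              seed = as.integer(seed), n_events = res$n_events)
  if (record_grids)
    out$grids <- lapply(res$grids, function(g)
      new_lattice_state(int_to_state(g$strain, c("blue", "orange")),
                        int_to_state(g$orientation, c("V", "H")),
                        time = g$t))
  class(out) <- "lm_trajectory"
  out
}

state_to_int <- function(m, levels) {
  matrix(match(m, levels) - 1L, nrow(m), ncol(m))
}

int_to_state <- function(m, levels) {
  matrix(levels[m + 1L], nrow(m), ncol(m))
}

#' @export
print.lm_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("lm_trajectory: %d x %d lattice, t in [0, %g], %d samples, %g events\n",
              x$params$M, x$params$N, max(s$t), nrow(s), x$n_events))
  cat(sprintf("  final f_orange = %.3f, f_H = %.3f, q = %.3f\n",
              s$frac_orange[nrow(s)], s$f_H[nrow(s)], s$q[nrow(s)]))
  invisible(x)
}

#' Ensemble of lattice-model replicates
#'
#' Runs `replicates` independent lattice simulations (seeds `seed + 0:(r-1)`)
#' and returns the per-time ensemble mean and standard deviation of the
#' orange strain fraction, horizontal fraction and order parameter.
#'
#' @inheritParams lm_simulate
#' @param replicates Number of independent replicates.
#' @return A list with `summary` (data frame: `t`, `mean_frac_orange`,
#'   `sd_frac_orange`, `mean_f_H`, `mean_q`), the per-replicate fraction
#'   matrix `frac` (time x replicate), and `params`.
#' @export
lm_ensemble <- function(params, replicates = 100, t_end = 6,
                        sample_dt = 0.05, seed = 1L, mode = "random",
                        orientation = "random") {
  runs <- lapply(seq_len(replicates) - 1L, function(k)
    lm_simulate(params, t_end = t_end, sample_dt = sample_dt,
                seed = as.integer(seed) + k, mode = mode,
                orientation = orientation)$summary)
  tt <- runs[[1]]$t
  frac <- vapply(runs, function(s) s$frac_orange, numeric(length(tt)))
  fH <- vapply(runs, function(s) s$f_H, numeric(length(tt)))
  qq <- vapply(runs, function(s) s$q, numeric(length(tt)))
  list(summary = data.frame(
         t = tt,
         mean_frac_orange = rowMeans(frac),
         sd_frac_orange = apply(frac, 1, stats::sd),
         mean_f_H = rowMeans(fH),
         mean_q = rowMeans(qq)),
       frac = frac, params = params)
}
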