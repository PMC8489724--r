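#' Parameters for the stochastic lattice model
#'
#' The lattice model (LM) represents the rectangular microfluidic trap as an
#' always-full `M x N` grid of cells, each either vertical (`"V"`) or
#' horizontal (`"H"`) and belonging to one of two strains (`"blue"`,
#' `"orange"`). Division rates are location dependent: a vertical cell in row
#' `i` (row 1 at the bottom) divides toward the top at rate
#' `lambda * exp(-kappa * (M - i))` and toward the bottom at rate
#' `lambda * exp(-kappa * (i - 1))`; horizontal cells divide left/right with
#' the analogous column rates. The rotation probability `p_rot` of a strain is
#' the proxy for its mean division length: shorter cells rotate more.
#'
#' Time is measured in units of the base division rate, i.e. `lambda = 1`
#' defines the model time unit; per-strain rotation probabilities switch from
#' `p_rot` to `p_rot_post` at `induction_time` (default 1), emulating induced
#' division-length reduction.
#'
#' @param M,N Lattice dimensions (rows x columns). Default `20 x 100`,
#'   mirroring the 20 x 100 um trap aspect ratio.
#' @param lambda Base growth (division) rate, > 0. Defaults to 1, which fixes
#'   the model time unit.
#' @param kappa Growth-modulation coefficient in `[0, Inf)`: how strongly the
#'   population between a cell and the boundary suppresses its growth.
#' @param p_rot Named numeric, intrinsic rotation probabilities in `[0, 1]`
#'   for strains `blue` and `orange` before induction.
#' @param induction_time Time at which `p_rot_post` replaces `p_rot`.
#' @param p_rot_post Per-strain rotation probabilities from `induction_time`
#'   onwards; defaults to `p_rot` (no change).
#'
#' @return An object of class `"lm_params"`.
#' @examples
#' p <- lm_params(M = 5, N = 5, kappa = 0.5)
#' lm_growth_rates(2, 3, p)
#' @export
lm_params <- function(M = 20L, N = 100L, lambda = 1, kappa = 0.25,
                      p_rot = c(blue = 0, orange = 0),
                      induction_time = 1,
                      p_rot_post = p_rot) {
  M <- as.integer(M); N <- as.integer(N)
  stopifnot(M >= 1, N >= 1)
  if (!is.numeric(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  if (!is.numeric(kappa) || kappa < 0) stop("`kappa` must be >= 0")
  p_rot <- check_prot(p_rot)
  p_rot_post <- check_prot(p_rot_post)
  if (!is.numeric(induction_time) || induction_time < 0)
    stop("`induction_time` must be >= 0")
  structure(list(M = M, N = N, lambda = lambda, kappa = kappa,
                 p_rot = p_rot, induction_time = induction_time,
                 p_rot_post = p_rot_post),
            class = "lm_params")
}

check_prot <- function(p) {
  if (length(p) == 1L) p <- c(blue = unname(p), orange = unname(p))
  if (is.null(names(p))) names(p) <- c("blue", "orange")
  p <- p[c("blue", "orange")]
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("rotation probabilities must lie in [0, 1] and be named blue/orange")
  p
}

#' @export
print.lm_params <- function(x, ...) {
  cat("Lattice model parameters\n")
  cat(sprintf("  lattice: %d x %d, lambda = %g, kappa = %g\n",
              x$M, x$N, x$lambda, x$kappa))
  cat(sprintf("  p_rot (pre):  blue = %g, orange = %g\n",
              x$p_rot["blue"], x$p_rot["orange"]))
  cat(sprintf("  p_rot (post): blue = %g, orange = %g at t >= %g\n",
              x$p_rot_post["blue"], x$p_rot_post["orange"], x$induction_time))
  invisible(x)
}

#' Initialize a fully occupied lattice state
#'
#' Fills every lattice site with a cell, per the seeding mode: `"random"`
#' assigns each site a strain by a fair coin, `"separated"` fills the left
#' half of the columns with blue (wild-type) cells and the right half with
#' orange (mutant) cells, `"banded"` lays down alternating single-strain vertical bands
#' of `band_width` columns (the striped steady state that emerges from
#' growth before rotation is switched on), and `"single"` uses one strain
#' everywhere.
#'
#' @param params An [lm_params()] object.
#' @param mode Seeding mode: `"random"`, `"separated"`, `"banded"`, or
#'   `"single"`.
#' @param orientation `"random"` (uniform V/H per site) or `"vertical"`.
#' @param strain Strain used in `"single"` mode.
#' @param band_width Band width in columns for `"banded"` mode.
#' @return A `"lattice_state"`: list with character matrices `strain`
#'   (`"blue"`/`"orange"`) and `orientation` (`"V"`/`"H"`), and `time`.
#'   Row 1 is the bottom row, column 1 the leftmost column.
#' @examples
#' st <- lm_seed(lm_params(M = 4, N = 6), mode = "random", seed = 1)
#' table(st$strain)
#' @param seed Optional integer seed for reproducible seeding.
#' @export
lm_seed <- function(params, mode = c("random", "separated", "banded",
                                     "single"),
                    orientation = c("random", "vertical"),
                    strain = "blue", seed = NULL, band_width = 10) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  if (!is.null(seed)) set.seed(seed)
  M <- params$M; N <- params$N
  strains <- switch(mode,
    random = matrix(sample(c("blue", "orange"), M * N, replace = TRUE), M, N),
    separated = matrix(rep(ifelse(seq_len(N) <= N / 2, "blue", "orange"),
                           each = M), M, N),
    banded = matrix(rep(rep(c("blue", "orange"), each = band_width,
                            length.out = N), each = M), M, N),
    single = matrix(match.arg(strain, c("blue", "orange")), M, N))
  orients <- if (orientation == "random")
    matrix(sample(c("V", "H"), M * N, replace = TRUE), M, N)
  else matrix("V", M, N)
  new_lattice_state(strains, orients, time = 0)
}

#' Construct a lattice state
#'
#' @param strain Character matrix of `"blue"`/`"orange"`.
#' @param orientation Character matrix of `"V"`/`"H"`, same dimensions.
#' @param time Model time attached to the state.
#' @return An object of class `"lattice_state"`.
#' @examples
#' new_lattice_state(matrix("blue", 2, 2), matrix("V", 2, 2))
#' @export
new_lattice_state <- function(strain, orientation, time = 0) {
  stopifnot(identical(dim(strain), dim(orientation)),
            all(strain %in% c("blue", "orange")),
            all(orientation %in% c("V", "H")))
  structure(list(strain = strain, orientation = orientation, time = time),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice_state: %d x %d, t = %g, f_orange = %.3f, f_H = %.3f\n",
              nrow(x$strain), ncol(x$strain), x$time,
              mean(x$strain == "orange"), mean(x$orientation == "H")))
  invisible(x)
}
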