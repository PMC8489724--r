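#' Generate an initial cell seeding for the trap
#'
#' Places `n` non-overlapping cells at random positions with uniform random
#' angles (rejection sampling on center distance). Modes: `"single"` (all
#' blue, default 32 cells), `"random"` (mixed strains assigned by fair coin,
#' default 64 cells) and `"separated"` (blue cells restricted to the left
#' half of the trap and orange cells to the right half, half of `n` each,
#' default 64).
#'
#' @param mode `"single"`, `"random"` or `"separated"`.
#' @param geometry A [trap_geometry()].
#' @param n Number of cells (defaults by mode).
#' @param l_d_bar Mean division lengths `c(blue, orange)` used for the
#'   daughters' division targets.
#' @param seed Integer seed (uses R's RNG, restored on exit).
#' @return A cell table (see [new_cells()]).
#' @examples
#' s <- make_seeding("separated", trap_geometry(), seed = 1)
#' table(s$strain, s$x < 50)
#' @export
make_seeding <- function(mode = "random", geometry = trap_geometry(),
                         n = NULL, l_d_bar = c(4.2, 4.2), seed = NULL) {
  mode <- match.arg(mode, c("single", "random", "separated"))
  if (is.null(n)) n <- if (mode == "single") 32L else 64L
  if (length(l_d_bar) == 1L) l_d_bar <- rep(l_d_bar, 2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  W <- geometry$width; H <- geometry$height
  strain <- switch(mode,
    single = rep("blue", n),
    random = ifelse(stats::runif(n) < 0.5, "blue", "orange"),
    separated = rep(c("blue", "orange"), c(ceiling(n / 2), floor(n / 2))))
  # rejection-sample centers at least 2 um apart (cells start ~2 um long)
  min_d2 <- 2^2
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    k <- length(xs) + 1L
    lo <- 0; hi <- W
    if (mode == "separated") {
      if (strain[k] == "blue") hi <- W / 2 else lo <- W / 2
    }
    x <- stats::runif(1, lo + 1, hi - 1)
    y <- stats::runif(1, 1, H - 1)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_d2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    } else {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place non-overlapping seed cells; ",
                               "reduce `n` or enlarge the trap")
    }
  }
  new_cells(x = xs, y = ys, phi = stats::runif(n, 0, pi),
            l = stats::runif(n, 1.8, 2.6), strain = strain,
            l_d_bar = l_d_bar[strain_idx(strain) + 1L])
}

#' Read a simulation configuration from YAML
#'
#' Parses a structured configuration with top-level fields `engine`
#' (`"lm"`, `"abm"` or `"osc"`), an engine parameter block (`lattice`,
#' `trap`/`strains`/`mechanics`/`qs`, or `oscillator`), optional `seeding`
#' (`mode`, `n`, `orientation`), and `run` (`t_end`, `sample_dt`, `seed`,
#' `replicates`).
#'
#' @param path Path to a YAML file.
#' @return A list: `engine`, constructed `params` object, `seeding` list and
#'   `run` list (with defaults filled in).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; restore the lattice
  # column-count field so configs need not quote it
  if (!is.null(cfg$lattice)) {
    nm <- names(cfg$lattice)
    names(cfg$lattice)[nm %in% c("FALSE", "no")] <- "N"
  }
  if (is.null(cfg$engine) || !cfg$engine %in% c("lm", "abm", "osc"))
    stop("config must set `engine` to one of 'lm', 'abm', 'osc'")
  params <- switch(cfg$engine,
    lm = do.call(lm_params, cfg$lattice %||% list()),
    abm = {
      args <- list()
      if (!is.null(cfg$trap)) args$geometry <- do.call(trap_geometry, cfg$trap)
      if (!is.null(cfg$strains$blue))
        args$blue <- do.call(strain_params, cfg$strains$blue)
      if (!is.null(cfg$strains$orange))
        args$orange <- do.call(strain_params, cfg$strains$orange)
      if (!is.null(cfg$qs)) args$qs <- do.call(qs_params, cfg$qs)
      if (!is.null(cfg$mechanics)) args <- c(args, cfg$mechanics)
      if (!is.null(cfg$induce_time)) args$induce_time <- unlist(cfg$induce_time)
      do.call(abm_params, args)
    },
    osc = do.call(osc_params, cfg$oscillator %||% list()))
  run <- cfg$run %||% list()
  run$seed <- run$seed %||% 1L
  run$replicates <- run$replicates %||% 1L
  list(engine = cfg$engine, params = params,
       seeding = cfg$seeding %||% list(mode = "random"), run = run)
}

#' Write a trajectory to disk
#'
#' Serializes the scalar summary as CSV and the metadata (engine, seed,
#' format version, final state / cell table) as JSON next to it: for a stem
#' `out`, writes `out_summary.csv`, `out_meta.json` and, when per-cell or
#' grid records exist, `out_cells.csv`.
#'
#' @param trajectory An `"lm_trajectory"` or `"abm_trajectory"`.
#' @param stem Output path stem (no extension).
#' @return Invisibly, the vector of files written.
#' @export
write_trajectory <- function(trajectory, stem) {
  files <- paste0(stem, c("_summary.csv", "_meta.json"))
  utils::write.csv(trajectory$summary, files[1], row.names = FALSE)
  engine <- if (inherits(trajectory, "lm_trajectory")) "lm" else "abm"
  meta <- list(format_version = 1L, engine = engine, seed = trajectory$seed,
               status = trajectory$status %||% "ok",
               t_final = trajectory$t_final %||% max(trajectory$summary$t))
  if (engine == "abm") {
    meta$final_cells <- trajectory$final_cells
  } else {
    meta$final_strain <- trajectory$final$strain
    meta$final_orientation <- trajectory$final$orientation
  }
  jsonlite::write_json(meta, files[2], auto_unbox = TRUE, digits = NA)
  if (!is.null(trajectory$cells)) {
    f <- paste0(stem, "_cells.csv")
    utils::write.csv(trajectory$cells, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param stem The path stem used when writing.
#' @return A list with `summary`, `meta` and (if present) `cells`; errors on
#'   an unknown format version.
#' @export
read_trajectory <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), 1L))
    stop("unsupported trajectory format version: ", meta$format_version)
  out <- list(summary = utils::read.csv(paste0(stem, "_summary.csv")),
              meta = meta)
  f <- paste0(stem, "_cells.csv")
  if (file.exists(f)) out$cells <- utils::read.csv(f)
  out
}

#' Named tiny fixture scenarios for tests and examples
#'
#' \describe{
#'   \item{`"lm-2x2"`}{a fully occupied 2 x 2 lattice, one strain per half,
#'     all vertical, with its [lm_params()].}
#'   \item{`"abm-column"`}{three stacked vertical cells in a narrow trap,
#'     with [abm_params()].}
#'   \item{`"osc-cycle"`}{[osc_params()] sized for roughly one cycle and the
#'     matching closed-form period.}
#'   \item{`"exp-series"`}{a noiseless invasion fraction series
#'     `1 - 0.5 exp(-2 (t - 1))` for exercising [fit_alpha()] exactly.}
#' }
#'
#' @param name One of the fixture names above.
#' @return A list describing the scenario (contents vary by fixture).
#' @examples
#' fixture_suite("lm-2x2")$state
#' @export
fixture_suite <- function(name) {
  name <- match.arg(name, c("lm-2x2", "abm-column", "osc-cycle", "exp-series"))
  switch(name,
    "lm-2x2" = {
      p <- lm_params(M = 2, N = 2, p_rot = c(blue = 0.2, orange = 0.2))
      st <- new_lattice_state(
        strain = matrix(c("orange", "orange", "blue", "blue"), 2, 2),
        orientation = matrix("V", 2, 2))
      list(params = p, state = st, seed = 42L)
    },
    "abm-column" = {
      g <- trap_geometry(width = 10, height = 12)
      cells <- new_cells(x = 5, y = c(3, 6, 9), phi = pi / 2, l = 2.8,
                         strain = "blue")
      list(params = abm_params(geometry = g), cells = cells, seed = 42L)
    },
    "osc-cycle" = {
      p <- osc_params(K1 = 0.2, K2 = 0.8, n = 64, eps = 1e-3)
      list(params = p, t_end = 2 * osc_period_limit(p) + 1,
           period_limit = osc_period_limit(p))
    },
    "exp-series" = {
      t <- seq(1, 4, by = 0.05)
      list(t = t, f = 1 - 0.5 * exp(-2 * (t - 1)), alpha = 2, t0 = 1)
    })
}
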