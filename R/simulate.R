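#' Configuration for the agent-based arena simulator
#'
#' The simulator emulates the assay's stated world: a population of worms
#' released at the centre of a rectangular arena, crawling for about an hour
#' before quadrant counts are taken. The arena is 80 mm x 10 mm so each of
#' the four quadrants spans 20 mm along the long axis and a worm must travel
#' ~20 mm from the origin to reach an extreme quadrant. Locomotion
#' parameters (speed, turning noise) are plausible-scale modelling choices
#' calibrated once so that `mode = "normal"` yields dispersal near 2 bits.
#'
#' Modes map onto the behavioural regimes the analysis must distinguish:
#' `normal` (free dispersal, no field), `locomotion_defect` (speed forced to
#' 0: worms never leave the central release zone), `origin_attraction`
#' (drift back towards the centre), `unknown_gradient` (a point-source
#' attractant in one seeded random quadrant), and `chemotaxis` (a linear
#' gradient along the long axis with drift strength and direction set by
#' `bias`).
#'
#' @param arena_length,arena_width Arena dimensions in mm (default 80 x 10).
#' @param duration Assay duration in seconds (default 3600, i.e. ~1 h).
#' @param dt Time step in seconds (default 1).
#' @param n_worms Worms released at the centre (default 150; the assay
#'   requires > 100 per plate).
#' @param speed Crawl speed in mm/s (default 0.15).
#' @param turn_sd Gaussian heading noise per step, radians (default 0.5).
#' @param mode Behaviour mode, see Details.
#' @param bias Chemotactic drift strength in `[-1, 1]`; positive = towards
#'   the odorant, negative = away.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(arena_length = 80, arena_width = 10,
                              duration = 3600, dt = 1, n_worms = 150,
                              speed = 0.15, turn_sd = 0.5,
                              mode = c("normal", "locomotion_defect",
                                       "origin_attraction",
                                       "unknown_gradient", "chemotaxis"),
                              bias = 0, seed = 1L) {
  mode <- match.arg(mode)
  num <- c(arena_length = arena_length, arena_width = arena_width,
           duration = duration, dt = dt, n_worms = n_worms, speed = speed)
  for (k in names(num)) {
    if (!is.finite(num[[k]]) || num[[k]] <= 0) {
      stop("config error: '", k, "' must be positive (got ", num[[k]], ")",
           call. = FALSE)
    }
  }
  if (!is.finite(turn_sd) || turn_sd < 0) {
    stop("config error: 'turn_sd' must be non-negative", call. = FALSE)
  }
  if (!is.finite(bias) || abs(bias) > 1) {
    stop("config error: 'bias' must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(arena_length = arena_length, arena_width = arena_width,
                 duration = duration, dt = dt,
                 n_worms = as.integer(n_worms), speed = speed,
                 turn_sd = turn_sd, mode = mode, bias = bias,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Build the concentration field implied by a simulator mode
#'
#' `normal`, `locomotion_defect`, and `origin_attraction` have no field;
#' `chemotaxis` gets a linear gradient along the long axis increasing
#' towards the odorant end; `unknown_gradient` gets a point source at the
#' centre of one quadrant, chosen reproducibly from the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `concentration_field` with `kind` (`"none"`,
#'   `"linear_long_axis"`, or `"point_source"`) and, where relevant,
#'   `direction` (+1 = towards the odorant end at `x = arena_length`) or
#'   `source` (mm coordinates).
#' @export
build_field <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  field <- switch(config$mode,
    chemotaxis = list(kind = "linear_long_axis", direction = 1),
    unknown_gradient = {
      set.seed(config$seed)
      quad <- sample.int(4L, 1L)
      list(kind = "point_source",
           source = c(x = config$arena_length * (2 * quad - 1) / 8,
                      y = config$arena_width / 2),
           quadrant = quad)
    },
    list(kind = "none"))
  structure(field, class = "concentration_field")
}

field_code <- function(field) {
  switch(field$kind, none = 0L, linear_long_axis = 1L, point_source = 2L)
}

# effective motion parameters for a mode: speed multiplier, drift strength
# towards the field, drift towards the origin
mode_params <- function(config) {
  switch(config$mode,
    normal = list(speed = config$speed, bias = 0, origin_gain = 0),
    locomotion_defect = list(speed = 0, bias = 0, origin_gain = 0),
    origin_attraction = list(speed = config$speed, bias = 0,
                             origin_gain = 0.6),
    unknown_gradient = list(speed = config$speed,
                            bias = if (config$bias != 0) config$bias else 0.9,
                            origin_gain = 0),
    chemotaxis = list(speed = config$speed, bias = config$bias,
                      origin_gain = 0))
}

#' Advance worms one (or more) steps of the biased random walk
#'
#' Exposes the walker core for inspection and testing. Headings are turned
#' towards the local up-gradient direction (down-gradient for negative
#' bias) with strength proportional to `|bias|`, jittered by Gaussian
#' noise, and positions advance by `speed * dt` with reflective boundaries.
#'
#' @param state A list or data frame with numeric `x`, `y`, `heading`
#'   (vectors of equal length, one entry per worm).
#' @param field A [build_field()] result.
#' @param config A [simulation_config()].
#' @param n_steps Number of steps to take (default 1).
#' @param field_direction +1 if the field's odorant end sits at
#'   `x = arena_length` (orientation A), -1 if mirrored (orientation B).
#' @param external_gradient Laboratory-frame drift along +x, applied
#'   identically whatever the orientation.
#' @return A list with updated `x`, `y`, `heading`.
#' @export
step_worm <- function(state, field, config, n_steps = 1L,
                      field_direction = 1, external_gradient = 0) {
  stopifnot(inherits(config, "simulation_config"))
  mp <- mode_params(config)
  src <- if (identical(field$kind, "point_source")) field$source else c(0, 0)
  out <- walk_worms_cpp(
    as.numeric(state$x), as.numeric(state$y), as.numeric(state$heading),
    as.integer(n_steps), config$dt, mp$speed, config$turn_sd,
    config$arena_length, config$arena_width,
    field_code(field), field_direction, src[1], src[2],
    mp$bias, mp$origin_gain, external_gradient, 0L)
  list(x = out$x, y = out$y, heading = out$heading)
}

#' Simulate one arena and return its quadrant counts
#'
#' Releases `n_worms` at the arena centre (with a small seeded jitter),
#' steps them for `duration / dt` steps, and bins final positions into the
#' four equal quadrants along the long axis. Counts are reported
#' left-to-right in the laboratory frame, as a one-row [arena_tbl()].
#' Orientation `B` mirrors the odorant field physically (odorant end on the
#' left) while any laboratory-frame `external_gradient` keeps its physical
#' direction, exactly as in the bench assay.
#'
#' @param config A [simulation_config()].
#' @param plate_id,cohort,vehicle Metadata for the output record.
#' @param orientation `"A"` or `"B"` (physical direction of the odorant
#'   end).
#' @param odorant Odorant label; defaults to `"butanone 10%"` for
#'   chemotaxis mode and `"none"` otherwise.
#' @param external_gradient Laboratory-frame drift along physical +x.
#' @param trajectories If a positive integer k, also return worm tracks
#'   sampled every k steps in attribute `"trajectories"` (a data frame
#'   `worm_id, t, x, y`).
#' @return A one-row [arena_tbl()]; counts sum to `n_worms`.
#' @export
simulate_arena <- function(config, plate_id = "P1", cohort = "c1",
                           orientation = "A", odorant = NULL,
                           vehicle = "ethanol", external_gradient = 0,
                           trajectories = 0L) {
  stopifnot(inherits(config, "simulation_config"),
            orientation %in% c("A", "B"))
  field <- build_field(config)
  mp <- mode_params(config)
  set.seed(config$seed)
  L <- config$arena_length; W <- config$arena_width
  n <- config$n_worms
  x <- pmin(pmax(L / 2 + stats::rnorm(n, 0, 1), 0), L)
  y <- pmin(pmax(W / 2 + stats::rnorm(n, 0, 0.5), 0), W)
  h <- stats::runif(n, -pi, pi)
  dir <- if (orientation == "A") 1 else -1
  src <- c(0, 0)
  if (identical(field$kind, "point_source")) {
    src <- field$source
    if (orientation == "B") src[1] <- L - src[1]
  }
  out <- walk_worms_cpp(
    x, y, h, as.integer(round(config$duration / config$dt)),
    config$dt, mp$speed, config$turn_sd, L, W,
    field_code(field), dir, src[1], src[2],
    mp$bias, mp$origin_gain, external_gradient,
    as.integer(trajectories))
  counts <- tabulate(pmin(findInterval(out$x, c(0, L / 4, L / 2, 3 * L / 4),
                                       rightmost.closed = TRUE), 4L),
                     nbins = 4L)
  if (is.null(odorant)) {
    odorant <- if (config$mode == "chemotaxis") "butanone 10%" else "none"
  }
  rec <- arena_tbl(data.frame(
    plate_id = plate_id,
    assay_type = if (config$mode == "chemotaxis") "chemotaxis"
                 else "dispersal",
    orientation = orientation,
    odorant = odorant,
    vehicle = if (identical(odorant, "none")) "none" else vehicle,
    cohort = cohort,
    c_left = counts[1], c_midleft = counts[2],
    c_midright = counts[3], c_right = counts[4],
    stringsAsFactors = FALSE))
  if (trajectories > 0L) {
    traj <- as.data.frame(out$traj)
    names(traj) <- c("worm_id", "t", "x", "y")
    attr(rec, "trajectories") <- traj
  }
  rec
}

# deterministic per-arena substream seeds from one experiment seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a full paired experiment
#'
#' Emits the arena set the assay design prescribes: paired no-odorant
#' dispersal arenas plus chemotaxis arenas in both physical orientations,
#' all in one cohort, each arena simulated on its own deterministic
#' substream of the experiment seed. An injected laboratory-frame gradient
#' (same physical direction for both orientations) is available to exercise
#' the orientation-consistency control.
#'
#' @param config A [simulation_config()]; its `mode` and `bias` apply to the
#'   chemotaxis arenas (mode is coerced to `"chemotaxis"` for them).
#' @param n_arenas_per_orientation Chemotaxis arenas per orientation
#'   (default 4).
#' @param n_dispersal Paired dispersal arenas (default
#'   `n_arenas_per_orientation`).
#' @param dispersal_mode Mode for the dispersal controls (default
#'   `"normal"`; set e.g. `"locomotion_defect"` to simulate failing
#'   controls).
#' @param odorant Odorant label for the chemotaxis arenas.
#' @param external_gradient Laboratory-frame drift along physical +x for
#'   every arena.
#' @param cohort Cohort label shared by all arenas.
#' @return An [experiment_set()].
#' @export
generate_experiment <- function(config, n_arenas_per_orientation = 4L,
                                n_dispersal = n_arenas_per_orientation,
                                dispersal_mode = "normal",
                                odorant = "butanone 10%",
                                external_gradient = 0,
                                cohort = "sim1") {
  stopifnot(inherits(config, "simulation_config"),
            n_arenas_per_orientation >= 1L, n_dispersal >= 1L)
  n_chem <- 2L * n_arenas_per_orientation
  seeds <- derive_seeds(config$seed, n_dispersal + n_chem)
  rows <- vector("list", n_dispersal + n_chem)
  disp_cfg <- config
  disp_cfg$mode <- dispersal_mode
  disp_cfg$bias <- if (dispersal_mode == "chemotaxis") config$bias else 0
  for (i in seq_len(n_dispersal)) {
    disp_cfg$seed <- seeds[i]
    rows[[i]] <- simulate_arena(disp_cfg, plate_id = sprintf("D%02d", i),
                                cohort = cohort, orientation = "A",
                                external_gradient = external_gradient)
  }
  chem_cfg <- config
  chem_cfg$mode <- "chemotaxis"
  k <- n_dispersal
  for (orient in c("A", "B")) {
    for (i in seq_len(n_arenas_per_orientation)) {
      k <- k + 1L
      chem_cfg$seed <- seeds[k]
      rows[[k]] <- simulate_arena(chem_cfg,
                                  plate_id = sprintf("C%s%02d", orient, i),
                                  cohort = cohort, orientation = orient,
                                  odorant = odorant,
                                  external_gradient = external_gradient)
    }
  }
  arenas <- do.call(rbind, rows)
  class(arenas) <- c("arena_tbl", "data.frame")
  experiment_set(arenas, odorant = odorant)
}
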