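# Overdamped bead transport in the time-varying energy landscape.

#' Simulation configuration
#'
#' @param dt time step, seconds; defaults to 1/250 of the field period and
#'   must not exceed 1/200 of it.
#' @param duration simulated time, seconds.
#' @param gradient_step central-difference step for the landscape force,
#'   micrometres.
#' @param max_substep_um stability cap on the displacement of any bead in a
#'   single forward-difference substep, micrometres.  The overdamped
#'   dynamics is stiff (relaxation into a well is far faster than the field
#'   rotation), so each field-resolution step of length `dt` is internally
#'   split into forward-difference substeps no bead moves more than this
#'   cap in.
#' @param contact_tol surface gap below which two beads count as touching,
#'   micrometres (100 nm).
#' @param thermal logical; add Brownian kicks (Stokes-Einstein diffusivity).
#' @param temperature_k temperature for the thermal kicks, kelvin.
#' @param seed RNG seed (only used when `thermal = TRUE`).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = NULL, duration = NULL, gradient_step = 0.05,
                       max_substep_um = 0.2, contact_tol = 0.1,
                       thermal = FALSE, temperature_k = 298, seed = 1L) {
  structure(list(dt = dt, duration = duration,
                 gradient_step = gradient_step,
                 max_substep_um = max_substep_um, contact_tol = contact_tol,
                 thermal = thermal, temperature_k = temperature_k,
                 seed = as.integer(seed)),
            class = "sim_config")
}

resolve_dt <- function(config, field) {
  period <- if (field$freq_hz > 0) 1 / field$freq_hz else Inf
  dt <- config$dt
  if (is.null(dt)) dt <- if (is.finite(period)) period / 250 else 0.01
  if (is.finite(period) && dt > period / 200)
    stop("invalid-spec: dt must be <= field period / 200")
  dt
}

#' Landscape force on a bead by central finite differences
#'
#' `F = -grad U` evaluated in the bead plane, with
#' `U = -1/2 mu0 V_p (chi_p - chi_f) |H_total|^2`.
#'
#' @param energy_fn function mapping an n x 2 matrix of in-plane positions
#'   (um) to energies (J), e.g. a closure over [energy_profile()] inputs.
#' @param position length-2 position `(x, y)`, micrometres.
#' @param h finite-difference step, micrometres.
#' @return in-plane force `(Fx, Fy)`, newtons.
#' @export
magnetic_force <- function(energy_fn, position, h = 0.05) {
  pts <- rbind(position + c(h, 0), position - c(h, 0),
               position + c(0, h), position - c(0, h))
  u <- energy_fn(pts)
  if (any(!is.finite(u)))
    stop("numerical-failure: non-finite energy near position ",
         paste(signif(position, 6), collapse = ", "))
  c(-(u[1] - u[2]), -(u[3] - u[4])) / (2 * h * 1e-6)
}

#' Point-dipole pair force
#'
#' Force on particle 1 from the dipole-dipole interaction with particle 2,
#' both moments induced by the local field: `m_i = 4 pi R_i^3 chi_i H / 3`.
#' Equal and opposite on particle 2.
#'
#' @param p1,p2 [magnetic_particle()] objects.
#' @param h_local local field, length-3 vector, A/m (the external drive by
#'   convention; the moment induced by the film stray field is neglected
#'   for the pair term).
#' @param r separation vector from particle 2 to particle 1, micrometres,
#'   length 2 (in-plane) or 3.
#' @return length-3 force on particle 1, newtons.
#' @export
dipole_pair_force <- function(p1, p2, h_local, r) {
  if (length(r) == 2) r <- c(r, 0)
  r_m <- r * 1e-6
  rmag <- sqrt(sum(r_m^2))
  if (rmag == 0) stop("singular-separation: |r| must be > 0")
  m1 <- 4 * pi * (p1$radius_um * 1e-6)^3 * p1$chi_p * h_local / 3
  m2 <- 4 * pi * (p2$radius_um * 1e-6)^3 * p2$chi_p * h_local / 3
  m1r <- sum(m1 * r_m); m2r <- sum(m2 * r_m)
  pref <- 3 * MU0 / (4 * pi * rmag^5)
  pref * (m1r * m2 + m2r * m1 + sum(m1 * m2) * r_m -
            5 * m1r * m2r * r_m / rmag^2)
}

#' Stokes drag velocity
#'
#' @param f force vector, newtons.
#' @param radius_um bead radius, micrometres.
#' @param eta_f fluid viscosity, Pa s.
#' @return velocity in micrometres per second, componentwise
#'   `v = F / (6 pi eta R)`.
#' @export
drag_velocity <- function(f, radius_um, eta_f) {
  if (radius_um <= 0 || eta_f <= 0)
    stop("invalid-argument: radius and viscosity must be > 0")
  f / (6 * pi * eta_f * radius_um * 1e-6) * 1e6
}

# internal stepping state
make_state <- function(particles, field, pattern, fluid, film, config,
                       sources) {
  pos <- do.call(rbind, lapply(particles, function(p) p$pos[1:2]))
  list(pos = pos, t = 0,
       radius = vapply(particles, `[[`, numeric(1), "radius_um"),
       chi = vapply(particles, `[[`, numeric(1), "chi_p"),
       vol = vapply(particles, `[[`, numeric(1), "volume_m3"),
       z = vapply(particles, eval_height, numeric(1)),
       field = field, fluid = fluid, film = film,
       sources = sources, config = config)
}

# instantaneous drift velocities (um/s) of all particles
state_velocities <- function(state) {
  cfg <- state$config
  np <- nrow(state$pos)
  h <- cfg$gradient_step
  h_ext <- external_field_at(state$field, state$t)
  vel <- matrix(0, np, 2)
  if (!is.null(state$sources)) {
    # batched 4-point central-difference stencil for every particle
    stencil <- do.call(rbind, lapply(seq_len(np), function(i) {
      p <- state$pos[i, ]
      cbind(rbind(p + c(h, 0), p - c(h, 0), p + c(0, h), p - c(0, h)),
            state$z[i])
    }))
    h2 <- h2_total(state$sources, state$field, state$film, stencil, state$t)
    for (i in seq_len(np)) {
      u4 <- -0.5 * MU0 * state$vol[i] *
        (state$chi[i] - state$fluid$chi_f) * h2[(i - 1) * 4 + 1:4]
      f <- c(-(u4[1] - u4[2]), -(u4[3] - u4[4])) / (2 * h * 1e-6)
      if (any(!is.finite(f)))
        stop("numerical-failure: non-finite landscape force at t = ",
             state$t)
      vel[i, ] <- f
    }
  }
  if (np > 1) {
    m_pref <- 4 * pi * (state$radius * 1e-6)^3 * state$chi / 3
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      r <- c(state$pos[i, ] - state$pos[j, ], 0) * 1e-6
      rmag <- sqrt(sum(r^2))
      if (rmag == 0) stop("singular-separation in pair force")
      m1 <- m_pref[i] * h_ext; m2 <- m_pref[j] * h_ext
      m1r <- sum(m1 * r); m2r <- sum(m2 * r)
      f <- 3 * MU0 / (4 * pi * rmag^5) *
        (m1r * m2 + m2r * m1 + sum(m1 * m2) * r - 5 * m1r * m2r * r / rmag^2)
      vel[i, ] <- vel[i, ] + f[1:2]
      vel[j, ] <- vel[j, ] - f[1:2]
    }
  }
  # force -> velocity (um/s)
  for (i in seq_len(np))
    vel[i, ] <- vel[i, ] / (6 * pi * state$fluid$eta_f *
                              state$radius[i] * 1e-6) * 1e6
  vel
}

# hard-sphere overlap: minimal symmetric projection
resolve_overlaps <- function(state) {
  np <- nrow(state$pos)
  if (np < 2) return(state)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    dvec <- state$pos[i, ] - state$pos[j, ]
    d <- sqrt(sum(dvec^2))
    dmin <- state$radius[i] + state$radius[j]
    if (d < dmin && d > 0) {
      push <- (dmin - d) / 2 * dvec / d
      state$pos[i, ] <- state$pos[i, ] + push
      state$pos[j, ] <- state$pos[j, ] - push
    }
  }
  state
}

# advance all particles by one field-resolution step of length state$dt,
# internally substepped so no bead moves more than max_substep_um per
# forward-difference update
step_state <- function(state) {
  cfg <- state$config
  np <- nrow(state$pos)
  remaining <- state$dt
  cap <- cfg$max_substep_um
  local_cap <- cap
  prev_vel <- NULL
  repeat {
    vel <- state_velocities(state)
    vmax <- max(sqrt(rowSums(vel^2)), 1e-12)
    # quasi-static early exit: nothing will move measurably before the
    # next field update
    if (!cfg$thermal && vmax * remaining < 0.002) {
      state$t <- state$t + remaining
      break
    }
    # overshoot damping: a velocity reversal means the bead is straddling
    # a stiff minimum; shrink the substep cap until it settles
    if (!is.null(prev_vel)) {
      if (sum(vel * prev_vel) < 0) local_cap <- max(local_cap / 2, 0.002)
      else local_cap <- min(local_cap * 1.5, cap)
    }
    prev_vel <- vel
    dt_sub <- min(remaining, local_cap / vmax)
    state$pos <- state$pos + vel * dt_sub
    if (cfg$thermal) {
      d_um2 <- KB * cfg$temperature_k /
        (6 * pi * state$fluid$eta_f * state$radius * 1e-6) * 1e12
      state$pos <- state$pos +
        matrix(stats::rnorm(2 * np, sd = sqrt(2 * d_um2 * dt_sub)), np, 2)
    }
    state <- resolve_overlaps(state)
    state$t <- state$t + dt_sub
    remaining <- remaining - dt_sub
    if (remaining <= 1e-12) break
  }
  state
}

#' Simulate overdamped bead transport
#'
#' Forward-difference integration `r_i = r_{i-1} + v_{i-1} dt` of beads in
#' the time-varying energy landscape of the pattern under the rotating
#' conical drive, including pairwise dipole forces and hard-sphere contact.
#' Motion is confined to each bead's horizontal plane `z = R_p + 0.5 um`.
#'
#' @param particles list of [magnetic_particle()] with starting positions.
#' @param pattern a `magnet_pattern`, or `NULL` for drive field only.
#' @param field an [external_field()].
#' @param config a [sim_config()]; `duration` defaults to 5 field periods.
#' @param fluid a [fluid_env()].
#' @param film a [film_response()].
#' @param sources optional precomputed [pattern_sources()].
#' @param bounds optional reflective arena walls `c(xlo, ylo, xhi, yhi)`
#'   (um), used by the encounter simulations.
#' @return a list of `trajectory` objects (one per particle): `times`,
#'   `xy` (matrix, um), `dt`, `field`, and transport `flags`.
#' @export
simulate_transport <- function(particles, pattern, field,
                               config = sim_config(),
                               fluid = fluid_env(), film = film_response(),
                               sources = NULL, bounds = NULL) {
  if (inherits(particles, "magnetic_particle")) particles <- list(particles)
  dt <- resolve_dt(config, field)
  duration <- config$duration
  if (is.null(duration))
    duration <- if (field$freq_hz > 0) 5 / field$freq_hz else 5
  nsteps <- ceiling(duration / dt)
  src <- if (is.null(pattern)) NULL
  else if (!is.null(sources)) sources else pattern_sources(pattern)
  np <- length(particles)
  pos0 <- do.call(rbind, lapply(particles, function(p) p$pos[1:2]))
  hin <- field$h_inplane_oe * OE_TO_AM
  hv <- field$h_vertical_oe * OE_TO_AM
  if (!is.null(src)) {
    m_in <- min(film$chi_film * hin /
                  (1 + film$chi_film * film$demag_inplane), film$ms)
    mz0 <- film$chi_film / (1 + film$chi_film * film$demag_vertical) * hv
    charge_pos <- src$edge_pos
    qx <- src$edge_normal[, 1] * m_in * src$thickness_m * src$edge_len_m
    qy <- src$edge_normal[, 2] * m_in * src$thickness_m * src$edge_len_m
    dipole_pos <- src$face_pos
    mzv <- mz0 * src$thickness_m * src$face_area_m2
  } else {
    charge_pos <- dipole_pos <- matrix(0, 0, 3)
    qx <- qy <- mzv <- numeric(0)
  }
  if (config$thermal) set.seed(config$seed)
  xs <- cpp_simulate(
    pos0, vapply(particles, eval_height, numeric(1)),
    vapply(particles, `[[`, numeric(1), "radius_um"),
    vapply(particles, `[[`, numeric(1), "chi_p"),
    vapply(particles, `[[`, numeric(1), "volume_m3"),
    charge_pos, qx, qy, dipole_pos, mzv,
    hin, hv, field$freq_hz, field$phase0,
    if (field$sense == "ccw") 1 else -1,
    fluid$chi_f, fluid$eta_f, dt, nsteps,
    config$max_substep_um, config$gradient_step,
    config$thermal, config$temperature_k,
    if (is.null(bounds)) 0 else bounds[1],
    if (is.null(bounds)) 0 else bounds[2],
    if (is.null(bounds)) 0 else bounds[3],
    if (is.null(bounds)) 0 else bounds[4],
    !is.null(bounds))
  xs <- array(xs, c(nsteps + 1, np, 2))
  times <- seq(0, by = dt, length.out = nsteps + 1)
  lapply(seq_len(np), function(i) {
    structure(list(times = times, xy = xs[, i, ], dt = dt,
                   particle = particles[[i]], field = field,
                   flags = character(0)),
              class = "trajectory")
  })
}

#' Mean transport speed over an integer number of field periods
#'
#' Net path progress (projected on the track direction) divided by elapsed
#' time, over the largest whole number of field periods in the trajectory.
#'
#' @param traj a `trajectory` from [simulate_transport()].
#' @param direction track direction unit vector (default +x).
#' @return speed in micrometres per second.
#' @export
mean_speed <- function(traj, direction = c(1, 0)) {
  f <- traj$field$freq_hz
  total <- traj$times[length(traj$times)]
  if (f <= 0) stop("insufficient-data: field frequency must be > 0")
  n_per <- floor(total * f + 1e-9)
  if (n_per < 1)
    stop("insufficient-data: trajectory must span >= 1 field period")
  # discard the first period as the settling transient when possible
  t0 <- if (n_per >= 2) 1 / f else 0
  t_end <- n_per / f
  i0 <- max(which(traj$times <= t0 + 1e-12))
  i1 <- max(which(traj$times <= t_end + 1e-12))
  direction <- direction / sqrt(sum(direction^2))
  disp <- traj$xy[i1, ] - traj$xy[i0, ]
  sum(disp * direction) / (traj$times[i1] - traj$times[i0])
}

#' Speed-frequency sweep and critical frequency
#'
#' Runs [simulate_transport()] across a grid of drive frequencies and
#' reports the frequency of maximum mean speed: below the critical
#' frequency the bead is phase-locked and speed grows as `lambda * f`;
#' above it the bead slips and the speed drops.
#'
#' @param particle a [magnetic_particle()] (starting position is used).
#' @param pattern a `magnet_pattern`.
#' @param field_template an [external_field()]; its frequency is replaced
#'   by each grid value.
#' @param f_grid ascending frequencies, Hz (>= 3 values).
#' @param n_periods periods to simulate at each frequency.
#' @param ... passed to [simulate_transport()] (fluid, film, config).
#' @return list with `f_crit` (Hz), `speeds` (data.frame f_hz, speed_um_s),
#'   and `trajectories`.
#' @export
critical_frequency <- function(particle, pattern, field_template, f_grid,
                               n_periods = 5, ...) {
  if (length(f_grid) < 3 || is.unsorted(f_grid))
    stop("invalid-argument: f_grid must be ascending with >= 3 points")
  src <- pattern_sources(pattern)
  dirv <- pattern$meta$direction
  if (is.null(dirv)) dirv <- c(1, 0)
  res <- lapply(f_grid, function(f) {
    fld <- field_template; fld$freq_hz <- f
    cfg <- sim_config(duration = n_periods / f)
    tr <- simulate_transport(particle, pattern, fld, cfg,
                             sources = src, ...)[[1]]
    list(speed = mean_speed(tr, dirv), traj = tr)
  })
  speeds <- vapply(res, `[[`, numeric(1), "speed")
  if (all(speeds <= 0))
    stop("no-transport: no frequency on the grid produced net transport")
  list(f_crit = f_grid[which.max(speeds)],
       speeds = data.frame(f_hz = f_grid, speed_um_s = speeds),
       trajectories = lapply(res, `[[`, "traj"))
}

#' Write trajectories to CSV
#' @param trajectories list of `trajectory` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
trajectories_to_csv <- function(trajectories, path) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(t_s = tr$times, x_um = tr$xy[, 1], y_um = tr$xy[, 2],
               particle = tr$particle$id)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
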