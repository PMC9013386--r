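# Transport classification, beta/gamma design-rule sweeps and bend
# validation by forward/backward energy-barrier analysis.

#' Classify a trajectory as locked, slipped or stuck
#'
#' Operationalizes "appropriate particle transport": a run is `locked` when
#' the bead crosses at least 3 consecutive inter-magnet gaps while its mean
#' progress per field period matches the track period within 2%
#' (`sync_ratio > 0.98`); `stuck` when it crosses no gap; `slipped`
#' otherwise.
#'
#' @param traj a `trajectory` from [simulate_transport()].
#' @param pattern the `magnet_pattern` the bead ran on (its `meta` supplies
#'   the period and direction).
#' @return a `transport_verdict` list: `status`, `gaps_crossed`,
#'   `sync_ratio`, `speed_um_s`.
#' @export
classify_transport <- function(traj, pattern) {
  f <- traj$field$freq_hz
  total <- traj$times[length(traj$times)]
  if (f <= 0 || total * f < 4 - 1e-9)
    stop("insufficient-data: trajectory must span >= 4 field periods")
  lambda <- pattern$meta$period
  if (is.null(lambda)) stop("invalid-pattern: pattern has no period")
  dirv <- pattern$meta$direction
  if (is.null(dirv)) dirv <- c(1, 0)
  s <- traj$xy %*% dirv                    # progress coordinate
  speed <- mean_speed(traj, dirv)
  sync_ratio <- min(abs(speed) / (lambda * f), 1.05)
  # gap mid-lines: path-order polygons projected on the direction
  cent <- vapply(pattern$polygons, function(p)
    sum(colMeans(p) * dirv), numeric(1))
  cent <- sort(cent)
  mids <- (cent[-1] + cent[-length(cent)]) / 2
  # gaps crossed net: gap mid-lines lying strictly between the start and
  # end progress coordinates (consecutive by construction)
  s0 <- s[1]; s1 <- s[length(s)]
  crossed <- sum(mids > min(s0, s1) & mids < max(s0, s1))
  status <- if (crossed >= 3 && sync_ratio > 0.98) "locked"
  else if (crossed == 0) "stuck" else "slipped"
  structure(list(status = status, gaps_crossed = crossed,
                 sync_ratio = sync_ratio, speed_um_s = speed),
            class = "transport_verdict")
}

# run one straight-track transport trial and classify it; the bead starts
# 15 um past a drop tail on the forward attractor
run_track_trial <- function(d_um, track, field, n_periods = 5,
                            chi_p = bead_chi_default(d_um),
                            fluid = fluid_env(), film = film_response(),
                            sources = NULL) {
  pat <- if (inherits(track, "magnet_pattern")) track
  else make_drop_track(track)
  src <- if (is.null(sources)) pattern_sources(pat) else sources
  lambda <- pat$meta$period
  x0 <- 2 * lambda + 15
  bead <- magnetic_particle(d_um / 2, chi_p, pos = c(x0, 0))
  cfg <- sim_config(duration = n_periods / field$freq_hz)
  tr <- simulate_transport(bead, pat, field, cfg, fluid = fluid,
                           film = film, sources = src)[[1]]
  list(verdict = classify_transport(tr, pat), traj = tr)
}

#' Recover the beta threshold by a diameter sweep
#'
#' Sweeps bead diameter on a straight drop-shape track at fixed gap G,
#' classifies each run, and bisects the smallest locked diameter so that
#' the threshold `beta* = d*/G` is resolved to `delta_beta`.
#'
#' @param g inter-magnet gap G, micrometres.
#' @param diameters ascending bead diameters spanning the transition, um.
#' @param field an [external_field()] (0.2 Hz sensing drive by default).
#' @param track a [track_spec()]; its `gap` is overridden by `g`.
#' @param delta_beta bisection resolution in beta units (<= 0.01).
#' @param n_periods periods simulated per trial.
#' @param ... forwarded to the trial runner (chi_p, fluid, film).
#' @return list with `beta_star`, `d_star_um` and the sweep `table`.
#' @export
sweep_beta <- function(g = 15, diameters = seq(1, 6, by = 1),
                       field = external_field(),
                       track = track_spec(), delta_beta = 0.01,
                       n_periods = 5, ...) {
  if (is.unsorted(diameters))
    stop("invalid-argument: diameters must be ascending")
  track$gap <- g
  track$period <- track$drop_length + g
  track$n_units <- max(track$n_units, n_periods + 4L)
  pat <- make_drop_track(track)
  src <- pattern_sources(pat)
  verdicts <- lapply(diameters, function(d)
    run_track_trial(d, pat, field, n_periods, sources = src, ...)$verdict)
  locked <- vapply(verdicts, function(v) v$status == "locked", logical(1))
  tab <- data.frame(d_um = diameters, beta = diameters / g,
                    status = vapply(verdicts, `[[`, character(1), "status"),
                    sync_ratio = vapply(verdicts, `[[`, numeric(1),
                                        "sync_ratio"))
  if (all(locked) || !any(locked))
    stop("unbracketed-threshold: the diameter sweep does not span the ",
         "transport transition")
  i <- which(locked)[1]
  if (i == 1)
    stop("unbracketed-threshold: smallest diameter is already locked")
  lo <- diameters[i - 1]; hi <- diameters[i]
  while ((hi - lo) / g > delta_beta) {
    mid <- (lo + hi) / 2
    v <- run_track_trial(mid, pat, field, n_periods, sources = src,
                         ...)$verdict
    tab <- rbind(tab, data.frame(d_um = mid, beta = mid / g,
                                 status = v$status,
                                 sync_ratio = v$sync_ratio))
    if (v$status == "locked") hi <- mid else lo <- mid
  }
  list(beta_star = hi / g, d_star_um = hi, table = tab[order(tab$d_um), ])
}

#' Recover the gamma threshold by a neck sweep
#'
#' Sweeps the drop neck width N downward at fixed bead diameter, classifies
#' transport through the neck region, and bisects the smallest locked neck
#' so the threshold `gamma* = d/N*` is resolved to `delta_gamma`.
#'
#' @param n_values descending neck widths N to scan, micrometres.
#' @param d_p fixed bead diameter, micrometres.
#' @param field an [external_field()].
#' @param track a [track_spec()] template; `neck` is overridden.
#' @param delta_gamma bisection resolution in gamma units (<= 0.05).
#' @param n_periods periods simulated per trial.
#' @param ... forwarded to the trial runner.
#' @return list with `gamma_star`, `n_star_um` and the sweep `table`.
#' @export
sweep_gamma <- function(n_values = seq(6, 2, by = -1), d_p = 6,
                        field = external_field(), track = track_spec(),
                        delta_gamma = 0.05, n_periods = 5, ...) {
  if (is.unsorted(rev(n_values)))
    stop("invalid-argument: n_values must be descending")
  trial <- function(n) {
    tk <- track; tk$neck <- n
    tk$n_units <- max(tk$n_units, n_periods + 4L)
    run_track_trial(d_p, tk, field, n_periods, ...)$verdict
  }
  verdicts <- lapply(n_values, trial)
  locked <- vapply(verdicts, function(v) v$status == "locked", logical(1))
  tab <- data.frame(n_um = n_values, gamma = d_p / n_values,
                    status = vapply(verdicts, `[[`, character(1), "status"),
                    sync_ratio = vapply(verdicts, `[[`, numeric(1),
                                        "sync_ratio"))
  if (all(locked) || !any(locked))
    stop("unbracketed-threshold: the neck sweep does not span the ",
         "transport transition")
  i <- max(which(locked))           # narrowest locked neck
  if (i == length(n_values))
    stop("unbracketed-threshold: narrowest neck is still locked")
  lo <- n_values[i + 1]; hi <- n_values[i]   # lo fails, hi locks
  while (d_p / lo - d_p / hi > delta_gamma) {
    mid <- (lo + hi) / 2
    v <- trial(mid)
    tab <- rbind(tab, data.frame(n_um = mid, gamma = d_p / mid,
                                 status = v$status,
                                 sync_ratio = v$sync_ratio))
    if (v$status == "locked") hi <- mid else lo <- mid
  }
  list(gamma_star = d_p / hi, n_star_um = hi,
       table = tab[order(-tab$n_um), ])
}

# ---- bend validation --------------------------------------------------------

# representative points of the three magnets around the corner:
# 1 = last arm-1 magnet, 2 = (middle) corner magnet, 3 = first magnet after
bend_corner_magnets <- function(pattern) {
  ci <- pattern$meta$corner_index
  if (is.null(ci)) stop("invalid-pattern: bend has no labeled corner")
  m2 <- ci[ceiling(length(ci) / 2)]
  list(m1 = m2 - 1L, m2 = m2, m3 = max(ci) + 1L)
}

poly_centroid <- function(p) colMeans(p)

# closest pair of boundary points between two polygons
closest_boundary_points <- function(poly1, poly2) {
  best <- Inf; pa <- NULL; pb <- NULL
  dense <- function(p) {
    n <- nrow(p)
    j <- c(2:n, 1)
    mid <- (p + p[j, , drop = FALSE]) / 2
    rbind(p, mid)
  }
  a <- dense(poly1); b <- dense(poly2)
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    k <- which.min(d2)
    if (d2[k] < best) { best <- d2[k]; pa <- a[i, ]; pb <- b[k, ] }
  }
  list(a = pa, b = pb, dist = sqrt(best))
}

# 2D hop integration from anchor a towards anchor b: the bead starts at
# the drive phase aligned with the hop direction and follows the full
# in-plane overdamped drift for half a period.  Reports whether it
# arrives near b, the smallest straight-line energy wall separating it
# from b during the attempt (0 when it arrives), and the energy range
# seen (for joint normalization).
hop_barrier_2d <- function(sources, field, film, fluid, particle, a, b,
                           n_steps = 1000, n_wall = 80) {
  z <- eval_height(particle)
  pref <- -0.5 * MU0 * particle$volume_m3 *
    (particle$chi_p - fluid$chi_f)
  len <- sqrt(sum((b - a)^2))
  dirv <- (b - a) / len
  period <- 1 / field$freq_hz
  phi0 <- atan2(dirv[2], dirv[1]) %% (2 * pi)
  sgn <- if (field$sense == "ccw") 1 else -1
  t0 <- ((phi0 - field$phase0) * sgn) %% (2 * pi) / (2 * pi) * period
  drag <- 6 * pi * fluid$eta_f * particle$radius_um * 1e-6
  dt <- period / n_steps
  h <- 0.05
  u_at <- function(pts, t) pref * h2_total(sources, field, film,
                                           cbind(pts, z), t)
  p <- a; t <- t0
  min_wall <- Inf; rng <- c(Inf, -Inf); crossed <- FALSE
  k <- 0L
  while (t < t0 + period / 2) {
    st <- rbind(p + c(h, 0), p - c(h, 0), p + c(0, h), p - c(0, h))
    u4 <- u_at(st, t)
    v <- c(-(u4[1] - u4[2]), -(u4[3] - u4[4])) / (2 * h * 1e-6) /
      drag * 1e6
    # substep cap for the stiff drift
    vmag <- max(sqrt(sum(v^2)), 1e-12)
    p <- p + v * min(dt, 0.25 / vmag)
    if (sum((p - b) * dirv) >= 0 || sqrt(sum((p - b)^2)) < 1.5) {
      crossed <- TRUE
    }
    if (k %% 25L == 0L || crossed) {
      tt <- seq(0, 1, length.out = n_wall + 1)
      line <- cbind(p[1] + tt * (b[1] - p[1]), p[2] + tt * (b[2] - p[2]))
      uu <- u_at(line, t)
      rng <- c(min(rng[1], min(uu)), max(rng[2], max(uu)))
      min_wall <- min(min_wall, max(c(0, uu - uu[1])))
    }
    if (crossed) break
    t <- t + dt
    k <- k + 1L
  }
  list(barrier_raw = if (crossed) 0 else min_wall, crossed = crossed,
       range = rng, t0 = t0)
}

#' Validate a bend design by forward/backward barrier analysis
#'
#' Evaluates, for the corner hand-off, the energy barrier a bead faces
#' along the forward path (from the corner magnet across the gap to the
#' next magnet, p to q2) and along the backward path (back towards the
#' previous magnet, p to q1).  Because the hand-off is dynamic, each path
#' is probed by a one-dimensional hop: starting at the drive phase aligned
#' with the path, the bead's along-path drift is integrated for half a
#' period, and the reported barrier is the smallest energy wall that ever
#' separates the advancing bead from the far end (zero when it crosses),
#' min-max normalized over both paths.  A bend passes when the forward
#' barrier is at most `barrier_tol` while the backward barrier exceeds it:
#' the bead leaves the corner forward and cannot return.
#'
#' @param pattern a bend `magnet_pattern` from [make_bend()].
#' @param particle a [magnetic_particle()].
#' @param field an [external_field()].
#' @param film a [film_response()].
#' @param fluid a [fluid_env()].
#' @param barrier_tol normalized barrier tolerance (0.05).
#' @return a `bend_report` list: `forward_barrier`, `backward_barrier`,
#'   `verdict` ("pass"/"fail"), `switch_time`, the anchors `p`, `q1`,
#'   `q2`, and the static profiles at the forward-aligned phase.
#' @export
validate_bend <- function(pattern, particle, field = external_field(),
                          film = film_response(), fluid = fluid_env(),
                          barrier_tol = 0.05) {
  mg <- bend_corner_magnets(pattern)
  src <- pattern_sources(pattern)
  cp23 <- closest_boundary_points(pattern$polygons[[mg$m2]],
                                  pattern$polygons[[mg$m3]])
  cp12 <- closest_boundary_points(pattern$polygons[[mg$m1]],
                                  pattern$polygons[[mg$m2]])
  # anchors: facing boundary points nudged into the gap (a bead's well
  # sits just off the film edge)
  gap_dir <- (cp23$b - cp23$a) / max(cp23$dist, 1e-9)
  p_anchor <- cp23$a + gap_dir * min(1, cp23$dist / 4)
  q2_anchor <- cp23$b + gap_dir * 1.5
  back_dir <- (cp12$a - cp12$b) / max(cp12$dist, 1e-9)
  q1_anchor <- cp12$a + back_dir * 1.5
  fwd <- hop_barrier_2d(src, field, film, fluid, particle,
                        p_anchor, q2_anchor)
  bwd <- hop_barrier_2d(src, field, film, fluid, particle,
                        p_anchor, q1_anchor)
  scale <- diff(range(c(fwd$range, bwd$range)))
  fb <- fwd$barrier_raw / scale
  bb <- bwd$barrier_raw / scale
  verdict <- if (fb <= barrier_tol && bb > barrier_tol) "pass" else "fail"
  pf <- energy_profile(pattern, field, film, fluid, particle,
                       rbind(p_anchor, q2_anchor), t = fwd$t0,
                       sources = src)
  pb <- energy_profile(pattern, field, film, fluid, particle,
                       rbind(p_anchor, q1_anchor), t = fwd$t0,
                       sources = src)
  structure(list(forward_barrier = fb, backward_barrier = bb,
                 verdict = verdict, switch_time = fwd$t0, p = p_anchor,
                 q1 = q1_anchor, q2 = q2_anchor,
                 forward_crossed = fwd$crossed,
                 backward_crossed = bwd$crossed,
                 profiles = normalize_profiles(list(forward = pf,
                                                    backward = pb))),
            class = "bend_report")
}

#' Simulate a bead through a bend and check corner passage
#'
#' Full-trajectory cross-check of [validate_bend()]: the bead starts on
#' arm 1 upstream of the corner and must progress past the first magnet of
#' arm 2 within the allotted periods.
#'
#' @param pattern a bend `magnet_pattern`.
#' @param particle a [magnetic_particle()]; its position is overridden.
#' @param field an [external_field()].
#' @param n_periods simulated periods.
#' @param ... forwarded to [simulate_transport()].
#' @return list with `crossed` (logical), and the trajectory.
#' @export
simulate_bend_crossing <- function(pattern, particle,
                                   field = external_field(),
                                   n_periods = 10, ...) {
  mg <- bend_corner_magnets(pattern)
  lambda <- pattern$meta$period
  # start one period upstream of the last arm-1 magnet, on the attractor
  arm_spec <- pattern$meta$spec$arm_specs
  x0 <- (mg$m1 - 2) * lambda + 15
  particle$pos <- c(x0, 0)
  cfg <- sim_config(duration = n_periods / field$freq_hz)
  tr <- simulate_transport(particle, pattern, field, cfg, ...)[[1]]
  # passage: the bead ends closer to the far end of arm 2 than the corner,
  # measured along the arm-2 heading from the corner magnet centroid
  c2 <- poly_centroid(pattern$polygons[[mg$m2]])
  c3 <- poly_centroid(pattern$polygons[[mg$m3]])
  dir2 <- (c3 - c2) / sqrt(sum((c3 - c2)^2))
  # farthest progress along arm 2 past the first arm-2 magnet (a bead that
  # reaches the open track end may wander afterwards)
  prog <- max(sweep(tr$xy, 2, c3) %*% dir2)
  list(crossed = prog > 0.5 * lambda, trajectory = tr,
       progress_um = prog)
}

#' @export
print.bend_report <- function(x, ...) {
  cat(sprintf(
    "bend report: %s (forward barrier %.3f, backward barrier %.3f)\n",
    x$verdict, x$forward_barrier, x$backward_barrier))
  invisible(x)
}

#' Write a sweep table to CSV
#' @param sweep result of [sweep_beta()] or [sweep_gamma()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
sweep_to_csv <- function(sweep, path) {
  utils::write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}
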