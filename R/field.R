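# Physical constants and unit conversions
MU0 <- 4 * pi * 1e-7          # vacuum permeability, T m / A
OE_TO_AM <- 1e3 / (4 * pi)    # 1 Oe = 10^3/(4 pi) A/m
KB <- 1.380649e-23            # Boltzmann constant, J/K

#' Rotating conical drive field
#'
#' The external drive is an in-plane field rotating at frequency `freq_hz`
#' superimposed on a static vertical bias: at time t the field is
#' `(H_in cos(2 pi f t + phase0), +/- H_in sin(2 pi f t + phase0), H_v)`,
#' the sign of the y component set by the rotation sense.  Amplitudes are
#' given in oersted, as chip drive fields usually are; conversions to A/m
#' happen internally.
#'
#' @param h_inplane_oe in-plane amplitude, Oe (70 in the sensing runs).
#' @param h_vertical_oe vertical bias amplitude, Oe (70; 0 gives the
#'   in-plane-only "2D" drive).
#' @param freq_hz rotation frequency, Hz.
#' @param phase0 initial phase, radians.
#' @param sense rotation sense, `"ccw"` or `"cw"`.
#' @return an object of class `external_field`.
#' @export
external_field <- function(h_inplane_oe = 70, h_vertical_oe = 70,
                           freq_hz = 0.2, phase0 = 0, sense = "ccw") {
  if (h_inplane_oe < 0 || h_vertical_oe < 0)
    stop("invalid-spec: field amplitudes must be >= 0")
  if (freq_hz < 0) stop("invalid-spec: frequency must be >= 0")
  sense <- match.arg(sense, c("ccw", "cw"))
  structure(list(h_inplane_oe = h_inplane_oe,
                 h_vertical_oe = h_vertical_oe,
                 freq_hz = freq_hz, phase0 = phase0, sense = sense),
            class = "external_field")
}

#' Evaluate the external drive field at a time
#'
#' @param field an [external_field()].
#' @param t time, seconds (may be a vector).
#' @return if `t` is scalar, a length-3 vector `(Hx, Hy, Hz)` in A/m;
#'   otherwise a matrix with one row per time.
#' @export
external_field_at <- function(field, t) {
  stopifnot(inherits(field, "external_field"))
  sgn <- if (field$sense == "ccw") 1 else -1
  ph <- 2 * pi * field$freq_hz * t + field$phase0
  hin <- field$h_inplane_oe * OE_TO_AM
  hv <- field$h_vertical_oe * OE_TO_AM
  out <- cbind(hin * cos(ph), sgn * hin * sin(ph), rep(hv, length(t)))
  if (length(t) == 1) as.numeric(out) else out
}

#' Soft thin-film magnetic response
#'
#' Linear-with-saturation model for the patterned permalloy film: the
#' in-plane magnetization follows the in-plane drive direction with
#' magnitude `chi_film |H_in| / (1 + chi_film * demag_inplane)` capped at
#' `ms`; the out-of-plane response is demagnetization-suppressed,
#' `chi_film / (1 + chi_film * demag_vertical) * H_z`, which for a thin film
#' (demag_vertical = 1) is roughly `H_z` itself.
#'
#' @param chi_film film susceptibility (soft permalloy, default 1000).
#' @param ms saturation magnetization, A/m (permalloy, 8.6e5).
#' @param demag_inplane in-plane demagnetizing factor (thin film: ~0).
#' @param demag_vertical out-of-plane demagnetizing factor (thin film: ~1).
#' @return an object of class `film_response`.
#' @export
film_response <- function(chi_film = 1000, ms = 8.6e5,
                          demag_inplane = 0, demag_vertical = 1) {
  if (chi_film <= 0) stop("invalid-spec: chi_film must be > 0")
  if (demag_inplane < 0 || demag_inplane > 1 ||
      demag_vertical < 0 || demag_vertical > 1)
    stop("invalid-spec: demagnetizing factors must lie in [0, 1]")
  structure(list(chi_film = chi_film, ms = ms,
                 demag_inplane = demag_inplane,
                 demag_vertical = demag_vertical),
            class = "film_response")
}

#' Film magnetization under an applied field
#'
#' @param film a [film_response()].
#' @param h_ext applied field, length-3 vector in A/m.
#' @return magnetization vector `(Mx, My, Mz)` in A/m.
#' @export
film_magnetization <- function(film, h_ext) {
  stopifnot(inherits(film, "film_response"), length(h_ext) == 3,
            all(is.finite(h_ext)))
  hmag <- sqrt(h_ext[1]^2 + h_ext[2]^2)
  if (hmag > 0) {
    m_in <- min(film$chi_film * hmag /
                  (1 + film$chi_film * film$demag_inplane), film$ms)
    mxy <- m_in * h_ext[1:2] / hmag
  } else mxy <- c(0, 0)
  mz <- film$chi_film / (1 + film$chi_film * film$demag_vertical) * h_ext[3]
  c(mxy, mz)
}

#' Fluid environment
#'
#' @param eta_f dynamic viscosity, Pa s (water: 1e-3).
#' @param chi_f fluid magnetic susceptibility (water: ~0).
#' @return an object of class `fluid_env`.
#' @export
fluid_env <- function(eta_f = 1e-3, chi_f = 0) {
  if (eta_f <= 0) stop("invalid-spec: viscosity must be > 0")
  structure(list(eta_f = eta_f, chi_f = chi_f, mu0 = MU0),
            class = "fluid_env")
}

# ---- surface-charge source model --------------------------------------------

#' Discretize a pattern into magnetostatic source elements
#'
#' The thin-film magnet is represented by (a) line charges on the polygon
#' edges, lambda = (M_inplane . n_hat) * thickness, discretized into point
#' charges, and (b) a vertical dipole sheet over each polygon face for the
#' out-of-plane magnetization, discretized into point dipoles.  Geometry is
#' precomputed here once per pattern; charges are scaled by the
#' instantaneous magnetization at evaluation time.
#'
#' @param pattern a `magnet_pattern`.
#' @param edge_step edge discretization step, micrometres.
#' @param face_step face-cell size for the dipole sheet, micrometres.
#' @return an object of class `pattern_sources` holding edge element
#'   midpoints (m), outward normals, lengths (m), and face cell centers (m)
#'   with areas (m^2).
#' @export
pattern_sources <- function(pattern, edge_step = 0.5, face_step = 1.0) {
  stopifnot(inherits(pattern, "magnet_pattern"))
  um <- 1e-6
  mids <- list(); norms <- list(); lens <- list()
  for (poly in pattern$polygons) {
    n <- nrow(poly)
    a <- poly
    b <- poly[c(2:n, 1), , drop = FALSE]
    seg <- b - a
    seglen <- sqrt(rowSums(seg^2))
    keep <- seglen > 1e-9
    a <- a[keep, , drop = FALSE]; seg <- seg[keep, , drop = FALSE]
    seglen <- seglen[keep]
    # outward normal of a CCW polygon edge: (dy, -dx)/len
    nrm <- cbind(seg[, 2], -seg[, 1]) / seglen
    for (i in seq_len(nrow(a))) {
      k <- max(1L, ceiling(seglen[i] / edge_step))
      tt <- (seq_len(k) - 0.5) / k
      mids[[length(mids) + 1]] <-
        cbind(a[i, 1] + tt * seg[i, 1], a[i, 2] + tt * seg[i, 2])
      norms[[length(norms) + 1]] <-
        matrix(nrm[i, ], k, 2, byrow = TRUE)
      lens[[length(lens) + 1]] <- rep(seglen[i] / k, k)
    }
  }
  edge_mid <- do.call(rbind, mids)
  edge_nrm <- do.call(rbind, norms)
  edge_len <- unlist(lens)
  # face cells
  bb <- pattern_bbox(pattern)
  fx <- seq(bb[1] + face_step / 2, bb[2], by = face_step)
  fy <- seq(bb[3] + face_step / 2, bb[4], by = face_step)
  pts <- cbind(rep(fx, each = length(fy)), rep(fy, times = length(fx)))
  inside <- rep(FALSE, nrow(pts))
  for (poly in pattern$polygons)
    inside <- inside | mgcv::in.out(rbind(poly, poly[1, ]), pts)
  face_pts <- pts[inside, , drop = FALSE]
  structure(list(
    # sources sit at mid-film height
    edge_pos = cbind(edge_mid * um, pattern$thickness * um / 2),
    edge_normal = edge_nrm,
    edge_len_m = edge_len * um,
    face_pos = cbind(face_pts * um, pattern$thickness * um / 2),
    face_area_m2 = rep((face_step * um)^2, nrow(face_pts)),
    thickness_m = pattern$thickness * um,
    bbox = bb), class = "pattern_sources")
}

# charges/dipoles for a given film magnetization (A/m)
source_strengths <- function(src, m_vec) {
  q <- (src$edge_normal[, 1] * m_vec[1] + src$edge_normal[, 2] * m_vec[2]) *
    src$thickness_m * src$edge_len_m
  mz <- rep(m_vec[3] * src$thickness_m, nrow(src$face_pos)) * src$face_area_m2
  list(q = q, mz = mz)
}

#' Stray field of a magnetized pattern at points in space
#'
#' Superposition of the edge line charges and the vertical dipole sheet of
#' every polygon, for a spatially uniform film magnetization.
#'
#' @param pattern a `magnet_pattern` (or a precomputed [pattern_sources()]).
#' @param m magnetization vector `(Mx, My, Mz)`, A/m.
#' @param points n x 3 matrix (or length-3 vector) of positions in
#'   micrometres; all points must lie strictly above the film (z > 0) and
#'   outside the film volume.
#' @return n x 3 matrix of stray-field vectors, A/m.
#' @export
stray_field <- function(pattern, m, points) {
  src <- if (inherits(pattern, "pattern_sources")) pattern
  else pattern_sources(pattern)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (any(points[, 3] <= pattern_thickness_um(pattern, src)))
    stop("domain error: evaluation points must lie above the film (z > 0)")
  st <- source_strengths(src, m)
  cpp_field_at(points * 1e-6, src$edge_pos, st$q, src$face_pos, st$mz)
}

pattern_thickness_um <- function(pattern, src) {
  if (inherits(pattern, "magnet_pattern")) pattern$thickness
  else src$thickness_m * 1e6
}

# |H_total|^2 at points (um), at time t, given precomputed sources
h2_total <- function(src, field, film, points_um, t) {
  h_ext <- external_field_at(field, t)
  m <- film_magnetization(film, h_ext)
  st <- source_strengths(src, m)
  cpp_h2_at(points_um * 1e-6, src$edge_pos, st$q, src$face_pos, st$mz, h_ext)
}

# ---- energy landscape -------------------------------------------------------

#' Superparamagnetic bead
#'
#' @param radius_um bead radius, micrometres.
#' @param chi_p effective bead susceptibility (dimensionless); defaults to
#'   the package calibration for the bead diameter, see
#'   [bead_chi_default()].
#' @param pos optional initial in-plane position `(x, y)`, micrometres.
#' @param id optional identifier.
#' @return an object of class `magnetic_particle`; `volume_m3` is the bead
#'   volume in cubic metres.
#' @export
magnetic_particle <- function(radius_um,
                              chi_p = bead_chi_default(2 * radius_um),
                              pos = c(0, 0), id = 1L) {
  if (radius_um <= 0) stop("invalid-argument: radius must be > 0")
  structure(list(radius_um = radius_um, chi_p = chi_p,
                 volume_m3 = 4 / 3 * pi * (radius_um * 1e-6)^3,
                 pos = pos, id = id),
            class = "magnetic_particle")
}

# default evaluation height: bead center resting on the non-fouling layer
# with a 0.5-um clearance
eval_height <- function(particle) particle$radius_um + 0.5

#' Default bead susceptibility calibration
#'
#' The effective volume susceptibilities of the commercial bead sets are
#' not published; the package calibrates them against the printed
#' operating points: 0.14 for the small sets (critical frequency of the
#' 5-5.9 um set at 0.6 Hz on the canonical track) and 0.12 for the large
#' 8-9.9 um set (critical frequency 0.8 Hz).
#'
#' @param d_um bead diameter, micrometres.
#' @return effective susceptibility (dimensionless).
#' @export
bead_chi_default <- function(d_um) ifelse(d_um >= 8, 0.12, 0.14)

#' Dipolar potential-energy landscape above the pattern
#'
#' Computes `U(x, y) = -1/2 mu0 V_p (chi_p - chi_f) |H_total|^2` on a
#' horizontal grid at height z, where `H_total` is the external drive plus
#' the film stray field.  With this sign convention a bead more magnetizable
#' than the fluid is attracted to field maxima, so the energy wells sit at
#' the attracting pole of each magnet.
#'
#' @param pattern a `magnet_pattern`.
#' @param field an [external_field()].
#' @param film a [film_response()].
#' @param fluid a [fluid_env()].
#' @param particle a [magnetic_particle()].
#' @param z evaluation height, micrometres; default `radius + 0.5`.
#' @param t time, seconds.
#' @param resolution grid spacing, micrometres.
#' @param pad padding beyond the pattern bounding box, micrometres.
#' @param sources optional precomputed [pattern_sources()].
#' @return an object of class `energy_landscape`: `grid` (J; rows = y,
#'   cols = x), `x`, `y`, `z`, `t`, `extent`.
#' @export
energy_landscape <- function(pattern, field, film, fluid, particle,
                             z = NULL, t = 0, resolution = 0.2, pad = 10,
                             sources = NULL) {
  if (!inherits(pattern, "magnet_pattern") || length(pattern$polygons) == 0)
    stop("empty-pattern: no polygons to evaluate")
  if (resolution <= 0) stop("invalid-argument: resolution must be > 0")
  if (is.null(z)) z <- eval_height(particle)
  if (z <= 0) stop("invalid-argument: z must be > 0")
  src <- if (is.null(sources)) pattern_sources(pattern) else sources
  bb <- src$bbox
  x <- seq(bb[1] - pad, bb[2] + pad, by = resolution)
  y <- seq(bb[3] - pad, bb[4] + pad, by = resolution)
  pts <- cbind(rep(x, each = length(y)), rep(y, times = length(x)), z)
  h2 <- h2_total(src, field, film, pts, t)
  pref <- -0.5 * MU0 * particle$volume_m3 * (particle$chi_p - fluid$chi_f)
  grid <- matrix(pref * h2, nrow = length(y), ncol = length(x))
  structure(list(grid = grid, x = x, y = y, z = z, t = t,
                 extent = c(range(x), range(y))),
            class = "energy_landscape")
}

#' Min-max normalize an energy landscape to [0, 1]
#'
#' @param landscape an `energy_landscape` (or any object with a `grid`).
#' @return the landscape with `grid` rescaled so min -> 0 and max -> 1;
#'   `norm_range` records the original range in joules.
#' @export
normalize_minmax <- function(landscape) {
  g <- landscape$grid
  if (!all(is.finite(g))) stop("invalid-argument: landscape must be finite")
  rng <- range(g)
  if (diff(rng) == 0)
    stop("degenerate-normalization: landscape is constant")
  landscape$grid <- (g - rng[1]) / diff(rng)
  landscape$norm_range <- rng
  landscape
}

#' Energy profile along a polyline path
#'
#' Samples the dipolar energy along a path at the bead-center height, as
#' used for the forward/backward bend-path barrier analysis.
#'
#' @inheritParams energy_landscape
#' @param path k x 2 matrix of way-points, micrometres (k >= 2).
#' @param n_per_segment samples per path segment (>= 100).
#' @return an object of class `energy_profile`: `s` (arclength, um),
#'   `energy` (J), `points` (sample coordinates).
#' @export
energy_profile <- function(pattern, field, film, fluid, particle, path,
                           z = NULL, t = 0, n_per_segment = 120,
                           sources = NULL) {
  path <- as.matrix(path)
  if (nrow(path) < 2)
    stop("invalid-argument: path needs at least 2 points")
  if (is.null(z)) z <- eval_height(particle)
  src <- if (is.null(sources)) pattern_sources(pattern) else sources
  n_per_segment <- max(100, n_per_segment)
  pts <- list(); s <- list(); s0 <- 0
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = n_per_segment + 1)
    if (i > 1) tt <- tt[-1]
    pts[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    s[[i]] <- s0 + tt * len
    s0 <- s0 + len
  }
  pts <- do.call(rbind, pts); s <- unlist(s)
  h2 <- h2_total(src, field, film, cbind(pts, z), t)
  pref <- -0.5 * MU0 * particle$volume_m3 *
    (particle$chi_p - fluid$chi_f)
  structure(list(s = s, energy = pref * h2, points = pts, z = z, t = t),
            class = "energy_profile")
}

#' Jointly min-max normalize several energy profiles
#'
#' Rescales a set of profiles using the common minimum and maximum over all
#' of them (the convention used when comparing forward and backward bend
#' paths).
#'
#' @param profiles list of `energy_profile` objects.
#' @return the list with each `energy` mapped to [0, 1] on the shared scale.
#' @export
normalize_profiles <- function(profiles) {
  rng <- range(unlist(lapply(profiles, `[[`, "energy")))
  if (diff(rng) == 0)
    stop("degenerate-normalization: profiles are constant")
  lapply(profiles, function(p) {
    p$energy <- (p$energy - rng[1]) / diff(rng)
    p$norm_range <- rng
    p
  })
}

#' Count local minima of a normalized landscape below a threshold
#'
#' Used to detect the two-well to one-well topology change when the
#' vertical bias is switched on: a grid cell is a local minimum if it is
#' strictly smaller than its 8 neighbours, and only minima below
#' `threshold` (on the normalized 0-1 scale) are counted.  Minima closer
#' together than `merge_dist` grid cells are merged.
#'
#' @param landscape a normalized `energy_landscape`.
#' @param threshold normalized energy cutoff (default 0.2).
#' @param merge_dist merge radius in grid cells.
#' @return number of distinct deep minima.
#' @export
count_energy_wells <- function(landscape, threshold = 0.2, merge_dist = 5) {
  g <- landscape$grid
  nr <- nrow(g); nc <- ncol(g)
  core <- g[2:(nr - 1), 2:(nc - 1)]
  is_min <- core < g[1:(nr - 2), 2:(nc - 1)] &
    core < g[3:nr, 2:(nc - 1)] &
    core < g[2:(nr - 1), 1:(nc - 2)] &
    core < g[2:(nr - 1), 3:nc] &
    core < g[1:(nr - 2), 1:(nc - 2)] &
    core < g[1:(nr - 2), 3:nc] &
    core < g[3:nr, 1:(nc - 2)] &
    core < g[3:nr, 3:nc] &
    core < threshold
  idx <- which(is_min, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  # merge nearby minima
  kept <- idx[1, , drop = FALSE]
  if (nrow(idx) > 1) {
    for (i in 2:nrow(idx)) {
      d2 <- (kept[, 1] - idx[i, 1])^2 + (kept[, 2] - idx[i, 2])^2
      if (all(d2 > merge_dist^2)) kept <- rbind(kept, idx[i, ])
    }
  }
  nrow(kept)
}

#' Export an energy landscape as CSV with a JSON metadata sidecar
#'
#' @param landscape an `energy_landscape`.
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
landscape_to_csv <- function(landscape, path) {
  utils::write.table(landscape$grid, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(z_um = landscape$z, t_s = landscape$t,
               extent_um = landscape$extent,
               x_um = range(landscape$x), y_um = range(landscape$y),
               norm_range_J = landscape$norm_range)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
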