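#' @useDynLib magcircuit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- basic 2D helpers -------------------------------------------------------

rot2 <- function(theta_rad) {
  matrix(c(cos(theta_rad), sin(theta_rad),
           -sin(theta_rad), cos(theta_rad)), 2, 2)
}

transform_poly <- function(poly, theta_rad = 0, shift = c(0, 0)) {
  out <- poly %*% t(rot2(theta_rad))
  out[, 1] <- out[, 1] + shift[1]
  out[, 2] <- out[, 2] + shift[2]
  out
}

# minimum distance between a set of points and a closed polygon boundary
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

#' Minimum boundary-to-boundary distance between two polygons (micrometres)
#' @keywords internal
poly_min_dist <- function(poly1, poly2) {
  d <- Inf
  n1 <- nrow(poly1); n2 <- nrow(poly2)
  for (i in seq_len(n1)) {
    a <- poly2
    b <- poly2[c(2:n2, 1), , drop = FALSE]
    p <- poly1[i, ]
    for (j in seq_len(n2)) {
      d <- min(d, point_segment_dist(p, a[j, ], b[j, ]))
    }
  }
  for (i in seq_len(n2)) {
    a <- poly1
    b <- poly1[c(2:n1, 1), , drop = FALSE]
    p <- poly2[i, ]
    for (j in seq_len(n1)) {
      d <- min(d, point_segment_dist(p, a[j, ], b[j, ]))
    }
  }
  d
}

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# ---- pattern container ------------------------------------------------------

#' Construct a patterned thin-film magnet layout
#'
#' A `magnet_pattern` is the polygonal layout of a soft-magnetic (permalloy)
#' thin film on the chip plane: a list of closed vertex loops in micrometres
#' (x right, y up), a film thickness, and a label.  Polygons are stored in
#' counter-clockwise orientation.
#'
#' @param polygons list of n x 2 numeric matrices, one closed loop each
#'   (last vertex implicitly joins the first).
#' @param thickness film thickness in micrometres (default 0.1, i.e. the
#'   100-nm permalloy layer).
#' @param label free-text label.
#' @param meta optional list of construction metadata (period, path order,
#'   corner gaps, ...).
#' @return an object of class `magnet_pattern`.
#' @export
magnet_pattern <- function(polygons, thickness = 0.1, label = "",
                           meta = list()) {
  if (!is.list(polygons) || length(polygons) == 0)
    stop("empty pattern: at least one polygon is required")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3)
      stop("each polygon must be an n x 2 matrix with n >= 3")
    if (signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    unname(p)
  })
  if (!is.numeric(thickness) || thickness <= 0)
    stop("invalid-spec: thickness must be > 0")
  structure(list(polygons = polygons, thickness = thickness,
                 label = label, meta = meta),
            class = "magnet_pattern")
}

#' @export
print.magnet_pattern <- function(x, ...) {
  bb <- pattern_bbox(x)
  cat(sprintf("magnet_pattern '%s': %d polygons, film %.3g um\n",
              x$label, length(x$polygons), x$thickness))
  cat(sprintf("  extent: x [%.1f, %.1f] um, y [%.1f, %.1f] um\n",
              bb[1], bb[2], bb[3], bb[4]))
  invisible(x)
}

#' Bounding box of a pattern
#' @param pattern a `magnet_pattern`.
#' @return numeric vector `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @export
pattern_bbox <- function(pattern) {
  allv <- do.call(rbind, pattern$polygons)
  c(min(allv[, 1]), max(allv[, 1]), min(allv[, 2]), max(allv[, 2]))
}

#' Consecutive inter-magnet gaps along the transport path
#'
#' Boundary-to-boundary distance between consecutive polygons in path order.
#'
#' @param pattern a `magnet_pattern`; the polygon list order is the path
#'   order.
#' @return numeric vector of length `n_polygons - 1`, micrometres.
#' @export
path_gaps <- function(pattern) {
  n <- length(pattern$polygons)
  if (n < 2) return(numeric(0))
  vapply(seq_len(n - 1), function(i) {
    poly_min_dist(pattern$polygons[[i]], pattern$polygons[[i + 1]])
  }, numeric(1))
}

# ---- track / bend specifications -------------------------------------------

#' Specification of a straight drop-shape track
#'
#' The track is a chain of identical pendant-drop magnets: a round head of
#' diameter `drop_width` joined to a smaller trailing bulb through a
#' concave neck of width `neck`, repeated with an inter-magnet gap `gap`
#' so that the spatial period is `drop_length + gap`.  The alternating
#' boundary curvature (convex head and bulb, concave neck) is what makes
#' directed transport under the conical drive possible.
#'
#' @param drop_length drop length along the track, micrometres.
#' @param drop_width maximum drop width (head diameter), micrometres.
#' @param neck neck (tail) width N, micrometres.
#' @param gap inter-magnet gap G, micrometres (15 in the fabricated chips).
#' @param n_units number of drops (>= 2).
#' @param orientation unit vector of the track direction.
#' @return an object of class `track_spec`.
#' @export
track_spec <- function(drop_length = 30, drop_width = 20, neck = 15,
                       gap = 15, n_units = 5, orientation = c(1, 0)) {
  if (any(!is.finite(c(drop_length, drop_width, neck, gap))) ||
      drop_length <= 0 || drop_width <= 0 || neck <= 0 || gap <= 0)
    stop("invalid-spec: all track dimensions must be > 0")
  if (neck > drop_width)
    stop("invalid-spec: neck width cannot exceed drop width")
  if (n_units < 2) stop("invalid-spec: n_units must be >= 2")
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(drop_length = drop_length, drop_width = drop_width,
                 neck = neck, gap = gap, n_units = as.integer(n_units),
                 orientation = orientation,
                 period = drop_length + gap),
            class = "track_spec")
}

#' Specification of a magnetophoretic bend
#'
#' @param style one of `"naive_obtuse"`, `"multi_drop_corner"`,
#'   `"corner_magnet_A"`, `"corner_magnet_B"`, `"inside_corner"`.
#' @param turn_angle interior angle between the two arms, degrees in
#'   (0, 180); the heading change is `180 - turn_angle`.
#' @param arm_specs a `track_spec` used for both arms.
#' @param corner_params optional named list of style-specific lengths (um).
#' @return an object of class `bend_spec`.
#' @export
bend_spec <- function(style, turn_angle = 90, arm_specs = track_spec(),
                      corner_params = list()) {
  styles <- c("naive_obtuse", "multi_drop_corner", "corner_magnet_A",
              "corner_magnet_B", "inside_corner")
  if (!style %in% styles)
    stop("unsupported-style: style must be one of ",
         paste(styles, collapse = ", "))
  if (!is.finite(turn_angle) || turn_angle <= 0 || turn_angle >= 180)
    stop("invalid-spec: turn_angle must lie in (0, 180) degrees")
  structure(list(style = style, turn_angle = turn_angle,
                 arm_specs = arm_specs, corner_params = corner_params),
            class = "bend_spec")
}

# ---- drop outline -----------------------------------------------------------

# Pendant-drop outline: a round head (diameter W) whose center sits at
# (L - W/2, 0), a trailing bulb at the other end, and a concave circular
# fillet carving the neck between them down to width N.  The convex head
# and bulb plus the concave neck give the boundary the alternating
# curvature sign that directed transport requires; the bulb is the
# launch point for the inter-magnet gap hop.
drop_polygon <- function(L, W, N, fillet = 3, n_arc = 36) {
  rh <- W / 2
  ch <- L - rh
  if (ch <= 0) stop("invalid-spec: drop_length must exceed drop_width/2")
  if (N >= W) stop("invalid-spec: neck width must be below drop width")
  # bulb radius rb (center at (rb, 0)) such that the fillet-carved neck
  # has width N; fillet circle tangent externally to head and bulb
  neck_halfwidth <- function(rb) {
    d <- ch - rb
    if (d <= 0) return(NA_real_)
    r1 <- fillet + rh; r2 <- fillet + rb
    xi <- (d^2 + r2^2 - r1^2) / (2 * d)
    if (r2^2 - xi^2 <= 0) return(NA_real_)
    sqrt(r2^2 - xi^2) - fillet
  }
  grid <- seq(N / 2 + 0.05, rh - 0.01, length.out = 200)
  vals <- vapply(grid, function(r) neck_halfwidth(r) - N / 2, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2 || all(vals[ok] > 0) || all(vals[ok] < 0))
    stop("invalid-spec: no pendant-drop bulb exists for these dimensions")
  i <- ok[which(diff(sign(vals[ok])) != 0)[1]]
  rb <- stats::uniroot(function(r) neck_halfwidth(r) - N / 2,
                       c(grid[i], grid[i + 1]))$root
  cb <- rb
  d <- ch - cb
  r1 <- fillet + rh; r2 <- fillet + rb
  xi <- (d^2 + r2^2 - r1^2) / (2 * d)
  O <- c(cb + xi, sqrt(r2^2 - xi^2))       # upper fillet center
  tb <- c(cb, 0) + rb * (O - c(cb, 0)) / r2
  th_ <- c(ch, 0) + rh * (O - c(ch, 0)) / r1
  a_b <- atan2(tb[2], tb[1] - cb)
  a_h <- atan2(th_[2], th_[1] - ch)
  af1 <- atan2(tb[2] - O[2], tb[1] - O[1])
  af2 <- atan2(th_[2] - O[2], th_[1] - O[1])
  arc <- seq(af2, af1, length.out = n_arc + 1)
  fil_up <- cbind(O[1] + fillet * cos(arc), O[2] + fillet * sin(arc))
  head <- cbind(ch + rh * cos(seq(-a_h, a_h, length.out = 2 * n_arc + 1)),
                rh * sin(seq(-a_h, a_h, length.out = 2 * n_arc + 1)))
  bulb <- cbind(cb + rb * cos(seq(a_b, 2 * pi - a_b,
                                  length.out = 2 * n_arc + 1)),
                rb * sin(seq(a_b, 2 * pi - a_b,
                             length.out = 2 * n_arc + 1)))
  fil_lo <- fil_up[rev(seq_len(nrow(fil_up))), , drop = FALSE]
  fil_lo[, 2] <- -fil_lo[, 2]
  poly <- rbind(head[-nrow(head), , drop = FALSE],
                fil_up[-nrow(fil_up), , drop = FALSE],
                bulb[-nrow(bulb), , drop = FALSE],
                fil_lo[-nrow(fil_lo), , drop = FALSE])
  if (signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

#' Build a straight drop-shape track
#'
#' Places `n_units` teardrop magnets tip-to-tail along the orientation with
#' inter-magnet gap G, so the pattern is periodic with spatial period
#' `drop_length + gap`.
#'
#' @param spec a [track_spec()].
#' @return a `magnet_pattern` whose `meta` records the period, the spec and
#'   the path order.
#' @export
make_drop_track <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  base <- drop_polygon(spec$drop_length, spec$drop_width, spec$neck)
  # mirror so the bulb leads: transport under a ccw-rotating conical
  # field then runs along +orientation
  base[, 1] <- spec$drop_length - base[, 1]
  theta <- atan2(spec$orientation[2], spec$orientation[1])
  lambda <- spec$period
  polys <- lapply(seq_len(spec$n_units) - 1, function(k) {
    transform_poly(base, theta, shift = spec$orientation * k * lambda)
  })
  magnet_pattern(polys, label = "drop_track",
                 meta = list(spec = spec, period = lambda,
                             path_order = seq_along(polys),
                             direction = spec$orientation))
}

# chain of drops, each with its own heading, placed so that consecutive
# tail points are `gap` beyond the previous tip along the new heading
chain_drops <- function(base, headings, start, gap, L) {
  polys <- list(); pos <- start
  for (h in headings) {
    dirv <- c(cos(h), sin(h))
    polys[[length(polys) + 1]] <- transform_poly(base, h, shift = pos)
    pos <- pos + dirv * L + dirv * gap   # next tail = this tip + gap
  }
  list(polys = polys, end = pos, heading = utils::tail(headings, 1))
}

#' Build a magnetophoretic bend
#'
#' Two straight track arms joined at the given interior angle by a
#' style-specific corner construction.  For every style except
#' `naive_obtuse` the corner keeps every inter-magnet gap along the particle
#' path at or below the arm gap G (so the beta design ratio is preserved);
#' `naive_obtuse` deliberately enlarges the corner gap, reproducing the
#' failing design.
#'
#' @param spec a [bend_spec()].
#' @return a `magnet_pattern`; `meta$corner_gap` records the largest gap
#'   along the path, `meta$corner_index` the polygon indices of the corner
#'   construction.
#' @export
make_bend <- function(spec) {
  stopifnot(inherits(spec, "bend_spec"))
  arm <- spec$arm_specs
  L <- arm$drop_length; W <- arm$drop_width
  N <- arm$neck; G <- arm$gap
  lambda <- arm$period
  base <- drop_polygon(L, W, N)
  base[, 1] <- L - base[, 1]    # bulb leads, as in make_drop_track
  delta <- (180 - spec$turn_angle) * pi / 180   # heading change
  n_arm <- arm$n_units

  arm1 <- chain_drops(base, rep(0, n_arm), c(0, 0), G, L)
  polys <- arm1$polys
  pos <- arm1$end            # tail point of the would-be next magnet
  corner_idx <- integer(0)

  cp <- spec$corner_params
  if (spec$style == "naive_obtuse") {
    # enlarged corner gap: next arm begins straight after a widened gap
    widen <- if (!is.null(cp$gap_factor)) cp$gap_factor else 2.4
    pos <- pos + c(cos(0), sin(0)) * (widen - 1) * G
    arm2 <- chain_drops(base, rep(delta, n_arm), pos, G, L)
    polys <- c(polys, arm2$polys)
    corner_idx <- n_arm + 1L
    corner_gap <- widen * G
  } else if (spec$style == "multi_drop_corner") {
    n_c <- if (!is.null(cp$n_corner)) cp$n_corner else
      max(3L, ceiling(delta / (12 * pi / 180)))
    steps <- delta * seq_len(n_c) / (n_c + 1)
    corner <- chain_drops(base, steps, pos, G, L)
    arm2 <- chain_drops(base, rep(delta, n_arm), corner$end, G, L)
    polys <- c(polys, corner$polys, arm2$polys)
    corner_idx <- n_arm + seq_len(n_c)
    corner_gap <- G
  } else if (spec$style %in% c("corner_magnet_A", "corner_magnet_B",
                               "inside_corner")) {
    scale <- if (!is.null(cp$scale)) cp$scale
    else if (spec$style == "corner_magnet_B") 1.2 else 1.6
    half <- delta / 2
    if (spec$style == "corner_magnet_B") {
      bigL <- 1.5 * scale * W
      big <- peanut_polygon(bigL, scale * W)
    } else {
      bigL <- scale * L
      big <- drop_polygon(bigL, scale * W, max(N, scale * N * 0.8))
      big[, 1] <- bigL - big[, 1]
    }
    offset <- c(0, 0)
    if (spec$style == "inside_corner") {
      # corner magnet pulled toward the inside of the bend so the particle
      # path runs inside the corner
      inward <- c(cos(half + pi / 2), sin(half + pi / 2))
      offset <- -inward * W / 4
    }
    polys <- c(polys, list(transform_poly(big, half, shift = pos + offset)))
    corner_idx <- n_arm + 1L
    dirv <- c(cos(delta), sin(delta))
    # place arm 2 so its first tail is G beyond the corner magnet tip
    tip <- pos + offset + c(cos(half), sin(half)) * bigL
    arm2 <- chain_drops(base, rep(delta, n_arm), tip + dirv * G, G, L)
    # shift arm 2 along its heading until the first gap is exactly <= G
    polys <- c(polys, arm2$polys)
    corner_gap <- NA_real_
  }
  pat <- magnet_pattern(polys, thickness = 0.1,
                        label = paste0("bend_", spec$style),
                        meta = list(spec = spec, period = lambda,
                                    path_order = seq_along(polys),
                                    corner_index = corner_idx,
                                    heading_change = delta))
  gaps <- path_gaps(pat)
  pat$meta$path_gap_max <- max(gaps)
  pat$meta$corner_gap <- if (spec$style == "naive_obtuse")
    max(gaps) else max(gaps[corner_idx - 1], gaps[corner_idx])
  pat
}

# peanut (double-lobe) outline: union of two equal circles of diameter W
# whose overlap leaves a concave waist; used for the corner_magnet_B style
peanut_polygon <- function(L, W, n_arc = 36) {
  rh <- W / 2
  if (L <= W || L >= 2 * W)
    stop("invalid-spec: peanut needs W < L < 2W for a waist")
  c1 <- c(rh, 0); c2 <- c(L - rh, 0)
  dh <- (c2[1] - c1[1]) / 2
  aj <- acos(dh / rh)                   # junction half-angle at each lobe
  th1 <- seq(aj, 2 * pi - aj, length.out = 2 * n_arc + 1)
  lobe1 <- cbind(c1[1] + rh * cos(th1), rh * sin(th1))
  th2 <- seq(-(pi - aj), pi - aj, length.out = 2 * n_arc + 1)
  lobe2 <- cbind(c2[1] + rh * cos(th2), rh * sin(th2))
  poly <- rbind(lobe1[-nrow(lobe1), ], lobe2[-nrow(lobe2), ])
  if (signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

# ---- design ratios ----------------------------------------------------------

#' Dimensionless design ratios beta and gamma
#'
#' `beta = d_P / G` (particle diameter over inter-magnet gap) and
#' `gamma = d_P / N` (diameter over neck width) govern whether a bead can be
#' transported along a drop-shape track: transport requires a large enough
#' beta (the bead must bridge the gap fields) and a small enough gamma (the
#' bead must resolve the neck).
#'
#' @param d_p particle diameter, micrometres.
#' @param g inter-magnet gap G, micrometres.
#' @param n neck width N, micrometres.
#' @return a `design_ratios` list with `beta` and `gamma`.
#' @examples
#' design_ratios(6, 15, 15)   # beta = gamma = 0.4
#' @export
design_ratios <- function(d_p, g, n) {
  if (any(!is.finite(c(d_p, g, n))) || d_p <= 0 || g <= 0 || n <= 0)
    stop("invalid-argument: d_p, g and n must all be > 0")
  structure(list(d_p = d_p, g = g, n = n,
                 beta = d_p / g, gamma = d_p / n),
            class = "design_ratios")
}

#' @export
print.design_ratios <- function(x, ...) {
  cat(sprintf("design ratios: beta = d_P/G = %.4g, gamma = d_P/N = %.4g\n",
              x$beta, x$gamma))
  invisible(x)
}

# ---- rasterization ----------------------------------------------------------

#' Rasterize a pattern to a boolean occupancy grid
#'
#' Marks grid cells whose center lies inside any polygon.  The grid covers
#' the pattern bounding box padded by at least 10 um.
#'
#' @param pattern a `magnet_pattern`.
#' @param resolution cell size in micrometres.
#' @param pad padding around the bounding box, micrometres (>= 10).
#' @return a list with `mask` (logical matrix, rows = y, cols = x), `x`,
#'   `y` (cell-center coordinates) and `resolution`.
#' @export
rasterize_pattern <- function(pattern, resolution = 0.2, pad = 10) {
  if (!inherits(pattern, "magnet_pattern") || length(pattern$polygons) == 0)
    stop("empty-pattern: nothing to rasterize")
  if (!is.finite(resolution) || resolution <= 0)
    stop("invalid-argument: resolution must be > 0")
  pad <- max(pad, 10)
  bb <- pattern_bbox(pattern)
  x <- seq(bb[1] - pad, bb[2] + pad, by = resolution)
  y <- seq(bb[3] - pad, bb[4] + pad, by = resolution)
  pts <- cbind(rep(x, each = length(y)), rep(y, times = length(x)))
  inside <- rep(FALSE, nrow(pts))
  for (poly in pattern$polygons) {
    inside <- inside | mgcv::in.out(rbind(poly, poly[1, ]), pts)
  }
  mask <- matrix(inside, nrow = length(y), ncol = length(x))
  list(mask = mask, x = x, y = y, resolution = resolution)
}

# ---- export -----------------------------------------------------------------

#' Export a pattern as a JSON polygon list
#' @param pattern a `magnet_pattern`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
pattern_to_json <- function(pattern, path) {
  obj <- list(label = pattern$label, thickness_um = pattern$thickness,
              polygons = lapply(pattern$polygons, function(p)
                list(x = p[, 1], y = p[, 2])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a pattern as an SVG drawing for visual inspection
#' @param pattern a `magnet_pattern`.
#' @param path output file path.
#' @param scale pixels per micrometre.
#' @return `path`, invisibly.
#' @export
pattern_to_svg <- function(pattern, path, scale = 4) {
  bb <- pattern_bbox(pattern)
  w <- (bb[2] - bb[1] + 10) * scale
  h <- (bb[4] - bb[3] + 10) * scale
  tx <- function(x) (x - bb[1] + 5) * scale
  ty <- function(y) h - (y - bb[3] + 5) * scale
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    w, h))
  for (p in pattern$polygons) {
    pts <- paste(sprintf("%.2f,%.2f", tx(p[, 1]), ty(p[, 2])),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="#888" stroke="#000" stroke-width="1"/>',
      pts))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
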