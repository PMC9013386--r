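# Synthetic data for the bead-pair assay: stochastic pair formation under
# a phenomenological binding model, physics-based background encounters,
# and rendered chamber micrographs with ground truth.

#' Phenomenological analyte-binding model
#'
#' Saturating (Langmuir-style) pair-formation probability per candidate
#' bead pair: `p(c) = p_bg + (p_max - p_bg) * c / (c + k)`.  The baseline
#' depends on the drive: the in-plane-only (2D) field lets beads attract
#' and form spurious pairs, the conical (3D) field suppresses them.
#' Concentrations are relative (dimensionless), matching the assay axes.
#'
#' @param p_bg_2d baseline pair probability per encounter, 2D drive.
#' @param p_bg_3d baseline under the conical drive.
#' @param p_max saturation pair probability.
#' @param k half-saturation concentration (relative units).
#' @return an object of class `binding_model`.
#' @export
binding_model <- function(p_bg_2d = 0.15, p_bg_3d = 0.02, p_max = 0.8,
                          k = 1e-11) {
  if (!(p_bg_3d >= 0 && p_bg_3d < p_bg_2d && p_bg_2d <= 1))
    stop("invalid-model: need 0 <= p_bg_3d < p_bg_2d <= 1")
  if (p_max <= 0 || p_max > 1) stop("invalid-model: p_max in (0, 1]")
  if (k <= 0) stop("invalid-model: k must be > 0")
  structure(list(p_bg_2d = p_bg_2d, p_bg_3d = p_bg_3d, p_max = p_max,
                 k = k), class = "binding_model")
}

#' Pair probability at a concentration
#' @param model a [binding_model()].
#' @param concentration relative concentration (>= 0), vectorized.
#' @param field_mode `"2D"` or `"3D"`.
#' @return pair-formation probability per candidate pair.
#' @export
pair_probability <- function(model, concentration, field_mode = "3D") {
  field_mode <- match.arg(field_mode, c("2D", "3D"))
  p_bg <- if (field_mode == "2D") model$p_bg_2d else model$p_bg_3d
  p_bg + (model$p_max - p_bg) * concentration / (concentration + model$k)
}

#' Simulate pair formation in one chamber
#'
#' Beads meet pairwise while the vertical bias is off; each candidate pair
#' (`floor(n_beads/2)` of them) forms a persistent analyte link with
#' probability `p(c)`; switching the bias back on separates all unlinked
#' beads.
#'
#' @param concentration relative analyte concentration.
#' @param model a [binding_model()].
#' @param n_beads beads loaded into the chamber.
#' @param field_mode `"2D"` or `"3D"`.
#' @param seed RNG seed.
#' @return list with `n_pairs`, `n_singles`, `p` (the probability used).
#' @export
simulate_binding <- function(concentration, model, n_beads = 200,
                             field_mode = "3D", seed = 1L) {
  if (concentration < 0)
    stop("invalid-argument: concentration must be >= 0")
  p <- pair_probability(model, concentration, field_mode)
  if (p < 0 || p > 1) stop("invalid-model: probability outside [0, 1]")
  set.seed(seed)
  n_cand <- floor(n_beads / 2)
  n_pairs <- stats::rbinom(1, n_cand, p)
  list(n_pairs = n_pairs, n_singles = n_beads - 2 * n_pairs, p = p)
}

#' Physics-based zero-analyte encounter simulation
#'
#' The mechanistic alternative to the binding model's baseline: unlinked
#' beads at 2% area fraction integrate the overdamped dynamics with
#' pairwise dipole forces and Brownian kicks under either the in-plane
#' (2D) or conical (3D) drive.  Persistent touching pairs are counted at
#' the end of the run: because the instantaneous dipole force alternates
#' sign within every rotation even when its time average is repulsive, a
#' pair only counts when its surface gap stays below 100 nm at every
#' sampled phase of the final field period.
#'
#' @param n_beads number of beads (>= 2).
#' @param field an [external_field()]; the 2D mode zeroes its vertical
#'   component.
#' @param mode `"2D"` or `"3D"`.
#' @param duration simulated seconds.
#' @param seed RNG seed.
#' @param bead_radius_um bead radius (2.8-um assay beads by default).
#' @param area_fraction packing fraction of the square arena.
#' @param contact_gap_um touching threshold (0.1 um).
#' @return list with `n_touching_pairs`, `positions`, `arena_um`.
#' @export
simulate_background_encounters <- function(n_beads = 50,
                                           field = external_field(),
                                           mode = c("3D", "2D"),
                                           duration = 60, seed = 1L,
                                           bead_radius_um = 1.4,
                                           area_fraction = 0.02,
                                           contact_gap_um = 0.1) {
  mode <- match.arg(mode)
  if (n_beads < 2) stop("invalid-argument: n_beads must be >= 2")
  side <- sqrt(n_beads * pi * bead_radius_um^2 / area_fraction)
  if (side < 6 * bead_radius_um)
    stop("packing error: arena too small for the bead count")
  set.seed(seed)
  pos <- matrix(NA_real_, n_beads, 2)
  placed <- 0L; tries <- 0L
  while (placed < n_beads) {
    cand <- stats::runif(2, bead_radius_um, side - bead_radius_um)
    # dispersed start: beads arrive in the chamber under the repulsive
    # conical drive, so no two start closer than one diameter of surface
    # gap
    ok <- placed == 0 ||
      all((pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2 >
            (4 * bead_radius_um)^2)
    if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
    tries <- tries + 1L
    if (tries > 200 * n_beads)
      stop("packing error: cannot place beads without overlap")
  }
  fld <- field
  if (mode == "2D") fld$h_vertical_oe <- 0
  beads <- lapply(seq_len(n_beads), function(i)
    magnetic_particle(bead_radius_um, pos = pos[i, ], id = i))
  cfg <- sim_config(duration = duration, thermal = TRUE, seed = seed)
  trs <- simulate_transport(beads, pattern = NULL, fld, cfg,
                            bounds = c(0, 0, side, side))
  times <- trs[[1]]$times
  period <- 1 / fld$freq_hz
  samp <- vapply(seq(0, period, length.out = 9)[-9], function(back) {
    max(which(times <= times[length(times)] - back + 1e-9))
  }, integer(1))
  lim <- 2 * bead_radius_um + contact_gap_um
  touching <- NULL
  for (i in samp) {
    posn <- do.call(rbind, lapply(trs, function(tr) tr$xy[i, ]))
    dmat <- as.matrix(stats::dist(posn))
    tch <- dmat < lim & upper.tri(dmat)
    touching <- if (is.null(touching)) tch else touching & tch
  }
  final <- do.call(rbind, lapply(trs, function(tr) tr$xy[nrow(tr$xy), ]))
  list(n_touching_pairs = sum(touching), positions = final,
       arena_um = side)
}

#' Chamber scene: bead layout with ground-truth links
#'
#' Places `n_pairs` touching doublets and `n_singles` isolated beads at
#' random non-overlapping positions in a square chamber.
#'
#' @param n_pairs,n_singles counts.
#' @param bead_radius_um bead radius, micrometres.
#' @param scale_um_per_px image scale (0.2 um/px).
#' @param image_px image side length, pixels.
#' @param snr signal-to-noise ratio of the rendering (`Inf` = noiseless).
#' @param seed RNG seed.
#' @return an object of class `chamber_scene` with bead centers (um),
#'   radii, pair links and rendering parameters.
#' @export
chamber_scene <- function(n_pairs, n_singles, bead_radius_um = 1.4,
                          scale_um_per_px = 0.2, image_px = 360,
                          snr = Inf, seed = 1L) {
  set.seed(seed)
  side <- image_px * scale_um_per_px
  r <- bead_radius_um
  margin <- 4 * r
  n_items <- n_pairs + n_singles
  centers <- matrix(NA_real_, 0, 2)
  links <- matrix(NA_integer_, 0, 2)
  place <- function(k) {
    # rejection-sample k item anchor points with generous spacing
    pts <- matrix(NA_real_, k, 2); placed <- 0L; tries <- 0L
    while (placed < k) {
      cand <- stats::runif(2, margin, side - margin)
      ok <- placed == 0 ||
        all((pts[seq_len(placed), 1] - cand[1])^2 +
              (pts[seq_len(placed), 2] - cand[2])^2 > (8 * r)^2)
      if (ok) { placed <- placed + 1L; pts[placed, ] <- cand }
      tries <- tries + 1L
      if (tries > 500 * k)
        stop("invalid-scene: chamber too small for the bead count")
    }
    pts
  }
  anchors <- place(n_items)
  beads <- list()
  for (i in seq_len(n_items)) {
    if (i <= n_pairs) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- r * c(cos(ang), sin(ang))
      beads[[length(beads) + 1]] <- anchors[i, ] - off
      beads[[length(beads) + 1]] <- anchors[i, ] + off
      links <- rbind(links, c(length(beads) - 1L, length(beads)))
    } else {
      beads[[length(beads) + 1]] <- anchors[i, ]
    }
  }
  centers <- do.call(rbind, beads)
  if (any(centers < r) || any(centers > side - r))
    stop("invalid-scene: beads outside the frame")
  structure(list(centers_um = centers,
                 radii_um = rep(r, nrow(centers)), links = links,
                 scale_um_per_px = scale_um_per_px, image_px = image_px,
                 snr = snr, background = 0.15, seed = seed),
            class = "chamber_scene")
}

#' Render a chamber scene to an image with ground truth
#'
#' Beads are bright disks with a Gaussian-blurred edge on a uniform
#' background; finite SNR adds Poisson shot noise and Gaussian read noise
#' (SNR = disk contrast over the combined noise sd).  Deterministic for a
#' given scene (the scene's seed drives the noise).
#'
#' @param scene a [chamber_scene()].
#' @return list with `image` (matrix, rows = image rows) and
#'   `ground_truth` (data.frame: row, col, radius_px, link id).
#' @export
render_chamber_image <- function(scene) {
  stopifnot(inherits(scene, "chamber_scene"))
  npx <- scene$image_px
  sc <- scene$scale_um_per_px
  r_px <- scene$radii_um / sc
  rows <- scene$centers_um[, 2] / sc   # y -> row (top-left origin)
  cols <- scene$centers_um[, 1] / sc
  img <- matrix(scene$background, npx, npx)
  edge <- 0.75   # edge softness in px
  for (i in seq_along(r_px)) {
    r0 <- ceiling(r_px[i] + 4 * edge)
    ri <- round(rows[i]); ci <- round(cols[i])
    rr <- max(1, ri - r0):min(npx, ri + r0)
    cc <- max(1, ci - r0):min(npx, ci + r0)
    dd <- sqrt(outer((rr - rows[i])^2, (cc - cols[i])^2, "+"))
    disk <- stats::pnorm((r_px[i] - dd) / edge)
    img[rr, cc] <- pmax(img[rr, cc],
                        scene$background + (1 - scene$background) * disk)
  }
  if (is.finite(scene$snr)) {
    set.seed(scene$seed + 1L)
    contrast <- 1 - scene$background
    # split the noise budget between shot and read noise
    sd_total <- contrast / scene$snr
    gain <- 2 / sd_total^2        # photons per intensity unit at signal 1
    shot <- stats::rpois(length(img), as.vector(img) * gain) / gain
    img <- matrix(shot, npx, npx) +
      matrix(stats::rnorm(length(img), 0, sd_total / sqrt(2)), npx, npx)
    img <- pmin(pmax(img, 0), 1)
  }
  gt <- data.frame(row = rows, col = cols, radius_px = r_px,
                   link = NA_integer_)
  if (nrow(scene$links))
    for (k in seq_len(nrow(scene$links)))
      gt$link[scene$links[k, ]] <- k
  list(image = img, ground_truth = gt)
}

#' Generate a synthetic dose-response dataset
#'
#' @param concentrations ascending relative concentrations.
#' @param model a [binding_model()].
#' @param n_beads beads per chamber.
#' @param replicates chambers per concentration.
#' @param field_mode `"2D"` or `"3D"`.
#' @param seed base RNG seed; chamber seeds derive from it.
#' @return data.frame with one row per chamber: concentration, replicate,
#'   seed, n_pairs, n_singles, pair_percentage.
#' @export
generate_dose_series <- function(concentrations, model, n_beads = 200,
                                 replicates = 10, field_mode = "3D",
                                 seed = 1L) {
  if (is.unsorted(concentrations))
    stop("invalid-argument: concentrations must be ascending")
  rows <- list()
  for (ci in seq_along(concentrations)) for (r in seq_len(replicates)) {
    s <- seed + 1000L * ci + r
    sim <- simulate_binding(concentrations[ci], model, n_beads,
                            field_mode, seed = s)
    rows[[length(rows) + 1]] <- data.frame(
      concentration = concentrations[ci], replicate = r, seed = s,
      n_pairs = sim$n_pairs, n_singles = sim$n_singles,
      pair_percentage = 100 * 2 * sim$n_pairs /
        (2 * sim$n_pairs + sim$n_singles))
  }
  do.call(rbind, rows)
}

#' Recover binding-model parameters from a dose series
#'
#' Binomial maximum likelihood on the per-chamber pair counts (candidate
#' pairs = `floor(n_beads/2)`) with the saturating model
#' `p(c) = p_bg + (p_max - p_bg) c / (c + K)`, plus a bootstrap over
#' chambers for confidence intervals.
#'
#' @param dataset data.frame from [generate_dose_series()].
#' @param n_boot bootstrap resamples (0 to skip).
#' @return list with `estimate` (p_bg, p_max, k), `logLik` and `ci`
#'   (2.5/97.5% bootstrap quantiles when requested).
#' @export
recover_binding_params <- function(dataset, n_boot = 100) {
  if (length(unique(dataset$concentration)) < 4 ||
      min(table(dataset$concentration)) < 5)
    stop("insufficient-data: need >= 4 concentrations with >= 5 ",
         "replicates")
  if (all(dataset$n_pairs == 0))
    stop("fit-failure: all pair counts are zero")
  n_cand <- floor((2 * dataset$n_pairs + dataset$n_singles) / 2)
  fit_once <- function(df, nc) {
    nll <- function(par) {
      p_bg <- stats::plogis(par[1]); p_max <- stats::plogis(par[2])
      k <- exp(par[3])
      if (p_max <= p_bg) return(1e10)
      p <- p_bg + (p_max - p_bg) * df$concentration /
        (df$concentration + k)
      -sum(stats::dbinom(df$n_pairs, nc, pmin(pmax(p, 1e-12),
                                              1 - 1e-12), log = TRUE))
    }
    start <- c(stats::qlogis(max(mean(df$n_pairs[df$concentration ==
                                                   min(df$concentration)] /
                                        nc[df$concentration ==
                                             min(df$concentration)]),
                                 0.01)),
               stats::qlogis(0.7), log(stats::median(df$concentration)))
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000))
    c(p_bg = stats::plogis(opt$par[1]), p_max = stats::plogis(opt$par[2]),
      k = exp(opt$par[3]), nll = opt$value)
  }
  est <- fit_once(dataset, n_cand)
  ci <- NULL
  if (n_boot > 0) {
    boots <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(split(seq_len(nrow(dataset)),
                                 dataset$concentration),
                           function(ii) sample(ii, replace = TRUE)))
      boots[b, ] <- fit_once(dataset[idx, ], n_cand[idx])[1:3]
    }
    ci <- apply(boots, 2, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    colnames(ci) <- c("p_bg", "p_max", "k")
  }
  list(estimate = est[1:3], logLik = -est[["nll"]], ci = ci)
}
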