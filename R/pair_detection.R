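# Bead detection in chamber micrographs, single/pair classification and
# dose-response statistics.
#
# Image convention: numeric matrix in [0, 1], row = image row (origin at
# the top-left), column = image column; default scale 0.2 um/px.

#' Read a chamber micrograph
#'
#' Reads a PNG or TIFF grayscale image into the package's matrix
#' convention (rows = image rows, origin top-left).  Color images are
#' averaged to grayscale.
#'
#' @param path image file.
#' @return numeric matrix in [0, 1].
#' @export
read_chamber_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3) img <- EBImage::channel(img, "gray")
  # EBImage stores x (column) first; transpose to row-major convention
  t(EBImage::imageData(img))
}

#' Write a chamber image as PNG
#' @param image numeric matrix in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chamber_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(image, 0), 1))), path)
  invisible(path)
}

#' Detect beads by multiscale Laplacian-of-Gaussian blob detection
#'
#' Background-subtracts the image (large-kernel Gaussian), computes
#' scale-normalized difference-of-Gaussian responses over a geometric
#' scale ladder spanning the expected radius range, finds local maxima in
#' (row, column, scale), and suppresses duplicates within one radius.
#'
#' @param image numeric matrix in [0, 1] (bright beads on dark
#'   background).
#' @param radius_range expected bead radius range in pixels,
#'   `c(min, max)`.
#' @param threshold minimum response (fraction of the maximal response
#'   when `relative = TRUE`).
#' @param relative interpret `threshold` relative to the strongest blob.
#' @param n_scales number of scales on the ladder.
#' @return data.frame with `row`, `col`, `radius_px` and `score`
#'   (response normalized to the strongest detection).
#' @export
detect_beads <- function(image, radius_range = c(4, 12),
                         threshold = 0.25, relative = TRUE,
                         n_scales = 8) {
  if (!is.matrix(image) || length(image) == 0)
    stop("invalid-input: image must be a non-empty numeric matrix")
  if (any(radius_range <= 0) || diff(radius_range) < 0)
    stop("invalid-input: radius range must be positive and ascending")
  # Gaussian blur with the kernel capped to the image size
  safe_blur <- function(img, sigma) {
    cap <- min(dim(img)) - 1
    if (cap %% 2 == 0) cap <- cap - 1
    r <- min(2 * ceiling(3 * sigma) + 1, cap)
    EBImage::gblur(img, sigma = sigma, radius = r)
  }
  # background subtraction: remove illumination structure slower than the
  # largest bead
  bg_sigma <- 4 * radius_range[2]
  ebi <- EBImage::Image(t(image))
  work <- ebi - safe_blur(ebi, bg_sigma)
  sigmas <- exp(seq(log(radius_range[1] / sqrt(2)),
                    log(radius_range[2] / sqrt(2)),
                    length.out = n_scales))
  k <- exp(mean(diff(log(sigmas))))
  blurred <- lapply(sigmas, function(s)
    EBImage::imageData(safe_blur(work, s)))
  blurred_k <- lapply(sigmas * k, function(s)
    EBImage::imageData(safe_blur(work, s)))
  # scale-normalized DoG response (positive at bright blob centers)
  resp <- lapply(seq_along(sigmas), function(i)
    (blurred[[i]] - blurred_k[[i]]) / (k - 1))
  stack <- array(unlist(resp), dim = c(dim(work), length(sigmas)))
  cands <- local_maxima_3d(stack)
  if (nrow(cands) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius_px = numeric(0), score = numeric(0)))
  vmax <- max(cands$value)
  cut <- if (relative) threshold * vmax else threshold
  cands <- cands[cands$value >= cut, , drop = FALSE]
  if (nrow(cands) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius_px = numeric(0), score = numeric(0)))
  # refine the scale by parabolic interpolation across the ladder
  dlog <- mean(diff(log(sigmas)))
  sig_ref <- vapply(seq_len(nrow(cands)), function(i) {
    s <- cands$s[i]
    if (s == 1 || s == length(sigmas)) return(sigmas[s])
    v0 <- stack[cands$x[i], cands$y[i], s]
    vm <- stack[cands$x[i], cands$y[i], s - 1]
    vp <- stack[cands$x[i], cands$y[i], s + 1]
    den <- vm - 2 * v0 + vp
    off <- if (den < 0) max(-1, min(1, 0.5 * (vm - vp) / den)) else 0
    exp(log(sigmas[s]) + off * dlog)
  }, numeric(1))
  # EBImage data is (x, y): x index = our column
  det <- data.frame(row = cands$y, col = cands$x,
                    radius_px = sqrt(2) * sig_ref,
                    score = cands$value / vmax)
  det <- det[order(-det$score), ]
  # duplicate suppression within one radius
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      j <- (i + 1):nrow(det)
      d2 <- (det$row[j] - det$row[i])^2 + (det$col[j] - det$col[i])^2
      keep[j][d2 < pmax(det$radius_px[i], det$radius_px[j])^2] <- FALSE
    }
  }
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  det$radius_px <- vapply(seq_len(nrow(det)), function(i)
    refine_radius(image, det$row[i], det$col[i], det$radius_px[i]),
    numeric(1))
  det
}

# radius refinement: median half-maximum crossing of radial intensity
# profiles (robust to a touching neighbour affecting a few rays)
refine_radius <- function(image, row, col, r_est, n_rays = 16) {
  nr <- nrow(image); nc <- ncol(image)
  r_max <- 2 * r_est
  rad <- seq(0.5, r_max, by = 0.5)
  peak <- image[max(1, min(nr, round(row))), max(1, min(nc, round(col)))]
  bg <- stats::median(image)
  half <- bg + (peak - bg) / 2
  cross <- vapply(seq_len(n_rays), function(k) {
    th <- 2 * pi * (k - 1) / n_rays
    rr <- round(row + rad * sin(th)); cc <- round(col + rad * cos(th))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (!any(ok)) return(NA_real_)
    prof <- image[cbind(rr[ok], cc[ok])]
    below <- which(prof < half)
    if (length(below) == 0) return(NA_real_)
    rad[ok][below[1]]
  }, numeric(1))
  out <- stats::median(cross, na.rm = TRUE)
  if (!is.finite(out)) r_est else out
}

# 26-neighborhood local maxima of a 3D response stack, returned with
# (x, y, s) indices and values; borders excluded in x, y
local_maxima_3d <- function(stack) {
  dx <- dim(stack)[1]; dy <- dim(stack)[2]; ds <- dim(stack)[3]
  out <- list()
  for (s in seq_len(ds)) {
    sl <- stack[, , s]
    core <- sl[2:(dx - 1), 2:(dy - 1)]
    ismax <- core > 0
    for (ox in -1:1) for (oy in -1:1) {
      if (ox == 0 && oy == 0) next
      ismax <- ismax & core >= sl[2:(dx - 1) + ox, 2:(dy - 1) + oy]
    }
    if (s > 1) {
      lo <- stack[, , s - 1]
      for (ox in -1:1) for (oy in -1:1)
        ismax <- ismax & core >= lo[2:(dx - 1) + ox, 2:(dy - 1) + oy]
    }
    if (s < ds) {
      hi <- stack[, , s + 1]
      for (ox in -1:1) for (oy in -1:1)
        ismax <- ismax & core >= hi[2:(dx - 1) + ox, 2:(dy - 1) + oy]
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1]] <- data.frame(
        x = idx[, 1] + 1L, y = idx[, 2] + 1L, s = s,
        value = core[ismax])
    }
  }
  if (length(out) == 0)
    return(data.frame(x = integer(0), y = integer(0), s = integer(0),
                      value = numeric(0)))
  do.call(rbind, out)
}

#' Classify detections into singles, pairs and clusters
#'
#' Two detections touch when their center distance is at most
#' `(r1 + r2) * (1 + tolerance)`.  Connected components of the touch
#' graph of size 1 are singles, size 2 pairs, size > 2 clusters (reported
#' but excluded from the pair percentage, which is the percentage of
#' beads that are members of a pair).
#'
#' @param detections data.frame from [detect_beads()] (or any frame with
#'   `row`, `col`, `radius_px`).
#' @param tolerance touch tolerance as a fraction of the summed radii.
#' @return a `pair_summary` list: `n_singles`, `n_pairs`,
#'   `n_clusters_gt2`, `cluster_sizes`, `pair_percentage`, `components`.
#' @export
classify_pairs <- function(detections, tolerance = 0.2) {
  if (tolerance < 0) stop("invalid-argument: tolerance must be >= 0")
  n <- nrow(detections)
  if (n == 0)
    return(structure(list(n_singles = 0L, n_pairs = 0L,
                          n_clusters_gt2 = 0L, cluster_sizes = integer(0),
                          pair_percentage = NaN,
                          components = integer(0)),
                     class = "pair_summary"))
  # union-find with per-pair contact thresholds
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((detections$row[i] - detections$row[j])^2 +
                (detections$col[i] - detections$col[j])^2)
    lim <- (detections$radius_px[i] + detections$radius_px[j]) *
      (1 + tolerance)
    if (d <= lim) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  sizes <- tabulate(comp)
  n_singles <- sum(sizes == 1)
  n_pairs <- sum(sizes == 2)
  n_clusters <- sum(sizes > 2)
  denom <- 2 * n_pairs + n_singles
  structure(list(n_singles = n_singles, n_pairs = n_pairs,
                 n_clusters_gt2 = n_clusters,
                 cluster_sizes = sizes[sizes > 2],
                 pair_percentage =
                   if (denom > 0) 100 * 2 * n_pairs / denom else NaN,
                 components = comp),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf(
    "pair summary: %d singles, %d pairs, %d clusters(>2); pair%% = %.1f\n",
    x$n_singles, x$n_pairs, x$n_clusters_gt2, x$pair_percentage))
  invisible(x)
}

#' Build a pair summary directly from counts
#' @param n_pairs,n_singles,n_clusters_gt2 counts.
#' @return a `pair_summary`.
#' @export
pair_summary <- function(n_pairs, n_singles, n_clusters_gt2 = 0L) {
  denom <- 2 * n_pairs + n_singles
  structure(list(n_singles = as.integer(n_singles),
                 n_pairs = as.integer(n_pairs),
                 n_clusters_gt2 = as.integer(n_clusters_gt2),
                 cluster_sizes = integer(0),
                 pair_percentage =
                   if (denom > 0) 100 * 2 * n_pairs / denom else NaN,
                 components = integer(0)),
            class = "pair_summary")
}

#' Dose-response table from per-chamber pair summaries
#'
#' @param summaries list of `pair_summary` objects (replicate chambers).
#' @param concentrations relative analyte concentration per summary
#'   (dimensionless, matching the assay axis labels).
#' @return data.frame with one row per concentration: `median`, `q1`,
#'   `q3`, `sd` and `n` of the replicate pair percentages.
#' @export
dose_response <- function(summaries, concentrations) {
  if (length(summaries) == 0)
    stop("insufficient-data: no chambers supplied")
  if (length(summaries) != length(concentrations))
    stop("invalid-argument: one concentration per summary required")
  pp <- vapply(summaries, `[[`, numeric(1), "pair_percentage")
  split_pp <- split(pp, concentrations)
  conc <- as.numeric(names(split_pp))
  out <- data.frame(
    concentration = conc,
    median = vapply(split_pp, stats::median, numeric(1)),
    q1 = vapply(split_pp, stats::quantile, numeric(1), probs = 0.25),
    q3 = vapply(split_pp, stats::quantile, numeric(1), probs = 0.75),
    sd = vapply(split_pp, stats::sd, numeric(1)),
    n = vapply(split_pp, length, numeric(1)))
  out <- out[order(out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Zero-analyte background fold change between 2D and 3D drives
#'
#' Mean spontaneous pair count under the in-plane-only (2D) drive divided
#' by the mean under the conical (3D) drive.
#'
#' @param pairs_2d,pairs_3d numeric vectors of zero-analyte pair counts
#'   (or lists of `pair_summary` objects).
#' @return the fold change; `Inf` when the 3D mean is zero.
#' @export
field_mode_ratio <- function(pairs_2d, pairs_3d) {
  as_counts <- function(x) {
    if (is.list(x)) vapply(x, `[[`, numeric(1), "n_pairs") else x
  }
  a <- as_counts(pairs_2d); b <- as_counts(pairs_3d)
  if (length(a) == 0 || length(b) == 0)
    stop("insufficient-data: both field modes need at least one chamber")
  if (mean(b) == 0) return(Inf)
  mean(a) / mean(b)
}
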