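#' Specification of a synthetic agave field
#'
#' Describes a segmented-layer image to be generated: rows of roughly
#' circular plants on a jittered lattice, with the geometry of commercial
#' blue-agave plantations at a 3 cm/px ground sampling distance — 3.5 m row
#' spacing (117 px), 1.1 m in-row plant spacing (37 px) and plant diameters
#' of roughly 1--2 m (radii 16--33 px), so that large plants overlap their
#' row neighbours by geometry alone. Degradations emulate what the upstream
#' segmentation produces: weed speckle (small off-lattice blobs), interior
#' holes, and illumination dropouts that erase angular sectors of a plant.
#'
#' @param height_px,width_px Canvas size in pixels.
#' @param row_spacing_px Distance between plant rows (default 117 px = 3.5 m).
#' @param plant_spacing_px In-row distance between plants (default 37 px =
#'   1.1 m).
#' @param plant_radius_px_range Min/max plant radius in pixels (default
#'   c(16, 33), i.e. diameters of ~1--2 m).
#' @param jitter_px Uniform positional jitter applied to each plant center
#'   (default 2).
#' @param overlap_prob Probability that a plant is shifted toward its left
#'   row neighbour until the two disks intersect (default 0.3).
#' @param weed_density_per_kpx Expected weeds per 1000 pixels of canvas
#'   (default 0.05); weeds are disks of radius 1--4 px.
#' @param hole_prob Probability that a plant gets 1--3 small interior holes
#'   (default 0.2).
#' @param dropout_prob Probability that an angular sector of a plant
#'   (25--100% of the disk) is erased, mimicking illumination loss; at
#'   fraction 1 the plant is absent from the image but present in the
#'   ground truth (default 0.05).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class \code{"field_spec"}.
#' @seealso [generate_field()], [field_presets()]
#' @export
field_spec <- function(height_px = 585L, width_px = 900L,
                       row_spacing_px = 117, plant_spacing_px = 37,
                       plant_radius_px_range = c(16, 33),
                       jitter_px = 2, overlap_prob = 0.3,
                       weed_density_per_kpx = 0.05,
                       hole_prob = 0.2, dropout_prob = 0.05,
                       seed = 1L) {
  stopifnot(height_px >= 1, width_px >= 1,
            row_spacing_px > 0, plant_spacing_px > 0,
            length(plant_radius_px_range) == 2L,
            plant_radius_px_range[1L] > 0,
            plant_radius_px_range[1L] <= plant_radius_px_range[2L],
            jitter_px >= 0)
  for (p in c(overlap_prob, hole_prob, dropout_prob))
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  if (weed_density_per_kpx < 0) stop("weed density must be >= 0")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 row_spacing_px = row_spacing_px,
                 plant_spacing_px = plant_spacing_px,
                 plant_radius_px_range = as.numeric(plant_radius_px_range),
                 jitter_px = jitter_px,
                 overlap_prob = overlap_prob,
                 weed_density_per_kpx = weed_density_per_kpx,
                 hole_prob = hole_prob,
                 dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(paste0("field spec: %dx%d px, rows every %g px, plants every ",
                     "%g px, radius %g-%g px\n  jitter %g, overlap %g, weeds ",
                     "%g/kpx, holes %g, dropout %g, seed %d\n"),
              x$height_px, x$width_px, x$row_spacing_px, x$plant_spacing_px,
              x$plant_radius_px_range[1L], x$plant_radius_px_range[2L],
              x$jitter_px, x$overlap_prob, x$weed_density_per_kpx,
              x$hole_prob, x$dropout_prob, x$seed))
  invisible(x)
}

# draw value into a disk (optionally restricted to an angular sector)
paint_disk <- function(canvas, cy, cx, rad, value,
                       sector = NULL) {
  H <- nrow(canvas); W <- ncol(canvas)
  r1 <- max(1L, floor(cy - rad)); r2 <- min(H, ceiling(cy + rad))
  c1 <- max(1L, floor(cx - rad)); c2 <- min(W, ceiling(cx + rad))
  if (r1 > r2 || c1 > c2) return(canvas)
  dy2 <- (r1:r2 - cy)^2
  dx2 <- (c1:c2 - cx)^2
  inside <- outer(dy2, dx2, "+") <= rad^2
  if (!is.null(sector)) {
    ang <- outer(r1:r2 - cy, c1:c2 - cx, function(y, x) atan2(y, x)) %% (2 * pi)
    a0 <- sector[1L] %% (2 * pi)
    width <- sector[2L]
    rel <- (ang - a0) %% (2 * pi)
    inside <- inside & rel <= width
  }
  sub <- canvas[r1:r2, c1:c2, drop = FALSE]
  sub[inside] <- value
  canvas[r1:r2, c1:c2] <- sub
  canvas
}

#' Generate a synthetic segmented agave field
#'
#' Builds a segmented-layer image plus exact ground truth from a
#' [field_spec()]. Plants are placed row by row, left to right; every
#' stochastic choice consumes the seeded generator in a fixed, documented
#' order (radii, jitter, overlap, holes, dropout, then weeds), so the same
#' spec yields a bit-identical field on any platform.
#'
#' Ground truth contains every generated plant center — including plants
#' fully erased by dropout, which become guaranteed false negatives for any
#' counter, just as illumination losses do in real surveys.
#'
#' @param spec A [field_spec()].
#' @return An object of class \code{"synthetic_field"}: list with
#'   \describe{
#'     \item{image}{H x W x 3 array, plant pixels in green (0, 170, 0) on
#'       black}
#'     \item{mask}{the binary plant+weed mask the image encodes}
#'     \item{gt}{data frame of plant centers \code{row}, \code{col}
#'       (1-based)}
#'     \item{plants}{data frame with per-plant center, radius and the
#'       degradations applied}
#'     \item{weeds}{data frame of weed centers and radii}
#'     \item{spec}{the input spec}
#'   }
#' @export
generate_field <- function(spec) {
  if (!inherits(spec, "field_spec")) stop("'spec' must be a field_spec")
  H <- spec$height_px; W <- spec$width_px
  rmin <- spec$plant_radius_px_range[1L]
  rmax <- spec$plant_radius_px_range[2L]
  margin <- rmax + spec$jitter_px
  n_rows <- floor((H - 2 * margin) / spec$row_spacing_px) + 1
  n_per_row <- floor((W - 2 * margin) / spec$plant_spacing_px) + 1
  if (n_rows < 1 || n_per_row < 1)
    stop("lattice infeasible for image size")
  y0 <- (H - (n_rows - 1) * spec$row_spacing_px) / 2
  x0 <- (W - (n_per_row - 1) * spec$plant_spacing_px) / 2
  n <- n_rows * n_per_row

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  # fixed draw order (all vectors over plants in raster order)
  radius <- stats::runif(n, rmin, rmax)
  jy <- stats::runif(n, -spec$jitter_px, spec$jitter_px)
  jx <- stats::runif(n, -spec$jitter_px, spec$jitter_px)
  ov_event <- stats::runif(n) < spec$overlap_prob
  ov_depth <- stats::runif(n, 3, 9)
  hole_event <- stats::runif(n) < spec$hole_prob
  n_holes <- floor(stats::runif(n, 1, 4))           # 1..3
  hole_frac <- matrix(stats::runif(3L * n, 0.1, 0.6), ncol = 3L)
  hole_ang <- matrix(stats::runif(3L * n, 0, 2 * pi), ncol = 3L)
  hole_rad <- matrix(stats::runif(3L * n, 1, 3), ncol = 3L)
  drop_event <- stats::runif(n) < spec$dropout_prob
  drop_frac <- stats::runif(n, 0.25, 1)
  drop_ang <- stats::runif(n, 0, 2 * pi)

  row_of <- rep(seq_len(n_rows), each = n_per_row)
  pos_of <- rep(seq_len(n_per_row), times = n_rows)
  cy <- y0 + (row_of - 1) * spec$row_spacing_px + jy
  cx <- x0 + (pos_of - 1) * spec$plant_spacing_px + jx

  # overlap: shift a flagged plant toward its (already placed) left
  # neighbour until the disks interpenetrate by ov_depth, never closer than
  # half the sum of radii
  for (i in seq_len(n)) {
    if (pos_of[i] == 1L || !ov_event[i]) next
    d <- cx[i] - cx[i - 1L]
    rsum <- radius[i] + radius[i - 1L]
    target <- max(rsum - ov_depth[i], 0.5 * rsum)
    if (d > target) cx[i] <- cx[i - 1L] + target
  }

  plant_mask <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    plant_mask <- paint_disk(plant_mask, cy[i], cx[i], radius[i], 1L)
  }
  # interior holes
  for (i in which(hole_event)) {
    for (h in seq_len(n_holes[i])) {
      hy <- cy[i] + hole_frac[i, h] * radius[i] * sin(hole_ang[i, h])
      hx <- cx[i] + hole_frac[i, h] * radius[i] * cos(hole_ang[i, h])
      plant_mask <- paint_disk(plant_mask, hy, hx, hole_rad[i, h], 0L)
    }
  }
  # illumination dropout: erase an angular sector of the plant disk
  for (i in which(drop_event)) {
    if (drop_frac[i] >= 0.999) {
      plant_mask <- paint_disk(plant_mask, cy[i], cx[i], radius[i] + 0.5, 0L)
    } else {
      plant_mask <- paint_disk(plant_mask, cy[i], cx[i], radius[i] + 0.5, 0L,
                               sector = c(drop_ang[i],
                                          drop_frac[i] * 2 * pi))
    }
  }

  # weeds, drawn last so degradations never erase them
  n_weeds <- stats::rpois(1L, spec$weed_density_per_kpx * H * W / 1000)
  wy <- stats::runif(n_weeds, 1, H)
  wx <- stats::runif(n_weeds, 1, W)
  wr <- stats::runif(n_weeds, 1, 4)
  mask <- plant_mask
  for (k in seq_len(n_weeds)) {
    mask <- paint_disk(mask, wy[k], wx[k], wr[k], 1L)
  }

  image <- array(0, dim = c(H, W, 3L))
  image[, , 2L][mask == 1L] <- 170

  structure(list(
    image = image,
    mask = mask,
    gt = data.frame(row = cy, col = cx),
    plants = data.frame(row = cy, col = cx, radius_px = radius,
                        overlapped = ov_event & pos_of > 1L,
                        holes = ifelse(hole_event, n_holes, 0L),
                        dropout_frac = ifelse(drop_event, drop_frac, 0)),
    weeds = data.frame(row = wy, col = wx, radius_px = wr),
    spec = spec
  ), class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("synthetic field: %dx%d px, %d plant(s), %d weed(s), seed %d\n",
              nrow(x$mask), ncol(x$mask), nrow(x$gt), nrow(x$weeds),
              x$spec$seed))
  invisible(x)
}

#' Named presets emulating the three surveyed fields
#'
#' \describe{
#'   \item{field1}{high plant-size heterogeneity and heavy along-row
#'     overlap; little weed, good illumination}
#'   \item{field2}{moderate overlap, weeds, and illumination dropouts}
#'   \item{field3}{homogeneous plant sizes, moderate overlap, the most weed}
#' }
#'
#' @param name Optional preset name; if omitted, all presets are returned as
#'   a named list.
#' @param seed Seed stored in the returned spec(s).
#' @return A \code{field_spec} (if \code{name} given) or a named list of the
#'   three.
#' @export
field_presets <- function(name = NULL, seed = 1L) {
  presets <- list(
    field1 = field_spec(plant_radius_px_range = c(16, 33),
                        jitter_px = 3, overlap_prob = 0.6,
                        weed_density_per_kpx = 0.02,
                        hole_prob = 0.2, dropout_prob = 0.02, seed = seed),
    field2 = field_spec(plant_radius_px_range = c(15, 30),
                        jitter_px = 3, overlap_prob = 0.35,
                        weed_density_per_kpx = 0.06,
                        hole_prob = 0.2, dropout_prob = 0.12, seed = seed),
    field3 = field_spec(plant_radius_px_range = c(19, 24),
                        jitter_px = 2, overlap_prob = 0.35,
                        weed_density_per_kpx = 0.08,
                        hole_prob = 0.15, dropout_prob = 0.02, seed = seed)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s' (have: %s)", name,
                 paste(names(presets), collapse = ", ")))
  presets[[name]]
}
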