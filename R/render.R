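#' Imaging configuration for the bright-field renderer and segmenter
#'
#' @param pixel_size Pixel size in µm/px. The default 0.34 µm/px is a
#'   typical calibration for the microfluidic imaging setup and is
#'   deliberately configurable; measurement accuracy improves as it
#'   shrinks.
#' @param frame_width,frame_height Frame size in pixels.
#' @param channel_width Width of the microfluidic channel in µm (the
#'   constriction cross-section is 15 µm x 15 µm; the vertical dimension
#'   is rendered with dark wall bands).
#' @param background,cell_intensity,wall_intensity Grayscale levels in
#'   `[0, 1]` of the background, the cell interior and the channel walls.
#' @param blur_sigma Gaussian point-spread blur in pixels (0 disables).
#' @param noise_sd Additive Gaussian noise SD (0 disables).
#' @param supersample Sub-pixel sampling factor for anti-aliased coverage.
#' @return A list of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 0.34,
                           frame_width = 80,
                           frame_height = 60,
                           channel_width = 15,
                           background = 0.8,
                           cell_intensity = 0.3,
                           wall_intensity = 0.1,
                           blur_sigma = 0,
                           noise_sd = 0,
                           supersample = 8) {
  stopifnot(pixel_size > 0, frame_width >= 16, frame_height >= 16,
            supersample >= 1, blur_sigma >= 0, noise_sd >= 0,
            background > cell_intensity)
  structure(list(pixel_size = pixel_size, frame_width = frame_width,
                 frame_height = frame_height, channel_width = channel_width,
                 background = background, cell_intensity = cell_intensity,
                 wall_intensity = wall_intensity, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, supersample = supersample),
            class = "imaging_config")
}

# anti-aliased coverage of an ellipse on the pixel grid:
# fraction of each pixel inside the ellipse, by supersampling
ellipse_coverage <- function(nx, ny, px, cx, cy, a, b, theta = 0, ss = 8) {
  xs <- ((seq_len(nx * ss)) - 0.5) / ss * px
  ys <- ((seq_len(ny * ss)) - 0.5) / ss * px
  X <- matrix(xs, ny * ss, nx * ss, byrow = TRUE)
  Y <- matrix(ys, ny * ss, nx * ss)
  ct <- cos(theta); st <- sin(theta)
  U <- (X - cx) * ct + (Y - cy) * st
  V <- -(X - cx) * st + (Y - cy) * ct
  inside <- ((U / a)^2 + (V / b)^2 <= 1) + 0
  t1 <- t(rowsum(t(inside), rep(seq_len(nx), each = ss)))
  rowsum(t1, rep(seq_len(ny), each = ss)) / ss^2
}

# sub-pixel polygon of the same ellipse, in pixel coordinates
# (pixel centres at integer coordinates, x right / y down)
ellipse_polygon <- function(px, cx, cy, a, b, theta = 0, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- a * cos(t); v <- b * sin(t)
  x <- (cx + u * cos(theta) - v * sin(theta)) / px + 0.5
  y <- (cy + u * sin(theta) + v * cos(theta)) / px + 0.5
  list(x = x, y = y)
}

#' Render a bright-field frame of a single cell in the channel
#'
#' Draws the event's ground-truth ellipse as a dark, anti-aliased object
#' on a brighter background, with the channel walls as dark horizontal
#' bands, optional Gaussian point-spread blur and additive Gaussian
#' noise. The cell is placed at the centre of the frame horizontally and
#' at the event's `center_y` offset from the channel axis.
#'
#' @param event A single ground-truth event (one row of
#'   [sample_events()]), or `NULL` for a background-only frame.
#' @param imaging An [imaging_config()].
#' @return A list with `image` (matrix, rows = y, columns = x, values in
#'   `[0, 1]`) and `truth` (an `fdc_contour` with the sub-pixel ellipse
#'   boundary; `NULL` for a blank frame).
#' @export
render_frame <- function(event, imaging = imaging_config()) {
  stopifnot(inherits(imaging, "imaging_config"))
  px <- imaging$pixel_size
  nx <- imaging$frame_width
  ny <- imaging$frame_height
  img <- matrix(imaging$background, ny, nx)

  # channel walls: dark bands beyond +/- channel_width/2 from the axis
  yc <- ny / 2 * px
  yy <- (seq_len(ny) - 0.5) * px
  wall <- abs(yy - yc) > imaging$channel_width / 2
  img[wall, ] <- imaging$wall_intensity

  truth <- NULL
  if (!is.null(event)) {
    ev <- as.list(event)
    q <- ev$aspect_ratio
    b <- sqrt(ev$true_area / (pi * q))
    a <- q * b
    cx <- nx / 2 * px
    cy <- yc + ev$center_y
    if (2 * a >= (nx - 4) * px || (abs(ev$center_y) + b) >
        imaging$channel_width / 2 || 2 * b >= (ny - 4) * px) {
      stop("cell does not fit inside the field of view", call. = FALSE)
    }
    cov <- ellipse_coverage(nx, ny, px, cx, cy, a, b, ev$orientation,
                            imaging$supersample)
    img <- img - (imaging$background - imaging$cell_intensity) * cov
    poly <- ellipse_polygon(px, cx, cy, a, b, ev$orientation)
    truth <- fdc_contour(poly$x, poly$y, pixel_size = px)
  }

  if (imaging$blur_sigma > 0) {
    img <- gaussian_blur(img, imaging$blur_sigma)
  }
  if (imaging$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, imaging$noise_sd), ny, nx)
  }
  list(image = img, truth = truth)
}

# separable Gaussian blur with reflected borders
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rev(v[seq_len(r)]), v, rev(v[seq(length(v) - r + 1, length(v))]))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(tmp, 1, pad_conv))
}

#' Render a two-channel confocal platelet image
#'
#' Produces a synthetic confocal section of a spread platelet with an
#' alpha-tubulin marginal-band channel and an F-actin channel, for
#' validating the line-profile metrics. The tubulin channel is a Gaussian
#' annulus at the platelet radius (`ring` mode) or at a condensed radius
#' (`coiled` mode, emulating marginal-band coiling); the ground-truth
#' edge-to-edge distance of the ring is twice the annulus radius. The
#' actin channel is a uniform disc (`uniform`) or an edge-weighted disc
#' whose outer band (the subcortical region) is brighter by
#' `actin_edge_weight` (`subcortical`).
#'
#' @param radius Platelet radius in µm, in `(0.5, 5)`.
#' @param tubulin_mode `"ring"` or `"coiled"`.
#' @param actin_mode `"uniform"` or `"subcortical"`.
#' @param actin_edge_weight Intensity multiplier of the subcortical band.
#' @param coil_factor Fraction of the platelet radius at which the coiled
#'   ring sits.
#' @param band_fraction Radial width fraction of the subcortical band
#'   (matches the outer band of [actin_peripheral_index()]).
#' @param ring_sigma Radial thickness (Gaussian SD, µm) of the tubulin
#'   annulus.
#' @param pixel_size Pixel size in µm/px (confocal sampling).
#' @param blur_sigma Point-spread blur in µm (applied to both channels).
#' @return A list with `tubulin` and `actin` image matrices, `pixel_size`,
#'   `center` (µm), and ground-truth fields `ring_radius` and
#'   `edge_distance` (µm).
#' @export
render_confocal_platelet <- function(radius,
                                     tubulin_mode = c("ring", "coiled"),
                                     actin_mode = c("uniform", "subcortical"),
                                     actin_edge_weight = 2,
                                     coil_factor = 0.6,
                                     band_fraction = 0.25,
                                     ring_sigma = 0.15,
                                     pixel_size = 0.08,
                                     blur_sigma = 0.05) {
  tubulin_mode <- match.arg(tubulin_mode)
  actin_mode <- match.arg(actin_mode)
  stopifnot(radius > 0.5, radius < 5, actin_edge_weight > 0)

  half <- radius + 1.5                     # field half-width, µm
  n <- 2 * ceiling(half / pixel_size) + 1
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_size
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  rho <- sqrt(X^2 + Y^2)

  r_ring <- if (tubulin_mode == "ring") radius else coil_factor * radius
  tubulin <- exp(-(rho - r_ring)^2 / (2 * ring_sigma^2))

  actin <- (rho <= radius) + 0
  if (actin_mode == "subcortical") {
    band <- rho > (1 - band_fraction) * radius & rho <= radius
    actin[band] <- actin_edge_weight
  }

  if (blur_sigma > 0) {
    s_px <- blur_sigma / pixel_size
    tubulin <- gaussian_blur(tubulin, s_px)
    actin <- gaussian_blur(actin, s_px)
  }

  # physical coordinate of pixel j is (j - 0.5) * pixel_size
  list(tubulin = tubulin, actin = actin, pixel_size = pixel_size,
       center = c(x = n / 2 * pixel_size, y = n / 2 * pixel_size),
       ring_radius = r_ring, edge_distance = 2 * r_ring)
}
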