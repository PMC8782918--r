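#' Closed cell contour in pixel coordinates
#'
#' Constructs an `fdc_contour`: an ordered, closed polygon of (sub-pixel)
#' boundary coordinates with a pixel-size calibration. Coordinates are
#' pixel-centred (pixel `j` sits at coordinate `j`), x right / y down.
#' The polygon is normalised to counter-clockwise orientation (positive
#' signed area in the image coordinate system) and must have at least 8
#' distinct vertices.
#'
#' @param x,y Vertex coordinates in pixels, without a repeated closing
#'   vertex.
#' @param pixel_size Calibration in µm/px.
#' @param frame_id Optional frame identifier.
#' @return An object of class `fdc_contour`.
#' @export
fdc_contour <- function(x, y, pixel_size, frame_id = NA_character_) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            is.numeric(pixel_size), pixel_size > 0)
  if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  if (length(unique(paste(x, y))) < 8) {
    stop("a contour needs at least 8 distinct vertices", call. = FALSE)
  }
  sa <- signed_area(x, y)
  if (sa < 0) {             # normalise to positive signed area
    x <- rev(x)
    y <- rev(y)
  }
  structure(list(x = x, y = y, pixel_size = pixel_size,
                 frame_id = frame_id),
            class = "fdc_contour")
}

#' @export
print.fdc_contour <- function(x, ...) {
  cat(sprintf("<fdc_contour> %d vertices, %.3g um/px, area %.4g um^2\n",
              length(x$x), x$pixel_size, contour_area(x)))
  invisible(x)
}

signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

check_contour <- function(c) {
  if (!inherits(c, "fdc_contour")) {
    stop("expected an `fdc_contour`", call. = FALSE)
  }
  if (length(unique(paste(c$x, c$y))) < 3) {
    stop("degenerate contour: fewer than 3 distinct vertices",
         call. = FALSE)
  }
  invisible(c)
}

#' Contour area (shoelace formula)
#'
#' @param c An [fdc_contour()].
#' @return Absolute polygon area times `pixel_size^2`, in µm².
#' @export
contour_area <- function(c) {
  check_contour(c)
  abs(signed_area(c$x, c$y)) * c$pixel_size^2
}

#' Contour perimeter
#'
#' @param c An [fdc_contour()].
#' @return Sum of Euclidean edge lengths of the closed polygon times
#'   `pixel_size`, in µm.
#' @export
contour_perimeter <- function(c) {
  check_contour(c)
  x <- c(c$x, c$x[1])
  y <- c(c$y, c$y[1])
  sum(sqrt(diff(x)^2 + diff(y)^2)) * c$pixel_size
}

#' Convex-hull area ratio
#'
#' Ratio of the convex-hull area of the vertices to the contour area.
#' Equals 1 for convex shapes and grows with boundary roughness or
#' apparent aggregates; it is the debris filter used upstream of gating
#' (events with ratio above 1.1 are rejected by the default gates).
#'
#' @param c An [fdc_contour()].
#' @return Dimensionless ratio `>= 1`.
#' @export
area_ratio <- function(c) {
  check_contour(c)
  h <- grDevices::chull(c$x, c$y)
  hull_area <- abs(signed_area(c$x[h], c$y[h]))
  poly_area <- abs(signed_area(c$x, c$y))
  if (poly_area <= 0) stop("degenerate contour: zero area", call. = FALSE)
  max(hull_area / poly_area, 1)
}

# circular moving-average smoothing of a closed polygon coordinate
smooth_closed <- function(v, k) {
  if (k <= 1) return(v)
  h <- k %/% 2
  vp <- c(tail(v, h), v, head(v, h))
  stats::filter(vp, rep(1 / k, k), sides = 2)[(h + 1):(h + length(v))]
}

# spline upsampling of an image on the unit pixel grid
upsample_image <- function(img, f) {
  ny <- nrow(img)
  nx <- ncol(img)
  xo <- seq(1, nx, length.out = (nx - 1) * f + 1)
  yo <- seq(1, ny, length.out = (ny - 1) * f + 1)
  interp <- function(x, y, xout) spline(x, y, xout = xout,
                                        method = "natural")$y
  t1 <- apply(img, 1, function(r) interp(seq_len(nx), r, xo))
  t2 <- apply(t1, 1, function(cc) interp(seq_len(ny), cc, yo))
  list(img = t2, x = xo, y = yo)
}

# discrete signed curvature of a closed polygon (per vertex, 1/px)
polygon_curvature <- function(x, y, smooth = 15) {
  n <- length(x)
  nxt <- function(v) c(v[-1], v[1])
  prv <- function(v) c(v[n], v[-n])
  dx <- (nxt(x) - prv(x)) / 2
  dy <- (nxt(y) - prv(y)) / 2
  ddx <- nxt(x) - 2 * x + prv(x)
  ddy <- nxt(y) - 2 * y + prv(y)
  sp <- pmax((dx^2 + dy^2)^1.5, 1e-12)
  kap <- (dx * ddy - dy * ddx) / sp
  smooth_closed(kap, smooth)
}

#' Segment a bright-field frame into cell contours
#'
#' Reproduces the measurement stage of the acquisition software on
#' synthetic (or user-supplied) bright-field frames. The background is
#' estimated as the median of the border pixels; pixels darker than
#' `background - threshold_offset` form the detection mask. Connected
#' components touching the frame border (channel walls) or smaller than
#' `min_area_px` are discarded. Each remaining cell's boundary is traced
#' as a sub-pixel iso-intensity polygon, at the level halfway between the
#' background and the cell's interior intensity, on a spline-upsampled
#' copy of the frame; the polygon is then smoothed with a circular moving
#' average and each vertex is pushed outward along its normal by
#' \eqn{\kappa \sigma^2 / 2} (with \eqn{\sigma^2} the pixel-integration
#' variance `1/12` px² plus any point-spread variance), the first-order
#' correction for the inward bias of a threshold level set at curved
#' boundaries.
#'
#' @param image Grayscale matrix (rows = y, columns = x).
#' @param pixel_size Calibration in µm/px.
#' @param params List of tuning parameters: `threshold_offset` (intensity
#'   units below background, default 0.15), `min_area_px` (default 10),
#'   `smoothing` (vertex moving-average window on the upsampled polygon,
#'   default 7), `upsample` (default 8), `psf_sigma` (known point-spread
#'   SD in px contributing to the level-set correction, default 0),
#'   `curvature_smoothing` (default 15).
#' @param frame_id Optional identifier stored on the contours.
#' @return A list of [fdc_contour()] objects (possibly empty).
#' @export
segment_frame <- function(image, pixel_size = 0.34,
                          params = list(), frame_id = NA_character_) {
  stopifnot(is.matrix(image), is.numeric(image))
  p <- utils::modifyList(list(threshold_offset = 0.15, min_area_px = 10,
                              smoothing = 7, upsample = 8, psf_sigma = 0,
                              curvature_smoothing = 15), params)
  ny <- nrow(image)
  nx <- ncol(image)
  border <- c(image[1, ], image[ny, ], image[, 1], image[, nx])
  bg <- stats::median(border)

  mask <- image < (bg - p$threshold_offset)
  # when dark channel-wall bands dominate the border, the median lands on
  # the walls and the mask degenerates; fall back to the bright border
  # quantile as the background estimate
  if (!any(mask) || mean(mask) > 0.5) {
    bg <- as.numeric(stats::quantile(border, 0.9))
    mask <- image < (bg - p$threshold_offset)
  }
  if (!any(mask)) return(list())

  lab <- EBImage::bwlabel(EBImage::Image(t(mask + 0)))   # EBImage is x,y
  lab <- t(EBImage::imageData(lab))
  ids <- setdiff(unique(as.vector(lab)), 0)
  # drop components touching the border (channel walls span the frame)
  touching <- unique(c(lab[1, ], lab[ny, ], lab[, 1], lab[, nx]))
  ids <- setdiff(ids, touching)
  ids <- ids[vapply(ids, function(i) sum(lab == i), 0) >= p$min_area_px]
  if (length(ids) == 0) return(list())

  u <- upsample_image(image, p$upsample)
  sigma2 <- 1 / 12 + p$psf_sigma^2
  out <- list()
  for (i in ids) {
    sel <- lab == i
    fg <- stats::median(image[sel])
    level <- (bg + fg) / 2
    cl <- grDevices::contourLines(x = u$x, y = u$y, z = t(u$img),
                                  levels = level)
    if (length(cl) == 0) next
    # keep the polygon that encloses this component's centroid
    cen <- c(mean(col(lab)[sel]), mean(row(lab)[sel]))
    enclosing <- Filter(function(cc) {
      length(cc$x) >= 8 &&
        abs(cc$x[1] - cc$x[length(cc$x)]) < 1e-9 &&
        abs(cc$y[1] - cc$y[length(cc$y)]) < 1e-9 &&
        point_in_polygon(cen[1], cen[2], cc$x, cc$y)
    }, cl)
    if (length(enclosing) == 0) next
    areas <- vapply(enclosing, function(cc)
      abs(signed_area(cc$x, cc$y)), 0)
    cc <- enclosing[[which.min(areas)]]      # innermost enclosing polygon
    vx <- cc$x[-length(cc$x)]
    vy <- cc$y[-length(cc$y)]
    vx <- smooth_closed(vx, p$smoothing)
    vy <- smooth_closed(vy, p$smoothing)
    kap <- polygon_curvature(vx, vy, p$curvature_smoothing)
    n <- length(vx)
    nxt <- function(v) c(v[-1], v[1])
    prv <- function(v) c(v[n], v[-n])
    dx <- (nxt(vx) - prv(vx)) / 2
    dy <- (nxt(vy) - prv(vy)) / 2
    s <- if (signed_area(vx, vy) > 0) 1 else -1
    nn <- pmax(sqrt(dx^2 + dy^2), 1e-12)
    off <- (sigma2 / 2) * s * kap
    vx <- vx + off * (s * dy / nn)
    vy <- vy + off * (-s * dx / nn)
    out[[length(out) + 1]] <- fdc_contour(vx, vy, pixel_size = pixel_size,
                                          frame_id = frame_id)
  }
  out
}

# even-odd ray-casting point-in-polygon test
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
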