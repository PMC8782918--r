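#' Isoperimetric deformation of a cell cross-section
#'
#' Deformation is one minus circularity,
#' \deqn{d = 1 - \frac{2\sqrt{\pi A}}{P},}
#' where `A` is the projected (cross-sectional) area and `P` the perimeter
#' of the cell contour. A circle has deformation 0; elongated or rough
#' shapes approach 1. By the isoperimetric inequality \eqn{P \ge
#' 2\sqrt{\pi A}}, so the metric is non-negative for exact geometry.
#' Measured contours can undershoot the bound by a sliver after vertex
#' smoothing; such values are clamped to 0 and the number of clamps is
#' reported via the `"clamped"` attribute.
#'
#' @param area Projected area in µm² (vectorised, must be positive).
#' @param perimeter Contour perimeter in µm (vectorised, must be positive).
#' @return Numeric vector of deformation values in `[0, 1)`, with attribute
#'   `"clamped"` giving the count of negative raw values clamped to zero.
#' @examples
#' deformation(pi, 2 * pi)        # circle: 0
#' deformation(2, 4 * sqrt(2 * pi)) # P = 4 sqrt(pi A): 0.5
#' @export
deformation <- function(area, perimeter) {
  if (!is.numeric(area) || !is.numeric(perimeter)) {
    stop("`area` and `perimeter` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    stop("`area` and `perimeter` must be finite and positive", call. = FALSE)
  }
  d <- 1 - 2 * sqrt(pi * area) / perimeter
  clamped <- sum(d < 0)
  if (clamped > 0) d[d < 0] <- 0
  attr(d, "clamped") <- clamped
  d
}

#' Exact ellipse geometry for a given aspect ratio and area
#'
#' Computes the circumference of the ellipse with semi-axes
#' `a = aspect_ratio * b` and area `pi * a * b = area`, using the complete
#' elliptic integral of the second kind. This is the analytic shape model
#' of the synthetic event generator: every simulated cell is an ellipse,
#' so area and perimeter (and hence deformation) are available in closed
#' form without rasterisation.
#'
#' @param aspect_ratio Ratio of major to minor semi-axis, `>= 1`
#'   (vectorised).
#' @param area Ellipse area in µm², `> 0` (vectorised or scalar).
#' @return A list with components `area` (µm²) and `perimeter` (µm).
#' @examples
#' ellipse_geometry(1, pi) # unit circle: perimeter 2*pi
#' @export
ellipse_geometry <- function(aspect_ratio, area) {
  if (!is.numeric(aspect_ratio) || !is.numeric(area) ||
      any(!is.finite(aspect_ratio)) || any(!is.finite(area))) {
    stop("`aspect_ratio` and `area` must be finite numerics", call. = FALSE)
  }
  if (any(aspect_ratio < 1)) {
    stop("`aspect_ratio` must be >= 1", call. = FALSE)
  }
  if (any(area <= 0)) {
    stop("`area` must be positive", call. = FALSE)
  }
  n <- max(length(aspect_ratio), length(area))
  q <- rep_len(aspect_ratio, n)
  A <- rep_len(area, n)
  b <- sqrt(A / (pi * q))
  a <- q * b
  # eccentricity squared; ellipke is vectorised over m
  m <- 1 - (b / a)^2
  P <- 4 * a * pracma::ellipke(m)$e
  list(area = A, perimeter = P)
}

#' Aspect ratio of the ellipse with a given deformation
#'
#' Inverts the ellipse shape model: finds the aspect ratio whose exact
#' circumference yields the requested isoperimetric deformation. The
#' deformation of an ellipse depends only on its aspect ratio (area cancels
#' from the circularity), so the solution is area-independent. Solved by
#' bisection on `[1, 1e4]` in log-aspect.
#'
#' @param d Deformation in `[0, 1)` (vectorised).
#' @param tol Absolute tolerance on the recovered deformation
#'   (default `1e-9`).
#' @return Aspect ratio(s) `>= 1`.
#' @examples
#' solve_aspect_for_deformation(0)   # circle: 1
#' @export
solve_aspect_for_deformation <- function(d, tol = 1e-9) {
  if (!is.numeric(d) || any(!is.finite(d))) {
    stop("`d` must be finite numeric", call. = FALSE)
  }
  if (any(d < 0 | d >= 1)) {
    stop("`d` must lie in [0, 1)", call. = FALSE)
  }
  ellipse_def <- function(q) {
    g <- ellipse_geometry(q, pi)
    1 - 2 * sqrt(pi * g$area) / g$perimeter
  }
  lo <- rep(0, length(d))            # log10 aspect
  hi <- rep(4, length(d))
  # ~60 bisection steps: interval 4/2^60 in log10-aspect, far below tol
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    fmid <- ellipse_def(10^mid)
    below <- fmid < d
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-14) break
  }
  q <- 10^((lo + hi) / 2)
  q[d == 0] <- 1
  bad <- abs(ellipse_def(q) - d) > tol
  if (any(bad)) {
    stop("aspect solve did not converge for ", sum(bad), " value(s)",
         call. = FALSE)
  }
  q
}
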