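# Independent oracles used across tests.

# Ellipse circumference by direct numeric quadrature of the arc length
# (independent of pracma::ellipke used by the implementation).
arc_length_perimeter <- function(aspect, area) {
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# analytic deformation of an ellipse with the given aspect ratio
analytic_ellipse_deformation <- function(aspect, area = pi) {
  P <- arc_length_perimeter(aspect, area)
  1 - 2 * sqrt(pi * area) / P
}

# shoelace area of a bare polygon (oracle for contour_area / area_ratio)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# line-profile band means computed by quadrature on an analytic radial
# intensity profile, including the perpendicular-width footprint of the
# averaged line (independent of image rendering and bilinear sampling)
footprint_band_index <- function(radial_fun, half_width, width = 1,
                                 band_fraction = 0.25,
                                 central_fraction = 0.5) {
  line_val <- function(s) {
    vapply(s, function(si) {
      stats::integrate(function(t) radial_fun(sqrt(si^2 + t^2)),
                       -width / 2, width / 2, rel.tol = 1e-8)$value / width
    }, 0)
  }
  band_mean <- function(lo, hi) {
    ss <- seq(lo, hi, length.out = 201)
    mean(c(line_val(ss), line_val(-ss)))
  }
  peri <- band_mean((1 - band_fraction) * half_width, half_width)
  cent <- band_mean(0, central_fraction * half_width) # symmetric band
  peri / cent
}

# per-donor summaries of a gated panel, as a tibble
panel_summaries <- function(panel, gates = gate_config()) {
  rec <- apply_gates(as_event_records(panel), gates)$kept
  groups <- split(rec, paste(rec$donor_id, rec$condition_label))
  dplyr::bind_rows(lapply(groups, summarize_sample))
}
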