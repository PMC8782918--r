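#' Geometric-mean fluorescence
#'
#' The standard cytometry location statistic for log-skewed intensity
#' data: `exp(mean(log(x)))` over strictly positive values. Non-positive
#' intensities cannot enter a log mean; they are excluded and their count
#' reported via the `"excluded"` attribute.
#'
#' @param x Numeric intensities in AU.
#' @return Geometric mean with attribute `"excluded"`.
#' @export
gmean <- function(x) {
  if (length(x) == 0) stop("empty intensity vector", call. = FALSE)
  pos <- x > 0 & is.finite(x)
  if (!any(pos)) stop("no positive intensities", call. = FALSE)
  g <- exp(mean(log(x[pos])))
  attr(g, "excluded") <- sum(!pos)
  g
}

#' Summarise one gated sample
#'
#' Produces the per-sample statistics used for condition-level analysis:
#' median deformation, median projected area, per-channel geometric-mean
#' fluorescence, optional percent-positive fractions, and the event
#' count. Medians use the midpoint convention for even counts
#' ([stats::median()]).
#'
#' @param events Gated event tibble (see [apply_gates()]); must be
#'   non-empty.
#' @param positivity_cutoff Optional named numeric of per-channel AU
#'   cutoffs (names among `cd62p`, `pac1`); when supplied, the summary
#'   gains `pct_positive_*` columns.
#' @return One-row tibble (a sample summary): `donor_id`,
#'   `condition_label`, `n_events`, `median_deformation`,
#'   `median_area_um2`, `gmean_cd61`, `gmean_cd62p`, `gmean_pac1` and
#'   optionally `pct_positive_cd62p`, `pct_positive_pac1`.
#' @export
summarize_sample <- function(events, positivity_cutoff = NULL) {
  if (nrow(events) == 0) {
    stop("cannot summarise a sample with zero events", call. = FALSE)
  }
  out <- tibble::tibble(
    donor_id = if ("donor_id" %in% names(events))
      events$donor_id[1] else NA_character_,
    condition_label = if ("condition_label" %in% names(events))
      events$condition_label[1] else NA_character_,
    n_events = nrow(events),
    median_deformation = stats::median(events$deformation),
    median_area_um2 = stats::median(events$area_um2),
    gmean_cd61 = as.numeric(gmean(events$cd61)),
    gmean_cd62p = as.numeric(gmean(events$cd62p)),
    gmean_pac1 = as.numeric(gmean(events$pac1))
  )
  if (!is.null(positivity_cutoff)) {
    for (ch in names(positivity_cutoff)) {
      out[[paste0("pct_positive_", ch)]] <-
        percent_positive(events[[ch]], positivity_cutoff[[ch]])
    }
  }
  out
}

#' Percent of events above a positivity cutoff
#'
#' @param intensities Numeric intensities in AU (non-empty).
#' @param cutoff Positivity threshold in AU, `> 0`. No cutoff is printed
#'   with the protocol; the conventional surrogate is a quantile of the
#'   matched non-stimulated control, see [control_cutoff()].
#' @return Percentage in `[0, 100]` of events strictly above the cutoff.
#' @export
percent_positive <- function(intensities, cutoff) {
  if (length(intensities) == 0) {
    stop("empty intensity vector", call. = FALSE)
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  100 * sum(intensities > cutoff) / length(intensities)
}

#' Positivity cutoff from a matched control sample
#'
#' Default percent-positive convention: the cutoff is the `q`-quantile
#' (default 99th percentile) of the matched vehicle-control sample's
#' intensities, an isotype/FMO-style surrogate gate.
#'
#' @param control_intensities Intensities of the non-stimulated control.
#' @param q Quantile level, default 0.99.
#' @return Cutoff in AU.
#' @export
control_cutoff <- function(control_intensities, q = 0.99) {
  stopifnot(length(control_intensities) > 0, q > 0, q < 1)
  as.numeric(stats::quantile(control_intensities, q))
}

#' Fold change between a stimulated and an unstimulated sample summary
#'
#' Follows the reporting convention of the condition-level results:
#' deformation and size drop on TRAP-6 stimulation, so their fold change
#' is the *decrease factor* `unstim / stim` (baseline 1, values above 1
#' mean a decrease); fluorescence (CD62P, PAC-1) rises, so its fold
#' change is the *increase factor* `stim / unstim`.
#'
#' @param stim,unstim One-row sample summaries ([summarize_sample()]) for
#'   the same donor and anticoagulant.
#' @param metric One of `"deformation"`, `"area"`, `"cd61"`, `"cd62p"`,
#'   `"pac1"`.
#' @return One-row tibble with `donor_id`, `condition_label`, `metric`,
#'   `ratio`.
#' @export
fold_change <- function(stim, unstim, metric = "deformation") {
  metric <- match.arg(metric,
                      c("deformation", "area", "cd61", "cd62p", "pac1"))
  col <- switch(metric,
                deformation = "median_deformation",
                area = "median_area_um2",
                cd61 = "gmean_cd61",
                cd62p = "gmean_cd62p",
                pac1 = "gmean_pac1")
  s <- stim[[col]]
  u <- unstim[[col]]
  mech <- metric %in% c("deformation", "area")
  den <- if (mech) s else u
  if (!is.finite(den) || den == 0) {
    stop("zero or non-finite denominator in fold change", call. = FALSE)
  }
  tibble::tibble(
    donor_id = stim$donor_id,
    condition_label = stim$condition_label,
    metric = metric,
    ratio = if (mech) u / s else s / u
  )
}

#' Per-event kernel density for event-density scatter plots
#'
#' Bivariate Gaussian product-kernel density with Scott's-rule bandwidth
#' per axis (`sd * n^(-1/6)`), evaluated at each event and rescaled to
#' `[0, 1]` (min to 0, max to 1) for a linear colour scale from sparse to
#' dense.
#'
#' @param x,y Numeric event coordinates (e.g. size and deformation), at
#'   least 10 finite values.
#' @param scale If `FALSE`, return the raw density instead of the
#'   `[0, 1]`-rescaled one.
#' @return Numeric vector of densities, one per event.
#' @export
kde_density <- function(x, y, scale = TRUE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) {
    stop("need at least 10 events for a density estimate", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite event coordinates", call. = FALSE)
  }
  n <- length(x)
  hx <- stats::sd(x) * n^(-1 / 6)
  hy <- stats::sd(y) * n^(-1 / 6)
  if (hx <= 0 || hy <= 0) {
    stop("degenerate axis: zero variance", call. = FALSE)
  }
  dens <- numeric(n)
  # chunked evaluation keeps the n x n kernel matrix bounded
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    K <- exp(-0.5 * (outer(x[idx], x, "-") / hx)^2) *
      exp(-0.5 * (outer(y[idx], y, "-") / hy)^2)
    dens[idx] <- rowSums(K) / (n * 2 * pi * hx * hy)
  }
  if (!scale) return(dens)
  rng <- range(dens)
  if (rng[1] == rng[2]) return(rep(0, n))
  (dens - rng[1]) / (rng[2] - rng[1])
}

#' Tidy condition-level panel table
#'
#' Pivots a set of sample summaries into the long export format used for
#' external statistical testing (e.g. mixed-effects models): one row per
#' (donor, condition, metric) plus, per (condition, metric), a summary
#' row carrying the mean and SD across donors (`statistic =
#' "condition_mean_sd"`, donor_id `NA`). The table round-trips losslessly
#' through [write_events()]'s CSV writer conventions.
#'
#' @param summaries Tibble of stacked sample summaries
#'   ([summarize_sample()] rows).
#' @return Long tibble with columns `donor_id`, `condition_label`,
#'   `metric`, `statistic`, `value`, `sd`.
#' @export
condition_panel_table <- function(summaries) {
  if (nrow(summaries) == 0) stop("no summaries supplied", call. = FALSE)
  metrics <- setdiff(names(summaries),
                     c("donor_id", "condition_label", "n_events"))
  long <- tidyr::pivot_longer(
    summaries[, c("donor_id", "condition_label", metrics)],
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long$statistic <- "donor_value"
  long$sd <- NA_real_
  agg <- long |>
    dplyr::group_by(.data$condition_label, .data$metric) |>
    dplyr::summarise(
      mu = if (any(is.finite(.data$value)))
        mean(.data$value[is.finite(.data$value)]) else NA_real_,
      sigma = if (sum(is.finite(.data$value)) > 1)
        stats::sd(.data$value[is.finite(.data$value)]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::rename(value = "mu", sd = "sigma")
  agg$donor_id <- NA_character_
  agg$statistic <- "condition_mean_sd"
  dplyr::bind_rows(long, agg)[, c("donor_id", "condition_label",
                                  "metric", "statistic", "value", "sd")]
}
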