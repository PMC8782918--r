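#' Gate configuration and acquisition stop criterion
#'
#' Defaults follow the platelet acquisition protocol: a CD61-PE hard
#' gate of 150–33000 AU identifies single platelets, the convex-hull
#' area ratio is limited to at most 1.1 (debris/aggregate filter), the
#' projected area to 0–10 µm², and acquisition stops at 5000 gated
#' events or after 10 minutes, whichever comes first. The size limit is
#' interpreted as projected area in µm² (sizes are reported in µm²
#' throughout the condition-level results).
#'
#' @param cd61_range Length-2 numeric, CD61-PE hard gate in AU.
#' @param area_ratio_max Maximum convex-hull area ratio.
#' @param size_range Length-2 numeric, projected-area gate in µm².
#' @param max_events Acquisition stop: maximum gated events.
#' @param max_time Acquisition stop: maximum time in seconds.
#' @param positivity_cutoff Optional named numeric of per-channel
#'   positivity cutoffs in AU (see [percent_positive()]); `NULL` defers
#'   to a matched-control quantile at analysis time.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(cd61_range = c(150, 33000),
                        area_ratio_max = 1.1,
                        size_range = c(0, 10),
                        max_events = 5000,
                        max_time = 600,
                        positivity_cutoff = NULL) {
  stopifnot(length(cd61_range) == 2, diff(cd61_range) > 0,
            length(size_range) == 2, diff(size_range) > 0,
            area_ratio_max >= 1, max_events >= 1, max_time > 0)
  structure(list(cd61_range = cd61_range, area_ratio_max = area_ratio_max,
                 size_range = size_range, max_events = max_events,
                 max_time = max_time, positivity_cutoff = positivity_cutoff),
            class = "gate_config")
}

#' Assemble event records from analytic ground truth
#'
#' Converts generator output (or any table carrying `true_area` and
#' `true_perimeter`) into the event-record layout used by gating and
#' summaries. Deformation is recomputed from area and perimeter with
#' [deformation()]; for analytic events the area ratio is exactly 1
#' (ellipses are convex).
#'
#' @param truth A tibble from [sample_events()] or
#'   [simulate_donor_panel()].
#' @param donor_id,condition_label Defaults used when `truth` lacks the
#'   corresponding columns.
#' @return A tibble of event records with columns `donor_id`,
#'   `condition_label`, `area_um2`, `perimeter_um`, `deformation`,
#'   `area_ratio`, `cd61`, `cd62p`, `pac1`, `timestamp`.
#' @export
as_event_records <- function(truth, donor_id = "donor01",
                             condition_label = "unspecified") {
  req <- c("true_area", "true_perimeter", "cd61", "cd62p", "pac1",
           "timestamp")
  miss <- setdiff(req, names(truth))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    donor_id = if ("donor_id" %in% names(truth)) truth$donor_id
               else donor_id,
    condition_label = if ("condition_label" %in% names(truth))
      truth$condition_label else condition_label,
    area_um2 = truth$true_area,
    perimeter_um = truth$true_perimeter,
    deformation = as.numeric(deformation(truth$true_area,
                                         truth$true_perimeter)),
    area_ratio = if ("area_ratio" %in% names(truth)) truth$area_ratio
                 else 1,
    cd61 = truth$cd61,
    cd62p = truth$cd62p,
    pac1 = truth$pac1,
    timestamp = truth$timestamp
  )
}

#' Event records from segmented contours
#'
#' Measures a list of contours ([segment_frame()] output) and pairs them
#' with per-event fluorescence maxima, producing the same event-record
#' layout as [as_event_records()].
#'
#' @param contours List of [fdc_contour()] objects.
#' @param fluor Optional tibble with columns `cd61`, `cd62p`, `pac1` (one
#'   row per contour); defaults to `NA` intensities.
#' @param donor_id,condition_label Identifiers.
#' @param timestamps Optional numeric vector of event times in seconds.
#' @return Event-record tibble; see [as_event_records()].
#' @export
events_from_contours <- function(contours, fluor = NULL,
                                 donor_id = "donor01",
                                 condition_label = "unspecified",
                                 timestamps = NULL) {
  n <- length(contours)
  if (n == 0) {
    return(as_event_records(tibble::tibble(
      true_area = numeric(), true_perimeter = numeric(),
      cd61 = numeric(), cd62p = numeric(), pac1 = numeric(),
      timestamp = numeric()
    ), donor_id, condition_label))
  }
  A <- vapply(contours, contour_area, 0)
  P <- vapply(contours, contour_perimeter, 0)
  ar <- vapply(contours, area_ratio, 0)
  if (is.null(fluor)) {
    fluor <- tibble::tibble(cd61 = rep(NA_real_, n), cd62p = NA_real_,
                            pac1 = NA_real_)
  }
  out <- as_event_records(tibble::tibble(
    true_area = A, true_perimeter = P,
    cd61 = fluor$cd61, cd62p = fluor$cd62p, pac1 = fluor$pac1,
    timestamp = if (is.null(timestamps)) seq_len(n) else timestamps
  ), donor_id, condition_label)
  out$area_ratio <- ar
  out
}

#' Apply the hard gates to an event table
#'
#' An event is kept iff its CD61-PE maximum lies inside the hard gate,
#' its convex-hull area ratio does not exceed the maximum, and its
#' projected area lies inside the size gate. Gating is order-independent
#' and idempotent. Events are not dropped from the returned table:
#' per-gate pass flags and an overall `gate_all` flag are appended, so
#' audits and re-gating need no re-processing; `kept` is the filtered
#' view.
#'
#' @param events Event-record tibble (see [as_event_records()]).
#' @param gates A [gate_config()].
#' @return A list with `kept` (events passing all gates), `events` (all
#'   events with flag columns `gate_cd61`, `gate_area_ratio`,
#'   `gate_size`, `gate_all`), `audit` (named count of events violating
#'   each gate; an event failing several gates is counted once per
#'   violated gate) and `n_rejected` (count of unique rejected events,
#'   so that `nrow(kept) + n_rejected` equals the input count).
#' @export
apply_gates <- function(events, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  req <- c("cd61", "area_ratio", "area_um2")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0) {
    stop("missing gated field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ev <- events
  ev$gate_cd61 <- ev$cd61 >= gates$cd61_range[1] &
    ev$cd61 <= gates$cd61_range[2]
  ev$gate_area_ratio <- ev$area_ratio <= gates$area_ratio_max
  ev$gate_size <- ev$area_um2 >= gates$size_range[1] &
    ev$area_um2 <= gates$size_range[2]
  ev$gate_all <- ev$gate_cd61 & ev$gate_area_ratio & ev$gate_size
  audit <- c(cd61 = sum(!ev$gate_cd61),
             area_ratio = sum(!ev$gate_area_ratio),
             size = sum(!ev$gate_size))
  list(kept = ev[ev$gate_all, , drop = FALSE],
       events = ev,
       audit = audit,
       n_rejected = sum(!ev$gate_all))
}

#' Truncate a gated event stream at the acquisition stop criterion
#'
#' Acquisition stops at the earlier of the `max_events`-th gated event
#' and the `max_time` timestamp: the returned stream contains at most
#' `max_events` events, all with `timestamp <= max_time`.
#'
#' @param events Time-ordered event tibble with a `timestamp` column
#'   (non-decreasing, in seconds).
#' @param gates A [gate_config()] supplying `max_events` and `max_time`.
#' @return The truncated tibble.
#' @export
acquisition_stop <- function(events, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  if (!"timestamp" %in% names(events)) {
    stop("missing field: timestamp", call. = FALSE)
  }
  if (nrow(events) == 0) return(events)
  if (is.unsorted(events$timestamp)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  ev <- events[events$timestamp <= gates$max_time, , drop = FALSE]
  utils::head(ev, gates$max_events)
}
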