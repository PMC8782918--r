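# Deterministic child-seed derivation. Streams are split hierarchically
# (panel -> donor -> sample) so that adding donors or conditions does not
# perturb the draws of earlier ones. Tags may be strings or integers; the
# combination is hashed into [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (t in tags) {
    if (is.character(t)) t <- sum(utf8ToInt(t) * seq_along(utf8ToInt(t)))
    for (v in as.double(t)) {
      h <- (h * 48271 + v * 16807 + 11) %% 2147483647
    }
  }
  as.integer(h)
}

# mean-one multiplicative log-normal jitter with relative SD s
rjitter <- function(n, s) {
  if (s <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + s^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# log-normal with given median and coefficient of variation, truncated by
# rejection to [lo, hi]; the truncation bounds are wide enough that the
# median shift is negligible for all calibrated presets
rlnorm_median_cv <- function(n, median, cv, lo = 0, hi = Inf) {
  sdlog <- sqrt(log(1 + cv^2))
  x <- rlnorm(n, meanlog = log(median), sdlog = sdlog)
  bad <- which(x < lo | x > hi)
  guard <- 0
  while (length(bad) > 0 && guard < 50) {
    x[bad] <- rlnorm(length(bad), meanlog = log(median), sdlog = sdlog)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1
  }
  if (length(bad) > 0) x[bad] <- median
  x
}

rfluor <- function(n, p) {
  if (!is.null(p$f_pos) && p$f_pos > 0) {
    pos <- runif(n) < p$f_pos
    x <- numeric(n)
    x[!pos] <- rlnorm(sum(!pos), log(p$gmean), p$sdlog)
    x[pos] <- rlnorm(sum(pos), log(p$gmean_pos), p$sdlog)
    x
  } else {
    rlnorm(n, log(p$gmean), p$sdlog)
  }
}

#' Sample analytic ground-truth events from a population model
#'
#' Draws single-platelet events with exact ellipse geometry. Deformation
#' and projected area are log-normal with the model's medians and CVs
#' (deformation truncated to `[0, 0.6]`); the perimeter is defined
#' exactly from the drawn deformation by inverting the isoperimetric
#' relation, `P = 2 sqrt(pi A) / (1 - d)`, so that [deformation()] applied
#' to `(true_area, true_perimeter)` recovers the draw to machine
#' precision. The aspect ratio is the ellipse consistent with that
#' circumference (see [solve_aspect_for_deformation()]), used by the
#' raster renderer. Per-channel fluorescence maxima are log-normal in AU
#' and timestamps follow a homogeneous Poisson process at the model's
#' event rate.
#'
#' @param model A [population_model()].
#' @param n Number of events, `>= 1`.
#' @param seed Integer seed; draws are reproducible given `(model, n,
#'   seed)` and do not disturb the caller's RNG state.
#' @param channel_width Channel cross-section width in µm (cells are
#'   centred vertically with a small jitter, constrained by the wall).
#' @return A tibble of ground-truth events with columns `true_area`
#'   (µm²), `true_perimeter` (µm), `true_deformation`, `aspect_ratio`,
#'   `orientation` (radians), `center_x`, `center_y` (µm), `cd61`,
#'   `cd62p`, `pac1` (AU), `timestamp` (s).
#' @export
sample_events <- function(model, n, seed = 1L, channel_width = 15) {
  stopifnot(inherits(model, "population_model"),
            is.numeric(n), length(n) == 1, n >= 1)
  withr::with_seed(seed, {
    d <- rlnorm_median_cv(n, model$deformation_median,
                          model$deformation_cv, lo = 0, hi = 0.6)
    A <- rlnorm_median_cv(n, model$area_median, model$area_cv,
                          lo = 0, hi = 20)
    P <- 2 * sqrt(pi * A) / (1 - d)
    q <- solve_aspect_for_deformation(d, tol = 1e-7)

    b <- sqrt(A / (pi * q))       # minor semi-axis, for wall clearance
    ymax <- pmax(channel_width / 2 - b - 1, 0)
    tibble::tibble(
      true_area = A,
      true_perimeter = P,
      true_deformation = d,
      aspect_ratio = q,
      orientation = 0,
      center_x = rep(0, n),
      center_y = runif(n, -1, 1) * pmin(ymax, 2),
      cd61 = rfluor(n, model$fluor_params$cd61),
      cd62p = rfluor(n, model$fluor_params$cd62p),
      pac1 = rfluor(n, model$fluor_params$pac1),
      timestamp = cumsum(rexp(n, rate = model$event_rate))
    )
  })
}

# apply a donor's multiplicative jitter (and, for stimulated samples, the
# donor's fold-response jitter) to a model's location parameters
scale_model <- function(model, jit, resp = NULL) {
  m <- model
  m$deformation_median <- model$deformation_median * jit[["deformation"]]
  m$area_median <- model$area_median * jit[["area"]]
  for (ch in c("cd61", "cd62p", "pac1")) {
    m$fluor_params[[ch]]$gmean <- model$fluor_params[[ch]]$gmean * jit[["fluor"]]
  }
  if (!is.null(resp)) {
    # resp jitters the fold response: mechanics medians shrink by the
    # fold, so a donor with a stronger response (resp > 1) sits lower
    m$deformation_median <- m$deformation_median / resp[["deformation"]]
    m$area_median <- m$area_median / resp[["area"]]
    m$fluor_params$cd62p$gmean <- m$fluor_params$cd62p$gmean * resp[["cd62p"]]
    m$fluor_params$pac1$gmean <- m$fluor_params$pac1$gmean * resp[["pac1"]]
  }
  m$deformation_median <- min(m$deformation_median, 0.3)
  m$area_median <- min(m$area_median, 9.99)
  m
}

#' Simulate a multi-donor, multi-condition event panel
#'
#' Emulates the paired experimental design: each simulated donor
#' contributes one sample per condition, and all conditions sharing a
#' donor's (anticoagulant, treatment, phenotype) group reuse that donor's
#' median jitter, so stimulated/non-stimulated pairs are donor-consistent
#' and per-donor fold changes are meaningful. Stimulated samples receive
#' an additional donor-level jitter of the fold response itself (relative
#' SD `response_sd`), reproducing the published between-donor spread of
#' fold changes.
#'
#' @param presets A list of [population_model()] objects (e.g. from
#'   [fdc_presets()]), or a single model.
#' @param n_donors Number of simulated donors, `>= 1`.
#' @param n_events Events drawn per donor and condition.
#' @param seed Integer panel seed. Donor streams are derived
#'   hierarchically, so extending the panel leaves existing donors
#'   unchanged.
#' @return A tibble of ground-truth events with `donor_id` and
#'   `condition_label` prepended.
#' @export
simulate_donor_panel <- function(presets, n_donors, n_events, seed = 1L) {
  if (inherits(presets, "population_model")) presets <- list(presets)
  stopifnot(length(presets) >= 1, n_donors >= 1, n_events >= 1)
  out <- vector("list", length(presets) * n_donors)
  k <- 0
  for (model in presets) {
    stopifnot(inherits(model, "population_model"))
    group <- paste(model$anticoagulant, model$treatment, model$phenotype,
                   sep = "|")
    for (dnr in seq_len(n_donors)) {
      jseed <- derive_seed(seed, "jitter", group, dnr)
      jit <- withr::with_seed(jseed, c(
        deformation = rjitter(1, model$donor_sd[["deformation"]]),
        area = rjitter(1, model$donor_sd[["area"]]),
        fluor = rjitter(1, model$donor_sd[["fluor"]])
      ))
      resp <- NULL
      if (model$stimulation == "TRAP-6") {
        rseed <- derive_seed(seed, "response", group, dnr)
        resp <- withr::with_seed(rseed, c(
          deformation = rjitter(1, model$response_sd[["deformation"]]),
          area = rjitter(1, model$response_sd[["area"]]),
          cd62p = rjitter(1, model$response_sd[["cd62p"]]),
          pac1 = rjitter(1, model$response_sd[["pac1"]])
        ))
      }
      dm <- scale_model(model, jit, resp)
      eseed <- derive_seed(seed, "events", group, model$condition_label, dnr)
      ev <- sample_events(dm, n_events, seed = eseed)
      k <- k + 1
      out[[k]] <- dplyr::bind_cols(
        tibble::tibble(donor_id = sprintf("donor%02d", dnr),
                       condition_label = model$condition_label),
        ev
      )
    }
  }
  dplyr::bind_rows(out)
}
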