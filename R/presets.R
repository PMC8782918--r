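#' Construct a platelet population model
#'
#' A `population_model` is the generative description of one platelet
#' sample condition: an anticoagulant, a stimulation state (vehicle or
#' TRAP-6), a treatment (vehicle or LatB) and a phenotype (healthy or
#' MYH9-like). Event-level deformation, projected area and per-channel
#' fluorescence are modelled as log-normal (strictly positive and
#' right-skewed, the usual cytometry convention); medians are the
#' calibrated location parameters and coefficients of variation the
#' spreads. Donor-level variability enters as a multiplicative, mean-one
#' log-normal jitter on the medians (see [simulate_donor_panel()]).
#'
#' @param condition_label Text label, e.g. `"ACD-A:none"`.
#' @param anticoagulant One of `"ACD-A"`, `"Na-Citrate"`, `"K2-EDTA"`,
#'   `"Li-Heparin"`, `"r-Hirudin"`.
#' @param stimulation `"none"` or `"TRAP-6"`.
#' @param treatment `"vehicle"` or `"LatB"`.
#' @param phenotype `"healthy"` or `"MYH9-like"`.
#' @param deformation_median Median event deformation, in `(0, 0.3]`.
#' @param deformation_cv Event-level coefficient of variation of
#'   deformation (dimensionless, `> 0`).
#' @param area_median Median projected area in µm², in `(1, 10)`.
#' @param area_cv Event-level CV of area.
#' @param fluor_params Named list per channel (`cd61`, `cd62p`, `pac1`),
#'   each a list with `gmean` (geometric-mean location, AU) and `sdlog`
#'   (log-scale spread). A channel may additionally carry `f_pos` and
#'   `gmean_pos` describing a two-component log-normal mixture (a
#'   positive fraction `f_pos` centred at `gmean_pos`), used to emulate
#'   partially activated samples.
#' @param donor_sd Named numeric: relative between-donor SD of the median
#'   for `deformation`, `area` and `fluor`.
#' @param response_sd Named numeric: relative between-donor SD of the
#'   stimulated-over-basal fold response for `deformation`, `area`,
#'   `cd62p`, `pac1`. Only consulted for stimulated models when paired
#'   simulation is requested.
#' @param event_rate Mean event rate of the acquisition, events/s.
#' @return An object of class `population_model`.
#' @seealso [fdc_preset()] for the calibrated built-in conditions.
#' @export
population_model <- function(condition_label,
                             anticoagulant,
                             stimulation = "none",
                             treatment = "vehicle",
                             phenotype = "healthy",
                             deformation_median,
                             deformation_cv = 0.45,
                             area_median,
                             area_cv = 0.35,
                             fluor_params,
                             donor_sd = c(deformation = 0.25, area = 0.08,
                                          fluor = 0.25),
                             response_sd = c(deformation = 0.2, area = 0.1,
                                             cd62p = 0.4, pac1 = 0.3),
                             event_rate = 12) {
  anticoagulant <- match.arg(anticoagulant, fdc_anticoagulants())
  stimulation <- match.arg(stimulation, c("none", "TRAP-6"))
  treatment <- match.arg(treatment, c("vehicle", "LatB"))
  phenotype <- match.arg(phenotype, c("healthy", "MYH9-like"))
  stopifnot(
    is.numeric(deformation_median), length(deformation_median) == 1,
    deformation_median > 0, deformation_median <= 0.3,
    is.numeric(area_median), length(area_median) == 1,
    area_median > 1, area_median < 10,
    deformation_cv > 0, area_cv > 0, event_rate > 0
  )
  for (ch in c("cd61", "cd62p", "pac1")) {
    p <- fluor_params[[ch]]
    if (is.null(p) || !is.numeric(p$gmean) || p$gmean <= 0 ||
        !is.numeric(p$sdlog) || p$sdlog <= 0) {
      stop("fluor_params$", ch, " needs positive `gmean` and `sdlog`",
           call. = FALSE)
    }
  }
  if (any(donor_sd < 0) || any(response_sd < 0)) {
    stop("donor_sd and response_sd must be non-negative", call. = FALSE)
  }
  structure(
    list(
      condition_label = condition_label,
      anticoagulant = anticoagulant,
      stimulation = stimulation,
      treatment = treatment,
      phenotype = phenotype,
      deformation_median = deformation_median,
      deformation_cv = deformation_cv,
      area_median = area_median,
      area_cv = area_cv,
      fluor_params = fluor_params,
      donor_sd = donor_sd,
      response_sd = response_sd,
      event_rate = event_rate
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> ", x$condition_label, "\n", sep = "")
  cat(sprintf("  deformation median %.4g (cv %.2g), area median %.4g um^2 (cv %.2g)\n",
              x$deformation_median, x$deformation_cv,
              x$area_median, x$area_cv))
  cat(sprintf("  gMean AU  cd61 %.4g  cd62p %.4g  pac1 %.4g\n",
              x$fluor_params$cd61$gmean, x$fluor_params$cd62p$gmean,
              x$fluor_params$pac1$gmean))
  invisible(x)
}

#' Supported ex vivo anticoagulants
#' @return Character vector of the five anticoagulant labels.
#' @export
fdc_anticoagulants <- function() {
  c("ACD-A", "Na-Citrate", "K2-EDTA", "Li-Heparin", "r-Hirudin")
}

# Calibration constants -------------------------------------------------
#
# Condition-level anchors: per-anticoagulant medians of the non-stimulated
# state, fold responses to TRAP-6, and between-donor spreads. Stimulated
# medians are derived by dividing the basal medians by the fold response
# (mechanics decrease on stimulation) or multiplying (fluorescence
# increases). Values without a printed anchor (Na-Citrate and r-Hirudin
# basal size, basal fluorescence locations other than Li-Heparin PAC-1)
# are package choices documented in the methods vignette.
.fdc_calibration <- function() {
  ac <- fdc_anticoagulants()
  tibble::tibble(
    anticoagulant = ac,
    def_median = c(0.127, 0.111, 0.037, 0.071, 0.100),
    def_donor_sd = c(0.033 / 0.127, 0.025 / 0.111, 0.010 / 0.037,
                     0.016 / 0.071, 0.023 / 0.100),
    area_median = c(5.035, 4.70, 4.158, 4.337, 4.60),
    area_donor_sd = c(0.49 / 5.035, 0.08, 0.241 / 4.158,
                      0.344 / 4.337, 0.08),
    def_fold = c(2.76, 2.58, 1.14, 1.72, 2.27),
    def_fold_sd = c(0.64 / 2.76, 0.49 / 2.58, 0.33 / 1.14,
                    0.47 / 1.72, 0.45 / 2.27),
    area_fold = c(1.28, 1.14, 0.98, 1.04, 1.18),
    area_fold_sd = c(0.13 / 1.28, 0.14 / 1.14, 0.08 / 0.98,
                     0.04 / 1.04, 0.16 / 1.18),
    cd62p_basal = c(10, 10, 10, 10, 10),
    cd62p_fold = c(18.19, 21.48, 2.03, 9.82, 15.72),
    cd62p_fold_sd = c(8.88 / 18.19, 8.54 / 21.48, 1.16 / 2.03,
                      7.78 / 9.82, 6.76 / 15.72),
    pac1_basal = c(45, 42, 25, 82.48, 40),
    pac1_fold = c(2.86, 3.39, 1.00, 2.64, 3.55),
    pac1_fold_sd = c(0.82 / 2.86, 0.9 / 3.39, 0.2,
                     0.7 / 2.64, 0.98 / 3.55)
  )
}

# MYH9-like phenotype anchors (single-patient medians, ACD-A and K2-EDTA;
# the paired same-day healthy control is the standard healthy preset).
.fdc_myh9 <- function() {
  tibble::tibble(
    anticoagulant = c("ACD-A", "ACD-A", "K2-EDTA"),
    stimulation = c("none", "TRAP-6", "none"),
    def_median = c(0.068, 0.036, 0.0195),
    area_median = c(5.77, 6.585, 7.515)
  )
}

# Deformation increase under LatB-like actin disruption (no printed
# anchor; chosen as a moderate softening, see vignette).
.fdc_latb_factor <- 1.4

#' Calibrated built-in population presets
#'
#' Returns the generative model for one study condition, calibrated so
#' that the expected condition-level statistics (means over donors of the
#' per-donor medians, and mean fold responses to TRAP-6) reproduce the
#' published per-anticoagulant values. Stimulated presets are derived
#' from the basal ones through the fold response: deformation and size
#' medians are divided by their fold factors (both drop on activation,
#' except size in K2-EDTA which is essentially flat), CD62P and PAC-1
#' locations are multiplied by theirs.
#'
#' @param anticoagulant One of [fdc_anticoagulants()].
#' @param stimulation `"none"` or `"TRAP-6"`.
#' @param treatment `"vehicle"` or `"LatB"` (LatB raises deformation).
#' @param phenotype `"healthy"` or `"MYH9-like"` (large, stiff platelets
#'   from a single MYH9 p.E1841K donor; only available in ACD-A and, for
#'   the non-stimulated state, K2-EDTA; `donor_sd` is zero because the
#'   anchors are single-patient medians).
#' @return A [population_model()].
#' @examples
#' fdc_preset("ACD-A")
#' fdc_preset("K2-EDTA", stimulation = "TRAP-6")
#' @export
fdc_preset <- function(anticoagulant,
                       stimulation = c("none", "TRAP-6"),
                       treatment = c("vehicle", "LatB"),
                       phenotype = c("healthy", "MYH9-like")) {
  anticoagulant <- match.arg(anticoagulant, fdc_anticoagulants())
  stimulation <- match.arg(stimulation)
  treatment <- match.arg(treatment)
  phenotype <- match.arg(phenotype)

  cal <- .fdc_calibration()
  row <- cal[cal$anticoagulant == anticoagulant, ]
  stim <- stimulation == "TRAP-6"

  def_med <- row$def_median
  area_med <- row$area_median
  if (stim) {
    def_med <- def_med / row$def_fold
    area_med <- area_med / row$area_fold
  }
  if (treatment == "LatB") def_med <- min(def_med * .fdc_latb_factor, 0.3)

  donor_sd <- c(deformation = row$def_donor_sd, area = row$area_donor_sd,
                fluor = 0.25)

  if (phenotype == "MYH9-like") {
    m9 <- .fdc_myh9()
    hit <- m9[m9$anticoagulant == anticoagulant &
                m9$stimulation == stimulation, ]
    if (nrow(hit) == 0) {
      stop("no MYH9-like anchor for ", anticoagulant, " / ", stimulation,
           call. = FALSE)
    }
    def_med <- hit$def_median
    area_med <- hit$area_median
    donor_sd <- c(deformation = 0, area = 0, fluor = 0)
  }

  fl <- list(
    cd61 = list(gmean = 1500, sdlog = 0.5),
    cd62p = list(gmean = if (stim) row$cd62p_basal * row$cd62p_fold
                 else row$cd62p_basal,
                 sdlog = 0.7),
    pac1 = list(gmean = if (stim) row$pac1_basal * row$pac1_fold
                else row$pac1_basal,
                sdlog = 0.8)
  )

  label <- paste0(anticoagulant, ":", stimulation,
                  if (treatment != "vehicle") paste0(":", treatment) else "",
                  if (phenotype != "healthy") paste0(":", phenotype) else "")

  population_model(
    condition_label = label,
    anticoagulant = anticoagulant,
    stimulation = stimulation,
    treatment = treatment,
    phenotype = phenotype,
    deformation_median = def_med,
    area_median = area_med,
    fluor_params = fl,
    donor_sd = donor_sd,
    response_sd = c(deformation = row$def_fold_sd,
                    area = row$area_fold_sd,
                    cd62p = row$cd62p_fold_sd,
                    pac1 = row$pac1_fold_sd)
  )
}

#' All built-in healthy presets
#'
#' @param stimulation Optional filter, `"none"` or `"TRAP-6"`; default
#'   returns both states for every anticoagulant.
#' @return Named list of [population_model()] objects, one per
#'   (anticoagulant, stimulation) combination.
#' @export
fdc_presets <- function(stimulation = c("none", "TRAP-6")) {
  grid <- expand.grid(anticoagulant = fdc_anticoagulants(),
                      stimulation = stimulation,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    fdc_preset(grid$anticoagulant[i], grid$stimulation[i])
  })
  names(out) <- paste0(grid$anticoagulant, ":", grid$stimulation)
  out
}
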