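# Synthetic population generator: reproducibility, calibration, panels.

test_that("sampling is seed-reproducible and seed-isolated", {
  m <- fdc_preset("ACD-A")
  a <- sample_events(m, 200, seed = 11)
  b <- sample_events(m, 200, seed = 11)
  expect_identical(a, b)
  c <- sample_events(m, 200, seed = 12)
  expect_false(identical(a$true_deformation, c$true_deformation))
  # caller RNG state is untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(sample_events(m, 10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("generated geometry satisfies the deformation identity", {
  m <- fdc_preset("Na-Citrate")
  ev <- sample_events(m, 500, seed = 3)
  d <- 1 - 2 * sqrt(pi * ev$true_area) / ev$true_perimeter
  expect_lt(max(abs(d - ev$true_deformation)), 1e-9)
  # ellipse model consistent with the drawn deformation
  g <- ellipse_geometry(ev$aspect_ratio, ev$true_area)
  expect_lt(max(abs(g$perimeter / ev$true_perimeter - 1)), 1e-5)
  expect_true(all(ev$aspect_ratio >= 1))
  expect_true(all(ev$true_deformation >= 0 & ev$true_deformation <= 0.6))
})

test_that("degenerate spread collapses all events onto the median", {
  m <- fdc_preset("ACD-A")
  m$deformation_cv <- 1e-9
  ev <- sample_events(m, 50, seed = 1)
  expect_equal(ev$true_deformation,
               rep(m$deformation_median, 50), tolerance = 1e-6)
})

test_that("sample medians converge to the preset medians", {
  m <- fdc_preset("ACD-A")
  ev <- sample_events(m, 20000, seed = 7)
  # 3 standard errors of the median (asymptotic, log-normal density)
  se_med <- function(x) 1.2533 * stats::sd(x) / sqrt(length(x))
  expect_lt(abs(stats::median(ev$true_deformation) - 0.127),
            3 * se_med(ev$true_deformation))
  expect_lt(abs(stats::median(ev$true_area) - 5.035),
            3 * se_med(ev$true_area))
})

test_that("timestamps follow a homogeneous Poisson process at event_rate", {
  m <- fdc_preset("r-Hirudin")
  ev <- sample_events(m, 5000, seed = 2)
  gaps <- diff(c(0, ev$timestamp))
  expect_true(all(gaps > 0))
  expect_equal(mean(gaps), 1 / m$event_rate, tolerance = 0.1)
})

test_that("stimulated presets encode the printed fold responses", {
  for (ac in fdc_anticoagulants()) {
    un <- fdc_preset(ac, "none")
    st <- fdc_preset(ac, "TRAP-6")
    expect_gt(un$deformation_median / st$deformation_median, 1.1 - 1e-9)
    cal_fold <- un$deformation_median / st$deformation_median
    expect_equal(st$deformation_median * cal_fold, un$deformation_median,
                 tolerance = 1e-12)
  }
  # K2-EDTA is the near-null responder
  edta <- fdc_preset("K2-EDTA", "none")$deformation_median /
    fdc_preset("K2-EDTA", "TRAP-6")$deformation_median
  acd <- fdc_preset("ACD-A", "none")$deformation_median /
    fdc_preset("ACD-A", "TRAP-6")$deformation_median
  expect_lt(edta, 1.2)
  expect_gt(acd, 2.5)
})

test_that("zero donor_sd makes donors exchangeable draws of one model", {
  m <- fdc_preset("Li-Heparin")
  m$donor_sd[] <- 0
  panel <- simulate_donor_panel(m, n_donors = 4, n_events = 3000, seed = 5)
  med <- tapply(panel$true_deformation, panel$donor_id, stats::median)
  # all donor medians within Monte-Carlo error of the preset median
  expect_lt(max(abs(med - m$deformation_median)),
            4 * 1.2533 * stats::sd(panel$true_deformation) / sqrt(3000))
})

test_that("donor streams are hierarchical: earlier donors are stable", {
  m <- fdc_preset("ACD-A")
  p3 <- simulate_donor_panel(m, n_donors = 3, n_events = 100, seed = 9)
  p5 <- simulate_donor_panel(m, n_donors = 5, n_events = 100, seed = 9)
  expect_identical(p3, p5[p5$donor_id %in% unique(p3$donor_id), ])
})

test_that("paired conditions share donor jitter for consistent folds", {
  presets <- list(fdc_preset("ACD-A"), fdc_preset("ACD-A", "TRAP-6"))
  panel <- simulate_donor_panel(presets, n_donors = 12, n_events = 3000,
                                seed = 31)
  summ <- panel_summaries(panel)
  w <- tidyr::pivot_wider(
    summ[, c("donor_id", "condition_label", "median_deformation")],
    names_from = "condition_label", values_from = "median_deformation")
  r <- w[["ACD-A:none"]] / w[["ACD-A:TRAP-6"]]
  # mean fold tracks the calibrated 2.76 despite donor-level jitter of
  # both the baseline and the response
  expect_lt(abs(mean(r) - 2.76), 3 * stats::sd(r) / sqrt(length(r)))
})

test_that("MYH9-like preset is a large, stiff single-patient sample", {
  m9 <- fdc_preset("ACD-A", phenotype = "MYH9-like")
  hc <- fdc_preset("ACD-A")
  expect_lt(m9$deformation_median, hc$deformation_median)
  expect_gt(m9$area_median, hc$area_median)
  expect_true(all(m9$donor_sd == 0))
  expect_error(fdc_preset("Li-Heparin", phenotype = "MYH9-like"),
               "anchor")
})

test_that("LatB treatment raises deformation above vehicle", {
  expect_gt(fdc_preset("ACD-A", treatment = "LatB")$deformation_median,
            fdc_preset("ACD-A")$deformation_median)
})

test_that("model validation rejects out-of-range parameters", {
  expect_error(fdc_preset("EDTA"), "arg")
  m <- fdc_preset("ACD-A")
  expect_error(population_model("x", "ACD-A",
                                deformation_median = 0.5,
                                area_median = 5,
                                fluor_params = m$fluor_params))
  expect_error(population_model("x", "ACD-A",
                                deformation_median = 0.1,
                                area_median = 12,
                                fluor_params = m$fluor_params))
  expect_error(sample_events(m, 0), "n >= 1")
})
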