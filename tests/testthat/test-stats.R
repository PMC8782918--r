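# Sample summaries, fold changes, percent-positive and KDE densities.

test_that("geometric mean follows the log-mean definition", {
  expect_equal(as.numeric(gmean(c(10, 1000))), 100)
  expect_equal(as.numeric(gmean(rep(7.3, 25))), 7.3)
  g <- gmean(c(10, 1000, 0, -5))
  expect_equal(as.numeric(g), 100)
  expect_equal(attr(g, "excluded"), 2L)
  expect_error(gmean(numeric()), "empty")
  # AM-GM: gMean never exceeds the arithmetic mean
  set.seed(1)
  for (i in 1:5) {
    x <- rlnorm(100, 3, 1)
    expect_lte(as.numeric(gmean(x)), mean(x))
  }
})

test_that("sample summary uses midpoint medians and rejects empties", {
  ev <- tibble::tibble(donor_id = "d", condition_label = "c",
                       deformation = c(0.1, 0.2, 0.4),
                       area_um2 = c(4, 5, 6),
                       cd61 = c(10, 1000, 100),
                       cd62p = c(1, 1, 1), pac1 = c(2, 2, 2))
  s <- summarize_sample(ev)
  expect_equal(s$median_deformation, 0.2)
  even <- summarize_sample(ev[c(1, 2, 1, 3), ])
  expect_equal(even$median_deformation, 0.15)  # midpoint of 0.1, 0.2
  expect_error(summarize_sample(ev[0, ]), "zero events")
})

test_that("percent positive counts events above the cutoff", {
  expect_equal(percent_positive(c(1, 2, 3, 4), 2.5), 50)
  expect_equal(percent_positive(c(1, 2), 10), 0)
  expect_error(percent_positive(numeric(), 1), "empty")
})

test_that("bimodal mixture recovers the activated fraction", {
  m <- fdc_preset("ACD-A")
  f <- 0.35
  m$fluor_params$cd62p <- list(gmean = 10, sdlog = 0.4, f_pos = f,
                               gmean_pos = 1000)
  ev <- sample_events(m, 8000, seed = 13)
  # cutoff between the modes
  pct <- percent_positive(ev$cd62p, 100)
  expect_equal(pct, 100 * f, tolerance = 0.05)
  # default convention: 99th percentile of a matched control
  ctrl <- sample_events(fdc_preset("ACD-A"), 8000, seed = 14)
  cut <- control_cutoff(ctrl$cd62p)
  expect_equal(as.numeric(stats::quantile(ctrl$cd62p, 0.99)), cut)
  expect_equal(percent_positive(ctrl$cd62p, cut), 1, tolerance = 0.3)
})

test_that("fold changes follow the decrease/increase conventions", {
  mk <- function(def, area, cd62p) tibble::tibble(
    donor_id = "d", condition_label = "c",
    median_deformation = def, median_area_um2 = area,
    gmean_cd61 = 1500, gmean_cd62p = cd62p, gmean_pac1 = 50)
  # identical summaries: baseline 1 for every metric
  s <- mk(0.12, 5, 10)
  for (metric in c("deformation", "area", "cd61", "cd62p", "pac1")) {
    expect_equal(fold_change(s, s, metric)$ratio, 1)
  }
  # mechanics: decrease factor unstim/stim
  expect_equal(fold_change(mk(0.06, 5, 10), mk(0.12, 5, 10),
                           "deformation")$ratio, 2)
  # fluorescence: increase factor stim/unstim
  expect_equal(fold_change(mk(0.12, 5, 182), mk(0.12, 5, 10),
                           "cd62p")$ratio, 18.2)
  zero <- mk(0, 5, 10)
  expect_error(fold_change(zero, s, "deformation"), "denominator")
})

test_that("kde density is high at the mode and ~0 at far outliers", {
  set.seed(5)
  x <- c(rnorm(500, 0, 0.05), 50)
  y <- c(rnorm(500, 0, 0.05), 50)
  dens <- kde_density(x, y)
  expect_lt(dens[501], 1e-6)
  expect_equal(max(dens), 1)
  expect_equal(min(dens), 0)
})

test_that("kde at the mode approaches the analytic normal density", {
  n <- 10000
  sx <- 1.3
  sy <- 0.6
  analytic <- 1 / (2 * pi * sx * sy)
  # the point estimate carries ~3% sampling noise on top of the
  # bandwidth-smoothing bias, so average the error over replicates
  rel_err <- vapply(c(8, 21, 33), function(s) {
    set.seed(s)
    x <- rnorm(n, 0, sx)
    y <- rnorm(n, 0, sy)
    # evaluate at the true mode by appending the origin as an event
    kde_density(c(0, x), c(0, y), scale = FALSE)[1] / analytic - 1
  }, 0)
  expect_lt(abs(mean(rel_err)), 0.1)
})

test_that("kde scaling is invariant to duplication and permutation", {
  set.seed(3)
  x <- rnorm(300)
  y <- rnorm(300)
  d1 <- kde_density(x, y)
  p <- sample.int(300)
  d2 <- kde_density(x[p], y[p])
  expect_equal(d2[order(p)], d1, tolerance = 1e-12)
  expect_error(kde_density(rep(1, 20), rnorm(20)), "degenerate")
  expect_error(kde_density(1:5, 1:5), "at least 10")
})

test_that("condition panel table is tidy and CSV round-trips", {
  m <- fdc_preset("ACD-A")
  panel <- simulate_donor_panel(m, n_donors = 6, n_events = 400,
                                seed = 17)
  summ <- panel_summaries(panel)
  tab <- condition_panel_table(summ)
  donor_rows <- tab[tab$statistic == "donor_value" &
                      tab$metric == "median_deformation", ]
  expect_equal(nrow(donor_rows), 6)
  agg <- tab[tab$statistic == "condition_mean_sd" &
               tab$metric == "median_deformation", ]
  expect_equal(nrow(agg), 1)
  expect_equal(agg$value, mean(donor_rows$value))
  expect_equal(agg$sd, stats::sd(donor_rows$value))
  # lossless numeric round-trip through CSV
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  unlink(f)
  # missing metric values surface as NA, not zero
  summ2 <- summ
  summ2$gmean_pac1 <- NA_real_
  tab2 <- condition_panel_table(summ2)
  expect_true(is.na(tab2$value[tab2$metric == "gmean_pac1" &
                                 tab2$statistic == "condition_mean_sd"]))
})
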