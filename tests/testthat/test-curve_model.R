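test_that("the logistic response honors its asymptotes and midpoint", {
  fit <- list(alpha = 100, beta = 1000, gamma = 1)
  expect_equal(response(-50, fit), 100, tolerance = 1e-12)
  expect_equal(response(0, fit), 600)
  expect_lt(response(50, fit), 1100 + 1e-9)
  expect_equal(response(2, list(alpha = 0, beta = 1, gamma = 1)),
               0.880797, tolerance = 1e-6)
  x <- seq(-10, 10, by = 0.25)
  expect_true(all(diff(response(x, fit)) > 0))
})

test_that("a noise-free slide is recovered essentially exactly", {
  g <- generate_slide(small_scenario(seed = 31, sigma_y = 0))
  sc <- fit_generated(g)
  expect_true(sc$fit$converged)
  expect_equal(sc$fit$alpha, 200, tolerance = 1e-6)
  expect_equal(sc$fit$beta, 40000, tolerance = 1e-6)
  expect_equal(sc$fit$gamma, 0.8, tolerance = 1e-6)
  expect_gte(sc$fit$r2, 1 - 1e-9)
  al <- align_truth(sc$estimates, g$truth$series)
  expect_lt(max(abs(al$xhat - al$x_true)), 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  series <- data.frame(series_id = rep(sprintf("S%02d", 1:10), each = 2),
                       d = rep(c(0, -1), 10), y = 500, excluded = FALSE)
  expect_error(fit_supercurve(series), "no signal",
               class = "rppa_slide_error")
  expect_error(fit_supercurve(series[1:8, ]), "minimum",
               class = "rppa_slide_error")
})

test_that("post-hoc projection inverts the forward model and flags asymptotes", {
  fit <- structure(list(alpha = 100, beta = 1000, gamma = 1, sigma2 = 1,
                        converged = TRUE), class = "rppa_fit")
  d <- -(0:3)
  on_curve <- data.frame(series_id = "X", spot_type = "Sample",
                         d = d, y = response(1.5 + d, fit))
  est <- estimate_excluded(on_curve, fit)
  expect_equal(est$x, 1.5, tolerance = 1e-6)
  expect_false(est$in_fit)

  low <- data.frame(series_id = "L", spot_type = "Sample", d = d, y = rep(100, 4))
  est <- estimate_excluded(low, fit)
  expect_match(est$flags, "BelowDetection")
  expect_equal(est$x, fit_options()$x_bounds[1])

  high <- data.frame(series_id = "H", spot_type = "Sample", d = d, y = rep(1100, 4))
  est <- estimate_excluded(high, fit)
  expect_match(est$flags, "Saturated")
  expect_equal(est$x, fit_options()$x_bounds[2])
})

test_that("excluding a series equals removing it, and it still gets an estimate", {
  g <- generate_slide(small_scenario(seed = 32))
  design <- infer_design(g$slide)
  ser <- dilution_series(g$slide, design, exclude = "S007")
  with_excl <- suppressWarnings(fit_supercurve(ser))
  without <- suppressWarnings(
    fit_supercurve(ser[ser$series_id != "S007", ]))

  keep <- with_excl$estimates$series_id != "S007"
  e1 <- with_excl$estimates[keep, ]
  e2 <- without$estimates[match(e1$series_id, without$estimates$series_id), ]
  expect_lt(max(abs(e1$x - e2$x)), 1e-6)

  excl <- with_excl$estimates[!keep, ]
  expect_false(excl$in_fit)
  expect_true(is.finite(excl$x))
})

test_that("series order never changes any estimate", {
  g <- generate_slide(small_scenario(seed = 33))
  design <- infer_design(g$slide)
  ser <- dilution_series(g$slide, design)
  f1 <- fit_supercurve(ser)
  set.seed(2)
  perm <- unlist(split(seq_len(nrow(ser)), ser$series_id)[
    sample(length(unique(ser$series_id)))], use.names = FALSE)
  f2 <- fit_supercurve(ser[perm, ])
  e2 <- f2$estimates[match(f1$estimates$series_id, f2$estimates$series_id), ]
  expect_equal(e2$x, f1$estimates$x, tolerance = 1e-9)
})

test_that("raising a series' intensities never lowers its position", {
  fit <- structure(list(alpha = 200, beta = 40000, gamma = 0.8, sigma2 = 1,
                        converged = TRUE), class = "rppa_fit")
  d <- -(0:3)
  for (x0 in c(-2, 0, 1.5)) {
    y <- response(x0 + d, fit)
    x_lo <- estimate_excluded(data.frame(d = d, y = y), fit)$x
    x_hi <- estimate_excluded(data.frame(d = d, y = y * 1.2), fit)$x
    expect_gte(x_hi, x_lo)
  }
})

test_that("the pinned midpoint makes positions identifiable", {
  g <- generate_slide(small_scenario(seed = 34))
  sc <- fit_generated(g)
  ser <- dilution_series(g$slide, infer_design(g$slide))
  ids <- unique(ser$series_id)
  x <- sc$estimates$x[match(ids, sc$estimates$series_id)]
  rss_at <- function(shift) {
    xx <- (x + shift)[match(ser$series_id, ids)]
    sum((ser$y - response(xx + ser$d, sc$fit))^2)
  }
  for (delta in c(-0.5, -0.1, 0.1, 0.5)) {
    expect_gt(rss_at(delta), rss_at(0))
  }
})

test_that("diagnostics rank a planted outlier first", {
  sc0 <- small_scenario(seed = 35)
  g <- generate_slide(sc0)
  # pick a mid-range series and distort it 5x
  tr <- g$truth$series
  target <- tr$series_id[which.min(abs(tr$x_true - (-1.5)))]
  g2 <- generate_slide(small_scenario(
    seed = 35, outliers = data.frame(series_id = target, factor = 5)))
  fit <- fit_generated(g2)
  diag <- fit_diagnostics(fit)
  expect_equal(diag$ranking$series_id[1], target)

  # noise-free slide: perfect fit, no exclusion candidates
  gnf <- generate_slide(small_scenario(seed = 36, sigma_y = 0))
  dnf <- fit_diagnostics(fit_generated(gnf))
  expect_gte(dnf$r2, 1 - 1e-9)
  expect_equal(nrow(dnf$candidates), 0L)
})

test_that("alternating optimization matches a simultaneous optimizer", {
  g <- generate_slide(small_scenario(seed = 37, n_samples = 12L,
                                     n_replicates = 0L, sigma_y = 800))
  ser <- dilution_series(g$slide, infer_design(g$slide))
  mine <- fit_supercurve(ser)$fit$rss
  oracle <- oracle_rss(ser)
  expect_lt(abs(mine - oracle) / oracle, 1e-6)
})
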