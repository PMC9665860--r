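planted_matrix <- function(seed, n_samples = 20L, n_antibodies = 30L,
                           noise_sd = 0.05) {
  set.seed(seed)
  truth <- matrix(rnorm(n_samples * n_antibodies), n_samples, n_antibodies,
                  dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                  sprintf("AB%02d", seq_len(n_antibodies))))
  offsets <- rnorm(n_samples)
  list(truth = truth, offsets = offsets,
       values = truth + offsets + matrix(rnorm(length(truth), 0, noise_sd),
                                         n_samples, n_antibodies))
}

test_that("no-normalization is the identity with the right tag", {
  p <- planted_matrix(1)
  v <- p$values
  v[3, 5] <- NA
  out <- normalize_none(v)
  expect_equal(unclass(out)[, ], v[, ])
  expect_true(is.na(out[3, 5]))
  expect_equal(attr(out, "normalization"), "none")
})

test_that("median centering removes per-sample shifts and keeps NAs in place", {
  # a sample equal to another plus a constant becomes identical to it
  v <- matrix(rnorm(30), 3, 10)
  v <- rbind(v, v[1, ] + 2)
  out <- normalize_median_centering(v)
  expect_equal(out[4, ], out[1, ], tolerance = 1e-12)

  # one-sample matrix is unchanged (its median is the grand median)
  one <- matrix(c(1, 5, 9), 1, 3)
  expect_equal(unclass(normalize_median_centering(one))[, ], one[, ])

  # every sample's cross-antibody median equals the grand median afterwards
  p <- planted_matrix(2)
  out <- normalize_median_centering(p$values)
  rmed <- apply(out, 1, median)
  expect_equal(rmed, rep(median(rmed), length(rmed)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # NA cells stay NA, all-NA rows pass through with a warning
  v <- p$values
  v[2, ] <- NA
  v[5, 7] <- NA
  expect_warning(out <- normalize_median_centering(v), "all-NA",
                 class = "rppa_warning")
  expect_true(all(is.na(out[2, ])))
  expect_true(is.na(out[5, 7]))
  expect_error(normalize_median_centering(p$values[, 1, drop = FALSE]),
               "at least 2")
})

test_that("median centering recovers a planted offset-free matrix", {
  p <- planted_matrix(3)
  out <- normalize_median_centering(p$values)
  # compare on the per-sample-centered scale truth defines up to one shift
  # absolute level is arbitrary for both: align grand medians before comparing
  rmse <- function(a, b) sqrt(mean(((a - median(a)) - (b - median(b)))^2))
  centered_truth <- p$truth - apply(p$truth, 1, median)
  expect_lte(rmse(out, centered_truth), 0.1)
  expect_lt(rmse(out, centered_truth), rmse(p$values, centered_truth))
})

test_that("median polish removes sample effects only", {
  # exact additive matrix: zero residuals, rows identical after correction
  r <- c(-1, 0.5, 2, -0.3)
  cc <- c(0, 1, -2, 4, 0.5)
  v <- outer(r, rep(1, 5)) + outer(rep(1, 4), cc)
  out <- normalize_median_polish_loading(v)
  expect_equal(out[1, ], out[3, ], tolerance = 1e-12)
  expect_equal(diff(out[1, ]), diff(cc), tolerance = 1e-12)

  # all-zero matrix unchanged
  z <- matrix(0, 3, 3)
  expect_equal(unclass(normalize_median_polish_loading(z))[, ], z[, ])

  # planted additive effects recovered
  set.seed(4)
  r_true <- rnorm(30)
  c_true <- rnorm(40)
  va <- outer(r_true, rep(1, 40)) + outer(rep(1, 30), c_true) +
    matrix(rnorm(1200, 0, 0.05), 30, 40)
  out <- suppressWarnings(normalize_median_polish_loading(va))
  eff <- attr(out, "sample_effects")
  expect_gte(cor(eff, r_true), 0.99)
})

test_that("median polish agrees with the classical two-way decomposition", {
  set.seed(5)
  va <- outer(rnorm(20), rep(1, 30)) + outer(rep(1, 20), rnorm(30)) +
    matrix(rnorm(600, 0, 0.05), 20, 30)
  ours <- attr(suppressWarnings(normalize_median_polish_loading(va)),
               "sample_effects")
  ref <- stats::medpolish(va, eps = 1e-12, maxiter = 200, trace.iter = FALSE)
  # with even-length medians the polish fixed point is not unique, so the
  # two implementations may settle on slightly different decompositions
  a <- ours - median(ours)
  b <- ref$row - median(ref$row)
  expect_gte(cor(a, b), 0.9999)
  expect_lt(max(abs(a - b)), 0.01)
})

test_that("every method is idempotent and permutation-equivariant", {
  p <- planted_matrix(6)
  for (method in c("none", "median_centering", "median_polish_loading")) {
    once <- suppressWarnings(apply_loading_normalization(p$values, method))
    twice <- suppressWarnings(apply_loading_normalization(once, method))
    expect_equal(unclass(twice)[, ], unclass(once)[, ], tolerance = 1e-9)

    set.seed(7)
    pi_ <- sample(nrow(p$values))
    pj <- sample(ncol(p$values))
    perm <- suppressWarnings(apply_loading_normalization(p$values[pi_, pj], method))
    expect_equal(unclass(perm)[, ], unclass(once)[pi_, pj],
                 tolerance = 1e-12)
  }
})
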