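test_that("a well-formed file parses in file order", {
  path <- withr::local_tempfile(fileext = ".txt")
  df <- write_tiny_fixture(path)
  slide <- read_slide_file(path)
  expect_s3_class(slide, "rppa_slide")
  expect_equal(nrow(slide$records), 8L)
  expect_equal(slide$records$order, 1:8)
  expect_equal(slide$records$net, df$Net.Value)
  expect_equal(slide$records$dilution_step, rep(1:4, 2))
  expect_equal(slide$antibody, tools::file_path_sans_ext(basename(path)))
})

test_that("missing required columns raise a slide-level error naming them", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_fixture(path, drop_column = "Dilution")
  expect_error(read_slide_file(path), "Dilution", class = "rppa_slide_error")
})

test_that("structural problems are slide-level errors, bad values row-level warnings", {
  path <- withr::local_tempfile(fileext = ".txt")

  # duplicate grid coordinate
  df <- write_tiny_fixture(path)
  ll <- readLines(path)
  writeLines(c(ll, ll[2]), path)
  expect_error(read_slide_file(path), "duplicate grid coordinate",
               class = "rppa_slide_error")

  # unknown spot type
  write_tiny_fixture(path)
  writeLines(gsub("\tSample\t", "\tMystery\t", readLines(path)), path)
  expect_error(read_slide_file(path), "unknown spot type",
               class = "rppa_slide_error")

  # header-only file
  writeLines(readLines(path)[1], path)
  expect_error(read_slide_file(path), "no data rows",
               class = "rppa_slide_error")

  # negative intensity: warning, value retained
  net <- seq(1000, by = -100, length.out = 8)
  net[3] <- -25
  write_tiny_fixture(path, net = net)
  expect_warning(slide <- read_slide_file(path), "negative net intensity",
                 class = "rppa_warning")
  expect_equal(slide$records$net[3], -25)

  # unparseable numeric field: warning, NA retained in place
  write_tiny_fixture(path)
  ll <- readLines(path)
  ll[4] <- sub("800", "8oo", ll[4])
  writeLines(ll, path)
  expect_warning(slide <- read_slide_file(path), "unparseable",
                 class = "rppa_warning")
  expect_true(is.na(slide$records$net[3]))
})

test_that("generator output round-trips exactly and matches its truth table", {
  g <- generate_slide(sim_scenario(seed = 42), antibody = "RT01",
                      dir = td <- withr::local_tempdir())
  expect_equal(nrow(g$slide$records), 768L)
  back <- suppressWarnings(read_slide_file(file.path(td, "RT01.txt")))
  expect_identical(back$records, g$slide$records)
  # noiseless check is in test-synthetic; here: spot identity row-for-row
  expect_identical(back$records$series_id, g$truth$spots$series_id)
  expect_identical(back$records$dilution_step, g$truth$spots$step)
})

test_that("design inference recovers layout, ladder and roster", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_fixture(path)
  design <- infer_design(read_slide_file(path))
  expect_equal(design$n_steps, 4L)
  expect_equal(design$dilution_factor, 2)
  expect_equal(design$dilutions, c(1, 0.5, 0.25, 0.125))
  expect_equal(design$roster$series_id, c("S001", "S002"))

  # from the generator, with a non-default ladder
  g <- generate_slide(small_scenario(seed = 7, dilution_factor = 3,
                                     n_steps = 5L))
  d2 <- infer_design(g$slide)
  expect_equal(d2$n_steps, 5L)
  expect_equal(d2$dilution_factor, 3, tolerance = 1e-9)
  expect_equal(d2$n_main_rows, 2L)
  expect_equal(d2$n_sub_cols, 4L)
  expect_setequal(
    d2$roster$series_id[d2$roster$spot_type == "Sample"],
    g$truth$series$series_id[g$truth$series$spot_type == "Sample"])
})

test_that("one-dot layouts and inconsistent series are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tiny_fixture(path, dilutions = 1)   # single step per series
  expect_error(infer_design(read_slide_file(path)), "one-dot",
               class = "rppa_slide_error")

  write_tiny_fixture(path)
  ll <- readLines(path)
  writeLines(ll[-3], path)                  # S001 now has 3 steps, S002 has 4
  expect_error(infer_design(read_slide_file(path)), "S001",
               class = "rppa_slide_error")

  # non-geometric ladder
  write_tiny_fixture(path, dilutions = c(1, 0.5, 0.3, 0.15))
  expect_error(infer_design(read_slide_file(path)), "not geometric",
               class = "rppa_slide_error")
})

test_that("validation flags exactly the perturbed positions", {
  g <- generate_slide(small_scenario(seed = 3))
  design <- infer_design(g$slide)
  expect_equal(nrow(validate_against_design(g$slide, design)), 0L)

  # one spot type changed
  s2 <- g$slide
  i <- which(s2$records$spot_type == "Sample")[1]
  s2$records$spot_type[i] <- "Buffer"
  disc <- validate_against_design(s2, design)
  expect_equal(nrow(disc), 1L)
  expect_equal(disc$field, "spot_type")
  expect_equal(disc$main_row, s2$records$main_row[i])
  expect_equal(disc$sub_col, s2$records$sub_col[i])

  # two series swapped: every repositioned spot is flagged
  s3 <- g$slide
  a <- s3$records$series_id == "S001"
  b <- s3$records$series_id == "S002"
  s3$records$series_id[a] <- "S002"
  s3$records$series_id[b] <- "S001"
  disc <- validate_against_design(s3, design)
  expect_equal(nrow(disc), sum(a) + sum(b))
  expect_true(all(disc$field == "series_id"))
})

test_that("estimates do not depend on input row order", {
  g <- generate_slide(small_scenario(seed = 9))
  design <- infer_design(g$slide)
  fit1 <- fit_generated(g)

  g2 <- g
  set.seed(1)
  g2$slide$records <- g2$slide$records[sample(nrow(g2$slide$records)), ]
  expect_equal(nrow(validate_against_design(g2$slide, design)), 0L)
  fit2 <- suppressWarnings(
    fit_supercurve(dilution_series(g2$slide, infer_design(g2$slide))))
  e1 <- fit1$estimates
  e2 <- fit2$estimates[match(e1$series_id, fit2$estimates$series_id), ]
  expect_equal(e2$x, e1$x, tolerance = 1e-9)
})

test_that("write_outputs emits the expected files, byte-stable across re-runs", {
  base <- small_scenario(seed = 20)
  td <- withr::local_tempdir()
  generate_batch(replicate_scenarios(base, 2), dir = td)
  file.remove(list.files(td, pattern = "truth", full.names = TRUE))

  run_once <- function() {
    od <- withr::local_tempdir(.local_envir = parent.frame())
    run_batch(run_config(input_dir = td, output_dir = od,
                         loading = list(method = "median_centering")))
    od
  }
  od1 <- run_once()
  manifest <- readLines(file.path(od1, "manifest.txt"))
  expect_setequal(manifest, c(
    "AB01_concentrations.tsv", "AB02_concentrations.tsv", "fit_summary.tsv",
    "concentration_matrix_raw.tsv", "concentration_matrix_normalized.tsv",
    "errors.txt", "warnings.txt"))
  expect_equal(length(readLines(file.path(od1, "errors.txt"))), 0L)

  od2 <- run_once()
  numeric_files <- setdiff(manifest, c("errors.txt", "warnings.txt"))
  for (f in numeric_files) {
    expect_identical(readLines(file.path(od2, f)),
                     readLines(file.path(od1, f)))
  }
})
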