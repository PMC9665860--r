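# Input dialect: tab-separated, UTF-8, header row, one data row per printed
# spot. `Dilution` is the relative concentration of the step (1, 0.5, 0.25,
# ...); grid coordinates are 1-based; step 1 = undiluted.
.required_columns <- c(
  "Order", "Main.Row", "Main.Col", "Sub.Row", "Sub.Col",
  "Series.Id", "Spot.Type", "Dilution",
  "Net.Value", "Raw.Value", "Background.Value"
)
.numeric_columns <- c(
  "Order", "Main.Row", "Main.Col", "Sub.Row", "Sub.Col",
  "Dilution", "Net.Value", "Raw.Value", "Background.Value"
)
.spot_types <- c("Sample", "PosCtrl", "NegCtrl", "Buffer", "Blank", "NoiseRep")

#' Read a per-antibody spot quantification file
#'
#' Parses one tab-delimited slide quantification file into a slide object.
#' The file must carry a header row with columns `Order`, `Main.Row`,
#' `Main.Col`, `Sub.Row`, `Sub.Col`, `Series.Id`, `Spot.Type`, `Dilution`,
#' `Net.Value`, `Raw.Value`, `Background.Value`. Rows are kept in file order.
#' Unparseable numeric fields are reported per row (warning) and set to
#' `NA`, never silently dropped; negative net intensities are retained with
#' a warning. Missing required columns, duplicate grid coordinates, unknown
#' spot types or invalid coordinates raise a slide-level error that, in
#' batch mode, skips the slide without halting the batch.
#'
#' @param path path to the tab-delimited quantification file.
#' @param antibody antibody name; defaults to the file basename without
#'   extension (no separate slide design file exists to carry names).
#' @return An object of class `rppa_slide`: a list with elements `antibody`,
#'   `records` (one data frame row per spot with columns `order`,
#'   `main_row`, `main_col`, `sub_row`, `sub_col`, `series_id`, `spot_type`,
#'   `dilution`, `dilution_step`, `net`, `raw`, `background`) and `path`.
#' @seealso [infer_design()], [validate_against_design()]
#' @export
read_slide_file <- function(path, antibody = NULL) {
  if (is.null(antibody)) antibody <- tools::file_path_sans_ext(basename(path))
  if (!file.exists(path)) {
    rppa_error(sprintf("input file not found: %s", path),
               slide = antibody, stage = "read")
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      fill = FALSE, colClasses = "character"),
    error = function(e) {
      rppa_error(sprintf("slide '%s': cannot parse file: %s",
                         antibody, conditionMessage(e)),
                 slide = antibody, stage = "read")
    }
  )
  miss <- setdiff(.required_columns, names(df))
  if (length(miss)) {
    rppa_error(sprintf("slide '%s': missing required column(s): %s",
                       antibody, paste(miss, collapse = ", ")),
               slide = antibody, stage = "read")
  }
  if (nrow(df) == 0L) {
    rppa_error(sprintf("slide '%s': no data rows", antibody),
               slide = antibody, stage = "read")
  }

  bad_rows <- integer(0)
  for (cc in .numeric_columns) {
    v <- trimws(df[[cc]])
    nv <- suppressWarnings(as.numeric(v))
    bad_rows <- union(bad_rows, which(is.na(nv) & !(toupper(v) %in% c("NA", ""))))
    df[[cc]] <- nv
  }
  if (length(bad_rows)) {
    shown <- paste(utils::head(sort(bad_rows), 10L), collapse = ", ")
    rppa_warning(sprintf(
      "slide '%s': %d row(s) with unparseable numeric fields set to NA (rows %s%s)",
      antibody, length(bad_rows), shown,
      if (length(bad_rows) > 10L) ", ..." else ""),
      slide = antibody, stage = "read")
  }

  rec <- data.frame(
    order      = as.integer(df$Order),
    main_row   = as.integer(df$Main.Row),
    main_col   = as.integer(df$Main.Col),
    sub_row    = as.integer(df$Sub.Row),
    sub_col    = as.integer(df$Sub.Col),
    series_id  = as.character(df$Series.Id),
    spot_type  = as.character(df$Spot.Type),
    dilution   = df$Dilution,
    net        = df$Net.Value,
    raw        = df$Raw.Value,
    background = df$Background.Value,
    stringsAsFactors = FALSE
  )

  coord_cols <- c("main_row", "main_col", "sub_row", "sub_col")
  coord_bad <- !stats::complete.cases(rec[coord_cols]) |
    apply(rec[coord_cols] < 1L, 1L, any)
  if (any(coord_bad)) {
    rppa_error(sprintf(
      "slide '%s': %d row(s) with missing or non-positive grid coordinates (first at row %d)",
      antibody, sum(coord_bad), which(coord_bad)[1L]),
      slide = antibody, stage = "read")
  }
  key <- do.call(paste, c(rec[coord_cols], sep = ":"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    rppa_error(sprintf("slide '%s': duplicate grid coordinate (main_row:main_col:sub_row:sub_col = %s)",
                       antibody, dup),
               slide = antibody, stage = "read")
  }
  unknown <- setdiff(unique(rec$spot_type), .spot_types)
  if (length(unknown)) {
    rppa_error(sprintf("slide '%s': unknown spot type(s): %s",
                       antibody, paste(unknown, collapse = ", ")),
               slide = antibody, stage = "read")
  }
  if (anyNA(rec$dilution) || any(rec$dilution <= 0)) {
    rppa_error(sprintf("slide '%s': missing or non-positive Dilution values",
                       antibody),
               slide = antibody, stage = "read")
  }

  # dilution step: rank of declared relative concentration within the series,
  # step 1 = most concentrated
  rec$dilution_step <- NA_integer_
  for (idx in split(seq_len(nrow(rec)), rec$series_id)) {
    lad <- sort(unique(rec$dilution[idx]), decreasing = TRUE)
    rec$dilution_step[idx] <- match(rec$dilution[idx], lad)
  }

  n_neg <- sum(rec$net < 0, na.rm = TRUE)
  if (n_neg) {
    rppa_warning(sprintf(
      "slide '%s': %d spot(s) with negative net intensity (retained)",
      antibody, n_neg),
      slide = antibody, stage = "read")
  }
  has3 <- stats::complete.cases(rec[c("net", "raw", "background")])
  chk <- has3 & rec$raw >= rec$background
  bad_net <- chk & abs(rec$net - (rec$raw - rec$background)) >
    1e-6 * pmax(1, abs(rec$raw))
  if (any(bad_net)) {
    rppa_warning(sprintf(
      "slide '%s': %d spot(s) where Net.Value != Raw.Value - Background.Value",
      antibody, sum(bad_net)),
      slide = antibody, stage = "read")
  }

  structure(list(antibody = antibody, records = rec, path = path),
            class = "rppa_slide")
}

#' @export
print.rppa_slide <- function(x, ...) {
  cat(sprintf("RPPA slide '%s': %d spots, %d series\n",
              x$antibody, nrow(x$records), length(unique(x$records$series_id))))
  tt <- table(x$records$spot_type)
  cat("  spot types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' Infer the slide design from a parsed slide
#'
#' Determines the slide layout (grid dimensions), the dilution ladder
#' (number of steps and dilution factor), the spot-type map and the series
#' roster from a slide, so that no separate slide-design file is needed.
#' In batch processing the design is inferred from the first valid input
#' file and every subsequent slide must match it exactly.
#'
#' The dilution factor is the ratio of consecutive declared `Dilution`
#' values; all consecutive ratios must agree within a relative tolerance of
#' 1e-6. Serial dilutions are required: a design with a single dilution
#' step per sample (one-dot format) is rejected.
#'
#' @param slide an `rppa_slide` from [read_slide_file()].
#' @return An object of class `rppa_design`: grid dimensions
#'   (`n_main_rows`, `n_main_cols`, `n_sub_rows`, `n_sub_cols`), dilution
#'   ladder (`dilutions`, `dilution_factor`, `n_steps`), the series roster
#'   (`roster`: `series_id`, `spot_type`, `n_spots` in first-occurrence
#'   order) and the per-position spot map (`spot_map`).
#' @export
infer_design <- function(slide) {
  rec <- slide$records
  ab <- slide$antibody

  samp <- rec[rec$spot_type == "Sample", , drop = FALSE]
  if (!nrow(samp)) {
    rppa_error(sprintf("slide '%s': no Sample spots; cannot infer design", ab),
               slide = ab, stage = "design")
  }
  D <- max(samp$dilution_step)
  if (D < 2L) {
    rppa_error(sprintf(
      "slide '%s': only one dilution step per sample; serial dilutions are required (one-dot format unsupported)",
      ab), slide = ab, stage = "design")
  }
  n_steps <- tapply(samp$dilution_step, samp$series_id,
                    function(s) length(unique(s)))
  bad <- names(n_steps)[n_steps != D]
  if (length(bad)) {
    rppa_error(sprintf(
      "slide '%s': Sample series with inconsistent dilution step counts (expected %d): %s",
      ab, D, paste(bad, collapse = ", ")),
      slide = ab, stage = "design")
  }

  ladders <- lapply(split(samp$dilution, samp$series_id),
                    function(d) sort(unique(d), decreasing = TRUE))
  lad <- ladders[[1L]]
  same <- vapply(ladders, function(l) {
    length(l) == length(lad) && all(abs(l / lad - 1) <= 1e-9)
  }, logical(1))
  if (!all(same)) {
    rppa_error(sprintf(
      "slide '%s': Sample series with dilution ladders differing from %s: %s",
      ab, paste(signif(lad, 6), collapse = ", "),
      paste(names(ladders)[!same], collapse = ", ")),
      slide = ab, stage = "design")
  }
  ratios <- lad[-length(lad)] / lad[-1L]
  f <- ratios[1L]
  if (any(abs(ratios / f - 1) > 1e-6)) {
    rppa_error(sprintf(
      "slide '%s': dilution ladder is not geometric; consecutive ratios %s disagree",
      ab, paste(signif(ratios, 6), collapse = ", ")),
      slide = ab, stage = "design")
  }
  if (f <= 1) {
    rppa_error(sprintf("slide '%s': dilution factor must exceed 1 (got %g)", ab, f),
               slide = ab, stage = "design")
  }

  first <- !duplicated(rec$series_id)
  roster <- data.frame(series_id = rec$series_id[first],
                       spot_type = rec$spot_type[first],
                       stringsAsFactors = FALSE)
  mixed <- tapply(rec$spot_type, rec$series_id,
                  function(s) length(unique(s)) > 1L)
  if (any(mixed)) {
    rppa_error(sprintf("slide '%s': series with mixed spot types: %s",
                       ab, paste(names(mixed)[mixed], collapse = ", ")),
               slide = ab, stage = "design")
  }
  cnt <- table(rec$series_id)
  roster$n_spots <- as.integer(cnt[roster$series_id])

  structure(list(
    n_main_rows = max(rec$main_row), n_main_cols = max(rec$main_col),
    n_sub_rows  = max(rec$sub_row),  n_sub_cols  = max(rec$sub_col),
    dilutions = lad, dilution_factor = f, n_steps = as.integer(D),
    roster = roster,
    spot_map = rec[c("main_row", "main_col", "sub_row", "sub_col",
                     "series_id", "spot_type", "dilution")]
  ), class = "rppa_design")
}

#' @export
print.rppa_design <- function(x, ...) {
  cat(sprintf("RPPA slide design: %dx%d main grid, %dx%d sub grid (%d positions)\n",
              x$n_main_rows, x$n_main_cols, x$n_sub_rows, x$n_sub_cols,
              nrow(x$spot_map)))
  cat(sprintf("  dilution ladder: %s (factor %.6g, %d steps)\n",
              paste(signif(x$dilutions, 6), collapse = ", "),
              x$dilution_factor, x$n_steps))
  tt <- table(x$roster$spot_type)
  cat("  series:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' Check a slide against an inferred design
#'
#' Compares a slide position-by-position with the design inferred from the
#' first valid file of the batch. The comparison covers grid dimensions and,
#' at every coordinate, the series ID, spot type and declared dilution.
#'
#' @param slide an `rppa_slide`.
#' @param design an `rppa_design`.
#' @return A data frame of discrepancies (zero rows when the slide matches
#'   the design exactly) with columns `main_row`, `main_col`, `sub_row`,
#'   `sub_col`, `field`, `expected`, `observed`. In batch mode a non-empty
#'   result escalates to a slide-level error.
#' @export
validate_against_design <- function(slide, design) {
  rec <- slide$records
  map <- design$spot_map
  coord_cols <- c("main_row", "main_col", "sub_row", "sub_col")

  disc <- list()
  add <- function(coord, field, expected, observed) {
    disc[[length(disc) + 1L]] <<- data.frame(
      main_row = coord[1L], main_col = coord[2L],
      sub_row = coord[3L], sub_col = coord[4L],
      field = field, expected = as.character(expected),
      observed = as.character(observed), stringsAsFactors = FALSE)
  }

  dims <- c("n_main_rows", "n_main_cols", "n_sub_rows", "n_sub_cols")
  obs_dims <- c(max(rec$main_row), max(rec$main_col),
                max(rec$sub_row), max(rec$sub_col))
  for (k in seq_along(dims)) {
    if (obs_dims[k] != design[[dims[k]]]) {
      add(rep(NA_integer_, 4L), dims[k], design[[dims[k]]], obs_dims[k])
    }
  }

  ks <- do.call(paste, c(rec[coord_cols], sep = ":"))
  km <- do.call(paste, c(map[coord_cols], sep = ":"))
  for (k in setdiff(km, ks)) {
    i <- match(k, km)
    add(as.integer(map[i, coord_cols]), "presence", "spot", "absent")
  }
  for (k in setdiff(ks, km)) {
    i <- match(k, ks)
    add(as.integer(rec[i, coord_cols]), "presence", "absent", "spot")
  }

  common <- intersect(km, ks)
  ir <- match(common, ks)
  im <- match(common, km)
  for (field in c("series_id", "spot_type")) {
    differ <- which(rec[[field]][ir] != map[[field]][im])
    for (j in differ) {
      add(as.integer(rec[ir[j], coord_cols]), field,
          map[[field]][im[j]], rec[[field]][ir[j]])
    }
  }
  differ <- which(abs(rec$dilution[ir] / map$dilution[im] - 1) > 1e-9)
  for (j in differ) {
    add(as.integer(rec[ir[j], coord_cols]), "dilution",
        signif(map$dilution[im[j]], 6), signif(rec$dilution[ir[j]], 6))
  }

  if (length(disc)) do.call(rbind, disc) else data.frame(
    main_row = integer(0), main_col = integer(0), sub_row = integer(0),
    sub_col = integer(0), field = character(0), expected = character(0),
    observed = character(0), stringsAsFactors = FALSE)
}

# fixed numeric output format: 6 significant digits, NA for missing
.fmt_cell <- function(x) {
  if (is.double(x)) {
    ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
  } else {
    ifelse(is.na(x), "NA", as.character(x))
  }
}

.write_tsv <- function(df, path) {
  cols <- lapply(df, .fmt_cell)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
}

#' Write all tabular outputs for a processed batch
#'
#' Writes, tab-delimited with headers and a fixed numeric format (6
#' significant digits, `NA` for missing): one concentration table per
#' successfully processed slide (one row per series with its relative log2
#' concentration, standard error, the slide's mean replicate expression and
#' flags), a per-slide fit summary (curve parameters, fit diagnostics and
#' the noise metric), the batch-wide samples-by-antibodies concentration
#' matrix in raw and loading-normalized variants, the errors and warnings
#' files, and a plain-text manifest of everything written. Outputs are
#' byte-identical across re-runs on identical inputs (the errors and
#' warnings files carry event timestamps and are the only exception).
#'
#' @param batch an `rppa_batch` from [run_batch()].
#' @param out_dir output directory; created if needed. An unwritable
#'   directory is a fatal batch error.
#' @return Invisibly, the character vector of files written (the manifest).
#' @export
write_outputs <- function(batch, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory: %s", out_dir))
  }
  manifest <- character(0)
  emit <- function(df, name) {
    .write_tsv(df, file.path(out_dir, name))
    manifest <<- c(manifest, name)
  }

  ok <- Filter(function(s) identical(s$status, "ok"), batch$slides)
  fs <- list()
  for (s in ok) {
    rep_mean <- if (!is.null(s$noise)) s$noise$replicate_mean else NA_real_
    ct <- data.frame(
      series_id = s$estimates$series_id,
      spot_type = s$estimates$spot_type,
      log2_concentration = s$estimates$x,
      se = s$estimates$se_x,
      replicate_mean = rep_mean,
      in_fit = s$estimates$in_fit,
      flags = ifelse(s$estimates$flags == "", "-", s$estimates$flags),
      stringsAsFactors = FALSE)
    emit(ct, paste0(s$antibody, "_concentrations.tsv"))
    fs[[length(fs) + 1L]] <- data.frame(
      antibody = s$antibody, alpha = s$fit$alpha, beta = s$fit$beta,
      gamma = s$fit$gamma, rss = s$fit$rss, r2 = s$fit$r2,
      n_series_used = s$fit$n_series_used, n_spots_used = s$fit$n_spots_used,
      converged = s$fit$converged, n_iterations = s$fit$n_iterations,
      n_replicates = if (!is.null(s$noise)) s$noise$n_replicates else NA_integer_,
      noise_sd = if (!is.null(s$noise)) s$noise$noise_sd else NA_real_,
      replicate_mean = rep_mean,
      stringsAsFactors = FALSE)
  }
  if (length(fs)) {
    emit(do.call(rbind, fs), "fit_summary.tsv")
  }

  mat_df <- function(m) {
    data.frame(sample_id = rownames(m),
               as.data.frame(m, optional = TRUE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(batch$matrix_raw) && ncol(batch$matrix_raw)) {
    emit(mat_df(batch$matrix_raw), "concentration_matrix_raw.tsv")
    emit(mat_df(batch$matrix_norm), "concentration_matrix_normalized.tsv")
  }

  report_errors(batch, out_dir)
  manifest <- c(manifest, "errors.txt", "warnings.txt")
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}
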