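.spatial_defaults <- function() list(enabled = FALSE, span = 0.75,
                                     min_controls = 10L, clamp = c(0.25, 4))
.noise_defaults <- function() list(enabled = TRUE)
.loading_defaults <- function() list(method = "none", max_iter = 50L,
                                     tol = 1e-10)

.merge_opts <- function(defaults, user, what) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown %s option(s): %s", what,
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, user)
}

#' Build a batch run configuration
#'
#' Validates and assembles all settings for [run_batch()]. Unknown option
#' keys are a configuration error raised before any processing. Curve
#' fitting cannot be disabled; spatial adjustment (off by default) and the
#' noise metric (on by default) are optional; loading normalization always
#' runs with the configured method, which may be `"none"`.
#'
#' @param input_dir directory of per-antibody quantification files.
#' @param output_dir directory for tabular outputs (`NULL` to skip writing).
#' @param workers number of parallel workers for the per-slide stages.
#'   Results are bit-identical for any worker count.
#' @param spatial list: `enabled`, `span`, `min_controls`, `clamp`.
#' @param noise list: `enabled`.
#' @param loading list: `method` (one of `"none"`, `"median_centering"`,
#'   `"median_polish_loading"`), `max_iter`, `tol`.
#' @param fit list of [fit_options()] overrides.
#' @param excluded_series series IDs excluded from curve fitting on every
#'   slide of the batch (they are still normalized post hoc).
#' @param seed optional integer recorded for simulation harnesses; the
#'   pipeline itself is deterministic.
#' @return An object of class `rppa_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL, workers = 1L,
                       spatial = list(), noise = list(), loading = list(),
                       fit = list(), excluded_series = character(),
                       seed = NULL) {
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("workers must be a positive integer")
  spatial <- .merge_opts(.spatial_defaults(), spatial, "spatial")
  noise <- .merge_opts(.noise_defaults(), noise, "noise")
  loading <- .merge_opts(.loading_defaults(), loading, "loading")
  loading$method <- match.arg(loading$method, .loading_methods)
  fit <- do.call(fit_options, fit)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 workers = workers, spatial = spatial, noise = noise,
                 loading = loading, fit = fit,
                 excluded_series = as.character(excluded_series),
                 seed = seed),
            class = "rppa_config")
}

#' Read a run configuration file
#'
#' Reads a YAML key/value file whose keys mirror the arguments of
#' [run_config()]; arguments supplied in `...` (e.g. from command-line
#' flags) override the file.
#'
#' @param path path to the YAML configuration file.
#' @param ... overrides, as in [run_config()].
#' @return An `rppa_config`.
#' @export
read_run_config <- function(path, ...) {
  conf <- yaml::read_yaml(path)
  if (is.null(conf)) conf <- list()
  if (!is.list(conf)) stop(sprintf("configuration file '%s' is not a key/value mapping", path))
  unknown <- setdiff(names(conf), names(formals(run_config)))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s) in '%s': %s", path,
                 paste(unknown, collapse = ", ")))
  }
  over <- list(...)
  conf[names(over)] <- over
  do.call(run_config, conf)
}

#' Plan the processing stages for a configuration
#'
#' Returns the fixed stage order: read, validate, optional spatial
#' adjustment, curve fitting (always on), optional noise metric, matrix
#' assembly, loading normalization (always present, possibly with method
#' "none") and output writing. Per-slide stages are parallelizable across
#' slides; matrix assembly, loading and writing are serial.
#'
#' @param config an `rppa_config`.
#' @return Data frame with columns `stage`, `parallel`, `optional`, in
#'   execution order.
#' @export
plan_stages <- function(config) {
  stopifnot(inherits(config, "rppa_config"))
  stages <- c("read", "validate",
              if (config$spatial$enabled) "spatial",
              "curve_fit",
              if (config$noise$enabled) "noise",
              "assemble_matrix", "loading", "write")
  data.frame(stage = stages,
             parallel = stages %in% c("read", "validate", "spatial",
                                      "curve_fit", "noise"),
             optional = stages %in% c("spatial", "noise"),
             stringsAsFactors = FALSE)
}

# process one slide end to end; never throws — returns a status record with
# collected warnings so one problematic slide cannot halt the batch
.process_slide <- function(path, design, config) {
  t0 <- proc.time()[["elapsed"]]
  warns <- list()
  res <- withCallingHandlers(
    tryCatch({
      slide <- read_slide_file(path)
      disc <- validate_against_design(slide, design)
      if (nrow(disc)) {
        ex <- disc[1L, ]
        rppa_error(sprintf(
          "slide '%s': %d discrepancies against inferred design (first: %s at %s,%s,%s,%s expected '%s' observed '%s')",
          slide$antibody, nrow(disc), ex$field, ex$main_row, ex$main_col,
          ex$sub_row, ex$sub_col, ex$expected, ex$observed),
          slide = slide$antibody, stage = "validate")
      }
      surface <- NULL
      if (config$spatial$enabled) {
        surface <- fit_spatial_surface(
          slide, design, span = config$spatial$span,
          min_controls = config$spatial$min_controls,
          clamp = config$spatial$clamp)
        slide <- apply_spatial_adjustment(slide, surface)
      }
      ser <- dilution_series(slide, design, exclude = config$excluded_series,
                             options = config$fit)
      sc <- fit_supercurve(ser, options = config$fit)
      noise <- if (config$noise$enabled) {
        compute_noise(sc$estimates, slide$antibody)
      }
      list(antibody = slide$antibody, file = basename(path), status = "ok",
           fit = sc$fit, estimates = sc$estimates, residuals = sc$residuals,
           noise = noise,
           surface = if (!is.null(surface)) {
             surface[c("n_controls_used", "control_rmse_before",
                       "control_rmse_after")]
           },
           error = NULL)
    }, error = function(e) {
      list(antibody = tools::file_path_sans_ext(basename(path)),
           file = basename(path), status = "error",
           error = list(message = conditionMessage(e),
                        stage = .cond_stage(e)))
    }),
    warning = function(w) {
      warns[[length(warns) + 1L]] <<- list(message = conditionMessage(w),
                                           stage = .cond_stage(w))
      invokeRestart("muffleWarning")
    })
  res$warnings <- warns
  res$elapsed <- proc.time()[["elapsed"]] - t0
  res
}

#' Run a batch of antibody slides through the pipeline
#'
#' Orchestrates the full stage chain over every quantification file in the
#' input directory: the slide design is inferred from the first valid file
#' (lexicographic filename order) and assumed for all subsequent slides;
#' each slide is validated, optionally spatially adjusted, curve-fitted
#' (with configured series exclusions normalized post hoc) and given a
#' noise report; the samples x antibodies matrix is assembled, loading
#' normalization applied, and all outputs written.
#'
#' Slides run in parallel across `workers` processes; because every stage
#' is deterministic, numeric outputs are bit-identical for any worker
#' count. A slide that fails at any stage is recorded in the errors file
#' and skipped — it never halts the processing of subsequent slides, and
#' the surviving slides' outputs equal those of a batch containing only the
#' survivors.
#'
#' @param config an `rppa_config` from [run_config()] /
#'   [read_run_config()].
#' @return An object of class `rppa_batch`: `design`, `slides` (per-slide
#'   status records with fit, estimates and noise report), `matrix_raw`,
#'   `matrix_norm`, `errors` and `warnings` data frames (slide, stage,
#'   message, time), `timing`, and the `config` used. Raised as a fatal
#'   error only when no file exists or no file yields a valid design.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "rppa_config"))
  files <- list.files(config$input_dir, pattern = "\\.(txt|tsv)$",
                      full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (!length(files)) {
    stop(sprintf("no candidate input files (*.txt, *.tsv) in '%s'",
                 config$input_dir))
  }

  design <- NULL
  for (f in files) {
    design <- tryCatch(
      suppressWarnings(infer_design(read_slide_file(f))),
      error = function(e) NULL)
    if (!is.null(design)) break
  }
  if (is.null(design)) {
    stop("no valid input file from which to infer the slide design")
  }

  worker <- function(f) .process_slide(f, design, config)
  results <- if (config$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, worker, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(files, worker)
  }
  # a crashed worker surfaces as a try-error: demote to a slide error
  for (i in seq_along(results)) {
    if (inherits(results[[i]], "try-error") || is.null(results[[i]]$status)) {
      results[[i]] <- list(
        antibody = tools::file_path_sans_ext(basename(files[i])),
        file = basename(files[i]), status = "error",
        error = list(message = as.character(results[[i]]),
                     stage = "process"),
        warnings = list(), elapsed = NA_real_)
    }
  }
  names(results) <- vapply(results, `[[`, "", "antibody")

  now <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ev <- function(kind) {
    rows <- list()
    for (s in results) {
      if (kind == "error" && !is.null(s$error)) {
        rows[[length(rows) + 1L]] <- data.frame(
          time = now, slide = s$antibody, stage = s$error$stage,
          message = s$error$message, stringsAsFactors = FALSE)
      }
      if (kind == "warning") {
        for (w in s$warnings) {
          rows[[length(rows) + 1L]] <- data.frame(
            time = now, slide = s$antibody, stage = w$stage,
            message = w$message, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else data.frame(
      time = character(0), slide = character(0), stage = character(0),
      message = character(0), stringsAsFactors = FALSE)
  }
  errors <- ev("error")
  warnings_df <- ev("warning")

  ok <- Filter(function(s) identical(s$status, "ok"), results)
  samples <- design$roster$series_id[design$roster$spot_type == "Sample"]
  mat <- matrix(NA_real_, length(samples), length(ok),
                dimnames = list(samples, vapply(ok, `[[`, "", "antibody")))
  for (s in ok) {
    i <- match(s$estimates$series_id, samples)
    keep <- !is.na(i)
    mat[i[keep], s$antibody] <- s$estimates$x[keep]
  }
  matn <- if (ncol(mat)) {
    tryCatch(
      withCallingHandlers(
        apply_loading_normalization(mat, config$loading$method,
                                    max_iter = config$loading$max_iter,
                                    tol = config$loading$tol),
        warning = function(w) {
          warnings_df <<- rbind(warnings_df, data.frame(
            time = now, slide = "<batch>", stage = "loading",
            message = conditionMessage(w), stringsAsFactors = FALSE))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warnings_df <<- rbind(warnings_df, data.frame(
          time = now, slide = "<batch>", stage = "loading",
          message = sprintf("loading normalization '%s' failed (%s); raw matrix kept",
                            config$loading$method, conditionMessage(e)),
          stringsAsFactors = FALSE))
        normalize_none(mat)
      })
  } else {
    normalize_none(mat)
  }

  batch <- structure(list(
    design = design, slides = results, matrix_raw = mat, matrix_norm = matn,
    errors = errors, warnings = warnings_df,
    timing = data.frame(slide = names(results),
                        seconds = vapply(results, function(s)
                          s$elapsed %||% NA_real_, numeric(1)),
                        stringsAsFactors = FALSE),
    config = config), class = "rppa_batch")
  if (!is.null(config$output_dir)) write_outputs(batch, config$output_dir)
  batch
}

#' @export
print.rppa_batch <- function(x, ...) {
  st <- vapply(x$slides, `[[`, "", "status")
  cat(sprintf("RPPA batch: %d slide(s) — %d ok, %d failed; %d warning(s)\n",
              length(st), sum(st == "ok"), sum(st != "ok"),
              nrow(x$warnings)))
  if (nrow(x$errors)) {
    cat("  errors:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat(sprintf("    [%s] %s: %s\n", x$errors$stage[i], x$errors$slide[i],
                  x$errors$message[i]))
    }
  }
  invisible(x)
}

#' Write the errors and warnings files
#'
#' One line per event — ISO-8601 timestamp, slide name, stage and message,
#' tab-separated. Both files are created even when empty, so their absence
#' never has to be interpreted.
#'
#' @param batch an `rppa_batch`.
#' @param out_dir output directory.
#' @return Invisibly, the two file paths.
#' @export
report_errors <- function(batch, out_dir) {
  line <- function(df) {
    if (!nrow(df)) return(character(0))
    sprintf("%s\t%s\t%s\t%s", df$time, df$slide, df$stage, df$message)
  }
  ep <- file.path(out_dir, "errors.txt")
  wp <- file.path(out_dir, "warnings.txt")
  writeLines(line(batch$errors), ep)
  writeLines(line(batch$warnings), wp)
  invisible(c(ep, wp))
}
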