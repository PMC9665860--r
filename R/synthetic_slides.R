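#' Define a synthetic slide scenario
#'
#' A scenario fixes everything about a ground-truthed synthetic slide: the
#' grid layout, the dilution ladder, the true response curve, the
#' distribution of sample concentrations, the technical-replicate series
#' (all printing one sample at a common true concentration), the intensity
#' noise model, an optional smooth spatial bias field and optional planted
#' outlier series. Defaults emulate a production-scale slide: a 4x12 main
#' grid of 4x4 sub-grids (768 spots), 96 sample series at 4 two-fold
#' dilution steps, 24 replicate series, a curve with baseline 200,
#' dynamic range 40000 and slope 0.8 per log2 unit, and additive Gaussian
#' intensity noise with sd equal to 1% of the dynamic range.
#'
#' @param n_main_rows,n_main_cols,n_sub_rows,n_sub_cols grid dimensions.
#' @param n_samples number of sample dilution series.
#' @param n_replicates number of technical-replicate series.
#' @param n_steps dilution steps per series (at least 2).
#' @param dilution_factor fold dilution between consecutive steps.
#' @param alpha,beta,gamma true curve: baseline intensity, dynamic range,
#'   slope per log2 unit.
#' @param x_range range of the uniform distribution of true sample log2
#'   concentrations.
#' @param replicate_x common true log2 concentration of all replicate
#'   series.
#' @param sigma_y intensity noise sd (scanner fluorescence units).
#' @param proportional_noise if `TRUE` the noise sd scales with the
#'   noiseless signal (`sigma_y * clean / beta`) instead of being constant.
#' @param spatial_field `"none"`, `"gradient"` (left-to-right linear
#'   multiplicative gradient) or `"blob"` (radial bump).
#' @param spatial_fold fold range of the spatial field.
#' @param outliers data frame (`series_id`, `factor`) of series whose
#'   intensities are multiplied by `factor`.
#' @param seed mandatory integer seed.
#' @return An object of class `rppa_scenario`.
#' @export
sim_scenario <- function(n_main_rows = 4L, n_main_cols = 12L,
                         n_sub_rows = 4L, n_sub_cols = 4L,
                         n_samples = 96L, n_replicates = 24L,
                         n_steps = 4L, dilution_factor = 2,
                         alpha = 200, beta = 40000, gamma = 0.8,
                         x_range = c(-4, 4), replicate_x = 0,
                         sigma_y = 400, proportional_noise = FALSE,
                         spatial_field = c("none", "gradient", "blob"),
                         spatial_fold = 2,
                         outliers = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for a scenario")
  spatial_field <- match.arg(spatial_field)
  stopifnot(n_main_rows >= 1L, n_main_cols >= 1L, n_sub_rows >= 1L,
            n_sub_cols >= 1L, n_samples >= 1L, n_replicates >= 0L,
            n_steps >= 2L, dilution_factor > 1, beta > 0, gamma > 0,
            sigma_y >= 0, spatial_fold >= 1,
            length(x_range) == 2L, x_range[1L] < x_range[2L])
  P <- n_main_rows * n_main_cols * n_sub_rows * n_sub_cols
  need <- (n_samples + n_replicates) * n_steps
  if (need > P) {
    stop(sprintf("grid too small: %d positions for %d series spots", P, need))
  }
  structure(as.list(environment()), class = "rppa_scenario")
}

.spatial_field_matrix <- function(sc, R, C) {
  m <- switch(sc$spatial_field,
    none = matrix(1, R, C),
    gradient = {
      raw <- 1 + (sc$spatial_fold - 1) * (seq_len(C) - 1) / max(1L, C - 1L)
      matrix(rep(raw, each = R), R, C)
    },
    blob = {
      r0 <- (R + 1) / 2
      c0 <- (C + 1) / 2
      s2 <- (min(R, C) / 3)^2
      d2 <- outer((seq_len(R) - r0)^2, (seq_len(C) - c0)^2, `+`)
      1 + (sc$spatial_fold - 1) * exp(-d2 / (2 * s2))
    })
  m / stats::median(m)
}

#' Generate one ground-truthed synthetic slide
#'
#' Builds spot intensities as
#' `y = m(r, c) * outlier_factor * [alpha + beta / (1 + exp(-gamma * (x_i + d_j)))] + eps`
#' with `eps ~ N(0, sigma_y^2)`, seeded from the scenario. Replicate series
#' spots are placed on an evenly spaced lattice over the flattened physical
#' grid so they cover the slide; sample series fill the remaining positions
#' sequentially and leftovers become buffer spots at baseline level.
#' Negative noisy intensities are retained (the pipeline keeps them too).
#'
#' @param scenario an [sim_scenario()].
#' @param antibody antibody name (becomes the file basename).
#' @param dir if non-`NULL`, the slide file and plain-text truth tables are
#'   written there.
#' @param x_offset optional per-sample additive offset on the true log2
#'   concentrations (length `n_samples`), used to plant shared loading
#'   effects across a batch.
#' @return A list: `slide` (an `rppa_slide`), `truth` (list with `params`,
#'   per-series `series` table of true `x`, the spatial field matrix `m`,
#'   per-spot `spots` table with noiseless intensities, and `sigma_y`), and
#'   `path` (the written file or `NA`).
#' @export
generate_slide <- function(scenario, antibody = "AB01", dir = NULL,
                           x_offset = NULL) {
  sc <- scenario
  stopifnot(inherits(sc, "rppa_scenario"))
  set.seed(sc$seed)
  R <- sc$n_main_rows * sc$n_sub_rows
  C <- sc$n_main_cols * sc$n_sub_cols
  P <- R * C

  x_s <- stats::runif(sc$n_samples, sc$x_range[1L], sc$x_range[2L])
  if (!is.null(x_offset)) {
    stopifnot(length(x_offset) == sc$n_samples)
    x_s <- x_s + x_offset
  }
  ids_s <- sprintf("S%03d", seq_len(sc$n_samples))
  ids_r <- if (sc$n_replicates) sprintf("NR%02d", seq_len(sc$n_replicates))

  # replicate spots on a deterministic 2-D stratified lattice so they cover
  # the slide surface (spatial correction needs scattered controls)
  n_rep_spots <- sc$n_replicates * sc$n_steps
  idx_rep <- integer(0)
  if (n_rep_spots) {
    nr <- max(1L, min(R, round(sqrt(n_rep_spots * R / C))))
    nc <- ceiling(n_rep_spots / nr)
    if (nc > C) {
      nc <- C
      nr <- ceiling(n_rep_spots / nc)
    }
    rows <- unique(round(seq(1, R, length.out = nr)))
    cols <- unique(round(seq(1, C, length.out = nc)))
    lat <- expand.grid(r = rows, c = cols)
    if (nrow(lat) < n_rep_spots) {
      stop("grid too small to scatter the replicate spots on a lattice")
    }
    lat <- lat[seq_len(n_rep_spots), ]
    idx_rep <- (lat$c - 1L) * R + lat$r
  }
  rest <- setdiff(seq_len(P), idx_rep)
  idx_samp <- rest[seq_len(sc$n_samples * sc$n_steps)]
  idx_buf <- rest[-seq_len(sc$n_samples * sc$n_steps)]

  series <- character(P)
  type <- character(P)
  step <- integer(P)
  xs_all <- numeric(P)
  series[idx_rep] <- rep(ids_r, each = sc$n_steps)
  type[idx_rep] <- "NoiseRep"
  step[idx_rep] <- rep(seq_len(sc$n_steps), times = sc$n_replicates)
  xs_all[idx_rep] <- sc$replicate_x
  series[idx_samp] <- rep(ids_s, each = sc$n_steps)
  type[idx_samp] <- "Sample"
  step[idx_samp] <- rep(seq_len(sc$n_steps), times = sc$n_samples)
  xs_all[idx_samp] <- rep(x_s, each = sc$n_steps)
  if (length(idx_buf)) {
    series[idx_buf] <- sprintf("BUF%04d", seq_along(idx_buf))
    type[idx_buf] <- "Buffer"
    step[idx_buf] <- 1L
    xs_all[idx_buf] <- -Inf          # buffer spots sit at the baseline
  }

  dil <- sc$dilution_factor^-(step - 1L)
  d <- log2(dil)
  clean <- sc$alpha + sc$beta * stats::plogis(sc$gamma * (xs_all + d))

  m <- .spatial_field_matrix(sc, R, C)
  pr <- ((seq_len(P) - 1L) %% R) + 1L    # column-major flattening
  pc <- ((seq_len(P) - 1L) %/% R) + 1L
  mult <- m[cbind(pr, pc)]

  ofac <- rep(1, P)
  if (!is.null(sc$outliers) && nrow(sc$outliers)) {
    i <- match(series, sc$outliers$series_id)
    ofac[!is.na(i)] <- sc$outliers$factor[i[!is.na(i)]]
  }

  noiseless <- mult * ofac * clean
  sdv <- if (sc$proportional_noise) sc$sigma_y * clean / sc$beta else sc$sigma_y
  y <- noiseless + if (sc$sigma_y > 0) stats::rnorm(P, 0, sdv) else 0

  background <- rep(50, P)
  rec <- data.frame(
    order = seq_len(P),
    main_row = ((pr - 1L) %/% sc$n_sub_rows) + 1L,
    main_col = ((pc - 1L) %/% sc$n_sub_cols) + 1L,
    sub_row = ((pr - 1L) %% sc$n_sub_rows) + 1L,
    sub_col = ((pc - 1L) %% sc$n_sub_cols) + 1L,
    series_id = series, spot_type = type, dilution = dil,
    net = y, raw = y + background, background = background,
    dilution_step = step, stringsAsFactors = FALSE)
  slide <- structure(list(antibody = antibody, records = rec,
                          path = NA_character_), class = "rppa_slide")

  truth <- list(
    params = c(alpha = sc$alpha, beta = sc$beta, gamma = sc$gamma),
    series = data.frame(
      series_id = c(ids_s, ids_r),
      spot_type = c(rep("Sample", sc$n_samples),
                    rep("NoiseRep", sc$n_replicates)),
      x_true = c(x_s, rep(sc$replicate_x, sc$n_replicates)),
      stringsAsFactors = FALSE),
    m = m,
    spots = data.frame(order = seq_len(P), series_id = series, step = step,
                       noiseless = noiseless, clean = clean,
                       stringsAsFactors = FALSE),
    sigma_y = sc$sigma_y)

  path <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, paste0(antibody, ".txt"))
    write_slide_file(slide, path)
    .write_tsv(truth$series, file.path(dir, paste0(antibody, "_truth_series.tsv")))
    .write_tsv(data.frame(r = pr, c = pc, m = mult),
               file.path(dir, paste0(antibody, "_truth_spatial.tsv")))
    .write_tsv(truth$spots, file.path(dir, paste0(antibody, "_truth_spots.tsv")))
    slide$path <- path
  }
  list(slide = slide, truth = truth, path = path)
}

#' Write a slide object as a quantification file
#'
#' Emits the tab-delimited input dialect with full double precision (17
#' significant digits) so that generate -> write -> read round-trips every
#' field exactly.
#'
#' @param slide an `rppa_slide`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_slide_file <- function(slide, path) {
  rec <- slide$records
  num <- function(x) sprintf("%.17g", x)
  lines <- c(paste(.required_columns, collapse = "\t"),
             paste(rec$order, rec$main_row, rec$main_col, rec$sub_row,
                   rec$sub_col, rec$series_id, rec$spot_type,
                   num(rec$dilution), num(rec$net), num(rec$raw),
                   num(rec$background), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Derive per-antibody scenarios from a base scenario
#'
#' Returns `n` copies of `base` that differ only in their seed — the usual
#' way to build a batch of antibodies sharing one slide design.
#'
#' @param base an [sim_scenario()].
#' @param n number of scenarios.
#' @param seeds integer seeds, one per scenario (defaults to
#'   `base$seed + 1:n`).
#' @return A list of `rppa_scenario` objects.
#' @export
replicate_scenarios <- function(base, n, seeds = base$seed + seq_len(n)) {
  stopifnot(inherits(base, "rppa_scenario"), n >= 1L, length(seeds) == n)
  lapply(seeds, function(s) { base$seed <- s; base })
}

.design_fields <- c("n_main_rows", "n_main_cols", "n_sub_rows", "n_sub_cols",
                    "n_samples", "n_replicates", "n_steps", "dilution_factor")

#' Generate a batch of synthetic slides sharing one design
#'
#' One slide per scenario, all sharing the same layout, series roster and
#' dilution ladder (mismatching designs are an error, mirroring the
#' single-design assumption of batch processing). Optional per-sample
#' loading offsets, shared across antibodies, are added to every antibody's
#' true concentrations — the planted effect that loading normalization
#' should remove.
#'
#' @param scenarios list of [sim_scenario()] objects (e.g. from
#'   [replicate_scenarios()]).
#' @param dir if non-`NULL`, slide files and truth tables are written there.
#' @param antibodies antibody names, one per scenario.
#' @param loading_offsets optional numeric vector of per-sample log2
#'   loading offsets (length `n_samples`).
#' @return A list: `slides` (per-antibody [generate_slide()] results),
#'   `loading_offsets`, and `manifest` (antibody/file table linking every
#'   slide to its truth).
#' @export
generate_batch <- function(scenarios, dir = NULL, antibodies = NULL,
                           loading_offsets = NULL) {
  n <- length(scenarios)
  if (!n) stop("at least one scenario is required")
  ref <- scenarios[[1L]][.design_fields]
  same <- vapply(scenarios, function(s) identical(s[.design_fields], ref),
                 logical(1))
  if (!all(same)) {
    stop(sprintf("scenarios %s do not share the first scenario's slide design",
                 paste(which(!same), collapse = ", ")))
  }
  if (is.null(antibodies)) antibodies <- sprintf("AB%02d", seq_len(n))
  stopifnot(length(antibodies) == n)
  slides <- Map(function(sc, ab) generate_slide(sc, ab, dir = dir,
                                                x_offset = loading_offsets),
                scenarios, antibodies)
  names(slides) <- antibodies
  list(slides = slides, loading_offsets = loading_offsets,
       manifest = data.frame(antibody = antibodies,
                             file = vapply(slides, `[[`, "", "path"),
                             stringsAsFactors = FALSE))
}
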