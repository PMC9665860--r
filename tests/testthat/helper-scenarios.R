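# small, fast slide used by most module tests: 2x8 main grid of 4x4
# sub-grids (256 positions), 24 sample series + 8 replicate series at 4
# two-fold dilution steps
small_scenario <- function(seed, n_samples = 24L, n_replicates = 8L, ...) {
  sim_scenario(n_main_rows = 2L, n_main_cols = 8L, n_sub_rows = 4L,
               n_sub_cols = 4L, n_samples = n_samples,
               n_replicates = n_replicates, seed = seed, ...)
}

fit_generated <- function(g, exclude = character(), options = fit_options()) {
  design <- infer_design(g$slide)
  suppressWarnings(
    fit_supercurve(dilution_series(g$slide, design, exclude = exclude,
                                   options = options),
                   options = options))
}

# align estimates with a truth table by series id
align_truth <- function(estimates, truth_series, spot_type = "Sample") {
  tr <- truth_series[truth_series$spot_type %in% spot_type, , drop = FALSE]
  est <- estimates[match(tr$series_id, estimates$series_id), , drop = FALSE]
  cbind(tr, xhat = est$x, se = est$se_x)
}

# an 8-row, 2-series hand fixture in the input dialect
write_tiny_fixture <- function(path, dilutions = c(1, 0.5, 0.25, 0.125),
                               drop_column = NULL, net = NULL) {
  n <- 2L * length(dilutions)
  df <- data.frame(
    Order = seq_len(n),
    Main.Row = 1L, Main.Col = 1L,
    Sub.Row = rep(1:2, each = length(dilutions)),
    Sub.Col = rep(seq_along(dilutions), 2L),
    Series.Id = rep(c("S001", "S002"), each = length(dilutions)),
    Spot.Type = "Sample",
    Dilution = rep(dilutions, 2L),
    Net.Value = if (is.null(net)) seq(1000, by = -100, length.out = n) else net,
    Raw.Value = NA_real_, Background.Value = NA_real_)
  df$Raw.Value <- df$Net.Value + 50
  df$Background.Value <- 50
  if (!is.null(drop_column)) df[[drop_column]] <- NULL
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, path)
  invisible(df)
}
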