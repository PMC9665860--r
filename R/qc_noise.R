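#' Per-slide noise metric from technical replicates
#'
#' Technical replicates are repeated dilution series of one sample that
#' expresses the protein of interest; any variation among their estimated
#' concentrations cannot be biological and is therefore measurement error.
#' The noise metric is the sample standard deviation (n - 1 denominator) of
#' the replicate series' relative log2 concentration estimates; the
#' replicate mean expression is reported alongside. Both are on the
#' log2-concentration scale, the same scale as the sample output, so a
#' slide's noise can be read directly against its dynamic range. A high
#' value relative to prior slides indicates a poor-quality slide; no
#' automatic rejection threshold is applied.
#'
#' Replicate series flagged `Saturated` or `BelowDetection` carry no
#' concentration information and are excluded with a warning.
#'
#' @param estimates the `estimates` table of an [fit_supercurve()] result
#'   (or any data frame with `series_id`, `spot_type`, `x`, `flags`).
#' @param antibody antibody (slide) name recorded in the report.
#' @return A one-row data frame (`antibody_name`, `n_replicates`,
#'   `noise_sd`, `replicate_mean`, `scale = "log2-concentration"`), with
#'   `noise_sd = NA` and a warning when fewer than 2 usable replicates
#'   exist, or `NULL` (with a warning) when the slide has no replicate
#'   series at all.
#' @export
compute_noise <- function(estimates, antibody = NA_character_) {
  reps <- estimates[estimates$spot_type == "NoiseRep", , drop = FALSE]
  if (!nrow(reps)) {
    rppa_warning(sprintf(
      "slide '%s': no technical-replicate series; noise metric not computed",
      antibody), slide = antibody, stage = "noise")
    return(NULL)
  }
  flagged <- grepl("Saturated|BelowDetection", reps$flags)
  if (any(flagged)) {
    rppa_warning(sprintf(
      "slide '%s': %d flagged replicate series excluded from noise metric",
      antibody, sum(flagged)), slide = antibody, stage = "noise")
  }
  xs <- reps$x[!flagged]
  n <- length(xs)
  if (n < 2L) {
    rppa_warning(sprintf(
      "slide '%s': fewer than 2 usable replicate series; noise_sd undefined",
      antibody), slide = antibody, stage = "noise")
    sdv <- NA_real_
  } else {
    sdv <- stats::sd(xs)
  }
  data.frame(antibody_name = antibody, n_replicates = n, noise_sd = sdv,
             replicate_mean = if (n) mean(xs) else NA_real_,
             scale = "log2-concentration", stringsAsFactors = FALSE)
}

#' Correlation of noise with replicate expression level across slides
#'
#' Descriptive check that the noise metric does not track the expression
#' level of the replicates: the Pearson correlation between `noise_sd` and
#' `replicate_mean` across slides. A low correlation supports using one
#' per-slide noise value for all samples regardless of their expression.
#' No threshold is applied.
#'
#' @param reports a data frame of per-slide noise reports (rows from
#'   [compute_noise()]).
#' @return A list with `r` (Pearson correlation, `NA` with a warning when
#'   fewer than 3 valid slides or when either quantity has zero variance)
#'   and `n` (number of slides used).
#' @export
noise_expression_independence <- function(reports) {
  ok <- is.finite(reports$noise_sd) & is.finite(reports$replicate_mean)
  x <- reports$noise_sd[ok]
  y <- reports$replicate_mean[ok]
  n <- length(x)
  if (n < 3L) {
    rppa_warning(sprintf(
      "only %d slide(s) with a valid noise report; correlation not computed", n),
      stage = "noise")
    return(list(r = NA_real_, n = n))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rppa_warning("zero variance in noise or replicate mean across slides; correlation undefined",
                 stage = "noise")
    return(list(r = NA_real_, n = n))
  }
  list(r = stats::cor(x, y), n = n)
}
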