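# physical coordinates: the main x sub grid flattened to scanner-like rows
# and columns (always available, independent of any scanner X/Y fields)
.phys_coords <- function(rec, n_sub_rows, n_sub_cols) {
  list(r = (rec$main_row - 1L) * n_sub_rows + rec$sub_row,
       c = (rec$main_col - 1L) * n_sub_cols + rec$sub_col)
}

.identity_surface <- function(design, span, n_controls = 0L,
                              rmse = NA_real_, clamp = c(0.25, 4)) {
  R <- design$n_main_rows * design$n_sub_rows
  C <- design$n_main_cols * design$n_sub_cols
  structure(list(m = matrix(1, R, C), span = span,
                 n_controls_used = n_controls,
                 control_rmse_before = rmse, control_rmse_after = rmse,
                 clamp = clamp,
                 n_sub_rows = design$n_sub_rows, n_sub_cols = design$n_sub_cols),
            class = "rppa_surface")
}

# log2 deviation of each control spot from the trimmed mean of all
# same-replicate observations (replicate series share one true
# concentration, so spots at the same dilution step are exchangeable)
.control_deviations <- function(y, group, trim) {
  tm <- tapply(y, group, mean, trim = trim)
  log2(y) - log2(as.numeric(tm[as.character(group)]))
}

#' Estimate the spatial bias surface from technical-replicate spots
#'
#' Print and staining artifacts produce smooth position-dependent intensity
#' bias across a slide. Technical-replicate control spots, scattered over
#' the grid and all printing the same sample, expose that bias: each
#' control's log2 deviation from the trimmed mean of its replicate group
#' (same dilution step across all replicate series) is smoothed over the
#' physical grid by local linear regression with tricube distance weights
#' (degree-1 loess), giving a multiplicative correction `m(r, c)` at every
#' grid node. The surface is clamped to `clamp` and median-centered so a
#' global intensity shift (not a spatial effect) is never removed.
#'
#' @param slide an `rppa_slide`.
#' @param design the batch `rppa_design` (supplies grid dimensions).
#' @param span loess span in (0, 1]; larger is smoother.
#' @param min_controls minimum number of usable control spots; with fewer,
#'   a warning is issued and the identity surface returned.
#' @param clamp lower/upper bounds on the multiplicative correction.
#' @param trim trim fraction of the per-group trimmed mean.
#' @param control_types spot types providing control spots.
#' @return An object of class `rppa_surface`: the correction matrix `m`
#'   (physical rows x columns, median 1), `span`, `n_controls_used`, and
#'   the control-spot RMSE (log2 scale) before and after applying the
#'   correction to the controls themselves. A warning is attached when the
#'   controls cover less than a quarter of the grid area.
#' @export
fit_spatial_surface <- function(slide, design, span = 0.75,
                                min_controls = 10L, clamp = c(0.25, 4),
                                trim = 0.1, control_types = "NoiseRep") {
  rec <- slide$records
  is_ctrl <- rec$spot_type %in% control_types
  usable <- is_ctrl & is.finite(rec$net) & rec$net > 0
  if (any(is_ctrl & !usable)) {
    rppa_warning(sprintf(
      "slide '%s': %d control spot(s) with non-positive or missing intensity dropped from spatial fit",
      slide$antibody, sum(is_ctrl & !usable)),
      slide = slide$antibody, stage = "spatial")
  }
  ctrl <- rec[usable, , drop = FALSE]
  if (nrow(ctrl) < min_controls) {
    rppa_warning(sprintf(
      "slide '%s': only %d usable control spot(s) (minimum %d); no spatial adjustment applied",
      slide$antibody, nrow(ctrl), min_controls),
      slide = slide$antibody, stage = "spatial")
    return(.identity_surface(design, span, nrow(ctrl), clamp = clamp))
  }

  grp <- factor(ctrl$dilution_step)
  delta <- .control_deviations(ctrl$net, grp, trim)
  pp <- .phys_coords(ctrl, design$n_sub_rows, design$n_sub_cols)
  R <- design$n_main_rows * design$n_sub_rows
  C <- design$n_main_cols * design$n_sub_cols

  if ((diff(range(pp$r)) + 1) * (diff(range(pp$c)) + 1) < 0.25 * R * C) {
    rppa_warning(sprintf(
      "slide '%s': control spots cover less than 25%% of the grid area; spatial surface is extrapolated",
      slide$antibody), slide = slide$antibody, stage = "spatial")
  }

  df <- data.frame(delta = delta, pr = pp$r, pc = pp$c)
  lf <- stats::loess(delta ~ pr + pc, data = df, span = span, degree = 1,
                     family = "gaussian", normalize = FALSE,
                     control = stats::loess.control(surface = "direct"))
  grid <- expand.grid(pr = seq_len(R), pc = seq_len(C))
  sm <- stats::predict(lf, newdata = grid)
  m <- matrix(2^sm, R, C)            # expand.grid varies pr fastest
  m <- pmin(pmax(m, clamp[1L]), clamp[2L])
  m <- m / stats::median(m)

  adj <- ctrl$net / m[cbind(pp$r, pp$c)]
  delta_after <- .control_deviations(adj, grp, trim)
  structure(list(m = m, span = span, n_controls_used = nrow(ctrl),
                 control_rmse_before = sqrt(mean(delta^2)),
                 control_rmse_after = sqrt(mean(delta_after^2)),
                 clamp = clamp,
                 n_sub_rows = design$n_sub_rows, n_sub_cols = design$n_sub_cols),
            class = "rppa_surface")
}

#' @export
print.rppa_surface <- function(x, ...) {
  cat(sprintf(
    "Spatial correction surface %dx%d (span %.3g, %d controls)\n  m range [%.4g, %.4g]; control RMSE %.4g -> %.4g (log2)\n",
    nrow(x$m), ncol(x$m), x$span, x$n_controls_used,
    min(x$m), max(x$m), x$control_rmse_before, x$control_rmse_after))
  invisible(x)
}

#' Apply a spatial correction surface to a slide
#'
#' Divides every spot's net intensity by the multiplicative correction at
#' its physical grid position. Raw and background intensities are left
#' untouched; the adjustment is recorded in the slide's provenance. The
#' identity surface is a byte-for-byte no-op on the intensities.
#'
#' @param slide an `rppa_slide`.
#' @param surface an `rppa_surface` fitted on the same grid.
#' @return The adjusted `rppa_slide`.
#' @export
apply_spatial_adjustment <- function(slide, surface) {
  stopifnot(inherits(surface, "rppa_surface"))
  pp <- .phys_coords(slide$records, surface$n_sub_rows, surface$n_sub_cols)
  if (max(pp$r) > nrow(surface$m) || max(pp$c) > ncol(surface$m)) {
    rppa_error(sprintf("slide '%s': surface grid %dx%d does not cover slide",
                       slide$antibody, nrow(surface$m), ncol(surface$m)),
               slide = slide$antibody, stage = "spatial")
  }
  slide$records$net <- slide$records$net / surface$m[cbind(pp$r, pp$c)]
  slide$adjustments <- c(slide$adjustments, "spatial")
  slide
}
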