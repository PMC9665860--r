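#' Curve fitting options
#'
#' @param max_iterations maximum number of alternating-optimization
#'   iterations (curve update given concentrations, then concentration
#'   update given the curve).
#' @param rss_tolerance relative decrease of the residual sum of squares
#'   below which the alternation is declared converged.
#' @param x_bounds bounds (log2 units) for every series' relative
#'   concentration during 1-D updates and post-hoc projection.
#' @param clamp_fractions fractions of the dynamic range `beta` defining the
#'   below-detection and saturation clamps; a series whose intensities all
#'   sit outside `(alpha + beta*clamp[1], alpha + beta*clamp[2])` cannot be
#'   placed on the curve and is flagged.
#' @param min_series minimum number of non-excluded dilution series required
#'   to fit the shared curve (the 3 curve parameters plus one position per
#'   series need support).
#' @param min_signal minimum intensity range (fluorescence units) below
#'   which a slide is declared to carry no signal.
#' @param fit_spot_types spot types whose series participate in curve
#'   fitting. Positive controls and noise replicates are genuine dilution
#'   series and are included by default; negative controls, buffer and
#'   blank spots are not.
#' @param polish run a final joint Levenberg-Marquardt refinement over the
#'   curve parameters and all series positions, started from the
#'   alternating-optimization solution. Guarantees convergence to the joint
#'   least-squares optimum; disable to inspect the raw alternation.
#' @return A list of options for [fit_supercurve()].
#' @export
fit_options <- function(max_iterations = 100L, rss_tolerance = 1e-8,
                        x_bounds = c(-15, 15), clamp_fractions = c(0.01, 0.99),
                        min_series = 8L, min_signal = 1e-3,
                        fit_spot_types = c("Sample", "PosCtrl", "NoiseRep"),
                        polish = TRUE) {
  stopifnot(max_iterations >= 1L, rss_tolerance > 0,
            length(x_bounds) == 2L, x_bounds[1L] < x_bounds[2L],
            length(clamp_fractions) == 2L,
            clamp_fractions[1L] > 0, clamp_fractions[2L] < 1,
            clamp_fractions[1L] < clamp_fractions[2L],
            min_series >= 1L, min_signal >= 0)
  list(max_iterations = as.integer(max_iterations),
       rss_tolerance = rss_tolerance, x_bounds = x_bounds,
       clamp_fractions = clamp_fractions, min_series = as.integer(min_series),
       min_signal = min_signal, fit_spot_types = fit_spot_types,
       polish = isTRUE(polish))
}

#' Logistic intensity response
#'
#' Predicted spot intensity at relative log2 concentration `x`:
#' `alpha + beta / (1 + exp(-gamma * x))`. The curve is strictly
#' increasing, bounded in `(alpha, alpha + beta)`, with its midpoint
#' `alpha + beta/2` pinned at `x = 0` — the anchor that makes the series
#' positions identifiable in the joint fit.
#'
#' @param x relative log2 concentration (vectorized).
#' @param fit a fitted curve ([fit_supercurve()]) or any list with elements
#'   `alpha`, `beta`, `gamma`.
#' @return Predicted intensities, same length as `x`.
#' @export
response <- function(x, fit) {
  fit$alpha + fit$beta * stats::plogis(fit$gamma * x)
}

#' Extract dilution series for curve fitting
#'
#' Converts a slide into the long-form table the curve fitter consumes: one
#' row per spot of every dilution series eligible for fitting, with the
#' effective log2 dilution offset `d` (0 for the most concentrated step,
#' `-log2(f)` per further step, taken from the declared dilutions) and the
#' net intensity `y`. Series named in `exclude` are marked excluded from
#' curve construction; they are still normalized post hoc against the
#' fitted curve.
#'
#' @param slide an `rppa_slide`.
#' @param design the batch `rppa_design`.
#' @param exclude character vector of series IDs excluded from curve
#'   fitting (applied identically to every slide of a batch).
#' @param options a [fit_options()] list; determines which spot types
#'   contribute series.
#' @return Data frame with columns `series_id`, `spot_type`, `step`, `d`,
#'   `y`, `excluded`, in first-occurrence order of the series.
#' @export
dilution_series <- function(slide, design, exclude = character(),
                            options = fit_options()) {
  rec <- slide$records
  keep <- rec$spot_type %in% options$fit_spot_types
  rec <- rec[keep, , drop = FALSE]
  n_steps <- table(rec$series_id)
  rec <- rec[n_steps[rec$series_id] >= 2L, , drop = FALSE]
  d <- log2(rec$dilution)
  # anchor each series at its most concentrated step: d_1 = 0
  d <- d - stats::ave(d, rec$series_id, FUN = max)
  out <- data.frame(series_id = rec$series_id, spot_type = rec$spot_type,
                    step = rec$dilution_step, d = d, y = rec$net,
                    excluded = rec$series_id %in% exclude,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# derivative of the response wrt x at x (vectorized)
.response_slope <- function(x, fit) {
  p <- stats::plogis(fit$gamma * x)
  fit$beta * fit$gamma * p * (1 - p)
}

# curvature-based standard error of a series position
.x_se <- function(xhat, d, fit) {
  g <- .response_slope(xhat + d, fit)
  ss <- sum(g^2)
  if (ss <= 0) Inf else sqrt(fit$sigma2 / ss)
}

# minimize the series' residual sum of squares over x by bounded 1-D search
.project_x <- function(y, d, fit, bounds) {
  stats::optimize(function(xx) sum((y - response(xx + d, fit))^2),
                  interval = bounds, tol = 1e-10)$minimum
}

#' Fit the shared response curve and all series concentrations
#'
#' Fits one logistic intensity-versus-log2-concentration curve per slide
#' jointly to all non-excluded dilution series, minimizing
#' `sum_ij (y_ij - response(x_i + d_j))^2` over the curve parameters
#' `(alpha, beta, gamma)` and every series position `x_i`. A handful of
#' outlier spots barely moves the shared curve, but users may exclude
#' known-bad series entirely; excluded series are normalized post hoc
#' against the frozen curve ([estimate_excluded()]).
#'
#' The optimization alternates (a) nonlinear least squares on the three
#' curve parameters given the positions with (b) independent bounded 1-D
#' minimization of each position given the curve, until the relative
#' decrease in RSS falls below `rss_tolerance` or `max_iterations` is
#' reached, and by default finishes with a joint Levenberg-Marquardt
#' refinement over all parameters (analytic Jacobian). Initialization is
#' deterministic and scale-aware: `alpha` and `alpha + beta` start at the
#' 5th and 95th intensity percentiles, `gamma` at 1, and each position at
#' the inverse logistic of its series' clamped mean intensity. Least
#' squares is unweighted; negative net intensities are retained.
#'
#' @param series long-form series table from [dilution_series()].
#' @param options a [fit_options()] list.
#' @return An object of class `rppa_supercurve`: a list with
#'   \describe{
#'     \item{fit}{class `rppa_fit`: `alpha`, `beta`, `gamma`, `rss`, `r2`,
#'       `n_series_used`, `n_spots_used`, `converged`, `n_iterations`,
#'       `sigma2` (residual variance used for standard errors).}
#'     \item{estimates}{one row per input series (fitted and excluded):
#'       `series_id`, `spot_type`, `x`, `se_x`, `in_fit`, `flags`
#'       (`Saturated`, `BelowDetection`, `PoorFit`, semicolon-joined),
#'       `max_abs_residual`.}
#'     \item{residuals}{per-spot table: `series_id`, `step`, `d`,
#'       `observed`, `fitted`, `residual`.}
#'   }
#'   Non-convergence is reported via `converged = FALSE`, `PoorFit` flags
#'   and a warning; estimates are still returned. Degenerate flat data
#'   (intensity range at most `min_signal`) raises a "no signal"
#'   slide-level error.
#' @export
fit_supercurve <- function(series, options = fit_options()) {
  stopifnot(is.data.frame(series),
            all(c("series_id", "d", "y") %in% names(series)))
  if (is.null(series$excluded)) series$excluded <- FALSE
  if (is.null(series$spot_type)) series$spot_type <- "Sample"

  fit_df <- series[!series$excluded, , drop = FALSE]
  ids <- unique(fit_df$series_id)
  n_series <- length(ids)
  if (n_series < options$min_series) {
    rppa_error(sprintf(
      "only %d non-excluded series available for curve fitting (minimum %d)",
      n_series, options$min_series), stage = "curve_fit")
  }
  per <- table(fit_df$series_id)
  if (any(per < 2L)) {
    rppa_error(sprintf("series with fewer than 2 dilution steps: %s",
                       paste(names(per)[per < 2L], collapse = ", ")),
               stage = "curve_fit")
  }
  y <- fit_df$y
  d <- fit_df$d
  if (!all(is.finite(y)) || !all(is.finite(d))) {
    rppa_error("non-finite intensities or dilution offsets in fitting data",
               stage = "curve_fit")
  }
  if (diff(range(y)) <= options$min_signal) {
    rppa_error(sprintf(
      "no signal: intensity range %.3g is at or below the minimum %.3g",
      diff(range(y)), options$min_signal), stage = "curve_fit")
  }

  si <- match(fit_df$series_id, ids)
  idx_by_series <- split(seq_along(si), si)
  tss <- sum((y - mean(y))^2)

  # deterministic, scale-aware initialization
  a <- unname(stats::quantile(y, 0.05))
  top <- unname(stats::quantile(y, 0.95))
  b <- max(top - a, options$min_signal, .Machine$double.eps)
  g <- 1
  ybar <- unname(vapply(idx_by_series, function(ix) mean(y[ix]), numeric(1)))
  p0 <- pmin(pmax((ybar - a) / b, 0.01), 0.99)
  x <- stats::qlogis(p0) / g
  par_init <- c(a, b, g, x)

  rss_of <- function(a, b, g, x) sum((y - (a + b * stats::plogis(g * (x[si] + d))))^2)
  rss <- rss_of(a, b, g, x)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(options$max_iterations)) {
    lm <- minpack.lm::nls.lm(
      par = c(a, b, g),
      fn = function(p) y - (p[1L] + p[2L] * stats::plogis(p[3L] * (x[si] + d))),
      lower = c(-Inf, 1e-8, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 100))
    a <- lm$par[1L]; b <- lm$par[2L]; g <- lm$par[3L]
    fit_now <- list(alpha = a, beta = b, gamma = g)
    for (i in seq_len(n_series)) {
      ix <- idx_by_series[[i]]
      x[i] <- .project_x(y[ix], d[ix], fit_now, options$x_bounds)
    }
    new_rss <- rss_of(a, b, g, x)
    # converged: relative RSS decrease below tolerance, or RSS negligible
    # against the total sum of squares (noise-free data decays geometrically
    # and would otherwise never satisfy a relative criterion)
    if (rss - new_rss <= options$rss_tolerance * max(rss, .Machine$double.eps) ||
        new_rss <= 1e-14 * tss) {
      rss <- min(rss, new_rss)
      converged <- TRUE
      break
    }
    rss <- new_rss
  }

  if (options$polish) {
    n <- length(y)
    resid_fn <- function(p) {
      y - (p[1L] + p[2L] * stats::plogis(p[3L] * (p[3L + si] + d)))
    }
    jac_fn <- function(p) {
      xx <- p[3L + si] + d
      pr <- stats::plogis(p[3L] * xx)
      J <- matrix(0, n, 3L + n_series)
      J[, 1L] <- -1
      J[, 2L] <- -pr
      core <- p[2L] * pr * (1 - pr)
      J[, 3L] <- -core * xx
      J[cbind(seq_len(n), 3L + si)] <- -core * p[3L]
      J
    }
    refine <- function(par) {
      minpack.lm::nls.lm(
        par = par, fn = resid_fn, jac = jac_fn,
        lower = c(-Inf, 1e-8, 1e-8, rep(options$x_bounds[1L], n_series)),
        upper = c(Inf, Inf, Inf, rep(options$x_bounds[2L], n_series)),
        control = minpack.lm::nls.lm.control(
          maxiter = 400, ftol = 1e-15, ptol = 1e-15, gtol = 0))
    }
    # refine from the alternating solution and, as a guard against the
    # degenerate near-linear basin (gamma -> 0 with huge beta) the
    # alternation can occasionally wander into, also from the deterministic
    # initialization; keep the better optimum
    pl <- refine(c(a, b, g, x))
    pl2 <- refine(par_init)
    if (is.finite(pl2$deviance) &&
        (!is.finite(pl$deviance) || pl2$deviance < pl$deviance)) {
      pl <- pl2
    }
    if (is.finite(pl$deviance) && pl$deviance <= rss) {
      a <- pl$par[1L]; b <- pl$par[2L]; g <- pl$par[3L]
      x <- pl$par[3L + seq_len(n_series)]
      rss <- pl$deviance
      converged <- converged || pl$info %in% 1:4
    }
  }
  if (!converged) {
    rppa_warning(sprintf(
      "curve fit did not converge after %d iterations (relative RSS tolerance %g); estimates flagged PoorFit",
      iter, options$rss_tolerance), stage = "curve_fit")
  }

  n_par <- 3L + n_series
  sigma2 <- rss / max(1L, length(y) - n_par)
  fit <- structure(list(
    alpha = a, beta = b, gamma = g, rss = rss,
    r2 = min(1, max(0, 1 - rss / tss)),
    n_series_used = n_series, n_spots_used = length(y),
    converged = converged, n_iterations = iter, sigma2 = sigma2
  ), class = "rppa_fit")

  all_ids <- unique(series$series_id)
  est <- vector("list", length(all_ids))
  resids <- vector("list", length(all_ids))
  lo <- a + b * options$clamp_fractions[1L]
  hi <- a + b * options$clamp_fractions[2L]
  for (k in seq_along(all_ids)) {
    rows <- series[series$series_id == all_ids[k], , drop = FALSE]
    if (rows$excluded[1L]) {
      e <- estimate_excluded(rows, fit, options)
    } else {
      xi <- x[match(all_ids[k], ids)]
      flags <- character(0)
      if (all(rows$y >= hi)) flags <- c(flags, "Saturated")
      if (all(rows$y <= lo)) flags <- c(flags, "BelowDetection")
      if (!converged) flags <- c(flags, "PoorFit")
      e <- data.frame(series_id = all_ids[k], spot_type = rows$spot_type[1L],
                      x = xi, se_x = .x_se(xi, rows$d, fit), in_fit = TRUE,
                      flags = paste(flags, collapse = ";"),
                      stringsAsFactors = FALSE)
    }
    fitted <- response(e$x + rows$d, fit)
    r <- rows$y - fitted
    e$max_abs_residual <- max(abs(r))
    est[[k]] <- e
    resids[[k]] <- data.frame(series_id = all_ids[k], step = rows$step,
                              d = rows$d, observed = rows$y, fitted = fitted,
                              residual = r, stringsAsFactors = FALSE)
  }

  structure(list(fit = fit, estimates = do.call(rbind, est),
                 residuals = do.call(rbind, resids)),
            class = "rppa_supercurve")
}

#' @export
print.rppa_fit <- function(x, ...) {
  cat(sprintf(
    "Shared response curve: alpha=%.6g beta=%.6g gamma=%.6g\n  RSS=%.6g R2=%.6g (%d series, %d spots)%s\n",
    x$alpha, x$beta, x$gamma, x$rss, x$r2, x$n_series_used, x$n_spots_used,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
print.rppa_supercurve <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d series estimated (%d in fit, %d post hoc), %d flagged\n",
              nrow(x$estimates), sum(x$estimates$in_fit),
              sum(!x$estimates$in_fit), sum(x$estimates$flags != "")))
  invisible(x)
}

#' Normalize an excluded series against a frozen curve
#'
#' Places a series that did not participate in curve construction onto the
#' already-fitted curve: its relative log2 concentration is the bounded 1-D
#' minimizer of the series' residual sum of squares against the frozen
#' curve. Series whose intensities all sit at the saturation (or
#' below-detection) clamp cannot be placed and get the upper (lower) bound
#' with a `Saturated` (`BelowDetection`) flag.
#'
#' @param series rows of one series as produced by [dilution_series()]
#'   (columns `d`, `y`, optionally `series_id`, `spot_type`).
#' @param fit the slide's fitted curve (`rppa_fit` or the `fit` element of
#'   an `rppa_supercurve`).
#' @param options a [fit_options()] list.
#' @return One-row data frame: `series_id`, `spot_type`, `x`, `se_x`,
#'   `in_fit = FALSE`, `flags`.
#' @export
estimate_excluded <- function(series, fit, options = fit_options()) {
  if (inherits(fit, "rppa_supercurve")) fit <- fit$fit
  y <- series$y
  d <- series$d
  lo <- fit$alpha + fit$beta * options$clamp_fractions[1L]
  hi <- fit$alpha + fit$beta * options$clamp_fractions[2L]
  flags <- character(0)
  if (all(y >= hi)) {
    xi <- options$x_bounds[2L]
    flags <- "Saturated"
  } else if (all(y <= lo)) {
    xi <- options$x_bounds[1L]
    flags <- "BelowDetection"
  } else {
    xi <- .project_x(y, d, fit, options$x_bounds)
  }
  if (!isTRUE(fit$converged)) flags <- c(flags, "PoorFit")
  data.frame(
    series_id = if (!is.null(series$series_id)) series$series_id[1L] else NA_character_,
    spot_type = if (!is.null(series$spot_type)) series$spot_type[1L] else NA_character_,
    x = xi, se_x = .x_se(xi, d, fit), in_fit = FALSE,
    flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Slide-level fit diagnostics
#'
#' Summarizes how well each series sits on the shared curve, ranking series
#' by their largest absolute residual relative to the curve's dynamic range
#' `beta`. The ranking is the exclusion-candidate list: the suggested
#' workflow is to run all samples, inspect the large-residual series, and
#' re-run with chosen exclusions.
#'
#' @param object an `rppa_supercurve`.
#' @param residual_threshold fraction of `beta` above which a series' max
#'   absolute residual makes it an exclusion candidate.
#' @return A list: `r2`, `ranking` (series ranked by `max_abs_residual /
#'   beta`, descending), `candidates` (the subset above the threshold),
#'   `flag_counts` (named counts of `Saturated`, `BelowDetection`,
#'   `PoorFit`).
#' @export
fit_diagnostics <- function(object, residual_threshold = 0.2) {
  stopifnot(inherits(object, "rppa_supercurve"))
  est <- object$estimates
  rel <- est$max_abs_residual / object$fit$beta
  ord <- order(rel, decreasing = TRUE)
  ranking <- data.frame(series_id = est$series_id[ord],
                        spot_type = est$spot_type[ord],
                        relative_max_residual = rel[ord],
                        stringsAsFactors = FALSE)
  flag_counts <- vapply(c("Saturated", "BelowDetection", "PoorFit"),
                        function(f) sum(grepl(f, est$flags)), integer(1))
  list(r2 = object$fit$r2, ranking = ranking,
       candidates = ranking[ranking$relative_max_residual > residual_threshold, ,
                            drop = FALSE],
       flag_counts = flag_counts)
}
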