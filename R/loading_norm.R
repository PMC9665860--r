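# Protein loading normalization of the samples x antibodies log2
# concentration matrix. Samples are rows, antibodies columns; NA cells stay
# NA and all medians ignore NAs. Three methods ship: none, median
# centering, and median-polish loading correction; the registry is
# deliberately small and extensible, and "none" exists so users can apply
# any loading correction of their own downstream.

.loading_methods <- c("none", "median_centering", "median_polish_loading")

.set_norm <- function(values, method) {
  attr(values, "normalization") <- method
  values
}

#' No loading normalization
#'
#' Returns the matrix bit-identical, tagged as unnormalized, so protein
#' loading adjustment can be done downstream by any user-chosen method.
#'
#' @param values samples x antibodies matrix of log2 concentrations.
#' @return The same matrix with attribute `normalization = "none"`.
#' @export
normalize_none <- function(values) .set_norm(values, "none")

#' Median-centering loading normalization
#'
#' Removes per-sample loading offsets by shifting each sample (row) so its
#' median across antibodies equals the grand median of all per-sample
#' medians. Medians are NA-aware; an all-NA row is passed through with a
#' warning.
#'
#' @param values samples x antibodies matrix of log2 concentrations; at
#'   least 2 antibodies.
#' @return The normalized matrix, attribute
#'   `normalization = "median_centering"`.
#' @export
normalize_median_centering <- function(values) {
  if (ncol(values) < 2L) {
    stop("median centering requires at least 2 antibodies")
  }
  rmed <- apply(values, 1L, stats::median, na.rm = TRUE)
  all_na <- !is.finite(rmed)
  if (any(all_na)) {
    rppa_warning(sprintf("%d all-NA sample row(s) passed through unchanged",
                         sum(all_na)), stage = "loading")
  }
  grand <- stats::median(rmed[!all_na])
  shift <- ifelse(all_na, 0, rmed - grand)
  .set_norm(values - shift, "median_centering")
}

#' Median-polish loading normalization
#'
#' Decomposes the matrix into sample (row) and antibody (column) effects by
#' iterative row/column median sweeps, stopping when the largest absolute
#' median swept in an iteration falls below `tol` or after `max_iter`
#' iterations (non-convergence returns the last iterate with a warning).
#' Only the sample effects -- the loading component -- are removed; antibody
#' effects are retained and the overall level is preserved, so antibodies
#' remain on their own scales.
#'
#' @param values samples x antibodies matrix of log2 concentrations; at
#'   least 2 samples and 2 antibodies.
#' @param max_iter maximum number of sweep iterations.
#' @param tol convergence tolerance on the largest swept median.
#' @return The normalized matrix, attribute
#'   `normalization = "median_polish_loading"`; the removed per-sample
#'   effects are attached as attribute `sample_effects`.
#' @export
normalize_median_polish_loading <- function(values, max_iter = 50L,
                                            tol = 1e-10) {
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("median polish requires at least 2 samples and 2 antibodies")
  }
  r <- rep(0, nrow(values))
  resid <- values
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rm_ <- apply(resid, 1L, stats::median, na.rm = TRUE)
    rm_[!is.finite(rm_)] <- 0
    resid <- resid - rm_
    r <- r + rm_
    cm <- apply(resid, 2L, stats::median, na.rm = TRUE)
    cm[!is.finite(cm)] <- 0
    resid <- sweep(resid, 2L, cm)
    if (max(abs(c(rm_, cm))) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rppa_warning(sprintf(
      "median polish did not converge in %d iterations; last iterate used",
      max_iter), stage = "loading")
  }
  effects <- r - stats::median(r)   # keep the overall level in the matrix
  out <- .set_norm(values - effects, "median_polish_loading")
  attr(out, "sample_effects") <- effects
  out
}

#' Apply the configured loading normalization
#'
#' Dispatches on the method name; both the raw and the normalized matrix
#' are written by [write_outputs()] so downstream correction remains
#' possible whichever method is chosen.
#'
#' @param values samples x antibodies matrix of log2 concentrations.
#' @param method one of `"none"`, `"median_centering"`,
#'   `"median_polish_loading"`.
#' @param ... passed to the method (e.g. `max_iter`, `tol` for median
#'   polish).
#' @return The normalized matrix with its `normalization` attribute set.
#' @export
apply_loading_normalization <- function(values, method = "none", ...) {
  method <- match.arg(method, .loading_methods)
  switch(method,
         none = normalize_none(values),
         median_centering = normalize_median_centering(values),
         median_polish_loading = normalize_median_polish_loading(values, ...))
}
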