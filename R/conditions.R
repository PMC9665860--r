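#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a slide-level error
#'
#' Slide-level errors abort processing of one slide; in batch mode they are
#' recorded in the errors file and the batch continues with the next slide.
#'
#' @param message error message; should name the offending slide, column or
#'   series so the errors file is actionable.
#' @param slide slide (antibody) name, if known.
#' @param stage processing stage at which the error occurred.
#' @keywords internal
rppa_error <- function(message, slide = NA_character_, stage = "process") {
  stop(structure(
    class = c("rppa_slide_error", "error", "condition"),
    list(message = message, call = NULL, slide = slide, stage = stage)
  ))
}

#' Signal a processing warning
#'
#' Warnings never abort a slide; in batch mode they are collected into the
#' warnings file.
#'
#' @inheritParams rppa_error
#' @keywords internal
rppa_warning <- function(message, slide = NA_character_, stage = "process") {
  warning(structure(
    class = c("rppa_warning", "warning", "condition"),
    list(message = message, call = NULL, slide = slide, stage = stage)
  ))
}

# stage attached to a condition, with a fallback for plain conditions
.cond_stage <- function(cond, default = "process") {
  st <- cond$stage
  if (is.null(st) || is.na(st)) default else st
}
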