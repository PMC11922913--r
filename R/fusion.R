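#' Multi-fusion enhancement recipe
#'
#' An ordered list of enhancement steps applied left-to-right to a mammogram:
#' local contrast enhancement (CLAHE), intensity inversion, and high-boost
#' sharpening.  The default recipe — CLAHE followed by high-boost — pairs local
#' contrast stretching with edge amplification; inversion is available as an
#' optional step for highlighting dark structure on bright backgrounds.
#'
#' @param steps list of steps built by [step_clahe()], [step_invert()],
#'   [step_high_boost()], or a character vector of step names
#'   (`"clahe"`, `"invert"`, `"highboost"`) using each step's defaults.
#'   An empty list is the identity pipeline.
#' @return an object of class `fusion_config`.
#' @examples
#' cfg <- fusion_config(list(step_clahe(), step_high_boost(A = 1.5)))
#' @export
fusion_config <- function(steps = list(step_clahe(), step_high_boost())) {
  if (is.character(steps)) {
    steps <- lapply(steps, function(s) {
      switch(tolower(gsub("[-_]", "", s)),
             clahe = step_clahe(),
             invert = step_invert(),
             highboost = step_high_boost(),
             stopf("unknown fusion step: %s", s))
    })
  }
  if (!is.list(steps)) stopf("`steps` must be a list of fusion steps")
  ok <- vapply(steps, inherits, logical(1), what = "fusion_step")
  if (length(steps) && !all(ok)) stopf("all steps must be fusion_step objects")
  structure(list(steps = steps), class = "fusion_config")
}

#' @rdname fusion_config
#' @param cfg a [clahe_config()] for the CLAHE step.
#' @export
step_clahe <- function(cfg = clahe_config()) {
  structure(list(kind = "clahe", cfg = cfg), class = "fusion_step")
}

#' @rdname fusion_config
#' @export
step_invert <- function() structure(list(kind = "invert"), class = "fusion_step")

#' @rdname fusion_config
#' @param A amplification factor of the high-boost step (> 0).
#' @param sigma Gaussian blur width of the high-boost step (> 0).
#' @export
step_high_boost <- function(A = 1.5, sigma = 1) {
  if (A <= 0 || sigma <= 0) stopf("high-boost requires A > 0 and sigma > 0")
  structure(list(kind = "high_boost", A = A, sigma = sigma), class = "fusion_step")
}

#' @export
print.fusion_config <- function(x, ...) {
  if (!length(x$steps)) {
    cat("<fusion_config: identity>\n")
  } else {
    cat("<fusion_config:",
        paste(vapply(x$steps, `[[`, character(1), "kind"), collapse = " -> "),
        ">\n")
  }
  invisible(x)
}

#' Apply a multi-fusion enhancement recipe
#'
#' Runs each configured step in order on the input image.  An empty recipe
#' returns the input unchanged.
#'
#' @param img a [gray_image()] or intensity matrix.
#' @param cfg a [fusion_config()].
#' @return the enhanced [gray_image()].
#' @export
apply_fusion <- function(img, cfg = fusion_config()) {
  if (!inherits(cfg, "fusion_config")) stopf("`cfg` must be a fusion_config")
  img <- as_gray_image(img)
  for (s in cfg$steps) {
    img <- switch(s$kind,
                  clahe = clahe(img, s$cfg),
                  invert = invert(img),
                  high_boost = high_boost(img, A = s$A, sigma = s$sigma),
                  stopf("unknown fusion step kind: %s", s$kind))
  }
  img
}
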