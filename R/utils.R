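`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg, class = "agrisurvey_invalid_input") {
  stop(structure(class = c(class, "agrisurvey_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    abort_input(sprintf("%s must be finite numeric", what))
  invisible(x)
}
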