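#' @keywords internal
#' Structured error helper. Every user-facing failure in the package signals a
#' condition inheriting from "clinlang_error" plus a specific subclass so
#' callers (and the test suite) can branch on the failure kind rather than on
#' message text.
cl_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
    class = c(class, "clinlang_error", "error", "condition"),
    call = call
  ))
}

cl_empty_input <- function(what = "input text") {
  cl_abort(sprintf("empty %s: content is empty or whitespace-only", what),
    "cl_empty_input")
}

cl_unsupported_language <- function(language) {
  cl_abort(sprintf("unsupported language '%s'", language),
    "cl_unsupported_language")
}

cl_missing_resource <- function(what) {
  cl_abort(sprintf("missing resource: %s", what), "cl_missing_resource")
}

cl_missing_annotation <- function(what) {
  cl_abort(sprintf("missing annotation: %s", what), "cl_missing_annotation")
}
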