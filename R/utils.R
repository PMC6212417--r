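#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## user-facing errors carry a condition class so the CLI can map them to exit 1
miract_error <- function(msg, class = "miract_user_error", call. = FALSE) {
  stop(structure(
    class = c(class, "miract_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) miract_error(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_proportion <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

## numbers written with enough digits that fixtures round-trip (>= 12 s.f.)
format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         character(1))
}

suffix_min <- function(v) rev(cummin(rev(v)))
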