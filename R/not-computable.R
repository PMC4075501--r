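#' The NOT_COMPUTABLE sentinel
#'
#' Derived data elements are computed on read. When a computation cannot
#' proceed — an input is missing from the patient's record, a division by
#' zero, a non-numeric operand — the result is this in-band sentinel rather
#' than an error, so a partially filled record still renders as a whole.
#'
#' @param reason Short diagnostic explaining why the value could not be
#'   computed.
#' @return An object of class `regkit_not_computable` carrying `reason`.
#' @examples
#' nc <- not_computable("missing input 'Weight'")
#' is_not_computable(nc)
#' @export
not_computable <- function(reason = "value cannot be computed") {
  structure(list(reason = reason), class = "regkit_not_computable")
}

#' @rdname not_computable
#' @param x Object to test.
#' @export
is_not_computable <- function(x) inherits(x, "regkit_not_computable")

#' @export
format.regkit_not_computable <- function(x, ...) {
  sprintf("NOT_COMPUTABLE (%s)", x$reason)
}

#' @export
print.regkit_not_computable <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}
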