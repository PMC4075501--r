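`%||%` <- function(x, y) if (is.null(x)) y else x

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_num_scalar <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Domain errors carry a condition class so callers can branch on the kind of
# failure rather than matching message text.
regkit_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "regkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1L), ...)
  )
  stop(cond)
}

regkit_warn <- function(message, class) {
  warning(structure(
    class = c(class, "regkit_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1L))
  ))
}

assert_identifier <- function(x, what) {
  if (!is_string(x) || !nzchar(x)) {
    regkit_abort(sprintf("%s must be a non-empty string", what), "regkit_bad_identifier")
  }
  invisible(x)
}

# Record keys flatten form/section/code into one string; "/" and "%" are
# escaped so the encoding stays injective whatever the display names contain.
encode_key_component <- function(x) {
  gsub("/", "%2F", gsub("%", "%25", x, fixed = TRUE), fixed = TRUE)
}

decode_key_component <- function(x) {
  gsub("%25", "%", gsub("%2F", "/", x, fixed = TRUE), fixed = TRUE)
}

#' Encode a record key
#'
#' Patient record entries are stored flat, one key-value pair per captured
#' field. The key folds the registry form structure (form name, section name,
#' data-element code) into a single string, escaping the separator so the
#' encoding is injective.
#'
#' @param form_name,section_name,de_code Key components; all must be non-empty.
#' @return A single string, e.g. `"Clinical/Anthropometry/Height"`.
#' @export
encode_record_key <- function(form_name, section_name, de_code) {
  for (x in list(form_name, section_name, de_code)) {
    if (!is_string(x) || !nzchar(x)) {
      regkit_abort("record key components must be non-empty strings", "regkit_bad_key")
    }
  }
  paste(
    vapply(c(form_name, section_name, de_code), encode_key_component, character(1)),
    collapse = "/"
  )
}

#' Decode a record key
#'
#' @param key A string produced by [encode_record_key()].
#' @return A named list with `form_name`, `section_name` and `de_code`.
#' @export
decode_record_key <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    regkit_abort(sprintf("malformed record key: %s", key), "regkit_bad_key")
  }
  parts <- vapply(parts, decode_key_component, character(1), USE.NAMES = FALSE)
  list(form_name = parts[[1]], section_name = parts[[2]], de_code = parts[[3]])
}

compact <- function(x) x[!vapply(x, is.null, logical(1))]
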