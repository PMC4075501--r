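#' @name data-elements
#' @title Reusable data elements and permitted value groups
#'
#' @description
#' Data elements (DEs) are the unit of sharing in the registry framework: a
#' typed field definition — code, display name, one of five datatypes
#' (integer, float, string, date, file) — plus validation rules. Numeric
#' elements take inclusive `min`/`max` bounds; string elements take either a
#' full-match regular-expression `pattern` or a reference to a permitted
#' value group (PVG), a named enumeration of allowed codes. An element
#' defined once can be attached to any number of registries.
NULL

REGKIT_DATATYPES <- c("integer", "float", "string", "date", "file")

#' Define a permitted value group
#'
#' A PVG is a reusable enumeration — for example a group `Size` with
#' permissible values large, medium and small — attachable to any string
#' data element.
#'
#' @param code Unique identifier for the group.
#' @param name Display name.
#' @param values Allowed values, as a named character vector: names are the
#'   value codes, elements the human-readable labels
#'   (e.g. `c(large = "Large", medium = "Medium")`).
#' @return An object of class `regkit_pvg`.
#' @examples
#' pvg("Size", "Size", c(large = "Large", medium = "Medium", small = "Small"))
#' @export
pvg <- function(code, name = code, values = character()) {
  assert_identifier(code, "PVG code")
  if (!is_string(name)) regkit_abort("PVG name must be a string", "regkit_bad_pvg")
  if (length(values) == 0L) {
    regkit_abort(sprintf("PVG '%s' must have at least one permitted value", code),
                 "regkit_empty_pvg")
  }
  codes <- names(values)
  if (is.null(codes) || any(!nzchar(codes))) {
    regkit_abort("permitted values must be a named character vector (codes as names)",
                 "regkit_bad_pvg")
  }
  if (anyDuplicated(codes)) {
    regkit_abort(sprintf("duplicate value codes in PVG '%s': %s", code,
                         paste(unique(codes[duplicated(codes)]), collapse = ", ")),
                 "regkit_duplicate_value_code")
  }
  structure(
    list(code = code, name = name,
         values = data.frame(code = codes, label = unname(as.character(values)),
                             stringsAsFactors = FALSE)),
    class = "regkit_pvg"
  )
}

#' @export
print.regkit_pvg <- function(x, ...) {
  cat(sprintf("<PVG %s (%s): %s>\n", x$code, x$name,
              paste(x$values$code, collapse = ", ")))
  invisible(x)
}

#' Define a data element
#'
#' Constructs (and checks the invariants of) a reusable field definition.
#' Validation attributes are datatype-specific: `min`/`max` apply only to
#' integer and float elements and are inclusive; `pattern` (an anchored,
#' full-match regular expression) and `pvg_code` apply only to string
#' elements and are mutually exclusive.
#'
#' @param code Globally unique element code.
#' @param name Display name; defaults to the code.
#' @param datatype One of `"integer"`, `"float"`, `"string"`, `"date"`,
#'   `"file"`.
#' @param min,max Optional inclusive numeric bounds (numeric datatypes only).
#' @param pattern Optional regular expression the whole value must match
#'   (string datatype only).
#' @param pvg_code Optional code of a permitted value group (string datatype
#'   only).
#' @param units Optional display units (e.g. `"kg"`).
#' @param required Whether a value must be supplied; defaults to `FALSE`.
#' @return An object of class `regkit_de`.
#' @examples
#' data_element("DOB", "Date of birth", "date")
#' data_element("Height", datatype = "float", min = 0.3, max = 2.5, units = "m")
#' @export
data_element <- function(code, name = code, datatype,
                         min = NULL, max = NULL, pattern = NULL,
                         pvg_code = NULL, units = NULL, required = FALSE) {
  assert_identifier(code, "data element code")
  if (!is_string(name)) regkit_abort("element name must be a string", "regkit_bad_element")
  if (!is_string(datatype) || !datatype %in% REGKIT_DATATYPES) {
    regkit_abort(
      sprintf("unknown datatype '%s'; must be one of: %s",
              as.character(datatype)[1], paste(REGKIT_DATATYPES, collapse = ", ")),
      "regkit_unknown_datatype"
    )
  }
  numeric_dt <- datatype %in% c("integer", "float")
  if ((!is.null(min) || !is.null(max)) && !numeric_dt) {
    regkit_abort(sprintf("min/max apply only to numeric datatypes (element '%s' is %s)",
                         code, datatype), "regkit_bad_element")
  }
  if (!is.null(min) && !is_num_scalar(min)) {
    regkit_abort("min must be a single number", "regkit_bad_element")
  }
  if (!is.null(max) && !is_num_scalar(max)) {
    regkit_abort("max must be a single number", "regkit_bad_element")
  }
  if (!is.null(min) && !is.null(max) && min > max) {
    regkit_abort(sprintf("element '%s': min (%s) exceeds max (%s)", code, min, max),
                 "regkit_bad_range")
  }
  if (!is.null(pattern) || !is.null(pvg_code)) {
    if (datatype != "string") {
      regkit_abort(sprintf("pattern/pvg apply only to string datatype (element '%s' is %s)",
                           code, datatype), "regkit_bad_element")
    }
  }
  if (!is.null(pattern) && !is.null(pvg_code)) {
    regkit_abort(sprintf("element '%s': pattern and pvg_code are mutually exclusive", code),
                 "regkit_bad_element")
  }
  if (!is.null(pattern)) {
    if (!is_string(pattern)) regkit_abort("pattern must be a string", "regkit_bad_element")
    ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      regkit_abort(sprintf("element '%s': invalid regular expression: %s", code, pattern),
                   "regkit_bad_element")
    }
  }
  if (!is.null(pvg_code)) assert_identifier(pvg_code, "pvg_code")
  structure(
    list(code = code, name = name, datatype = datatype,
         min = min, max = max, pattern = pattern, pvg_code = pvg_code,
         units = units, required = isTRUE(required)),
    class = "regkit_de"
  )
}

#' Define a derived data element
#'
#' A derived data element (DDE) is a field whose value is computed from
#' other elements by an arithmetic expression — the canonical example is
#' body mass index from height and weight. DDE values are evaluated on every
#' read and never stored, so they are up to date as soon as any input
#' changes. Derived elements are restricted to numeric datatypes and carry
#' no entry-validation rules of their own.
#'
#' @param code Globally unique element code.
#' @param name Display name.
#' @param datatype `"float"` or `"integer"`. An integer DDE rounds its
#'   computed value half-to-even.
#' @param expression Calculation as expression text, e.g.
#'   `"Weight / (Height * Height)"`. See [expr_parse()] for the grammar.
#' @param units Optional display units.
#' @return An object of class `regkit_dde` (also inheriting `regkit_de`).
#' @examples
#' derived_element("BMI", "Body mass index", "float",
#'                 "Weight / (Height * Height)", units = "kg/m^2")
#' @export
derived_element <- function(code, name = code, datatype = "float", expression,
                            units = NULL) {
  assert_identifier(code, "data element code")
  if (!datatype %in% c("integer", "float")) {
    regkit_abort(sprintf("derived element '%s': datatype must be integer or float", code),
                 "regkit_bad_element")
  }
  expr <- if (inherits(expression, "regkit_expression")) expression else expr_parse(expression)
  structure(
    list(code = code, name = name, datatype = datatype,
         min = NULL, max = NULL, pattern = NULL, pvg_code = NULL,
         units = units, required = FALSE,
         inputs = expr_refs(expr), expression = expr),
    class = c("regkit_dde", "regkit_de")
  )
}

#' @rdname derived_element
#' @param de An element definition.
#' @export
is_derived <- function(de) inherits(de, "regkit_dde")

#' @export
print.regkit_de <- function(x, ...) {
  extras <- character()
  if (!is.null(x$min)) extras <- c(extras, paste0("min=", x$min))
  if (!is.null(x$max)) extras <- c(extras, paste0("max=", x$max))
  if (!is.null(x$pattern)) extras <- c(extras, paste0("pattern=", x$pattern))
  if (!is.null(x$pvg_code)) extras <- c(extras, paste0("pvg=", x$pvg_code))
  if (is_derived(x)) extras <- c(extras, paste0("= ", x$expression$source_text))
  cat(sprintf("<%s %s: %s%s>\n", if (is_derived(x)) "DDE" else "DE",
              x$code, x$datatype,
              if (length(extras)) paste0(" [", paste(extras, collapse = "; "), "]") else ""))
  invisible(x)
}

# ---- typed values ----------------------------------------------------------

typed_value <- function(de_code, value, datatype) {
  structure(list(de_code = de_code, value = value, datatype = datatype),
            class = "regkit_typed_value")
}

#' @export
print.regkit_typed_value <- function(x, ...) {
  cat(sprintf("<%s = %s (%s)>\n", x$de_code, render_value(x), x$datatype))
  invisible(x)
}

is_typed_value <- function(x) inherits(x, "regkit_typed_value")

validation_error <- function(de_code, rule, message) {
  structure(list(de_code = de_code, rule = rule, message = message),
            class = "regkit_validation_error")
}

validation_errors <- function(errors) {
  structure(errors, class = "regkit_validation_errors")
}

#' Did validation succeed?
#'
#' @param x Result of [validate_value()].
#' @return `TRUE` for a typed value or an absent (blank, non-required)
#'   result; `FALSE` for a list of validation errors.
#' @export
is_valid_result <- function(x) !inherits(x, "regkit_validation_errors")

#' @export
print.regkit_validation_errors <- function(x, ...) {
  for (e in x) cat(sprintf("[%s/%s] %s\n", e$de_code, e$rule, e$message))
  invisible(x)
}

# ---- coercion --------------------------------------------------------------

is_blank <- function(raw) {
  if (is.null(raw)) return(TRUE)
  if (length(raw) == 1L && is.na(raw) && !inherits(raw, "regkit_file_value")) return(TRUE)
  if (is_string(raw) && !nzchar(trimws(raw))) return(TRUE)
  FALSE
}

coerce_integer <- function(raw) {
  if (is_num_scalar(raw)) {
    if (is.finite(raw) && raw == trunc(raw)) return(as.numeric(raw))
    return(NULL)
  }
  if (is_string(raw) && grepl("^[+-]?[0-9]+$", trimws(raw))) {
    return(as.numeric(trimws(raw)))
  }
  NULL
}

coerce_float <- function(raw) {
  if (is_num_scalar(raw)) {
    if (is.finite(raw)) return(as.numeric(raw))
    return(NULL)
  }
  if (is_string(raw) &&
      grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", trimws(raw))) {
    return(as.numeric(trimws(raw)))
  }
  NULL
}

coerce_string <- function(raw) if (is_string(raw)) raw else NULL

# Canonical text form for dates is ISO-8601 (YYYY-MM-DD); impossible
# calendar dates (e.g. Feb 30) coerce to NA and are rejected.
coerce_date <- function(raw) {
  if (inherits(raw, "Date") && length(raw) == 1L && !is.na(raw)) return(raw)
  if (is_string(raw) && grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", trimws(raw))) {
    d <- as.Date(trimws(raw), format = "%Y-%m-%d")
    if (!is.na(d) && format(d, "%Y-%m-%d") == trimws(raw)) return(d)
  }
  NULL
}

coerce_file <- function(raw) {
  if (inherits(raw, "regkit_file_value")) raw else NULL
}

type_error_message <- function(datatype) {
  switch(datatype,
    integer = "not a whole number",
    float = "not a number",
    string = "not a text value",
    date = "not a valid ISO-8601 date (YYYY-MM-DD)",
    file = "not a stored file value"
  )
}

#' Validate and coerce a raw value against a data element
#'
#' Applies every validation rule of the element — type coercion, inclusive
#' min/max range, full-match pattern, permitted-value-group membership,
#' required — and reports *all* violated rules, not just the first.
#' Validation failures are returned as values, never raised.
#'
#' @param de A [data_element()] definition (derived elements cannot be
#'   validated for entry: their values are computed, not entered).
#' @param raw Input value: text as entered, or an already-typed scalar.
#' @param pvg The resolved [pvg()] object when `de$pvg_code` is set (the
#'   registry engine resolves this automatically).
#' @return On success, a typed value (class `regkit_typed_value`); for a
#'   blank input on a non-required element, `NULL` (meaning "store
#'   nothing"); on failure, a list of validation errors (class
#'   `regkit_validation_errors`), one per violated rule.
#' @examples
#' age <- data_element("Age", datatype = "integer", min = 0, max = 120)
#' validate_value(age, "42")
#' validate_value(age, "-3")
#' @export
validate_value <- function(de, raw, pvg = NULL) {
  stopifnot(inherits(de, "regkit_de"))
  if (is_derived(de)) {
    regkit_abort(sprintf("'%s' is a derived element; its value is computed, not entered",
                         de$code), "regkit_derived_readonly")
  }
  if (is_blank(raw)) {
    if (de$required) {
      return(validation_errors(list(
        validation_error(de$code, "required",
                         sprintf("'%s' is required but no value was given", de$code))
      )))
    }
    return(NULL)
  }

  val <- switch(de$datatype,
    integer = coerce_integer(raw),
    float   = coerce_float(raw),
    string  = coerce_string(raw),
    date    = coerce_date(raw),
    file    = coerce_file(raw)
  )
  if (is.null(val)) {
    return(validation_errors(list(
      validation_error(de$code, "type",
                       sprintf("'%s' expects %s: %s", de$code, de$datatype,
                               type_error_message(de$datatype)))
    )))
  }

  errs <- list()
  if (de$datatype %in% c("integer", "float")) {
    if (!is.null(de$min) && val < de$min) {
      errs <- c(errs, list(validation_error(
        de$code, "range", sprintf("%s is below the minimum %s", val, de$min))))
    }
    if (!is.null(de$max) && val > de$max) {
      errs <- c(errs, list(validation_error(
        de$code, "range", sprintf("%s is above the maximum %s", val, de$max))))
    }
  }
  if (!is.null(de$pattern) && !pattern_full_match(de$pattern, val)) {
    errs <- c(errs, list(validation_error(
      de$code, "pattern",
      sprintf("value does not match the required pattern %s", de$pattern))))
  }
  if (!is.null(de$pvg_code)) {
    if (is.null(pvg)) {
      regkit_abort(sprintf("element '%s' references PVG '%s' but no group was supplied",
                           de$code, de$pvg_code), "regkit_unknown_pvg")
    }
    if (!val %in% pvg$values$code) {
      errs <- c(errs, list(validation_error(
        de$code, "pvg",
        sprintf("'%s' is not a permitted value of group '%s' (%s)", val, pvg$code,
                paste(pvg$values$code, collapse = ", ")))))
    }
  }

  if (length(errs)) return(validation_errors(errs))
  typed_value(de$code, val, de$datatype)
}

# Patterns are full-match: the paper's credit-card example implies the whole
# value must conform, so the pattern is wrapped in non-capturing anchors.
pattern_full_match <- function(pattern, value) {
  grepl(paste0("^(?:", pattern, ")$"), value, perl = TRUE)
}

#' Render a typed value to its canonical text form
#'
#' The inverse of coercion: `validate_value(de, render_value(v))`
#' reproduces `v` exactly, including doubles (rendered with 17 significant
#' digits) and dates (ISO-8601).
#'
#' @param tv A typed value as returned by [validate_value()].
#' @return A single string.
#' @export
render_value <- function(tv) {
  stopifnot(is_typed_value(tv))
  switch(tv$datatype,
    integer = format(tv$value, scientific = FALSE),
    float   = sprintf("%.17g", tv$value),
    string  = tv$value,
    date    = format(tv$value, "%Y-%m-%d"),
    file    = sprintf("%s (%d bytes, sha256:%s)", tv$value$filename,
                      tv$value$size, substr(tv$value$digest, 1, 12))
  )
}
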