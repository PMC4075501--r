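#' @name registry-model
#' @title Registries as compositions of shared elements
#'
#' @description
#' A registry definition is data, not code: an ordered list of forms, each
#' holding ordered sections, each holding ordered data-element codes. The
#' codes resolve against a single shared element store, so one element
#' defined once (say a date of birth) can be attached to any number of
#' registries and edited in one place. Definition validation checks that
#' every referenced code resolves, that every derived element's inputs are
#' defined, and that the derived-element dependency graph is acyclic.
NULL

new_registry_definition <- function(code, name, version, description = NULL) {
  assert_identifier(code, "registry code")
  if (!is_string(name)) regkit_abort("registry name must be a string", "regkit_bad_registry")
  if (!is_string(version)) regkit_abort("registry version must be a string", "regkit_bad_registry")
  structure(
    list(code = code, name = name, version = version,
         description = description, forms = list()),
    class = "regkit_registry"
  )
}

#' @export
print.regkit_registry <- function(x, ...) {
  cat(sprintf("<registry %s '%s' v%s: %d form(s), %d element reference(s)>\n",
              x$code, x$name, x$version, length(x$forms),
              length(registry_section_codes(x))))
  invisible(x)
}

# append a code, creating form/section on first mention
definition_attach <- function(def, form_name, section_name, de_code) {
  assert_identifier(form_name, "form name")
  assert_identifier(section_name, "section name")
  assert_identifier(de_code, "data element code")
  fi <- match(form_name, vapply(def$forms, `[[`, character(1), "name"))
  if (is.na(fi)) {
    def$forms[[length(def$forms) + 1L]] <- list(name = form_name, sections = list())
    fi <- length(def$forms)
  }
  sections <- def$forms[[fi]]$sections
  si <- match(section_name, vapply(sections, `[[`, character(1), "name"))
  if (is.na(si)) {
    sections[[length(sections) + 1L]] <- list(name = section_name,
                                              element_codes = character())
    si <- length(sections)
  }
  if (de_code %in% sections[[si]]$element_codes) {
    regkit_abort(
      sprintf("element '%s' is already attached to section '%s' of form '%s'",
              de_code, section_name, form_name),
      "regkit_duplicate_attachment"
    )
  }
  sections[[si]]$element_codes <- c(sections[[si]]$element_codes, de_code)
  def$forms[[fi]]$sections <- sections
  def
}

# every code directly referenced by the registry's sections, layout order
registry_section_codes <- function(def) {
  unlist(lapply(def$forms, function(f) {
    unlist(lapply(f$sections, `[[`, "element_codes"), use.names = FALSE)
  }), use.names = FALSE) %||% character()
}

# layout location (form, section) of a code; first occurrence wins
registry_locate <- function(def, de_code) {
  for (f in def$forms) {
    for (s in f$sections) {
      if (de_code %in% s$element_codes) {
        return(list(form_name = f$name, section_name = s$name))
      }
    }
  }
  NULL
}

definition_error <- function(kind, message) list(kind = kind, message = message)

#' Validate a registry definition against an element store
#'
#' @param def A registry definition.
#' @param lookup Function taking a code and returning the element definition
#'   or `NULL` when undefined.
#' @return A list of findings (each with `kind` and `message`); empty when
#'   the definition is sound: all codes resolve, all derived-element inputs
#'   are defined, and the derived-element dependency graph reachable from
#'   this registry is acyclic.
#' @keywords internal
validate_definition_impl <- function(def, lookup) {
  errors <- list()
  seen <- character()
  queue <- unique(registry_section_codes(def))
  deps <- list()   # DDE code -> inputs, over the reachable closure
  while (length(queue)) {
    code <- queue[[1]]; queue <- queue[-1]
    if (code %in% seen) next
    seen <- c(seen, code)
    el <- lookup(code)
    if (is.null(el)) {
      errors <- c(errors, list(definition_error(
        "unresolved", sprintf("element '%s' is referenced but not defined", code))))
      next
    }
    if (is_derived(el)) {
      deps[[code]] <- el$inputs
      for (inp in el$inputs) {
        if (is.null(lookup(inp))) {
          errors <- c(errors, list(definition_error(
            "unresolved",
            sprintf("derived element '%s' needs input '%s', which is not defined",
                    code, inp))))
        } else {
          queue <- c(queue, inp)
        }
      }
    }
  }
  cyc <- find_cycle(deps)
  if (!is.null(cyc)) {
    errors <- c(errors, list(definition_error(
      "cycle", sprintf("derived elements form a dependency cycle: %s",
                       paste(cyc, collapse = " -> ")))))
  }
  errors
}

# depth-first search over DDE -> input edges; returns a witness cycle or NULL
find_cycle <- function(deps) {
  state <- new.env(parent = emptyenv())   # "open" while on stack, "done" after
  visit <- function(code, trail) {
    st <- if (exists(code, envir = state, inherits = FALSE)) {
      get(code, envir = state, inherits = FALSE)
    } else ""
    if (st == "done") return(NULL)
    if (st == "open") return(c(trail[which(trail == code)[1]:length(trail)], code))
    assign(code, "open", envir = state)
    for (inp in deps[[code]] %||% character()) {
      if (!is.null(deps[[inp]]) || identical(inp, code)) {
        cyc <- visit(inp, c(trail, code))
        if (!is.null(cyc)) return(cyc)
      }
    }
    assign(code, "done", envir = state)
    NULL
  }
  for (code in names(deps)) {
    cyc <- visit(code, character())
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

# transitive closure of the registry's codes through DDE inputs, sorted;
# assumes the definition already validated
catalogue_codes <- function(def, lookup) {
  seen <- character()
  queue <- unique(registry_section_codes(def))
  while (length(queue)) {
    code <- queue[[1]]; queue <- queue[-1]
    if (code %in% seen) next
    seen <- c(seen, code)
    el <- lookup(code)
    if (!is.null(el) && is_derived(el)) queue <- c(queue, el$inputs)
  }
  sort(seen)
}
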