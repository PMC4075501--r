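#' @name serialization
#' @title Canonical YAML interchange for registry definitions
#'
#' @description
#' A complete registry definition — metadata, forms and sections, every
#' data element it uses (including derived elements' transitive inputs),
#' the permitted value groups those elements reference, and the permission
#' rules scoped to the registry — exports to a single self-contained,
#' human-readable YAML file. Export is canonical: fixed top-level key
#' order (`format_version`, `registry`, `data_elements`, `pvgs`,
#' `permissions`), code-sorted lists, ISO dates, expressions as source
#' text, doubles at full precision — so identical definitions always
#' produce byte-identical files, ready for version control and sharing.
NULL

REGKIT_FORMAT_VERSION <- "1.0"

element_to_list <- function(de) {
  if (is_derived(de)) {
    compact(list(
      code = de$code, name = de$name, datatype = de$datatype,
      derived = TRUE,
      inputs = as.list(de$inputs),
      expression = de$expression$source_text,
      units = de$units
    ))
  } else {
    c(
      compact(list(
        code = de$code, name = de$name, datatype = de$datatype,
        min = if (!is.null(de$min)) as.numeric(de$min),
        max = if (!is.null(de$max)) as.numeric(de$max),
        pattern = de$pattern, pvg_code = de$pvg_code, units = de$units
      )),
      list(required = de$required)
    )
  }
}

pvg_to_list <- function(g) {
  list(code = g$code, name = g$name,
       values = lapply(seq_len(nrow(g$values)), function(i) {
         list(code = g$values$code[i], label = g$values$label[i])
       }))
}

registry_to_list <- function(def) {
  compact(list(
    code = def$code, name = def$name, version = def$version,
    description = def$description,
    forms = lapply(def$forms, function(f) {
      list(name = f$name, sections = lapply(f$sections, function(s) {
        list(name = s$name, elements = as.list(s$element_codes))
      }))
    })
  ))
}

rule_to_list <- function(r) {
  list(role = r$role, registry = r$registry, de_code = r$de_code, access = r$access)
}

sort_rules <- function(rules) {
  if (!length(rules)) return(list())
  key <- vapply(rules, function(r) paste(r$role, r$de_code, r$access, sep = "\r"),
                character(1))
  rules <- rules[!duplicated(key)]
  key <- key[!duplicated(key)]
  ord <- order(vapply(rules, `[[`, character(1), "role"),
               vapply(rules, `[[`, character(1), "de_code"),
               vapply(rules, `[[`, character(1), "access"))
  rules[ord]
}

#' Export a registry definition to canonical YAML
#'
#' @param engine A [registry_engine()].
#' @param registry_code Code of a registry that passes
#'   [validate_definition()]; export refuses to write a partial file for an
#'   invalid registry.
#' @return The YAML document as a single string. Exporting the same
#'   definition state twice yields byte-identical text.
#' @export
export_registry <- function(engine, registry_code) {
  elements <- engine$catalogue(registry_code)   # errors if invalid
  def <- engine$get_registry(registry_code)
  pvg_codes <- sort(unique(unlist(lapply(elements, `[[`, "pvg_code"))))
  rules <- Filter(function(r) r$registry == registry_code, engine$rules_table())
  doc <- list(
    format_version = REGKIT_FORMAT_VERSION,
    registry = registry_to_list(def),
    data_elements = lapply(elements, element_to_list),
    pvgs = lapply(pvg_codes, function(code) pvg_to_list(engine$get_pvg(code))),
    permissions = lapply(sort_rules(rules), rule_to_list)
  )
  yaml::as.yaml(doc, indent = 2, precision = 17)
}

# ---- import ----------------------------------------------------------------

parse_element_entry <- function(e) {
  if (isTRUE(e$derived)) {
    dde <- derived_element(e$code, e$name %||% e$code, e$datatype %||% "float",
                           e$expression, units = e$units)
    declared <- sort(unique(as.character(unlist(e$inputs))))
    if (length(declared) && !identical(declared, dde$inputs)) {
      regkit_abort(
        sprintf("derived element '%s': declared inputs (%s) do not match its expression (%s)",
                e$code, paste(declared, collapse = ", "),
                paste(dde$inputs, collapse = ", ")),
        "regkit_bad_file"
      )
    }
    dde
  } else {
    data_element(e$code, e$name %||% e$code, e$datatype,
                 min = if (!is.null(e$min)) as.numeric(e$min),
                 max = if (!is.null(e$max)) as.numeric(e$max),
                 pattern = e$pattern, pvg_code = e$pvg_code,
                 units = e$units, required = isTRUE(e$required))
  }
}

parse_pvg_entry <- function(p) {
  vals <- vapply(p$values, function(v) as.character(v$label), character(1))
  names(vals) <- vapply(p$values, function(v) as.character(v$code), character(1))
  pvg(p$code, p$name %||% p$code, vals)
}

#' Parse a registry YAML file into its components
#'
#' Performs full structural validation: known `format_version`, known
#' datatypes only, parseable derived-element expressions, and
#' self-containment (every code referenced anywhere in the file — section
#' layouts, derived-element inputs, PVG references — must be defined in
#' the file).
#'
#' @param text Registry file content as a string.
#' @return A list with components `registry` (definition), `elements`,
#'   `pvgs` and `rules`.
#' @export
parse_registry_file <- function(text) {
  y <- tryCatch(yaml::yaml.load(text), error = function(e) {
    regkit_abort(sprintf("not parseable as YAML: %s", conditionMessage(e)),
                 "regkit_bad_file")
  })
  if (!is.list(y) || is.null(y$format_version)) {
    regkit_abort("registry file lacks a format_version", "regkit_unknown_format")
  }
  if (!identical(as.character(y$format_version), REGKIT_FORMAT_VERSION)) {
    regkit_abort(sprintf("unknown format_version '%s' (this build reads %s)",
                         y$format_version, REGKIT_FORMAT_VERSION),
                 "regkit_unknown_format")
  }
  pvgs <- lapply(y$pvgs %||% list(), parse_pvg_entry)
  names(pvgs) <- vapply(pvgs, `[[`, character(1), "code")
  elements <- lapply(y$data_elements %||% list(), parse_element_entry)
  names(elements) <- vapply(elements, `[[`, character(1), "code")

  r <- y$registry
  if (is.null(r$code)) regkit_abort("registry block lacks a code", "regkit_bad_file")
  def <- new_registry_definition(r$code, r$name %||% r$code,
                                 as.character(r$version %||% "1.0"),
                                 r$description)
  for (f in r$forms %||% list()) {
    for (s in f$sections %||% list()) {
      for (code in s$elements %||% list()) {
        def <- definition_attach(def, f$name, s$name, as.character(code))
      }
    }
  }
  rules <- lapply(y$permissions %||% list(), function(p) {
    permission_rule(p$role, p$registry %||% def$code, p$de_code, p$access)
  })

  # self-containment
  referenced <- unique(c(
    registry_section_codes(def),
    unlist(lapply(elements, function(e) if (is_derived(e)) e$inputs))
  ))
  missing <- setdiff(referenced, names(elements))
  if (length(missing)) {
    regkit_abort(sprintf("file references undefined element code(s): %s",
                         paste(sort(missing), collapse = ", ")),
                 "regkit_undefined_code")
  }
  missing_pvg <- setdiff(
    unique(unlist(lapply(elements, `[[`, "pvg_code"))), names(pvgs))
  if (length(missing_pvg)) {
    regkit_abort(sprintf("file references undefined PVG(s): %s",
                         paste(sort(missing_pvg), collapse = ", ")),
                 "regkit_undefined_code")
  }
  list(registry = def, elements = unname(elements), pvgs = unname(pvgs),
       rules = rules)
}

#' Import a registry YAML file into an engine
#'
#' Import is transactional and idempotent: the whole file is checked
#' before anything is applied. A definition whose code already exists with
#' an identical definition is a no-op; a conflicting redefinition is an
#' error (shared elements in use by other registries are never silently
#' overwritten). Re-importing the same file succeeds and changes nothing.
#'
#' @param engine A [registry_engine()].
#' @param text Registry file content as a string.
#' @return The parsed bundle, invisibly.
#' @export
import_registry <- function(engine, text) {
  bundle <- parse_registry_file(text)

  conflict <- function(kind, code) {
    regkit_abort(sprintf("%s '%s' already exists with a different definition",
                         kind, code), "regkit_conflicting_definition")
  }
  for (g in bundle$pvgs) {
    if (engine$has_pvg(g$code) &&
        !identical(pvg_to_list(engine$get_pvg(g$code)), pvg_to_list(g))) {
      conflict("PVG", g$code)
    }
  }
  for (el in bundle$elements) {
    if (engine$has_element(el$code) &&
        !identical(element_to_list(engine$get_element(el$code)),
                   element_to_list(el))) {
      conflict("data element", el$code)
    }
  }
  registry_exists <- engine$has_registry(bundle$registry$code)
  if (registry_exists &&
      !identical(registry_to_list(engine$get_registry(bundle$registry$code)),
                 registry_to_list(bundle$registry))) {
    conflict("registry", bundle$registry$code)
  }

  for (g in bundle$pvgs) {
    if (!engine$has_pvg(g$code)) engine$define_pvg(g$code, g$name, {
      v <- g$values$label; names(v) <- g$values$code; v
    })
  }
  # plain elements first so derived inputs resolve in any file order
  ordered <- c(Filter(Negate(is_derived), bundle$elements),
               Filter(is_derived, bundle$elements))
  for (el in ordered) {
    if (engine$has_element(el$code)) next
    if (is_derived(el)) {
      engine$define_derived(el$code, el$name, el$datatype,
                            el$expression$source_text, units = el$units)
    } else {
      engine$define_element(el$code, el$name, el$datatype,
                            min = el$min, max = el$max, pattern = el$pattern,
                            pvg_code = el$pvg_code, units = el$units,
                            required = el$required)
    }
  }
  if (!registry_exists) {
    def <- bundle$registry
    engine$create_registry(def$code, def$name, def$version, def$description)
    for (f in def$forms) {
      for (s in f$sections) {
        for (code in s$element_codes) {
          engine$attach_element(def$code, f$name, s$name, code)
        }
      }
    }
  }
  existing <- lapply(engine$rules_table(), rule_to_list)
  for (rule in bundle$rules) {
    if (!any(vapply(existing, identical, logical(1), rule_to_list(rule)))) {
      engine$grant(rule$role, rule$registry, rule$de_code, rule$access)
    }
  }
  invisible(bundle)
}

# ---- catalogue export ------------------------------------------------------

validation_summary <- function(de) {
  parts <- character()
  if (!is.null(de$min)) parts <- c(parts, paste0("min=", de$min))
  if (!is.null(de$max)) parts <- c(parts, paste0("max=", de$max))
  if (!is.null(de$pattern)) parts <- c(parts, paste0("pattern=", de$pattern))
  if (de$required) parts <- c(parts, "required")
  paste(parts, collapse = "; ")
}

catalogue_frame <- function(engine, registry_code) {
  elements <- engine$catalogue(registry_code)
  rows <- lapply(elements, function(de) {
    pvg_values <- ""
    if (!is.null(de$pvg_code)) {
      pvg_values <- paste(engine$get_pvg(de$pvg_code)$values$code, collapse = "|")
    }
    data.frame(
      code = de$code, name = de$name, datatype = de$datatype,
      validation = validation_summary(de),
      pvg = de$pvg_code %||% "", pvg_values = pvg_values,
      units = de$units %||% "",
      derived = is_derived(de),
      inputs = if (is_derived(de)) paste(de$inputs, collapse = "|") else "",
      expression = if (is_derived(de)) de$expression$source_text else "",
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(code = character(), name = character(),
                      datatype = character(), validation = character(),
                      pvg = character(), pvg_values = character(),
                      units = character(), derived = logical(),
                      inputs = character(), expression = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Export the data-element catalogue of a registry
#'
#' The catalogue lists every element the registry uses — the codes attached
#' to its sections plus the transitive inputs of its derived elements, so
#' the export is always self-contained — one entry per element, sorted by
#' code.
#'
#' @param engine A [registry_engine()].
#' @param registry_code A valid registry code.
#' @param format `"yaml"` or `"csv"` (RFC 4180, header row included).
#' @return The catalogue as a single string.
#' @export
export_catalogue <- function(engine, registry_code, format = c("yaml", "csv")) {
  format <- match.arg(format)
  df <- catalogue_frame(engine, registry_code)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  entries <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  yaml::as.yaml(entries, indent = 2, precision = 17)
}

#' Dump a registry's patient records as JSON lines
#'
#' Companion plumbing to the definition export: one JSON object per
#' patient document (`patient_id` plus encoded key/value entries). Patient
#' data is deliberately not part of the registry definition file.
#'
#' @param engine A [registry_engine()].
#' @param registry_code Registry whose collection to dump.
#' @return A string, one line per patient.
#' @export
export_records <- function(engine, registry_code) {
  pids <- engine$list_patients(registry_code)
  lines <- vapply(pids, function(pid) {
    doc <- engine$store$backend$get_doc(registry_code, pid)
    as.character(jsonlite::toJSON(list(patient_id = pid, entries = doc),
                                  auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
}

# ---- whole-engine state (CLI persistence) ----------------------------------

engine_dump_state <- function(self, private) {
  doc <- list(
    format_version = REGKIT_FORMAT_VERSION,
    pvgs = lapply(self$list_pvgs(), pvg_to_list),
    data_elements = lapply(self$list_elements(), element_to_list),
    registries = lapply(self$list_registries(), registry_to_list),
    users = lapply(self$list_users(), function(u) {
      list(username = u$username, role = u$role,
           workgroups = as.list(u$workgroups))
    }),
    workgroups = {
      out <- list()
      for (wg in sort(ls(private$wgroups))) {
        entry <- get(wg, envir = private$wgroups, inherits = FALSE)
        out[[wg]] <- lapply(entry, as.list)
      }
      out
    },
    rules = lapply(private$rules, rule_to_list)
  )
  yaml::as.yaml(doc, indent = 2, precision = 17)
}

engine_load_state <- function(self, private, text) {
  y <- yaml::yaml.load(text)
  for (p in y$pvgs %||% list()) {
    g <- parse_pvg_entry(p)
    v <- g$values$label; names(v) <- g$values$code
    self$define_pvg(g$code, g$name, v)
  }
  entries <- lapply(y$data_elements %||% list(), parse_element_entry)
  for (el in c(Filter(Negate(is_derived), entries), Filter(is_derived, entries))) {
    if (is_derived(el)) {
      self$define_derived(el$code, el$name, el$datatype,
                          el$expression$source_text, units = el$units)
    } else {
      self$define_element(el$code, el$name, el$datatype,
                          min = el$min, max = el$max, pattern = el$pattern,
                          pvg_code = el$pvg_code, units = el$units,
                          required = el$required)
    }
  }
  for (r in y$registries %||% list()) {
    self$create_registry(r$code, r$name %||% r$code,
                         as.character(r$version %||% "1.0"), r$description)
    for (f in r$forms %||% list()) {
      for (s in f$sections %||% list()) {
        for (code in s$elements %||% list()) {
          self$attach_element(r$code, f$name, s$name, as.character(code))
        }
      }
    }
  }
  for (u in y$users %||% list()) {
    self$add_user(u$username, u$role, as.character(unlist(u$workgroups)))
  }
  for (wg in names(y$workgroups %||% list())) {
    for (reg in names(y$workgroups[[wg]])) {
      for (pid in y$workgroups[[wg]][[reg]]) {
        self$assign_patient_to_workgroup(wg, reg, as.character(pid))
      }
    }
  }
  for (r in y$rules %||% list()) {
    self$grant(r$role, r$registry, r$de_code, r$access)
  }
  invisible(TRUE)
}
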