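#' Metadata-driven registry engine
#'
#' @description
#' The engine is the central handle of the package, playing the role the
#' original framework splits between a relational metadata database and a
#' schema-less document store: it owns the shared element store (data
#' elements, derived elements, permitted value groups — the static
#' definition side) and a per-registry record store (the dynamic patient
#' side), plus users, workgroups and permission rules. All user-facing
#' operations ([create_registry()], [put_value()], [view_document()], ...)
#' are thin wrappers over its methods.
#'
#' With `data_dir = NULL` the engine is fully in-memory (the test backend);
#' given a directory it persists definitions to `definitions.yaml` and
#' patient records to an append-logged JSON-lines file per registry
#' collection, with uploaded files as content-addressed blobs.
#'
#' @param data_dir Optional directory for durable storage.
#' @return A `RegistryEngine` R6 object.
#' @examples
#' eng <- registry_engine()
#' define_element(eng, "DOB", "Date of birth", "date")
#' create_registry(eng, "dm1", "Myotonic Dystrophy", "1.0")
#' attach_element(eng, "dm1", "Demographics", "Identity", "DOB")
#' @export
registry_engine <- function(data_dir = NULL) {
  RegistryEngine$new(data_dir)
}

#' @rdname registry_engine
#' @export
RegistryEngine <- R6::R6Class("RegistryEngine",
  public = list(
    store = NULL,
    data_dir = NULL,

    initialize = function(data_dir = NULL) {
      private$elements <- new.env(parent = emptyenv())
      private$pvgs <- new.env(parent = emptyenv())
      private$registries <- new.env(parent = emptyenv())
      private$users <- new.env(parent = emptyenv())
      private$wgroups <- new.env(parent = emptyenv())
      private$rules <- list()
      self$data_dir <- data_dir
      if (is.null(data_dir)) {
        self$store <- RecordStore$new(memory_backend())
      } else {
        dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
        self$store <- RecordStore$new(file_backend(data_dir))
        state_path <- file.path(data_dir, "definitions.yaml")
        if (file.exists(state_path)) {
          engine_load_state(self, private,
                            paste(readLines(state_path, encoding = "UTF-8"),
                                  collapse = "\n"))
        }
      }
      if (!self$has_user("admin")) self$add_user("admin", "admin")
    },

    save = function() {
      if (is.null(self$data_dir)) return(invisible(FALSE))
      writeLines(engine_dump_state(self, private),
                 file.path(self$data_dir, "definitions.yaml"), useBytes = TRUE)
      invisible(TRUE)
    },

    # ---- element store -----------------------------------------------------

    define_pvg = function(code, name = code, values = character()) {
      g <- pvg(code, name, values)
      if (self$has_pvg(g$code)) {
        regkit_abort(sprintf("PVG code '%s' is already defined", g$code),
                     "regkit_duplicate_code")
      }
      assign(g$code, g, envir = private$pvgs)
      invisible(g)
    },

    has_pvg = function(code) exists(code, envir = private$pvgs, inherits = FALSE),

    get_pvg = function(code) {
      if (!self$has_pvg(code)) {
        regkit_abort(sprintf("unknown PVG '%s'", code), "regkit_unknown_pvg")
      }
      get(code, envir = private$pvgs, inherits = FALSE)
    },

    list_pvgs = function() {
      lapply(sort(ls(private$pvgs)), self$get_pvg)
    },

    define_element = function(code, name = code, datatype,
                              min = NULL, max = NULL, pattern = NULL,
                              pvg_code = NULL, units = NULL, required = FALSE) {
      de <- data_element(code, name, datatype, min = min, max = max,
                        pattern = pattern, pvg_code = pvg_code,
                        units = units, required = required)
      private$register_element(de)
    },

    define_derived = function(code, name = code, datatype = "float", expression,
                              units = NULL) {
      dde <- derived_element(code, name, datatype, expression, units = units)
      private$register_element(dde)
    },

    has_element = function(code) exists(code, envir = private$elements, inherits = FALSE),

    get_element = function(code) {
      if (!self$has_element(code)) {
        regkit_abort(sprintf("unknown data element '%s'", code), "regkit_unknown_element")
      }
      get(code, envir = private$elements, inherits = FALSE)
    },

    list_elements = function() {
      lapply(sort(ls(private$elements)), self$get_element)
    },

    # deletion is refused while any registry still references the code
    # (directly or through a derived element's input closure)
    delete_element = function(code) {
      self$get_element(code)
      for (reg in ls(private$registries)) {
        def <- self$get_registry(reg)
        if (code %in% catalogue_codes(def, private$lookup_fn())) {
          regkit_abort(
            sprintf("cannot delete element '%s': registry '%s' references it",
                    code, reg),
            "regkit_element_in_use"
          )
        }
      }
      rm(list = code, envir = private$elements)
      invisible(TRUE)
    },

    # replace an existing element definition in place (shared: every
    # registry referencing the code sees the edit)
    redefine_element = function(de) {
      stopifnot(inherits(de, "regkit_de"))
      if (!self$has_element(de$code)) {
        regkit_abort(sprintf("unknown data element '%s'", de$code),
                     "regkit_unknown_element")
      }
      if (!is.null(de$pvg_code)) self$get_pvg(de$pvg_code)
      assign(de$code, de, envir = private$elements)
      invisible(de)
    },

    # ---- registries --------------------------------------------------------

    create_registry = function(code, name, version = "1.0", description = NULL) {
      def <- new_registry_definition(code, name, version, description)
      if (self$has_registry(code)) {
        regkit_abort(sprintf("registry code '%s' is already in use", code),
                     "regkit_duplicate_code")
      }
      assign(code, def, envir = private$registries)
      invisible(def)
    },

    has_registry = function(code) {
      is_string(code) && exists(code, envir = private$registries, inherits = FALSE)
    },

    get_registry = function(code) {
      if (!self$has_registry(code)) {
        regkit_abort(sprintf("unknown registry '%s'", as.character(code)[1]),
                     "regkit_unknown_registry")
      }
      get(code, envir = private$registries, inherits = FALSE)
    },

    list_registries = function() {
      lapply(sort(ls(private$registries)), self$get_registry)
    },

    attach_element = function(registry_code, form_name, section_name, de_code) {
      def <- self$get_registry(registry_code)
      if (!self$has_element(de_code)) {
        regkit_abort(sprintf("cannot attach unknown element '%s'", de_code),
                     "regkit_unknown_element")
      }
      def <- definition_attach(def, form_name, section_name, de_code)
      assign(registry_code, def, envir = private$registries)
      invisible(def)
    },

    validate_definition = function(registry_code) {
      def <- self$get_registry(registry_code)
      validate_definition_impl(def, private$lookup_fn())
    },

    catalogue = function(registry_code) {
      errs <- self$validate_definition(registry_code)
      if (length(errs)) {
        regkit_abort(sprintf("registry '%s' fails validation: %s", registry_code,
                             paste(vapply(errs, `[[`, character(1), "message"),
                                   collapse = "; ")),
                     "regkit_invalid_registry")
      }
      def <- self$get_registry(registry_code)
      lapply(catalogue_codes(def, private$lookup_fn()), self$get_element)
    },

    # ---- patient records ---------------------------------------------------

    add_patient = function(registry_code, patient_id) {
      self$get_registry(registry_code)
      assert_identifier(patient_id, "patient id")
      self$store$register_patient(registry_code, patient_id)
    },

    put_value = function(registry_code, patient_id, de_code, raw,
                         form_name = NULL, section_name = NULL) {
      loc <- private$resolve_location(registry_code, patient_id, de_code,
                                      form_name, section_name)
      de <- self$get_element(de_code)
      if (is_derived(de)) {
        regkit_abort(sprintf("'%s' is a derived element and is read-only", de_code),
                     "regkit_derived_readonly")
      }
      group <- if (!is.null(de$pvg_code)) self$get_pvg(de$pvg_code) else NULL
      res <- validate_value(de, raw, pvg = group)
      if (!is_valid_result(res)) {
        regkit_abort(
          paste0(sprintf("invalid value for '%s': ", de_code),
                 paste(vapply(res, `[[`, character(1), "message"), collapse = "; ")),
          "regkit_validation_failure", errors = res
        )
      }
      key <- encode_record_key(loc$form_name, loc$section_name, de_code)
      self$store$register_patient(registry_code, patient_id)
      if (is.null(res)) {
        # blank on a non-required element: store no key
        self$store$remove_key(registry_code, patient_id, key)
        return(invisible(NULL))
      }
      self$store$put(registry_code, patient_id, key, res)
      invisible(res)
    },

    get_value = function(registry_code, patient_id, de_code,
                         form_name = NULL, section_name = NULL) {
      loc <- private$resolve_location(registry_code, patient_id, de_code,
                                      form_name, section_name)
      de <- self$get_element(de_code)
      if (is_derived(de)) {
        return(private$compute_derived(registry_code, patient_id, de))
      }
      key <- encode_record_key(loc$form_name, loc$section_name, de_code)
      self$store$get(registry_code, patient_id, key)
    },

    get_patient_document = function(registry_code, patient_id) {
      def <- self$get_registry(registry_code)
      stored <- self$store$doc(registry_code, patient_id)
      if (is.null(stored)) {
        regkit_abort(sprintf("unknown patient '%s' in registry '%s'",
                             patient_id, registry_code), "regkit_unknown_patient")
      }
      entries <- stored
      for (code in unique(registry_section_codes(def))) {
        el <- private$lookup_fn()(code)
        if (is.null(el) || !is_derived(el)) next
        loc <- registry_locate(def, code)
        key <- encode_record_key(loc$form_name, loc$section_name, code)
        entries[[key]] <- private$compute_derived(registry_code, patient_id, el)
      }
      structure(list(patient_id = patient_id, registry = registry_code,
                     entries = entries),
                class = "regkit_document")
    },

    list_patients = function(registry_code) {
      self$get_registry(registry_code)
      self$store$list_patients(registry_code)
    },

    delete_patient = function(registry_code, patient_id) {
      self$get_registry(registry_code)
      self$store$delete_patient(registry_code, patient_id)
    },

    store_file = function(registry_code, patient_id, de_code, bytes,
                          filename = "upload", form_name = NULL, section_name = NULL) {
      de <- self$get_element(de_code)
      if (de$datatype != "file") {
        regkit_abort(sprintf("element '%s' has datatype %s, not file",
                             de_code, de$datatype), "regkit_bad_element")
      }
      stopifnot(is.raw(bytes))
      dg <- self$store$store_blob(bytes)
      fv <- file_value(filename, dg, length(bytes))
      self$put_value(registry_code, patient_id, de_code, fv,
                     form_name = form_name, section_name = section_name)
      invisible(fv)
    },

    fetch_file = function(fv) {
      stopifnot(inherits(fv, "regkit_file_value"))
      self$store$fetch_blob(fv)
    },

    # ---- users, workgroups, permissions ------------------------------------

    add_user = function(username, role, workgroups = character()) {
      u <- registry_user(username, role, workgroups)
      assign(u$username, u, envir = private$users)
      invisible(u)
    },

    has_user = function(username) exists(username, envir = private$users, inherits = FALSE),

    get_user = function(username) {
      if (!self$has_user(username)) {
        regkit_abort(sprintf("unknown user '%s'", username), "regkit_unknown_user")
      }
      get(username, envir = private$users, inherits = FALSE)
    },

    list_users = function() lapply(sort(ls(private$users)), self$get_user),

    assign_patient_to_workgroup = function(workgroup, registry_code, patient_id) {
      wg <- if (exists(workgroup, envir = private$wgroups, inherits = FALSE)) {
        get(workgroup, envir = private$wgroups, inherits = FALSE)
      } else list()
      wg[[registry_code]] <- unique(c(wg[[registry_code]] %||% character(), patient_id))
      assign(workgroup, wg, envir = private$wgroups)
      invisible(TRUE)
    },

    workgroup_patients = function(workgroup, registry_code) {
      if (!exists(workgroup, envir = private$wgroups, inherits = FALSE)) return(character())
      wg <- get(workgroup, envir = private$wgroups, inherits = FALSE)
      wg[[registry_code]] %||% character()
    },

    grant = function(role, registry_code, de_code = "*", access = "read") {
      rule <- permission_rule(role, registry_code, de_code, access)
      private$rules <- c(private$rules, list(rule))
      invisible(rule)
    },

    revoke = function(role, registry_code, de_code = "*") {
      private$rules <- Filter(function(r) {
        !(r$role == role && r$registry == registry_code && r$de_code == de_code)
      }, private$rules)
      invisible(TRUE)
    },

    rules_table = function() private$rules,

    set_rules = function(rules) {
      private$rules <- lapply(rules, function(r) {
        permission_rule(r$role, r$registry, r$de_code, r$access)
      })
      invisible(TRUE)
    },

    can_access = function(username, registry_code, de_code, mode = c("read", "write")) {
      mode <- match.arg(mode)
      u <- self$get_user(username)
      self$get_registry(registry_code)
      if (u$role == "admin") return(TRUE)
      level <- resolve_access(private$rules, u$role, registry_code, de_code)
      if (mode == "read") level >= 1L else level >= 2L
    },

    visible_patients = function(username, registry_code) {
      u <- self$get_user(username)
      self$get_registry(registry_code)
      if (u$role == "admin") return(self$store$list_patients(registry_code))
      ids <- unlist(lapply(u$workgroups, self$workgroup_patients,
                           registry_code = registry_code), use.names = FALSE)
      sort(unique(ids %||% character()))
    },

    view_document = function(username, registry_code, patient_id) {
      u <- self$get_user(username)
      if (u$role != "admin" &&
          !patient_id %in% self$visible_patients(username, registry_code)) {
        regkit_abort(
          sprintf("user '%s' may not view patient '%s' in registry '%s'",
                  username, patient_id, registry_code),
          "regkit_access_denied"
        )
      }
      doc <- self$get_patient_document(registry_code, patient_id)
      if (u$role == "admin") return(doc)
      keep <- vapply(names(doc$entries), function(k) {
        self$can_access(username, registry_code, decode_record_key(k)$de_code, "read")
      }, logical(1))
      doc$entries <- doc$entries[keep]
      doc
    },

    # ---- serialization hooks ----------------------------------------------

    element_lookup = function() private$lookup_fn()
  ),

  private = list(
    elements = NULL, pvgs = NULL, registries = NULL,
    users = NULL, wgroups = NULL, rules = NULL,

    lookup_fn = function() {
      function(code) {
        if (exists(code, envir = private$elements, inherits = FALSE)) {
          get(code, envir = private$elements, inherits = FALSE)
        } else NULL
      }
    },

    register_element = function(de) {
      if (self$has_element(de$code)) {
        regkit_abort(sprintf("data element code '%s' is already defined", de$code),
                     "regkit_duplicate_code")
      }
      if (!is.null(de$pvg_code)) self$get_pvg(de$pvg_code)
      assign(de$code, de, envir = private$elements)
      invisible(de)
    },

    resolve_location = function(registry_code, patient_id, de_code,
                                form_name, section_name) {
      def <- self$get_registry(registry_code)
      assert_identifier(patient_id, "patient id")
      if (!self$has_element(de_code)) {
        regkit_abort(sprintf("unknown data element '%s'", de_code),
                     "regkit_unknown_element")
      }
      if (is.null(form_name) != is.null(section_name)) {
        regkit_abort("give both form_name and section_name, or neither",
                     "regkit_bad_key")
      }
      if (is.null(form_name)) {
        loc <- registry_locate(def, de_code)
        if (is.null(loc)) {
          regkit_abort(
            sprintf("element '%s' is not attached to registry '%s'",
                    de_code, registry_code),
            "regkit_layout_error"
          )
        }
        return(loc)
      }
      for (f in def$forms) {
        if (f$name != form_name) next
        for (s in f$sections) {
          if (s$name == section_name && de_code %in% s$element_codes) {
            return(list(form_name = form_name, section_name = section_name))
          }
        }
      }
      regkit_abort(
        sprintf("element '%s' is not attached at %s/%s of registry '%s'",
                de_code, form_name, section_name, registry_code),
        "regkit_layout_error"
      )
    },

    # context for DDE evaluation: the patient's current stored values by
    # element code (first layout occurrence wins if a code repeats)
    compute_derived = function(registry_code, patient_id, dde) {
      stored <- self$store$doc(registry_code, patient_id) %||% list()
      ctx <- list()
      for (k in names(stored)) {
        code <- decode_record_key(k)$de_code
        if (is.null(ctx[[code]])) ctx[[code]] <- stored[[k]]
      }
      out <- expr_eval(dde$expression, ctx)
      if (is_not_computable(out)) return(out)
      if (dde$datatype == "integer") out <- round(out)   # half-to-even
      typed_value(dde$code, out, dde$datatype)
    }
  )
)

#' @export
print.regkit_document <- function(x, ...) {
  cat(sprintf("<patient %s in registry %s: %d entr%s>\n", x$patient_id,
              x$registry, length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  for (k in names(x$entries)) {
    v <- x$entries[[k]]
    txt <- if (is_not_computable(v)) format(v) else render_value(v)
    cat(sprintf("  %s = %s\n", k, txt))
  }
  invisible(x)
}
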