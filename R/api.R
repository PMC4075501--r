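#' @name registry-api
#' @title Functional surface over a registry engine
#'
#' @description
#' Every engine method has a plain-function counterpart taking the engine
#' as its first argument, in the style of a database interface: scripts and
#' examples read naturally, and the engine handle stays explicit.
#'
#' @param engine A [registry_engine()].
#' @param code,registry_code,de_code,pvg_code Identifier strings.
#' @param name,version,description Display metadata.
#' @param values Named character vector of permitted values (codes as
#'   names, labels as values).
#' @param datatype One of integer, float, string, date, file.
#' @param min,max,pattern,units,required Validation attributes; see
#'   [data_element()].
#' @param expression Calculation text for a derived element; see
#'   [expr_parse()].
#' @param form_name,section_name Layout location within the registry.
#' @param patient_id Patient identifier.
#' @param raw Raw input value for validation and storage.
#' @param bytes Raw vector of file content.
#' @param filename Original filename of an upload.
#' @param fv A file value as returned by [store_file()].
#' @param username A registered user name.
#' @param role A role name (default vocabulary: admin, curator, genetic,
#'   clinical).
#' @param workgroups,workgroup Workgroup names.
#' @param access One of none, read, read_write.
#' @param mode `"read"` or `"write"`.
NULL

#' @rdname registry-api
#' @export
define_pvg <- function(engine, code, name = code, values = character()) {
  engine$define_pvg(code, name, values)
}

#' @rdname registry-api
#' @export
define_element <- function(engine, code, name = code, datatype,
                           min = NULL, max = NULL, pattern = NULL,
                           pvg_code = NULL, units = NULL, required = FALSE) {
  engine$define_element(code, name, datatype, min = min, max = max,
                        pattern = pattern, pvg_code = pvg_code,
                        units = units, required = required)
}

#' @rdname registry-api
#' @export
define_derived <- function(engine, code, name = code, datatype = "float",
                           expression, units = NULL) {
  engine$define_derived(code, name, datatype, expression, units = units)
}

#' @rdname registry-api
#' @export
delete_element <- function(engine, code) engine$delete_element(code)

#' @rdname registry-api
#' @export
create_registry <- function(engine, code, name, version = "1.0",
                            description = NULL) {
  engine$create_registry(code, name, version, description)
}

#' @rdname registry-api
#' @export
attach_element <- function(engine, registry_code, form_name, section_name,
                           de_code) {
  engine$attach_element(registry_code, form_name, section_name, de_code)
}

#' @rdname registry-api
#' @export
validate_definition <- function(engine, registry_code) {
  engine$validate_definition(registry_code)
}

#' @rdname registry-api
#' @export
catalogue <- function(engine, registry_code) engine$catalogue(registry_code)

#' @rdname registry-api
#' @export
add_patient <- function(engine, registry_code, patient_id) {
  engine$add_patient(registry_code, patient_id)
}

#' @rdname registry-api
#' @export
put_value <- function(engine, registry_code, patient_id, de_code, raw,
                      form_name = NULL, section_name = NULL) {
  engine$put_value(registry_code, patient_id, de_code, raw,
                   form_name = form_name, section_name = section_name)
}

#' @rdname registry-api
#' @export
get_value <- function(engine, registry_code, patient_id, de_code,
                      form_name = NULL, section_name = NULL) {
  engine$get_value(registry_code, patient_id, de_code,
                   form_name = form_name, section_name = section_name)
}

#' @rdname registry-api
#' @export
get_patient_document <- function(engine, registry_code, patient_id) {
  engine$get_patient_document(registry_code, patient_id)
}

#' @rdname registry-api
#' @export
list_patients <- function(engine, registry_code) engine$list_patients(registry_code)

#' @rdname registry-api
#' @export
delete_patient <- function(engine, registry_code, patient_id) {
  engine$delete_patient(registry_code, patient_id)
}

#' @rdname registry-api
#' @export
store_file <- function(engine, registry_code, patient_id, de_code, bytes,
                       filename = "upload", form_name = NULL,
                       section_name = NULL) {
  engine$store_file(registry_code, patient_id, de_code, bytes,
                    filename = filename, form_name = form_name,
                    section_name = section_name)
}

#' @rdname registry-api
#' @export
fetch_file <- function(engine, fv) engine$fetch_file(fv)

#' @rdname registry-api
#' @export
add_user <- function(engine, username, role, workgroups = character()) {
  engine$add_user(username, role, workgroups)
}

#' @rdname registry-api
#' @export
assign_patient_to_workgroup <- function(engine, workgroup, registry_code,
                                        patient_id) {
  engine$assign_patient_to_workgroup(workgroup, registry_code, patient_id)
}

#' @rdname registry-api
#' @export
grant <- function(engine, role, registry_code, de_code = "*", access = "read") {
  engine$grant(role, registry_code, de_code, access)
}

#' @rdname registry-api
#' @export
revoke <- function(engine, role, registry_code, de_code = "*") {
  engine$revoke(role, registry_code, de_code)
}

#' @rdname registry-api
#' @export
can_access <- function(engine, username, registry_code, de_code,
                       mode = c("read", "write")) {
  engine$can_access(username, registry_code, de_code, mode)
}

#' @rdname registry-api
#' @export
visible_patients <- function(engine, username, registry_code) {
  engine$visible_patients(username, registry_code)
}

#' @rdname registry-api
#' @export
view_document <- function(engine, username, registry_code, patient_id) {
  engine$view_document(username, registry_code, patient_id)
}
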