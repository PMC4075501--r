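#' @name access-control
#' @title Field-level role-based access control
#'
#' @description
#' Access is multi-level: roles gate which data elements a user may read or
#' write (down to the individual element), and workgroups gate which
#' patients a user may see at all. The role vocabulary defaults to the four
#' demonstration roles — admin, curator, genetic, clinical — and is
#' extensible. Permission rules are `(role, registry, element-or-wildcard,
#' access)` tuples with default deny; an exact element rule is more
#' specific than a wildcard.
#'
#' Resolution semantics: the effective access for a (role, registry,
#' element) is the strongest matching *grant* (`read` or `read_write`)
#' that is not overridden by a strictly more specific `none` rule; a
#' `none` rule cancels less-specific grants only. This preserves both
#' properties the model promises: an exact `none` beats a wildcard grant,
#' and adding a grant rule can never remove access someone already had.
NULL

REGKIT_ROLES <- c("admin", "curator", "genetic", "clinical")
REGKIT_ACCESS_LEVELS <- c(none = 0L, read = 1L, read_write = 2L)

permission_rule <- function(role, registry_code, de_code, access) {
  if (!is_string(role) || !nzchar(role)) {
    regkit_abort("rule role must be a non-empty string", "regkit_bad_rule")
  }
  assert_identifier(registry_code, "rule registry code")
  if (!is_string(de_code) || !nzchar(de_code)) {
    regkit_abort("rule de_code must be an element code or '*'", "regkit_bad_rule")
  }
  if (!is_string(access) || !access %in% names(REGKIT_ACCESS_LEVELS)) {
    regkit_abort(sprintf("access must be one of: %s",
                         paste(names(REGKIT_ACCESS_LEVELS), collapse = ", ")),
                 "regkit_bad_rule")
  }
  list(role = role, registry = registry_code, de_code = de_code, access = access)
}

rule_specificity <- function(rule) if (identical(rule$de_code, "*")) 1L else 2L

# effective access level (0/1/2) for role x registry x element
resolve_access <- function(rules, role, registry_code, de_code) {
  matching <- Filter(function(r) {
    r$role == role && r$registry == registry_code &&
      (r$de_code == "*" || r$de_code == de_code)
  }, rules)
  if (!length(matching)) return(0L)
  deny_spec <- vapply(matching, function(r) {
    if (r$access == "none") rule_specificity(r) else 0L
  }, integer(1))
  max_deny <- max(deny_spec)
  level <- 0L
  for (r in matching) {
    if (r$access == "none") next
    if (rule_specificity(r) < max_deny) next   # cancelled by a more specific deny
    level <- max(level, REGKIT_ACCESS_LEVELS[[r$access]])
  }
  level
}

# user record constructor
registry_user <- function(username, role, workgroups = character()) {
  assert_identifier(username, "username")
  if (!is_string(role) || !nzchar(role)) {
    regkit_abort("role must be a non-empty string", "regkit_bad_user")
  }
  list(username = username, role = role, workgroups = unique(as.character(workgroups)))
}
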