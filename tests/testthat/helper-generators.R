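# Shared helpers: random definition generators and independent brute-force
# oracles. The oracles are deliberately written from the contract, not from
# the implementation, so property tests compare two independent routes.

rand_code <- function(prefix = "E") {
  paste0(prefix, paste(sample(LETTERS, 8, replace = TRUE), collapse = ""))
}

# pool of patterns the fixture synthesizer understands
rand_patterns <- c(
  "\\d{4} \\d{4} \\d{4} \\d{4}",
  "[A-Z]{2}\\d{3}",
  "(ab|cd)+x?",
  "\\w{3}-\\d{2}"
)

# a random non-derived element; returns the regkit_de (plus its pvg if any)
rand_element <- function(engine = NULL, datatypes = c("integer", "float", "string", "date")) {
  dt <- sample(datatypes, 1)
  code <- rand_code()
  de <- switch(dt,
    integer = {
      if (runif(1) < 0.5) {
        lo <- sample(-50:50, 1)
        data_element(code, datatype = "integer", min = lo, max = lo + sample(1:100, 1))
      } else data_element(code, datatype = "integer")
    },
    float = {
      if (runif(1) < 0.5) {
        lo <- runif(1, -10, 10)
        data_element(code, datatype = "float", min = lo, max = lo + runif(1, 0.1, 50))
      } else data_element(code, datatype = "float")
    },
    date = data_element(code, datatype = "date"),
    string = {
      kind <- sample(c("plain", "pattern", "pvg"), 1)
      if (kind == "pattern") {
        data_element(code, datatype = "string", pattern = sample(rand_patterns, 1))
      } else if (kind == "pvg" && !is.null(engine)) {
        g <- engine$define_pvg(rand_code("G"), values = {
          v <- replicate(sample(2:4, 1), paste(sample(letters, 5, TRUE), collapse = ""))
          names(v) <- paste0("v", seq_along(v), "_", substr(v, 1, 3))
          v
        })
        data_element(code, datatype = "string", pvg_code = g$code)
      } else data_element(code, datatype = "string")
    }
  )
  de
}

register_element <- function(engine, de) {
  if (is_derived(de)) {
    engine$define_derived(de$code, de$name, de$datatype, de$expression$source_text,
                          units = de$units)
  } else {
    engine$define_element(de$code, de$name, de$datatype, min = de$min, max = de$max,
                          pattern = de$pattern, pvg_code = de$pvg_code,
                          units = de$units, required = de$required)
  }
}

# a raw value for an element: valid with probability p_valid, else off-contract
rand_raw <- function(de, pvg = NULL, p_valid = 0.6) {
  valid <- runif(1) < p_valid
  switch(de$datatype,
    integer = if (valid) {
      as.character(sample((de$min %||% -100):(de$max %||% 100), 1))
    } else {
      sample(c("4.2", "abc", as.character((de$max %||% 100) + sample(1:99, 1)),
               as.character((de$min %||% -100) - sample(1:99, 1))), 1)
    },
    float = if (valid) {
      sprintf("%.17g", runif(1, de$min %||% -100, de$max %||% 100))
    } else {
      sample(c("not-a-number", sprintf("%.6f", (de$max %||% 100) + runif(1, 1, 9))), 1)
    },
    date = if (valid) {
      format(as.Date("1970-01-01") + sample(0:15000, 1), "%Y-%m-%d")
    } else {
      sample(c("2020-02-30", "20200101", "yesterday"), 1)
    },
    string = if (!is.null(de$pattern)) {
      if (valid) regkit:::pattern_synthesize(de$pattern)
      else paste(sample(c("!", "@", "#"), 6, TRUE), collapse = "")
    } else if (!is.null(de$pvg_code)) {
      if (valid) sample(pvg$values$code, 1) else "definitely-not-permitted"
    } else {
      paste(sample(letters, 6, TRUE), collapse = "")
    }
  )
}

# --- independent rule-checker oracle for validate_value ---------------------
# applies each rule separately, straight from the contract
oracle_violations <- function(de, raw, pvg = NULL) {
  if (is.null(raw) || (is.character(raw) && !nzchar(trimws(raw)))) {
    return(if (de$required) "required" else character())
  }
  txt <- if (is.character(raw)) trimws(raw) else raw
  parsed <- switch(de$datatype,
    integer = if (is.character(txt)) {
      if (grepl("^[+-]?[0-9]+$", txt)) as.numeric(txt) else NULL
    } else if (is.numeric(txt) && txt == trunc(txt)) txt else NULL,
    float = if (is.character(txt)) {
      ok <- grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", txt)
      if (ok) as.numeric(txt) else NULL
    } else if (is.numeric(txt)) txt else NULL,
    date = if (is.character(txt) && grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", txt) &&
               !is.na(as.Date(txt, "%Y-%m-%d")) &&
               format(as.Date(txt, "%Y-%m-%d"), "%Y-%m-%d") == txt) txt else NULL,
    string = if (is.character(txt)) txt else NULL
  )
  if (is.null(parsed)) return("type")
  out <- character()
  if (de$datatype %in% c("integer", "float")) {
    if (!is.null(de$min) && parsed < de$min) out <- c(out, "range")
    if (!is.null(de$max) && parsed > de$max) out <- c(out, "range")
  }
  if (!is.null(de$pattern) &&
      !grepl(paste0("^(?:", de$pattern, ")$"), parsed, perl = TRUE)) {
    out <- c(out, "pattern")
  }
  if (!is.null(de$pvg_code) && !parsed %in% pvg$values$code) out <- c(out, "pvg")
  out
}

# --- closure oracle for catalogue -------------------------------------------
# iterate set union to a fixpoint; independent of the DFS in the package
oracle_closure <- function(section_codes, inputs_of) {
  codes <- unique(section_codes)
  repeat {
    extra <- unique(unlist(lapply(codes, function(c) inputs_of[[c]])))
    grown <- union(codes, extra)
    if (setequal(grown, codes)) return(sort(codes))
    codes <- grown
  }
}

# --- cycle oracle ------------------------------------------------------------
# Kahn-style elimination: repeatedly drop nodes with no outgoing edges; a
# cycle exists iff nodes remain
oracle_has_cycle <- function(deps) {
  nodes <- union(names(deps), unlist(deps))
  edges <- deps
  repeat {
    sinks <- Filter(function(n) length(intersect(edges[[n]] %||% character(), nodes)) == 0,
                    nodes)
    if (!length(sinks)) break
    nodes <- setdiff(nodes, sinks)
  }
  length(nodes) > 0
}

# --- ACL oracle --------------------------------------------------------------
# re-derives effective access from the stated semantics: strongest matching
# grant not overridden by a strictly more specific none-rule
oracle_access <- function(rules, role, registry, de_code) {
  lv <- c(none = 0, read = 1, read_write = 2)
  spec <- function(r) if (r$de_code == "*") 1 else 2
  m <- Filter(function(r) r$role == role && r$registry == registry &&
                (r$de_code == "*" || r$de_code == de_code), rules)
  deny <- m[vapply(m, function(r) r$access == "none", logical(1))]
  top_deny <- if (length(deny)) max(vapply(deny, spec, numeric(1))) else 0
  best <- 0
  for (r in m) {
    if (r$access == "none") next
    if (spec(r) >= top_deny) best <- max(best, lv[[r$access]])
  }
  best
}

# --- random registry builder -------------------------------------------------
# defines fresh elements (and possibly a DDE over the numeric ones) in the
# engine, creates a registry and attaches everything; returns its code
rand_registry <- function(engine, n_elements = 5, with_dde = TRUE,
                          with_rules = FALSE) {
  reg <- rand_code("R")
  engine$create_registry(reg, paste("Registry", reg), "1.0")
  codes <- character()
  numeric_codes <- character()
  for (i in seq_len(n_elements)) {
    de <- rand_element(engine)
    register_element(engine, de)
    codes <- c(codes, de$code)
    if (de$datatype %in% c("integer", "float")) numeric_codes <- c(numeric_codes, de$code)
  }
  if (with_dde && length(numeric_codes) >= 2) {
    ins <- sample(numeric_codes, 2)
    dde_code <- rand_code("D")
    engine$define_derived(dde_code, datatype = sample(c("float", "integer"), 1),
                          expression = sprintf("(%s + %s) / 2", ins[1], ins[2]))
    codes <- c(codes, dde_code)
  }
  forms <- paste0("Form", 1:2)
  sections <- paste0("Sec", 1:2)
  for (code in codes) {
    engine$attach_element(reg, sample(forms, 1), sample(sections, 1), code)
  }
  if (with_rules) {
    for (role in sample(c("curator", "genetic", "clinical"), 2)) {
      engine$grant(role, reg,
                   sample(c("*", sample(codes, 1)), 1),
                   sample(c("none", "read", "read_write"), 1))
    }
  }
  reg
}
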