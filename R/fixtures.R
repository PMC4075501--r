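#' @name fixtures
#' @title Demonstration registry and synthetic patients
#'
#' @description
#' A self-contained, deterministic demonstration bundle — a Myotonic
#' Dystrophy (DM1) style registry with two forms, four sections, at least
#' one element of each of the five datatypes, the `Size` permitted value
#' group (large/medium/small), a BMI derived element over Height and
#' Weight, the four demonstration roles (admin, curator, genetic,
#' clinical) and fixture permission rules (the clinical role is denied the
#' genetics section's elements; the curator is read-only) — plus a seeded
#' generator of synthetic patient records. The clinical field inventory is
#' representative, invented for the fixture; no real cohort data is
#' involved, and plausibility beyond the declared range constraints is not
#' attempted.
NULL

#' Build the demonstration registry bundle
#'
#' Deterministic (no randomness): repeated calls return identical
#' structures. The bundle passes definition validation with zero errors
#' and survives a YAML export/import round trip.
#'
#' @return A list with components `registry`, `elements`, `pvgs`, `users`
#'   and `rules`, mirroring the import format of [parse_registry_file()].
#' @export
build_demo_bundle <- function() {
  pvgs <- list(
    pvg("Size", "Size", c(large = "Large", medium = "Medium", small = "Small"))
  )
  elements <- list(
    data_element("DOB", "Date of birth", "date", required = TRUE),
    data_element("AgeAtOnset", "Age at symptom onset", "integer",
                 min = 0, max = 120, units = "years"),
    data_element("Height", "Height", "float", min = 0.3, max = 2.5, units = "m"),
    data_element("Weight", "Weight", "float", min = 1, max = 300, units = "kg"),
    data_element("InsuranceNumber", "Insurance card number", "string",
                 pattern = "\\d{4} \\d{4} \\d{4} \\d{4}"),
    data_element("CTGRepeatLength", "CTG repeat length", "integer",
                 min = 5, max = 4000, units = "repeats"),
    data_element("RepeatExpansionSize", "Repeat expansion size category",
                 "string", pvg_code = "Size"),
    data_element("ConsentForm", "Signed consent form", "file"),
    derived_element("BMI", "Body mass index", "float",
                    "Weight / (Height * Height)", units = "kg/m^2")
  )
  layout <- list(
    list("Demographics", "Identity", "DOB"),
    list("Demographics", "Identity", "AgeAtOnset"),
    list("Demographics", "Consent", "ConsentForm"),
    list("Demographics", "Consent", "InsuranceNumber"),
    list("Clinical", "Anthropometry", "Height"),
    list("Clinical", "Anthropometry", "Weight"),
    list("Clinical", "Anthropometry", "BMI"),
    list("Clinical", "Genetics", "CTGRepeatLength"),
    list("Clinical", "Genetics", "RepeatExpansionSize")
  )
  def <- new_registry_definition("dm1", "Myotonic Dystrophy", "1.0",
                                 "DM1 demonstration registry")
  for (at in layout) def <- definition_attach(def, at[[1]], at[[2]], at[[3]])

  users <- list(
    registry_user("admin", "admin"),
    registry_user("curator", "curator", "DM1Unit"),
    registry_user("genetic", "genetic", "DM1Unit"),
    registry_user("clinical", "clinical", "DM1Unit")
  )
  rules <- list(
    permission_rule("curator", "dm1", "*", "read"),
    permission_rule("genetic", "dm1", "*", "read_write"),
    permission_rule("clinical", "dm1", "*", "read_write"),
    permission_rule("clinical", "dm1", "CTGRepeatLength", "none"),
    permission_rule("clinical", "dm1", "RepeatExpansionSize", "none")
  )
  list(registry = def, elements = elements, pvgs = pvgs,
       users = users, rules = rules)
}

#' Load the demonstration bundle into an engine
#'
#' @param data_dir Optional durable storage directory, as for
#'   [registry_engine()].
#' @return An engine populated with the demonstration registry, elements,
#'   users and permission rules.
#' @export
demo_engine <- function(data_dir = NULL) {
  eng <- registry_engine(data_dir)
  bundle <- build_demo_bundle()
  for (g in bundle$pvgs) {
    v <- g$values$label; names(v) <- g$values$code
    eng$define_pvg(g$code, g$name, v)
  }
  for (el in c(Filter(Negate(is_derived), bundle$elements),
               Filter(is_derived, bundle$elements))) {
    if (is_derived(el)) {
      eng$define_derived(el$code, el$name, el$datatype,
                         el$expression$source_text, units = el$units)
    } else {
      eng$define_element(el$code, el$name, el$datatype,
                         min = el$min, max = el$max, pattern = el$pattern,
                         pvg_code = el$pvg_code, units = el$units,
                         required = el$required)
    }
  }
  def <- bundle$registry
  eng$create_registry(def$code, def$name, def$version, def$description)
  for (f in def$forms) {
    for (s in f$sections) {
      for (code in s$element_codes) eng$attach_element(def$code, f$name, s$name, code)
    }
  }
  for (u in bundle$users) {
    if (!eng$has_user(u$username)) eng$add_user(u$username, u$role, u$workgroups)
  }
  for (r in bundle$rules) eng$grant(r$role, r$registry, r$de_code, r$access)
  eng
}

# ---- pattern synthesis -----------------------------------------------------

# Generate a string from a restricted regular-expression subset: literals,
# \d \w \s escapes, [...] classes with ranges, groups with alternation, and
# the quantifiers ? + * {n} {n,m}. Unbounded quantifiers are capped at 3
# repetitions. Every synthesized string is verified against the full
# pattern; unsupported constructs raise an error rather than guessing.
pattern_synthesize <- function(pattern) {
  src <- sub("^\\^", "", sub("\\$$", "", pattern))
  chars <- strsplit(src, "")[[1]]
  pos <- 1L
  n <- length(chars)

  peek <- function() if (pos <= n) chars[[pos]] else NA_character_
  advance <- function() { ch <- chars[[pos]]; pos <<- pos + 1L; ch }
  fail <- function(what) {
    regkit_abort(sprintf("unsupported pattern construct (%s) in: %s", what, pattern),
                 "regkit_unsupported_pattern")
  }

  pick <- function(opts) opts[[floor(stats::runif(1) * length(opts)) + 1L]]

  gen_class <- function() {      # after consuming "["
    if (identical(peek(), "^")) fail("negated class")
    members <- character()
    while (!identical(peek(), "]")) {
      if (is.na(peek())) fail("unterminated class")
      ch <- advance()
      if (ch == "\\") ch <- advance()
      if (identical(peek(), "-") && pos + 1L <= n && chars[[pos + 1L]] != "]") {
        advance()
        hi <- advance()
        members <- c(members, intToUtf8(utf8ToInt(ch):utf8ToInt(hi), multiple = TRUE))
      } else {
        members <- c(members, ch)
      }
    }
    advance()   # "]"
    if (!length(members)) fail("empty class")
    function() pick(members)
  }

  gen_escape <- function(ch) {
    switch(ch,
      d = function() pick(as.character(0:9)),
      w = function() pick(c(letters, LETTERS, as.character(0:9), "_")),
      s = function() " ",
      if (ch %in% c("\\", ".", "+", "*", "?", "(", ")", "[", "]", "{", "}",
                    "|", "^", "$", "-", "/")) {
        function() ch
      } else fail(sprintf("escape \\%s", ch))
    )
  }

  read_quantifier <- function() {
    ch <- peek()
    if (is.na(ch)) return(NULL)
    if (ch == "?") { advance(); return(c(0L, 1L)) }
    if (ch == "+") { advance(); return(c(1L, 3L)) }
    if (ch == "*") { advance(); return(c(0L, 3L)) }
    is_digit <- function(x) !is.na(x) && grepl("[0-9]", x)
    if (ch == "{") {
      advance()
      num <- ""
      while (is_digit(peek())) num <- paste0(num, advance())
      lo <- as.integer(num)
      hi <- lo
      if (identical(peek(), ",")) {
        advance()
        num2 <- ""
        while (is_digit(peek())) num2 <- paste0(num2, advance())
        hi <- if (nzchar(num2)) as.integer(num2) else lo + 3L
      }
      if (!identical(advance(), "}")) fail("malformed quantifier")
      return(c(lo, hi))
    }
    NULL
  }

  gen_alternation <- function() {
    branches <- list(gen_sequence())
    while (identical(peek(), "|")) {
      advance()
      branches[[length(branches) + 1L]] <- gen_sequence()
    }
    if (length(branches) == 1L) return(branches[[1]])
    function() pick(branches)()
  }

  gen_sequence <- function() {
    atoms <- list()
    repeat {
      ch <- peek()
      if (is.na(ch) || ch == "|" || ch == ")") break
      atom <-
        if (ch == "(") {
          advance()
          if (identical(peek(), "?")) {   # non-capturing "(?:"
            advance()
            if (!identical(advance(), ":")) fail("group modifier")
          }
          g <- gen_alternation()
          if (!identical(advance(), ")")) fail("unbalanced group")
          g
        } else if (ch == "[") {
          advance(); gen_class()
        } else if (ch == "\\") {
          advance(); gen_escape(advance())
        } else if (ch == ".") {
          advance(); function() pick(c(letters, as.character(0:9)))
        } else if (ch %in% c("+", "*", "?", "{", "}", "]", "^", "$")) {
          fail(sprintf("stray metacharacter '%s'", ch))
        } else {
          advance(); (function(lit) { force(lit); function() lit })(ch)
        }
      q <- read_quantifier()
      atoms[[length(atoms) + 1L]] <- if (is.null(q)) atom else {
        (function(a, lo, hi) {
          force(a); force(lo); force(hi)
          function() {
            reps <- lo + floor(stats::runif(1) * (hi - lo + 1L))
            paste(vapply(seq_len(reps), function(i) a(), character(1)), collapse = "")
          }
        })(atom, q[[1]], q[[2]])
      }
    }
    (function(as) { force(as); function() {
      paste(vapply(as, function(a) a(), character(1)), collapse = "")
    }})(atoms)
  }

  gen <- gen_alternation()
  if (pos <= n) fail("trailing input")
  out <- gen()
  if (!pattern_full_match(pattern, out)) {
    regkit_abort(sprintf("synthesized value '%s' does not satisfy pattern: %s",
                         out, pattern), "regkit_unsupported_pattern")
  }
  out
}

# ---- synthetic patients ----------------------------------------------------

#' Generate synthetic patient records for a bundle
#'
#' Draws one raw value per non-derived element of the bundle's registry:
#' integers and floats uniform inside their inclusive `[min, max]` (with
#' `[0, 100]` where no bounds are declared), dates uniform in a configured
#' epoch window, PVG-backed strings uniform over the permitted codes,
#' pattern strings synthesized from the pattern, free strings as random
#' alphanumerics, and file elements as small random payloads. Every value
#' passes [validate_value()] by construction.
#'
#' Randomness uses R's Mersenne-Twister stream exclusively (the kind is
#' set explicitly, not left to the session default), so a given seed
#' produces byte-identical records on every platform; the caller's RNG
#' state is restored afterwards.
#'
#' @param bundle A bundle from [build_demo_bundle()] (or any list with
#'   `registry`, `elements`, `pvgs`).
#' @param n Number of patients (`n = 0` gives an empty list).
#' @param seed Integer seed.
#' @param date_window Two dates bounding generated date values.
#' @return A list of records, each `list(patient_id, values, files)`:
#'   `values` maps element code to a raw value ready for [put_value()];
#'   `files` maps file-element codes to `list(filename, content)`.
#' @export
generate_patients <- function(bundle, n, seed = 1L,
                              date_window = as.Date(c("1940-01-01", "2010-12-31"))) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  pvg_lookup <- list()
  for (g in bundle$pvgs) pvg_lookup[[g$code]] <- g
  elements <- Filter(Negate(is_derived), bundle$elements)
  epoch <- as.integer(date_window)

  lapply(seq_len(n), function(i) {
    pid <- sprintf("p%03d", i)
    values <- list()
    files <- list()
    for (de in elements) {
      if (de$datatype == "file") {
        content <- as.raw(floor(stats::runif(16) * 256))
        files[[de$code]] <- list(filename = sprintf("%s_%s.bin", pid, de$code),
                                 content = content)
        next
      }
      values[[de$code]] <- switch(de$datatype,
        integer = {
          lo <- de$min %||% 0; hi <- de$max %||% 100
          floor(stats::runif(1, lo, hi + 1))
        },
        float = {
          lo <- de$min %||% 0; hi <- de$max %||% 100
          stats::runif(1, lo, hi)
        },
        date = as.Date(floor(stats::runif(1, epoch[1], epoch[2] + 1)),
                       origin = "1970-01-01"),
        string = {
          if (!is.null(de$pvg_code)) {
            g <- pvg_lookup[[de$pvg_code]]
            g$values$code[[floor(stats::runif(1) * nrow(g$values)) + 1L]]
          } else if (!is.null(de$pattern)) {
            pattern_synthesize(de$pattern)
          } else {
            paste(sample(c(letters, LETTERS, 0:9), 8, replace = TRUE),
                  collapse = "")
          }
        }
      )
    }
    list(patient_id = pid, values = values, files = files)
  })
}

#' Load generated patient records into an engine
#'
#' @param engine An engine holding the bundle's registry (for example
#'   [demo_engine()]).
#' @param registry_code Target registry.
#' @param patients Records from [generate_patients()].
#' @return The patient ids, invisibly.
#' @export
load_patients <- function(engine, registry_code, patients) {
  for (p in patients) {
    engine$add_patient(registry_code, p$patient_id)
    for (code in names(p$values)) {
      engine$put_value(registry_code, p$patient_id, code, p$values[[code]])
    }
    for (code in names(p$files)) {
      f <- p$files[[code]]
      engine$store_file(registry_code, p$patient_id, code, f$content,
                        filename = f$filename)
    }
  }
  invisible(vapply(patients, `[[`, character(1), "patient_id"))
}
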