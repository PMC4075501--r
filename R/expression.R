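#' @name expression-engine
#' @title Derived-element calculation expressions
#'
#' @description
#' Derived data elements are computed from other elements by a closed
#' arithmetic/conditional expression grammar rather than an embedded
#' scripting language: evaluating arbitrary scripts over patient data is a
#' sandboxing liability, and the documented use case (BMI-style arithmetic)
#' needs only arithmetic, comparisons and a conditional. The grammar is:
#'
#' * numeric literals and data-element code references,
#' * unary minus, binary `+ - * / ^`,
#' * comparisons `< <= > >= == !=`,
#' * `if (cond) a else b`.
#'
#' Precedence (tightest first): `^`, unary minus, `* /`, `+ -`,
#' comparisons, conditional; parentheses override. Evaluation is a pure
#' function of the supplied context: an expression can read nothing outside
#' it — no files, no store, no clock — and failures (missing input,
#' division by zero, non-numeric operand) yield the in-band
#' [not_computable()] sentinel rather than an error.
NULL

EXPR_BINOPS <- c("+", "-", "*", "/", "^")
EXPR_CMPOPS <- c("<", "<=", ">", ">=", "==", "!=")

#' Parse calculation expression text
#'
#' @param text Expression source, e.g. `"Weight / (Height * Height)"`.
#' @return An object of class `regkit_expression` holding the syntax tree
#'   and the original `source_text`.
#' @examples
#' e <- expr_parse("Weight / (Height * Height)")
#' expr_refs(e)
#' expr_eval(e, list(Height = 1.8, Weight = 81))
#' @export
expr_parse <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) {
    regkit_abort("expression text must be a non-empty string", "regkit_expr_syntax")
  }
  lang <- tryCatch(
    str2lang(text),
    error = function(e) {
      regkit_abort(sprintf("syntax error in expression %s: %s",
                           deparse(text), conditionMessage(e)),
                   "regkit_expr_syntax")
    }
  )
  structure(list(tree = lang_to_node(lang), source_text = text),
            class = "regkit_expression")
}

# Convert an R language object into the package's own closed AST. Anything
# outside the whitelist (function calls, subsetting, assignment, ...) is
# rejected, so the evaluator below can never touch the host environment.
lang_to_node <- function(x) {
  if (is.numeric(x) && length(x) == 1L && !is.na(x)) {
    return(list(kind = "num", value = as.numeric(x)))
  }
  if (is.symbol(x)) {
    code <- as.character(x)
    if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", code)) {
      regkit_abort(sprintf("invalid data element code in expression: '%s'", code),
                   "regkit_expr_syntax")
    }
    return(list(kind = "ref", code = code))
  }
  if (is.call(x)) {
    head <- x[[1]]
    if (!is.symbol(head)) {
      regkit_abort("disallowed construct in expression", "regkit_expr_syntax")
    }
    op <- as.character(head)
    if (op == "(") return(lang_to_node(x[[2]]))
    if (op == "-" && length(x) == 2L) {
      return(list(kind = "unary", op = "-", operand = lang_to_node(x[[2]])))
    }
    if (op == "+" && length(x) == 2L) return(lang_to_node(x[[2]]))
    if (op %in% EXPR_BINOPS && length(x) == 3L) {
      return(list(kind = "binop", op = op,
                  lhs = lang_to_node(x[[2]]), rhs = lang_to_node(x[[3]])))
    }
    if (op %in% EXPR_CMPOPS && length(x) == 3L) {
      return(list(kind = "cmp", op = op,
                  lhs = lang_to_node(x[[2]]), rhs = lang_to_node(x[[3]])))
    }
    if (op == "if") {
      if (length(x) < 4L) {
        regkit_abort("conditional expression requires an else branch", "regkit_expr_syntax")
      }
      return(list(kind = "if", cond = lang_to_node(x[[2]]),
                  yes = lang_to_node(x[[3]]), no = lang_to_node(x[[4]])))
    }
    regkit_abort(sprintf("disallowed construct '%s' in expression", op),
                 "regkit_expr_syntax")
  }
  regkit_abort("unsupported element in expression", "regkit_expr_syntax")
}

#' Data-element codes referenced by an expression
#'
#' @param expr A parsed expression.
#' @return Sorted character vector of the distinct codes appearing as
#'   leaves (set semantics: `a + a` references `a` once).
#' @export
expr_refs <- function(expr) {
  stopifnot(inherits(expr, "regkit_expression"))
  sort(unique(collect_refs(expr$tree)))
}

collect_refs <- function(node) {
  switch(node$kind,
    num   = character(),
    ref   = node$code,
    unary = collect_refs(node$operand),
    binop = c(collect_refs(node$lhs), collect_refs(node$rhs)),
    cmp   = c(collect_refs(node$lhs), collect_refs(node$rhs)),
    `if`  = c(collect_refs(node$cond), collect_refs(node$yes), collect_refs(node$no))
  )
}

#' Evaluate an expression over a patient's current values
#'
#' @param expr A parsed expression.
#' @param ctx Evaluation context: a named list mapping data-element code to
#'   a numeric scalar or a typed value. Values of non-numeric datatypes
#'   make any reference to them `NOT_COMPUTABLE`.
#' @return A numeric scalar (comparisons at top level yield 1/0), or a
#'   [not_computable()] sentinel when an input is missing or an arithmetic
#'   error occurs.
#' @export
expr_eval <- function(expr, ctx = list()) {
  stopifnot(inherits(expr, "regkit_expression"))
  out <- eval_node(expr$tree, ctx)
  if (is_not_computable(out)) return(out)
  if (is.logical(out)) out <- as.numeric(out)
  if (!is.finite(out)) return(not_computable("arithmetic overflow or undefined result"))
  out
}

ctx_numeric <- function(ctx, code) {
  if (!code %in% names(ctx)) {
    return(not_computable(sprintf("missing input '%s'", code)))
  }
  v <- ctx[[code]]
  if (is_typed_value(v)) v <- v$value
  if (!is_num_scalar(v)) {
    return(not_computable(sprintf("input '%s' is not numeric", code)))
  }
  as.numeric(v)
}

eval_node <- function(node, ctx) {
  switch(node$kind,
    num = node$value,
    ref = ctx_numeric(ctx, node$code),
    unary = {
      v <- eval_node(node$operand, ctx)
      if (is_not_computable(v)) v else -as_number(v)
    },
    binop = {
      a <- eval_node(node$lhs, ctx)
      if (is_not_computable(a)) return(a)
      b <- eval_node(node$rhs, ctx)
      if (is_not_computable(b)) return(b)
      a <- as_number(a); b <- as_number(b)
      if (node$op == "/" && b == 0) return(not_computable("division by zero"))
      r <- switch(node$op, `+` = a + b, `-` = a - b, `*` = a * b, `/` = a / b, `^` = a ^ b)
      if (is.na(r) || is.nan(r)) return(not_computable("undefined arithmetic result"))
      r
    },
    cmp = {
      a <- eval_node(node$lhs, ctx)
      if (is_not_computable(a)) return(a)
      b <- eval_node(node$rhs, ctx)
      if (is_not_computable(b)) return(b)
      a <- as_number(a); b <- as_number(b)
      switch(node$op, `<` = a < b, `<=` = a <= b, `>` = a > b,
             `>=` = a >= b, `==` = a == b, `!=` = a != b)
    },
    `if` = {
      cond <- eval_node(node$cond, ctx)
      if (is_not_computable(cond)) return(cond)
      if (isTRUE(cond) || (is.numeric(cond) && cond != 0)) {
        eval_node(node$yes, ctx)
      } else {
        eval_node(node$no, ctx)
      }
    }
  )
}

as_number <- function(x) if (is.logical(x)) as.numeric(x) else x

#' Print an expression back to canonical source text
#'
#' Inserts only the parentheses precedence requires, so
#' `expr_parse(expr_print(e))` is structurally identical to `e`.
#'
#' @param expr A parsed expression.
#' @return A single string.
#' @export
expr_print <- function(expr) {
  stopifnot(inherits(expr, "regkit_expression"))
  print_node(expr$tree, 0L)
}

#' @export
format.regkit_expression <- function(x, ...) expr_print(x)

#' @export
print.regkit_expression <- function(x, ...) {
  cat("<expression ", expr_print(x), ">\n", sep = "")
  invisible(x)
}

node_prec <- function(node) {
  switch(node$kind,
    num = 7L, ref = 7L,
    `if` = 1L, cmp = 2L,
    binop = if (node$op %in% c("+", "-")) 3L else if (node$op %in% c("*", "/")) 4L else 6L,
    unary = 5L
  )
}

print_node <- function(node, min_prec) {
  p <- node_prec(node)
  txt <- switch(node$kind,
    num = format(node$value, digits = 17, scientific = FALSE),
    ref = node$code,
    unary = paste0("-", print_node(node$operand, p)),
    binop = {
      # left-assoc for + - * /; ^ is right-assoc
      if (node$op == "^") {
        paste0(print_node(node$lhs, p + 1L), " ^ ", print_node(node$rhs, p))
      } else {
        paste0(print_node(node$lhs, p), " ", node$op, " ", print_node(node$rhs, p + 1L))
      }
    },
    cmp = paste0(print_node(node$lhs, p + 1L), " ", node$op, " ",
                 print_node(node$rhs, p + 1L)),
    `if` = paste0("if (", print_node(node$cond, 0L), ") ",
                  print_node(node$yes, 2L), " else ", print_node(node$no, 2L))
  )
  if (p < min_prec) paste0("(", txt, ")") else txt
}
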