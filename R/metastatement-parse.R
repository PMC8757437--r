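# Metastatement grammar and parser.
#
# A metastatement is a single expression over metadata names, literals and
# built-in functions, evaluated once per record against the whole ensemble.
# Grammar (loosest to tightest binding):
#
#   or      := and  ( '|' and )*
#   and     := cmp  ( '&' cmp )*
#   cmp     := add  ( CMP add )?          CMP: < <= > >= = != (and the
#                                         glyphs <U+2264> <U+2265> <U+2260>, == as =)
#   add     := mul  ( ('+'|'-') mul )*
#   mul     := unary ( ('*'|'/') unary )*
#   unary   := '-' unary | postfix
#   postfix := primary ( '{' '}'                    key extraction
#                      | '(' CMP add ')'            value slice
#                      | '(' or ')' )*              key indexing
#   primary := NUMBER | STRING | NAME | BUILTIN '(' args ')' | '(' or ')'
#
# NAME is [A-Za-z_][A-Za-z0-9_]*; metadata whose names contain other
# characters are referenced in quoted form "name". A quoted token that does
# not resolve as metadata on a record is a string literal there. `name(...)`
# is a function call only when `name` is a registered builtin; otherwise the
# parentheses slice or index the metadata value.

BUILTIN_NAMES <- c("max", "min", "avg", "sum", "mmax", "mmin", "mavg", "msum",
                   "mrank", "mcount", "log10", "ln", "abs", "pow", "sqrt",
                   "confcol", "dist")
BUILTIN_ARITY <- c(max = 1L, min = 1L, avg = 1L, sum = 1L,
                   mmax = 1L, mmin = 1L, mavg = 1L, msum = 1L,
                   mrank = 1L, mcount = 0L, log10 = 1L, ln = 1L, abs = 1L,
                   pow = 2L, sqrt = 1L, confcol = 1L, dist = 3L)

# comparator glyph normalization: ASCII digraphs and Unicode glyphs
CMP_CANON <- c("<=" = "<=", ">=" = ">=", "==" = "=", "!=" = "!=",
               "≤" = "<=", "≥" = ">=", "≠" = "!=",
               "<" = "<", ">" = ">", "=" = "=")

tokenize_statement <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    start <- i
    if (ch == '"') {
      j <- i + 1L
      while (j <= n && chars[j] != '"') j <- j + 1L
      if (j > n) stop(sprintf("metastatement syntax error at character %d: unterminated string", start))
      push("STRING", paste(chars[(i + 1L):(j - 1L)][seq_len(max(0L, j - i - 1L))], collapse = ""), start)
      i <- j + 1L
    } else if (grepl("[0-9.]", ch) &&
               (grepl("[0-9]", ch) || (i < n && grepl("[0-9]", chars[i + 1L])))) {
      j <- i
      while (j <= n && grepl("[0-9.]", chars[j])) j <- j + 1L
      if (j <= n && grepl("[eE]", chars[j]) &&
          (j < n && grepl("[0-9+-]", chars[j + 1L]))) {
        j <- j + 1L
        if (grepl("[+-]", chars[j])) j <- j + 1L
        while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      }
      push("NUMBER", paste(chars[i:(j - 1L)], collapse = ""), start)
      i <- j
    } else if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[j])) j <- j + 1L
      push("NAME", paste(chars[i:(j - 1L)], collapse = ""), start)
      i <- j
    } else if (ch %in% c("<", ">", "=", "!")) {
      if (i < n && chars[i + 1L] == "=") {
        push("CMP", CMP_CANON[[paste0(ch, "=")]], start); i <- i + 2L
      } else if (ch == "!") {
        stop(sprintf("metastatement syntax error at character %d: '!' must be '!='", start))
      } else {
        push("CMP", ch, start); i <- i + 1L
      }
    } else if (ch %in% c("≤", "≥", "≠")) {
      push("CMP", CMP_CANON[[ch]], start); i <- i + 1L
    } else if (ch %in% c("+", "-", "*", "/", "&", "|")) {
      push("OP", ch, start); i <- i + 1L
    } else if (ch == "−") {                       # Unicode minus sign
      push("OP", "-", start); i <- i + 1L
    } else if (ch %in% c("(", ")", "{", "}", ",")) {
      push("PUNCT", ch, start); i <- i + 1L
    } else {
      stop(sprintf("metastatement syntax error at character %d: unexpected '%s'", start, ch))
    }
  }
  toks
}

#' Parse a metastatement
#'
#' @param text the statement, e.g. `"TOTAL_SCORE/mmax(TOTAL_SCORE)"` or
#'   `"glutadist(<=2.5)"`
#' @return the statement's syntax tree (class `metastatement`)
#' @export
parse_statement <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("metastatement must be a non-empty string")
  toks <- tokenize_statement(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  node <- ms_parse_or(st)
  if (st$pos <= length(st$toks)) {
    t <- st$toks[[st$pos]]
    stop(sprintf("metastatement syntax error at character %d: unexpected '%s'", t$pos, t$value))
  }
  class(node) <- c("metastatement", "list")
  node
}

ms_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
ms_next <- function(st) { t <- ms_peek(st); st$pos <- st$pos + 1L; t }
ms_expect <- function(st, type, value = NULL) {
  t <- ms_peek(st)
  if (is.null(t) || t$type != type || (!is.null(value) && t$value != value))
    stop(sprintf("metastatement syntax error%s: expected %s",
                 if (is.null(t)) " at end of statement" else sprintf(" at character %d", t$pos),
                 if (is.null(value)) type else paste0("'", value, "'")))
  ms_next(st)
}
ms_at <- function(st, type, value = NULL) {
  t <- ms_peek(st)
  !is.null(t) && t$type == type && (is.null(value) || t$value %in% value)
}

ms_parse_or <- function(st) {
  node <- ms_parse_and(st)
  while (ms_at(st, "OP", "|")) {
    ms_next(st)
    node <- list(kind = "binop", op = "|", lhs = node, rhs = ms_parse_and(st))
  }
  node
}
ms_parse_and <- function(st) {
  node <- ms_parse_cmp(st)
  while (ms_at(st, "OP", "&")) {
    ms_next(st)
    node <- list(kind = "binop", op = "&", lhs = node, rhs = ms_parse_cmp(st))
  }
  node
}
ms_parse_cmp <- function(st) {
  node <- ms_parse_add(st)
  if (ms_at(st, "CMP")) {
    op <- ms_next(st)$value
    node <- list(kind = "binop", op = op, lhs = node, rhs = ms_parse_add(st))
  }
  node
}
ms_parse_add <- function(st) {
  node <- ms_parse_mul(st)
  while (ms_at(st, "OP", c("+", "-"))) {
    op <- ms_next(st)$value
    node <- list(kind = "binop", op = op, lhs = node, rhs = ms_parse_mul(st))
  }
  node
}
ms_parse_mul <- function(st) {
  node <- ms_parse_unary(st)
  while (ms_at(st, "OP", c("*", "/"))) {
    op <- ms_next(st)$value
    node <- list(kind = "binop", op = op, lhs = node, rhs = ms_parse_unary(st))
  }
  node
}
ms_parse_unary <- function(st) {
  if (ms_at(st, "OP", "-")) {
    ms_next(st)
    return(list(kind = "neg", x = ms_parse_unary(st)))
  }
  ms_parse_postfix(st)
}

ms_parse_postfix <- function(st) {
  node <- ms_parse_primary(st)
  repeat {
    if (ms_at(st, "PUNCT", "{")) {
      ms_next(st)
      ms_expect(st, "PUNCT", "}")
      node <- list(kind = "key_extract", x = node)
    } else if (ms_at(st, "PUNCT", "(") && node$kind %in% c("ref", "quoted_ref", "key_extract", "key_index", "slice")) {
      ms_next(st)
      if (ms_at(st, "CMP")) {
        op <- ms_next(st)$value
        thr <- ms_parse_add(st)
        # a bare name as slice threshold (e.g. `close_types(=O)`) resolves
        # meta-first, then as a literal, like the quoted form
        if (identical(thr$kind, "ref")) thr$kind <- "quoted_ref"
        ms_expect(st, "PUNCT", ")")
        node <- list(kind = "slice", x = node, cmp = op, threshold = thr)
      } else {
        keys <- ms_parse_or(st)
        ms_expect(st, "PUNCT", ")")
        node <- list(kind = "key_index", x = node, keys = keys)
      }
    } else break
  }
  node
}

ms_parse_primary <- function(st) {
  t <- ms_peek(st)
  if (is.null(t)) stop("metastatement syntax error: unexpected end of statement")
  if (t$type == "NUMBER") {
    ms_next(st)
    return(list(kind = "num", value = coerce_scalar(t$value)))
  }
  if (t$type == "STRING") {
    ms_next(st)
    return(list(kind = "quoted_ref", name = t$value))
  }
  if (t$type == "NAME") {
    ms_next(st)
    if (t$value %in% BUILTIN_NAMES && ms_at(st, "PUNCT", "(")) {
      ms_next(st)
      args <- list()
      if (!ms_at(st, "PUNCT", ")")) {
        repeat {
          args[[length(args) + 1L]] <- ms_parse_or(st)
          if (ms_at(st, "PUNCT", ",")) ms_next(st) else break
        }
      }
      ms_expect(st, "PUNCT", ")")
      if (length(args) != BUILTIN_ARITY[[t$value]])
        stop(sprintf("builtin %s() takes %d argument(s), got %d",
                     t$value, BUILTIN_ARITY[[t$value]], length(args)))
      return(list(kind = "call", fun = t$value, args = args))
    }
    return(list(kind = "ref", name = t$value))
  }
  if (t$type == "PUNCT" && t$value == "(") {
    ms_next(st)
    node <- ms_parse_or(st)
    ms_expect(st, "PUNCT", ")")
    return(node)
  }
  stop(sprintf("metastatement syntax error at character %d: unexpected '%s'", t$pos, t$value))
}

#' Render a parsed metastatement back to text
#'
#' `parse_statement(unparse_statement(ast))` reproduces the tree.
#'
#' @param node a parsed metastatement
#' @return a single string
#' @export
unparse_statement <- function(node) {
  u <- unparse_node(node)
  u
}

unparse_node <- function(node) {
  switch(node$kind,
    num = scalar_to_str(node$value),
    quoted_ref = sprintf('"%s"', node$name),
    ref = node$name,
    neg = sprintf("(-%s)", unparse_node(node$x)),
    binop = sprintf("(%s %s %s)", unparse_node(node$lhs), node$op, unparse_node(node$rhs)),
    call = sprintf("%s(%s)", node$fun,
                   paste(vapply(node$args, unparse_node, character(1)), collapse = ", ")),
    slice = sprintf("%s(%s%s)", unparse_node(node$x), node$cmp, unparse_node(node$threshold)),
    key_extract = sprintf("%s{}", unparse_node(node$x)),
    key_index = sprintf("%s(%s)", unparse_node(node$x), unparse_node(node$keys)),
    stop(sprintf("unknown node kind '%s'", node$kind))
  )
}

#' @export
print.metastatement <- function(x, ...) {
  cat("metastatement:", unparse_statement(x), "\n")
  invisible(x)
}
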