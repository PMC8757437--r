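# Metastatement evaluation.
#
# A statement is evaluated for the whole ensemble at once: every node
# yields one result per record (a meta_value or ABSENT). Aggregate
# builtins therefore see the full column of their argument; the unprefixed
# aggregates (max, min, avg, sum) reduce over the whole file, the
# m-prefixed ones (mmax, ...) over each record's molecule group. ABSENT
# propagates: with the single exception of `|`, any ABSENT sub-result
# makes the record's result ABSENT.

#' Evaluate a metastatement against an ensemble
#'
#' @param statement a statement string or a tree from [parse_statement()]
#' @param ens an `sdf_ensemble`
#' @param ignore element symbols excluded from atom-wise builtins
#'   (`dist`); default hydrogens
#' @return a list with one element per record: an anonymous `meta_value`,
#'   or `ABSENT` where the statement has no value
#' @export
evaluate_statement <- function(statement, ens, ignore = c("H")) {
  node <- if (inherits(statement, "metastatement") || (is.list(statement) && !is.null(statement$kind)))
    statement else parse_statement(statement)
  env <- list(ens = ens, ignore = ignore,
              group_of = group_index_of(ens))
  eval_node(node, env)
}

group_index_of <- function(ens) {
  keys <- group_keys(ens)
  match(keys, unique(keys))
}

eval_node <- function(node, env) {
  nrec <- length(env$ens$records)
  switch(node$kind,
    num = rep(list(meta_value(node$value)), nrec),
    ref = lapply(env$ens$records, function(r) {
      mv <- r$meta[[node$name]]
      if (is.null(mv)) ABSENT else mv
    }),
    quoted_ref = lapply(env$ens$records, function(r) {
      mv <- r$meta[[node$name]]
      if (is.null(mv)) meta_value(node$name) else mv
    }),
    neg = lapply(eval_node(node$x, env), negate_value),
    binop = eval_binop(node, env),
    call = eval_call(node, env),
    slice = {
      xs <- eval_node(node$x, env)
      ths <- eval_node(node$threshold, env)
      mapply(function(x, th) {
        if (is_absent(x) || is_absent(th)) return(ABSENT)
        if (th$structure != "single") return(ABSENT)
        slice_by_value(x, node$cmp, th$payload)
      }, xs, ths, SIMPLIFY = FALSE)
    },
    key_extract = lapply(eval_node(node$x, env), key_extract),
    key_index = {
      xs <- eval_node(node$x, env)
      ks <- eval_node(node$keys, env)
      mapply(key_index, xs, ks, SIMPLIFY = FALSE)
    },
    stop(sprintf("unknown node kind '%s'", node$kind))
  )
}

negate_value <- function(x) {
  if (is_absent(x)) return(ABSENT)
  if (!is_numeric_meta(x)) {
    warning("unary minus on a string value yields ABSENT")
    return(ABSENT)
  }
  meta_value(-x$payload, x$structure, keys = x$keys)
}

# ---- binary operators ---------------------------------------------------

eval_binop <- function(node, env) {
  ls <- eval_node(node$lhs, env)
  rs <- eval_node(node$rhs, env)
  op <- node$op
  if (op == "&") {
    return(mapply(function(a, b) {
      if (is_absent(a) || is_absent(b)) ABSENT else meta_value(1L)
    }, ls, rs, SIMPLIFY = FALSE))
  }
  if (op == "|") {
    return(mapply(function(a, b) {
      if (is_absent(a) && is_absent(b)) ABSENT else meta_value(1L)
    }, ls, rs, SIMPLIFY = FALSE))
  }
  if (op %in% names(CMP_CANON)) {
    return(mapply(function(a, b) {
      if (is_absent(a) || is_absent(b)) return(ABSENT)
      if (b$structure != "single") return(ABSENT)
      slice_by_value(a, op, b$payload)
    }, ls, rs, SIMPLIFY = FALSE))
  }
  mapply(function(a, b) combine_values(a, b, op), ls, rs, SIMPLIFY = FALSE)
}

# Arithmetic with structure lifting: scalars broadcast over lists and
# dicts; dict-dict joins on common keys (inner join); list-list requires
# equal lengths. String `+` concatenates, string `-` removes a regular
# expression; any other op involving a string is ABSENT.
combine_values <- function(a, b, op) {
  if (is_absent(a) || is_absent(b)) return(ABSENT)
  a_str <- a$dtype == "string"; b_str <- b$dtype == "string"
  if (a_str || b_str) {
    if (!(a_str && b_str)) {
      warning(sprintf("'%s' between string and number yields ABSENT", op))
      return(ABSENT)
    }
    if (op == "+") return(lift_binary(a, b, function(x, y) paste0(x, y)))
    if (op == "-") return(lift_binary(a, b, function(x, y) regex_subtract(x, y)))
    warning(sprintf("'%s' on strings yields ABSENT", op))
    return(ABSENT)
  }
  fun <- switch(op,
    "+" = `+`, "-" = `-`, "*" = `*`,
    "/" = function(x, y) { if (any(y == 0)) NULL else x / y },
    "^" = `^`,
    stop(sprintf("unknown operator '%s'", op)))
  int_result <- a$dtype == "int" && b$dtype == "int" && op %in% c("+", "-", "*")
  lift_binary(a, b, fun, int_result = int_result)
}

# Apply f elementwise under the lifting rules; f returning NULL (division
# by zero) makes the record ABSENT.
lift_binary <- function(a, b, f, int_result = FALSE) {
  post <- function(v, structure, keys = NULL) {
    if (is.null(v)) return(ABSENT)
    if (int_result) v <- as.integer(v)
    if (length(v) == 0L) return(ABSENT)
    meta_value(v, structure, keys = keys)
  }
  if (a$structure == "single" && b$structure == "single")
    return(post(f(a$payload, b$payload), "single"))
  if (a$structure == "dict" && b$structure == "single")
    return(post(f(a$payload, rep(b$payload, length(a$payload))), "dict", a$keys))
  if (a$structure == "single" && b$structure == "dict")
    return(post(f(rep(a$payload, length(b$payload)), b$payload), "dict", b$keys))
  if (a$structure == "dict" && b$structure == "dict") {
    common <- intersect(as.character(a$keys), as.character(b$keys))
    if (length(common) == 0L) return(ABSENT)
    ia <- match(common, as.character(a$keys))
    ib <- match(common, as.character(b$keys))
    return(post(f(a$payload[ia], b$payload[ib]), "dict", a$keys[ia]))
  }
  if (a$structure == "list" && b$structure == "single")
    return(post(f(a$payload, rep(b$payload, length(a$payload))), "list"))
  if (a$structure == "single" && b$structure == "list")
    return(post(f(rep(a$payload, length(b$payload)), b$payload), "list"))
  if (a$structure == "list" && b$structure == "list") {
    if (length(a$payload) != length(b$payload)) {
      warning("list-list arithmetic needs equal lengths; yields ABSENT")
      return(ABSENT)
    }
    return(post(f(a$payload, b$payload), "list"))
  }
  warning("dict-list arithmetic is undefined; yields ABSENT")
  ABSENT
}

# ---- slicing, key extraction, key indexing ------------------------------

#' Slice a metadata value by comparison with a threshold
#'
#' Dictionaries keep the entries whose values pass, lists the passing
#' elements, and a single value passes or becomes ABSENT. An empty result
#' is ABSENT. Ordering comparators need numeric values; `=` and `!=` also
#' compare strings. Float equality uses a relative tolerance of 1e-9,
#' integer equality is exact.
#'
#' @param val a `meta_value`
#' @param cmp one of `<`, `<=`, `>`, `>=`, `=`, `!=` (Unicode glyphs are
#'   accepted)
#' @param threshold a scalar
#' @return the sliced `meta_value`, or `ABSENT`
#' @export
slice_by_value <- function(val, cmp, threshold) {
  if (is_absent(val)) return(ABSENT)
  cmp <- CMP_CANON[[cmp]]
  if (is.null(cmp)) stop("unknown comparator")
  v <- val$payload
  if (val$dtype == "string" || is.character(threshold)) {
    if (!(cmp %in% c("=", "!="))) return(ABSENT)
    pass <- if (cmp == "=") as.character(v) == as.character(threshold)
            else as.character(v) != as.character(threshold)
  } else if (cmp %in% c("=", "!=")) {
    eq <- if (val$dtype == "int" && is.numeric(threshold) && threshold == floor(threshold))
      v == threshold
    else abs(v - threshold) <= 1e-9 * pmax(abs(v), abs(threshold), 1e-300)
    pass <- if (cmp == "=") eq else !eq
  } else {
    pass <- switch(cmp, "<" = v < threshold, "<=" = v <= threshold,
                   ">" = v > threshold, ">=" = v >= threshold)
  }
  pass[is.na(pass)] <- FALSE
  if (!any(pass)) return(ABSENT)
  if (val$structure == "single") return(meta_value(v, "single"))
  if (val$structure == "dict")
    return(meta_value(v[pass], "dict", keys = val$keys[pass]))
  meta_value(v[pass], "list")
}

#' Extract the keys of a dictionary value
#'
#' @param val a dict `meta_value`
#' @return a list `meta_value` of the keys (values discarded), or `ABSENT`
#'   with a warning for non-dict input
#' @export
key_extract <- function(val) {
  if (is_absent(val)) return(ABSENT)
  if (val$structure != "dict") {
    warning("key extraction '{}' on a non-dictionary value yields ABSENT")
    return(ABSENT)
  }
  meta_value(val$keys, "list")
}

#' Restrict a dictionary to a set of keys
#'
#' @param source a dict `meta_value`
#' @param keys a list (or single) of keys, or a dict whose keys are used;
#'   keys missing from `source` are silently skipped
#' @return the sub-dictionary, or `ABSENT` when nothing matches
#' @export
key_index <- function(source, keys) {
  if (is_absent(source) || is_absent(keys)) return(ABSENT)
  if (source$structure != "dict") {
    warning("key indexing on a non-dictionary value yields ABSENT")
    return(ABSENT)
  }
  want <- if (keys$structure == "dict") keys$keys else keys$payload
  idx <- match(as.character(want), as.character(source$keys))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(ABSENT)
  meta_value(source$payload[idx], "dict", keys = source$keys[idx])
}

#' Remove every match of a regular expression from a string
#'
#' String subtraction in metastatements: `s - pattern` removes all
#' non-overlapping matches of `pattern` (PCRE) from `s`.
#'
#' @param s character vector
#' @param pattern a regular expression
#' @return `s` with matches removed
#' @export
regex_subtract <- function(s, pattern) {
  ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("invalid regular expression in string subtraction: '%s'", pattern))
  gsub(pattern, "", s, perl = TRUE)
}

# ---- builtin calls ------------------------------------------------------

eval_call <- function(node, env) {
  fun <- node$fun
  nrec <- length(env$ens$records)
  if (fun %in% c("max", "min", "avg", "sum", "mmax", "mmin", "mavg", "msum"))
    return(eval_aggregate(fun, eval_node(node$args[[1]], env), env))
  if (fun == "mcount")
    return(lapply(env$group_of, function(g) meta_value(sum(env$group_of == g))))
  if (fun == "mrank")
    return(eval_mrank(eval_node(node$args[[1]], env), env))
  if (fun %in% c("log10", "ln", "abs", "sqrt"))
    return(lapply(eval_node(node$args[[1]], env), apply_math, fun = fun))
  if (fun == "pow") {
    as_ <- eval_node(node$args[[1]], env)
    bs <- eval_node(node$args[[2]], env)
    return(mapply(function(a, b) {
      if (is_absent(a) || is_absent(b)) return(ABSENT)
      if (!is_numeric_meta(a) || !is_numeric_meta(b)) return(ABSENT)
      combine_values(a, b, "^")
    }, as_, bs, SIMPLIFY = FALSE))
  }
  if (fun == "confcol") {
    coln <- node$args[[1]]
    if (!(coln$kind == "num" && coln$value == floor(coln$value)))
      stop("confcol() takes a literal integer column number")
    return(lapply(env$ens$records, builtin_confcol, col = as.integer(coln$value)))
  }
  if (fun == "dist") {
    pt <- vapply(node$args, function(a) {
      v <- if (a$kind == "num") a$value
           else if (a$kind == "neg" && a$x$kind == "num") -a$x$value
           else stop("dist() takes literal x, y, z coordinates")
      as.numeric(v)
    }, numeric(1))
    return(lapply(env$ens$records, function(r)
      distances_to_point(r, pt, ignore = env$ignore)))
  }
  stop(sprintf("unknown builtin '%s'", fun))
}

# Reduce a per-record value to a single number for aggregation: dicts and
# lists are first reduced with the aggregate's own statistic.
reduce_record_value <- function(x, stat) {
  if (is_absent(x)) return(NA_real_)
  if (!is_numeric_meta(x)) return(NA_real_)
  stat(as.numeric(x$payload))
}

eval_aggregate <- function(fun, args, env) {
  grouped <- fun %in% c("mmax", "mmin", "mavg", "msum")
  base <- if (grouped) substring(fun, 2L) else fun
  stat <- switch(base, max = max, min = min, avg = mean, sum = sum)
  per_rec <- vapply(args, reduce_record_value, numeric(1), stat = stat)
  int_in <- all(vapply(args, function(a) is_absent(a) || a$dtype == "int", logical(1))) &&
    base != "avg"
  scope <- if (grouped) env$group_of else rep(1L, length(args))
  out <- vector("list", length(args))
  for (g in unique(scope)) {
    sel <- which(scope == g)
    vals <- per_rec[sel]
    vals <- vals[!is.na(vals)]
    res <- if (length(vals) == 0L) ABSENT
           else meta_value(if (int_in) as.integer(stat(vals)) else stat(vals))
    for (i in sel) out[[i]] <- res
  }
  out
}

eval_mrank <- function(args, env) {
  vals <- vapply(args, function(a) {
    if (is_absent(a) || !is_numeric_meta(a) || a$structure != "single") NA_real_
    else as.numeric(a$payload)
  }, numeric(1))
  confs <- conf_numbers(env$ens)
  out <- rep(list(ABSENT), length(args))
  for (g in unique(env$group_of)) {
    sel <- which(env$group_of == g & !is.na(vals))
    if (length(sel) == 0L) next
    ord <- sel[order(vals[sel], confs[sel])]
    for (k in seq_along(ord)) out[[ord[k]]] <- meta_value(as.integer(k))
  }
  out
}

apply_math <- function(x, fun) {
  if (is_absent(x)) return(ABSENT)
  if (!is_numeric_meta(x)) return(ABSENT)
  v <- as.numeric(x$payload)
  res <- switch(fun,
    log10 = if (any(v <= 0)) NULL else log10(v),
    ln = if (any(v <= 0)) NULL else log(v),
    abs = abs(v),
    sqrt = if (any(v < 0)) NULL else sqrt(v))
  if (is.null(res)) return(ABSENT)
  if (fun == "abs" && x$dtype == "int") res <- as.integer(res)
  meta_value(res, x$structure, keys = x$keys)
}

#' Atom-block column lookup (`confcol` builtin)
#'
#' Returns, for one record, a dictionary mapping atom number to the value
#' in whitespace-delimited column `col` of its V2000 atom lines: columns
#' 1-3 are the x, y, z coordinates and column 4 the element symbol.
#'
#' @param rec a conformation record
#' @param col 1-based column number
#' @return a dict `meta_value` keyed by atom number
#' @export
builtin_confcol <- function(rec, col) {
  lines <- rec$molfile$atom_lines
  if (length(lines) == 0L) return(ABSENT)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- min(lengths(fields))
  if (col < 1L || col > nf)
    stop(sprintf("confcol(%d): atom lines have only %d columns", col, nf))
  vals <- vapply(fields, `[[`, character(1), col)
  meta_value(coerce_vector(vals), "dict", keys = seq_along(lines))
}
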