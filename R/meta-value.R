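# MetaValue: the typed value carried by an SDF data item (extended notation).
#
# A value is one of three structures -- single, list, dictionary -- and one of
# three scalar types -- int, float, string. Dictionaries keep an ordered
# key vector alongside the payload; keys are atom numbers when produced
# internally (distances, atom columns) but may be arbitrary scalars when
# imported. A value is never empty: absence of data is modelled by the
# ABSENT sentinel, not by an empty payload.

#' Construct a metadata value
#'
#' @param payload atomic vector: the value(s). Integer payloads give dtype
#'   `"int"`, doubles `"float"`, character `"string"`.
#' @param structure one of `"single"`, `"list"`, `"dict"`. Defaults to
#'   `"single"` for length-1 payloads without keys, `"list"` otherwise.
#' @param keys for dictionaries, an atomic vector of unique keys, same
#'   length as `payload`.
#' @param name optional data-item name; anonymous values (metastatement
#'   results) have none.
#' @return an object of class `meta_value`.
#' @export
meta_value <- function(payload, structure = NULL, keys = NULL, name = NULL) {
  if (length(payload) == 0L)
    stop("meta_value payload must not be empty: there is no metadata if there is no value")
  if (is.logical(payload)) payload <- as.integer(payload)
  if (!is.atomic(payload)) stop("payload must be an atomic vector")
  if (is.null(structure)) {
    structure <- if (!is.null(keys)) "dict" else if (length(payload) == 1L) "single" else "list"
  }
  structure <- match.arg(structure, c("single", "list", "dict"))
  if (structure == "dict") {
    if (is.null(keys) || length(keys) != length(payload))
      stop("dict meta_value needs keys matching payload length")
    if (anyDuplicated(keys)) stop("dict keys must be unique")
  } else {
    keys <- NULL
    if (structure == "single" && length(payload) != 1L)
      stop("single meta_value must have exactly one value")
  }
  dtype <- if (is.integer(payload)) "int" else if (is.double(payload)) "float" else "string"
  out <- list(name = name, structure = structure, dtype = dtype,
              payload = payload, keys = keys)
  class(out) <- "meta_value"
  out
}

#' The marker for a value-less metastatement result
#'
#' Any record for which a statement has no value (missing metadata, empty
#' slice, invalid arithmetic) evaluates to `ABSENT`; the record then simply
#' carries no result.
#' @export
ABSENT <- structure(list(), class = "meta_absent")

#' Test for the ABSENT marker
#' @param x object to test
#' @export
is_absent <- function(x) inherits(x, "meta_absent")

#' @export
print.meta_absent <- function(x, ...) { cat("<ABSENT>\n"); invisible(x) }

#' @export
print.meta_value <- function(x, ...) {
  nm <- if (is.null(x$name)) "<anonymous>" else x$name
  cat(sprintf("meta_value %s [%s of %s]\n", nm, x$structure, x$dtype))
  if (x$structure == "dict") {
    cat(" ", paste(paste0(x$keys, ":", scalar_to_str(x$payload)), collapse = " "), "\n")
  } else {
    cat(" ", paste(scalar_to_str(x$payload), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
format.meta_value <- function(x, ...) serialize_meta_body(x)

is_numeric_meta <- function(x) !is_absent(x) && x$dtype %in% c("int", "float")

# ---- scalar coercion ---------------------------------------------------

#' Coerce a token to its natural scalar type
#'
#' Tokens are tried as integer first, then floating point, then kept as
#' string.
#'
#' @param token a non-empty character scalar
#' @return a length-1 integer, double or character vector
#' @export
coerce_scalar <- function(token) {
  coerce_tokens(token)[[1]]
}

# Vectorized coercion with the degrade-to-string rule: if the tokens do not
# all coerce to one numeric type, the whole set becomes strings.
coerce_tokens <- function(tokens) {
  int_ok <- grepl("^[+-]?[0-9]+$", tokens)
  if (all(int_ok)) {
    v <- suppressWarnings(as.integer(tokens))
    if (!anyNA(v)) return(as.list(v))    # overflow falls through to float
  }
  num_ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", tokens)
  if (all(num_ok)) {
    v <- suppressWarnings(as.numeric(tokens))
    if (!anyNA(v)) return(as.list(v))
  }
  as.list(tokens)
}

coerce_vector <- function(tokens) {
  vals <- coerce_tokens(tokens)
  unlist(vals, use.names = FALSE)
}

# ---- data-item body parsing and serialization --------------------------

# Extended-notation body syntax:
#   dict:   whitespace-separated key:value pairs
#   list:   whitespace-separated scalars
#   single: anything else (one token, or forced)
# A first body line of exactly [single], [list] or [dict] overrides
# detection; the writer emits [single] whenever a literal string would
# otherwise be mis-read as a list or dict.
parse_meta_body <- function(body, name = NULL) {
  forced <- NULL
  text <- trimws(paste(body, collapse = " "))
  m <- regmatches(text, regexec("^\\[(single|list|dict)\\][[:space:]]+", text))[[1]]
  if (length(m) == 2L) {
    forced <- m[2]
    text <- trimws(substring(text, nchar(m[1]) + 1L))
  }
  if (!nzchar(text)) return(NULL)            # no value, no metadata
  tokens <- strsplit(text, "[[:space:]]+")[[1]]
  looks_dict <- all(grepl("^[^:[:space:]]+:[^:[:space:]]*$", tokens))
  structure <- if (!is.null(forced)) forced
    else if (looks_dict) "dict"
    else if (length(tokens) > 1L) "list"
    else "single"
  if (structure == "dict") {
    if (!all(grepl(":", tokens, fixed = TRUE)))
      structure <- "single"                  # forced dict that is not pairs: degrade
  }
  switch(structure,
    dict = {
      keys <- sub(":.*$", "", tokens)
      vals <- sub("^[^:]*:", "", tokens)
      if (anyDuplicated(keys))
        stop(sprintf("duplicate dict keys in data item%s",
                     if (is.null(name)) "" else paste0(" '", name, "'")))
      meta_value(coerce_vector(vals), "dict", keys = coerce_vector(keys), name = name)
    },
    list = meta_value(coerce_vector(tokens), "list", name = name),
    single = meta_value(coerce_scalar(text), "single", name = name)
  )
}

# Serialize a meta_value payload to body text (no header, no wrapping).
serialize_meta_body <- function(mv) {
  if (mv$structure == "dict") {
    ks <- scalar_to_str(mv$keys)
    vs <- scalar_to_str(mv$payload)
    if (any(grepl("[[:space:]:]", ks)))
      stop("dict keys containing whitespace or ':' cannot be serialized")
    if (any(grepl("[[:space:]]", vs)))
      stop("dict values containing whitespace cannot be serialized")
    paste(paste0(ks, ":", vs), collapse = " ")
  } else if (mv$structure == "list") {
    vs <- scalar_to_str(mv$payload)
    if (any(grepl("[[:space:]]", vs)))
      stop("list values containing whitespace cannot be serialized")
    pre <- if (needs_override(vs, "list")) "[list] " else ""
    paste0(pre, paste(vs, collapse = " "))
  } else {
    v <- scalar_to_str(mv$payload)
    pre <- if (needs_override(v, "single")) "[single] " else ""
    paste0(pre, v)
  }
}

# Would the serialized tokens be mis-detected without an override prefix?
needs_override <- function(tokens, structure) {
  if (structure == "single") {
    grepl("[[:space:]]", tokens) || grepl("^[^:[:space:]]+:[^:[:space:]]*$", tokens) ||
      tokens %in% c("[single]", "[list]", "[dict]")
  } else {                                   # list
    length(tokens) == 1L ||
      all(grepl("^[^:[:space:]]+:[^:[:space:]]*$", tokens)) ||
      tokens[1] %in% c("[single]", "[list]", "[dict]")
  }
}

# Wrap body text at `width` characters, breaking at token boundaries;
# wrapped lines re-join with a space on read.
wrap_body <- function(text, width = 200L) {
  if (nchar(text) <= width) return(text)
  tokens <- strsplit(text, " ", fixed = TRUE)[[1]]
  lines <- character(0)
  cur <- ""
  for (tok in tokens) {
    cand <- if (nzchar(cur)) paste(cur, tok) else tok
    if (nchar(cand) > width && nzchar(cur)) {
      lines <- c(lines, cur)
      cur <- tok
    } else cur <- cand
  }
  c(lines, cur)
}
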