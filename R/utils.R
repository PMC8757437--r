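# shared low-level helpers

#' Shortest decimal string that round-trips to the same double
#' @noRd
num_to_str <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.integer(v)) return(as.character(v))
    if (v == floor(v) && abs(v) < 1e15) {
      s <- sprintf("%.1f", v)
      if (as.numeric(s) == v) return(s)
    }
    for (d in c(7L, 10L, 15L, 17L)) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Format any typed scalar vector for serialization
#' @noRd
scalar_to_str <- function(x) {
  if (is.character(x)) x else num_to_str(x)
}

#' Split a line on a delimiter, honoring RFC-4180-style double quotes
#' @noRd
split_quoted <- function(line, delim) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  cells <- character(0)
  cur <- character(0)
  in_q <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_q) {
      if (ch == '"') {
        if (i < n && chars[i + 1L] == '"') {
          cur <- c(cur, '"'); i <- i + 1L
        } else in_q <- FALSE
      } else cur <- c(cur, ch)
    } else if (ch == '"') {
      in_q <- TRUE
    } else if (ch == delim) {
      cells <- c(cells, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, ch)
    i <- i + 1L
  }
  c(cells, paste(cur, collapse = ""))
}

#' Quote a CSV cell when needed (RFC-4180)
#' @noRd
quote_cell <- function(x, delim) {
  needs <- grepl('"', x, fixed = TRUE) | grepl(delim, x, fixed = TRUE) |
    grepl("\n", x, fixed = TRUE)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

#' Split on commas that are not nested in (), {} or quotes
#' @noRd
split_toplevel_commas <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_q <- FALSE
  parts <- character(0)
  cur <- character(0)
  for (ch in chars) {
    if (in_q) {
      cur <- c(cur, ch)
      if (ch == '"') in_q <- FALSE
    } else if (ch == '"') {
      cur <- c(cur, ch); in_q <- TRUE
    } else if (ch %in% c("(", "{")) {
      depth <- depth + 1L; cur <- c(cur, ch)
    } else if (ch %in% c(")", "}")) {
      depth <- depth - 1L; cur <- c(cur, ch)
    } else if (ch == "," && depth == 0L) {
      parts <- c(parts, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, ch)
  }
  c(parts, paste(cur, collapse = ""))
}

#' Read a text file as UTF-8, falling back to Latin-1 (legacy SDF files)
#' @noRd
read_text_lines <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    Encoding(txt) <- "latin1"
    txt <- enc2utf8(txt)
  }
  strsplit(txt, "\r?\n")[[1]]
}
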