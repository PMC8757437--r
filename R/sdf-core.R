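# SDfile (MDL SDF, V2000 molfiles) reading, writing, grouping.
#
# An SDfile is a concatenation of entries, each a V2000 molfile followed by
# zero or more data items and a `$$$$` delimiter line. Entries become
# conformation records; records sharing a group key (the molecule name by
# default) form a molecule group, and each record gets a conformation
# number unique within its group. Atom, bond and property block lines are
# kept verbatim so that untouched structures round-trip bit-exactly.

# ---- record / ensemble constructors ------------------------------------

new_molfile <- function(name, comments, counts_line, atoms, atom_lines, tail_block) {
  list(name = name, comments = comments, counts_line = counts_line,
       atoms = atoms, atom_lines = atom_lines, tail_block = tail_block)
}

new_record <- function(molfile, meta = list(), group_key = molfile$name,
                       conf_number = NA_integer_) {
  list(molfile = molfile, meta = meta, group_key = group_key,
       conf_number = conf_number)
}

new_ensemble <- function(records = list(), group_field = "name") {
  ens <- list(records = records, group_field = group_field, groups = list())
  class(ens) <- "sdf_ensemble"
  rebuild_groups(ens)
}

#' Number of records in an ensemble
#' @param x an `sdf_ensemble`
#' @param ... ignored
#' @export
length.sdf_ensemble <- function(x) length(x$records)

#' @export
print.sdf_ensemble <- function(x, ...) {
  cat(sprintf("sdf_ensemble: %d records in %d groups (grouped by %s)\n",
              length(x$records), length(x$groups), x$group_field))
  invisible(x)
}

#' @export
summary.sdf_ensemble <- function(object, ...) {
  print(object)
  lm <- list_meta(object)
  if (nrow(lm)) {
    cat("metadata:\n")
    print(lm, row.names = FALSE)
  } else cat("no metadata\n")
  invisible(lm)
}

# Rebuild the group index from records' group keys; keys keep first-seen order.
rebuild_groups <- function(ens) {
  keys <- vapply(ens$records, function(r) r$group_key, character(1))
  ens$groups <- if (length(keys)) split(seq_along(keys), factor(keys, levels = unique(keys)))
                else list()
  ens
}

group_keys <- function(ens) vapply(ens$records, function(r) r$group_key, character(1))
conf_numbers <- function(ens) vapply(ens$records, function(r) r$conf_number, integer(1))

# ---- conformation-number tags ------------------------------------------

#' Encode / decode a conformation tag in a molecule name
#'
#' The tag syntax is `{[conf|N]}` appended to the name; `{` and `[` do not
#' occur in common molecule-naming schemes, so tagged and plain names never
#' collide. `decode_conf_tag` is the exact inverse; a name without a
#' well-formed tag decodes to `conf = NA`.
#'
#' @param name molecule name (without tag for encode, possibly tagged for
#'   decode)
#' @param conf positive integer conformation number
#' @return `encode_conf_tag`: the tagged name. `decode_conf_tag`: a list
#'   with elements `name` and `conf` (integer, `NA` when untagged).
#' @export
encode_conf_tag <- function(name, conf) {
  sprintf("%s{[conf|%d]}", name, as.integer(conf))
}

#' @rdname encode_conf_tag
#' @export
decode_conf_tag <- function(name) {
  m <- regmatches(name, regexec("^(.*)\\{\\[conf\\|([0-9]+)\\]\\}$", name))[[1]]
  if (length(m) == 3L) list(name = m[2], conf = as.integer(m[3]))
  else list(name = name, conf = NA_integer_)
}

# ---- molfile parsing ----------------------------------------------------

parse_molfile_entry <- function(lines, entry_idx) {
  perr <- function(msg) stop(sprintf("entry %d: %s", entry_idx, msg), call. = FALSE)
  if (length(lines) < 4L) perr("truncated molfile header")
  name <- lines[1]
  comments <- lines[2:3]
  counts_line <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
  if (is.na(natoms) || natoms < 0L) perr("unreadable atom count in counts line")
  if (length(lines) < 4L + natoms) perr("truncated atom block")
  atom_lines <- if (natoms > 0L) lines[5:(4L + natoms)] else character(0)
  atoms <- parse_atom_block(atom_lines, perr)
  rest <- lines[-seq_len(4L + natoms)]
  mend <- which(grepl("^M  END", rest))[1]
  if (is.na(mend)) perr("molfile has no 'M  END' line")
  tail_block <- rest[seq_len(mend)]
  data_lines <- rest[-seq_len(mend)]
  list(molfile = new_molfile(name, comments, counts_line, atoms, atom_lines, tail_block),
       data_lines = data_lines)
}

# Fixed-width V2000 atom line: x,y,z in columns 1-30 (3 x %10.4f), element
# in columns 32-34. The verbatim line is kept; only these fields are parsed.
parse_atom_block <- function(atom_lines, perr) {
  n <- length(atom_lines)
  if (n == 0L)
    return(data.frame(index = integer(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  if (any(nchar(atom_lines) < 32L)) perr("truncated atom line")
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  el <- trimws(substr(atom_lines, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z)) perr("unreadable coordinates in atom line")
  if (any(!nzchar(el))) perr("empty element field in atom line")
  data.frame(index = seq_len(n), element = el, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

#' Parse a data item into a metadata value
#'
#' The body is interpreted with the extended notation: whitespace-separated
#' `key:value` pairs form a dictionary, several plain tokens a list, and
#' anything else a single value; scalars are coerced int before float
#' before string, and mixed coercions degrade the whole item to strings.
#' Any body is at worst a single string, so no input fails.
#'
#' @param header_line the `>  <NAME>` line
#' @param body_lines character vector of body lines (wrapped lines re-join)
#' @return a `meta_value`, or `NULL` when the body is empty
#' @export
parse_data_item <- function(header_line, body_lines) {
  m <- regmatches(header_line, regexec("<([^<>]*)>", header_line))[[1]]
  if (length(m) < 2L)
    stop(sprintf("malformed data-item header: %s", header_line))
  parse_meta_body(body_lines, name = m[2])
}

parse_data_items <- function(data_lines, entry_idx) {
  meta <- list()
  i <- 1L
  n <- length(data_lines)
  while (i <= n) {
    ln <- data_lines[i]
    if (!nzchar(trimws(ln))) { i <- i + 1L; next }
    if (!startsWith(ln, ">"))
      stop(sprintf("entry %d: unexpected line between data items: %s", entry_idx, ln),
           call. = FALSE)
    j <- i + 1L
    while (j <= n && nzchar(trimws(data_lines[j])) && !startsWith(data_lines[j], ">"))
      j <- j + 1L
    mv <- parse_data_item(ln, if (j > i + 1L) data_lines[(i + 1L):(j - 1L)] else character(0))
    if (!is.null(mv)) {
      if (!is.null(meta[[mv$name]]))
        stop(sprintf("entry %d: duplicate data item '%s'", entry_idx, mv$name), call. = FALSE)
      meta[[mv$name]] <- mv
    }
    i <- j
  }
  meta
}

# ---- SDfile parse / write ----------------------------------------------

#' Parse an SDfile into a conformer ensemble
#'
#' Splits the file at `$$$$` delimiter lines, parses each V2000 molfile and
#' its data items, strips conformation tags from names, groups records by
#' molecule name and assigns conformation numbers.
#'
#' @param x path to an SDfile, or its content as a character vector of
#'   lines (or one string with embedded newlines)
#' @return an `sdf_ensemble`
#' @export
read_sdf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) read_text_lines(x)
           else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  parse_sdfile(lines)
}

#' @rdname read_sdf
#' @param lines character vector of SDfile lines
#' @export
parse_sdfile <- function(lines) {
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    return(new_ensemble())
  delims <- which(trimws(lines) == "$$$$")
  if (length(delims) == 0L || max(delims) < max(which(nzchar(trimws(lines)))))
    stop("SDfile content after the last '$$$$' delimiter (missing '$$$$' before EOF?)",
         call. = FALSE)
  starts <- c(1L, delims[-length(delims)] + 1L)
  records <- vector("list", length(delims))
  for (k in seq_along(delims)) {
    chunk <- lines[starts[k]:(delims[k] - 1L)]
    # leading blank lines between entries are not part of the molfile header
    while (length(chunk) > 0L && !nzchar(trimws(chunk[1])) && k > 1L)
      chunk <- chunk[-1L]
    ent <- parse_molfile_entry(chunk, k)
    meta <- parse_data_items(ent$data_lines, k)
    dec <- decode_conf_tag(ent$molfile$name)
    mol <- ent$molfile
    mol$name <- dec$name
    if (!nzchar(trimws(dec$name)))
      warning(sprintf("entry %d has a whitespace-only molecule name; group key is ''", k))
    records[[k]] <- new_record(mol, meta, group_key = trimws_name(dec$name),
                               conf_number = dec$conf)
  }
  ens <- new_ensemble(records, group_field = "name")
  assign_conf_numbers(ens)
}

trimws_name <- function(x) {
  y <- trimws(x)
  y
}

#' Assign conformation numbers within each molecule group
#'
#' Records whose names carried an encoded `{[conf|N]}` tag keep `N`; the
#' remaining records of each group are numbered in file order with the
#' smallest unused positive integers. Duplicated encoded pairs are an
#' error.
#'
#' @param ens an `sdf_ensemble` with groups built
#' @return the ensemble with `conf_number` set on every record
#' @export
assign_conf_numbers <- function(ens) {
  for (g in names(ens$groups)) {
    idx <- ens$groups[[g]]
    encoded <- vapply(ens$records[idx], function(r) r$conf_number, integer(1))
    used <- encoded[!is.na(encoded)]
    if (anyDuplicated(used)) {
      dup <- used[duplicated(used)][1]
      both <- idx[which(!is.na(encoded) & encoded == dup)]
      stop(sprintf("duplicate conformation number %d in group '%s' (entries %s)",
                   dup, g, paste(both, collapse = ", ")), call. = FALSE)
    }
    nxt <- 1L
    for (i in seq_along(idx)) {
      if (is.na(encoded[i])) {
        while (nxt %in% used) nxt <- nxt + 1L
        ens$records[[idx[i]]]$conf_number <- nxt
        used <- c(used, nxt)
      }
    }
  }
  ens
}

#' Regroup an ensemble by a metadata field
#'
#' Rebuilds molecule groups on the string form of a single-valued metadata
#' field (or on the header name when `field = "name"`) and reassigns
#' conformation numbers sequentially within the new groups.
#'
#' @param ens an `sdf_ensemble`
#' @param field a metadata name carried by every record, or `"name"`
#' @return the regrouped ensemble
#' @export
regroup <- function(ens, field) {
  for (i in seq_along(ens$records)) {
    r <- ens$records[[i]]
    if (identical(field, "name")) {
      key <- r$molfile$name
    } else {
      mv <- r$meta[[field]]
      if (is.null(mv))
        stop(sprintf("record %d ('%s' conf %d) lacks metadata '%s'",
                     i, r$group_key, r$conf_number, field), call. = FALSE)
      key <- paste(scalar_to_str(mv$payload), collapse = " ")
    }
    ens$records[[i]]$group_key <- key
    ens$records[[i]]$conf_number <- NA_integer_
  }
  ens$group_field <- field
  ens <- rebuild_groups(ens)
  assign_conf_numbers(ens)
}

#' Write an ensemble as SDfile text
#'
#' The serialization counterpart of [parse_sdfile()]: verbatim molfile
#' blocks, data items in the extended notation (bodies wrapped at 200
#' characters), one `$$$$` per record. Re-parsing the output reproduces
#' records, metadata and coordinates exactly.
#'
#' @param ens an `sdf_ensemble`
#' @param file optional path; when given the text is written there
#' @param tag_names append `{[conf|N]}` tags to molecule names so that
#'   conformation numbers survive the round trip explicitly
#' @return the SDfile text as a single string (invisibly when `file` is
#'   given); an empty ensemble yields `""`
#' @export
write_sdf <- function(ens, file = NULL, tag_names = FALSE) {
  out <- character(0)
  for (r in ens$records) {
    nm <- if (tag_names) encode_conf_tag(r$molfile$name, r$conf_number) else r$molfile$name
    out <- c(out, nm, r$molfile$comments, r$molfile$counts_line,
             r$molfile$atom_lines, r$molfile$tail_block)
    for (mv in r$meta) {
      if (grepl("[<>\n]", mv$name))
        stop(sprintf("metadata name '%s' cannot be serialized in a data-item header", mv$name))
      out <- c(out, sprintf(">  <%s>", mv$name),
               wrap_body(serialize_meta_body(mv)), "")
    }
    out <- c(out, "$$$$")
  }
  txt <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @rdname write_sdf
#' @export
write_sdfile <- write_sdf

# Structural equality of two ensembles (names, coordinates, meta, numbering).
ensembles_identical <- function(a, b) {
  if (length(a$records) != length(b$records)) return(FALSE)
  for (i in seq_along(a$records)) {
    ra <- a$records[[i]]; rb <- b$records[[i]]
    if (!identical(ra$molfile$name, rb$molfile$name)) return(FALSE)
    if (!identical(ra$molfile$atom_lines, rb$molfile$atom_lines)) return(FALSE)
    if (!identical(ra$molfile$tail_block, rb$molfile$tail_block)) return(FALSE)
    if (!identical(ra$conf_number, rb$conf_number)) return(FALSE)
    if (!identical(sort(names(ra$meta)), sort(names(rb$meta)))) return(FALSE)
    for (nm in names(ra$meta)) {
      ma <- ra$meta[[nm]]; mb <- rb$meta[[nm]]
      if (!identical(ma$structure, mb$structure) || !identical(ma$dtype, mb$dtype) ||
          !identical(ma$payload, mb$payload) || !identical(ma$keys, mb$keys))
        return(FALSE)
    }
  }
  TRUE
}
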