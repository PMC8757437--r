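# External data interchange: CSV import/export, SDfile-to-SDfile metadata
# combination, and TRIPOS mol2 SYBYL atom-type import.

# ---- CSV table ----------------------------------------------------------

#' Read a comma- or tab-separated table
#'
#' The delimiter is auto-detected (tab wins if the header line contains a
#' tab, comma otherwise) unless given. Cells keep their raw string form;
#' typing happens at import. The first column is the molecule-name key
#' column by default.
#'
#' @param x path to a file, or the table content as a character vector of
#'   lines (or one string with embedded newlines)
#' @param delim `","`, `"\t"`, or `NULL` to auto-detect
#' @return a `csv_table`: list with `delim`, `header`, `rows`
#' @export
read_csv_table <- function(x, delim = NULL) {
  lines <- if (length(x) == 1L && file.exists(x)) read_text_lines(x)
           else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty CSV input")
  if (is.null(delim))
    delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- split_quoted(lines[1], delim)
  rows <- lapply(lines[-1], function(ln) {
    cells <- split_quoted(ln, delim)
    if (length(cells) != length(header))
      stop(sprintf("CSV row has %d cells, header has %d: %s",
                   length(cells), length(header), ln))
    cells
  })
  structure(list(delim = delim, header = header, rows = rows), class = "csv_table")
}

#' @export
print.csv_table <- function(x, ...) {
  cat(sprintf("csv_table: %d rows, %d columns (%s-separated)\n",
              length(x$rows), length(x$header),
              if (x$delim == "\t") "tab" else "comma"))
  cat("columns:", paste(x$header, collapse = ", "), "\n")
  invisible(x)
}

write_csv_table <- function(tab, file = NULL) {
  fmt_line <- function(cells) paste(quote_cell(cells, tab$delim), collapse = tab$delim)
  lines <- c(fmt_line(tab$header), vapply(tab$rows, fmt_line, character(1)))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}

# ---- CSV import / export ------------------------------------------------

#' Import CSV columns as metadata
#'
#' Rows are matched to records by molecule name: a key carrying a
#' `{[conf|N]}` tag attaches only to that conformation, a plain key to
#' every conformation of the name. Each non-key column becomes one
#' metadata; cells in the `key:value` dictionary syntax import as
#' dictionaries, other cells follow the int/float/string coercion order.
#' Empty cells add nothing. Unmatched rows are reported as a warning, not
#' an error.
#'
#' @param ens an `sdf_ensemble`
#' @param table a `csv_table` (or path / text accepted by
#'   [read_csv_table()])
#' @param name_col index or name of the key column (default first)
#' @param overwrite replace existing metadata of the same name
#' @return the updated ensemble
#' @export
import_csv <- function(ens, table, name_col = 1L, overwrite = TRUE) {
  if (!inherits(table, "csv_table")) table <- read_csv_table(table)
  if (is.character(name_col)) {
    name_col <- match(name_col, table$header)
    if (is.na(name_col)) stop("name_col not found in CSV header")
  }
  if (name_col < 1L || name_col > length(table$header)) stop("name_col out of range")
  keys <- vapply(table$rows, `[[`, character(1), name_col)
  decs <- lapply(keys, decode_conf_tag)
  keyid <- vapply(decs, function(d)
    paste0(d$name, if (!is.na(d$conf)) sprintf("|%d", d$conf) else ""), character(1))
  if (anyDuplicated(keyid))
    stop(sprintf("duplicate keys in CSV: %s",
                 paste(unique(keyid[duplicated(keyid)]), collapse = ", ")))
  rec_names <- vapply(ens$records, function(r) r$molfile$name, character(1))
  rec_confs <- conf_numbers(ens)
  unmatched <- 0L
  for (ri in seq_along(table$rows)) {
    d <- decs[[ri]]
    hit <- which(rec_names == d$name & (is.na(d$conf) | rec_confs == d$conf))
    if (length(hit) == 0L) { unmatched <- unmatched + 1L; next }
    for (ci in seq_along(table$header)[-name_col]) {
      cell <- table$rows[[ri]][[ci]]
      mv <- parse_meta_body(cell, name = table$header[ci])
      if (is.null(mv)) next
      for (i in hit) {
        if (!overwrite && !is.null(ens$records[[i]]$meta[[mv$name]])) next
        ens$records[[i]]$meta[[mv$name]] <- mv
      }
    }
  }
  if (unmatched > 0L)
    warning(sprintf("%d CSV row(s) matched no record and were skipped", unmatched))
  ens
}

#' Export metadata to a CSV table
#'
#' One row per record; the key column holds the conformation-tagged name.
#' Dictionaries flatten to `key:value` pairs in one cell, so that
#' re-importing the table restores the metadata exactly.
#'
#' @param ens an `sdf_ensemble`
#' @param meta_names metadata names to export (each must resolve on at
#'   least one record)
#' @param delim output delimiter, default comma
#' @return a `csv_table`
#' @export
export_csv <- function(ens, meta_names, delim = ",") {
  present <- unique(unlist(lapply(ens$records, function(r) names(r$meta))))
  if (length(ens$records) > 0L && !any(meta_names %in% present))
    stop(sprintf("none of the requested metadata (%s) is present in the ensemble",
                 paste(meta_names, collapse = ", ")))
  rows <- lapply(ens$records, function(r) {
    cells <- vapply(meta_names, function(nm) {
      mv <- r$meta[[nm]]
      if (is.null(mv)) "" else serialize_meta_body(mv)
    }, character(1))
    c(encode_conf_tag(r$molfile$name, r$conf_number), unname(cells))
  })
  structure(list(delim = delim, header = c("name", meta_names), rows = rows),
            class = "csv_table")
}

# ---- SDfile combination -------------------------------------------------

#' Copy metadata from another ensemble
#'
#' Metadata of `other` is copied onto records of `ens` matching by
#' molecule name; when the donor carries several conformations of a name,
#' the conformation numbers must match too, while a single-conformation
#' donor entry applies to every conformation of that name
#' (molecule-level data). Structures in `ens` are never touched; existing
#' metadata is kept unless `overwrite`.
#'
#' @param ens an `sdf_ensemble` (receives the metadata)
#' @param other an `sdf_ensemble` (donates the metadata)
#' @param overwrite replace metadata already present on `ens`
#' @return the updated ensemble
#' @export
combine_sdf <- function(ens, other, overwrite = FALSE) {
  don_names <- vapply(other$records, function(r) r$molfile$name, character(1))
  don_confs <- conf_numbers(other)
  unmatched <- 0L
  for (i in seq_along(ens$records)) {
    r <- ens$records[[i]]
    cand <- which(don_names == r$molfile$name)
    if (length(cand) == 0L) { unmatched <- unmatched + 1L; next }
    hit <- if (length(cand) == 1L) cand
           else cand[don_confs[cand] == r$conf_number]
    if (length(hit) != 1L) { unmatched <- unmatched + 1L; next }
    for (nm in names(other$records[[hit]]$meta)) {
      if (!overwrite && !is.null(r$meta[[nm]])) next
      ens$records[[i]]$meta[[nm]] <- other$records[[hit]]$meta[[nm]]
    }
  }
  if (unmatched > 0L)
    warning(sprintf("%d record(s) had no matching donor entry in combine", unmatched))
  ens
}

# ---- mol2 SYBYL atom types ----------------------------------------------

#' Import SYBYL atom types from a mol2 file
#'
#' Reads the TRIPOS MOLECULE and ATOM sections and attaches, per record, a
#' dictionary atom number -> SYBYL type string (column 6 of the ATOM
#' lines, e.g. `"O.3"`, `"N.4"`). Matching is positional: molecule i of
#' the mol2 file types record i of the ensemble, because format converters
#' routinely mangle names. Molecule and atom counts must agree.
#'
#' @param ens an `sdf_ensemble`
#' @param mol2 path to a mol2 file, or its content as lines / one string
#' @param meta_name name for the new metadata (e.g. `"sybyl"`)
#' @return the updated ensemble
#' @export
import_mol2_atomtypes <- function(ens, mol2, meta_name = "sybyl") {
  check_meta_name(meta_name)
  lines <- if (length(mol2) == 1L && file.exists(mol2)) read_text_lines(mol2)
           else unlist(strsplit(mol2, "\n", fixed = TRUE), use.names = FALSE)
  mol_starts <- which(trimws(lines) == "@<TRIPOS>MOLECULE")
  if (length(mol_starts) == 0L) stop("no @<TRIPOS>MOLECULE section in mol2 input")
  if (length(mol_starts) != length(ens$records))
    stop(sprintf("mol2 has %d molecules but the ensemble has %d records",
                 length(mol_starts), length(ens$records)))
  bounds <- c(mol_starts, length(lines) + 1L)
  for (i in seq_along(mol_starts)) {
    chunk <- lines[mol_starts[i]:(bounds[i + 1L] - 1L)]
    mol_name <- trimws(chunk[2])
    atom_at <- which(trimws(chunk) == "@<TRIPOS>ATOM")[1]
    if (is.na(atom_at))
      stop(sprintf("mol2 molecule %d ('%s') has no @<TRIPOS>ATOM section", i, mol_name))
    j <- atom_at + 1L
    atom_lines <- character(0)
    while (j <= length(chunk) && !startsWith(trimws(chunk[j]), "@<TRIPOS>")) {
      if (nzchar(trimws(chunk[j]))) atom_lines <- c(atom_lines, chunk[j])
      j <- j + 1L
    }
    n_ens <- nrow(ens$records[[i]]$molfile$atoms)
    if (length(atom_lines) != n_ens)
      stop(sprintf("mol2 molecule %d ('%s') has %d atoms but record %d has %d",
                   i, mol_name, length(atom_lines), i, n_ens))
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    if (any(lengths(fields) < 6L))
      stop(sprintf("mol2 molecule %d ('%s'): ATOM line with fewer than 6 fields", i, mol_name))
    types <- vapply(fields, `[[`, character(1), 6L)
    ens$records[[i]]$meta[[meta_name]] <-
      meta_value(types, "dict", keys = seq_along(types), name = meta_name)
  }
  ens
}
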