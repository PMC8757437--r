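# Record-level filtering, renaming and metadata bookkeeping.

check_meta_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("metadata name must be a non-empty string")
  if (grepl("[<>\n]", name))
    stop(sprintf("metadata name '%s' contains characters illegal in a data item", name))
  invisible(name)
}

# Existence-based truthiness: ABSENT and empty payloads are false, every
# present value (including 0) is true.
is_truthy <- function(x) !is_absent(x) && length(x$payload) > 0L

#' Filter records by a metastatement
#'
#' A record is kept iff the statement evaluates to a present, non-empty
#' value for it; `&` requires both sides present, `|` either. Filtering
#' preserves record order and conformation numbers.
#'
#' @param ens an `sdf_ensemble`
#' @param statement statement string or parsed tree
#' @param invert keep the records the statement rejects instead
#' @param ignore element ignore list passed to atom-wise builtins
#' @return the filtered ensemble
#' @export
filter_records <- function(ens, statement, invert = FALSE, ignore = c("H")) {
  res <- evaluate_statement(statement, ens, ignore = ignore)
  keep <- vapply(res, is_truthy, logical(1))
  if (invert) keep <- !keep
  ens$records <- ens$records[keep]
  rebuild_groups(ens)
}

#' Rename records by a metastatement
#'
#' The statement must yield a single value per record; its string form
#' replaces the header name. Groups and conformation numbers are
#' recomputed; molecules collapsing onto one name merge into one group
#' (with a warning) and are renumbered.
#'
#' @inheritParams filter_records
#' @return the renamed ensemble
#' @export
rename_records <- function(ens, statement, ignore = c("H")) {
  res <- evaluate_statement(statement, ens, ignore = ignore)
  n_groups_before <- length(ens$groups)
  for (i in seq_along(res)) {
    x <- res[[i]]
    if (is_absent(x))
      stop(sprintf("rename statement has no value for record %d ('%s' conf %d): a molecule cannot be nameless",
                   i, ens$records[[i]]$group_key, ens$records[[i]]$conf_number), call. = FALSE)
    if (x$structure != "single")
      stop(sprintf("rename statement must yield a single value; record %d got a %s", i, x$structure),
           call. = FALSE)
    ens$records[[i]]$molfile$name <- as.character(scalar_to_str(x$payload))
  }
  ens <- regroup(ens, "name")
  if (length(ens$groups) < n_groups_before && n_groups_before > 1L &&
      length(unique(vapply(res, function(x) scalar_to_str(x$payload), character(1)))) <
        n_groups_before)
    message(sprintf("rename merged %d groups into %d; conformations renumbered",
                    n_groups_before, length(ens$groups)))
  ens
}

#' Store the header name as metadata
#'
#' @param ens an `sdf_ensemble`
#' @param meta_name name for the new single string metadata
#' @param overwrite replace an existing metadata of that name
#' @return the updated ensemble
#' @export
store_header_as_meta <- function(ens, meta_name, overwrite = FALSE) {
  check_meta_name(meta_name)
  for (i in seq_along(ens$records)) {
    if (!overwrite && !is.null(ens$records[[i]]$meta[[meta_name]]))
      stop(sprintf("metadata '%s' already present on record %d (use overwrite)", meta_name, i),
           call. = FALSE)
    ens$records[[i]]$meta[[meta_name]] <-
      meta_value(ens$records[[i]]$molfile$name, "single", name = meta_name)
  }
  ens
}

#' List the metadata found in an ensemble
#'
#' @param ens an `sdf_ensemble`
#' @return a data frame with one row per metadata name: its structure,
#'   scalar type and the number of records carrying it ("mixed" when
#'   records disagree)
#' @export
list_meta <- function(ens) {
  names_all <- unique(unlist(lapply(ens$records, function(r) names(r$meta))))
  if (length(names_all) == 0L)
    return(data.frame(name = character(0), structure = character(0),
                      dtype = character(0), count = integer(0)))
  rows <- lapply(names_all, function(nm) {
    mvs <- Filter(Negate(is.null), lapply(ens$records, function(r) r$meta[[nm]]))
    st <- unique(vapply(mvs, `[[`, character(1), "structure"))
    dt <- unique(vapply(mvs, `[[`, character(1), "dtype"))
    data.frame(name = nm,
               structure = if (length(st) == 1L) st else "mixed",
               dtype = if (length(dt) == 1L) dt else "mixed",
               count = length(mvs))
  })
  do.call(rbind, rows)
}

#' Remove or keep metadata by name
#'
#' `remove_meta` deletes the listed names wherever they occur; `keep_meta`
#' deletes every other name. Names absent on some records are tolerated.
#'
#' @param ens an `sdf_ensemble`
#' @param names character vector of metadata names
#' @return the updated ensemble
#' @export
remove_meta <- function(ens, names) {
  for (i in seq_along(ens$records))
    ens$records[[i]]$meta <- ens$records[[i]]$meta[
      !(names(ens$records[[i]]$meta) %in% names)]
  ens
}

#' @rdname remove_meta
#' @export
keep_meta <- function(ens, names) {
  for (i in seq_along(ens$records))
    ens$records[[i]]$meta <- ens$records[[i]]$meta[
      names(ens$records[[i]]$meta) %in% names]
  ens
}

#' Create metadata from a metastatement
#'
#' Evaluates the statement per record and stores the result under `name`;
#' records where the statement is ABSENT simply lack the new metadata
#' (there is no metadata if there is no value).
#'
#' @param ens an `sdf_ensemble`
#' @param name name for the new metadata
#' @param statement statement string or parsed tree
#' @param overwrite replace an existing metadata of that name
#' @param ignore element ignore list passed to atom-wise builtins
#' @return the updated ensemble
#' @export
new_meta <- function(ens, name, statement, overwrite = TRUE, ignore = c("H")) {
  check_meta_name(name)
  res <- evaluate_statement(statement, ens, ignore = ignore)
  for (i in seq_along(res)) {
    x <- res[[i]]
    if (is_absent(x)) next
    if (!overwrite && !is.null(ens$records[[i]]$meta[[name]]))
      stop(sprintf("metadata '%s' already present on record %d (use overwrite)", name, i),
           call. = FALSE)
    x$name <- name
    ens$records[[i]]$meta[[name]] <- x
  }
  ens
}
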