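# Atom-level spatial computations against a point of interest.
#
# All atom-wise operations honor an ignore list of element symbols;
# hydrogens are ignored by default, so distance filters that need the
# hydrogens (e.g. a hydroxyl H near a binding-site atom) must pass an
# empty ignore list. Element matching is case-sensitive on the stripped
# V2000 element field.

#' Distances from a record's atoms to a point
#'
#' Euclidean distance in Angstrom from every non-ignored atom to the given
#' point, as a dictionary keyed by atom number.
#'
#' @param rec a conformation record
#' @param point numeric length-3 `c(x, y, z)` in Angstrom
#' @param ignore element symbols to skip; default `"H"`. Use
#'   `character(0)` to include every atom.
#' @return a dict `meta_value` atom number -> distance, or `ABSENT` when
#'   every atom is ignored
#' @export
distances_to_point <- function(rec, point, ignore = c("H")) {
  stopifnot(is.numeric(point), length(point) == 3L, all(is.finite(point)))
  at <- rec$molfile$atoms
  sel <- !(at$element %in% ignore)
  if (!any(sel)) return(ABSENT)
  d <- sqrt((at$x[sel] - point[1])^2 + (at$y[sel] - point[2])^2 + (at$z[sel] - point[3])^2)
  meta_value(d, "dict", keys = at$index[sel])
}

#' Geometric centroid of a record or an ensemble
#'
#' For one record: the unweighted mean of its non-ignored atom
#' coordinates. For an ensemble: the mean of the per-record centroids
#' (mean of means), e.g. the average centroid of top-ranked docking poses.
#'
#' @param x a conformation record or an `sdf_ensemble`
#' @param ignore element symbols to skip; default `"H"`
#' @return numeric `c(x, y, z)`
#' @export
centroid <- function(x, ignore = c("H")) {
  if (inherits(x, "sdf_ensemble")) {
    if (length(x$records) == 0L) stop("centroid of an empty ensemble")
    cents <- vapply(x$records, record_centroid, numeric(3), ignore = ignore)
    return(rowMeans(cents))
  }
  record_centroid(x, ignore)
}

record_centroid <- function(rec, ignore) {
  at <- rec$molfile$atoms
  sel <- !(at$element %in% ignore)
  if (!any(sel)) stop("centroid: every atom of the record is on the ignore list")
  c(x = mean(at$x[sel]), y = mean(at$y[sel]), z = mean(at$z[sel]))
}

#' Store atom distances to a point as named metadata
#'
#' Convenience wrapper running [distances_to_point()] over the whole
#' ensemble and storing the dictionaries under `meta_name`; records whose
#' atoms are all ignored simply lack the new metadata.
#'
#' @param ens an `sdf_ensemble`
#' @param meta_name name for the new metadata
#' @param point numeric `c(x, y, z)`
#' @param ignore element symbols to skip; default `"H"`
#' @return the updated ensemble
#' @export
add_distance_meta <- function(ens, meta_name, point, ignore = c("H")) {
  check_meta_name(meta_name)
  for (i in seq_along(ens$records)) {
    mv <- distances_to_point(ens$records[[i]], point, ignore)
    if (!is_absent(mv)) {
      mv$name <- meta_name
      ens$records[[i]]$meta[[meta_name]] <- mv
    }
  }
  ens
}
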