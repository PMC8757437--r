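# Fixture builders shared by the test files. Everything is generated in
# code; no binary data.

# A minimal V2000 entry with arbitrary atoms and data items.
# atoms: data.frame(element, x, y, z); meta: named list of body strings.
sdf_entry <- function(name, atoms, meta = list()) {
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$x, atoms$y, atoms$z, atoms$element)
  bond_lines <- if (nrow(atoms) > 1L)
    sprintf("%3d%3d%3d  0", seq_len(nrow(atoms) - 1L), seq_len(nrow(atoms) - 1L) + 1L, 1L)
  else character(0)
  items <- unlist(lapply(names(meta), function(nm)
    c(sprintf(">  <%s>", nm), meta[[nm]], "")), use.names = FALSE)
  paste(c(name, "  test", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(atoms), max(0L, nrow(atoms) - 1L)),
          atom_lines, bond_lines, "M  END", items, "$$$$"),
        collapse = "\n")
}

water_atoms <- function(origin = c(0, 0, 0)) {
  data.frame(element = c("O", "H", "H"),
             x = origin[1] + c(0, 0.96, -0.24),
             y = origin[2] + c(0, 0, 0.93),
             z = origin[3] + c(0, 0, 0))
}

# An ensemble of n_groups molecules x n_confs conformers with a numeric
# single "score" and (optionally) dict / list metadata, built through the
# public SDF surface so tests exercise parse + assignment.
random_meta_ensemble <- function(n_groups = 4L, n_confs = 3L, seed = 1L,
                                 with_dicts = FALSE) {
  set.seed(seed)
  entries <- character(0)
  for (g in seq_len(n_groups)) {
    for (j in seq_len(n_confs)) {
      meta <- list(score = num_str(runif(1, 1, 100)))
      if (with_dicts) {
        nk <- sample(2:5, 1)
        keys <- sort(sample(1:9, nk))
        meta$dvals <- paste(sprintf("%d:%s", keys, num_str(runif(nk, 0, 5))), collapse = " ")
        meta$lvals <- paste(num_str(runif(sample(2:4, 1), -3, 3)), collapse = " ")
      }
      at <- data.frame(element = c("C", "O", "H"),
                       x = rnorm(3), y = rnorm(3), z = rnorm(3))
      entries <- c(entries, sdf_entry(sprintf("MOL%d", g), at, meta))
    }
  }
  read_sdf(paste(entries, collapse = "\n"))
}

num_str <- function(x) sprintf("%.6f", x)

# Plain-R views of an ensemble's metadata, for brute-force oracles that
# stay independent of the evaluation engine.
meta_column <- function(ens, name) {
  lapply(ens$records, function(r) {
    mv <- r$meta[[name]]
    if (is.null(mv)) return(NULL)
    if (mv$structure == "dict") stats::setNames(as.list(mv$payload), as.character(mv$keys))
    else mv$payload
  })
}

ens_group_ids <- function(ens) {
  keys <- vapply(ens$records, function(r) r$group_key, character(1))
  match(keys, unique(keys))
}

expect_meta_equal <- function(a, b) {
  expect_identical(is_absent(a), is_absent(b))
  if (!is_absent(a)) {
    expect_identical(a$structure, b$structure)
    expect_identical(a$dtype, b$dtype)
    expect_equal(a$payload, b$payload)
    expect_equal(a$keys, b$keys)
  }
}
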