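# Deterministic generator of docking-style fixtures.
#
# Emulates the output of a Plants-style docking run on a ligand library:
# N molecules x K conformers with mangled names
# `<name>_entry_<5-digit>_conf_<2-digit>`, a ranking CSV with
# per-conformer scores (lower = better), a name-correspondence CSV, a
# per-molecule activity CSV (IC50 in nM, coupled to the best score by a
# linear model plus noise), and a matching mol2 file with SYBYL atom
# types. Molecules are simple alkanol-like chains (C...C-O-H); the tool
# never perceives chemistry, so chemical validity is irrelevant. A
# controllable fraction of conformers is "planted": their hydroxyl O and
# H both lie within 2.5 Angstrom of the binding-site point, every other
# conformer keeps both well outside, and the assignment is emitted as a
# manifest so filters can be checked against the planted truth.

#' Generate a docking-style synthetic fixture
#'
#' @param n_molecules number of molecules (default 99)
#' @param n_confs conformers per molecule (default 10)
#' @param seed integer seed; the same seed gives byte-identical files
#' @param dir optional directory; when given, the fixture files are
#'   written there
#' @param planted_frac fraction of conformers whose hydroxyl O-H pair is
#'   placed within `cutoff` of `point` (default 0.2)
#' @param point binding-site point of interest, default
#'   `c(24.31, -3.29, 25.59)`
#' @param cutoff hydroxyl proximity cutoff in Angstrom (default 2.5)
#' @param score_range additive per-conformer score spread above the
#'   per-molecule base score (scores are positive, lower = better)
#' @param activity_noise_sd standard deviation of the Gaussian noise on
#'   the pIC50 ~ best-score linear model
#' @return a list with the file contents (`sdf`, `corresponding_names`,
#'   `ranking`, `activity`, `mol2`), the planted-truth `manifest` data
#'   frame, the `point`, and `paths` when `dir` was given
#' @export
generate_fixture <- function(n_molecules = 99L, n_confs = 10L, seed = 1L,
                             dir = NULL, planted_frac = 0.2,
                             point = c(24.31, -3.29, 25.59), cutoff = 2.5,
                             score_range = 15, activity_noise_sd = 0.4) {
  stopifnot(n_molecules >= 1L, n_confs >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  names_ <- sprintf("CHEMBLSYN%d", seq_len(n_molecules))
  entries <- sample.int(99999L, n_molecules)
  base_score <- stats::runif(n_molecules, 20, 70)
  n_total <- n_molecules * n_confs
  planted <- stats::runif(n_total) < planted_frac

  sdf_lines <- character(0)
  mol2_lines <- character(0)
  manifest <- data.frame(name = character(n_total), conf = integer(n_total),
                         mangled = character(n_total), total_score = numeric(n_total),
                         planted = logical(n_total), stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(n_molecules)) {
    n_c <- sample(3:6, 1L)
    for (j in seq_len(n_confs)) {
      k <- k + 1L
      mangled <- sprintf("%s_entry_%05d_conf_%02d", names_[i], entries[i], j)
      coords <- place_conformer(n_c, point, planted[k], cutoff)
      score <- round(base_score[i] + stats::runif(1, 0, score_range), 4)
      manifest$name[k] <- names_[i]; manifest$conf[k] <- j
      manifest$mangled[k] <- mangled; manifest$total_score[k] <- score
      manifest$planted[k] <- planted[k]
      sdf_lines <- c(sdf_lines, molfile_lines(mangled, coords), "$$$$")
      mol2_lines <- c(mol2_lines, mol2_block(mangled, coords))
    }
  }

  best <- tapply(manifest$total_score, factor(manifest$name, levels = names_), min)
  pic50 <- 10 - 0.08 * as.numeric(best) + stats::rnorm(n_molecules, 0, activity_noise_sd)
  ic50_nM <- round(10^(9 - pic50), 6)

  ranking <- c("LIGAND_ENTRY,TOTAL_SCORE,SCORE_RB_PEN,EVAL,TIME",
               sprintf("%s,%.4f,%.4f,%d,%.2f", manifest$mangled, manifest$total_score,
                       round(stats::runif(n_total, 0, 5), 4),
                       sample.int(5000L, n_total, replace = TRUE),
                       round(stats::runif(n_total, 1, 60), 2)))
  corresponding <- c("PLANTS_LIGAND_DESCRIPTION,OLD_LIGAND_DESCRIPTION",
                     sprintf("%s,%s", manifest$mangled, manifest$name))
  activity <- c("name,IC50_nM", sprintf("%s,%s", names_, num_to_str(ic50_nM)))

  out <- list(
    sdf = paste0(paste(sdf_lines, collapse = "\n"), "\n"),
    corresponding_names = paste0(paste(corresponding, collapse = "\n"), "\n"),
    ranking = paste0(paste(ranking, collapse = "\n"), "\n"),
    activity = paste0(paste(activity, collapse = "\n"), "\n"),
    mol2 = paste0(paste(mol2_lines, collapse = "\n"), "\n"),
    manifest = manifest, point = point, cutoff = cutoff
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(sdf = file.path(dir, "docked_structures.sdf"),
               corresponding_names = file.path(dir, "correspondingNames.csv"),
               ranking = file.path(dir, "ranking.csv"),
               activity = file.path(dir, "activity.csv"),
               mol2 = file.path(dir, "docked_structures.mol2"),
               manifest = file.path(dir, "manifest.csv"))
    writeLines(out$sdf, paths["sdf"], sep = "")
    writeLines(out$corresponding_names, paths["corresponding_names"], sep = "")
    writeLines(out$ranking, paths["ranking"], sep = "")
    writeLines(out$activity, paths["activity"], sep = "")
    writeLines(out$mol2, paths["mol2"], sep = "")
    utils::write.csv(manifest, paths["manifest"], row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# Atom order: C1..Cn chain, then O (bonded to Cn), then the hydroxyl H.
# Planted conformers put both O and H within the cutoff of the point;
# the rest keep both at least 1.5 Angstrom outside it (margins absorb the
# 4-decimal coordinate rounding).
place_conformer <- function(n_c, point, planted, cutoff) {
  u <- random_unit()
  if (planted) {
    d_o <- stats::runif(1, 1.2, cutoff - 0.2)
    o <- point + d_o * u
    h <- o + 0.96 * (point - o) / sqrt(sum((point - o)^2))
  } else {
    d_o <- stats::runif(1, cutoff + 1.5, cutoff + 5.5)
    o <- point + d_o * u
    h <- o + 0.96 * u
  }
  coords <- matrix(0, nrow = n_c + 2L, ncol = 3L)
  coords[n_c + 1L, ] <- o
  coords[n_c + 2L, ] <- h
  pos <- o + 1.43 * random_unit()
  coords[n_c, ] <- pos
  if (n_c > 1L) for (m in (n_c - 1L):1L) {
    pos <- pos + 1.52 * random_unit()
    coords[m, ] <- pos
  }
  list(coords = round(coords, 4), elements = c(rep("C", n_c), "O", "H"))
}

molfile_lines <- function(name, conf) {
  n_at <- nrow(conf$coords)
  n_c <- n_at - 2L
  bonds <- rbind(if (n_c > 1L) cbind(1:(n_c - 1L), 2:n_c),
                 c(n_c, n_c + 1L), c(n_c + 1L, n_c + 2L))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
                        conf$elements)
  bond_lines <- sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], 1L)
  c(name, "  confmeta synthetic docking pose", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, nrow(bonds)),
    atom_lines, bond_lines, "M  END")
}

SYBYL_TYPE <- c(C = "C.3", O = "O.3", H = "H")

mol2_block <- function(name, conf) {
  n_at <- nrow(conf$coords)
  n_c <- n_at - 2L
  n_bonds <- n_at - 1L
  counts <- table(factor(conf$elements, levels = unique(conf$elements)))
  atom_names <- unlist(lapply(unique(conf$elements), function(el)
    paste0(el, seq_len(counts[[el]]))))
  atom_lines <- sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
                        seq_len(n_at), atom_names,
                        conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
                        SYBYL_TYPE[conf$elements], 1L, "LIG1", 0)
  bonds <- rbind(if (n_c > 1L) cbind(1:(n_c - 1L), 2:n_c),
                 c(n_c, n_c + 1L), c(n_c + 1L, n_c + 2L))
  bond_lines <- sprintf("%6d %5d %5d %s", seq_len(nrow(bonds)), bonds[, 1], bonds[, 2], "1")
  c("@<TRIPOS>MOLECULE", name,
    sprintf("%5d %5d %5d %5d %5d", n_at, n_bonds, 1L, 0L, 0L),
    "SMALL", "NO_CHARGES", "@<TRIPOS>ATOM", atom_lines,
    "@<TRIPOS>BOND", bond_lines)
}
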