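#' Read a docking score table
#'
#' Expects CSV columns `compound,target,score_kcal_mol,group`. Duplicate
#' `(compound, target)` pairs and unparsable scores are rejected with the
#' offending line number. Docking scores are conventionally negative
#' (kcal/mol, more negative = stronger); `assume_negative = TRUE` flips bare
#' positive scores, for tables where a sign was dropped in transcription.
#'
#' @param path CSV path.
#' @param assume_negative Treat positive scores as negative. Default off.
#' @return A `score_table` tibble.
#' @export
read_score_table <- function(path, assume_negative = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("compound", "target", "score_kcal_mol", "group")
  if (nrow(raw) == 0L) stop("empty score table: ", path, call. = FALSE)
  if (!all(need %in% names(raw))) {
    stop("score table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(raw$score_kcal_mol))
  if (anyNA(score)) {
    stop("unparsable score at line ", which(is.na(score))[1L] + 1L, " of ", path, call. = FALSE)
  }
  dup <- duplicated(raw[c("compound", "target")])
  if (any(dup)) {
    stop("duplicate (compound, target) pair at line ", which(dup)[1L] + 1L, " of ", path, call. = FALSE)
  }
  if (assume_negative) score <- -abs(score)
  out <- tibble::tibble(compound = raw$compound, target = raw$target,
                        score_kcal_mol = score, group = raw$group)
  class(out) <- c("score_table", class(out))
  out
}

#' Rank compounds by docking score for one target
#'
#' Ascending by score (most negative, i.e. strongest predicted binding,
#' first); ties broken by compound id.
#'
#' @param table A `score_table`.
#' @param target Target name present in the table.
#' @param group Optional group filter (e.g. `"control"`).
#' @return Tibble of the target's rows, best first, with a `rank` column.
#' @export
rank_scores <- function(table, target, group = NULL) {
  rows <- table[table$target == target, ]
  if (!is.null(group)) rows <- rows[rows$group %in% group, ]
  if (nrow(rows) == 0L) stop("no rows for target: ", target, call. = FALSE)
  rows <- rows[order(rows$score_kcal_mol, rows$compound), ]
  rows$rank <- seq_len(nrow(rows))
  rows
}

#' Binding free energy from complex, receptor and ligand free energies
#'
#' `dG_bind = G_complex - (G_receptor + G_ligand)` (kcal/mol).
#'
#' @param g_complex,g_receptor,g_ligand Free energies (kcal/mol).
#' @return `dG_bind` in kcal/mol.
#' @export
binding_free_energy <- function(g_complex, g_receptor, g_ligand) {
  g_complex - (g_receptor + g_ligand)
}

#' Total free energy from its MM-PB/GBSA components
#'
#' `G = E_bond + E_vdw + E_elec + G_PB + G_SA - TS_S` (kcal/mol). All six
#' terms are required; a missing or NA term is an error.
#'
#' @param d List, data frame or named vector with elements `e_bond`,
#'   `e_vdw`, `e_elec`, `g_pb`, `g_sa`, `ts_s`.
#' @return Total energy (kcal/mol), one value per row of `d`.
#' @export
total_energy <- function(d) {
  need <- c("e_bond", "e_vdw", "e_elec", "g_pb", "g_sa", "ts_s")
  d <- as.list(d)
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop("missing energy component(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(d[need], as.numeric)
  if (anyNA(unlist(vals))) stop("energy components must not be NA", call. = FALSE)
  vals$e_bond + vals$e_vdw + vals$e_elec + vals$g_pb + vals$g_sa - vals$ts_s
}

#' Read an MM-GBSA energy component table
#'
#' Expects CSV columns
#' `compound,target,e_bond,e_vdw,e_elec,g_pb,g_sa,ts_s,dg_reported`.
#' Components may be empty (NA) when the source table does not print them;
#' the reported total is stored verbatim and never reconstructed. When all
#' six components are present but disagree with `dg_reported` by more than
#' 0.05 kcal/mol a warning (not an error) is raised.
#'
#' @param path CSV path.
#' @return An `energy_table` tibble.
#' @export
read_energy_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "target", "e_bond", "e_vdw", "e_elec",
            "g_pb", "g_sa", "ts_s", "dg_reported")
  if (nrow(raw) == 0L) stop("empty energy table: ", path, call. = FALSE)
  if (!all(need %in% names(raw))) {
    stop("energy table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(raw[c("compound", "target")])
  if (any(dup)) {
    stop("duplicate (compound, target) pair at line ", which(dup)[1L] + 1L, " of ", path, call. = FALSE)
  }
  num_cols <- setdiff(need, c("compound", "target"))
  for (cn in num_cols) raw[[cn]] <- as.numeric(raw[[cn]])
  out <- tibble::as_tibble(raw[need])
  complete <- stats::complete.cases(out[c("e_bond", "e_vdw", "e_elec", "g_pb", "g_sa", "ts_s")])
  if (any(complete)) {
    tot <- total_energy(out[complete, ])
    off <- abs(tot - out$dg_reported[complete]) > 0.05 & !is.na(out$dg_reported[complete])
    if (any(off)) {
      warning(sum(off), " row(s) whose components do not sum to the reported dG_bind",
              call. = FALSE)
    }
  }
  class(out) <- c("energy_table", class(out))
  out
}

#' Rank compounds by reported binding free energy for one target
#'
#' @param table An `energy_table`.
#' @param target Target name.
#' @param group Optional filter when the table has a `group` column.
#' @return Tibble sorted ascending by `dg_reported` (strongest first).
#' @export
rank_energies <- function(table, target, group = NULL) {
  rows <- table[table$target == target, ]
  if (!is.null(group) && "group" %in% names(rows)) rows <- rows[rows$group %in% group, ]
  if (nrow(rows) == 0L) stop("no rows for target: ", target, call. = FALSE)
  rows <- rows[order(rows$dg_reported, rows$compound), ]
  rows$rank <- seq_len(nrow(rows))
  rows
}

# Standard atomic masses (amu) for the elements seen in protein/ligand
# structures; extend here if an element is missing.
element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.453, Br = 79.904, I = 126.904, Na = 22.990,
  Mg = 24.305, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Se = 78.971, Mn = 54.938, Cu = 63.546
)

#' Build a structure snapshot from coordinates and masses
#'
#' @param xyz Numeric matrix `n x 3` (Angstrom).
#' @param mass Atomic masses (amu); a single value is recycled. Default 1
#'   (unweighted).
#' @return A `structure_snapshot`: list with `xyz`, `mass`, `n`, total mass
#'   `m_total`.
#' @export
structure_snapshot <- function(xyz, mass = 1) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) < 1L) stop("xyz must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  mass <- rep_len(as.numeric(mass), nrow(xyz))
  if (any(mass <= 0)) stop("masses must be positive", call. = FALSE)
  structure(list(xyz = unname(xyz), mass = mass, n = nrow(xyz),
                 m_total = sum(mass)),
            class = "structure_snapshot")
}

#' Read coordinates from a PDB file or whitespace XYZ table
#'
#' PDB `ATOM`/`HETATM` records are parsed with `bio3d::read.pdb`; masses come
#' from the element symbol (see `element_masses` in the package source). A
#' plain-text table is read as whitespace-separated `x y z [mass]` rows
#' (mass defaults to 1).
#'
#' @param path File path; `.pdb`/`.ent` files are treated as PDB.
#' @return A `structure_snapshot`.
#' @export
read_structure <- function(path) {
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    el <- trimws(at$elesy)
    blank <- is.na(el) | el == ""
    # fall back to the first letter of the atom name when the element
    # column is absent
    el[blank] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[blank])), 1, 1)
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
    m <- element_masses[el]
    if (anyNA(m)) stop("unknown element(s): ", paste(unique(el[is.na(m)]), collapse = ", "), call. = FALSE)
    structure_snapshot(cbind(at$x, at$y, at$z), unname(m))
  } else {
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) < 3L) stop("XYZ table needs at least 3 columns", call. = FALSE)
    structure_snapshot(as.matrix(tab[, 1:3]),
                       if (ncol(tab) >= 4L) tab[[4L]] else 1)
  }
}

# Mass-weighted Kabsch superposition: rotate + translate `mobile` onto
# `reference`, minimizing the mass-weighted squared deviation.
kabsch_superpose <- function(mobile, reference) {
  m <- mobile$mass
  cm <- colSums(mobile$xyz * m) / sum(m)
  cr <- colSums(reference$xyz * m) / sum(m)
  A <- sweep(mobile$xyz, 2, cm)
  B <- sweep(reference$xyz, 2, cr)
  H <- crossprod(A * m, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- mobile
  out$xyz <- t(R %*% t(A)) + matrix(cr, nrow(A), 3, byrow = TRUE)
  out
}

#' Mass-weighted RMSD between two structures
#'
#' `sqrt( (1/M) * sum_i m_i * ||X_i - Y_i||^2 )` with `M` the total mass and
#' atoms paired by index. As written the formula contains no fitting step;
#' set `superpose = TRUE` to apply an optimal mass-weighted rigid-body
#' (Kabsch) alignment of `target` onto `reference` first, as trajectory
#' tools do by default.
#'
#' @param target,reference `structure_snapshot`s with equal atom counts.
#' @param superpose Apply Kabsch alignment first. Default `FALSE`.
#' @return RMSD in Angstrom.
#' @export
mass_weighted_rmsd <- function(target, reference, superpose = FALSE) {
  stopifnot(inherits(target, "structure_snapshot"),
            inherits(reference, "structure_snapshot"))
  if (target$n != reference$n) stop("atom counts differ", call. = FALSE)
  if (superpose) target <- kabsch_superpose(target, reference)
  d2 <- rowSums((target$xyz - reference$xyz)^2)
  sqrt(sum(target$mass * d2) / target$m_total)
}

#' Per-atom root-mean-square fluctuation over a trajectory
#'
#' For each atom, the root of the mean squared displacement from its
#' time-averaged position: `sqrt(mean_f ||x_i(f) - <x_i>||^2)`.
#'
#' @param trajectory List of `structure_snapshot`s (>= 2 frames, equal atom
#'   counts).
#' @return Numeric vector of per-atom RMSF (Angstrom).
#' @export
rmsf <- function(trajectory) {
  if (length(trajectory) < 2L) stop("need at least 2 frames", call. = FALSE)
  ns <- vapply(trajectory, function(s) s$n, numeric(1))
  if (length(unique(ns)) != 1L) stop("inconsistent atom counts across frames", call. = FALSE)
  n <- trajectory[[1L]]$n
  mean_pos <- Reduce(`+`, lapply(trajectory, `[[`, "xyz")) / length(trajectory)
  dev2 <- vapply(trajectory, function(s) rowSums((s$xyz - mean_pos)^2), numeric(n))
  sqrt(rowMeans(matrix(dev2, nrow = n)))
}
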