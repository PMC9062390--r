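#' Hashed circular fingerprint of a molecular graph
#'
#' Atom-centered environments are grown iteratively (Morgan-style): at radius
#' 0 each atom is described by an invariant string
#' `element:aromatic:charge:degree:nH`; at radius r the previous identifier is
#' combined with the sorted `(bond, neighbour identifier)` pairs. Every
#' identifier is hashed with 64-bit FNV-1a (fixed constants, see `src/`) and
#' folded modulo `n_bits` to set one bit. Identical environments collapse to
#' the same bit, so highly symmetric molecules set few bits.
#'
#' @param graph A `mol_graph` from [parse_smiles()].
#' @param n_bits Fingerprint width in bits (>= 16). Default 1024.
#' @param radius Maximum environment radius (0-4). Default 2.
#' @return Logical vector of length `n_bits` with attributes `n_bits` and
#'   `radius`.
#' @examples
#' fp <- fingerprint(parse_smiles("c1ccccc1"))
#' sum(fp)  # six symmetric atoms share environments
#' @export
fingerprint <- function(graph, n_bits = 1024L, radius = 2L) {
  stopifnot(inherits(graph, "mol_graph"))
  if (nrow(graph$atoms) == 0L) stop("empty graph", call. = FALSE)
  n_bits <- as.integer(n_bits); radius <- as.integer(radius)
  if (n_bits < 16L) stop("n_bits must be >= 16", call. = FALSE)
  if (radius < 0L || radius > 4L) stop("radius must be in 0..4", call. = FALSE)

  n <- nrow(graph$atoms)
  nh <- implicit_h(graph)
  deg <- integer(n)
  adj <- vector("list", n)  # matrix cols: neighbour, bond code
  bond_code <- ifelse(graph$bonds$aromatic, "a", as.character(graph$bonds$order))
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$from[k]; j <- graph$bonds$to[k]
    adj[[i]] <- rbind(adj[[i]], c(j, k)); adj[[j]] <- rbind(adj[[j]], c(i, k))
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }

  ids <- .fnv1a64_hex(sprintf("%s:%d:%d:%d:%d", graph$atoms$element,
                              as.integer(graph$atoms$aromatic),
                              graph$atoms$charge, deg, as.integer(nh)))
  all_ids <- ids
  r <- 0L
  while (r < radius) {
    codes <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (is.null(nb)) return(paste0(ids[a], "|"))
      pairs <- sort(paste0(bond_code[nb[, 2L]], ":", ids[nb[, 1L]]))
      paste0(ids[a], "|", paste(pairs, collapse = ";"))
    }, character(1))
    ids <- .fnv1a64_hex(codes)
    all_ids <- c(all_ids, ids)
    r <- r + 1L
  }
  bits <- unique(.fnv1a64_mod(unique(all_ids), n_bits))
  fp <- logical(n_bits)
  fp[bits + 1L] <- TRUE
  structure(fp, n_bits = n_bits, radius = radius)
}

#' Fold a fingerprint to a smaller width
#'
#' Bitwise OR of equal slices; the standard width reduction used before
#' feeding fingerprints to a model. `length(fp)` must be a multiple of
#' `n_bits_out`.
#'
#' @param fp Logical fingerprint vector.
#' @param n_bits_out Target width.
#' @return Logical vector of length `n_bits_out`.
#' @export
fold_fingerprint <- function(fp, n_bits_out) {
  n <- length(fp)
  n_bits_out <- as.integer(n_bits_out)
  if (n %% n_bits_out != 0L) stop("fingerprint length must be a multiple of n_bits_out", call. = FALSE)
  folded <- as.logical(rowSums(matrix(fp, nrow = n_bits_out)) > 0)
  structure(folded, n_bits = n_bits_out, radius = attr(fp, "radius"))
}

#' Tanimoto similarity between two bit vectors
#'
#' `|a AND b| / |a OR b|`, with the degenerate empty/empty case defined as 1
#' (two empty fingerprints are identical).
#'
#' @param a,b Logical vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch", call. = FALSE)
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

# Tanimoto of one query against the rows of a fingerprint matrix, vectorized.
tanimoto_rows <- function(mat, q) {
  inter <- as.numeric(mat %*% q)
  uni <- rowSums(mat) + sum(q) - inter
  out <- ifelse(uni == 0, 1, inter / uni)
  as.numeric(out)
}

#' Topological descriptors of a molecular graph
#'
#' Fixed ordered vector of 8 descriptors: heavy-atom count, molecular weight
#' (standard atomic masses, implicit hydrogens included), ring count (cycle
#' rank), aromatic-atom count, heteroatom count, hydrogen-bond donor proxy
#' (N/O carrying at least one hydrogen), acceptor proxy (N/O count), and
#' rotatable-bond proxy (acyclic single bonds between non-terminal heavy
#' atoms).
#'
#' @param graph A `mol_graph`.
#' @return Named numeric vector of length 8.
#' @export
descriptors <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  masses <- c(B = 10.811, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
              S = 32.06, F = 18.998, Cl = 35.453, Br = 79.904, I = 126.904)
  nh <- implicit_h(graph)
  el <- graph$atoms$element
  deg <- integer(nrow(graph$atoms))
  for (k in seq_len(nrow(graph$bonds))) {
    deg[graph$bonds$from[k]] <- deg[graph$bonds$from[k]] + 1L
    deg[graph$bonds$to[k]] <- deg[graph$bonds$to[k]] + 1L
  }
  rot <- 0L
  for (k in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[k, ]
    if (b$aromatic || b$order != 1) next
    if (deg[b$from] < 2L || deg[b$to] < 2L) next
    if (!bond_in_ring(graph, k)) rot <- rot + 1L
  }
  c(heavy_atoms = nrow(graph$atoms),
    mol_weight = sum(masses[el]) + sum(nh) * 1.008,
    rings = ring_count(graph),
    aromatic_atoms = sum(graph$atoms$aromatic),
    heteroatoms = sum(el != "C"),
    hbd = sum(el %in% c("N", "O") & nh >= 1),
    hba = sum(el %in% c("N", "O")),
    rotatable_bonds = rot)
}

# A bond is in a ring iff its endpoints stay connected after removing it.
bond_in_ring <- function(graph, k) {
  g2 <- graph
  g2$bonds <- graph$bonds[-k, , drop = FALSE]
  target <- graph$bonds$to[k]
  adj <- adjacency_list(g2)
  seen <- logical(nrow(graph$atoms))
  queue <- graph$bonds$from[k]
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v == target) return(TRUE)
    queue <- c(queue, adj[[v]])
  }
  FALSE
}

#' Min-max feature scaling learned on a training matrix
#'
#' Column-wise scaling to \[0, 1\]. Constant columns map to 0. The learned
#' per-feature `(min, max)` is kept so unseen compounds are scaled with the
#' training statistics and clipped into \[0, 1\].
#'
#' @param x Numeric matrix (compounds in rows, >= 2 rows) or data frame.
#' @return A `feature_scaler`: list with `scaled` (matrix in \[0,1\]) and
#'   `ranges` (tibble: `feature`, `min`, `max`).
#' @seealso [apply_scaler()]
#' @export
normalize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to learn feature ranges", call. = FALSE)
  if (ncol(x) == 0L) stop("empty feature matrix", call. = FALSE)
  mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
  structure(list(
    scaled = scale_minmax(x, mins, maxs),
    ranges = tibble::tibble(
      feature = if (is.null(colnames(x))) paste0("f", seq_len(ncol(x))) else colnames(x),
      min = unname(mins), max = unname(maxs))
  ), class = "feature_scaler")
}

scale_minmax <- function(x, mins, maxs) {
  span <- maxs - mins
  out <- sweep(x, 2, mins, "-")
  out <- sweep(out, 2, ifelse(span == 0, 1, span), "/")
  out[, span == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Apply a learned feature scaler to new data
#'
#' @param scaler A `feature_scaler` from [normalize_features()].
#' @param x Numeric matrix or vector with the same features.
#' @return Matrix scaled with the training `(min, max)`, clipped to \[0, 1\].
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != nrow(scaler$ranges)) stop("feature count mismatch", call. = FALSE)
  scale_minmax(x, scaler$ranges$min, scaler$ranges$max)
}

#' Assemble a compound library
#'
#' @param smiles Character vector of SMILES.
#' @param id Compound identifiers; defaults to `cpd1`, `cpd2`, ... Ids must
#'   be unique.
#' @param provenance Free-text provenance label.
#' @return A `compound_library`: tibble with columns `id`, `smiles` and a
#'   list-column `graph` of parsed `mol_graph` objects.
#' @export
compound_library <- function(smiles, id = NULL, provenance = "user") {
  if (length(smiles) == 0L) stop("empty compound library", call. = FALSE)
  if (is.null(id)) id <- paste0("cpd", seq_along(smiles))
  if (anyDuplicated(id)) stop("compound ids must be unique", call. = FALSE)
  lib <- tibble::tibble(id = as.character(id), smiles = as.character(smiles),
                        graph = purrr::map(smiles, parse_smiles))
  attr(lib, "provenance") <- provenance
  class(lib) <- c("compound_library", class(lib))
  lib
}

#' Read a SMILES file into a compound library
#'
#' One record per line, `SMILES<TAB>id`; the id is optional (auto-generated
#' as `cpd{n}`); lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @param provenance Provenance label; defaults to the file name.
#' @return A `compound_library`.
#' @export
read_smiles_file <- function(path, provenance = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no SMILES records in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L && nzchar(parts[[i]][[2L]])) parts[[i]][[2L]]
    else paste0("cpd", i)
  }, character(1))
  compound_library(smiles, id, provenance)
}

#' Write a compound library as a SMILES file
#'
#' @param library A `compound_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(library, path) {
  writeLines(paste0(library$smiles, "\t", library$id), path)
  invisible(path)
}

#' Fingerprint every compound in a library
#'
#' @param library A `compound_library`.
#' @inheritParams fingerprint
#' @return Logical matrix, one row per compound, rownames = ids.
#' @export
library_fingerprints <- function(library, n_bits = 1024L, radius = 2L) {
  m <- t(vapply(library$graph, function(g) as.logical(fingerprint(g, n_bits, radius)),
                logical(n_bits)))
  rownames(m) <- library$id
  m
}

#' Descriptor matrix for a library
#'
#' @param library A `compound_library`.
#' @return Numeric matrix, one row per compound, 8 descriptor columns.
#' @export
library_descriptors <- function(library) {
  m <- t(vapply(library$graph, descriptors, numeric(8)))
  rownames(m) <- library$id
  m
}

#' Hex encoding of a fingerprint
#'
#' Bits are packed 4 per hex digit, most significant bit first.
#' @param fp Logical fingerprint (length a multiple of 4).
#' @return Hex string.
#' @export
fp_to_hex <- function(fp) {
  stopifnot(length(fp) %% 4L == 0L)
  nib <- matrix(as.integer(fp), nrow = 4L)
  vals <- as.integer(c(8, 4, 2, 1) %*% nib)
  paste(format.hexmode(vals), collapse = "")
}

#' @rdname fp_to_hex
#' @param hex Hex string produced by `fp_to_hex`.
#' @export
hex_to_fp <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], 16L)
  as.logical(as.vector(vapply(vals, function(v) as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L), integer(4))))
}

#' Export library fingerprints as CSV (id + hex-encoded bits)
#'
#' @param library A `compound_library`.
#' @param path Output CSV path.
#' @inheritParams fingerprint
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(library, path, n_bits = 1024L, radius = 2L) {
  m <- library_fingerprints(library, n_bits, radius)
  hex <- apply(m, 1, fp_to_hex)
  utils::write.csv(data.frame(id = rownames(m), fingerprint = hex),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
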