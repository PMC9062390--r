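#' Specification of a synthetic screening benchmark
#'
#' Defines a compound library with a planted structure-activity
#' relationship: a `neighbor_fraction` of the library is generated as
#' bounded graph edits of a seed scaffold (guaranteeing elevated Tanimoto
#' similarity to it), the rest is assembled independently from a fragment
#' grammar. Two designated "true" targets are labelled active with
#' probability `plogis(alpha * tanimoto + intercept)` (labels then flipped
#' at rate `noise`); the remaining targets are labelled at `base_rate`
#' independently of structure.
#'
#' The defaults describe the study conditions used throughout the package's
#' tests: 2000 compounds, an 8-target panel with 2 true targets, 10%
#' scaffold neighbours, a logistic activity rule centred at Tanimoto 0.5
#' (`alpha = 12`, `intercept = -6`), 5% label noise and a 5% off-target
#' base rate.
#'
#' @param n_compounds Library size.
#' @param n_targets Panel size (>= 2).
#' @param target_names Target names; defaults to an 8-member panel named
#'   after classic small-molecule targets.
#' @param true_targets The targets whose labels follow the planted rule.
#' @param seed_scaffold SMILES of the seed scaffold (default: a
#'   piperamide-like scaffold in the supported dialect).
#' @param neighbor_fraction Fraction of the library generated as scaffold
#'   edits, in \[0, 1\].
#' @param alpha,intercept Logistic activity rule coefficients.
#' @param noise Label flip rate in \[0, 0.5\].
#' @param base_rate Active rate of non-true targets.
#' @param n_bits,radius Fingerprint parameters used for the planted rule.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_compounds = 2000L, n_targets = 8L,
                           target_names = NULL,
                           true_targets = c("MAOA", "MAOB"),
                           seed_scaffold = "O=C(C=CC=Cc1ccc2OCOc2c1)N1CCCCC1",
                           neighbor_fraction = 0.1,
                           alpha = 12, intercept = -6,
                           noise = 0.05, base_rate = 0.05,
                           n_bits = 1024L, radius = 2L) {
  if (is.null(target_names)) {
    pool <- c("MAOA", "MAOB", "TRPV1", "NFKB", "CA1", "CA2", "LOX", "PGP1",
              paste0("T", seq_len(max(0L, n_targets - 8L))))
    target_names <- pool[seq_len(n_targets)]
  }
  if (n_targets < 2L) stop("n_targets must be >= 2", call. = FALSE)
  if (length(target_names) != n_targets) stop("target_names length mismatch", call. = FALSE)
  if (!all(true_targets %in% target_names)) stop("true_targets must be in target_names", call. = FALSE)
  if (neighbor_fraction < 0 || neighbor_fraction > 1) stop("neighbor_fraction must be in [0,1]", call. = FALSE)
  if (noise < 0 || noise > 0.5) stop("noise must be in [0, 0.5]", call. = FALSE)
  parse_smiles(seed_scaffold)  # errors early on an unparsable scaffold
  structure(list(n_compounds = as.integer(n_compounds),
                 n_targets = as.integer(n_targets),
                 target_names = target_names, true_targets = true_targets,
                 seed_scaffold = seed_scaffold,
                 neighbor_fraction = neighbor_fraction,
                 alpha = alpha, intercept = intercept, noise = noise,
                 base_rate = base_rate, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "benchmark_spec")
}

# fragment grammar for background compounds
.frag_rings <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "c1ccoc1",
                 "C1CCOC1", "c1ccsc1", "C1CCC1", "c1cc[nH]c1")
.frag_chains <- c("CC", "CCC", "CCCC", "C=CC", "CCO", "CCN", "C#N",
                  "C(=O)O", "C(=O)N", "CC(C)C", "COC", "CS")
.frag_subs <- c("O", "N", "F", "Cl", "Br", "C", "OC", "C=O")

random_background_smiles <- function() {
  repeat {
    base <- sample(c(.frag_rings, .frag_chains), 1L,
                   prob = rep(c(2, 1), c(length(.frag_rings), length(.frag_chains))))
    n_extra <- sample(0:3, 1L)
    s <- base
    for (i in seq_len(n_extra)) {
      frag <- sample(c(.frag_chains, .frag_subs, .frag_rings), 1L)
      s <- if (stats::runif(1) < 0.3) paste0(s, "(", frag, ")") else paste0(s, frag)
    }
    g <- tryCatch(parse_smiles(s), error = function(e) NULL)
    if (!is.null(g)) return(s)
  }
}

# one bounded random edit of a molecular graph; returns the graph unchanged
# when no edit site exists
edit_graph <- function(graph) {
  nh <- implicit_h(graph)
  deg <- integer(nrow(graph$atoms))
  ordsum <- numeric(nrow(graph$atoms))
  for (k in seq_len(nrow(graph$bonds))) {
    f <- graph$bonds$from[k]; t <- graph$bonds$to[k]
    deg[f] <- deg[f] + 1L; deg[t] <- deg[t] + 1L
    o <- if (graph$bonds$aromatic[k]) 1 else graph$bonds$order[k]
    ordsum[f] <- ordsum[f] + o; ordsum[t] <- ordsum[t] + o
  }
  op <- sample(c("substitute", "append", "delete"), 1L)
  if (op == "substitute") {
    el <- sample(c("N", "O"), 1L)
    cap <- if (el == "O") 2 else 3
    cand <- which(!graph$atoms$aromatic & graph$atoms$element == "C" & ordsum <= cap)
    if (length(cand) == 0L) return(graph)
    graph$atoms$element[resample(cand)] <- el
  } else if (op == "append") {
    cand <- which(nh >= 1)
    if (length(cand) == 0L) return(graph)
    at <- resample(cand)
    el <- sample(c("C", "N", "O", "F", "Cl"), 1L)
    graph$atoms <- tibble::add_row(graph$atoms, idx = nrow(graph$atoms) + 1L,
                                   element = el, aromatic = FALSE,
                                   charge = 0L, h_explicit = NA_integer_)
    graph$bonds <- tibble::add_row(graph$bonds, from = at,
                                   to = nrow(graph$atoms), order = 1,
                                   aromatic = FALSE)
  } else {
    cand <- which(deg == 1L)
    if (length(cand) == 0L || nrow(graph$atoms) <= 3L) return(graph)
    at <- resample(cand)
    keep <- graph$bonds$from != at & graph$bonds$to != at
    graph$bonds <- graph$bonds[keep, ]
    graph$atoms <- graph$atoms[-at, ]
    graph$atoms$idx <- seq_len(nrow(graph$atoms))
    graph$bonds$from <- graph$bonds$from - (graph$bonds$from > at)
    graph$bonds$to <- graph$bonds$to - (graph$bonds$to > at)
  }
  graph
}

resample <- function(x) if (length(x) == 1L) x else sample(x, 1L)

neighbor_smiles <- function(scaffold_graph) {
  g <- scaffold_graph
  for (i in seq_len(sample(1:3, 1L))) g <- edit_graph(g)
  write_smiles(g)
}

#' Generate a synthetic compound library
#'
#' Deterministic under `seed`: `neighbor_fraction * n_compounds` compounds
#' are bounded edits (heteroatom substitutions, terminal additions and
#' deletions) of the seed scaffold, the rest independent fragment-grammar
#' assemblies. All SMILES re-parse under [parse_smiles()].
#'
#' @param spec A [benchmark_spec()].
#' @param seed Integer seed.
#' @return A `compound_library`; ids `nbr...` for scaffold neighbours and
#'   `bg...` for background compounds.
#' @export
generate_library <- function(spec, seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  n <- spec$n_compounds
  n_nbr <- as.integer(round(spec$neighbor_fraction * n))
  scaffold <- parse_smiles(spec$seed_scaffold)
  withr::with_seed(as.integer(seed), {
    nbr <- vapply(seq_len(n_nbr), function(i) neighbor_smiles(scaffold), character(1))
    bg <- vapply(seq_len(n - n_nbr), function(i) random_background_smiles(), character(1))
    ids <- c(sprintf("nbr%04d", seq_len(n_nbr)),
             sprintf("bg%04d", seq_len(n - n_nbr)))
    compound_library(c(nbr, bg), ids,
                     provenance = sprintf("synthetic benchmark (seed %d)", as.integer(seed)))
  })
}

#' Plant a structure-activity signal over a library
#'
#' @param library A `compound_library` (typically from [generate_library()]).
#' @param spec A [benchmark_spec()].
#' @param seed Integer seed.
#' @return An `activity_dataset` with an attached `ground_truth` tibble
#'   (`id`, `tanimoto_to_seed`, per-true-target activity probability).
#' @export
generate_activity <- function(library, spec, seed) {
  stopifnot(inherits(library, "compound_library"), inherits(spec, "benchmark_spec"))
  seed_fp <- as.logical(fingerprint(parse_smiles(spec$seed_scaffold),
                                    spec$n_bits, spec$radius))
  fps <- library_fingerprints(library, spec$n_bits, spec$radius)
  sim <- tanimoto_rows(fps, seed_fp)
  n <- nrow(library)
  act <- tibble::tibble(id = library$id)
  gt <- tibble::tibble(id = library$id, tanimoto_to_seed = sim)
  withr::with_seed(as.integer(seed), {
    for (tg in spec$target_names) {
      if (tg %in% spec$true_targets) {
        p <- stats::plogis(spec$alpha * sim + spec$intercept)
        lab <- stats::rbinom(n, 1L, p)
        flip <- stats::rbinom(n, 1L, spec$noise) == 1L
        lab[flip] <- 1L - lab[flip]
        gt[[paste0("p_", tg)]] <- p
      } else {
        lab <- stats::rbinom(n, 1L, spec$base_rate)
      }
      act[[tg]] <- lab
    }
  })
  ds <- activity_dataset(library, act)
  attr(ds, "ground_truth") <- gt
  ds
}

#' Build the full benchmark fixture in one call
#'
#' Library + planted activity + split + a manifest echoing the spec, all
#' deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param spec A [benchmark_spec()]; defaults to the standard study
#'   conditions.
#' @param test_fraction Held-out fraction for the recorded split.
#' @return A `benchmark`: list with `spec`, `library`, `dataset`,
#'   `ground_truth`, `split` and `manifest`.
#' @export
make_benchmark <- function(seed, spec = benchmark_spec(), test_fraction = 0.3) {
  seed <- as.integer(seed)
  library <- generate_library(spec, seed)
  dataset <- generate_activity(library, spec, seed + 1L)
  split <- split_dataset(nrow(library), test_fraction, seed + 2L)
  gt <- attr(dataset, "ground_truth")
  manifest <- list(
    spec = unclass(spec), seed = seed, test_fraction = test_fraction,
    n_compounds = nrow(library),
    n_neighbors = sum(startsWith(library$id, "nbr")),
    active_rate = vapply(dataset$activity[spec$target_names], mean, numeric(1))
  )
  structure(list(spec = spec, library = library, dataset = dataset,
                 ground_truth = gt, split = split, manifest = manifest),
            class = "benchmark")
}

#' @export
print.benchmark <- function(x, ...) {
  cat(sprintf("<benchmark> %d compounds (%d scaffold neighbours), %d targets (true: %s)\n",
              x$manifest$n_compounds, x$manifest$n_neighbors,
              x$spec$n_targets, paste(x$spec$true_targets, collapse = ", ")))
  invisible(x)
}

#' Write a benchmark to disk as plain-text files
#'
#' Emits `library.smi` (SMILES + id), `activity.csv`, `ground_truth.csv` and
#' `manifest.json` into `dir`.
#'
#' @param benchmark A `benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_smiles_file(benchmark$library, file.path(dir, "library.smi"))
  utils::write.csv(benchmark$dataset$activity, file.path(dir, "activity.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(benchmark$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(benchmark$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
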