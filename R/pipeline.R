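#' Bundle a compound library with a compound-by-target activity panel
#'
#' @param library A `compound_library`.
#' @param activity Data frame: column `id` plus one column per target with
#'   binary labels (0/1) or real affinities. Rows must cover exactly the
#'   library ids; no missing values.
#' @return An `activity_dataset`: list with `library`, `activity` (tibble,
#'   library row order) and `targets` (character).
#' @export
activity_dataset <- function(library, activity) {
  stopifnot(inherits(library, "compound_library"))
  activity <- tibble::as_tibble(activity)
  if (!"id" %in% names(activity)) stop("activity table needs an `id` column", call. = FALSE)
  if (!setequal(activity$id, library$id)) {
    stop("activity ids do not match the library", call. = FALSE)
  }
  activity <- activity[match(library$id, activity$id), ]
  if (anyNA(activity)) stop("activity table contains missing values", call. = FALSE)
  targets <- setdiff(names(activity), "id")
  if (length(targets) < 1L) stop("activity table has no target columns", call. = FALSE)
  structure(list(library = library, activity = activity, targets = targets),
            class = "activity_dataset")
}

#' Read an activity table (CSV: id column + one column per target)
#'
#' @param path CSV path.
#' @return Tibble suitable for [activity_dataset()].
#' @export
read_activity_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' Shuffle-split record indices into training and test sets
#'
#' The test set takes `floor(test_fraction * n)` records (the rounding rule
#' that reproduces a 40197/17226 split of 57423 records at 30% test); the
#' rest train. The permutation is drawn from a seeded generator, so splits
#' are reproducible.
#'
#' @param n Number of records.
#' @param test_fraction Test fraction in (0, 1). Default 0.3.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (disjoint, covering
#'   `1:n`).
#' @export
split_dataset <- function(n, test_fraction = 0.3, seed) {
  if (length(n) != 1L || is.na(n) || n < 1L || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  n_test <- as.integer(floor(test_fraction * n))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  list(train = sort(perm[seq_len(n - n_test)]),
       test = if (n_test > 0L) sort(perm[n - n_test + seq_len(n_test)]) else integer(0))
}

#' Featurize a library for the target-prediction network
#'
#' Network input is the hashed circular fingerprint folded to `nn_bits`
#' concatenated with the 8 descriptors scaled by `scaler` (learned on the
#' training split only).
#' @noRd
model_features <- function(library, scaler, fp_bits, nn_bits, radius) {
  fps <- library_fingerprints(library, fp_bits, radius)
  folded <- t(apply(fps, 1, function(r) as.numeric(fold_fingerprint(r, nn_bits))))
  desc <- apply_scaler(scaler, library_descriptors(library))
  cbind(folded, desc)
}

#' Train the multitask target-prediction network
#'
#' Splits the dataset, learns descriptor scaling on the training split,
#' trains one sigmoid-output network over all targets with the
#' Levenberg-Marquardt loop, and evaluates on the held-out split.
#'
#' @param dataset An `activity_dataset`.
#' @param seed Integer seed (split, weight initialization).
#' @param test_fraction Held-out fraction, default 0.3.
#' @param hidden Hidden layer sizes, default 8.
#' @param fp_bits,radius Fingerprint parameters (default 1024 bits, radius
#'   2).
#' @param nn_bits Folded fingerprint width fed to the network, default 64.
#' @param control [lm_control()] for training; default caps iterations at
#'   60.
#' @param threshold Classification threshold for held-out accuracy.
#' @return A `target_model`: list with `fit` (`lmnet_fit`), `scaler`,
#'   feature settings, `targets`, `split`, and `metrics` (held-out
#'   `metrics_report`).
#' @export
train_target_model <- function(dataset, seed, test_fraction = 0.3,
                               hidden = 8L, fp_bits = 1024L, nn_bits = 64L,
                               radius = 2L,
                               control = lm_control(max_iter = 60L),
                               threshold = 0.5) {
  stopifnot(inherits(dataset, "activity_dataset"))
  n <- nrow(dataset$library)
  split <- split_dataset(n, test_fraction, seed)
  if (length(split$train) < 2L) stop("fewer than 2 training samples", call. = FALSE)

  desc <- library_descriptors(dataset$library)
  scaler <- normalize_features(desc[split$train, , drop = FALSE])
  feats <- model_features(dataset$library, scaler, fp_bits, nn_bits, radius)
  targets <- as.matrix(dataset$activity[dataset$targets])

  net <- lmnet(c(ncol(feats), hidden, length(dataset$targets)),
               "sigmoid", seed = seed)
  fit <- lm_train(net, feats[split$train, , drop = FALSE],
                  targets[split$train, , drop = FALSE], control)

  scores_test <- predict(fit$net, feats[split$test, , drop = FALSE])
  eval_df <- tibble::tibble(t = as.vector(targets[split$test, , drop = FALSE]),
                            y = as.vector(scores_test))
  metrics <- metrics_report(eval_df, label = "t", threshold = threshold)

  structure(list(fit = fit, scaler = scaler, fp_bits = as.integer(fp_bits),
                 nn_bits = as.integer(nn_bits), radius = as.integer(radius),
                 targets = dataset$targets, split = split, seed = seed,
                 threshold = threshold, metrics = metrics),
            class = "target_model")
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf("<target_model> %d targets | held-out accuracy %.3f | %s\n",
              length(x$targets), x$metrics$accuracy, x$fit$state$status))
  invisible(x)
}

#' @export
glance.target_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit), x$metrics["accuracy"])
}

query_graph <- function(query) {
  if (inherits(query, "mol_graph")) query else parse_smiles(query)
}

query_features <- function(model, query) {
  g <- query_graph(query)
  fp <- fold_fingerprint(fingerprint(g, model$fp_bits, model$radius), model$nn_bits)
  c(as.numeric(fp), as.numeric(apply_scaler(model$scaler, descriptors(g))))
}

#' Score and rank targets for a query compound
#'
#' Forward pass of the trained network on the query's features; targets are
#' sorted by descending score, ties broken by target name.
#'
#' @param model A `target_model`.
#' @param query SMILES string or `mol_graph`.
#' @param query_id Label recorded on the result.
#' @return A `target_ranking` tibble: `target`, `score`.
#' @export
predict_targets <- function(model, query, query_id = "query") {
  stopifnot(inherits(model, "target_model"))
  x <- query_features(model, query)
  scores <- as.numeric(predict(model$fit$net, matrix(x, nrow = 1L)))
  out <- tibble::tibble(target = model$targets, score = scores)
  out <- out[order(-out$score, out$target), ]
  attr(out, "query_id") <- query_id
  class(out) <- c("target_ranking", class(out))
  out
}

#' Top-k fingerprint similarity search against a library
#'
#' Tanimoto similarity of the query fingerprint against every library
#' member; the top `k` are returned sorted by descending similarity, ties
#' broken by id. A library member whose id equals `query_id` is excluded
#' (structural duplicates under other ids are kept).
#'
#' @param query SMILES string or `mol_graph`.
#' @param library A `compound_library`.
#' @param k Number of hits, default 100.
#' @param n_bits,radius Fingerprint parameters.
#' @param query_id Id of the query (for self-exclusion and labelling).
#' @return A `hit_list` tibble: `id`, `smiles`, `similarity`.
#' @export
similarity_search <- function(query, library, k = 100L, n_bits = 1024L,
                              radius = 2L, query_id = "query") {
  stopifnot(inherits(library, "compound_library"))
  if (nrow(library) == 0L) stop("empty library", call. = FALSE)
  qfp <- as.logical(fingerprint(query_graph(query), n_bits, radius))
  keep <- library$id != query_id
  lib <- library[keep, ]
  if (nrow(lib) == 0L) stop("library contains only the query itself", call. = FALSE)
  fps <- library_fingerprints(lib, n_bits, radius)
  sim <- tanimoto_rows(fps, qfp)
  ord <- order(-sim, lib$id)
  take <- ord[seq_len(min(k, length(ord)))]
  out <- tibble::tibble(id = lib$id[take], smiles = lib$smiles[take],
                        similarity = sim[take])
  attr(out, "query_id") <- query_id
  attr(out, "k") <- as.integer(k)
  class(out) <- c("hit_list", class(out))
  out
}

#' Prioritize similarity hits with the target-prediction network
#'
#' Re-scores every hit with the network output for one chosen target and
#' keeps the `top_n` by score; ties broken by similarity, then id.
#'
#' @param hits A `hit_list` (needs `id`, `smiles`, `similarity`).
#' @param model A `target_model`.
#' @param target Target name from the model's panel.
#' @param top_n Number of compounds to keep, default 5.
#' @return A `hit_list` tibble with an extra `nn_score` column, sorted by
#'   descending `nn_score`.
#' @export
prioritize_hits <- function(hits, model, target, top_n = 5L) {
  stopifnot(inherits(model, "target_model"))
  if (nrow(hits) == 0L) stop("empty hit list", call. = FALSE)
  ti <- match(target, model$targets)
  if (is.na(ti)) stop("unknown target: ", target, call. = FALSE)
  X <- t(vapply(hits$smiles, function(s) query_features(model, s),
                numeric(model$nn_bits + 8L)))
  scores <- predict(model$fit$net, X)[, ti]
  out <- hits
  out$nn_score <- as.numeric(scores)
  out <- out[order(-out$nn_score, -out$similarity, out$id), ]
  out <- out[seq_len(min(top_n, nrow(out))), ]
  attr(out, "query_id") <- attr(hits, "query_id")
  attr(out, "target") <- target
  class(out) <- unique(c("hit_list", class(out)))
  out
}

#' Save / load a trained target model as portable JSON
#'
#' Stores the network (weights at full precision), descriptor scaling
#' ranges, target panel and featurization settings, so predictions from the
#' reloaded model are bit-identical.
#'
#' @param model A `target_model`.
#' @param path File path.
#' @return `path` invisibly; `read_target_model` returns the `target_model`
#'   (without the training split and held-out metrics, which belong to the
#'   training run).
#' @export
write_target_model <- function(model, path) {
  stopifnot(inherits(model, "target_model"))
  net <- model$fit$net
  payload <- list(
    layer_sizes = net$layer_sizes,
    activations = net$activations,
    weights = lapply(net$weights, function(w) as.vector(t(w))),
    biases = net$biases,
    scaler_ranges = model$scaler$ranges,
    targets = model$targets,
    fp_bits = model$fp_bits, nn_bits = model$nn_bits, radius = model$radius,
    threshold = model$threshold, seed = model$seed
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_target_model
#' @export
read_target_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  net <- rebuild_lmnet(p)
  ranges <- dplyr::bind_rows(lapply(p$scaler_ranges, tibble::as_tibble))
  scaler <- structure(list(scaled = NULL, ranges = ranges),
                      class = "feature_scaler")
  structure(list(fit = structure(list(net = net, state = NULL, control = NULL),
                                 class = "lmnet_fit"),
                 scaler = scaler, fp_bits = as.integer(unlist(p$fp_bits)),
                 nn_bits = as.integer(unlist(p$nn_bits)),
                 radius = as.integer(unlist(p$radius)),
                 targets = as.character(unlist(p$targets)), split = NULL,
                 seed = unlist(p$seed), threshold = unlist(p$threshold),
                 metrics = NULL),
            class = "target_model")
}
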