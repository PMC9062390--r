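test_that("library generation is byte-identical under a fixed seed", {
  spec <- small_spec(100L)
  l1 <- generate_library(spec, 11)
  l2 <- generate_library(spec, 11)
  expect_identical(l1$smiles, l2$smiles)
  expect_identical(l1$id, l2$id)
  expect_false(identical(generate_library(spec, 12)$smiles, l1$smiles))
  expect_equal(sum(startsWith(l1$id, "nbr")), 10L)
})

test_that("every generated SMILES round-trips through the parser", {
  lib <- generate_library(small_spec(120L), 3)
  for (i in seq_len(nrow(lib))) {
    g <- lib$graph[[i]]
    g2 <- parse_smiles(write_smiles(g))
    expect_equal(nrow(g2$atoms), nrow(g$atoms), info = lib$smiles[i])
    expect_equal(nrow(g2$bonds), nrow(g$bonds), info = lib$smiles[i])
  }
})

test_that("planted neighbours dominate background similarity (rank test across seeds)", {
  spec <- small_spec(150L)
  seed_fp <- as.logical(fingerprint(parse_smiles(spec$seed_scaffold)))
  p_values <- vapply(1:20, function(seed) {
    lib <- generate_library(spec, seed)
    fps <- library_fingerprints(lib)
    sim <- lmscreen:::tanimoto_rows(fps, seed_fp)
    nbr <- startsWith(lib$id, "nbr")
    stats::wilcox.test(sim[nbr], sim[!nbr], alternative = "greater", exact = FALSE)$p.value
  }, numeric(1))
  expect_true(all(p_values < 1e-3))
})

test_that("neighbour fraction controls the similarity structure", {
  all_nbr <- generate_library(benchmark_spec(n_compounds = 60L, neighbor_fraction = 1), 5)
  no_nbr <- generate_library(benchmark_spec(n_compounds = 60L, neighbor_fraction = 0), 5)
  seed_fp <- as.logical(fingerprint(parse_smiles(benchmark_spec()$seed_scaffold)))
  sim_nbr <- lmscreen:::tanimoto_rows(library_fingerprints(all_nbr), seed_fp)
  sim_bg <- lmscreen:::tanimoto_rows(library_fingerprints(no_nbr), seed_fp)
  expect_gt(stats::median(sim_nbr), stats::median(sim_bg))
  expect_true(all(startsWith(all_nbr$id, "nbr")))
  expect_true(all(startsWith(no_nbr$id, "bg")))
})

test_that("noise-free steep activity labels are a near-step function of similarity", {
  spec <- benchmark_spec(n_compounds = 150L, alpha = 400, intercept = -200, noise = 0)
  lib <- generate_library(spec, 9)
  ds <- generate_activity(lib, spec, 10)
  gt <- attr(ds, "ground_truth")
  lab <- ds$activity$MAOA
  expect_true(all(lab[gt$tanimoto_to_seed > 0.52] == 1))
  expect_true(all(lab[gt$tanimoto_to_seed < 0.48] == 0))
})

test_that("off-target labels follow the base rate, independent of similarity", {
  spec <- benchmark_spec(n_compounds = 400L, base_rate = 0.2)
  lib <- generate_library(spec, 21)
  ds <- generate_activity(lib, spec, 22)
  rate <- mean(ds$activity$TRPV1)
  expect_equal(rate, 0.2, tolerance = 0.3)
  gt <- attr(ds, "ground_truth")
  # no monotone association with similarity for a base-rate target
  ct <- stats::cor.test(gt$tanimoto_to_seed, ds$activity$TRPV1, method = "spearman",
                        exact = FALSE)
  expect_gt(ct$p.value, 0.01)
})

test_that("make_benchmark produces a deterministic, self-describing fixture", {
  b1 <- make_benchmark(7, small_spec(100L))
  b2 <- make_benchmark(7, small_spec(100L))
  expect_identical(b1$library$smiles, b2$library$smiles)
  expect_identical(b1$dataset$activity, b2$dataset$activity)
  expect_identical(b1$split, b2$split)
  expect_equal(b1$manifest$n_compounds, 100L)
  expect_true(all(c("spec", "active_rate") %in% names(b1$manifest)))

  dir <- withr::local_tempdir()
  write_benchmark(b1, dir)
  expect_true(all(file.exists(file.path(dir, c("library.smi", "activity.csv",
                                               "ground_truth.csv", "manifest.json")))))
  relib <- read_smiles_file(file.path(dir, "library.smi"))
  expect_identical(relib$smiles, b1$library$smiles)
})

test_that("ground truth suffices to score a hit list for enrichment", {
  bm <- small_benchmark()
  hits <- similarity_search(bm$spec$seed_scaffold, bm$library, k = 30)
  gt <- bm$ground_truth
  act <- bm$dataset$activity
  hit_rate <- mean(act$MAOA[match(hits$id, act$id)])
  base_rate <- mean(act$MAOA)
  expect_gt(hit_rate, base_rate)
})
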