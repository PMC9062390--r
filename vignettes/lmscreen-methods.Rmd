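---
title: "Methods: ligand-based screening with Levenberg-Marquardt networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based screening with Levenberg-Marquardt networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmscreen)
```

## What the package does

`lmscreen` implements a two-step ligand-based virtual screen. Step one trains
a small multitask feedforward network to score a panel of protein targets for
a query compound; step two runs a fingerprint (Tanimoto) similarity search of
the query against a compound library and re-scores the top hits with the
network to prioritize a short list. Around this core the package provides the
evaluation metrics used for such models (RMSE, MAE, Pearson's R, residual
regression deviation, thresholded accuracy) and the arithmetic used to
analyse docking and molecular-dynamics output downstream of a screen:
docking-score ranking, MM-GBSA-style binding-free-energy bookkeeping, and
mass-weighted RMSD/RMSF over coordinate sets.

The motivating use case is a natural-product query (a piperamide scaffold)
screened against an 8-member target panel in which the two monoamine
oxidases are the true targets; the synthetic benchmark below reproduces that
situation with known ground truth.

## Molecular representation

**SMILES dialect.** The parser covers the organic subset (B, C, N, O, P, S,
F, Cl, Br, I), aromatic lowercase atoms plus `[nH]`, branches, ring closures
`1`-`9`/`%nn`, and explicit `-`, `=`, `#`, `:` bonds. Stereochemistry,
isotopes, charges and general bracket atoms are deliberately out of scope:
the screening method operates on 2D connectivity, and the restricted dialect
covers the scaffold and drug-like molecules the package generates. A bond
written without a symbol between two aromatic atoms is aromatic; implicit
hydrogen counts follow standard valences with aromatic atoms consuming one
extra valence unit (so benzene carbons carry one H and pyridine's nitrogen
none). `write_smiles()` inverts the parser up to graph isomorphism: atom,
bond and ring counts are preserved through a parse-emit-parse cycle, which
the generator relies on when it emits edited scaffolds.

**Fingerprints.** Featurization uses a hashed circular (Morgan-type)
fingerprint: each atom's environment at radii 0..2 is summarized as a
canonical invariant string, hashed with 64-bit FNV-1a (fixed constants,
implemented in C++ so the bits are identical across platforms), and folded
modulo 1024 bits. Tanimoto similarity `|A∩B|/|A∪B|` is the search metric,
with the empty/empty case defined as 1. Eight cheap topological descriptors
(heavy atoms, molecular weight, cycle rank, aromatic atoms, heteroatoms,
donor/acceptor proxies, rotatable-bond proxy) complement the bits.

**Normalization.** Descriptors are min-max scaled to [0, 1] per feature,
with the ranges learned on the training split only and unseen compounds
clipped into the unit interval; constant columns map to 0. Min-max scaling
is the natural choice in front of a sigmoid-output network.

## The training loop

The network is fully connected with one hidden layer (sigmoid activations
throughout by default); weights `w_l` map layer `l-1` to `l`, with a
separate bias vector per layer. Training minimizes `F(w) = e'e` where `e`
stacks the residuals `prediction - target` sample-major. Each iteration
solves the damped normal equations

```
(J'J + mu I) delta = J'e,      w <- w - delta
```

with `J` the analytic Jacobian of the residuals (per-output
backpropagation; validated in the tests against a central finite-difference
oracle to 1e-6 relative). A step that lowers `F` is accepted and the damping
shrinks (`mu <- mu * beta`); otherwise the weights are kept and the damping
grows (`mu <- mu / beta`). Defaults are `mu = 0.01` and `beta = 0.1`. The
sign convention matters: with residuals defined as prediction minus target,
the *subtraction* `w - delta` is the descent update — the only reading under
which accepted steps can decrease `F` — so that is what `lm_step()`
implements. At vanishing `mu` a single accepted step on a linear model lands
on the normal-equations solution, which the acceptance tests verify to
1e-8.

Numerical choices: the damped system is solved by Cholesky factorization
with a least-squares (`qr.solve`) fallback when the factorization fails —
damping usually, but not always, regularizes `J'J`. Training stops when `F`
falls below `f_tol` (1e-6), when the relative improvement over the last 5
accepted steps drops below `rel_tol` (1e-9), at `max_iter` (200), or when
`mu` exceeds `1e10` (reported as `mu_overflow`). Weights initialize
uniform(-0.5, 0.5) from a mandatory seed, so every run is exactly
reproducible; model files are JSON with 17 significant digits, enough for
bit-identical reloads.

The accepted-step `F` history is monotonically non-increasing by
construction; the test suite checks this across 20 seeded random problems
rather than trusting the construction.

## The screening pipeline

`split_dataset()` shuffles with a seeded generator and takes
`floor(test_fraction * n)` records for the test set — the rounding rule
under which 57 423 records at 30% test give exactly 40 197 training and
17 226 test records. `train_target_model()` fits one multitask network with
one sigmoid output per target (a single network rather than per-target
models: the targets share structure and one training loop is cheaper and
more stable than eight). Its input is the 1024-bit fingerprint folded by OR
to 64 bits plus the 8 scaled descriptors. Folding is the standard width
reduction for model input: full-width input would put ~16k parameters into
`J'J` (gigabytes per iteration) without adding signal at the corpus sizes
this package targets; 64 bits plus descriptors recovers the planted signal
comfortably (held-out accuracy ≈ 0.92 at the default conditions). The
default hidden width is 8 and training caps at 60 iterations — past that the
fit is deep into diminishing returns on the benchmark.

`predict_targets()` ranks the panel by network score (ties broken by target
name); `similarity_search()` ranks the library by Tanimoto similarity (top
100 by default, ties by compound id, the query's own id excluded but
structural duplicates kept); `prioritize_hits()` re-scores hits with the
network output for a chosen target and keeps the top 5 by default. All tie
breaks are lexicographic so results are byte-identical under a fixed seed.

## The synthetic benchmark

No public corpus accompanies the workflow this package implements, so the
generator builds one with the statistical structure the pipeline assumes,
and with ground truth retained so every claim is checkable:

* **Library** (default n = 2000): 10% are bounded edits of the seed scaffold
  (heteroatom substitutions on aliphatic carbons, terminal additions,
  terminal deletions, 1-3 edits per molecule), which concentrates their
  Tanimoto similarity to the seed around 0.5-0.9; the remaining 90% are
  fragment-grammar assemblies (rings, chains, substituents) whose similarity
  to the seed sits near 0.05-0.15.
* **Activity**: for the two true targets, `P(active) =
  plogis(12 * tanimoto - 6)` — a logistic rule centred at similarity 0.5, so
  background compounds are almost never active and close neighbours almost
  always are — with 5% label flips. The six decoy targets are Bernoulli(0.05)
  independent of structure. A 5% active rate reflects how rare actives are
  in screening corpora; it also means a useful model must beat a ~90-95%
  majority-class baseline on the true targets, which the network does by a
  clear margin on the seed compound ranking (both true targets score near 1,
  decoys near 0).

Everything is deterministic under one seed. The benchmark emulates the
*statistical* shape of a screening corpus — a similarity-driven activity
cliff plus structureless decoys — not the property distributions of real
vendor libraries (no medicinal-chemistry filters, no tautomers or charge
states, no assay-specific noise structure). Passing the recovery tests shows
the machinery extracts a planted signal; it does not certify performance on
real assay panels.

Problem sizes in the shipped tests and acceptance script (2000 compounds,
70/30 split, 20-seed enrichment replicates, hidden width 8) are the
package's standard desk-scale conditions; all are plain function arguments.

## Post-docking arithmetic

The analysis helpers operate on tabulated results, not on structures or
trajectories:

* `rank_scores()` sorts docking scores ascending (most negative = strongest
  predicted binding). Docking tables occasionally drop a minus sign in
  transcription; tables are stored verbatim and an `assume_negative` flag
  (default off) lets an analysis treat bare positives as negative.
* `binding_free_energy()` is `G_complex - (G_receptor + G_ligand)`;
  `total_energy()` is the component sum
  `E_bond + E_vdw + E_elec + G_PB + G_SA - TS_S`. Published component tables
  often omit terms (typically polar solvation); the reader therefore stores
  the reported total verbatim, never reconstructs it from components, and
  warns — not errors — when complete components contradict it.
* `mass_weighted_rmsd()` implements exactly
  `sqrt((1/M) * sum_i m_i ||X_i - Y_i||^2)` with atoms paired by index. The
  plain formula contains no fitting step, so superposition is **off by
  default**; `superpose = TRUE` applies a mass-weighted Kabsch alignment
  first, matching what trajectory tools do by default. Superposed RMSD is
  never larger than raw RMSD. `rmsf()` is the per-atom root mean squared
  deviation from the time-averaged position.

## Known limitations

* The SMILES dialect excludes stereochemistry and charged species; the
  fingerprint is 2D only.
* The regression deviation uses the measured-on-predicted direction with an
  `n - 1` denominator; both are conventions (stated in `regression_sd()`
  docs) rather than universals, so compare like with like.
* Levenberg-Marquardt scales quadratically in parameter count; the
  implementation is meant for the small networks used here, not for deep
  models.
* The benchmark's decoy targets are structureless by design; a model can
  do nothing better than the base rate on them, which bounds attainable
  panel-wide accuracy.
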