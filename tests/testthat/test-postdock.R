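test_that("score table reader validates and ranks the docking fixture", {
  tab <- read_score_table(fixture_path("table1_docking_scores.csv"))
  expect_equal(nrow(tab), 18L)
  expect_setequal(unique(tab$target), c("MAO-A", "MAO-B"))

  r <- rank_scores(tab, "MAO-A")
  expect_equal(r$compound[1], "Compound 2")
  expect_equal(r$score_kcal_mol[1], -9.8)
  rc <- rank_scores(tab, "MAO-A", group = "control")
  expect_equal(rc$compound[1], "Lazabemide")
  expect_equal(rc$score_kcal_mol[1], -6.06)
  expect_error(rank_scores(tab, "MAO-X"), "no rows")

  # ranking is a permutation of the target's rows, invariant to input order
  shuffled <- tab[withr::with_seed(2, sample(nrow(tab))), ]
  class(shuffled) <- class(tab)
  expect_equal(rank_scores(shuffled, "MAO-B")$compound,
               rank_scores(tab, "MAO-B")$compound)
  expect_setequal(rank_scores(tab, "MAO-B")$compound,
                  tab$compound[tab$target == "MAO-B"])
})

test_that("assume_negative flips the sign-dropped transcription value", {
  tab <- read_score_table(fixture_path("table1_docking_scores.csv"))
  # compound 5 vs MAO-B is printed as bare 9.3 and transcribed verbatim
  expect_equal(tab$score_kcal_mol[tab$compound == "Compound 5" & tab$target == "MAO-B"], 9.3)
  fixed <- read_score_table(fixture_path("table1_docking_scores.csv"),
                            assume_negative = TRUE)
  expect_equal(fixed$score_kcal_mol[fixed$compound == "Compound 5" & fixed$target == "MAO-B"], -9.3)
})

test_that("malformed score tables are rejected with line numbers", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,target,score_kcal_mol,group",
               "a,T,-1.0,g", "a,T,-2.0,g"), bad)
  expect_error(read_score_table(bad), "duplicate.*line 3")
  writeLines(c("compound,target,score_kcal_mol,group", "a,T,oops,g"), bad)
  expect_error(read_score_table(bad), "unparsable.*line 2")
  writeLines("compound,target,score_kcal_mol,group", bad)
  expect_error(read_score_table(bad), "empty")
})

test_that("binding free energy and component-sum arithmetic", {
  expect_equal(binding_free_energy(-100, -30, -20), -50)
  expect_equal(binding_free_energy(0, 0, 0), 0)
  expect_equal(binding_free_energy(-73.38, -10, -4), -59.38)
  # direct testable identity: dG(x + y + z, y, z) = x
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- stats::rnorm(1); y <- stats::rnorm(1); z <- stats::rnorm(1)
      expect_equal(binding_free_energy(x + y + z, y, z), x)
    }
  })

  expect_equal(total_energy(list(e_bond = 0, e_vdw = 0, e_elec = 0,
                                 g_pb = 0, g_sa = 0, ts_s = 0)), 0)
  expect_equal(total_energy(list(e_bond = 0, e_vdw = 0, e_elec = 0,
                                 g_pb = 0, g_sa = 0, ts_s = 5)), -5)
  expect_equal(total_energy(list(e_bond = 1, e_vdw = 2, e_elec = 3,
                                 g_pb = 4, g_sa = 5, ts_s = 6)), 9)
  expect_error(total_energy(list(e_bond = 1)), "missing energy component")
  # linear in each component
  base <- list(e_bond = 1, e_vdw = 1, e_elec = 1, g_pb = 1, g_sa = 1, ts_s = 1)
  up <- base; up$e_vdw <- base$e_vdw + 2
  expect_equal(total_energy(up) - total_energy(base), 2)
})

test_that("energy fixture ranks reproduce the tabulated minima", {
  et <- read_energy_table(fixture_path("table2_mmgbsa.csv"))
  expect_equal(nrow(et), 18L)
  ra <- rank_energies(et, "MAO-A")
  expect_equal(ra$compound[1], "Compound 1")
  expect_equal(ra$dg_reported[1], -59.24)
  rb <- rank_energies(et, "MAO-B")
  expect_equal(rb$compound[1], "Compound 1")
  expect_equal(rb$dg_reported[1], -59.81)

  # every predicted compound binds MAO-B more strongly than every control
  raw <- tibble::as_tibble(utils::read.csv(fixture_path("table2_mmgbsa.csv")))
  b <- raw[raw$target == "MAO-B", ]
  expect_lt(max(b$dg_reported[b$group == "predicted"]),
            min(b$dg_reported[b$group == "control"]))
})

test_that("complete rows that contradict the reported total raise a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,target,e_bond,e_vdw,e_elec,g_pb,g_sa,ts_s,dg_reported",
               "a,T,1,1,1,1,1,1,4",      # components sum to 4: consistent
               "b,T,1,1,1,1,1,1,-10"),   # inconsistent: warn, keep verbatim
             f)
  expect_warning(et <- read_energy_table(f), "do not sum")
  expect_equal(et$dg_reported, c(4, -10))
})

test_that("mass-weighted RMSD matches hand evaluations", {
  a <- structure_snapshot(matrix(0, 3, 3), c(12, 1, 16))
  expect_equal(mass_weighted_rmsd(a, a), 0)

  # one atom translated 3 A, any masses: still 3 A when it is the only atom
  one <- structure_snapshot(matrix(c(0, 0, 0), 1, 3), 7)
  one_moved <- structure_snapshot(matrix(c(3, 0, 0), 1, 3), 7)
  expect_equal(mass_weighted_rmsd(one_moved, one), 3)

  # two atoms, masses (1, 3), displacements (2, 0): sqrt(1*4/4) = 1
  ref <- structure_snapshot(rbind(c(0, 0, 0), c(1, 1, 1)), c(1, 3))
  mob <- structure_snapshot(rbind(c(2, 0, 0), c(1, 1, 1)), c(1, 3))
  expect_equal(mass_weighted_rmsd(mob, ref), 1)

  expect_error(mass_weighted_rmsd(one, ref), "atom counts")
  expect_error(structure_snapshot(matrix(0, 2, 3), c(1, -1)), "positive")
})

test_that("Kabsch superposition removes rigid-body motion and never hurts", {
  withr::with_seed(13, {
    xyz <- matrix(stats::rnorm(30), 10, 3)
    mass <- stats::runif(10, 1, 16)
    theta <- 0.7
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
    rotated <- structure_snapshot(t(R %*% t(xyz)) + 2.5, mass)
    ref <- structure_snapshot(xyz, mass)
    expect_gt(mass_weighted_rmsd(rotated, ref), 1)
    expect_equal(mass_weighted_rmsd(rotated, ref, superpose = TRUE), 0,
                 tolerance = 1e-10)
    # superposed RMSD <= raw RMSD on noisy structures too
    noisy <- structure_snapshot(rotated$xyz + stats::rnorm(30, sd = 0.1), mass)
    expect_lte(mass_weighted_rmsd(noisy, ref, superpose = TRUE),
               mass_weighted_rmsd(noisy, ref))
  })
})

test_that("rmsf matches hand variance and is frame-order invariant", {
  still <- replicate(4, structure_snapshot(matrix(1, 5, 3)), simplify = FALSE)
  expect_equal(rmsf(still), rep(0, 5))

  # one atom alternating +/- 1 A on x: RMSF 1
  f1 <- structure_snapshot(matrix(c(1, 0, 0), 1, 3))
  f2 <- structure_snapshot(matrix(c(-1, 0, 0), 1, 3))
  expect_equal(rmsf(list(f1, f2, f1, f2)), 1)
  expect_equal(rmsf(list(f2, f1, f2, f1)), rmsf(list(f1, f2, f1, f2)))

  expect_error(rmsf(list(f1)), "2 frames")
  expect_error(rmsf(list(f1, structure_snapshot(matrix(0, 2, 3)))), "inconsistent")
})

test_that("coordinates load from PDB records and XYZ tables", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 1, " CA ", "", "ALA", "A", 1, "", 1.0, 2.0, 3.0, 1.0, 0.0, "C"),
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 2, " N  ", "", "ALA", "A", 1, "", 4.0, 5.0, 6.0, 1.0, 0.0, "N")),
    pdb)
  snap <- read_structure(pdb)
  expect_equal(snap$n, 2L)
  expect_equal(snap$xyz[1, ], c(1, 2, 3))
  expect_equal(snap$mass, c(12.011, 14.007))

  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0 12.011", "1 0 0 1.008"), xyz)
  snap2 <- read_structure(xyz)
  expect_equal(snap2$mass, c(12.011, 1.008))
  writeLines(c("0 0 0", "1 0 0"), xyz)
  expect_equal(read_structure(xyz)$mass, c(1, 1))
})
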