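# detector fixtures are built atom by atom so every distance is exact

test_that("hydrogen bonds: cutoff, typing, deduplication", {
  mk <- function(d) fix_structure(
    list(name = "OG", resname = "SER", resid = 1, chain = "A", element = "O",
         x = 0, y = 0, z = 0),
    list(name = "OD1", resname = "ASN", resid = 2, chain = "B", element = "O",
         x = d, y = 0, z = 0))
  r <- find_hbonds(mk(2.9), "chain A", "chain B")
  expect_equal(nrow(r), 1)
  expect_equal(r$distance_A, 2.9)
  expect_equal(nrow(find_hbonds(mk(3.6), "chain A", "chain B")), 0)
  # carbon is neither donor nor acceptor
  s <- fix_structure(
    list(name = "CB", resname = "ALA", resid = 1, chain = "A", element = "C",
         x = 0, y = 0, z = 0),
    list(name = "O", resname = "ALA", resid = 2, chain = "B", element = "O",
         x = 2.9, y = 0, z = 0))
  expect_equal(nrow(find_hbonds(s, "chain A", "chain B")), 0)
})

test_that("explicit hydrogens enable the D-H...A angle criterion", {
  # donor N-H pointing AWAY from the acceptor: angle ~30 deg, rejected
  bad <- fix_structure(
    list(name = "NZ", resname = "LYS", resid = 1, chain = "A", element = "N",
         x = 0, y = 0, z = 0),
    list(name = "HZ1", resname = "LYS", resid = 1, chain = "A", element = "H",
         x = -0.5, y = 0.87, z = 0),
    list(name = "OD1", resname = "ASP", resid = 2, chain = "B", element = "O",
         x = 3.0, y = 0, z = 0))
  expect_equal(nrow(find_hbonds(bad, "chain A", "chain B")), 0)
  # H between donor and acceptor: angle ~180 deg, kept (neutral donor)
  good <- fix_structure(
    list(name = "OG", resname = "SER", resid = 1, chain = "A", element = "O",
         x = 0, y = 0, z = 0),
    list(name = "HG", resname = "SER", resid = 1, chain = "A", element = "H",
         x = 1.0, y = 0, z = 0),
    list(name = "O", resname = "GLY", resid = 2, chain = "B", element = "O",
         x = 3.0, y = 0, z = 0))
  expect_equal(nrow(find_hbonds(good, "chain A", "chain B")), 1)
  # an oppositely charged pair is a salt bridge, not an H-bond record
  sb <- fix_structure(
    list(name = "NZ", resname = "LYS", resid = 1, chain = "A", element = "N",
         x = 0, y = 0, z = 0),
    list(name = "OD1", resname = "ASP", resid = 2, chain = "B", element = "O",
         x = 3.0, y = 0, z = 0))
  expect_equal(nrow(find_hbonds(sb, "chain A", "chain B")), 0)
  expect_equal(nrow(find_salt_bridges(sb, "chain A", "chain B")), 1)
})

test_that("hydrophobic contacts: typing and aggregation per residue pair", {
  mk <- function(d) fix_structure(
    list(name = "CD1", resname = "LEU", resid = 1, chain = "A", element = "C",
         x = 0, y = 0, z = 0),
    list(name = "CG1", resname = "VAL", resid = 2, chain = "B", element = "C",
         x = d, y = 0, z = 0))
  r <- find_hydrophobic(mk(3.6), "chain A", "chain B")
  expect_equal(nrow(r), 1)
  expect_equal(r$distance_A, 3.6)
  expect_equal(nrow(find_hydrophobic(mk(4.3), "chain A", "chain B")), 0)
  # oxygen is never hydrophobic
  s <- fix_structure(
    list(name = "OG", resname = "SER", resid = 1, chain = "A", element = "O",
         x = 0, y = 0, z = 0),
    list(name = "CD1", resname = "LEU", resid = 2, chain = "B", element = "C",
         x = 3.5, y = 0, z = 0))
  expect_equal(nrow(find_hydrophobic(s, "chain A", "chain B")), 0)
  # a carbon with a bonded O (1.4 A) is polar: excluded
  s2 <- fix_structure(
    list(name = "CB", resname = "SER", resid = 1, chain = "A", element = "C",
         x = 0, y = 0, z = 0),
    list(name = "OG", resname = "SER", resid = 1, chain = "A", element = "O",
         x = 0, y = 1.4, z = 0),
    list(name = "CD1", resname = "LEU", resid = 2, chain = "B", element = "C",
         x = 3.5, y = 0, z = 0))
  expect_equal(nrow(find_hydrophobic(s2, "chain A", "chain B")), 0)
})

test_that("salt bridges: charged-group typing and cutoff", {
  mk <- function(d, nm2 = "NH1", rn2 = "ARG", el2 = "N") fix_structure(
    list(name = "OD1", resname = "ASP", resid = 1, chain = "A", element = "O",
         x = 0, y = 0, z = 0),
    list(name = nm2, resname = rn2, resid = 2, chain = "B", element = el2,
         x = d, y = 0, z = 0))
  expect_equal(nrow(find_salt_bridges(mk(3.5), "chain A", "chain B")), 1)
  expect_equal(nrow(find_salt_bridges(mk(4.5), "chain A", "chain B")), 0)
  expect_equal(nrow(find_salt_bridges(mk(3.0, "OG", "SER", "O"),
                                      "chain A", "chain B")), 0)
})

test_that("detectors are permutation invariant and respect their cutoffs", {
  b <- fix_bundle(extended = TRUE)
  lig <- make_ideal_helix(15, chain = "Q")
  plants <- list(
    list(a = list(chain = "R", resid = 148, resname = "ASP", atom = "OD1"),
         b = list(chain = "Q", resid = 8, resname = "LYS", atom = "NZ"),
         kind = "saltbridge", frames = 1),
    list(a = list(chain = "R", resid = 126, resname = "SER", atom = "OG"),
         b = list(chain = "Q", resid = 3, resname = "ASN", atom = "OD1"),
         kind = "hbond", frames = 1),
    list(a = list(chain = "R", resid = 170, resname = "LEU", atom = "CD1"),
         b = list(chain = "Q", resid = 12, resname = "VAL", atom = "CG1"),
         kind = "hydrophobic", frames = 1))
  r <- make_complex_trajectory(b$structure, lig, approach = 35,
                               plants = plants, seed = 4)
  s <- get_frame(r$traj, 1)
  for (fn in list(find_hbonds, find_hydrophobic, find_salt_bridges)) {
    ab <- fn(s, "chain R", "chain Q")
    ba <- fn(s, "chain Q", "chain R")
    key <- function(x) sort(sprintf("%s%d-%s%d", x$chainA, x$residA,
                                    x$chainB, x$residB))
    expect_identical(key(ab), key(ba))
    crit <- interaction_criteria()
    lim <- switch(ab$kind[1] %||% "hbond", hbond = crit$hbond_da_max,
                  hydrophobic = crit$hydrophobic_cc_max,
                  saltbridge = crit$saltbridge_max)
    if (nrow(ab)) expect_true(all(ab$distance_A <= lim))
  }
})

test_that("tightening cutoffs never increases the record count", {
  b <- fix_bundle(extended = TRUE)
  lig <- make_ideal_helix(15, chain = "Q")
  plants <- list(
    list(a = list(chain = "R", resid = 148, resname = "ASP", atom = "OD1"),
         b = list(chain = "Q", resid = 8, resname = "LYS", atom = "NZ"),
         kind = "saltbridge", frames = 1))
  r <- make_complex_trajectory(b$structure, lig, approach = 35,
                               plants = plants, seed = 4)
  s <- get_frame(r$traj, 1)
  n_at <- vapply(c(4.0, 3.5, 3.0, 2.5), function(cut)
    nrow(find_salt_bridges(s, "chain R", "chain Q",
                           interaction_criteria(saltbridge_max = cut))),
    integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("arginine cage: planted schedule, misnamed residue warns", {
  b <- fix_bundle(extended = TRUE)
  lig <- make_ideal_helix(10, chain = "Q")
  plants <- list(
    list(a = list(chain = "R", resid = 148, resname = "ASP", atom = "OD1"),
         b = list(chain = "R", resid = 149, resname = "ARG", atom = "NH1"),
         kind = "saltbridge", frames = c(1, 2)))
  r <- make_complex_trajectory(b$structure, lig, approach = c(30, 30, 30),
                               plants = plants, seed = 1)
  cage <- arginine_cage_state(r$traj)
  expect_equal(cage$present, c(TRUE, TRUE, FALSE))
  # residue 149 left as Ala: warning and all-absent
  r2 <- make_complex_trajectory(b$structure, lig, approach = 30, seed = 1)
  w <- testthat::capture_warnings(c2 <- arginine_cage_state(r2$traj))
  expect_true(any(grepl("not Asp/Glu|not Arg/Lys", w)))
  expect_false(any(c2$present))
  expect_error(arginine_cage_state(r$traj,
    d_res = list(chain = "R", resid = 999)), "not found")
})

test_that("contact timetable: planted counts, empty group, stride overflow", {
  b <- fix_bundle(extended = TRUE)
  lig <- make_ideal_helix(15, chain = "Q")
  plants <- list(
    list(a = list(chain = "R", resid = 126, resname = "SER", atom = "OG"),
         b = list(chain = "Q", resid = 3, resname = "ASN", atom = "OD1"),
         kind = "hbond", frames = c(2, 3)),
    list(a = list(chain = "R", resid = 148, resname = "ASP", atom = "OD1"),
         b = list(chain = "Q", resid = 8, resname = "LYS", atom = "NZ"),
         kind = "saltbridge", frames = 3))
  r <- make_complex_trajectory(b$structure, lig, approach = c(35, 35, 35),
                               plants = plants, seed = 2)
  tt <- contact_timetable(r$traj, "chain R", "chain Q")
  expect_equal(tt$counts$total, c(0, 1, 2))
  # wide table mirrors the records
  expect_equal(sum(tt$table), sum(tt$counts$total))
  p <- withr::local_tempfile(fileext = ".csv")
  write_timetable_csv(tt, p)
  expect_true(file.exists(p))

  empty <- contact_timetable(r$traj, "chain R", "resname ZZZ")
  expect_true(all(empty$counts$total == 0))
  one <- contact_timetable(r$traj, "chain R", "chain Q", stride = 99)
  expect_equal(nrow(one$counts), 1)
})
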