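# PDBQT/PDB parsing, typing, pose ordering, search box, round-trip.

pdbqt_line <- function(serial, name, res, x, y, z, type, charge = 0) {
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          serial, name, res, serial, x, y, z, 1, 0, charge, type)
}

test_that("multi-MODEL ligand files parse energies, TORSDOF and pose order", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:    -8.7      0.000      0.000",
    "ROOT",
    pdbqt_line(1, "C1", "LIG", 0, 0, 0, "C"),
    pdbqt_line(2, "C2", "LIG", 1.5, 0, 0, "C"),
    "ENDROOT",
    "BRANCH   2   3",
    pdbqt_line(3, "O3", "LIG", 2.2, 1.2, 0, "OA"),
    "ENDBRANCH   2   3",
    "TORSDOF 5",
    "ENDMDL",
    "MODEL 2",
    "REMARK VINA RESULT:    -9.1      1.200      2.100",
    "ROOT",
    pdbqt_line(1, "C1", "LIG", 0, 0, 1, "C"),
    pdbqt_line(2, "C2", "LIG", 1.5, 0, 1, "C"),
    "ENDROOT",
    "BRANCH   2   3",
    pdbqt_line(3, "O3", "LIG", 2.2, 1.2, 1, "OA"),
    "ENDBRANCH   2   3",
    "TORSDOF 5",
    "ENDMDL"), path)

  ps <- read_pdbqt(path, role = "ligand")
  expect_s3_class(ps, "pose_set")
  expect_length(ps$docked, 2)
  # stored sorted ascending by energy: the -9.1 model comes first
  expect_equal(vapply(ps$docked, `[[`, numeric(1), "vina_energy"),
               c(-9.1, -8.7))
  expect_equal(vapply(ps$docked, `[[`, integer(1), "rank"), 1:2)
  expect_identical(ps$nrot, 5L)
  # branch tree: atom 3 sits in its own rigid body
  expect_equal(ps$topology$body, c(0L, 0L, 1L))
  expect_equal(ps$docked[[1]]$atoms$z, c(1, 1, 1))
})

test_that("receptors drop waters, keep metal ions, and type atoms", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    pdbqt_line(1, "C1", "ALA", 0, 0, 0, "C"),
    pdbqt_line(2, "N2", "ALA", 1.4, 0, 0, "N"),
    pdbqt_line(3, "O", "HOH", 5, 5, 5, "OA"),
    pdbqt_line(4, "O", "HOH", 6, 6, 6, "OA"),
    pdbqt_line(5, "ZN", "ZN", 3, 3, 3, "ZN")), path)
  rec <- read_pdbqt(path, role = "receptor")
  expect_equal(nrow(rec$atoms), 3)
  expect_false(any(toupper(rec$atoms$resname) == "HOH"))
  zn <- rec$atoms[rec$atoms$element == "Zn", ]
  expect_equal(nrow(zn), 1)
  expect_true(zn$is_metal && zn$is_donor && zn$is_heavy)
  # carbon bonded to N (1.4 A) is not hydrophobic
  expect_false(rec$atoms$is_hydrophobic[1])
  expect_true(rec$atoms$is_acceptor[2] == FALSE)  # plain N, not NA type
})

test_that("typing flags follow AutoDock type conventions deterministically", {
  # N-H(D) donor pair, OA acceptor, lone aromatic carbon, chlorine
  atoms <- mk_atoms(c("N", "H", "O", "C", "Cl"),
                    c(0, 0, 0,  1, 0, 0,  5, 0, 0,  9, 0, 0,  12, 0, 0),
                    ad_types = c("N", "HD", "OA", "A", "Cl"))
  expect_equal(atoms$is_heavy, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_true(atoms$is_donor[1])    # carries the HD hydrogen
  expect_true(atoms$is_acceptor[3])
  expect_true(atoms$is_hydrophobic[4])  # carbon with no polar neighbour
  expect_true(atoms$is_hydrophobic[5])  # halogen
  atoms2 <- mk_atoms(c("N", "H", "O", "C", "Cl"),
                     c(0, 0, 0,  1, 0, 0,  5, 0, 0,  9, 0, 0,  12, 0, 0),
                     ad_types = c("N", "HD", "OA", "A", "Cl"))
  expect_identical(atoms, atoms2)
})

test_that("malformed and unsupported records are reported by line", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(pdbqt_line(1, "C1", "LIG", 0, 0, 0, "C"),
               "ATOM      2  C2  LIG A   2        bad   0.000"), path)
  expect_error(read_pdbqt(path, role = "ligand"), "line 2")

  path2 <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(pdbqt_line(1, "C1", "LIG", 0, 0, 0, "C"),
               pdbqt_line(2, "SI2", "LIG", 2, 0, 0, "Si")), path2)
  expect_error(read_pdbqt(path2, role = "ligand"), "unsupported element")
  expect_warning(ps <- read_pdbqt(path2, role = "ligand",
                                  on_unknown = "skip"), "skipped")
  expect_equal(nrow(ps$docked[[1]]$atoms), 1)
})

test_that("write/read round-trip preserves atoms, coordinates and TORSDOF", {
  cx <- make_complex(fixture_config(), seed = 11)
  path <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt(cx$poses, path)
  back <- read_pdbqt(path, role = "ligand")
  expect_length(back$docked, length(cx$poses$docked))
  expect_identical(back$nrot, cx$poses$nrot)
  for (k in seq_along(back$docked)) {
    a <- cx$poses$docked[[k]]$atoms
    b <- back$docked[[k]]$atoms
    expect_equal(nrow(b), nrow(a))
    expect_equal(b$ad_type, a$ad_type)
    expect_equal(b$x, a$x, tolerance = 1e-3)
    expect_equal(b$y, a$y, tolerance = 1e-3)
    expect_equal(b$z, a$z, tolerance = 1e-3)
  }
  # re-parsing the same file twice yields identical flag assignments
  again <- read_pdbqt(path, role = "ligand")
  expect_identical(back$docked[[1]]$atoms, again$docked[[1]]$atoms)
  # body assignment survives the round trip
  expect_identical(back$topology$body, cx$poses$topology$body)
})

test_that("search box covers the ligand as a margin-extended cube", {
  p1 <- mk_pose("C", c(0, 0, 0))
  box <- define_search_box(p1, margin = 10)
  expect_equal(box$center, c(0, 0, 0))
  expect_equal(box$edge, 20)

  p2 <- mk_pose(c("C", "C"), c(0, 0, 0, 4, 0, 0))
  expect_equal(define_search_box(p2, margin = 0),
               list(center = c(2, 0, 0), edge = 4))
  expect_equal(define_search_box(p2, margin = 10)$edge, 24)
  expect_error(define_search_box(list(atoms = mk_atoms(character(0),
                                                       numeric(0)))),
               "empty")
})
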