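# Pose selection (schemes 1-4), feature assembly and padding (schemes 5-6).

# a pose set with controlled energies and geometry: crystal at the origin,
# docked poses shifted along x so RMSD vs crystal is the shift magnitude
mk_scheme_set <- function(energies, shifts, affinity = NA_real_) {
  crystal <- mk_pose(c("C", "C"), c(0, 0, 0, 1.5, 0, 0), source = "crystal")
  docked <- lapply(seq_along(energies), function(k)
    mk_pose(c("C", "C"),
            c(shifts[k], 0, 0, 1.5 + shifts[k], 0, 0),
            energy = energies[k]))
  pose_set("tst", docked = docked, crystal = crystal, nrot = 2L,
           measured_affinity = affinity)
}

test_that("schemes 1-4 choose the documented pose", {
  ps <- mk_scheme_set(energies = c(-9.1, -8.7, -7.0),
                      shifts = c(3.2, 0.9, 5.5), affinity = 6.0)
  expect_identical(select_pose(ps, 1), ps$crystal)
  expect_equal(select_pose(ps, 2)$vina_energy, -9.1)
  # lowest RMSD vs crystal: the 0.9 A shift
  expect_equal(select_pose(ps, 3)$vina_energy, -8.7)
  # pKd-converted scores: 6.67, 6.38, 5.13; closest to 6.0 is -8.7
  expect_equal(select_pose(ps, 4)$vina_energy, -8.7)

  # prerequisites
  ps_nocry <- pose_set("x", docked = ps$docked, nrot = 0L)
  expect_error(select_pose(ps_nocry, 1), "scheme 1")
  expect_error(select_pose(ps_nocry, 3), "scheme 3")
  expect_error(select_pose(ps_nocry, 4), "scheme 4")

  # ties broken by lowest rank
  ps_tie <- mk_scheme_set(energies = c(-8, -8), shifts = c(1, 1))
  expect_equal(select_pose(ps_tie, 2)$rank, 1L)
})

test_that("assembled vectors have the published lengths", {
  cx <- shared_dataset()$complexes[[2]]
  # 5 poses in the shared fixture: padding engaged for scheme 5
  for (fs in c("vina11", "vinaelem47")) {
    for (sc in 1:6) {
      f <- assemble_features(cx$poses, cx$receptor, sc, fs)
      expect_length(f, scheme_feature_length(sc, fs))
      expect_equal(sum(names(f) == "nrot"), 1)  # nrot appears exactly once
    }
  }
  expect_equal(scheme_feature_length(5, "vina11"), 91)
  expect_equal(scheme_feature_length(5, "vinaelem47"), 415)
  expect_equal(scheme_feature_length(6, "vina11"), 21)
  expect_equal(scheme_feature_length(6, "vinaelem47"), 93)
  expect_equal(scheme_feature_length(2, "vinaelem47"), 47)
})

test_that("padding repeats the best-scored pose's block", {
  ps1 <- mk_scheme_set(energies = -9, shifts = 1)  # single docked pose
  rec <- mk_receptor(c("C", "O"), c(0, 4.5, 0, 2, -4, 1))
  f6 <- assemble_features(ps1, rec, 6, "vinaelem47")
  expect_length(f6, 93)
  b1 <- f6[startsWith(names(f6), "p1.")]
  b2 <- f6[startsWith(names(f6), "p2.")]
  expect_equal(unname(b1), unname(b2))  # the two 46-value blocks identical

  ps4 <- mk_scheme_set(energies = c(-9, -8, -7, -6), shifts = c(1, 2, 3, 4))
  f5 <- assemble_features(ps4, rec, 5, "vinaelem47")
  expect_length(f5, 415)
  blocks <- lapply(1:9, function(k)
    unname(f5[startsWith(names(f5), paste0("p", k, "."))]))
  for (k in 5:9) expect_equal(blocks[[k]], blocks[[1]])  # padded from best
  expect_false(isTRUE(all.equal(blocks[[2]], blocks[[1]])))

  # padding idempotence: a full 9-pose set has 9 distinct-source blocks
  cx <- shared_dataset()$complexes[[1]]
  full <- make_complex(fixture_config(n_poses = 9), seed = 77)
  f <- assemble_features(full$poses, full$receptor, 5, "vina11")
  expect_length(f, 91)
  raw <- lapply(full$poses$docked, function(p)
    compute_terms(full$receptor, p, full$poses$nrot,
                  full$poses$topology)[1:10])
  for (k in 1:9) {
    expect_equal(unname(f[startsWith(names(f), paste0("p", k, "."))]),
                 unname(raw[[k]]))
  }
})

test_that("scheme 2 equals scheme 1 when the best pose is the crystal pose", {
  cx <- shared_dataset()$complexes[[3]]
  ps <- cx$poses
  # plant the crystal geometry as the best-scored docked pose
  fake <- ps$crystal
  fake$source <- "docked"
  fake$vina_energy <- min(vapply(ps$docked, `[[`, numeric(1),
                                 "vina_energy")) - 1
  ps2 <- pose_set(ps$ligand_id, docked = c(list(fake), ps$docked[1:4]),
                  crystal = ps$crystal, nrot = ps$nrot,
                  topology = ps$topology)
  f1 <- assemble_features(ps2, cx$receptor, 1, "vinaelem47")
  f2 <- assemble_features(ps2, cx$receptor, 2, "vinaelem47")
  expect_equal(unname(f1), unname(f2))
})

test_that("featurize_complexes produces a rectangular table with affinities", {
  ds <- shared_dataset()
  tab <- featurize_complexes(ds$complexes[1:5], 2, "vina11")
  expect_equal(dim(tab), c(5, 3 + 11))
  expect_equal(tab$scheme, rep(2, 5))
  fm <- feature_matrix(tab)
  expect_equal(dim(fm$X), c(5, 11))
  expect_equal(fm$y, vapply(ds$complexes[1:5],
                            function(cx) cx$poses$measured_affinity,
                            numeric(1)))
})
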