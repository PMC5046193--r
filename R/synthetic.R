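# synthetic_fixtures: seeded generators for receptors, ligands, docked pose
# ensembles with controlled geometric error, and affinities with a known
# dependence on the implemented features. These fixtures exercise code paths
# and statistics; they make no claim of physical realism beyond plausible
# geometry (covalent bond lengths, non-overlapping atoms, pocket-scale
# contact distances).

# run code under a temporary RNG state so generation is reproducible and
# leaves the caller's stream untouched
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

.runit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

.rot_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Fixture generator configuration
#'
#' @param n_complexes number of complexes in a dataset.
#' @param protein_atoms range (min, max) of receptor heavy atoms.
#' @param ligand_atoms range (min, max) of ligand heavy atoms.
#' @param n_poses docked poses per ligand (1-9).
#' @param perturbation list with `translation` (rigid shift magnitude, A),
#'   `rotation` (max rigid rotation, degrees) and `jitter` (per-coordinate
#'   Gaussian noise SD, A) applied to the crystal pose to fake docking output.
#'   Pure translation with zero rotation/jitter gives every docked pose an
#'   RMSD exactly equal to `translation`.
#' @param affinity_model how measured affinities depend on the features:
#'   `"linear-terms"` (linear in the 10 Vina terms with a rotor denominator
#'   `1 + w6_true * nrot`), `"vina"` (exactly the fixed-weight Vina
#'   prediction), `"contacts"` (linear in a subset of the 36 contact counts),
#'   or `"nonlinear"` (smooth monotone saturating functions of two features,
#'   learnable by forests but not by OLS).
#' @param affinity_pose pose whose features generate the affinity:
#'   `"crystal"` (default; reproduces the pose-generation-error setting when
#'   models train on docked features) or `"best"` (best-scored docked pose).
#' @param noise_sd Gaussian noise added to affinities, pKd units.
#' @param w6_true rotor coefficient of the `"linear-terms"` generator.
#' @param span target affinity range in pKd units (default 6.5, echoing
#'   benchmark sets spanning many orders of magnitude); linear/nonlinear
#'   generators are rescaled to reach it, the `"vina"` generator is not.
#' @param d_cutoff contact cutoff used by contact-based generators.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_complexes = 100,
                           protein_atoms = c(60, 110),
                           ligand_atoms = c(12, 24),
                           n_poses = 9,
                           perturbation = list(translation = 1.5,
                                               rotation = 40, jitter = 0.3),
                           affinity_model = c("linear-terms", "vina",
                                              "contacts", "nonlinear"),
                           affinity_pose = c("crystal", "best"),
                           noise_sd = 0.3, w6_true = 0.02, span = 6.5,
                           d_cutoff = 12) {
  stopifnot(n_poses >= 1, n_poses <= 9)
  structure(list(
    n_complexes = n_complexes, protein_atoms = protein_atoms,
    ligand_atoms = ligand_atoms, n_poses = n_poses,
    perturbation = perturbation,
    affinity_model = match.arg(affinity_model),
    affinity_pose = match.arg(affinity_pose),
    noise_sd = noise_sd, w6_true = w6_true, span = span,
    d_cutoff = d_cutoff
  ), class = "fixture_config")
}

.LIG_ELEMENT_FREQ <- c(C = 0.62, N = 0.13, O = 0.13, S = 0.03, F = 0.04,
                       Cl = 0.03, P = 0.01, Br = 0.005, I = 0.005)
.PROT_ELEMENT_FREQ <- c(C = 0.63, N = 0.16, O = 0.16, S = 0.05)

.lig_ad_type <- function(element) {
  switch(element,
         C = "C",
         N = sample(c("N", "NA"), 1),
         O = "OA",
         S = sample(c("S", "SA"), 1),
         element)
}

# self-avoiding chain of heavy atoms at covalent bond length, plus polar
# hydrogens on some N/O; returns atoms, frame (ROOT/BRANCH layout) and nrot
.make_ligand <- function(n_heavy) {
  el <- sample(names(.LIG_ELEMENT_FREQ), n_heavy, replace = TRUE,
               prob = .LIG_ELEMENT_FREQ)
  el[1:2] <- "C"  # anchor the chain with carbons
  pos <- matrix(0, n_heavy, 3)
  for (i in 2:n_heavy) {
    for (try in 1:80) {
      cand <- pos[i - 1, ] + 1.5 * .runit()
      if (i == 2) break
      prev <- pos[seq_len(i - 2), , drop = FALSE]
      d2 <- rowSums((prev - matrix(cand, i - 2, 3, byrow = TRUE))^2)
      if (min(d2) > 1.8^2) break
    }
    pos[i, ] <- cand
  }
  pos <- sweep(pos, 2, colMeans(pos))  # centre on the pocket origin

  # rotatable bonds: a subset of internal chain bonds (not terminal)
  internal <- if (n_heavy >= 5) 2:(n_heavy - 2) else integer(0)
  nrot <- if (length(internal)) sample(0:min(4, length(internal)), 1) else 0L
  rot_at <- sort(sample(internal, nrot))  # bond i -- i+1 is rotatable

  # assemble atoms (H children right after their heavy parent)
  rows <- list(); seg_of <- integer(0)
  seg <- 1L
  serial <- 0L
  heavy_serial <- integer(n_heavy)
  for (i in seq_len(n_heavy)) {
    serial <- serial + 1L
    heavy_serial[i] <- serial
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, name = paste0(el[i], i), resname = "LIG", chain = "A",
      resseq = 1L, x = pos[i, 1], y = pos[i, 2], z = pos[i, 3], charge = 0,
      ad_type = .lig_ad_type(el[i]), element = el[i],
      stringsAsFactors = FALSE)
    seg_of <- c(seg_of, seg)
    if (el[i] %in% c("N", "O") && runif(1) < 0.4) {
      serial <- serial + 1L
      hp <- pos[i, ] + 1.0 * .runit()
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = paste0("H", i), resname = "LIG", chain = "A",
        resseq = 1L, x = hp[1], y = hp[2], z = hp[3], charge = 0,
        ad_type = "HD", element = "H", stringsAsFactors = FALSE)
      seg_of <- c(seg_of, seg)
    }
    if (i %in% rot_at) seg <- seg + 1L
  }
  atoms <- do.call(rbind, rows)

  # nested ROOT/BRANCH frame along the linear chain
  frame <- list(list(kind = "ROOT"),
                list(kind = "ATOMS", idx = which(seg_of == 1L)),
                list(kind = "ENDROOT"))
  for (s in seq_len(seg) - 1L) {
    if (s == 0L) next
    parent <- heavy_serial[rot_at[s]]
    child <- heavy_serial[rot_at[s] + 1L]
    frame[[length(frame) + 1]] <- list(kind = "BRANCH",
                                       serials = c(parent, child))
    frame[[length(frame) + 1]] <- list(kind = "ATOMS",
                                       idx = which(seg_of == s + 1L))
  }
  for (s in seq_len(seg - 1L)) {
    k <- seg - s
    frame[[length(frame) + 1]] <- list(
      kind = "ENDBRANCH",
      serials = c(heavy_serial[rot_at[k]], heavy_serial[rot_at[k] + 1L]))
  }
  list(atoms = atoms, frame = frame, nrot = nrot)
}

.make_receptor_atoms <- function(n_atoms, lig_pos) {
  nl <- nrow(lig_pos)
  pos <- matrix(NA_real_, n_atoms, 3)
  el <- sample(names(.PROT_ELEMENT_FREQ), n_atoms, replace = TRUE,
               prob = .PROT_ELEMENT_FREQ)
  k <- 0L
  guard <- 0L
  while (k < n_atoms && guard < n_atoms * 200) {
    guard <- guard + 1L
    anchor <- lig_pos[sample.int(nl, 1), ]
    cand <- anchor + runif(1, 2.9, 7.2) * .runit()
    dl <- min(rowSums(sweep(lig_pos, 2, cand)^2))
    ok <- dl > 2.7^2
    if (ok && k > 0) {
      dr <- min(rowSums(sweep(pos[seq_len(k), , drop = FALSE], 2, cand)^2))
      ok <- dr > 1.9^2
    }
    if (ok) {
      k <- k + 1L
      pos[k, ] <- cand
    }
  }
  n_atoms <- k
  el <- el[seq_len(n_atoms)]
  pos <- pos[seq_len(n_atoms), , drop = FALSE]
  ad <- vapply(el, function(e)
    switch(e, C = "C", N = sample(c("N", "NA"), 1), O = "OA", S = "S"),
    character(1))
  # polar hydrogens on some N/O so the receptor carries donors too
  hsel <- which(el %in% c("N", "O") & runif(n_atoms) < 0.3)
  hpos <- t(vapply(hsel, function(i) pos[i, ] + 1.0 * .runit(), numeric(3)))
  el <- c(el, rep("H", length(hsel)))
  ad <- c(ad, rep("HD", length(hsel)))
  pos <- rbind(pos, hpos)
  n <- length(el)
  data.frame(serial = seq_len(n), name = paste0(el, seq_len(n)),
             resname = "REC", chain = "A", resseq = seq_len(n),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], charge = 0,
             ad_type = ad, element = el, stringsAsFactors = FALSE)
}

#' Generate one synthetic protein-ligand complex
#'
#' The crystal ligand is a self-avoiding heavy-atom chain centred in a pocket
#' of receptor atoms placed 3.4-7.5 A from randomly chosen ligand atoms.
#' Docked poses are rigid transforms of the crystal pose (rotation up to the
#' configured angle about the ligand centroid, translation of exactly the
#' configured magnitude in a random direction) plus per-atom Gaussian jitter;
#' each docked pose is scored with the Vina function so that best-score pose
#' selection (scheme 2) is well defined, and poses are stored sorted by
#' energy.
#'
#' @param config a [fixture_config()].
#' @param seed integer seed; generation is bit-reproducible given
#'   (config, seed).
#' @param id complex identifier.
#' @return list with `receptor` (a `receptor`) and `poses` (a [pose_set()]
#'   holding the crystal pose and the docked ensemble).
#' @export
make_complex <- function(config, seed = 1, id = sprintf("cx%04d", seed)) {
  .with_seed(seed, {
    n_lig <- sample(config$ligand_atoms[1]:config$ligand_atoms[2], 1)
    n_rec <- sample(config$protein_atoms[1]:config$protein_atoms[2], 1)
    lig <- .make_ligand(n_lig)
    ratoms <- .make_receptor_atoms(n_rec, as.matrix(
      lig$atoms[lig$atoms$element != "H", c("x", "y", "z")]))
    receptor <- structure(list(id = id, atoms = type_atoms(ratoms)),
                          class = "receptor")

    typed <- type_atoms(lig$atoms)
    topology <- list(bonds = attr(typed, "bonds"),
                     body = .assign_bodies(lig$frame, nrow(typed)),
                     rot_bonds = .frame_rot_bonds(lig$frame, typed$serial),
                     frame = lig$frame)
    crystal <- pose_record(typed, rank = 1L, source = "crystal")

    pert <- config$perturbation
    centroid <- colMeans(typed[typed$is_heavy, c("x", "y", "z")])
    docked <- vector("list", config$n_poses)
    for (k in seq_len(config$n_poses)) {
      R <- .rot_matrix(.runit(), runif(1, 0, pert$rotation))
      shift <- pert$translation * .runit()
      co <- as.matrix(typed[, c("x", "y", "z")])
      co <- t(R %*% (t(co) - centroid) + centroid) +
        matrix(shift, nrow(co), 3, byrow = TRUE)
      if (pert$jitter > 0) {
        co <- co + matrix(rnorm(length(co), 0, pert$jitter), nrow(co), 3)
      }
      at <- typed
      at[, c("x", "y", "z")] <- co
      docked[[k]] <- pose_record(at, rank = k, source = "docked")
    }
    ps <- pose_set(id, docked = docked, crystal = crystal, nrot = lig$nrot,
                   topology = topology)
    e <- score_pose_set(receptor, ps)
    for (k in seq_along(ps$docked)) ps$docked[[k]]$vina_energy <- e[k]
    ps <- pose_set(id, docked = ps$docked, crystal = crystal,
                   nrot = lig$nrot, topology = topology)
    list(receptor = receptor, poses = ps)
  })
}

# affinity generator: returns y and the ground-truth parameters
.gen_affinity <- function(complexes, config) {
  pose_of <- function(cx) {
    if (config$affinity_pose == "crystal") cx$poses$crystal else
      cx$poses$docked[[1]]
  }
  vina_feats <- t(vapply(complexes, function(cx)
    compute_terms(cx$receptor, pose_of(cx), cx$poses$nrot,
                  cx$poses$topology), numeric(11)))
  contact_feats <- t(vapply(complexes, function(cx)
    count_contacts(cx$receptor, pose_of(cx), config$d_cutoff),
    numeric(36)))
  nrot <- vina_feats[, 11]

  rescale <- function(y0, truth) {
    rng <- diff(range(y0))
    a <- if (rng > 0) config$span / rng else 1
    b <- 5 - a * stats::median(y0)  # centre near pKd 5
    truth$scale <- c(a = a, b = b)
    list(y = a * y0 + b, truth = truth)
  }

  if (config$affinity_model == "vina") {
    w <- vina_weights()
    e <- as.vector(vina_feats[, 1:5] %*% w[1:5]) / (1 + w[["w6"]] * nrot)
    y <- energy_to_pkd(e)
    truth <- list(model = "vina", weights = w)
  } else if (config$affinity_model == "linear-terms") {
    coefs <- c(-0.8, -0.1, 2.0, -0.9, -1.5, -0.5, -0.1, 1.2, -0.4, -0.9)
    y0 <- as.vector((vina_feats[, 1:10] / (1 + config$w6_true * nrot)) %*%
                      coefs)
    r <- rescale(y0, list(model = "linear-terms", w6 = config$w6_true))
    # rescaling a linear model keeps it linear: record the final parameters
    r$truth$coefficients <- coefs * r$truth$scale[["a"]]
    r$truth$intercept <- r$truth$scale[["b"]]
    y <- r$y; truth <- r$truth
  } else if (config$affinity_model == "contacts") {
    coefs <- setNames(numeric(36), contact_feature_names())
    coefs[c("x_C_C", "x_N_O", "x_O_N", "x_C_O")] <- c(0.05, 0.4, 0.3, -0.08)
    y0 <- as.vector(contact_feats %*% coefs)
    r <- rescale(y0, list(model = "contacts"))
    r$truth$coefficients <- coefs * r$truth$scale[["a"]]
    r$truth$intercept <- r$truth$scale[["b"]]
    y <- r$y; truth <- r$truth
  } else {  # nonlinear: saturating responses, learnable by trees not by OLS
    z1 <- scale(vina_feats[, "gauss1_inter"])[, 1]
    z2 <- scale(log1p(contact_feats[, "x_C_C"]))[, 1]
    y0 <- 3 * stats::pnorm(2 * z1) + 2 * stats::pnorm(2 * z2) +
      0.8 * stats::pnorm(-3 * z1 * z2)
    r <- rescale(y0, list(model = "nonlinear",
                          centers = attr(scale(vina_feats[, "gauss1_inter"]),
                                         "scaled:center")))
    y <- r$y; truth <- r$truth
  }
  noise <- if (config$noise_sd > 0) rnorm(length(y), 0, config$noise_sd) else 0
  list(y = y + noise, truth = truth,
       vina_feats = vina_feats, contact_feats = contact_feats)
}

#' Generate a synthetic dataset of complexes with known affinity model
#'
#' Affinities are drawn as `y = f(features of the designated pose) + noise`
#' with `f` and its parameters returned for recovery tests. With
#' `affinity_pose = "crystal"` (the default) the affinity is tied to the
#' crystal-pose features while docked poses carry geometric error -- the
#' pose-generation-error setting.
#'
#' @param config a [fixture_config()].
#' @param seed integer seed.
#' @return list with `complexes` (each `list(receptor, poses)` with
#'   `measured_affinity` filled in), `truth` (generator parameters), and
#'   `config`.
#' @export
make_dataset <- function(config = fixture_config(), seed = 1) {
  complexes <- lapply(seq_len(config$n_complexes), function(i)
    make_complex(config, seed = seed * 100000L + i,
                 id = sprintf("cx%06d", seed * 1000L + i)))
  gen <- .with_seed(seed * 7 + 13, .gen_affinity(complexes, config))
  for (i in seq_along(complexes)) {
    complexes[[i]]$poses$measured_affinity <- gen$y[i]
  }
  list(complexes = complexes, truth = gen$truth, config = config)
}

#' Write a dataset as a PDBbind-like directory tree
#'
#' One sub-directory per complex holding `receptor.pdbqt`,
#' `ligand_crystal.pdbqt` and `ligand_docked.pdbqt` (multi-MODEL with Vina
#' energies), plus a top-level `affinities.csv` keyed by complex id.
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(0); pkd <- numeric(0)
  for (cx in dataset$complexes) {
    id <- cx$poses$ligand_id
    d <- file.path(dir, id)
    dir.create(d, showWarnings = FALSE)
    write_pdbqt(cx$receptor, file.path(d, "receptor.pdbqt"))
    write_pdbqt(cx$poses, file.path(d, "ligand_crystal.pdbqt"),
                which = "crystal")
    write_pdbqt(cx$poses, file.path(d, "ligand_docked.pdbqt"))
    ids <- c(ids, id); pkd <- c(pkd, cx$poses$measured_affinity)
  }
  write.csv(data.frame(id = ids, pKd = pkd), file.path(dir, "affinities.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Load a PDBbind-like directory tree written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list of complexes as in [make_dataset()]`$complexes`.
#' @export
load_dataset <- function(dir) {
  aff <- read_affinity_table(file.path(dir, "affinities.csv"))
  lapply(seq_len(nrow(aff)), function(i) {
    id <- aff$id[i]
    d <- file.path(dir, id)
    receptor <- read_pdbqt(file.path(d, "receptor.pdbqt"), role = "receptor",
                           id = id)
    ps <- read_pdbqt(file.path(d, "ligand_docked.pdbqt"), role = "ligand",
                     id = id)
    cry_path <- file.path(d, "ligand_crystal.pdbqt")
    if (file.exists(cry_path)) {
      cry <- read_pdbqt(cry_path, role = "ligand", source = "crystal", id = id)
      ps$crystal <- cry$crystal
    }
    ps$measured_affinity <- aff$pKd[i]
    list(receptor = receptor, poses = ps)
  })
}
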