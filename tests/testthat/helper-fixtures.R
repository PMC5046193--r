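# Hand-built micro-structures and independent brute-force oracles used across
# the suite. Oracles deliberately re-derive every quantity with naive scalar
# loops and explicit formulas so they share no code path with the package
# implementation.

# build a typed atom table from parallel vectors
mk_atoms <- function(elements, coords, ad_types = NULL, resname = "LIG") {
  n <- length(elements)
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  if (is.null(ad_types)) {
    ad_types <- vapply(elements, function(e)
      switch(e, O = "OA", S = "SA", toupper(e)), character(1))
  }
  type_atoms(data.frame(
    serial = seq_len(n), name = paste0(elements, seq_len(n)),
    resname = rep(resname, n), chain = rep("A", n), resseq = rep(1L, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], charge = rep(0, n),
    ad_type = ad_types, element = elements, stringsAsFactors = FALSE))
}

mk_receptor <- function(elements, coords, ad_types = NULL, id = "rec") {
  structure(list(id = id,
                 atoms = mk_atoms(elements, coords, ad_types, "REC")),
            class = "receptor")
}

mk_pose <- function(elements, coords, ad_types = NULL, energy = NA_real_,
                    source = "docked") {
  pose_record(mk_atoms(elements, coords, ad_types), vina_energy = energy,
              source = source)
}

# shift all coordinates of a pose by a fixed vector
shift_pose <- function(pose, delta) {
  pose$atoms$x <- pose$atoms$x + delta[1]
  pose$atoms$y <- pose$atoms$y + delta[2]
  pose$atoms$z <- pose$atoms$z + delta[3]
  pose
}

# apply one rigid motion (rotation matrix + translation) to an atom table
rigid_move <- function(atoms, R, t) {
  co <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")]))) +
    matrix(t, nrow(atoms), 3, byrow = TRUE)
  atoms$x <- co[, 1]; atoms$y <- co[, 2]; atoms$z <- co[, 3]
  atoms
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ---- brute-force oracles ----------------------------------------------------

# Vina xs radii, restated independently for the oracle
.oracle_radius <- function(el) {
  r <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5, Cl = 1.8,
         Br = 2.0, I = 2.2)[el]
  if (is.na(r)) 1.2 else unname(r)  # metals
}

# per-pair 5 terms from explicit scalar formulas
.oracle_pair <- function(d, hyd, da) {
  g1 <- exp(-(d / 0.5)^2)
  g2 <- exp(-((d - 3) / 2)^2)
  rp <- if (d < 0) d * d else 0
  hy <- if (!hyd) 0 else if (d <= 0.5) 1 else if (d >= 1.5) 0 else 1.5 - d
  hb <- if (!da) 0 else if (d <= -0.7) 1 else if (d >= 0) 0 else -d / 0.7
  c(g1, g2, rp, hy, hb)
}

# inter-molecular term sums by naive double loop over heavy atoms
bf_inter_terms <- function(receptor, pose) {
  ra <- receptor$atoms[receptor$atoms$is_heavy, ]
  la <- pose$atoms[pose$atoms$is_heavy, ]
  acc <- numeric(5)
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
    d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
              (ra$z[i] - la$z[j])^2)
    if (d > 8) next
    ds <- d - .oracle_radius(ra$element[i]) - .oracle_radius(la$element[j])
    hyd <- ra$is_hydrophobic[i] && la$is_hydrophobic[j]
    da <- (ra$is_donor[i] && la$is_acceptor[j]) ||
          (ra$is_acceptor[i] && la$is_donor[j])
    acc <- acc + .oracle_pair(ds, hyd, da)
  }
  acc
}

# contact counts by naive triple loop
bf_contacts <- function(receptor, pose, d_cutoff = 12) {
  lig_el <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
  prot_el <- c("C", "N", "O", "S")
  out <- matrix(0L, length(lig_el), length(prot_el),
                dimnames = list(lig_el, prot_el))
  ra <- receptor$atoms
  la <- pose$atoms
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(ra))) {
    ei <- la$element[i]; ej <- ra$element[j]
    if (!(ei %in% lig_el) || !(ej %in% prot_el)) next
    d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
              (la$z[i] - ra$z[j])^2)
    if (d <= d_cutoff) out[ei, ej] <- out[ei, ej] + 1L
  }
  out
}

# residual SD of measured-on-predicted regression, via lm()
oracle_sd <- function(pred, meas) {
  fit <- lm(meas ~ pred)
  sqrt(sum(residuals(fit)^2) / (length(pred) - 2))
}

# small synthetic dataset shared by several expensive tests (cached per run)
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(fixture_config(n_complexes = 30, n_poses = 5),
                             seed = 42)
    }
    cache
  }
})
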