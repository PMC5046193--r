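# vina_terms: the five AutoDock Vina interaction terms, computed once over
# receptor-ligand atom pairs (inter) and once over flexible ligand atom pairs
# (intra), plus the composite score with its rotatable-bond penalty and the
# kcal/mol -> pKd conversion.
#
# All pair terms are functions of the *surface distance*
#   d = ||r_i - r_j|| - (R_i + R_j)
# where R are the Vina van-der-Waals radii; pairs beyond an 8 A interatomic
# cutoff contribute nothing.

.TERM_NAMES <- c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbonding")

#' Names of the 11 Vina features in canonical order
#'
#' Five inter-molecular term sums, five intra-molecular term sums, and the
#' rotatable-bond count last. This fixed flattening order is used by every
#' feature table in the package.
#'
#' @return character vector of length 11.
#' @export
vina_term_names <- function() {
  c(paste0(.TERM_NAMES, "_inter"), paste0(.TERM_NAMES, "_intra"), "nrot")
}

#' The published Vina weights
#'
#' @return named numeric vector `w1`..`w6`: the weights of gauss1, gauss2,
#'   repulsion, hydrophobic and hydrogen-bonding terms, and the rotatable-bond
#'   penalty coefficient.
#' @export
vina_weights <- function() {
  c(w1 = -0.035579, w2 = -0.005156, w3 = 0.840245,
    w4 = -0.035069, w5 = -0.587439, w6 = 0.05846)
}

# kcal/mol -> pKd conversion factor
.PKD_PER_KCAL <- -0.73349480509

# interatomic distance cutoff (A) beyond which pairs are ignored
.VINA_CUTOFF <- 8

#' Per-pair Vina term values at a given surface distance
#'
#' @param surface_distance `d` in Angstrom (interatomic distance minus the sum
#'   of the two Vina van-der-Waals radii); may be negative.
#' @param hydrophobic_pair are both atoms hydrophobic?
#' @param donor_acceptor_pair is one atom a hydrogen-bond donor and the other
#'   an acceptor?
#' @return named numeric 5-vector `(gauss1, gauss2, repulsion, hydrophobic,
#'   hbonding)`:
#'   `gauss1 = exp(-(d/0.5)^2)`, `gauss2 = exp(-((d-3)/2)^2)`,
#'   `repulsion = d^2` for `d < 0` else 0, `hydrophobic` a linear ramp from 1
#'   at `d <= 0.5` to 0 at `d >= 1.5` (hydrophobic pairs only), `hbonding` a
#'   linear ramp from 1 at `d <= -0.7` to 0 at `d >= 0` (donor-acceptor pairs
#'   only).
#' @export
term_pair <- function(surface_distance, hydrophobic_pair = FALSE,
                      donor_acceptor_pair = FALSE) {
  d <- surface_distance
  if (any(!is.finite(d))) stop("surface distance must be finite")
  g1 <- exp(-(d / 0.5)^2)
  g2 <- exp(-((d - 3) / 2)^2)
  rep_ <- ifelse(d < 0, d^2, 0)
  hyd <- ifelse(hydrophobic_pair, pmin(1, pmax(0, (1.5 - d) / 1)), 0)
  hb <- ifelse(donor_acceptor_pair, pmin(1, pmax(0, d / (-0.7))), 0)
  if (length(d) == 1) {
    c(gauss1 = g1, gauss2 = g2, repulsion = rep_, hydrophobic = hyd,
      hbonding = hb)
  } else {
    cbind(gauss1 = g1, gauss2 = g2, repulsion = rep_, hydrophobic = hyd,
          hbonding = hb)
  }
}

# sum the 5 terms over given atom pairs of two typed atom tables
.sum_terms <- function(atoms_a, atoms_b, pairs) {
  if (!nrow(pairs)) return(setNames(numeric(5), .TERM_NAMES))
  ca <- as.matrix(atoms_a[, c("x", "y", "z")])
  cb <- as.matrix(atoms_b[, c("x", "y", "z")])
  i <- pairs[, 1]; j <- pairs[, 2]
  dist <- sqrt(rowSums((ca[i, , drop = FALSE] - cb[j, , drop = FALSE])^2))
  keep <- dist <= .VINA_CUTOFF
  if (!any(keep)) return(setNames(numeric(5), .TERM_NAMES))
  i <- i[keep]; j <- j[keep]; dist <- dist[keep]
  dsurf <- dist - .xs_radius(atoms_a$element[i]) - .xs_radius(atoms_b$element[j])
  hyd <- atoms_a$is_hydrophobic[i] & atoms_b$is_hydrophobic[j]
  da <- (atoms_a$is_donor[i] & atoms_b$is_acceptor[j]) |
        (atoms_a$is_acceptor[i] & atoms_b$is_donor[j])
  vals <- term_pair(dsurf, hyd, da)
  if (!is.matrix(vals)) vals <- t(vals)
  setNames(colSums(vals), .TERM_NAMES)
}

# intra-molecular pair eligibility: heavy atoms in different rigid bodies,
# separated by more than three consecutive covalent bonds (moving pairs only).
.intra_pairs <- function(atoms, topology) {
  heavy <- which(atoms$is_heavy)
  if (length(heavy) < 2 || is.null(topology)) {
    return(matrix(integer(0), ncol = 2))
  }
  body <- topology$body %||% rep.int(0L, nrow(atoms))
  if (length(unique(body[heavy])) < 2) return(matrix(integer(0), ncol = 2))
  near <- .bond_neighbourhood(nrow(atoms), topology$bonds, depth = 3)
  out_i <- integer(0); out_j <- integer(0)
  for (a in seq_along(heavy)) {
    for (b in seq_len(a - 1L)) {
      i <- heavy[a]; j <- heavy[b]
      if (body[i] != body[j] && !near[i, j]) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
      }
    }
  }
  cbind(out_i, out_j, deparse.level = 0)
}

# logical matrix: TRUE where the bond-graph distance is <= depth
.bond_neighbourhood <- function(n, bonds, depth = 3) {
  adj <- matrix(FALSE, n, n)
  if (!is.null(bonds) && nrow(bonds)) {
    adj[bonds] <- TRUE
    adj[bonds[, c(2, 1), drop = FALSE]] <- TRUE
  }
  near <- adj | diag(TRUE, n)
  reach <- adj
  for (k in seq_len(depth - 1)) {
    reach <- (reach %*% adj) > 0
    near <- near | reach
  }
  near
}

#' Compute the 11 Vina features of one pose
#'
#' Sums the five pair terms over receptor-ligand heavy-atom pairs within the
#' 8 A cutoff (inter block) and over ligand heavy-atom pairs that can move
#' relative to each other -- different rigid bodies of the rotatable-bond tree
#' and more than three covalent bonds apart (intra block). Hydrogens carry no
#' terms. Metals take part in the inter sums (radius 1.2 A, donor role).
#'
#' @param receptor a `receptor` object.
#' @param pose a [pose_record()].
#' @param nrot rotatable-bond count, copied into the result.
#' @param topology ligand topology (bonds, rigid bodies) as stored in a
#'   [pose_set()]; `NULL` treats the ligand as rigid (all intra terms zero).
#' @return named numeric vector of length 11 in [vina_term_names()] order.
#' @export
compute_terms <- function(receptor, pose, nrot = 0L, topology = NULL) {
  ratoms <- receptor$atoms[receptor$atoms$is_heavy, , drop = FALSE]
  latoms <- pose$atoms
  lheavy <- latoms[latoms$is_heavy, , drop = FALSE]
  if (nrow(ratoms) && nrow(lheavy)) {
    pairs <- as.matrix(expand.grid(seq_len(nrow(ratoms)),
                                   seq_len(nrow(lheavy))))
    inter <- .sum_terms(ratoms, lheavy, pairs)
  } else {
    inter <- setNames(numeric(5), .TERM_NAMES)
  }
  ip <- .intra_pairs(latoms, topology)
  intra <- .sum_terms(latoms, latoms, ip)
  out <- c(inter, intra, nrot)
  names(out) <- vina_term_names()
  out
}

#' Composite Vina score of a pose
#'
#' `e'_k = (e_inter + e_intra - e_intra_pose1) / (1 + w6 * nrot)` where
#' `e_inter` and `e_intra` are the weighted sums of the five inter and intra
#' term blocks. For the best-ranked pose the intra contributions cancel
#' exactly.
#'
#' @param terms 11-vector from [compute_terms()] (nrot in the last slot).
#' @param intra_pose1 the 5 unweighted intra term sums of the rank-1 pose of
#'   the same ligand; defaults to this pose's own intra block (exact
#'   cancellation, the `k = 1` case).
#' @param weights Vina weights, see [vina_weights()].
#' @return predicted free energy of binding in kcal/mol.
#' @export
vina_score <- function(terms, intra_pose1 = NULL, weights = vina_weights()) {
  w5 <- weights[1:5]
  inter <- terms[1:5]
  intra <- terms[6:10]
  nrot <- terms[[11]]
  if (is.null(intra_pose1)) intra_pose1 <- intra
  e <- sum(w5 * inter) + sum(w5 * intra) - sum(w5 * intra_pose1)
  unname(e / (1 + weights[["w6"]] * nrot))
}

#' Convert a Vina free energy to pKd units
#'
#' `pKd = -0.73349480509 * e`, with `e` in kcal/mol.
#'
#' @param e free energy of binding in kcal/mol.
#' @return predicted affinity in pKd units.
#' @export
energy_to_pkd <- function(e) {
  if (any(!is.finite(e))) stop("energy must be finite")
  .PKD_PER_KCAL * e
}

#' Score every docked pose of a pose set with the Vina function
#'
#' Recomputes the 11 terms per pose, identifies the best pose by the raw
#' weighted inter+intra energy, and returns each pose's composite score
#' relative to that pose's intra block (the reference pose of the rotor
#' penalty formula).
#'
#' @param receptor a `receptor`.
#' @param ps a [pose_set()].
#' @param weights Vina weights.
#' @return numeric vector of kcal/mol scores, one per docked pose (in the
#'   pose set's current order).
#' @export
score_pose_set <- function(receptor, ps, weights = vina_weights()) {
  if (!length(ps$docked)) stop("pose set has no docked poses")
  w5 <- weights[1:5]
  tlist <- lapply(ps$docked, function(p)
    compute_terms(receptor, p, ps$nrot, ps$topology))
  e_inter <- vapply(tlist, function(t) sum(w5 * t[1:5]), numeric(1))
  e_intra <- vapply(tlist, function(t) sum(w5 * t[6:10]), numeric(1))
  best <- which.min(e_inter + e_intra)
  (e_inter + e_intra - e_intra[best]) / (1 + weights[["w6"]] * ps$nrot)
}
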