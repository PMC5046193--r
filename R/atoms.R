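#' @useDynLib dockrescore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm.fit rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- element and atom-type tables -------------------------------------------

# Vina xs van-der-Waals radii (Angstrom), by element; metals share one radius.
.XS_RADIUS <- c(
  C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
  F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2, H = 0.0, MET = 1.2
)

# covalent radii used only for bond inference (Cordero et al. values)
.COV_RADIUS <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
  S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, MET = 1.35
)

# metals recognised by Vina and retained as receptor atoms
.METALS <- c("ZN", "MG", "MN", "CA", "FE", "NI", "CO", "CU", "NA", "K",
             "SR", "CD", "HG")

.LIGAND_ELEMENTS  <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
.PROTEIN_ELEMENTS <- c("C", "N", "O", "S")

#' Map an AutoDock atom type string to an element symbol
#'
#' AutoDock types "A" (aromatic carbon) and "C" are carbon; "OA"/"NA"/"SA" are
#' the acceptor variants of O/N/S; "HD" is a polar (donor-carried) hydrogen.
#' Metal types map to the pseudo-element "MET" used for radius lookup while the
#' real symbol is kept in the atom table.
#'
#' @param ad_type character vector of AutoDock/Vina atom types.
#' @return character vector of element symbols ("C", "N", ..., "H", or the
#'   metal symbol itself, e.g. "Zn").
#' @keywords internal
ad_type_element <- function(ad_type) {
  up <- toupper(ad_type)
  out <- character(length(ad_type))
  out[up %in% c("C", "A")] <- "C"
  out[up %in% c("N", "NA")] <- "N"
  out[up %in% c("O", "OA")] <- "O"
  out[up %in% c("S", "SA")] <- "S"
  out[up == "P"] <- "P"
  out[up == "F"] <- "F"
  out[up == "CL"] <- "Cl"
  out[up == "BR"] <- "Br"
  out[up == "I"] <- "I"
  out[up %in% c("H", "HD", "HS")] <- "H"
  metal <- up %in% .METALS
  out[metal] <- paste0(substr(ad_type[metal], 1, 1),
                       tolower(substr(ad_type[metal], 2, 10)))
  out
}

.is_metal_element <- function(element) toupper(element) %in% .METALS

.xs_radius <- function(element) {
  r <- .XS_RADIUS[element]
  r[.is_metal_element(element)] <- .XS_RADIUS[["MET"]]
  if (anyNA(r)) {
    stop("no van-der-Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

.cov_radius <- function(element) {
  r <- .COV_RADIUS[element]
  r[.is_metal_element(element)] <- .COV_RADIUS[["MET"]]
  r[is.na(r)] <- 1.0
  unname(r)
}

# ---- geometry helpers -------------------------------------------------------

# all pairs (i, j), i < j, with euclidean distance <= cutoff, via spatial
# binning; exact (bit-identical to the O(n^2) loop) because candidate pairs are
# re-checked with the true distance.
.close_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (n <= 150) {
    d <- as.matrix(stats::dist(coords))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    return(unname(idx))
  }
  cell <- floor(sweep(coords, 2, rep(0, 3)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  cellmat <- unique(cell)
  keyof <- function(v) paste(v[1], v[2], v[3])
  res_i <- integer(0); res_j <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in seq_len(nrow(cellmat))) {
    home <- buckets[[keyof(cellmat[b, ])]]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nb <- buckets[[keyof(cellmat[b, ] + offs[o, ])]]
      if (!is.null(nb)) cand <- c(cand, nb)
    }
    for (i in home) {
      js <- cand[cand > i]
      if (!length(js)) next
      d2 <- (coords[js, 1] - coords[i, 1])^2 +
            (coords[js, 2] - coords[i, 2])^2 +
            (coords[js, 3] - coords[i, 3])^2
      keep <- js[d2 <= cutoff^2]
      res_i <- c(res_i, rep.int(i, length(keep)))
      res_j <- c(res_j, keep)
    }
  }
  cbind(res_i, res_j, deparse.level = 0)
}

# cross distances receptor x ligand as a dense matrix (ligands are small)
.cross_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 +
       outer(a[, 2], b[, 2], "-")^2 +
       outer(a[, 3], b[, 3], "-")^2)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below 1.15 x the sum of their
#' covalent radii (and above 0.4 A, to guard against duplicate coordinates).
#'
#' @param atoms atom data frame with `x`, `y`, `z`, `element` columns.
#' @return two-column integer matrix of bonded atom row indices.
#' @keywords internal
infer_bonds <- function(atoms) {
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rc <- .cov_radius(atoms$element)
  pairs <- .close_pairs(coords, cutoff = 1.15 * 2 * max(rc))
  if (!nrow(pairs)) return(pairs)
  d <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                     coords[pairs[, 2], , drop = FALSE])^2))
  lim <- 1.15 * (rc[pairs[, 1]] + rc[pairs[, 2]])
  pairs[d <= lim & d > 0.4, , drop = FALSE]
}

#' Assign interaction-role flags to a parsed atom table
#'
#' Flags follow Vina's conventions: hydrogens are non-heavy and carry no terms;
#' carbons are hydrophobic unless covalently bonded to N or O; halogens are
#' hydrophobic; AutoDock types OA/NA/SA are hydrogen-bond acceptors; a heavy
#' atom bonded to an HD (polar) hydrogen is a donor, as are recognised metals.
#'
#' @param atoms data frame with `x`, `y`, `z`, `element`, `ad_type`.
#' @return the same data frame with logical columns `is_heavy`,
#'   `is_hydrophobic`, `is_donor`, `is_acceptor`, `is_metal` added.
#' @keywords internal
type_atoms <- function(atoms) {
  n <- nrow(atoms)
  el <- atoms$element
  up <- toupper(atoms$ad_type)
  atoms$is_metal <- .is_metal_element(el)
  atoms$is_heavy <- el != "H"
  atoms$is_acceptor <- up %in% c("OA", "NA", "SA")
  atoms$is_donor <- atoms$is_metal
  atoms$is_hydrophobic <- el %in% c("F", "Cl", "Br", "I")

  bonds <- infer_bonds(atoms)
  nbr <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  for (i in seq_len(n)) {
    if (el[i] == "C") {
      atoms$is_hydrophobic[i] <- !any(el[nbr[[i]]] %in% c("N", "O"))
    }
    if (atoms$is_heavy[i] && any(up[nbr[[i]]] == "HD")) {
      atoms$is_donor[i] <- TRUE
    }
  }
  attr(atoms, "bonds") <- bonds
  atoms
}

.empty_atoms <- function() {
  data.frame(serial = integer(0), name = character(0), resname = character(0),
             chain = character(0), resseq = integer(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             charge = numeric(0), ad_type = character(0),
             element = character(0), stringsAsFactors = FALSE)
}
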