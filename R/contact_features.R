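# contact_features: the 36 elemental occurrence-count features.
#
# x_ij = number of (ligand atom of element i, protein atom of element j)
# pairs within d_cutoff Angstrom, for the 9 ligand elements
# C, N, O, F, P, S, Cl, Br, I crossed with the 4 protein elements C, N, O, S.
# Hydrogens, metals and any other element are excluded from counting.

#' Names of the 36 contact features in canonical order
#'
#' Row-major over ligand elements (C, N, O, F, P, S, Cl, Br, I) crossed with
#' protein elements (C, N, O, S): `x_C_C, x_C_N, x_C_O, x_C_S, x_N_C, ...`.
#'
#' @return character vector of length 36.
#' @export
contact_feature_names <- function() {
  as.vector(t(outer(.LIGAND_ELEMENTS, .PROTEIN_ELEMENTS,
                    function(i, j) paste0("x_", i, "_", j))))
}

#' Count elemental protein-ligand contacts
#'
#' Counts, for every (ligand element, protein element) pair, the heavy-atom
#' pairs whose Euclidean distance is at most `d_cutoff` (the boundary counts
#' as inside: the Heaviside step is taken with `H(0) = 1`).
#'
#' @param receptor a `receptor`.
#' @param pose a [pose_record()].
#' @param d_cutoff contact neighbourhood radius in Angstrom (default 12, the
#'   original RF-Score convention).
#' @return named integer vector of length 36 in [contact_feature_names()]
#'   order.
#' @export
count_contacts <- function(receptor, pose, d_cutoff = 12) {
  if (!is.numeric(d_cutoff) || length(d_cutoff) != 1 || d_cutoff <= 0)
    stop("d_cutoff must be a positive number")
  out <- setNames(integer(36), contact_feature_names())
  prot <- receptor$atoms
  prot <- prot[prot$element %in% .PROTEIN_ELEMENTS, , drop = FALSE]
  lig <- pose$atoms
  lig <- lig[lig$element %in% .LIGAND_ELEMENTS, , drop = FALSE]
  if (!nrow(prot) || !nrow(lig)) return(out)
  d <- .cross_dist(as.matrix(lig[, c("x", "y", "z")]),
                   as.matrix(prot[, c("x", "y", "z")]))
  within <- d <= d_cutoff
  for (i in .LIGAND_ELEMENTS) {
    li <- lig$element == i
    if (!any(li)) next
    for (j in .PROTEIN_ELEMENTS) {
      pj <- prot$element == j
      if (!any(pj)) next
      out[[paste0("x_", i, "_", j)]] <- sum(within[li, pj])
    }
  }
  out
}
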