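# pose_schemes: which pose(s) of a ligand supply the model-ready feature
# vector, and how short pose lists are padded.
#
#   scheme 1  crystal pose
#   scheme 2  docked pose with the best (lowest) Vina score
#   scheme 3  docked pose with the lowest RMSD vs the crystal pose
#             (training only: test complexes have no crystal reference)
#   scheme 4  docked pose whose Vina score, in pKd units, is closest to the
#             measured affinity (training only)
#   scheme 5  all nine docked poses, padded by repeating the best-scored
#             pose's block when fewer than nine were returned
#   scheme 6  the two best-scored docked poses, padded likewise
#
# The rotatable-bond count is pose-invariant, so it enters every vector
# exactly once (appended last); the pose-dependent block therefore holds 10
# Vina terms, or 46 values when the 36 contact counts are added. This yields
# the characteristic lengths 11/47 (schemes 1-4), 91/415 (scheme 5) and
# 21/93 (scheme 6).

.FEATURE_SETS <- c("vina11", "vinaelem47")

#' Select a single pose under schemes 1-4
#'
#' Ties are broken by the lowest pose rank.
#'
#' @param poses a [pose_set()].
#' @param scheme_id 1, 2, 3 or 4.
#' @param crystal_ref crystal reference pose for scheme 3; defaults to the
#'   pose set's own crystal pose.
#' @return the selected [pose_record()].
#' @export
select_pose <- function(poses, scheme_id, crystal_ref = NULL) {
  if (!scheme_id %in% 1:4) stop("select_pose handles schemes 1-4 only")
  if (scheme_id == 1) {
    if (is.null(poses$crystal))
      stop("scheme 1 requires a crystal pose for ", poses$ligand_id)
    return(poses$crystal)
  }
  if (!length(poses$docked))
    stop(sprintf("scheme %d requires docked poses for %s", scheme_id,
                 poses$ligand_id))
  key <- switch(as.character(scheme_id),
    "2" = vapply(poses$docked, function(p) p$vina_energy, numeric(1)),
    "3" = {
      ref <- crystal_ref %||% poses$crystal
      if (is.null(ref))
        stop("scheme 3 requires a crystal reference pose for ",
             poses$ligand_id)
      vapply(poses$docked, function(p) rmsd(ref, p), numeric(1))
    },
    "4" = {
      if (is.na(poses$measured_affinity))
        stop("scheme 4 requires a measured affinity for ", poses$ligand_id)
      pk <- energy_to_pkd(vapply(poses$docked, function(p) p$vina_energy,
                                 numeric(1)))
      abs(pk - poses$measured_affinity)
    })
  poses$docked[[which.min(key)]]  # which.min: first minimum = lowest rank
}

# one pose-dependent feature block: the 10 Vina terms, optionally + 36 contacts
.pose_block <- function(receptor, pose, poses, feature_set, d_cutoff) {
  terms <- compute_terms(receptor, pose, poses$nrot, poses$topology)
  block <- terms[1:10]
  if (feature_set == "vinaelem47") {
    block <- c(block, count_contacts(receptor, pose, d_cutoff))
  }
  block
}

#' Assemble the feature vector of one complex under a scheme
#'
#' @param poses a [pose_set()].
#' @param receptor the matching `receptor`.
#' @param scheme_id scheme 1-6.
#' @param feature_set `"vina11"` (10 Vina terms + nrot) or `"vinaelem47"`
#'   (adds the 36 contact counts per pose block).
#' @param d_cutoff contact cutoff in Angstrom, for `"vinaelem47"`.
#' @return named numeric vector of length 11/47 (schemes 1-4), 91/415
#'   (scheme 5) or 21/93 (scheme 6).
#' @export
assemble_features <- function(poses, receptor, scheme_id,
                              feature_set = c("vina11", "vinaelem47"),
                              d_cutoff = 12) {
  feature_set <- match.arg(feature_set)
  if (!scheme_id %in% 1:6) stop("scheme_id must be in 1..6")

  if (scheme_id %in% 1:4) {
    pose <- select_pose(poses, scheme_id)
    out <- c(.pose_block(receptor, pose, poses, feature_set, d_cutoff),
             nrot = poses$nrot)
    return(out)
  }

  if (!length(poses$docked))
    stop(sprintf("scheme %d requires docked poses for %s", scheme_id,
                 poses$ligand_id))
  m <- if (scheme_id == 5) 9L else 2L
  blocks <- lapply(poses$docked, .pose_block, receptor = receptor,
                   poses = poses, feature_set = feature_set,
                   d_cutoff = d_cutoff)
  # padding: repeat the best-scored pose's block (rank 1 after sorting)
  blocks <- c(blocks, rep(blocks[1], max(0, m - length(blocks))))[seq_len(m)]
  out <- numeric(0)
  for (k in seq_len(m)) {
    b <- blocks[[k]]
    names(b) <- paste0("p", k, ".", names(b))
    out <- c(out, b)
  }
  c(out, nrot = poses$nrot)
}

#' Feature-vector length implied by a scheme and feature set
#'
#' `m * (B - 1) + 1` with per-pose block size `B - 1` (10 or 46) and pose
#' multiplicity `m` (1, 2 or 9).
#'
#' @param scheme_id scheme 1-6.
#' @param feature_set `"vina11"` or `"vinaelem47"`.
#' @return integer length.
#' @export
scheme_feature_length <- function(scheme_id, feature_set = "vina11") {
  b <- if (feature_set == "vinaelem47") 46L else 10L
  m <- if (scheme_id == 5) 9L else if (scheme_id == 6) 2L else 1L
  m * b + 1L
}

#' Featurize a list of complexes
#'
#' @param complexes list of `list(receptor = , poses = )` pairs.
#' @param scheme_id scheme 1-6.
#' @param feature_set `"vina11"` or `"vinaelem47"`.
#' @param d_cutoff contact cutoff in Angstrom.
#' @return data frame with columns `complex_id`, `scheme`, one column per
#'   feature, and `affinity` (the measured pKd, `NA` when unknown).
#' @export
featurize_complexes <- function(complexes, scheme_id,
                                feature_set = c("vina11", "vinaelem47"),
                                d_cutoff = 12) {
  feature_set <- match.arg(feature_set)
  rows <- lapply(complexes, function(cx) {
    f <- assemble_features(cx$poses, cx$receptor, scheme_id, feature_set,
                           d_cutoff)
    stopifnot(length(f) == scheme_feature_length(scheme_id, feature_set))
    data.frame(complex_id = cx$poses$ligand_id, scheme = scheme_id,
               as.list(f), affinity = cx$poses$measured_affinity,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a feature table into the design matrix and response
#'
#' @param tab data frame from [featurize_complexes()] (or the same layout
#'   read back from CSV).
#' @return list with `X` (numeric matrix of features), `y` (affinities,
#'   possibly `NA`), `ids`.
#' @export
feature_matrix <- function(tab) {
  drop <- c("complex_id", "scheme", "affinity")
  X <- as.matrix(tab[, setdiff(names(tab), drop), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = tab$affinity, ids = tab$complex_id)
}
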