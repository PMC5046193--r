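# structures_io: PDBQT/PDB parsing, atom typing, pose sets, search box.
#
# PDBQT is AutoDock/Vina's dialect of PDB: fixed-column ATOM records carrying a
# partial charge (cols 71-76) and an AutoDock atom type (cols 78-79), plus
# ROOT/BRANCH/TORSDOF records describing the ligand's rotatable-bond tree and,
# for docked output, one MODEL block per pose with a "REMARK VINA RESULT" line.

.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# ---- constructors -----------------------------------------------------------

#' Create a pose record
#'
#' @param atoms typed atom data frame (see [type_atoms()]).
#' @param vina_energy Vina score of this pose in kcal/mol (`NA` if unknown).
#' @param rank 1-based pose rank; docked poses must have rank in 1..9.
#' @param source `"crystal"` or `"docked"`.
#' @return an object of class `pose_record`.
#' @export
pose_record <- function(atoms, vina_energy = NA_real_, rank = 1L,
                        source = c("docked", "crystal")) {
  source <- match.arg(source)
  if (!nrow(atoms)) stop("pose must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("pose coordinates must be finite")
  if (source == "docked" && (rank < 1 || rank > 9))
    stop("docked pose rank must be in [1, 9]")
  structure(list(atoms = atoms, vina_energy = vina_energy,
                 rank = as.integer(rank), source = source),
            class = "pose_record")
}

#' Create a pose set
#'
#' A pose set bundles the (optional) crystal pose and up to nine docked poses
#' of one ligand, its rotatable-bond count, and its measured affinity. Docked
#' poses are stored sorted by increasing Vina energy and re-ranked 1..n.
#'
#' @param ligand_id complex/ligand identifier.
#' @param docked list of [pose_record()]s.
#' @param crystal optional crystal [pose_record()].
#' @param nrot non-negative rotatable-bond count.
#' @param measured_affinity measured binding affinity in pKd units, or `NA`.
#' @param topology internal topology descriptor (bonds, rigid bodies, frame).
#' @return an object of class `pose_set`.
#' @export
pose_set <- function(ligand_id, docked = list(), crystal = NULL, nrot = 0L,
                     measured_affinity = NA_real_, topology = NULL) {
  if (length(docked) > 9) stop("at most 9 docked poses are supported")
  if (length(docked)) {
    e <- vapply(docked, function(p) p$vina_energy, numeric(1))
    ord <- order(e)  # stable: ties keep input order
    docked <- docked[ord]
    for (k in seq_along(docked)) docked[[k]]$rank <- k
    nat <- vapply(docked, function(p) sum(p$atoms$is_heavy), integer(1))
    if (length(unique(nat)) != 1)
      stop("all docked poses must share the same heavy-atom count")
  }
  structure(list(ligand_id = ligand_id, nrot = as.integer(nrot),
                 crystal = crystal, docked = docked,
                 measured_affinity = measured_affinity, topology = topology),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set %s: %d docked pose(s)%s, nrot=%d, pKd=%s>\n",
              x$ligand_id, length(x$docked),
              if (is.null(x$crystal)) "" else " + crystal", x$nrot,
              format(x$measured_affinity)))
  invisible(x)
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor %s: %d atoms (%d heavy)>\n", x$id, nrow(x$atoms),
              sum(x$atoms$is_heavy)))
  invisible(x)
}

# ---- parsing ----------------------------------------------------------------

.parse_atom_line <- function(line, lineno, format, on_unknown = "error") {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop(sprintf("malformed ATOM record at line %d: bad %s '%s'",
                               lineno, what, trimws(s)))
    v
  }
  if (nchar(line) < 54)
    stop(sprintf("malformed ATOM record at line %d: too short", lineno))
  name <- trimws(substr(line, 13, 16))
  ad_type <- trimws(substr(line, 78, 80))
  if (format == "pdbqt" && nzchar(ad_type)) {
    element <- ad_type_element(ad_type)
  } else {
    # PDB: element columns 77-78, else leading alpha of the atom name
    element <- trimws(substr(line, 77, 78))
    if (!nzchar(element)) element <- gsub("[^A-Za-z].*", "", name)
    element <- paste0(toupper(substr(element, 1, 1)),
                      tolower(substr(element, 2, 2)))
    if (element %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H")) {
      # synthesise the closest AutoDock type (O/S default to acceptor forms)
      ad_type <- c(C = "C", N = "N", O = "OA", S = "SA", P = "P", F = "F",
                   Cl = "Cl", Br = "Br", I = "I", H = "H")[[element]]
    } else {
      ad_type <- toupper(element)
    }
  }
  if (!(element %in% names(.XS_RADIUS)) && !.is_metal_element(element)) {
    if (identical(element, "")) element <- "?"
    msg <- sprintf("unsupported element '%s' at line %d", element, lineno)
    if (on_unknown == "skip") {
      warning(msg, ", atom skipped", call. = FALSE)
      return(NULL)
    }
    stop(msg)
  }
  charge <- suppressWarnings(as.numeric(trimws(substr(line, 71, 76))))
  data.frame(
    serial = as.integer(num(substr(line, 7, 11), "serial")),
    name = name,
    resname = trimws(substr(line, 18, 20)),
    chain = trimws(substr(line, 22, 22)),
    resseq = suppressWarnings(as.integer(trimws(substr(line, 23, 26)))),
    x = num(substr(line, 31, 38), "x"),
    y = num(substr(line, 39, 46), "y"),
    z = num(substr(line, 47, 54), "z"),
    charge = if (is.na(charge)) 0 else charge,
    ad_type = ad_type, element = element, stringsAsFactors = FALSE
  )
}

.detect_format <- function(path) {
  if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
}

#' Read a receptor or ligand structure file
#'
#' Reads PDBQT (AutoDock/Vina dialect, the canonical pose format) or plain PDB.
#' For `role = "receptor"` water molecules are removed while metal ions are
#' retained; the result is a single `receptor` object. For `role = "ligand"`
#' each `MODEL` block becomes one docked pose (Vina energies taken from
#' `REMARK VINA RESULT` lines when present); a file without `MODEL` blocks
#' yields a single pose. The rotatable-bond count is taken from the `TORSDOF`
#' record if present, otherwise from the number of `BRANCH` records.
#'
#' @param path path to a `.pdbqt` or `.pdb` file.
#' @param role `"receptor"` or `"ligand"`.
#' @param source pose source tag for ligands: `"docked"` or `"crystal"`.
#' @param id identifier; defaults to the file name without extension.
#' @param on_unknown what to do with atoms of unsupported element:
#'   `"error"` (default) or `"skip"` (drop with a warning).
#' @return a `receptor` (for receptors) or a [pose_set()] (for ligands).
#' @export
read_pdbqt <- function(path, role = c("receptor", "ligand"),
                       source = c("docked", "crystal"), id = NULL,
                       on_unknown = c("error", "skip")) {
  role <- match.arg(role)
  source <- match.arg(source)
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  format <- .detect_format(path)
  lines <- readLines(path, warn = FALSE)

  if (role == "receptor") {
    recs <- list()
    for (i in seq_along(lines)) {
      if (grepl("^(ATOM|HETATM)", lines[i])) {
        a <- .parse_atom_line(lines[i], i, format, on_unknown)
        if (!is.null(a)) recs[[length(recs) + 1]] <- a
      }
    }
    atoms <- if (length(recs)) do.call(rbind, recs) else .empty_atoms()
    atoms <- atoms[!(toupper(atoms$resname) %in% .WATER_RESNAMES), ,
                   drop = FALSE]
    rownames(atoms) <- NULL
    atoms <- type_atoms(atoms)
    return(structure(list(id = id, atoms = atoms), class = "receptor"))
  }

  # ligand: split into MODEL blocks (whole file = one block if none)
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts)) {
    ends <- c(starts[-1] - 1, length(lines))
    Map(function(s, e) list(lines = lines[s:e], off = s - 1), starts, ends)
  } else {
    list(list(lines = lines, off = 0))
  }

  energies <- numeric(0)
  models <- list()
  frame <- NULL
  nrot <- NA_integer_
  rot_bonds <- NULL
  for (b in blocks) {
    bl <- b$lines
    e <- NA_real_
    rem <- grep("^REMARK VINA RESULT", bl, value = TRUE)
    if (length(rem)) {
      e <- suppressWarnings(as.numeric(strsplit(trimws(
        sub("^REMARK VINA RESULT:?", "", rem[1])), "\\s+")[[1]][1]))
    }
    td <- grep("^TORSDOF", bl, value = TRUE)
    if (length(td) && is.na(nrot)) {
      nrot <- as.integer(strsplit(trimws(td[1]), "\\s+")[[1]][2])
    }
    recs <- list()
    this_frame <- list()
    open_atoms <- integer(0)
    skipped <- FALSE
    for (i in seq_along(bl)) {
      ln <- bl[i]
      if (grepl("^(ATOM|HETATM)", ln)) {
        a <- .parse_atom_line(ln, i + b$off, format, on_unknown)
        if (is.null(a)) { skipped <- TRUE; next }
        recs[[length(recs) + 1]] <- a
        open_atoms <- c(open_atoms, length(recs))
      } else if (grepl("^(ROOT|ENDROOT|BRANCH|ENDBRANCH)", ln)) {
        if (length(open_atoms)) {
          this_frame[[length(this_frame) + 1]] <-
            list(kind = "ATOMS", idx = open_atoms)
          open_atoms <- integer(0)
        }
        tok <- strsplit(trimws(ln), "\\s+")[[1]]
        this_frame[[length(this_frame) + 1]] <-
          list(kind = tok[1],
               serials = if (length(tok) >= 3) as.integer(tok[2:3]) else NULL)
      }
    }
    if (length(open_atoms)) {
      this_frame[[length(this_frame) + 1]] <-
        list(kind = "ATOMS", idx = open_atoms)
    }
    if (!length(recs)) next
    atoms <- do.call(rbind, recs)
    rownames(atoms) <- NULL
    if (is.null(frame)) frame <- this_frame
    models[[length(models) + 1]] <- atoms
    energies <- c(energies, e)
  }
  if (!length(models)) stop("no atoms found in ", path)

  # typing and topology from the first model; all models share atom order
  typed <- type_atoms(models[[1]])
  body <- .assign_bodies(frame, nrow(typed))
  rot_bonds <- .frame_rot_bonds(frame, typed$serial)
  if (is.na(nrot)) nrot <- nrow(rot_bonds)
  topology <- list(bonds = attr(typed, "bonds"), body = body,
                   rot_bonds = rot_bonds, frame = frame)

  poses <- vector("list", length(models))
  for (k in seq_along(models)) {
    at <- typed
    at[, c("x", "y", "z")] <- models[[k]][, c("x", "y", "z")]
    at$serial <- models[[k]]$serial
    poses[[k]] <- pose_record(at, vina_energy = energies[k],
                              rank = min(k, 9L), source = source)
  }
  if (source == "crystal") {
    pose_set(id, docked = list(), crystal = poses[[1]], nrot = nrot,
             topology = topology)
  } else {
    pose_set(id, docked = poses, nrot = nrot, topology = topology)
  }
}

# rigid-body index per atom from the ROOT/BRANCH frame (0 = root body);
# no frame (plain PDB ligand) = one rigid body.
.assign_bodies <- function(frame, n_atoms) {
  body <- rep.int(0L, n_atoms)
  if (is.null(frame) || !length(frame)) return(body)
  stack <- integer(0)
  next_body <- 0L
  cur <- 0L
  for (rec in frame) {
    if (rec$kind == "ROOT") {
      cur <- 0L
    } else if (rec$kind == "BRANCH") {
      next_body <- next_body + 1L
      stack <- c(stack, cur)
      cur <- next_body
    } else if (rec$kind == "ENDBRANCH") {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (rec$kind == "ATOMS") {
      body[rec$idx] <- cur
    }
  }
  body
}

.frame_rot_bonds <- function(frame, serials) {
  out <- matrix(integer(0), ncol = 2)
  if (is.null(frame)) return(out)
  for (rec in frame) {
    if (rec$kind == "BRANCH" && !is.null(rec$serials)) {
      out <- rbind(out, match(rec$serials, serials))
    }
  }
  out
}

# ---- writing ----------------------------------------------------------------

.format_atom_line <- function(a) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          a$serial, a$name, a$resname,
          ifelse(nzchar(a$chain), a$chain, "A"),
          ifelse(is.na(a$resseq), 1L, a$resseq),
          a$x, a$y, a$z, 1.00, 0.00, a$charge, a$ad_type)
}

.write_pose_body <- function(pose, topology, con) {
  atoms <- pose$atoms
  frame <- topology$frame
  if (is.null(frame) || !length(frame)) {
    for (i in seq_len(nrow(atoms))) writeLines(.format_atom_line(atoms[i, ]), con)
    return(invisible())
  }
  for (rec in frame) {
    if (rec$kind == "ATOMS") {
      for (i in rec$idx) writeLines(.format_atom_line(atoms[i, ]), con)
    } else if (rec$kind %in% c("BRANCH", "ENDBRANCH")) {
      writeLines(sprintf("%s %3d %3d", rec$kind, rec$serials[1],
                         rec$serials[2]), con)
    } else {
      writeLines(rec$kind, con)
    }
  }
}

#' Write a receptor or pose set as PDBQT
#'
#' Ligand pose sets are written as multi-`MODEL` files with
#' `REMARK VINA RESULT` energy lines and the stored `ROOT`/`BRANCH`/`TORSDOF`
#' frame, so that `read_pdbqt()` round-trips atom count, coordinates (3
#' decimals), atom types and the rotatable-bond count.
#'
#' @param x a `receptor` or [pose_set()].
#' @param path output file path.
#' @param which for pose sets: `"docked"` (default) writes the docked poses,
#'   `"crystal"` writes the crystal pose.
#' @return `path`, invisibly.
#' @export
write_pdbqt <- function(x, path, which = c("docked", "crystal")) {
  which <- match.arg(which)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "receptor")) {
    atoms <- x$atoms
    for (i in seq_len(nrow(atoms))) writeLines(.format_atom_line(atoms[i, ]), con)
    writeLines("TER", con)
    return(invisible(path))
  }
  if (!inherits(x, "pose_set")) stop("cannot write object of class ",
                                     paste(class(x), collapse = "/"))
  topo <- x$topology %||% list(frame = NULL)
  poses <- if (which == "crystal") {
    if (is.null(x$crystal)) stop("pose set has no crystal pose")
    list(x$crystal)
  } else {
    x$docked
  }
  multi <- which == "docked" && length(poses) >= 1
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    if (multi) {
      writeLines(sprintf("MODEL %8d", k), con)
      if (!is.na(p$vina_energy)) {
        writeLines(sprintf("REMARK VINA RESULT: %9.1f %10.3f %10.3f",
                           p$vina_energy, 0, 0), con)
      }
    }
    .write_pose_body(p, topo, con)
    writeLines(sprintf("TORSDOF %d", x$nrot), con)
    if (multi) writeLines("ENDMDL", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- search box and tables --------------------------------------------------

#' Define a cubic search box around a ligand pose
#'
#' The smallest cube covering all ligand atoms, with each face pushed outward
#' by `margin` Angstrom (the redocking convention: a 10 A margin around the
#' crystal ligand). Returned as center and edge length; used only for interop
#' with external docking software, never in scoring.
#'
#' @param ligand a [pose_record()].
#' @param margin outward extension per face in Angstrom (default 10).
#' @return list with `center` (3-vector) and `edge` (scalar, Angstrom).
#' @export
define_search_box <- function(ligand, margin = 10) {
  atoms <- ligand$atoms
  if (!nrow(atoms)) stop("empty atom list")
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z))
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z))
  list(center = (lo + hi) / 2, edge = max(hi - lo) + 2 * margin)
}

#' Read a measured-affinity table
#'
#' CSV/TSV with columns `id` and `pKd` (case-insensitive; `pkd` or `affinity`
#' also accepted for the value column).
#'
#' @param path file path.
#' @return data frame with columns `id`, `pKd`.
#' @export
read_affinity_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  vcol <- intersect(c("pkd", "affinity", "pki"), names(df))
  if (!("id" %in% names(df)) || !length(vcol))
    stop("affinity table needs columns 'id' and 'pKd'")
  data.frame(id = as.character(df$id), pKd = as.numeric(df[[vcol[1]]]),
             stringsAsFactors = FALSE)
}
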