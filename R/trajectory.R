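#' Atom topology for solvation trajectories
#'
#' Atoms carry a role (`sulfur`, `sulfur_hydrogen`, `water_oxygen`,
#' `water_hydrogen`, `other`) and a molecule id; bonds connect hydrogens
#' to their heavy atoms (O-H within waters, S-H on a thiol).  Validation:
#' every water oxygen has exactly two bonded water hydrogens (when the
#' topology contains water hydrogens at all) and every sulfur hydrogen is
#' bonded to exactly one sulfur.
#'
#' @param atoms data.frame with columns `id` (1..n), `element`, `role`,
#'   `mol`.
#' @param bonds data.frame with columns `atom1`, `atom2` (ids).
#' @return An `md_topology`.
#' @export
topology <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  req <- c("id", "element", "role", "mol")
  if (!all(req %in% names(atoms))) {
    stop("atoms needs columns: ", paste(req, collapse = ", "))
  }
  allowed <- c("sulfur", "sulfur_hydrogen", "water_oxygen",
               "water_hydrogen", "other")
  bad <- setdiff(unique(atoms$role), allowed)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(atoms$id)) stop("duplicate atom ids")
  if (nrow(bonds) && !all(c(bonds$atom1, bonds$atom2) %in% atoms$id)) {
    stop("bond references an unknown atom id")
  }
  role_of <- atoms$role[match(seq_len(max(atoms$id)), atoms$id)]
  partner_count <- function(ids, partner_role) {
    vapply(ids, function(i) {
      nb <- c(bonds$atom2[bonds$atom1 == i], bonds$atom1[bonds$atom2 == i])
      sum(role_of[nb] == partner_role)
    }, 0L)
  }
  wo <- atoms$id[atoms$role == "water_oxygen"]
  if (any(atoms$role == "water_hydrogen") && length(wo)) {
    nh <- partner_count(wo, "water_hydrogen")
    if (any(nh != 2L)) {
      stop("water oxygen id ", wo[which(nh != 2L)[1L]],
           " must have exactly 2 bonded water hydrogens")
    }
  }
  sh <- atoms$id[atoms$role == "sulfur_hydrogen"]
  if (length(sh)) {
    ns <- partner_count(sh, "sulfur")
    if (any(ns != 1L)) {
      stop("sulfur hydrogen id ", sh[which(ns != 1L)[1L]],
           " must be bonded to exactly one sulfur")
    }
  }
  structure(list(atoms = atoms, bonds = bonds), class = "md_topology")
}

#' @export
print.md_topology <- function(x, ...) {
  tb <- table(x$atoms$role)
  cat("<md_topology> ", nrow(x$atoms), " atoms: ",
      paste(sprintf("%s (%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# ids of atoms in a role
role_ids <- function(top, role) top$atoms$id[top$atoms$role == role]

# bonded hydrogen ids of a heavy atom
bonded_hydrogens <- function(top, heavy_id) {
  b <- top$bonds
  nb <- c(b$atom2[b$atom1 == heavy_id], b$atom1[b$atom2 == heavy_id])
  h_roles <- c("water_hydrogen", "sulfur_hydrogen")
  nb[top$atoms$role[match(nb, top$atoms$id)] %in% h_roles]
}

#' Multi-frame trajectory container
#'
#' @param coords numeric array, atoms x 3 x frames (Angstroms).
#' @param box orthorhombic box edge lengths, length 3 (Angstroms).
#' @param topology an `md_topology` with one entry per atom.
#' @param frame_spacing_ps frame spacing metadata in ps (never used in
#'   scoring).
#' @return An `md_trajectory`.
#' @export
trajectory <- function(coords, box, topology, frame_spacing_ps = 10) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an atoms x 3 x frames array")
  }
  if (length(box) != 3L || any(box <= 0)) {
    stop("box must be 3 positive edge lengths (orthorhombic)")
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (dim(coords)[1] != nrow(topology$atoms)) {
    stop("coords has ", dim(coords)[1], " atoms but the topology has ",
         nrow(topology$atoms))
  }
  structure(
    list(coords = coords, box = as.numeric(box), topology = topology,
         frame_spacing_ps = frame_spacing_ps),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", dim(x$coords)[1], " atoms x ",
      dim(x$coords)[3], " frames, box ",
      paste(format(x$box), collapse = " x "), " A\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

# minimum-image displacement components for an orthorhombic box
min_image <- function(d, box_len) d - box_len * round(d / box_len)

#' Write a trajectory as multi-frame XYZ
#'
#' One block per frame: atom count line, a comment line carrying the frame
#' index and box, then `element x y z` per atom (6 decimals).
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  n_at <- dim(traj$coords)[1]
  nf <- n_frames(traj)
  el <- traj$topology$atoms$element
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fr in seq_len(nf)) {
    writeLines(as.character(n_at), con)
    writeLines(sprintf("frame %d box %.4f %.4f %.4f", fr,
                       traj$box[1], traj$box[2], traj$box[3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el,
                       traj$coords[, 1, fr], traj$coords[, 2, fr],
                       traj$coords[, 3, fr]), con)
  }
  invisible(path)
}

#' Write a topology as a JSON sidecar
#' @param top an `md_topology`.
#' @param path output path.
#' @param box optional box lengths to embed.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path, box = NULL) {
  stopifnot(inherits(top, "md_topology"))
  obj <- list(atoms = top$atoms, bonds = top$bonds)
  if (!is.null(box)) obj$box <- box
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a topology JSON sidecar
#' @param path JSON file written by [write_topology()].
#' @return An `md_topology`; the embedded box (if any) is attached as
#'   attribute `"box"`.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bonds <- if (is.null(obj$bonds) || !length(obj$bonds)) {
    data.frame(atom1 = integer(), atom2 = integer())
  } else as.data.frame(obj$bonds)
  top <- topology(as.data.frame(obj$atoms), bonds)
  if (!is.null(obj$box)) attr(top, "box") <- as.numeric(obj$box)
  top
}

#' Read a multi-frame XYZ trajectory with its topology sidecar
#'
#' @param xyz_path multi-frame XYZ file (see [write_xyz()]).
#' @param topology_path JSON topology sidecar.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(xyz_path, topology_path) {
  if (!file.exists(xyz_path)) stop("file not found: ", xyz_path)
  top <- read_topology(topology_path)
  n_at <- nrow(top$atoms)
  lines <- readLines(xyz_path)
  block <- n_at + 2L
  if (length(lines) %% block != 0L) {
    # locate the first malformed frame for the error message
    fr <- length(lines) %/% block + 1L
    stop("frame ", fr, " has the wrong atom count (file is not a ",
         "whole number of ", n_at, "-atom frames)")
  }
  nf <- length(lines) %/% block
  coords <- array(NA_real_, c(n_at, 3L, nf))
  box <- NULL
  for (fr in seq_len(nf)) {
    off <- (fr - 1L) * block
    cnt <- suppressWarnings(as.integer(lines[off + 1L]))
    if (is.na(cnt) || cnt != n_at) {
      stop("frame ", fr, " declares ", lines[off + 1L],
           " atoms; topology has ", n_at)
    }
    if (is.null(box)) {
      m <- regmatches(lines[off + 2L],
                      regexec("box +([0-9.eE+-]+) +([0-9.eE+-]+) +([0-9.eE+-]+)",
                              lines[off + 2L]))[[1L]]
      if (length(m) == 4L) box <- as.numeric(m[2:4])
    }
    body <- strsplit(trimws(lines[off + 2L + seq_len(n_at)]), "[[:space:]]+")
    xyz <- t(vapply(body, function(tok) as.numeric(tok[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("unparseable coordinates in frame ", fr)
    coords[, , fr] <- xyz
  }
  if (is.null(box)) box <- attr(top, "box")
  if (is.null(box)) stop("no box found in XYZ comments or topology sidecar")
  trajectory(coords, box, top)
}

#' Write / read a hydrogen-bond schedule as CSV
#'
#' Columns: `donor_id, acceptor_id, direction, start_frame, end_frame`
#' (frames 1-based, inclusive).
#'
#' @param schedule a bond-schedule data.frame.
#' @param path file path.
#' @return `path` (write) or the schedule data.frame (read).
#' @export
write_bond_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bond_schedule
#' @export
read_bond_schedule <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
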