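# RMSD / RMSF metrics over multi-model PDB trajectories.
#
# The MD engine itself is out of scope: trajectories arrive as multi-model
# PDB files (one MODEL per frame) and only the stability metrics are
# computed here. Superposition is least-squares (Kabsch) via bio3d.

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL record becomes one frame. All frames share the atom table of
#' the first model (a PDB-format invariant).
#'
#' @param path Multi-model PDB file.
#' @param keep_hetatm Keep HETATM records (waters always dropped)?
#' @return An `abm_trajectory`: list with `xyz` (frames x 3N coordinate
#'   matrix), `atoms` (atom table as in [read_pdb()]) and `id`.
#' @export
read_trajectory <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  keep <- (keep_hetatm | at$type == "ATOM") &
    !(at$resid %in% c("HOH", "WAT", "DOD"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                          3 * which(keep)))
  new_trajectory(xyz[, cols, drop = FALSE],
                 new_structure(at[keep, , drop = FALSE])$atoms,
                 id = basename(path))
}

#' Build a trajectory from a list of structures
#'
#' @param structures List of `abm_structure` objects with identical atom
#'   tables (frames of one system).
#' @param id Label.
#' @return An `abm_trajectory`.
#' @export
as_trajectory <- function(structures, id = "trajectory") {
  stopifnot(length(structures) >= 1L)
  n <- vapply(structures, n_atoms, integer(1))
  if (length(unique(n)) != 1L)
    stop("all frames must have the same atom count (got ",
         paste(unique(n), collapse = ", "), ")")
  xyz <- do.call(rbind, lapply(structures, function(s) {
    as.vector(t(atom_coords(s)))
  }))
  new_trajectory(xyz, structures[[1L]]$atoms, id = id)
}

new_trajectory <- function(xyz, atoms, id = "trajectory") {
  structure(list(xyz = xyz, atoms = atoms, id = id),
            class = "abm_trajectory")
}

#' @export
print.abm_trajectory <- function(x, ...) {
  cat("abm_trajectory '", x$id, "': ", nrow(x$xyz), " frame(s), ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An `abm_trajectory`.
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

# xyz column indices (x,y,z triplets) for a set of atom row indices.
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}

# Resolve a residue selection ("L49"-style keys, or a data.frame with
# chain/resno/insert) to atom row indices; NULL = all atoms.
selection_atoms <- function(atoms, selection, heavy_only = TRUE) {
  idx <- seq_len(nrow(atoms))
  if (!is.null(selection)) {
    keys <- if (is.data.frame(selection)) {
      res_key(selection$chain, selection$resno,
              if (is.null(selection$insert)) "" else selection$insert)
    } else as.character(selection)
    atom_keys <- res_key(atoms$chain, atoms$resno, atoms$insert)
    missing <- setdiff(keys, atom_keys)
    if (length(missing))
      stop("selection residues not found: ", paste(missing, collapse = ", "))
    idx <- idx[atom_keys %in% keys]
  }
  if (heavy_only) idx <- idx[atoms$elesy[idx] != "H"]
  if (length(idx) == 0L) stop("empty atom selection")
  idx
}

#' RMSD per frame and RMSF per residue for a trajectory
#'
#' Every frame is optimally superposed on the reference frame by
#' least-squares rotation/translation (Kabsch, via [bio3d::fit.xyz()]) over
#' the selected heavy atoms before any metric is taken. RMSD is then the
#' root-mean-square atomic deviation from the reference; RMSF per residue is
#' the root-mean-square deviation of its superposed atom positions from
#' their mean position over the analysis `window` (e.g. the stable tail of
#' an MD run).
#'
#' @param trajectory An `abm_trajectory`.
#' @param reference Reference frame index (superposition target).
#' @param window Integer vector of frame indices (or `c(first, last)` range)
#'   over which RMSF is computed; default all frames.
#' @param selection Residues to analyse: `NULL` (all), residue keys like
#'   `"H62"`, or a data.frame with `chain`/`resno` columns.
#' @return A `trajectory_stats`: list with `rmsd_per_frame` (Å, one value
#'   per frame), `rmsf_per_residue` (data.frame `chain`, `resno`, `insert`,
#'   `resid`, `rmsf`), `reference`, `window`.
#' @export
compute_rmsd_rmsf <- function(trajectory, reference = 1L, window = NULL,
                              selection = NULL) {
  stopifnot(inherits(trajectory, "abm_trajectory"))
  nf <- n_frames(trajectory)
  if (nf < 1L) stop("trajectory has no frames")
  if (reference < 1L || reference > nf) stop("reference frame out of range")
  if (is.null(window)) {
    window <- seq_len(nf)
  } else if (length(window) == 2L && window[2] >= window[1]) {
    window <- seq.int(window[1], window[2])
  }
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty analysis window")
  if (any(window < 1L | window > nf)) stop("window frames out of range")

  at <- trajectory$atoms
  sel <- selection_atoms(at, selection, heavy_only = TRUE)
  cols <- xyz_cols(sel)
  ref <- trajectory$xyz[reference, ]
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = trajectory$xyz,
                           fixed.inds = cols, mobile.inds = cols)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)

  dev2 <- sweep(fitted[, cols, drop = FALSE], 2, ref[cols])^2
  # per-frame mean over atoms of |dx|^2 = row mean of triplet sums
  per_atom_frame <- dev2[, seq(1, length(cols), 3), drop = FALSE] +
    dev2[, seq(2, length(cols), 3), drop = FALSE] +
    dev2[, seq(3, length(cols), 3), drop = FALSE]
  rmsd <- sqrt(rowMeans(per_atom_frame))

  # RMSF: deviation from window-mean position, per atom, then pooled
  # (root mean square) over each residue's atoms
  win_xyz <- fitted[window, cols, drop = FALSE]
  mean_pos <- colMeans(win_xyz)
  fl2 <- sweep(win_xyz, 2, mean_pos)^2
  atom_fl2 <- colMeans(fl2[, seq(1, length(cols), 3), drop = FALSE] +
                         fl2[, seq(2, length(cols), 3), drop = FALSE] +
                         fl2[, seq(3, length(cols), 3), drop = FALSE])
  sat <- at[sel, , drop = FALSE]
  key <- res_key(sat$chain, sat$resno, sat$insert)
  res_fl2 <- tapply(atom_fl2, factor(key, levels = unique(key)), mean)
  first <- !duplicated(key)
  rmsf <- data.frame(chain = sat$chain[first], resno = sat$resno[first],
                     insert = sat$insert[first], resid = sat$resid[first],
                     rmsf = sqrt(as.numeric(res_fl2)), row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(rmsd_per_frame = as.numeric(rmsd), rmsf_per_residue = rmsf,
                 reference = reference, window = window),
            class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat("trajectory_stats: ", length(x$rmsd_per_frame), " frame(s), reference ",
      x$reference, "; RMSD range [",
      signif(min(x$rmsd_per_frame), 3), ", ",
      signif(max(x$rmsd_per_frame), 3), "] A; ",
      nrow(x$rmsf_per_residue), " residues in RMSF (window ",
      min(x$window), "-", max(x$window), ")\n", sep = "")
  invisible(x)
}
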