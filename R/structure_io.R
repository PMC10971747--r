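#' @importFrom stats rnorm runif median quantile setNames coef resid var
#' @importFrom utils read.csv write.csv
NULL

# Standard 3-letter -> 1-letter amino-acid code table. Non-standard residues
# (MSE, PTR, ligands, ...) are handled by the `nonstandard` policy of
# chain_sequence(), never silently remapped.
AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1 <- unname(AA3)
AA1TO3 <- setNames(names(AA3), unname(AA3))

#' Read a complex structure from a PDB file
#'
#' Parses ATOM records into a flat atom table wrapped in an `abm_structure`
#' object: the geometric substrate for all interface, contact and triage
#' distance rules. Parsing is delegated to [bio3d::read.pdb()]; this wrapper
#' applies the package's record policy.
#'
#' Policy: HETATM records and waters are skipped unless `keep_hetatm = TRUE`;
#' multi-model files keep model 1 (use [read_trajectory()] for all frames);
#' for alternate locations the highest-occupancy copy of each atom is kept,
#' ties broken by file order. Hydrogens are retained if present, but all
#' default distance criteria downstream use heavy atoms only.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param keep_hetatm Keep HETATM records (waters are always dropped)?
#' @param id Structure label; defaults to the file name.
#' @return An `abm_structure`: a list with `atoms` (data.frame with columns
#'   `type`, `eleno`, `elety`, `alt`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `o`, `b`, `elesy`) and `id`.
#' @seealso [write_pdb()], [chain_sequence()], [read_trajectory()]
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C"
#' ), pdb)
#' s <- read_pdb(pdb)
#' n_atoms(s)
read_pdb <- function(path, keep_hetatm = FALSE, id = basename(path)) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records retained from '", path, "'")
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    ln <- find_atom_line(path, at$eleno[which(bad)[1L]])
    stop("unparsable coordinate field in '", path, "' at line ", ln)
  }
  at <- resolve_altloc(at)
  new_structure(at, id = id)
}

# Locate the file line of an ATOM/HETATM record by serial, for error messages.
find_atom_line <- function(path, eleno) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  ser <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  hit <- which(rec & !is.na(ser) & ser == eleno)
  if (length(hit)) hit[1L] else NA_integer_
}

# Keep one altloc per (chain, resno, insert, elety): highest occupancy,
# ties broken by first listed.
resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  ord <- order(key, -occ, seq_len(nrow(at)))
  keep <- !duplicated(key[ord])
  idx <- sort(ord[keep])
  at[idx, , drop = FALSE]
}

new_structure <- function(atoms, id = "structure") {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)) || all(atoms$elesy == "")) {
    atoms$elesy <- guess_element(atoms$elety)
  } else {
    miss <- is.na(atoms$elesy) | atoms$elesy == ""
    atoms$elesy[miss] <- guess_element(atoms$elety[miss])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "abm_structure")
}

# Element from atom name: strip digits/primes, take leading letter
# (two-letter metals are out of scope for antibody chains).
guess_element <- function(elety) {
  nm <- gsub("[0-9']", "", trimws(elety))
  toupper(substr(nm, 1, 1))
}

#' @export
print.abm_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("abm_structure '", x$id, "': ", length(ch), " chain(s), ",
      nrow(residue_table(x)), " residues, ", n_atoms(x), " atoms\n", sep = "")
  for (c in ch) {
    rt <- residue_table(x)
    cat("  chain ", c, ": ", sum(rt$chain == c), " residues\n", sep = "")
  }
  invisible(x)
}

#' Basic accessors for `abm_structure` objects
#'
#' `chain_ids()` returns chain identifiers in file order; `n_atoms()` the
#' number of atoms; `residue_table()` one row per residue (`chain`, `resno`,
#' `insert`, `resid`) preserving file order; `atom_coords()` the n x 3
#' coordinate matrix in ångströms.
#'
#' @param structure An `abm_structure`.
#' @name structure-accessors
#' @export
chain_ids <- function(structure) {
  unique(structure$atoms$chain)
}

#' @rdname structure-accessors
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname structure-accessors
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  out <- at[first, c("chain", "resno", "insert", "resid")]
  rownames(out) <- NULL
  out
}

#' @rdname structure-accessors
#' @export
atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# Compact residue key "L49" / "L49A" (with insertion code).
res_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste0(chain, resno, insert)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column ATOM records (coordinates to 3 decimals) with
#' a TER record between chains and END at the end, so that
#' `read_pdb(write_pdb(s))` round-trips all retained fields.
#'
#' @param structure An `abm_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "abm_structure"))
  at <- structure$atoms
  if (any(nchar(trimws(at$chain)) > 1L))
    stop("PDB chain identifiers must be a single character")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  prev_chain <- at$chain[1L]
  for (i in seq_len(nrow(at))) {
    if (at$chain[i] != prev_chain) {
      writeLines("TER", con)
      prev_chain <- at$chain[i]
    }
    writeLines(format_atom_record(at[i, ]), con)
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

format_atom_record <- function(a) {
  name <- a$elety
  # atom names shorter than 4 characters start in column 14
  name <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(identical(a$type, "HETATM"), "HETATM", "ATOM"),
          as.integer(a$eleno) %% 100000L, name, substr(a$alt, 1, 1), a$resid,
          a$chain, as.integer(a$resno), substr(a$insert, 1, 1),
          a$x, a$y, a$z,
          ifelse(is.na(a$o), 1, a$o), ifelse(is.na(a$b), 0, a$b), a$elesy)
}

#' One-letter sequence of a chain
#'
#' Maps residue names through the standard 20 three-to-one table in residue
#' (file) order. Non-standard residues (e.g. MSE) map to the `nonstandard`
#' character, `"X"` by default, so mutated-sequence liability scans never
#' receive a silently remapped residue.
#'
#' @param structure An `abm_structure`.
#' @param chain_id Single chain identifier present in the structure.
#' @param nonstandard Replacement character for non-standard residue names.
#' @return A single character string, one letter per residue.
#' @export
chain_sequence <- function(structure, chain_id, nonstandard = "X") {
  stopifnot(inherits(structure, "abm_structure"), length(chain_id) == 1L)
  if (!chain_id %in% chain_ids(structure))
    stop("unknown chain id '", chain_id, "'")
  rt <- residue_table(structure)
  res3 <- rt$resid[rt$chain == chain_id]
  one <- unname(AA3[res3])
  one[is.na(one)] <- nonstandard
  paste(one, collapse = "")
}

#' All chain sequences of a structure
#'
#' @param structure An `abm_structure`.
#' @param nonstandard Passed to [chain_sequence()].
#' @return Named character vector, one sequence per chain.
#' @export
structure_sequences <- function(structure, nonstandard = "X") {
  ch <- chain_ids(structure)
  setNames(vapply(ch, chain_sequence, character(1),
                  structure = structure, nonstandard = nonstandard), ch)
}
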