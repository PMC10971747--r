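# Interface detection, contact typing and epitope footprint comparison.
#
# All distance rules operate on heavy atoms (element != H): docking poses
# typically lack hydrogens, so donors/acceptors are inferred from heavy atoms.

# Cross-group Euclidean distance matrix (rows = A atoms, cols = B atoms).
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

heavy_atoms <- function(structure, chains) {
  at <- structure$atoms
  at[at$chain %in% chains & at$elesy != "H", , drop = FALSE]
}

check_groups <- function(structure, group_a, group_b) {
  ch <- chain_ids(structure)
  missing <- setdiff(c(group_a, group_b), ch)
  if (length(missing))
    stop("unknown chain id(s): ", paste(missing, collapse = ", "))
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both chain groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("chain groups overlap: ", paste(intersect(group_a, group_b),
                                         collapse = ", "))
}

# Per-residue minimum of a per-atom distance vector.
residue_min <- function(atoms, dmin) {
  key <- res_key(atoms$chain, atoms$resno, atoms$insert)
  agg <- tapply(dmin, factor(key, levels = unique(key)), min)
  first <- !duplicated(key)
  data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
             insert = atoms$insert[first], resid = atoms$resid[first],
             min_dist = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Find interface residues between two chain groups
#'
#' A residue of group A belongs to the interface iff its minimum heavy-atom
#' distance to any heavy atom of group B is at most `cutoff` (and
#' symmetrically for group B). The default 4.5 Å is a conventional
#' heavy-atom interface definition; the stricter 3.0 Å antigen-proximity
#' rule used in mutation triage is configured separately in
#' [threshold_config()].
#'
#' @param structure An `abm_structure`.
#' @param group_a,group_b Disjoint, non-empty character vectors of chain ids
#'   (e.g. antigen vs antibody heavy+light chains).
#' @param cutoff Heavy-atom distance cutoff in ångströms (> 0).
#' @return An `interface_map`: list with data.frames `group_a` and `group_b`
#'   (columns `chain`, `resno`, `insert`, `resid`, `min_dist`, one row per
#'   interface residue), the chain groups, and `cutoff`.
#' @export
find_interface_residues <- function(structure, group_a, group_b, cutoff = 4.5) {
  stopifnot(inherits(structure, "abm_structure"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number")
  check_groups(structure, group_a, group_b)
  ha <- heavy_atoms(structure, group_a)
  hb <- heavy_atoms(structure, group_b)
  if (nrow(ha) == 0L || nrow(hb) == 0L) {
    empty <- data.frame(chain = character(), resno = integer(),
                        insert = character(), resid = character(),
                        min_dist = numeric(), stringsAsFactors = FALSE)
    return(structure(list(group_a = empty, group_b = empty,
                          group_a_chains = group_a, group_b_chains = group_b,
                          cutoff = cutoff), class = "interface_map"))
  }
  d <- cross_dist(as.matrix(ha[, c("x", "y", "z")]),
                  as.matrix(hb[, c("x", "y", "z")]))
  ra <- residue_min(ha, apply(d, 1, min))
  rb <- residue_min(hb, apply(d, 2, min))
  structure(list(group_a = ra[ra$min_dist <= cutoff, , drop = FALSE],
                 group_b = rb[rb$min_dist <= cutoff, , drop = FALSE],
                 group_a_chains = group_a, group_b_chains = group_b,
                 cutoff = cutoff),
            class = "interface_map")
}

#' @export
print.interface_map <- function(x, ...) {
  cat("interface_map (cutoff ", x$cutoff, " A): ",
      nrow(x$group_a), " residue(s) on {",
      paste(x$group_a_chains, collapse = ","), "}, ",
      nrow(x$group_b), " residue(s) on {",
      paste(x$group_b_chains, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# Sidechains whose carbons count as apolar for hydrophobic-contact typing,
# plus CB of every residue type (stated explicitly so tests are exact).
APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

is_apolar_carbon <- function(at) {
  at$elesy == "C" &
    (at$elety == "CB" |
       (at$resid %in% APOLAR_RESIDUES & !(at$elety %in% BACKBONE_ATOMS)))
}

#' Classify cross-group atomic contacts
#'
#' LigPlot-style typing of antigen-antibody contacts, used to describe how a
#' mutation shifts an interaction (e.g. from hydrogen bonding to hydrophobic
#' packing). For every cross-group heavy-atom pair within
#' `hydrophobic_cutoff`:
#' * `hydrogen_bond` — both atoms are donor/acceptor heavy atoms (N, O, S)
#'   within `hbond_cutoff` (default 3.35 Å);
#' * `hydrophobic` — both atoms are apolar carbons (sidechain carbons of
#'   A,V,L,I,P,F,M,W plus CB of any residue) within `hydrophobic_cutoff`
#'   (default 3.90 Å);
#' * `other` — any remaining pair within `hydrophobic_cutoff`.
#'
#' Each atom pair is reported once.
#'
#' @inheritParams find_interface_residues
#' @param hbond_cutoff Hydrogen-bond heavy-atom cutoff, Å.
#' @param hydrophobic_cutoff Non-bonded contact cutoff, Å.
#' @return A data.frame with one row per contact: `chain_a`, `resno_a`,
#'   `insert_a`, `resid_a`, `atom_a`, the same `_b` columns, `distance`, and
#'   `type`.
#' @export
classify_contacts <- function(structure, group_a, group_b,
                              hbond_cutoff = 3.35, hydrophobic_cutoff = 3.90) {
  stopifnot(inherits(structure, "abm_structure"))
  check_groups(structure, group_a, group_b)
  ha <- heavy_atoms(structure, group_a)
  hb <- heavy_atoms(structure, group_b)
  out <- data.frame(chain_a = character(), resno_a = integer(),
                    insert_a = character(), resid_a = character(),
                    atom_a = character(), chain_b = character(),
                    resno_b = integer(), insert_b = character(),
                    resid_b = character(), atom_b = character(),
                    distance = numeric(), type = character(),
                    stringsAsFactors = FALSE)
  if (nrow(ha) == 0L || nrow(hb) == 0L) return(out)
  d <- cross_dist(as.matrix(ha[, c("x", "y", "z")]),
                  as.matrix(hb[, c("x", "y", "z")]))
  idx <- which(d <= hydrophobic_cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  i <- idx[, 1]; j <- idx[, 2]
  dist <- d[idx]
  polar <- c("N", "O", "S")
  hb_pair <- ha$elesy[i] %in% polar & hb$elesy[j] %in% polar &
    dist <= hbond_cutoff
  phob_pair <- is_apolar_carbon(ha[i, ]) & is_apolar_carbon(hb[j, ])
  type <- ifelse(hb_pair, "hydrogen_bond",
                 ifelse(phob_pair, "hydrophobic", "other"))
  out <- data.frame(chain_a = ha$chain[i], resno_a = ha$resno[i],
                    insert_a = ha$insert[i], resid_a = ha$resid[i],
                    atom_a = ha$elety[i], chain_b = hb$chain[j],
                    resno_b = hb$resno[j], insert_b = hb$insert[j],
                    resid_b = hb$resid[j], atom_b = hb$elety[j],
                    distance = dist, type = type, stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$atom_a,
                   out$chain_b, out$resno_b, out$atom_b), ]
  rownames(out) <- NULL
  out
}

#' Write a contact table to TSV
#'
#' @param contacts Data.frame from [classify_contacts()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_contacts_tsv <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Antigen-side footprint of an interface map: the residues of whichever
# group covers the antigen chains.
antigen_footprint <- function(map, antigen_chains) {
  in_a <- all(antigen_chains %in% map$group_a_chains)
  in_b <- all(antigen_chains %in% map$group_b_chains)
  if (!in_a && !in_b)
    stop("interface map was not computed against antigen chain(s) ",
         paste(antigen_chains, collapse = ","))
  side <- if (in_a) map$group_a else map$group_b
  side[side$chain %in% antigen_chains, , drop = FALSE]
}

#' Compare the epitope footprints of two binders on a common antigen
#'
#' Set algebra over antigen-side interface residues: used to ask whether two
#' antibodies (or an antibody and a receptor) compete for the same epitope.
#' The Jaccard index is |shared| / |union|, defined as 0 when both
#' footprints are empty.
#'
#' @param a,b `interface_map` objects computed against the same antigen
#'   chains (each binder vs the antigen).
#' @param antigen_chains Character vector of antigen chain ids.
#' @return An `epitope_overlap`: list with data.frames `shared`, `only_a`,
#'   `only_b` (columns `chain`, `resno`, `insert`) and the numeric `jaccard`.
#' @export
epitope_overlap <- function(a, b, antigen_chains) {
  stopifnot(inherits(a, "interface_map"), inherits(b, "interface_map"))
  fa <- antigen_footprint(a, antigen_chains)
  fb <- antigen_footprint(b, antigen_chains)
  ka <- res_key(fa$chain, fa$resno, fa$insert)
  kb <- res_key(fb$chain, fb$resno, fb$insert)
  pick <- function(f, keys) {
    k <- res_key(f$chain, f$resno, f$insert)
    out <- f[match(keys, k), c("chain", "resno", "insert"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  shared_k <- intersect(ka, kb)
  union_n <- length(union(ka, kb))
  structure(list(
    shared = pick(fa, shared_k),
    only_a = pick(fa, setdiff(ka, kb)),
    only_b = pick(fb, setdiff(kb, ka)),
    jaccard = if (union_n == 0L) 0 else length(shared_k) / union_n
  ), class = "epitope_overlap")
}

#' @export
print.epitope_overlap <- function(x, ...) {
  cat("epitope_overlap: ", nrow(x$shared), " shared, ",
      nrow(x$only_a), " only in A, ", nrow(x$only_b),
      " only in B; Jaccard = ", signif(x$jaccard, 3), "\n", sep = "")
  invisible(x)
}
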