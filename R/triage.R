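# Candidate enumeration, sequence-liability scanning, the five-criterion
# screen, the dual-predictor cross-check, and pairwise combination of
# beneficial mutations.

#' Parse point-mutation labels
#'
#' Accepts the compact field notation `"L49Y"` (chain, position, mutant) and
#' the explicit form `"L:E49Y"` (chain, wild type, position, mutant).
#' Composite scheme labels join chain groups with `"-"` and concatenate
#' positions within a chain, e.g. `"H62Y-L49Y95D"` = H62->Y with L49->Y and
#' L95->D; see [parse_scheme()].
#'
#' @param label Character vector of single-mutation labels.
#' @return Data.frame with columns `chain`, `position`, `wt` (`NA` when not
#'   given), `mut`.
#' @export
parse_mutation <- function(label) {
  m <- regmatches(label,
                  regexec("^([A-Za-z])(?::([A-Z]))?([0-9]+)([A-Z])$", label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("unparsable mutation label(s): ",
         paste(label[bad], collapse = ", "))
  out <- data.frame(
    chain = vapply(m, `[`, character(1), 2),
    position = as.integer(vapply(m, `[`, character(1), 4)),
    wt = vapply(m, `[`, character(1), 3),
    mut = vapply(m, `[`, character(1), 5),
    stringsAsFactors = FALSE)
  out$wt[out$wt == ""] <- NA_character_
  validate_mutations(out, allow_na_wt = TRUE)
}

validate_mutations <- function(mut, allow_na_wt = FALSE) {
  req <- c("chain", "position", "mut")
  miss <- setdiff(req, names(mut))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  if (!"wt" %in% names(mut)) mut$wt <- NA_character_
  if (any(!mut$mut %in% AA1))
    stop("mutant residues must be standard 1-letter codes")
  known_wt <- !is.na(mut$wt)
  if (!allow_na_wt && any(!known_wt))
    stop("wild-type residues are required here")
  if (any(!mut$wt[known_wt] %in% AA1))
    stop("wild-type residues must be standard 1-letter codes")
  if (any(known_wt & mut$wt == mut$mut))
    stop("mutant must differ from wild type")
  mut$position <- as.integer(mut$position)
  mut[, c("chain", "position", "wt", "mut")]
}

#' Parse a composite mutation-scheme label
#'
#' @param label Scheme label such as `"H62Y-L49Y95D"` or a single `"L49Y"`.
#' @return Data.frame of point mutations (`chain`, `position`, `wt`, `mut`).
#' @export
parse_scheme <- function(label) {
  stopifnot(length(label) == 1L)
  parts <- strsplit(label, "-", fixed = TRUE)[[1L]]
  muts <- do.call(rbind, lapply(parts, function(p) {
    m <- regexec("^([A-Za-z])((?:[0-9]+[A-Z])+)$", p)
    g <- regmatches(p, m)[[1L]]
    if (length(g) == 0L) return(parse_mutation(p))
    chain <- g[2L]
    body <- g[3L]
    mm <- regmatches(body, gregexpr("[0-9]+[A-Z]", body))[[1L]]
    data.frame(chain = chain,
               position = as.integer(sub("[A-Z]$", "", mm)),
               wt = NA_character_,
               mut = sub("^[0-9]+", "", mm),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(paste0(muts$chain, muts$position)))
    stop("scheme '", label, "' mutates one position twice")
  validate_mutations(muts, allow_na_wt = TRUE)
}

#' Canonical label of a mutation scheme
#'
#' Heavy chain first, then light chain, then any other chains
#' alphabetically; positions ascending within a chain; the chain letter is
#' written once per group (`"H62Y-L49Y95D"` style).
#'
#' @param mutations Data.frame of point mutations (`chain`, `position`,
#'   `mut`).
#' @param heavy,light Chain ids treated as heavy/light for ordering.
#' @return A single label string.
#' @export
scheme_label <- function(mutations, heavy = "H", light = "L") {
  if (nrow(mutations) == 0L) return("")
  chains <- unique(mutations$chain)
  ord <- c(intersect(c(heavy, light), chains),
           sort(setdiff(chains, c(heavy, light))))
  parts <- vapply(ord, function(ch) {
    m <- mutations[mutations$chain == ch, , drop = FALSE]
    m <- m[order(m$position), , drop = FALSE]
    paste0(ch, paste0(m$position, m$mut, collapse = ""))
  }, character(1))
  paste(parts, collapse = "-")
}

#' Enumerate all single-residue substitutions at the key residues
#'
#' Each key residue is mutated to the remaining 19 amino acids, yielding a
#' deterministic candidate list ordered by chain, position, then mutant
#' alphabetically. Duplicate key residues are deduplicated first.
#'
#' @param key_residues Data.frame with `chain`, `position` (a
#'   `key_residue_set` or any position table); an optional `wt` column is
#'   checked against the sequence and a mismatch is an error.
#' @param sequences Named character vector/list of per-chain one-letter
#'   sequences, indexed so that residue number n is the nth letter.
#' @return Data.frame of candidates: `chain`, `position`, `wt`, `mut`,
#'   `label`.
#' @export
enumerate_substitutions <- function(key_residues, sequences) {
  kr <- unique(as.data.frame(key_residues)[, intersect(
    c("chain", "position", "wt"), names(key_residues)), drop = FALSE])
  kr <- kr[order(kr$chain, kr$position), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(kr)), function(i) {
    ch <- kr$chain[i]; pos <- kr$position[i]
    seq <- sequences[[ch]]
    if (is.null(seq)) stop("no sequence provided for chain '", ch, "'")
    if (pos < 1L || pos > nchar(seq))
      stop("position ", ch, pos, " outside chain sequence (length ",
           nchar(seq), ")")
    wt <- substr(seq, pos, pos)
    if (!wt %in% AA1)
      stop("wild type at ", ch, pos, " is non-standard ('", wt, "')")
    if ("wt" %in% names(kr) && !is.na(kr$wt[i]) && kr$wt[i] != wt)
      stop("wild-type mismatch at ", ch, pos, ": key-residue table says ",
           kr$wt[i], ", sequence says ", wt)
    muts <- sort(setdiff(AA1, wt))
    data.frame(chain = ch, position = pos, wt = wt, mut = muts,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(chain = character(),
                                      position = integer(),
                                      wt = character(), mut = character(),
                                      stringsAsFactors = FALSE)
  out$label <- paste0(out$chain, out$position, out$mut)
  rownames(out) <- NULL
  out
}

# Liability motif dictionary. x in the N-glycosylation sequon NxT/NxS is any
# standard residue by default (literal reading); sequon_x_excludes_proline
# switches to the biochemical x != P rule. The NS dimer belongs to both the
# deamidation and cleavage classes and is reported once with both attached.
liability_motifs <- function(sequon_x_excludes_proline = FALSE) {
  x <- if (sequon_x_excludes_proline) {
    paste(setdiff(AA1, "P"), collapse = "")
  } else paste(AA1, collapse = "")
  list(
    list(motif = "NxT", classes = "glycosylation",
         regex = paste0("N[", x, "]T")),
    list(motif = "NxS", classes = "glycosylation",
         regex = paste0("N[", x, "]S")),
    list(motif = "NS", classes = "deamidation;cleavage", regex = "NS"),
    list(motif = "NG", classes = "deamidation", regex = "NG"),
    list(motif = "NH", classes = "deamidation", regex = "NH"),
    list(motif = "DS", classes = "isomerization", regex = "DS"),
    list(motif = "DG", classes = "isomerization", regex = "DG"),
    list(motif = "DD", classes = "isomerization", regex = "DD"),
    list(motif = "DQ", classes = "cleavage", regex = "DQ")
  )
}

#' Scan a sequence for developability liability motifs
#'
#' Reports every occurrence of the N-linked glycosylation sequons (NxT,
#' NxS), asparagine deamidation dimers (NS, NG, NH), aspartate
#' isomerization dimers (DS, DG, DD) and enzymatic cleavage dimers (DQ,
#' NS). Overlapping occurrences are all reported; the NS dimer is reported
#' once carrying both the deamidation and cleavage classes. Positions are
#' 1-based. `X` never matches the sequon wildcard.
#'
#' @param sequence One-letter amino-acid string (may contain `X`).
#' @param sequon_x_excludes_proline Use the biochemical sequon rule x != P
#'   instead of the literal "any residue" wildcard (default `FALSE`).
#' @return A `liability_report` data.frame: `motif`, `start` (1-based),
#'   `classes` (`";"`-joined), `match` (the matched subsequence). Zero rows
#'   for a clean or empty sequence.
#' @export
scan_liabilities <- function(sequence, sequon_x_excludes_proline = FALSE) {
  stopifnot(length(sequence) == 1L)
  rows <- list()
  if (nchar(sequence) > 0L) {
    for (m in liability_motifs(sequon_x_excludes_proline)) {
      # lookahead so overlapping occurrences are all found
      hits <- gregexpr(paste0("(?=", m$regex, ")"), sequence, perl = TRUE)[[1L]]
      if (hits[1L] != -1L) {
        w <- nchar(m$motif)  # NxT/NxS are width 3, dimers width 2
        rows[[length(rows) + 1L]] <- data.frame(
          motif = m$motif, start = as.integer(hits), classes = m$classes,
          match = substring(sequence, hits, hits + w - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(), start = integer(), classes = character(),
               match = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("liability_report", "data.frame")
  out
}

#' Apply point mutations to per-chain sequences
#'
#' @param sequences Named vector/list of one-letter chain sequences.
#' @param mutations Data.frame with `chain`, `position`, `mut` (and
#'   optionally `wt`, validated against the sequence when present).
#' @return The mutated sequences (named character vector).
#' @export
apply_mutations <- function(sequences, mutations) {
  seqs <- vapply(sequences, identity, character(1))
  mutations <- validate_mutations(as.data.frame(mutations),
                                  allow_na_wt = TRUE)
  for (i in seq_len(nrow(mutations))) {
    ch <- mutations$chain[i]; pos <- mutations$position[i]
    if (is.null(seqs[[ch]])) stop("no sequence for chain '", ch, "'")
    if (pos < 1L || pos > nchar(seqs[[ch]]))
      stop("position ", ch, pos, " outside chain sequence")
    cur <- substr(seqs[[ch]], pos, pos)
    if (!is.na(mutations$wt[i]) && cur != mutations$wt[i])
      stop("wild-type mismatch at ", ch, pos, ": sequence has ", cur,
           ", mutation says ", mutations$wt[i])
    substr(seqs[[ch]], pos, pos) <- mutations$mut[i]
  }
  seqs
}

# Liability findings present in `mutated` but not in `wildtype` (same chain
# lengths assumed: point mutations only).
new_liability_findings <- function(wt_report, mut_report) {
  key <- function(r) paste(r$motif, r$start, r$classes, sep = "|")
  mut_report[!key(mut_report) %in% key(wt_report), , drop = FALSE]
}

# Minimum heavy-atom distance from each (chain, position) to any antigen
# heavy atom.
min_antigen_distance <- function(structure, positions, antigen_chains) {
  ag <- heavy_atoms(structure, antigen_chains)
  if (nrow(ag) == 0L) stop("no antigen heavy atoms found")
  agm <- as.matrix(ag[, c("x", "y", "z")])
  vapply(seq_len(nrow(positions)), function(i) {
    at <- structure$atoms
    sel <- at$chain == positions$chain[i] & at$resno == positions$position[i] &
      at$elesy != "H"
    if (!any(sel))
      stop("residue ", positions$chain[i], positions$position[i],
           " not found in structure")
    d <- cross_dist(as.matrix(at[sel, c("x", "y", "z")]), agm)
    min(d)
  }, numeric(1))
}

#' Apply the five screening criteria to candidate point mutations
#'
#' Every criterion is evaluated for every candidate (no short-circuiting)
#' and recorded individually:
#' 1. the mutant is not proline (too rigid for a CDR loop);
#' 2. the mutant is neither methionine nor tryptophan (oxidation-prone);
#' 3. the mutated sequence introduces no liability motif absent from the
#'    wild-type sequence (see [scan_liabilities()]);
#' 4. the wild-type residue's minimum heavy-atom distance to the antigen is
#'    at most `antigen_distance_max` (default 3.0 Å, boundary kept);
#' 5. the sign-normalized predicted improvement (mCSM-PPI2 records) is at
#'    least `triage_min_improvement` (default 1.0); a missing prediction
#'    fails this criterion with reason `"no prediction"`.
#'
#' The verdict is `selected` iff all five criteria pass (the Geo-PPI
#' cross-check, [crosscheck_predictors()], may later demote a selection).
#'
#' @param candidates Data.frame of candidates (`chain`, `position`, `wt`,
#'   `mut`), e.g. from [enumerate_substitutions()].
#' @param sequences Named per-chain sequences of the (possibly background-
#'   mutated) antibody.
#' @param structure The antigen-antibody complex `abm_structure`.
#' @param ddg Predictor `ddg_records` used for criterion 5 (mCSM-PPI2
#'   role).
#' @param thresholds A [threshold_config()].
#' @param antigen_chains Chain ids of the antigen.
#' @param sequon_x_excludes_proline Passed to [scan_liabilities()].
#' @return A `triage_decisions` data.frame: the candidate columns plus
#'   `c1_not_proline` ... `c5_ddg_improvement` (logical pass flags),
#'   `min_antigen_dist`, `improvement`, `c5_reason`, `crosscheck`
#'   (initially `"not_run"`), `verdict` (`"selected"`/`"excluded"`).
#' @export
apply_screening <- function(candidates, sequences, structure, ddg,
                            thresholds = threshold_config(),
                            antigen_chains = "A",
                            sequon_x_excludes_proline = FALSE) {
  cand <- validate_mutations(as.data.frame(candidates))
  ddg <- normalize_ddg(ddg)
  n <- nrow(cand)

  c1 <- cand$mut != "P"
  c2 <- !(cand$mut %in% c("M", "W"))

  wt_reports <- lapply(sequences, scan_liabilities,
                       sequon_x_excludes_proline = sequon_x_excludes_proline)
  c3 <- vapply(seq_len(n), function(i) {
    ch <- cand$chain[i]
    mutated <- apply_mutations(sequences, cand[i, , drop = FALSE])
    rep_mut <- scan_liabilities(mutated[[ch]],
                                sequon_x_excludes_proline = sequon_x_excludes_proline)
    nrow(new_liability_findings(wt_reports[[ch]], rep_mut)) == 0L
  }, logical(1))

  upos <- unique(cand[, c("chain", "position")])
  udist <- min_antigen_distance(structure, upos, antigen_chains)
  dist <- udist[match(paste0(cand$chain, cand$position), pos_key(upos))]
  c4 <- dist <= thresholds$antigen_distance_max

  key <- paste0(cand$chain, cand$position, cand$mut)
  dkey <- paste0(ddg$chain, ddg$position, ddg$mut)
  imp <- ddg$improvement[match(key, dkey)]
  c5 <- !is.na(imp) & imp >= thresholds$triage_min_improvement
  c5_reason <- ifelse(is.na(imp), "no prediction",
                      ifelse(c5, "", "improvement below threshold"))

  out <- cbind(cand, data.frame(
    label = paste0(cand$chain, cand$position, cand$mut),
    c1_not_proline = c1, c2_not_met_trp = c2, c3_no_new_liability = c3,
    c4_antigen_proximal = c4, c5_ddg_improvement = c5,
    min_antigen_dist = dist, improvement = imp, c5_reason = c5_reason,
    crosscheck = "not_run",
    stringsAsFactors = FALSE))
  out$verdict <- ifelse(c1 & c2 & c3 & c4 & c5, "selected", "excluded")
  rownames(out) <- NULL
  class(out) <- c("triage_decisions", "data.frame")
  out
}

#' Cross-check selected mutations with a second predictor
#'
#' A selection is `confirmed` iff the second predictor's sign-normalized
#' improvement is strictly greater than `geo_min_improvement` (default 0, a
#' declared assumption: any predicted gain confirms), `rejected` otherwise,
#' and `not_run` when the predictor has no record for the mutation (the
#' verdict is then left unchanged but flagged).
#'
#' @param decisions A `triage_decisions` data.frame from
#'   [apply_screening()].
#' @param geo `ddg_records` of the confirming predictor (Geo-PPI role).
#' @param geo_min_improvement Strict lower bound for confirmation.
#' @return The decisions with `crosscheck` filled in and `verdict` demoted
#'   to `"excluded"` where a previously selected candidate is rejected.
#' @export
crosscheck_predictors <- function(decisions, geo, geo_min_improvement = 0) {
  stopifnot(inherits(decisions, "data.frame"))
  geo <- normalize_ddg(geo)
  key <- paste0(decisions$chain, decisions$position, decisions$mut)
  gkey <- paste0(geo$chain, geo$position, geo$mut)
  gimp <- geo$improvement[match(key, gkey)]
  decisions$geo_improvement <- gimp
  decisions$crosscheck <- ifelse(is.na(gimp), "not_run",
                                 ifelse(gimp > geo_min_improvement,
                                        "confirmed", "rejected"))
  decisions$verdict <- ifelse(
    decisions$verdict == "selected" & decisions$crosscheck == "rejected",
    "excluded", decisions$verdict)
  decisions
}

#' Pairwise combinations of beneficial mutations on a fixed background
#'
#' Forms every unordered pair of individually beneficial point mutations
#' whose members sit at different (chain, position) sites, merges each pair
#' with the background scheme, drops pairs that collide with a background
#' position (logged), and drops combined schemes whose mutated sequences
#' introduce a new liability motif. Labels follow [scheme_label()].
#'
#' @param beneficial Data.frame of beneficial single mutations (`chain`,
#'   `position`, `mut`, optional `wt`) or character labels like `"H62Y"`.
#' @param background Background scheme: a label (e.g. `"L49Y"`), a
#'   mutation data.frame, or `NULL` for none.
#' @param sequences Named wild-type chain sequences (pre-background).
#' @param sequon_x_excludes_proline Passed to [scan_liabilities()].
#' @return A named list of mutation data.frames, one per retained combined
#'   scheme, named by canonical label. Attribute `"dropped"` records labels
#'   dropped for background collisions or new liabilities.
#' @export
combine_mutations <- function(beneficial, background = NULL, sequences,
                              sequon_x_excludes_proline = FALSE) {
  if (is.character(beneficial)) beneficial <- parse_mutation(beneficial)
  beneficial <- validate_mutations(as.data.frame(beneficial),
                                   allow_na_wt = TRUE)
  if (is.character(background)) background <- parse_scheme(background)
  if (!is.null(background))
    background <- validate_mutations(as.data.frame(background),
                                     allow_na_wt = TRUE)
  bg_keys <- if (is.null(background)) character() else
    paste0(background$chain, background$position)

  wt_reports <- lapply(sequences, scan_liabilities,
                       sequon_x_excludes_proline = sequon_x_excludes_proline)
  schemes <- list()
  dropped <- character()
  n <- nrow(beneficial)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      pair <- beneficial[c(i, j), , drop = FALSE]
      if (paste0(pair$chain[1], pair$position[1]) ==
          paste0(pair$chain[2], pair$position[2])) next
      pair_label <- scheme_label(rbind(if (is.null(background)) NULL else
        background, pair))
      if (any(paste0(pair$chain, pair$position) %in% bg_keys)) {
        message("dropping ", pair_label, ": collides with background position")
        dropped <- c(dropped, pair_label)
        next
      }
      full <- rbind(if (is.null(background)) NULL else background, pair)
      mutated <- apply_mutations(sequences, full)
      new_liab <- FALSE
      for (ch in unique(full$chain)) {
        rep_mut <- scan_liabilities(mutated[[ch]],
                                    sequon_x_excludes_proline = sequon_x_excludes_proline)
        if (nrow(new_liability_findings(wt_reports[[ch]], rep_mut)) > 0L) {
          new_liab <- TRUE
          break
        }
      }
      if (new_liab) {
        message("dropping ", pair_label, ": introduces a new liability motif")
        dropped <- c(dropped, pair_label)
        next
      }
      schemes[[pair_label]] <- full
    }
  }
  attr(schemes, "dropped") <- dropped
  schemes
}
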