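# Orchestration of one affinity-maturation round: scan concordance ->
# key residues -> saturation mutagenesis -> five-criterion triage ->
# dual-predictor cross-check -> assay ingest -> IC50 ranking -> winner.
# And the pairwise combination round built on a fixed background scheme.

#' Run one single-point mutation round
#'
#' Executes the full round workflow on in-memory inputs:
#' 1. interface detection (antibody vs antigen) and, when an experimental
#'    scan is supplied, the docking-model coverage check;
#' 2. computational alanine-scan thresholding and key-residue derivation
#'    (default mode, filtered to antibody-side interface residues);
#' 3. saturation enumeration (19 substitutions per key residue) on the
#'    background-mutated sequences;
#' 4. the five screening criteria, then the second-predictor cross-check;
#' 5. 4PL fitting of the supplied assay data (or a ready-made IC50 table)
#'    and ranking against the benchmark.
#'
#' Candidate counts after each criterion are recorded (monotone
#' non-increasing); every excluded candidate keeps its per-criterion detail
#' in `decisions`. The function is deterministic given its inputs.
#'
#' @param structure Antigen-antibody complex `abm_structure`.
#' @param chain_roles Named list: `antigen`, `heavy`, `light` chain ids.
#' @param mcsm_alanine,foldx_alanine `ddg_records` of the two computational
#'   alanine scans.
#' @param experimental_scan Optional `experimental_scan` data.frame.
#' @param mcsm_mutations `ddg_records` of the saturation-mutagenesis
#'   predictions (criterion 5).
#' @param geo_mutations Optional confirming-predictor `ddg_records`.
#' @param assay Optional dose-response data.frame (`label`,
#'   `concentration`, `response`); fitted per label.
#' @param ic50_table Optional ready-made data.frame (`label`, `ic50`); used
#'   instead of `assay` when given.
#' @param benchmark_label Benchmark antibody label in the assay.
#' @param thresholds A [threshold_config()].
#' @param background Background scheme for this round (label like
#'   `"L49Y"`, mutation data.frame, or `NULL`).
#' @param key_mode Key-residue combination mode, see
#'   [derive_key_residues()].
#' @param interface_cutoff Interface cutoff, Å.
#' @param sequences Optional named chain sequences; derived from the
#'   structure when `NULL`.
#' @param round_index Round number recorded in the report.
#' @param outdir Optional directory: writes `round<k>_report.json`,
#'   `candidates_round<k>.tsv` and `ranked_ic50_round<k>.tsv`.
#' @return A `round_report`: list with `round_index`, `coverage`,
#'   `key_residues`, `counts` (candidates surviving each stage),
#'   `decisions`, `selected` (scheme labels incl. background), `ranked`,
#'   `winner`.
#' @export
run_round <- function(structure, chain_roles,
                      mcsm_alanine, foldx_alanine,
                      experimental_scan = NULL,
                      mcsm_mutations, geo_mutations = NULL,
                      assay = NULL, ic50_table = NULL,
                      benchmark_label = "AMG157",
                      thresholds = threshold_config(),
                      background = NULL,
                      key_mode = "computational_then_experimental",
                      interface_cutoff = 4.5,
                      sequences = NULL,
                      round_index = 1L, outdir = NULL) {
  stopifnot(inherits(structure, "abm_structure"),
            all(c("antigen", "heavy", "light") %in% names(chain_roles)))
  antigen <- chain_roles$antigen
  antibody <- c(chain_roles$heavy, chain_roles$light)
  if (length(intersect(antigen, antibody)))
    stop("chain roles overlap")
  if (is.null(sequences)) sequences <- structure_sequences(structure)
  if (is.character(background)) background <- parse_scheme(background)

  # stage: interface & docking-model check -------------------------------
  iface <- stage("interface", find_interface_residues(
    structure, group_a = antibody, group_b = antigen,
    cutoff = interface_cutoff))
  exp_hits <- NULL
  coverage <- NA_real_
  if (!is.null(experimental_scan)) {
    exp_hits <- experimental_hits(experimental_scan)
    coverage <- stage("docking_validation",
                      validate_docking_model(iface, exp_hits))
  }

  # stage: scan concordance ----------------------------------------------
  hits <- stage("alanine_scan", computational_alanine_hits(
    rbind(as.data.frame(mcsm_alanine), as.data.frame(foldx_alanine)),
    thresholds))
  key <- stage("key_residues", derive_key_residues(
    mcsm_hits = if (is.null(hits$mcsm)) pos_set() else hits$mcsm,
    foldx_hits = if (is.null(hits$foldx)) pos_set() else hits$foldx,
    experimental_hits = if (is.null(exp_hits)) pos_set() else exp_hits,
    mode = key_mode))
  # pipeline default: key residues must sit at the antibody-side interface
  iface_keys <- paste0(iface$group_a$chain, iface$group_a$resno)
  key <- key[pos_key(key) %in% iface_keys, , drop = FALSE]

  # stage: enumeration on the background strain --------------------------
  seqs_bg <- if (is.null(background)) sequences else
    apply_mutations(sequences, background)
  candidates <- stage("enumeration",
                      enumerate_substitutions(key, seqs_bg))
  dropped_bg <- 0L
  if (!is.null(background) && nrow(candidates)) {
    collide <- paste0(candidates$chain, candidates$position) %in%
      paste0(background$chain, background$position)
    if (any(collide)) {
      message("dropping ", sum(collide),
              " candidate(s) at background-mutated positions")
      dropped_bg <- sum(collide)
      candidates <- candidates[!collide, , drop = FALSE]
    }
  }

  # stage: five-criterion screen + cross-check ---------------------------
  decisions <- if (nrow(candidates)) {
    d <- stage("screening", apply_screening(
      candidates, seqs_bg, structure, mcsm_mutations, thresholds,
      antigen_chains = antigen))
    if (!is.null(geo_mutations))
      d <- stage("crosscheck", crosscheck_predictors(d, geo_mutations))
    d
  } else NULL

  counts <- round_counts(decisions, n_in = nrow(candidates))
  selected_singles <- if (is.null(decisions)) character() else
    decisions$label[decisions$verdict == "selected"]
  selected <- vapply(selected_singles, function(lab) {
    scheme_label(rbind(background, parse_mutation(lab)),
                 heavy = chain_roles$heavy, light = chain_roles$light)
  }, character(1), USE.NAMES = FALSE)

  # stage: assay & ranking ------------------------------------------------
  ranked <- NULL
  winner <- NULL
  if (is.null(ic50_table) && !is.null(assay))
    ic50_table <- stage("ic50_fit", fit_ic50_table(assay))
  if (!is.null(ic50_table)) {
    ranked <- stage("ranking",
                    rank_candidates(ic50_table[, c("label", "ic50")],
                                    benchmark_label))
    winner <- stage("winner", select_round_winner(ranked))
  }

  report <- structure(list(
    round_index = round_index, coverage = coverage,
    key_residues = key, counts = counts, decisions = decisions,
    selected = selected, ranked = ranked, winner = winner,
    background = background,
    dropped_background_collisions = dropped_bg),
    class = "round_report")
  if (!is.null(outdir)) write_round_report(report, outdir)
  report
}

# Wrap a stage so failures carry the stage name.
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# Survivor counts through the ordered criteria (a candidate failing several
# criteria leaves the count at the first one it fails).
round_counts <- function(decisions, n_in) {
  if (is.null(decisions) || nrow(decisions) == 0L) {
    return(c(candidates = n_in, after_c1 = 0L, after_c2 = 0L, after_c3 = 0L,
             after_c4 = 0L, after_c5 = 0L, selected = 0L))
  }
  ok <- rep(TRUE, nrow(decisions))
  out <- c(candidates = nrow(decisions))
  for (cr in c("c1_not_proline", "c2_not_met_trp", "c3_no_new_liability",
               "c4_antigen_proximal", "c5_ddg_improvement")) {
    ok <- ok & decisions[[cr]]
    out[paste0("after_", substr(cr, 1, 2))] <- sum(ok)
  }
  out["selected"] <- sum(decisions$verdict == "selected")
  out
}

#' Run the pairwise combination round
#'
#' Combines individually beneficial single mutations in pairs on the fixed
#' background (see [combine_mutations()]), re-checks liabilities, ranks the
#' combined schemes by assay IC50 and selects the winner. With fewer than
#' two distinct beneficial singles the round is degenerate: an empty scheme
#' set is reported, with a note.
#'
#' @param beneficial_singles Character labels (e.g. `c("H62Y", "L95D")`) or
#'   a mutation data.frame of the beneficial single mutations.
#' @param background Background scheme label or mutation data.frame.
#' @param sequences Named wild-type chain sequences.
#' @param assay,ic50_table As in [run_round()]; labels must use the
#'   canonical combined-scheme labels.
#' @param benchmark_label Benchmark antibody label.
#' @param chain_roles Named list with `heavy` and `light` chain ids (for
#'   label canonicalization).
#' @param round_index Round number recorded in the report.
#' @param outdir Optional output directory, as in [run_round()].
#' @return A `round_report` with `schemes` (the combined mutation sets)
#'   instead of per-criterion decisions.
#' @export
run_combination_round <- function(beneficial_singles, background, sequences,
                                  assay = NULL, ic50_table = NULL,
                                  benchmark_label = "AMG157",
                                  chain_roles = list(heavy = "H", light = "L"),
                                  round_index = 3L, outdir = NULL) {
  schemes <- stage("combination", combine_mutations(
    beneficial_singles, background, sequences))
  note <- if (length(schemes) == 0L)
    "degenerate round: fewer than two combinable beneficial singles" else ""

  ranked <- NULL
  winner <- NULL
  if (length(schemes)) {
    if (is.null(ic50_table) && !is.null(assay))
      ic50_table <- stage("ic50_fit", fit_ic50_table(assay))
    if (!is.null(ic50_table)) {
      keep <- ic50_table$label %in% c(names(schemes), benchmark_label)
      missing <- setdiff(names(schemes), ic50_table$label)
      if (length(missing))
        message("no assay data for scheme(s): ",
                paste(missing, collapse = ", "))
      ranked <- stage("ranking",
                      rank_candidates(ic50_table[keep, c("label", "ic50")],
                                      benchmark_label))
      winner <- stage("winner", select_round_winner(ranked))
    }
  }
  report <- structure(list(
    round_index = round_index, schemes = schemes,
    selected = names(schemes), ranked = ranked, winner = winner,
    dropped = attr(schemes, "dropped"), note = note,
    counts = c(schemes = length(schemes)),
    background = background),
    class = "round_report")
  if (!is.null(outdir)) write_round_report(report, outdir)
  report
}

#' @export
print.round_report <- function(x, ...) {
  cat("round_report (round ", x$round_index, ")\n", sep = "")
  if (!is.null(x$coverage) && !is.na(x$coverage))
    cat("  docking-model hit coverage: ", signif(x$coverage, 3), "\n",
        sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = ", "), "\n", sep = "")
  if (length(x$selected))
    cat("  selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  if (!is.null(x$winner))
    cat("  winner: ", x$winner, " (better than benchmark: ",
        attr(x$winner, "better_than_benchmark"), ")\n", sep = "")
  if (!is.null(x$note) && nzchar(x$note)) cat("  note: ", x$note, "\n",
                                              sep = "")
  invisible(x)
}

#' Write a round report to disk
#'
#' Writes `round<k>_report.json` plus `candidates_round<k>.tsv` (the full
#' per-candidate decision table) and `ranked_ic50_round<k>.tsv`.
#'
#' @param report A `round_report`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_round_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  k <- report$round_index
  json <- list(
    round_index = k,
    coverage = if (is.null(report$coverage)) NULL else report$coverage,
    counts = as.list(report$counts),
    selected = as.list(report$selected),
    winner = if (is.null(report$winner)) NULL else as.character(report$winner),
    winner_better_than_benchmark = if (is.null(report$winner)) NULL else
      attr(report$winner, "better_than_benchmark"),
    note = if (is.null(report$note)) NULL else report$note)
  path <- file.path(outdir, sprintf("round%d_report.json", k))
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(report$decisions))
    utils::write.table(report$decisions,
                       file.path(outdir, sprintf("candidates_round%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ranked))
    utils::write.table(as.data.frame(report$ranked),
                       file.path(outdir, sprintf("ranked_ic50_round%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
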