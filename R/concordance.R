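# Concordance of computational and experimental alanine scans: thresholding
# of predictor ddG tables, combination into a key-residue set, and a
# docking-model plausibility check.

#' Threshold configuration for scan concordance and mutation triage
#'
#' Defaults follow the workflow's published operating point: an alanine-scan
#' position is significant for mCSM-PPI2 when |ddG| exceeds 1 kcal/mol and
#' for FoldX when |ddG| exceeds 5 (each predictor's native scale; strict
#' inequality). Triage keeps a candidate mutation only when its
#' sign-normalized predicted improvement is at least
#' `triage_min_improvement` (criterion 5) and its wild-type residue lies
#' within `antigen_distance_max` of the antigen surface (criterion 4,
#' boundary kept).
#'
#' @param mcsm_abs_threshold Alanine-scan |ddG| significance threshold for
#'   mCSM-PPI2 (kcal/mol).
#' @param foldx_abs_threshold Alanine-scan |ddG| significance threshold for
#'   FoldX (native units).
#' @param triage_min_improvement Minimum normalized improvement for triage
#'   criterion 5.
#' @param antigen_distance_max Maximum wild-type heavy-atom distance to the
#'   antigen, Å (criterion 4).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(mcsm_abs_threshold = 1.0,
                             foldx_abs_threshold = 5.0,
                             triage_min_improvement = 1.0,
                             antigen_distance_max = 3.0) {
  vals <- c(mcsm_abs_threshold, foldx_abs_threshold,
            triage_min_improvement, antigen_distance_max)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive and finite")
  structure(list(mcsm_abs_threshold = mcsm_abs_threshold,
                 foldx_abs_threshold = foldx_abs_threshold,
                 triage_min_improvement = triage_min_improvement,
                 antigen_distance_max = antigen_distance_max),
            class = "threshold_config")
}

DDG_CONVENTIONS <- c("positive_improves_binding", "positive_destabilizes")

#' Construct or validate a table of predictor ddG records
#'
#' A ddG record is one predictor's estimate for one point mutation. The sign
#' convention is explicit and never guessed: `positive_improves_binding`
#' means larger ddG = better binding; `positive_destabilizes` is the common
#' predictor convention where positive values weaken binding.
#'
#' @param predictor Predictor label (e.g. `"mcsm"`, `"foldx"`, `"geo"`).
#' @param chain,position,wt,mut Mutation coordinates (1-letter codes).
#' @param ddg Predicted ddG on the predictor's native scale.
#' @param convention One of `"positive_improves_binding"`,
#'   `"positive_destabilizes"` (recycled).
#' @return A `ddg_records` data.frame with those columns.
#' @export
ddg_records <- function(predictor, chain, position, wt, mut, ddg,
                        convention) {
  out <- data.frame(predictor = predictor, chain = chain,
                    position = as.integer(position), wt = wt, mut = mut,
                    ddg = as.numeric(ddg), convention = convention,
                    stringsAsFactors = FALSE)
  validate_ddg(out)
}

validate_ddg <- function(records) {
  req <- c("predictor", "chain", "position", "wt", "mut", "ddg", "convention")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("ddg records missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$wt == records$mut))
    stop("ddg records contain wild-type == mutant entries")
  if (any(!is.finite(records$ddg)))
    stop("ddg records contain non-finite ddG values")
  bad <- !(records$convention %in% DDG_CONVENTIONS)
  if (any(bad))
    stop("unknown ddG sign convention: ",
         paste(unique(records$convention[bad]), collapse = ", "))
  class(records) <- c("ddg_records", "data.frame")
  records
}

#' Read a ddG CSV (columns predictor,chain,position,wt,mut,ddg,convention)
#' @param path CSV file path.
#' @return A validated `ddg_records` data.frame.
#' @export
read_ddg_csv <- function(path) {
  validate_ddg(read.csv(path, stringsAsFactors = FALSE))
}

#' Sign-normalized improvement of ddG records
#'
#' Adds an `improvement` column on the internal scale where positive always
#' means better binding, using each record's convention flag.
#'
#' @param records A `ddg_records` data.frame.
#' @return The records with an `improvement` column.
#' @export
normalize_ddg <- function(records) {
  records <- validate_ddg(as.data.frame(records))
  records$improvement <- ifelse(
    records$convention == "positive_improves_binding",
    records$ddg, -records$ddg)
  records
}

#' Significant positions of a computational alanine scan
#'
#' A position is flagged for a predictor iff the absolute ddG of its
#' to-alanine mutation strictly exceeds that predictor's threshold
#' (absolute values: an alanine scan asks which residues matter, in either
#' direction).
#'
#' @param records `ddg_records` of to-alanine mutations (mutant `A`, or `G`
#'   where the wild type is alanine). Mixed non-alanine mutants are a
#'   validation error.
#' @param thresholds A [threshold_config()].
#' @return Named list (one element per predictor present) of data.frames
#'   with columns `chain`, `position`.
#' @export
computational_alanine_hits <- function(records, thresholds = threshold_config()) {
  records <- validate_ddg(as.data.frame(records))
  ok <- records$mut == "A" | (records$wt == "A" & records$mut == "G")
  if (any(!ok))
    stop("non-alanine mutants in alanine-scan records: ",
         paste(unique(paste0(records$wt, records$position,
                             records$mut)[!ok]), collapse = ", "))
  thr_for <- function(p) {
    switch(p,
           mcsm = thresholds$mcsm_abs_threshold,
           foldx = thresholds$foldx_abs_threshold,
           stop("no alanine-scan threshold defined for predictor '", p, "'"))
  }
  out <- lapply(split(records, records$predictor), function(r) {
    hit <- abs(r$ddg) > thr_for(r$predictor[1L])
    h <- unique(r[hit, c("chain", "position")])
    h <- h[order(h$chain, h$position), , drop = FALSE]
    rownames(h) <- NULL
    h
  })
  out
}

pos_key <- function(df) paste0(df$chain, df$position)

pos_set <- function(chain = character(), position = integer()) {
  data.frame(chain = chain, position = as.integer(position),
             stringsAsFactors = FALSE)
}

pos_union <- function(a, b) {
  u <- unique(rbind(a[, c("chain", "position")], b[, c("chain", "position")]))
  u[order(u$chain, u$position), , drop = FALSE]
}

#' Combine computational and experimental hits into a key-residue set
#'
#' Modes:
#' * `"computational_then_experimental"` (default) — the computational union
#'   (mCSM-PPI2 plus FoldX significant positions) defines the set;
#'   experimental hits are recorded as corroborating provenance where they
#'   coincide. This is the mode the round pipeline uses (further filtered to
#'   interface residues there).
#' * `"intersect"` — computational union intersected with experimental hits.
#' * `"union"` — computational union plus all experimental hits.
#'
#' An empty result is returned with a warning, never an error.
#'
#' @param mcsm_hits,foldx_hits Data.frames with `chain`, `position` (from
#'   [computational_alanine_hits()]).
#' @param experimental_hits Data.frame with `chain`, `position` of
#'   experimental alanine-scan hits (see [read_experimental_scan()]).
#' @param mode Combination mode, see Details.
#' @return A `key_residue_set` data.frame: `chain`, `position` plus logical
#'   provenance flags `computational_mcsm`, `computational_foldx`,
#'   `experimental`.
#' @export
derive_key_residues <- function(mcsm_hits, foldx_hits, experimental_hits,
                                mode = c("computational_then_experimental",
                                         "intersect", "union")) {
  mode <- match.arg(mode)
  comp <- pos_union(mcsm_hits, foldx_hits)
  exp_h <- unique(experimental_hits[, c("chain", "position")])
  keys <- switch(mode,
    computational_then_experimental = comp,
    intersect = comp[pos_key(comp) %in% pos_key(exp_h), , drop = FALSE],
    union = pos_union(comp, exp_h))
  keys <- keys[order(keys$chain, keys$position), , drop = FALSE]
  k <- pos_key(keys)
  out <- data.frame(chain = keys$chain, position = keys$position,
                    computational_mcsm = k %in% pos_key(mcsm_hits),
                    computational_foldx = k %in% pos_key(foldx_hits),
                    experimental = k %in% pos_key(exp_h),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("key-residue set is empty under mode '", mode, "'")
  class(out) <- c("key_residue_set", "data.frame")
  out
}

#' Read an experimental alanine-scan CSV
#'
#' Expected columns: `chain`, `position`, `wt`, `mutated_to`, `effect`.
#' `mutated_to` must be `A` (or `G` only where the wild type is alanine);
#' `effect` is `"hit"` or `"no_effect"`.
#'
#' @param path CSV file path.
#' @return A validated data.frame of class `experimental_scan`.
#' @export
read_experimental_scan <- function(path) {
  validate_experimental_scan(read.csv(path, stringsAsFactors = FALSE))
}

validate_experimental_scan <- function(scan) {
  req <- c("chain", "position", "wt", "mutated_to", "effect")
  miss <- setdiff(req, names(scan))
  if (length(miss))
    stop("experimental scan missing column(s): ", paste(miss, collapse = ", "))
  if (any(!scan$mutated_to %in% c("A", "G")))
    stop("experimental scan mutations must be to A (or G for wild-type A)")
  if (any(scan$mutated_to == "G" & scan$wt != "A"))
    stop("mutation to G is only valid where the wild type is alanine")
  if (any(!scan$effect %in% c("hit", "no_effect")))
    stop("effect must be 'hit' or 'no_effect'")
  scan$position <- as.integer(scan$position)
  class(scan) <- c("experimental_scan", "data.frame")
  scan
}

#' Hit positions of an experimental scan
#' @param scan An `experimental_scan` data.frame.
#' @return Data.frame with `chain`, `position` of rows with effect `"hit"`.
#' @export
experimental_hits <- function(scan) {
  scan <- validate_experimental_scan(as.data.frame(scan))
  h <- unique(scan[scan$effect == "hit", c("chain", "position")])
  h <- h[order(h$chain, h$position), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Docking-model plausibility from experimental hit coverage
#'
#' Fraction of experimental alanine-scan hit residues that lie in the
#' antibody-side interface of the docked model. High coverage supports the
#' docking pose: binding-critical residues should sit at the interface.
#'
#' @param interface An `interface_map` whose groups include the antibody
#'   chains the hits refer to.
#' @param hits Data.frame with `chain`, `position` of experimental hits
#'   (non-empty; an empty hit set leaves coverage undefined and is an
#'   error).
#' @return Coverage fraction in \[0, 1\].
#' @export
validate_docking_model <- function(interface, hits) {
  stopifnot(inherits(interface, "interface_map"))
  hits <- unique(as.data.frame(hits)[, c("chain", "position")])
  if (nrow(hits) == 0L)
    stop("coverage is undefined for an empty experimental hit set")
  iface <- rbind(interface$group_a[, c("chain", "resno")],
                 interface$group_b[, c("chain", "resno")])
  iface_keys <- paste0(iface$chain, iface$resno)
  mean(pos_key(hits) %in% iface_keys)
}
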