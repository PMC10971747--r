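# Synthetic-data generators with known ground truth: a toy docked complex
# with planted interface contacts, predictor ddG tables with planted
# beneficial mutations, experimental alanine scans with error rates, and
# 4PL dose-response curves with known IC50. Every generator is a pure
# function of its arguments: a single integer seed governs each call via a
# locally scoped RNG (withr), never global random state.

# Idealized residue: CA-CB-CG pseudo-sidechain stick. Enough geometry for
# every distance rule without real protein chemistry.
toy_residue_atoms <- function(base, direction, resname, chain, resno,
                              serial0) {
  d <- direction / sqrt(sum(direction^2))
  ca <- base
  cb <- base + 1.53 * d
  cg <- base + 3.00 * d
  nm <- c("CA", "CB", "CG")
  xyz <- rbind(ca, cb, cg)
  if (resname == "GLY") {  # glycine has no sidechain carbons
    nm <- "CA"
    xyz <- rbind(ca)
  }
  data.frame(type = "ATOM", eleno = serial0 + seq_len(nrow(xyz)) - 1L,
             elety = nm, alt = "", resid = resname, chain = chain,
             resno = as.integer(resno), insert = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
}

#' Generate a toy antigen-antibody complex with planted contacts
#'
#' Builds a deterministic `abm_structure` with antigen chain `A` and
#' antibody chains `H` and `L`. Residues are idealized CA-CB-CG sticks on a
#' 10 Å lattice with small coordinate jitter; antibody chains sit far from
#' the antigen (> 50 Å) except for the planted contact residues, which are
#' placed so that their closest heavy-atom distance to their antigen
#' partner equals the requested distance (realized within ±0.1 Å). All
#' non-planted cross-group residue pairs are therefore > 6 Å apart, giving
#' exact interface ground truth by construction.
#'
#' @param n_antigen,n_heavy,n_light Residue counts for chains A, H, L.
#' @param planted Data.frame with columns `ab_chain` (`"H"`/`"L"`),
#'   `ab_resno`, `ag_resno`, `distance` (Å, > 1.5). Antibody residues and
#'   antigen partners must each be distinct (one docking site per residue);
#'   anything else is an infeasible-geometry error.
#' @param sequences Optional named list of one-letter sequences for chains
#'   `A`, `H`, `L`; defaults to random sequences drawn from the seed.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param jitter_sd Coordinate jitter (Å) applied to non-planted residues.
#' @return An `abm_structure` with attribute `"planted"` (the realized
#'   contact table).
#' @export
make_toy_complex <- function(n_antigen = 20, n_heavy = 15, n_light = 15,
                             planted = NULL, sequences = NULL, seed = 1,
                             jitter_sd = 0.03) {
  if (is.null(planted))
    planted <- data.frame(ab_chain = character(), ab_resno = integer(),
                          ag_resno = integer(), distance = numeric(),
                          stringsAsFactors = FALSE)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    stopifnot(all(c("ab_chain", "ab_resno", "ag_resno", "distance") %in%
                    names(planted)))
    if (any(planted$distance <= 1.5))
      stop("planted contact distances must exceed 1.5 A")
    if (any(!planted$ab_chain %in% c("H", "L")))
      stop("planted antibody residues must be on chain H or L")
    n_ab <- ifelse(planted$ab_chain == "H", n_heavy, n_light)
    if (any(planted$ab_resno < 1 | planted$ab_resno > n_ab) ||
        any(planted$ag_resno < 1 | planted$ag_resno > n_antigen))
      stop("planted contact residues outside chain ranges")
    if (anyDuplicated(paste0(planted$ab_chain, planted$ab_resno)) ||
        anyDuplicated(planted$ag_resno))
      stop("infeasible geometry: planted antibody residues and antigen ",
           "partners must each be distinct")
  }

  withr::with_seed(seed, {
    if (is.null(sequences)) {
      sequences <- list(
        A = paste(sample(AA1, n_antigen, replace = TRUE), collapse = ""),
        H = paste(sample(AA1, n_heavy, replace = TRUE), collapse = ""),
        L = paste(sample(AA1, n_light, replace = TRUE), collapse = ""))
    }
    stopifnot(nchar(sequences$A) == n_antigen,
              nchar(sequences$H) == n_heavy,
              nchar(sequences$L) == n_light)

    rows <- list()
    serial <- 1L
    add_residue <- function(base, dir, chain, resno) {
      aa <- substr(sequences[[chain]], resno, resno)
      at <- toy_residue_atoms(base, dir, AA1TO3[[aa]], chain, resno, serial)
      serial <<- serial + nrow(at)
      rows[[length(rows) + 1L]] <<- at
    }
    jitter <- function() c(rnorm(1, 0, jitter_sd), 0, rnorm(1, 0, jitter_sd))

    # antigen chain A along y = 0, sidechains pointing down (-y)
    for (i in seq_len(n_antigen))
      add_residue(c(10 * (i - 1), 0, 0) + jitter(), c(0, -1, 0), "A", i)

    # antibody chains on distant shelves; planted residues reach down so
    # that their CG tip sits exactly `distance` above the partner's CA
    for (chain in c("H", "L")) {
      n <- if (chain == "H") n_heavy else n_light
      shelf_y <- if (chain == "H") 60 else 80
      for (j in seq_len(n)) {
        hit <- planted[planted$ab_chain == chain & planted$ab_resno == j, ]
        if (nrow(hit) == 1L) {
          i <- hit$ag_resno
          ag_ca <- c(10 * (i - 1), 0, 0)
          # re-read the jittered antigen CA actually placed
          ag <- rows[[i]]
          ag_ca <- c(ag$x[ag$elety == "CA"], ag$y[ag$elety == "CA"],
                     ag$z[ag$elety == "CA"])
          d <- hit$distance + runif(1, -0.05, 0.05)
          aa <- substr(sequences[[chain]], j, j)
          # closest atom is the sidechain tip (CG), or CA itself for glycine
          tip <- if (aa == "G") 0 else 3.0
          base <- ag_ca + c(0, d + tip, 0)
          add_residue(base, c(0, -1, 0), chain, j)
        } else {
          add_residue(c(10 * (j - 1), shelf_y, 0) + jitter(),
                      c(0, 1, 0), chain, j)
        }
      }
    }
    atoms <- do.call(rbind, rows)
    out <- new_structure(atoms, id = sprintf("toy_complex_seed%d", seed))
    attr(out, "planted") <- planted
    attr(out, "sequences") <- vapply(sequences[c("A", "H", "L")], identity,
                                     character(1))
    out
  })
}

#' Simulate predictor ddG tables with planted beneficial mutations
#'
#' For each key residue and each candidate mutant, every configured
#' predictor reports the planted true improvement (0 for unplanted
#' mutations) times its gain, plus Gaussian noise, expressed in its own
#' sign convention. Ground truth is therefore known exactly for triage
#' recovery tests.
#'
#' @param key_residues Data.frame with `chain`, `position`.
#' @param sequences Named chain sequences (for wild-type lookup).
#' @param planted Named numeric vector of true improvements keyed by
#'   mutation label (e.g. `c(L49Y = 1.5)`); positive = better binding.
#' @param predictors Named list configuring each predictor:
#'   `list(noise_sd =, convention =, gain =)`. Defaults give an
#'   mCSM-PPI2-like table (`positive_improves_binding`), a FoldX-like
#'   table (`positive_destabilizes`, gain 5) and a Geo-PPI-like table.
#' @param mutants `"saturation"` (all 19 substitutions per key residue) or
#'   `"alanine"` (to-alanine scan; G where the wild type is A).
#' @param seed Integer seed.
#' @return Named list of `ddg_records` data.frames, one per predictor.
#' @export
simulate_ddg_tables <- function(key_residues, sequences, planted = numeric(),
                                predictors = list(
                                  mcsm = list(noise_sd = 0,
                                              convention = "positive_improves_binding",
                                              gain = 1),
                                  foldx = list(noise_sd = 0,
                                               convention = "positive_destabilizes",
                                               gain = 5),
                                  geo = list(noise_sd = 0,
                                             convention = "positive_improves_binding",
                                             gain = 1)),
                                mutants = c("saturation", "alanine"),
                                seed = 1) {
  mutants <- match.arg(mutants)
  kr <- unique(as.data.frame(key_residues)[, c("chain", "position")])
  base <- if (mutants == "saturation") {
    enumerate_substitutions(kr, sequences)
  } else {
    rows <- lapply(seq_len(nrow(kr)), function(i) {
      wt <- substr(sequences[[kr$chain[i]]], kr$position[i], kr$position[i])
      data.frame(chain = kr$chain[i], position = kr$position[i], wt = wt,
                 mut = ifelse(wt == "A", "G", "A"), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$label <- paste0(out$chain, out$position, out$mut)
    out
  }
  true_imp <- unname(ifelse(base$label %in% names(planted),
                            planted[base$label], 0))
  withr::with_seed(seed, {
    out <- lapply(names(predictors), function(p) {
      cfg <- predictors[[p]]
      gain <- if (is.null(cfg$gain)) 1 else cfg$gain
      raw <- gain * true_imp + rnorm(nrow(base), 0, cfg$noise_sd)
      ddg <- if (cfg$convention == "positive_improves_binding") raw else -raw
      validate_ddg(data.frame(
        predictor = p, chain = base$chain, position = base$position,
        wt = base$wt, mut = base$mut, ddg = ddg,
        convention = cfg$convention, stringsAsFactors = FALSE))
    })
    names(out) <- names(predictors)
    out
  })
}

#' Simulate 4PL dose-response curves with known IC50
#'
#' @param true_ic50 Named numeric vector: true IC50 per antibody label.
#' @param doses Positive dose vector (>= 4 distinct values).
#' @param top,bottom,hill 4PL parameters of the decreasing blocking curve.
#' @param noise_sd Additive Gaussian noise on the response.
#' @param replicates Replicate measurements per dose.
#' @param seed Integer seed.
#' @return Data.frame `label`, `concentration`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(true_ic50, doses, top = 1, bottom = 0,
                                   hill = 1, noise_sd = 0.02,
                                   replicates = 1, seed = 1) {
  stopifnot(length(true_ic50) >= 1L, !is.null(names(true_ic50)),
            all(doses > 0), length(unique(doses)) >= 4L, noise_sd >= 0,
            replicates >= 1L)
  withr::with_seed(seed, {
    rows <- lapply(names(true_ic50), function(lab) {
      ic50 <- true_ic50[[lab]]
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        mu <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
        data.frame(label = lab, concentration = doses,
                   response = mu + rnorm(length(doses), 0, noise_sd),
                   replicate = r, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
}

#' Simulate an experimental alanine scan with error rates
#'
#' Every assayed position is reported; true key positions are hits unless
#' dropped at the false-negative rate, and non-key positions become hits at
#' the false-positive rate (independent Bernoulli flips).
#'
#' @param true_key Data.frame with `chain`, `position` of truly critical
#'   residues.
#' @param all_positions Data.frame with `chain`, `position` of every
#'   assayed position (must cover `true_key`).
#' @param sequences Named chain sequences for wild-type lookup.
#' @param fp_rate,fn_rate False-positive / false-negative rates in \[0,1\].
#' @param seed Integer seed.
#' @return An `experimental_scan` data.frame (`chain`, `position`, `wt`,
#'   `mutated_to`, `effect`).
#' @export
simulate_experimental_scan <- function(true_key, all_positions, sequences,
                                       fp_rate = 0, fn_rate = 0, seed = 1) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  pos <- unique(as.data.frame(all_positions)[, c("chain", "position")])
  pos <- pos[order(pos$chain, pos$position), , drop = FALSE]
  is_key <- pos_key(pos) %in% pos_key(as.data.frame(true_key))
  withr::with_seed(seed, {
    u <- runif(nrow(pos))
    hit <- ifelse(is_key, u >= fn_rate, u < fp_rate)
    wt <- vapply(seq_len(nrow(pos)), function(i) {
      substr(sequences[[pos$chain[i]]], pos$position[i], pos$position[i])
    }, character(1))
    validate_experimental_scan(data.frame(
      chain = pos$chain, position = pos$position, wt = wt,
      mutated_to = ifelse(wt == "A", "G", "A"),
      effect = ifelse(hit, "hit", "no_effect"), stringsAsFactors = FALSE))
  })
}
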