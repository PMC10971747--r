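#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system with known ground truth.
#
# The system emulates the inputs of a two-round antibody affinity-maturation
# campaign: a docked antigen-antibody complex (antigen chain A, antibody
# chains H/L) with six engineered interface contacts, computational
# alanine-scan tables from two ddG predictors (mCSM-PPI2-like and
# FoldX-like conventions), an experimental alanine scan with a small
# false-positive rate, saturation-mutagenesis ddG tables with planted
# beneficial mutations, and 4PL blocking-assay curves. Everything is
# written as plain text under results/synthetic/ for the later stages.

suppressPackageStartupMessages(library(abmature))

SEED <- 20240301L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# fixed, liability-free chain sequences (KVERI repeats)
seqs <- list(
  A = paste(rep_len(strsplit("KVERI", "")[[1]], 30), collapse = ""),
  H = paste(rep_len(strsplit("KVERI", "")[[1]], 20), collapse = ""),
  L = paste(rep_len(strsplit("KVERI", "")[[1]], 20), collapse = ""))

# six planted interface contacts = the ground-truth paratope
contacts <- data.frame(
  ab_chain = c("H", "H", "H", "L", "L", "L"),
  ab_resno = c(3, 6, 9, 5, 9, 12),
  ag_resno = c(2, 5, 8, 14, 17, 20),
  distance = c(2.7, 2.9, 2.8, 2.6, 2.9, 2.8))

cx <- make_toy_complex(n_antigen = 30, n_heavy = 20, n_light = 20,
                       planted = contacts, sequences = seqs, seed = SEED)
write_pdb(cx, file.path(out, "complex.pdb"))
message("wrote docked complex: ", n_atoms(cx), " atoms, contacts at ",
        paste0(contacts$ab_chain, contacts$ab_resno, collapse = ", "))

key <- data.frame(chain = contacts$ab_chain, position = contacts$ab_resno)
write.csv(key, file.path(out, "true_key_residues.csv"), row.names = FALSE)

# --- computational alanine scans: every true contact is significant -----
ala_labels <- vapply(seq_len(nrow(key)), function(i) {
  wt <- substr(seqs[[key$chain[i]]], key$position[i], key$position[i])
  paste0(key$chain[i], key$position[i], ifelse(wt == "A", "G", "A"))
}, character(1))
ala <- simulate_ddg_tables(
  key, seqs, planted = setNames(rep(-2, length(ala_labels)), ala_labels),
  predictors = list(
    mcsm = list(noise_sd = 0.10, convention = "positive_improves_binding",
                gain = 1),
    foldx = list(noise_sd = 0.50, convention = "positive_destabilizes",
                 gain = 5)),
  mutants = "alanine", seed = SEED + 1L)
write.csv(ala$mcsm, file.path(out, "alanine_mcsm.csv"), row.names = FALSE)
write.csv(ala$foldx, file.path(out, "alanine_foldx.csv"), row.names = FALSE)
message("wrote computational alanine scans (", nrow(ala$mcsm),
        " mutations each)")

# --- experimental alanine scan: all CDR-like positions assayed ----------
all_pos <- rbind(data.frame(chain = "H", position = 1:20),
                 data.frame(chain = "L", position = 1:20))
scan <- simulate_experimental_scan(key, all_pos, seqs,
                                   fp_rate = 0.05, fn_rate = 0,
                                   seed = SEED + 2L)
write.csv(scan, file.path(out, "experimental_scan.csv"), row.names = FALSE)
message("wrote experimental scan: ", sum(scan$effect == "hit"),
        " hits over ", nrow(scan), " positions")

# --- round 1: saturation ddG with two planted beneficial mutations ------
planted_r1 <- c(L5D = 1.6, H3Y = 1.3)
sat1 <- simulate_ddg_tables(
  key, seqs, planted = planted_r1,
  predictors = list(
    mcsm = list(noise_sd = 0.10, convention = "positive_improves_binding",
                gain = 1),
    geo = list(noise_sd = 0.10, convention = "positive_destabilizes",
               gain = 1)),
  mutants = "saturation", seed = SEED + 3L)
write.csv(sat1$mcsm, file.path(out, "saturation_round1_mcsm.csv"),
          row.names = FALSE)
write.csv(sat1$geo, file.path(out, "saturation_round1_geo.csv"),
          row.names = FALSE)
message("wrote round-1 saturation tables; planted: ",
        paste(names(planted_r1), sprintf("%+.1f", planted_r1),
              collapse = ", "))

# --- round 2 (on the expected L5D background): three planted singles ----
planted_r2 <- c(H3Y = 1.5, H6F = 1.3, L9Q = 1.4)
sat2 <- simulate_ddg_tables(
  key, seqs, planted = planted_r2,
  predictors = list(
    mcsm = list(noise_sd = 0.10, convention = "positive_improves_binding",
                gain = 1),
    geo = list(noise_sd = 0.10, convention = "positive_destabilizes",
               gain = 1)),
  mutants = "saturation", seed = SEED + 4L)
write.csv(sat2$mcsm, file.path(out, "saturation_round2_mcsm.csv"),
          row.names = FALSE)
write.csv(sat2$geo, file.path(out, "saturation_round2_geo.csv"),
          row.names = FALSE)
message("wrote round-2 saturation tables; planted: ",
        paste(names(planted_r2), sprintf("%+.1f", planted_r2),
              collapse = ", "))

# ground-truth assay model shared by all stages: log-additive improvements
# on the parent IC50 of 2.0 assay units; the benchmark sits at 0.45
# one true improvement per mutation (round-1 value wins where a mutation
# was planted in both predictor tables)
all_imp <- c(planted_r1, planted_r2)
all_imp <- all_imp[!duplicated(names(all_imp))]
truth <- list(parent_ic50 = 2.0, benchmark_ic50 = 0.45, scale = 0.6,
              improvements = as.list(all_imp))
jsonlite::write_json(truth, file.path(out, "assay_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote assay ground truth (parent IC50 ", truth$parent_ic50,
        ", benchmark ", truth$benchmark_ic50, ")")
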