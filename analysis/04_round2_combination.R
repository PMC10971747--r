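#!/usr/bin/env Rscript
# Stage 4: second mutation round on the round-1 winner, then pairwise
# combination of the beneficial second-round singles.
#
# Mirrors the campaign structure: the round-1 winning scheme becomes the
# fixed background, a fresh saturation triage is run on the background
# strain, the selected singles are assayed, and the individually
# beneficial ones are combined in pairs and assayed again.

suppressPackageStartupMessages(library(abmature))

ind <- "results/synthetic"
if (!file.exists("results/round1/winner.txt"))
  stop("run analysis/03_round1.R first")

cx <- read_pdb(file.path(ind, "complex.pdb"))
truth <- jsonlite::read_json(file.path(ind, "assay_truth.json"),
                             simplifyVector = TRUE)
background <- readLines("results/round1/winner.txt")
message("round-2 background strain: ", background)

true_ic50 <- function(labels) {
  vapply(labels, function(lab) {
    m <- parse_scheme(lab)
    keys <- paste0(m$chain, m$position, m$mut)
    imp <- sum(unlist(truth$improvements[keys]))
    truth$parent_ic50 * exp(-truth$scale * imp)
  }, numeric(1))
}
doses <- 10^seq(-2, 2, length.out = 8)

## ---- round 2: singles on the background --------------------------------
out2 <- "results/round2"
rep2 <- run_round(
  structure = cx,
  chain_roles = list(antigen = "A", heavy = "H", light = "L"),
  mcsm_alanine = read_ddg_csv(file.path(ind, "alanine_mcsm.csv")),
  foldx_alanine = read_ddg_csv(file.path(ind, "alanine_foldx.csv")),
  experimental_scan = read_experimental_scan(
    file.path(ind, "experimental_scan.csv")),
  mcsm_mutations = read_ddg_csv(file.path(ind, "saturation_round2_mcsm.csv")),
  geo_mutations = read_ddg_csv(file.path(ind, "saturation_round2_geo.csv")),
  background = background, round_index = 2L, outdir = out2)
print(rep2)

ic50s2 <- c(true_ic50(rep2$selected), AMG157 = truth$benchmark_ic50)
assay2 <- simulate_dose_response(ic50s2, doses, noise_sd = 0.02,
                                 replicates = 3, seed = 20240304L)
write.csv(assay2, file.path(out2, "assay_round2.csv"), row.names = FALSE)
ranked2 <- rank_candidates(fit_ic50_table(assay2)[, c("label", "ic50")],
                           "AMG157")
print(ranked2)
write.table(as.data.frame(ranked2), file.path(out2, "ranked_ic50.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
winner2 <- select_round_winner(ranked2)
message("best round-2 single: ", winner2)

## ---- round 3: pairwise combinations ------------------------------------
out3 <- "results/round3"
# beneficial singles = the round-2 selections, stripped of the background
bg <- parse_scheme(background)
singles <- lapply(rep2$selected, function(lab) {
  m <- parse_scheme(lab)
  m[!paste0(m$chain, m$position) %in% paste0(bg$chain, bg$position), ,
    drop = FALSE]
})
singles <- do.call(rbind, singles)
message("combining ", nrow(singles), " beneficial single(s): ",
        paste(paste0(singles$chain, singles$position, singles$mut),
              collapse = ", "))

seqs <- structure_sequences(cx)[c("H", "L")]
rep3 <- run_combination_round(
  singles, background = background, sequences = as.list(seqs),
  ic50_table = NULL, round_index = 3L)
combo_ic50 <- c(true_ic50(rep3$selected), AMG157 = truth$benchmark_ic50)
assay3 <- simulate_dose_response(combo_ic50, doses, noise_sd = 0.02,
                                 replicates = 3, seed = 20240305L)
rep3 <- run_combination_round(
  singles, background = background, sequences = as.list(seqs),
  assay = assay3, round_index = 3L, outdir = out3)
write.csv(assay3, file.path(out3, "assay_round3.csv"), row.names = FALSE)
print(rep3)
message("final winner of the combination round: ", rep3$winner,
        " (better than benchmark: ",
        attr(rep3$winner, "better_than_benchmark"), ")")
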