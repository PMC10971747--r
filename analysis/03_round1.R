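#!/usr/bin/env Rscript
# Stage 3: first round of single-point mutagenesis.
#
# Runs scan concordance -> key residues -> saturation triage ->
# dual-predictor cross-check on the simulated inputs, then "expresses" the
# selected candidates by simulating their blocking assays from the ground
# truth and ranking them against the benchmark.

suppressPackageStartupMessages(library(abmature))

ind <- "results/synthetic"
out <- "results/round1"
if (!file.exists(file.path(ind, "complex.pdb")))
  stop("run analysis/01_simulate_inputs.R first")

cx <- read_pdb(file.path(ind, "complex.pdb"))
truth <- jsonlite::read_json(file.path(ind, "assay_truth.json"),
                             simplifyVector = TRUE)

rep1 <- run_round(
  structure = cx,
  chain_roles = list(antigen = "A", heavy = "H", light = "L"),
  mcsm_alanine = read_ddg_csv(file.path(ind, "alanine_mcsm.csv")),
  foldx_alanine = read_ddg_csv(file.path(ind, "alanine_foldx.csv")),
  experimental_scan = read_experimental_scan(
    file.path(ind, "experimental_scan.csv")),
  mcsm_mutations = read_ddg_csv(file.path(ind, "saturation_round1_mcsm.csv")),
  geo_mutations = read_ddg_csv(file.path(ind, "saturation_round1_geo.csv")),
  round_index = 1L, outdir = out)
print(rep1)
message("round 1 selected ", length(rep1$selected), " scheme(s): ",
        paste(rep1$selected, collapse = ", "))

# blocking assays for the selected strains (+ benchmark), 3 replicates
true_ic50 <- function(labels) {
  vapply(labels, function(lab) {
    m <- parse_scheme(lab)
    keys <- paste0(m$chain, m$position, m$mut)
    imp <- sum(unlist(truth$improvements[keys]))
    truth$parent_ic50 * exp(-truth$scale * imp)
  }, numeric(1))
}
ic50s <- c(true_ic50(rep1$selected), AMG157 = truth$benchmark_ic50)
assay <- simulate_dose_response(ic50s, doses = 10^seq(-2, 2, length.out = 8),
                                noise_sd = 0.02, replicates = 3,
                                seed = 20240303L)
write.csv(assay, file.path(out, "assay_round1.csv"), row.names = FALSE)

fits <- fit_ic50_table(assay)
ranked <- rank_candidates(fits[, c("label", "ic50")], "AMG157")
winner <- select_round_winner(ranked)
print(ranked)
message("round-1 winner: ", winner, " (better than benchmark: ",
        attr(winner, "better_than_benchmark"), ")")
write.table(as.data.frame(ranked), file.path(out, "ranked_ic50.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(as.character(winner), file.path(out, "winner.txt"))
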