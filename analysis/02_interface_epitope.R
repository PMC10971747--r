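#!/usr/bin/env Rscript
# Stage 2: interface and epitope analysis of the docked complex.
#
# Detects the antibody-antigen interface, classifies atomic contacts,
# validates the docking pose against the experimental alanine scan
# (binding-critical residues should sit at the interface), and compares
# the antibody's epitope footprint with that of a receptor-like second
# binder to ask whether the two compete for the same antigen surface.

suppressPackageStartupMessages(library(abmature))

ind <- "results/synthetic"
out <- "results"
if (!file.exists(file.path(ind, "complex.pdb")))
  stop("run analysis/01_simulate_inputs.R first")

cx <- read_pdb(file.path(ind, "complex.pdb"))
scan <- read_experimental_scan(file.path(ind, "experimental_scan.csv"))

iface <- find_interface_residues(cx, group_a = c("H", "L"), group_b = "A",
                                 cutoff = 4.5)
print(iface)
write.table(rbind(iface$group_a, iface$group_b),
            file.path(out, "interface_residues.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

contacts <- classify_contacts(cx, c("H", "L"), "A")
write_contacts_tsv(contacts, file.path(out, "contacts.tsv"))
message("contact types: ",
        paste(names(table(contacts$type)), table(contacts$type),
              sep = "=", collapse = ", "))

coverage <- validate_docking_model(iface, experimental_hits(scan))
message(sprintf(
  "docking-model check: %.0f%% of experimental hits lie at the interface",
  100 * coverage))

# receptor-like binder occupying a partly overlapping antigen patch
receptor <- make_toy_complex(
  n_antigen = 30, n_heavy = 12, n_light = 4,
  planted = data.frame(ab_chain = "H", ab_resno = 1:4,
                       ag_resno = c(2, 5, 23, 26), distance = 2.8),
  sequences = list(
    A = chain_sequence(cx, "A"),
    H = paste(rep_len(strsplit("KVERI", "")[[1]], 12), collapse = ""),
    L = "KVER"),
  seed = 20240302L)
iface_rec <- find_interface_residues(receptor, c("H", "L"), "A", 4.5)
ov <- epitope_overlap(iface, iface_rec, antigen_chains = "A")
print(ov)
message(sprintf(
  "epitope competition: Jaccard %.2f -> the antibody %s the receptor site",
  ov$jaccard,
  if (ov$jaccard > 0.5) "largely occupies" else "only partly overlaps"))

summary <- data.frame(
  metric = c("interface_residues_antibody", "interface_residues_antigen",
             "hit_coverage", "epitope_jaccard"),
  value = c(nrow(iface$group_a), nrow(iface$group_b), coverage, ov$jaccard))
write.table(summary, file.path(out, "interface_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/interface_summary.tsv")
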