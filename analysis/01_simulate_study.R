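#!/usr/bin/env Rscript
# Generate the synthetic study: one species tree with a monophyletic
# endothermic clade, per-gene codon alignments (a minority evolving
# under positive selection on the endothermic stem), and the species
# class table. Everything downstream reads from results/study/.

library(thermosel)

out <- file.path("results", "study")
dir.create(file.path(out, "genes"), recursive = TRUE, showWarnings = FALSE)

n_genes <- 12
n_selected <- 3
study <- simulate_study(n_genes = n_genes, n_selected = n_selected,
                        n_taxa = 8, n_codons = 150, omega2_sel = 4,
                        seed = 2016)

writeLines(write_newick(study$tree), file.path(out, "species_tree.nwk"))
write.table(study$classes, file.path(out, "species_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (g in names(study$genes))
  write_fasta(alignment_strings(study$genes[[g]]),
              file.path(out, "genes", paste0(g, ".fasta")))
manifest <- data.frame(gene = names(study$genes),
                       truth_selected = study$truth,
                       omega2_truth = ifelse(study$truth, 4, 1))
write.table(manifest, file.path(out, "truth_manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated %d genes (%d under selection) on an 8-taxon tree;\n", n_genes,
  n_selected),
  sprintf("endothermic clade: %s (stem length %.2f).\n",
          paste(study$endo_species, collapse = ", "),
          study$tree$edge.length[foreground_edge(study$tree)]),
  sprintf("Study written to %s/.\n", out))
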